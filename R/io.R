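#' Write a recording to CSV
#'
#' Plain-text interchange format: metadata as `# key: value` comment lines,
#' then a header row `time_s,ipsi_mv,contra_mv[,temp_c][,activity]` and one
#' row per EEG sample ('.' decimal, comma separator). Telemetry values are
#' placed on the EEG row nearest their timestamp; other rows hold NA.
#' Amplitudes are written with 6 decimals (1 nV resolution), so a round trip
#' is exact to that declared precision; use the binary container
#' ([write_eeg_rec()]) for bit-exact storage.
#'
#' @param rec an [eeg_recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(rec, path) {
  if (!inherits(rec, "eeg_recording")) stop_input("'rec' must be an eeg_recording")
  n <- length(rec$ipsi)
  t <- (seq_len(n) - 1) / rec$fs
  cols <- list(time_s = sprintf("%.6f", t),
               ipsi_mv = sprintf("%.6f", rec$ipsi),
               contra_mv = sprintf("%.6f", rec$contra))
  meta <- c(sprintf("# subject_id: %s", rec$subject_id),
            sprintf("# group: %s", rec$group),
            sprintf("# fs: %.10g", rec$fs),
            sprintf("# t0: %.10g", rec$t0),
            "# units: mV")
  for (nm in c("temperature", "activity")) {
    ts <- rec[[nm]]
    if (is.null(ts)) next
    col <- rep(NA_character_, n)
    idx <- round((telemetry_times(ts) - rec$t0) * rec$fs) + 1
    keep <- idx >= 1 & idx <= n
    col[idx[keep]] <- sprintf("%.6f", ts$values[keep])
    cols[[if (nm == "temperature") "temp_c" else "activity"]] <- col
    meta <- c(meta, sprintf("# %s_interval_s: %.10g", nm, ts$interval_s),
              sprintf("# %s_start_s: %.10g", nm, ts$start_s))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(names(cols), collapse = ","), con)
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = ",", quote = FALSE, na = "",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

parse_csv_meta <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  stats::setNames(as.list(vals), trimws(keys))
}

#' Read a recording from CSV
#'
#' @param path file written by [write_eeg_csv()] (or following the same
#'   dialect; `fs` must be declared in the metadata header).
#' @return an [eeg_recording].
#' @export
read_eeg_csv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- lines[startsWith(lines, "#")]
  meta <- parse_csv_meta(meta_lines)
  if (is.null(meta$fs)) stop_input("CSV is missing the required '# fs:' metadata line")
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) < 2L) stop_input("CSV contains no data rows")
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  need <- c("time_s", "ipsi_mv", "contra_mv")
  if (!all(need %in% header))
    stop_input("CSV must declare channels: missing column(s) ",
               paste(setdiff(need, header), collapse = ", "))
  df <- utils::read.csv(text = body, header = TRUE, na.strings = "")
  fs <- as.numeric(meta$fs)
  t0 <- as.numeric(meta$t0 %||% 0)
  grab_ts <- function(col, nm) {
    if (!col %in% names(df)) return(NULL)
    present <- which(!is.na(df[[col]]))
    if (length(present) == 0L) return(NULL)
    interval <- as.numeric(meta[[paste0(nm, "_interval_s")]] %||% NA)
    start <- as.numeric(meta[[paste0(nm, "_start_s")]] %||% (t0 + (present[1L] - 1) / fs))
    if (is.na(interval)) {
      interval <- if (length(present) > 1L) (present[2L] - present[1L]) / fs else 1
    }
    telemetry_series(df[[col]][present], interval_s = interval, start_s = start)
  }
  eeg_recording(ipsi = df$ipsi_mv, contra = df$contra_mv, fs = fs,
                subject_id = meta$subject_id %||% "S1",
                group = meta$group %||% "collagenase", t0 = t0,
                temperature = grab_ts("temp_c", "temperature"),
                activity = grab_ts("activity", "activity"))
}

REC_MAGIC <- "EEGREC01"

#' Write a recording to the native binary container
#'
#' Single file: 8-byte magic, int32 header length, UTF-8 JSON metadata
#' header, then little-endian float64 blocks (ipsi, contra, temperature,
#' activity). Round trips are bit exact.
#'
#' @param rec an [eeg_recording].
#' @param path output path (conventional extension `.eegrec`).
#' @return `path`, invisibly.
#' @export
write_eeg_rec <- function(rec, path) {
  if (!inherits(rec, "eeg_recording")) stop_input("'rec' must be an eeg_recording")
  meta <- list(subject_id = rec$subject_id, group = rec$group, fs = rec$fs,
               t0 = rec$t0, n = length(rec$ipsi), units = "mV")
  for (nm in c("temperature", "activity")) {
    ts <- rec[[nm]]
    if (!is.null(ts))
      meta[[nm]] <- list(n = length(ts$values), interval_s = ts$interval_s,
                         start_s = ts$start_s)
  }
  hdr <- charToRaw(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(REC_MAGIC), con)
  writeBin(length(hdr), con, size = 4L, endian = "little")
  writeBin(hdr, con)
  writeBin(rec$ipsi, con, size = 8L, endian = "little")
  writeBin(rec$contra, con, size = 8L, endian = "little")
  for (nm in c("temperature", "activity"))
    if (!is.null(rec[[nm]]))
      writeBin(rec[[nm]]$values, con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a recording from the native binary container
#' @param path file written by [write_eeg_rec()].
#' @return an [eeg_recording].
#' @export
read_eeg_rec <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(REC_MAGIC)))
  if (!identical(magic, REC_MAGIC)) stop_input("not an EEG container file: ", path)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  ipsi <- readBin(con, "double", meta$n, size = 8L, endian = "little")
  contra <- readBin(con, "double", meta$n, size = 8L, endian = "little")
  grab <- function(nm) {
    if (is.null(meta[[nm]])) return(NULL)
    telemetry_series(readBin(con, "double", meta[[nm]]$n, size = 8L, endian = "little"),
                     interval_s = meta[[nm]]$interval_s, start_s = meta[[nm]]$start_s)
  }
  temperature <- grab("temperature")
  activity <- grab("activity")
  eeg_recording(ipsi = ipsi, contra = contra, fs = meta$fs,
                subject_id = meta$subject_id, group = meta$group, t0 = meta$t0,
                temperature = temperature, activity = activity)
}

#' Load a recording, dispatching on format
#' @param path input file.
#' @param format `"auto"` (by extension), `"csv"`, or `"rec"` (native
#'   container).
#' @return an [eeg_recording].
#' @export
load_recording <- function(path, format = c("auto", "csv", "rec")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "rec"
  switch(format, csv = read_eeg_csv(path), rec = read_eeg_rec(path))
}

#' Write an event table as TSV
#'
#' Columns: subject_id, onset_s, offset_s, duration_s, laterality,
#' rms_ratio, power_increase_mv2, affected_bands, coherence_change,
#' significant (columns absent from `events` are filled with NA).
#'
#' @param events a data frame of detected events ([detect_ictal_events()]
#'   output, possibly augmented by characterization columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_tsv <- function(events, path) {
  cols <- c("subject_id", "onset_s", "offset_s", "duration_s", "laterality",
            "rms_ratio", "power_increase_mv2", "affected_bands",
            "coherence_change", "significant")
  df <- as.data.frame(events)
  for (cl in setdiff(cols, names(df))) df[[cl]] <- NA
  utils::write.table(format(df[, cols], digits = 10, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
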