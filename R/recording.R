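#' Two-channel telemetry EEG recording
#'
#' Container for a synchronized pair of EEG channels (ipsilateral and
#' contralateral to the injection site) sampled at a fixed rate, with
#' subject metadata and optional telemetry (body temperature, relative
#' activity) series recorded by the same probe at a coarser fixed interval.
#'
#' Time convention: seconds, 0-based samples. Sample \code{i} (1-based R
#' index) covers time \code{[(i-1)/fs, i/fs)}. \code{t0} is the recording
#' start time in seconds relative to the intracerebral injection (negative
#' for pre-injury baseline recordings).
#'
#' @param ipsi,contra numeric vectors of equal length, amplitudes in mV.
#' @param fs sampling rate in samples/second (default 500, the telemetry
#'   probe's rate; acquisition is low-pass filtered at 100 Hz upstream and
#'   that filter is treated as a property of the data, not re-applied).
#' @param subject_id character scalar.
#' @param group experimental group.
#' @param t0 recording start in seconds relative to injection.
#' @param temperature,activity optional [telemetry_series] objects.
#' @return An object of class \code{eeg_recording}.
#' @seealso [extract_epoch()], [read_eeg_csv()], [write_eeg_csv()]
#' @export
eeg_recording <- function(ipsi, contra, fs = 500, subject_id = "S1",
                          group = c("collagenase", "blood", "saline", "iron"),
                          t0 = 0, temperature = NULL, activity = NULL) {
  group <- match.arg(group)
  check_number(fs, "fs", positive = TRUE)
  check_number(t0, "t0")
  ipsi <- as.numeric(ipsi); contra <- as.numeric(contra)
  if (length(ipsi) != length(contra))
    stop_input("channels must have the same length (ipsi: ", length(ipsi),
               ", contra: ", length(contra), ")")
  if (length(ipsi) == 0L) stop_input("recording must contain samples")
  if (!all(is.finite(ipsi)) || !all(is.finite(contra)))
    stop_input("amplitudes must be finite")
  if (!is.null(temperature) && !inherits(temperature, "telemetry_series"))
    stop_input("'temperature' must be a telemetry_series")
  if (!is.null(activity) && !inherits(activity, "telemetry_series"))
    stop_input("'activity' must be a telemetry_series")
  structure(list(subject_id = as.character(subject_id), group = group,
                 fs = fs, t0 = t0, ipsi = ipsi, contra = contra,
                 temperature = temperature, activity = activity),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s (%s)\n", x$subject_id, x$group))
  cat(sprintf("  %d samples/channel @ %g Hz = %.1f s, t0 = %+.1f s from injection\n",
              length(x$ipsi), x$fs, duration_s(x), x$t0))
  cat(sprintf("  ipsi RMS %.4f mV, contra RMS %.4f mV\n",
              sqrt(mean(x$ipsi^2)), sqrt(mean(x$contra^2))))
  if (!is.null(x$temperature))
    cat(sprintf("  temperature: %d points @ %g s\n",
                length(x$temperature$values), x$temperature$interval_s))
  if (!is.null(x$activity))
    cat(sprintf("  activity: %d points @ %g s\n",
                length(x$activity$values), x$activity$interval_s))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an [eeg_recording].
#' @return duration in seconds.
#' @export
duration_s <- function(rec) length(rec$ipsi) / rec$fs

#' Fixed-interval telemetry series (temperature or activity)
#'
#' @param values numeric vector (degrees C for temperature; unitless signal
#'   strength for activity).
#' @param interval_s sampling interval in seconds.
#' @param start_s time of the first point, seconds (same reference as the
#'   recording's \code{t0}).
#' @return An object of class \code{telemetry_series}.
#' @export
telemetry_series <- function(values, interval_s, start_s = 0) {
  check_number(interval_s, "interval_s", positive = TRUE)
  check_number(start_s, "start_s")
  values <- as.numeric(values)
  if (length(values) == 0L) stop_input("telemetry series must be non-empty")
  structure(list(values = values, interval_s = interval_s, start_s = start_s),
            class = "telemetry_series")
}

#' @export
print.telemetry_series <- function(x, ...) {
  cat(sprintf("<telemetry_series> %d points @ %g s from t=%g s (mean %.3f)\n",
              length(x$values), x$interval_s, x$start_s, mean(x$values)))
  invisible(x)
}

telemetry_times <- function(ts) ts$start_s + (seq_along(ts$values) - 1) * ts$interval_s

#' Extract an epoch from a recording
#'
#' Half-open interval convention: the epoch covers samples whose start times
#' fall in \code{[start_s, end_s)}; the sample count is
#' \code{floor((end_s - start_s) * fs)}, so adjacent epochs partition the
#' recording without double counting.
#'
#' @param rec an [eeg_recording].
#' @param channel one of \code{"both"}, \code{"ipsi"}, \code{"contra"}.
#' @param start_s,end_s epoch bounds in seconds of recording time
#'   (\code{0 <= start_s < end_s <= duration}).
#' @param label epoch annotation.
#' @return An object of class \code{eeg_epoch}: a sample matrix (one column
#'   per selected channel) with sampling metadata.
#' @export
extract_epoch <- function(rec, channel = c("both", "ipsi", "contra"),
                          start_s, end_s,
                          label = c("other", "baseline_preinjury",
                                    "baseline_day3", "ictal", "interictal")) {
  if (!inherits(rec, "eeg_recording")) stop_input("'rec' must be an eeg_recording")
  channel <- match.arg(channel)
  label <- match.arg(label)
  check_number(start_s, "start_s"); check_number(end_s, "end_s")
  if (end_s <= start_s) stop_input("'end_s' must be greater than 'start_s'")
  dur <- duration_s(rec)
  if (start_s < 0 || end_s > dur + 1e-9)
    stop_input(sprintf("epoch [%g, %g) outside recording [0, %g)", start_s, end_s, dur))
  i0 <- floor(start_s * rec$fs)
  n <- floor((end_s - start_s) * rec$fs)
  if (n < 1L) stop_input("epoch contains no samples")
  idx <- (i0 + 1L):(i0 + n)
  x <- switch(channel,
              both   = cbind(ipsi = rec$ipsi[idx], contra = rec$contra[idx]),
              ipsi   = cbind(ipsi = rec$ipsi[idx]),
              contra = cbind(contra = rec$contra[idx]))
  structure(list(x = x, fs = rec$fs, channel = channel,
                 start_s = start_s, end_s = end_s, label = label,
                 subject_id = rec$subject_id),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %s [%g, %g) s, %d samples @ %g Hz, channel=%s, label=%s\n",
              x$subject_id, x$start_s, x$end_s, nrow(x$x), x$fs, x$channel, x$label))
  invisible(x)
}

# coerce epochs / vectors to a sample matrix; used by the estimators
epoch_matrix <- function(x) {
  if (inherits(x, "eeg_epoch")) return(x$x)
  if (is.matrix(x)) return(x)
  cbind(x = as.numeric(x))
}

epoch_fs <- function(x, fs = NULL) {
  if (inherits(x, "eeg_epoch")) return(x$fs)
  if (is.null(fs)) stop_input("'fs' is required when input is not an eeg_epoch")
  check_number(fs, "fs", positive = TRUE)
  fs
}

#' Plot a recording's channels
#' @param x an [eeg_recording].
#' @param start_s,end_s window to plot (defaults to whole recording).
#' @param ... passed to [graphics::plot()].
#' @export
plot.eeg_recording <- function(x, start_s = 0, end_s = duration_s(x), ...) {
  ep <- extract_epoch(x, "both", start_s, end_s)
  t <- start_s + (seq_len(nrow(ep$x)) - 1) / x$fs
  off <- 3 * max(stats::sd(ep$x[, 1]), stats::sd(ep$x[, 2]))
  graphics::plot(t, ep$x[, 1] + off, type = "l", xlab = "time (s)",
                 ylab = "mV (offset)", yaxt = "n",
                 ylim = range(ep$x[, 1] + off, ep$x[, 2] - off),
                 main = sprintf("%s (%s)", x$subject_id, x$group), ...)
  graphics::lines(t, ep$x[, 2] - off, col = "grey40")
  graphics::legend("topright", legend = c("ipsi", "contra"), bty = "n",
                   col = c("black", "grey40"), lty = 1)
  invisible(x)
}
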