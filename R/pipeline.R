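# End-to-end orchestration: generate (or load) -> detect -> characterize ->
# summarize -> compare, as a configured, logged, reproducible run.

#' Pipeline run configuration
#'
#' A single configuration drives both cohort generation and analysis so a
#' complete run is one call. All seeds are explicit; a fixed configuration
#' reproduces its output tables byte for byte.
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort, or
#'   NULL when `recordings` is given.
#' @param recordings optional character vector of recording files
#'   (CSV/container) to analyze instead of generating.
#' @param rms_window_s,gain_threshold,min_duration_s,merge_gap_s event
#'   detection parameters (see [detect_ictal_events()]).
#' @param char_min_s minimum event duration for spectral/coherence
#'   characterization (traces shorter than 25 s are not analyzed for power
#'   and coherence).
#' @param psd_window_s,psd_overlap_s Welch PSD settings.
#' @param coh_window_s,coh_overlap_s coherence settings.
#' @param n_surrogates surrogate count for the coherence null; 0 disables
#'   coherence characterization.
#' @param spike_k spike detection threshold (baseline SD units).
#' @param seed analysis-stage seed (surrogate jitter etc.).
#' @return list of class \code{run_config}.
#' @export
pipeline_config <- function(cohort = cohort_config(), recordings = NULL,
                            rms_window_s = 3, gain_threshold = 2,
                            min_duration_s = 5, merge_gap_s = 2,
                            char_min_s = 25, psd_window_s = 6,
                            psd_overlap_s = 2, coh_window_s = 3,
                            coh_overlap_s = 1, n_surrogates = 40L,
                            spike_k = 3.5, seed = 1L) {
  if (is.null(cohort) && is.null(recordings))
    stop_input("either a cohort config or recording paths are required")
  if (!is.null(recordings) && !all(file.exists(recordings)))
    stop_input("missing recording file(s): ",
               paste(recordings[!file.exists(recordings)], collapse = ", "))
  structure(as.list(environment()), class = "run_config")
}

pipeline_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[ichseizr] ", fmt), ...))
}

characterize_event <- function(rec, ev, base_start, base_end, cfg) {
  out <- list(power_increase_mv2 = NA_real_, affected_bands = NA_character_,
              coherence_change = NA_real_, significant = NA)
  if (ev$duration_s < cfg$char_min_s) return(out)
  dur <- ev$duration_s
  ev_ep <- extract_epoch(rec, "both", ev$onset_s, ev$offset_s, "ictal")
  # baseline trace of equal duration, taken from the baseline window
  b_end <- min(base_start + dur, base_end)
  bl_ep <- extract_epoch(rec, "both", base_start, b_end, "other")
  ch <- if (ev$laterality == "contralateral") "contra" else "ipsi"
  if (dur >= cfg$psd_window_s * 2) {
    pe <- welch_psd(extract_epoch(rec, ch, ev$onset_s, ev$offset_s),
                    cfg$psd_window_s, cfg$psd_overlap_s)
    pb <- welch_psd(extract_epoch(rec, ch, base_start, b_end),
                    cfg$psd_window_s, cfg$psd_overlap_s)
    pi_ <- power_increase(pe, pb)
    out$power_increase_mv2 <- pi_$total_increase_mv2
    out$affected_bands <- format_bands(pi_)
    out$bands <- pi_$bands
  }
  if (cfg$n_surrogates > 0L && dur >= cfg$coh_window_s * 3) {
    null <- surrogate_null(ev_ep, window_s = cfg$coh_window_s,
                           overlap_s = cfg$coh_overlap_s,
                           n_surrogates = cfg$n_surrogates)
    cc <- coherence_change(ev_ep, bl_ep, null,
                           band = c(0.5, 40),
                           window_s = cfg$coh_window_s,
                           overlap_s = cfg$coh_overlap_s)
    out$coherence_change <- cc$band_mean
    out$significant <- any(cc$significant)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Stages: (1) generate the synthetic cohort (or load recordings);
#' (2) per subject: baseline amplitude statistics, ictal event detection
#' with laterality, spectral/coherence characterization of events of at
#' least `char_min_s`, interictal spike detection on the post-event tail;
#' (3) per-subject summaries; (4) cohort statistics: 2x2 incidence Fisher
#' exact p, Mann-Whitney U on per-subject seizure counts and total
#' durations, lesion volumes; (5) peri-event temperature/activity deltas;
#' (6) TSV outputs and a JSON run manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory for tables (created if needed); NULL
#'   keeps results in memory only.
#' @param quiet suppress stage logging.
#' @return An object of class \code{ich_report}: `events` (all subjects),
#'   `summaries`, `summary_table`, `cohort` (incidence table, Fisher p,
#'   Mann-Whitney results, lesion volumes), `telemetry`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (!inherits(config, "run_config")) stop_input("'config' must be a pipeline_config")
  t_start <- proc.time()[["elapsed"]]
  # ---- stage 1: inputs ----
  if (!is.null(config$recordings)) {
    subjects <- lapply(config$recordings, function(p)
      list(recording = load_recording(p), truth = NULL, histology = NULL))
    names(subjects) <- vapply(subjects, function(s) s$recording$subject_id, "")
    incidence <- NULL
    pipeline_log(quiet, "loaded %d recording(s)", length(subjects))
  } else {
    cohort <- generate_cohort(config$cohort)
    subjects <- cohort$subjects
    incidence <- cohort$incidence_table
    pipeline_log(quiet, "generated cohort: %d subject(s), seed %d",
                 length(subjects), config$cohort$seed)
  }
  # ---- stage 2: per-subject detection + characterization ----
  all_events <- NULL
  summaries <- list()
  lesions <- NULL
  temp_deltas <- list()
  act_deltas <- list()
  for (id in names(subjects)) {
    s <- subjects[[id]]
    rec <- s$recording
    base_end <- min(config$cohort$baseline_s %||% 120, duration_s(rec))
    bl <- baseline_stats(rec, 0, base_end)
    ev <- detect_ictal_events(rec, bl, config$rms_window_s,
                              config$gain_threshold, config$min_duration_s,
                              config$merge_gap_s,
                              baseline_window = c(0, base_end))
    if (nrow(ev) > 0L) {
      chars <- lapply(seq_len(nrow(ev)), function(i)
        characterize_event(rec, ev[i, ], 0, base_end, config))
      ev$power_increase_mv2 <- vapply(chars, `[[`, numeric(1), "power_increase_mv2")
      ev$affected_bands <- vapply(chars, `[[`, character(1), "affected_bands")
      ev$coherence_change <- vapply(chars, `[[`, numeric(1), "coherence_change")
      ev$significant <- vapply(chars, `[[`, logical(1), "significant")
      ev$rms_ratio <- ev$rms_ratio_ipsi
    }
    # interictal spike scan. For generated cohorts, the awake segment of
    # the final event-free state cycle is scanned against baseline
    # statistics from the (awake) recording head: amplitude thresholding is
    # only calibrated within a behavioral state, since sleep and wake
    # amplitude distributions differ severalfold. For loaded recordings the
    # last minute is scanned against its own robust (median/MAD) statistics.
    dur <- duration_s(rec)
    if (!is.null(config$cohort)) {
      cyc <- config$cohort$dwell_awake_s + config$cohort$dwell_sws_s
      scan <- c(dur - cyc + 5, dur - config$cohort$dwell_sws_s - 5)
      spk_bl <- amplitude_ci(extract_epoch(rec, "ipsi", 0,
                                           config$cohort$dwell_awake_s - 5))
      tail_ep <- extract_epoch(rec, "ipsi", scan[1L], scan[2L], "interictal")
    } else {
      tail_ep <- extract_epoch(rec, "ipsi", max(0, dur - 60), dur, "interictal")
      spk_bl <- amplitude_ci(tail_ep, robust = TRUE)
    }
    spk <- detect_spikes(tail_ep, spk_bl, k = config$spike_k)
    all_events <- rbind(all_events, as.data.frame(ev))
    summaries[[id]] <- summarize_subject(ev, spikes = spk, subject_id = id,
                                         group = rec$group)
    pipeline_log(quiet, "%s (%s): %d event(s), %d spike(s)", id, rec$group,
                 nrow(ev), spk$n)
    if (!is.null(s$histology)) {
      lv <- lesion_volume(s$histology$ipsi, s$histology$contra)
      lesions <- rbind(lesions, data.frame(subject_id = id, group = rec$group,
                                           lesion_mm3 = lv$lesion_mm3))
    }
    ev_abs <- rec$t0 + ev$onset_s
    if (!is.null(rec$temperature) && length(ev_abs) > 0L)
      temp_deltas[[id]] <- peri_event_delta(rec$temperature, ev_abs)
    if (!is.null(rec$activity) && length(ev_abs) > 0L)
      act_deltas[[id]] <- peri_event_delta(rec$activity, ev_abs,
                                           bin_s = 3600, n_bins = 1L)
  }
  # ---- stage 3/4: summaries + cohort statistics ----
  tab <- summary_table(summaries)
  groups <- vapply(summaries, `[[`, "", "group")
  counts <- vapply(summaries, `[[`, numeric(1), "incidence")
  totals <- vapply(summaries, `[[`, numeric(1), "total_duration_s")
  cohort_stats <- list()
  if (all(c("collagenase", "blood") %in% groups)) {
    cg <- groups == "collagenase"; bg <- groups == "blood"
    inc_tab <- matrix(c(sum(counts[cg] > 0), sum(counts[cg] == 0),
                        sum(counts[bg] > 0), sum(counts[bg] == 0)),
                      2L, 2L, byrow = TRUE,
                      dimnames = list(c("collagenase", "blood"),
                                      c("seizure", "no_seizure")))
    cohort_stats$incidence_table <- inc_tab
    cohort_stats$fisher_p <- fisher_exact_2x2(inc_tab)
    cohort_stats$mw_counts <- mann_whitney(counts[cg], counts[bg])
    cohort_stats$mw_duration <- mann_whitney(totals[cg], totals[bg])
    pipeline_log(quiet, "cohort: Fisher p = %.4f; U(counts) = %g (p = %.4f)",
                 cohort_stats$fisher_p, cohort_stats$mw_counts$statistic,
                 cohort_stats$mw_counts$p.value)
  }
  cohort_stats$lesions <- lesions
  if (!is.null(lesions))
    cohort_stats$lesion_means <- tapply(lesions$lesion_mm3, lesions$group, mean)
  manifest <- list(
    package = "ichseizr",
    version = as.character(utils::packageVersion("ichseizr")),
    parameters = config[setdiff(names(config), c("cohort", "recordings"))],
    cohort = if (!is.null(config$cohort)) unclass(config$cohort),
    n_subjects = length(subjects),
    n_events = if (is.null(all_events)) 0L else nrow(all_events))
  report <- structure(list(events = all_events, summaries = summaries,
                           summary_table = tab, cohort = cohort_stats,
                           telemetry = list(temperature = temp_deltas,
                                            activity = act_deltas),
                           manifest = manifest,
                           elapsed_s = proc.time()[["elapsed"]] - t_start),
                      class = "ich_report")
  # ---- stage 6: outputs ----
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(all_events))
      write_event_tsv(all_events, file.path(out_dir, "events.tsv"))
    utils::write.table(tab, file.path(out_dir, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(lesions))
      utils::write.table(lesions, file.path(out_dir, "lesions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cohort_stats$fisher_p)) {
      ct <- data.frame(
        statistic = c("fisher_p_incidence", "mw_U_counts", "mw_p_counts",
                      "mw_U_duration", "mw_p_duration"),
        value = c(cohort_stats$fisher_p, cohort_stats$mw_counts$statistic,
                  cohort_stats$mw_counts$p.value,
                  cohort_stats$mw_duration$statistic,
                  cohort_stats$mw_duration$p.value))
      utils::write.table(ct, file.path(out_dir, "cohort_stats.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    pipeline_log(quiet, "wrote tables to %s", out_dir)
  }
  report
}

#' @export
print.ich_report <- function(x, ...) {
  cat(sprintf("<ich_report> %d subject(s), %d event(s) [%.1f s]\n",
              x$manifest$n_subjects, x$manifest$n_events, x$elapsed_s))
  if (!is.null(x$cohort$incidence_table)) {
    print(x$cohort$incidence_table)
    cat(sprintf("Fisher exact p (incidence): %.4f\n", x$cohort$fisher_p))
    cat(sprintf("Mann-Whitney counts: U = %g, p = %.4f; total duration: U = %g, p = %.4f\n",
                x$cohort$mw_counts$statistic, x$cohort$mw_counts$p.value,
                x$cohort$mw_duration$statistic, x$cohort$mw_duration$p.value))
  }
  if (!is.null(x$cohort$lesion_means)) {
    lm_ <- x$cohort$lesion_means
    cat("Mean lesion volume (mm^3):",
        paste(sprintf("%s %.1f", names(lm_), lm_), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.ich_report <- function(object, ...) {
  print(object)
  cat("\nPer-subject summary:\n")
  print(object$summary_table, row.names = FALSE)
  invisible(object)
}
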