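# Synthetic cohort: per-subject recordings with injected events, telemetry
# series, and histology (serial section area) fixtures, with full ground
# truth. Default configuration encodes the emulated study conditions:
# 9 collagenase subjects of which 6 seize (per-subject event counts
# 1, 2, 3, 4, 8, 14; first onsets uniform in 10-36 h post injection; event
# durations uniform in 5-90 s) and 6 blood subjects with no events.
#
# Recording length is kept at desk scale: each subject's file covers a
# window around its events (a 120-s event-free baseline head, then events
# separated by inter-event gaps) rather than days of telemetry; t0 places
# that window at the subject's true post-injection latency.

#' Cohort generator configuration
#'
#' @param collagenase_n,blood_n group sizes.
#' @param seizing_n collagenase subjects with seizures (must not exceed
#'   `collagenase_n`).
#' @param event_counts events per seizing subject (length `seizing_n`).
#' @param onset_range_h first-event onset latency range, hours post
#'   injection.
#' @param duration_range_s per-event duration range (s).
#' @param gain_range ictal amplitude-gain range (sampled per event).
#' @param baseline_s event-free head of each recording (s), used as the
#'   within-subject baseline epoch (default 300 s — the 5-min epochs of
#'   non-epileptiform activity the analysis is referenced to).
#' @param gap_s gap between consecutive events (s).
#' @param lesion_mm3 named means of true lesion volume (mm^3) per group.
#' @param lesion_sd_mm3 between-subject SD of lesion volume.
#' @param spike_rates interictal spike rates (per minute) injected into the
#'   recording tails of the first `length(spike_rates)` seizing subjects;
#'   the default `c(20, 10)` mirrors the two subjects with extended
#'   interictal discharge periods (about 20 and 10 spikes/min).
#' @param coupling background cross-channel coupling fraction.
#' @param dwell_awake_s,dwell_sws_s behavioral-state dwell times passed to
#'   the background generator. Recordings are padded to a whole number of
#'   state cycles with at least one full event-free cycle at the end, whose
#'   awake segment hosts injected interictal spikes (and is the natural
#'   spike-scan window: state-matched to the awake recording head).
#' @param fs sampling rate (Hz).
#' @param seed master seed; per-subject seeds are derived from it.
#' @return list of class \code{cohort_config}.
#' @export
cohort_config <- function(collagenase_n = 9L, blood_n = 6L, seizing_n = 6L,
                          event_counts = c(1L, 2L, 3L, 4L, 8L, 14L),
                          onset_range_h = c(10, 36),
                          duration_range_s = c(5, 90),
                          gain_range = c(3, 5), baseline_s = 300,
                          gap_s = 45,
                          lesion_mm3 = c(collagenase = 32.5, blood = 40.9),
                          lesion_sd_mm3 = 8, spike_rates = c(20, 10),
                          coupling = 0.3, dwell_awake_s = 60,
                          dwell_sws_s = 40, fs = 500, seed = 1L) {
  if (seizing_n > collagenase_n)
    stop_input("'seizing_n' cannot exceed 'collagenase_n'")
  if (length(event_counts) != seizing_n)
    stop_input("'event_counts' must have one entry per seizing subject")
  if (any(event_counts < 1L)) stop_input("event counts must be >= 1")
  structure(list(collagenase_n = as.integer(collagenase_n),
                 blood_n = as.integer(blood_n),
                 seizing_n = as.integer(seizing_n),
                 event_counts = as.integer(event_counts),
                 onset_range_h = onset_range_h,
                 duration_range_s = duration_range_s,
                 gain_range = gain_range, baseline_s = baseline_s,
                 gap_s = gap_s, lesion_mm3 = lesion_mm3,
                 lesion_sd_mm3 = lesion_sd_mm3, spike_rates = spike_rates,
                 coupling = coupling, dwell_awake_s = dwell_awake_s,
                 dwell_sws_s = dwell_sws_s, fs = fs,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# histology fixture: serial coronal section areas for both hemispheres such
# that lesion_volume() recovers the injected deficit exactly
synth_histology <- function(target_lesion_mm3, n_sections = 40L,
                            interval_mm = 0.2, mean_area_mm2 = 30,
                            ventricle_mm2 = 2) {
  contra_total <- mean_area_mm2 + stats::rnorm(n_sections, 0, 1)
  contra <- section_series(total_mm2 = contra_total,
                           damage_mm2 = rep(0, n_sections),
                           ventricle_mm2 = rep(ventricle_mm2, n_sections),
                           interval_mm = interval_mm)
  # spread the deficit over sections with a smooth (parabolic) profile
  deficit_area_mean <- target_lesion_mm3 / (interval_mm * n_sections)
  prof <- 1 - (seq(-1, 1, length.out = n_sections))^2
  damage <- prof / mean(prof) * deficit_area_mean
  ipsi <- section_series(total_mm2 = contra_total,
                         damage_mm2 = damage,
                         ventricle_mm2 = rep(ventricle_mm2, n_sections),
                         interval_mm = interval_mm)
  list(ipsi = ipsi, contra = contra, true_lesion_mm3 = target_lesion_mm3)
}

synth_subject_telemetry <- function(rec_dur_s, t0, seed) {
  set.seed(seed)
  # temperature at 60-s intervals covering one hour before the recording
  start <- t0 - 3700
  n_temp <- ceiling((rec_dur_s + 7400) / 60)
  temp <- 37.2 + as.numeric(stats::filter(stats::rnorm(n_temp, 0, 0.08),
                                          rep(1 / 4, 4), sides = 1))
  temp[is.na(temp)] <- 37.2
  act <- pmax(0, stats::rnorm(n_temp, 1, 0.5))
  list(temperature = telemetry_series(temp, interval_s = 60, start_s = start),
       activity = telemetry_series(act, interval_s = 60, start_s = start))
}

#' Generate a synthetic cohort with ground truth
#'
#' @param cfg a [cohort_config()].
#' @return An object of class \code{synth_cohort}: `subjects` — a named
#'   list, one element per subject with `recording`, `truth`, `histology`;
#'   `incidence_table` — the 2x2 group-by-seizure-status contingency table;
#'   `config`.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  if (!inherits(cfg, "cohort_config")) stop_input("'cfg' must be a cohort_config")
  subjects <- list()
  sub_idx <- 0L
  make_subject <- function(group, n_events, seed, spike_rate = 0) {
    set.seed(seed)
    seizing <- n_events > 0L
    durs <- if (seizing)
      stats::runif(n_events, cfg$duration_range_s[1L], cfg$duration_range_s[2L])
    else numeric(0)
    gains <- if (seizing)
      stats::runif(n_events, cfg$gain_range[1L], cfg$gain_range[2L])
    else numeric(0)
    onset_h <- if (seizing)
      stats::runif(1L, cfg$onset_range_h[1L], cfg$onset_range_h[2L])
    else NA_real_
    supp_s <- 10
    cycle <- cfg$dwell_awake_s + cfg$dwell_sws_s
    rec_dur <- cfg$baseline_s +
      (if (seizing) sum(durs + supp_s + cfg$gap_s) else 0) + 60
    # pad so the final full state cycle is event-free (spike-scan window)
    rec_dur <- ceiling((rec_dur + 40) / cycle) * cycle
    t0 <- if (seizing) onset_h * 3600 - cfg$baseline_s - cfg$gap_s else
      12 * 3600
    bg <- generate_background(
      synth_config(duration_s = rec_dur, fs = cfg$fs,
                   coupling = cfg$coupling,
                   dwell_awake_s = cfg$dwell_awake_s,
                   dwell_sws_s = cfg$dwell_sws_s, seed = seed),
      subject_id = sprintf("%s%02d", toupper(substr(group, 1, 1)), sub_idx),
      group = group, t0 = t0)
    rec <- bg$recording; truth <- bg$truth
    if (seizing) {
      # one ipsilateral-only subject mirrors the cohort's unilateral case
      lats <- rep("bilateral", n_events)
      if (sub_idx == 1L) lats[] <- "ipsilateral"
      # gains are referenced to the baseline-epoch RMS so the injected gain
      # is the subject's tabulated RMS ratio regardless of the behavioral
      # state the event lands on
      bl <- baseline_stats(rec, 0, cfg$baseline_s)
      ref <- c(bl$ipsi$rms, bl$contra$rms)
      pos <- cfg$baseline_s + cfg$gap_s
      for (j in seq_len(n_events)) {
        out <- inject_ictal_event(rec, truth, onset_s = pos,
                                  duration_s = durs[j],
                                  amplitude_gain = gains[j],
                                  suppression_s = supp_s,
                                  laterality = lats[j], ref_rms = ref,
                                  store_component = FALSE)
        rec <- out$recording; truth <- out$truth
        pos <- pos + durs[j] + supp_s + cfg$gap_s
      }
      if (spike_rate > 0) {
        # awake segment of the final (event-free) state cycle
        out <- inject_spikes(rec, truth, rate_per_min = spike_rate,
                             window_s = c(rec_dur - cycle + 5,
                                          rec_dur - cfg$dwell_sws_s - 5),
                             seed = seed + 7L)
        rec <- out$recording; truth <- out$truth
      }
    }
    tel <- synth_subject_telemetry(rec_dur, t0, seed + 13L)
    rec$temperature <- tel$temperature
    rec$activity <- tel$activity
    lesion_target <- max(5, stats::rnorm(1L, cfg$lesion_mm3[[group]],
                                         cfg$lesion_sd_mm3))
    hist <- synth_histology(lesion_target)
    list(recording = rec, truth = truth, histology = hist)
  }
  for (i in seq_len(cfg$collagenase_n)) {
    sub_idx <- sub_idx + 1L
    n_ev <- if (i <= cfg$seizing_n) cfg$event_counts[i] else 0L
    sr <- if (i <= cfg$seizing_n && i <= length(cfg$spike_rates))
      cfg$spike_rates[i] else 0
    subjects[[sprintf("C%02d", sub_idx)]] <-
      make_subject("collagenase", n_ev, cfg$seed + 100L * sub_idx, sr)
  }
  for (i in seq_len(cfg$blood_n)) {
    sub_idx <- sub_idx + 1L
    subjects[[sprintf("B%02d", sub_idx)]] <-
      make_subject("blood", 0L, cfg$seed + 100L * sub_idx)
  }
  inc <- matrix(c(cfg$seizing_n, cfg$collagenase_n - cfg$seizing_n,
                  0L, cfg$blood_n), 2L, 2L, byrow = TRUE,
                dimnames = list(c("collagenase", "blood"),
                                c("seizure", "no_seizure")))
  structure(list(subjects = subjects, incidence_table = inc, config = cfg),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d subject(s)\n", length(x$subjects)))
  print(x$incidence_table)
  invisible(x)
}
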