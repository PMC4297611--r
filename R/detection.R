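# Ictal event delimitation, laterality classification, interictal spike
# detection, and per-subject summaries.
#
# The study delimited seizures by visual screening; here delimitation is
# automated with explicit, configurable rules: an event is a maximal run
# where the sliding RMS of either channel exceeds that channel's detection
# threshold, lasting at least `min_duration_s` (the observed seizures
# ranged ~5-90 s), with sub-`merge_gap_s` interruptions merged. The
# threshold is a multiple of the baseline RMS and — when a baseline window
# is available — at least the maximum sliding RMS observed in that window,
# so that normal high-amplitude states (slow-wave sleep) never qualify:
# abnormality is judged against the amplitude range of normal traces.
# Postictal suppression is not part of the event (events end at burst
# offset); it is reported as a descriptor.

#' Per-channel baseline amplitude statistics
#'
#' Convenience wrapper computing [amplitude_ci()] for both channels over a
#' non-epileptic baseline window (pre-injury, or the day-3 substitute
#' baseline).
#'
#' @param rec an [eeg_recording].
#' @param start_s,end_s baseline window (defaults to the whole recording).
#' @return list with elements `ipsi` and `contra` (class
#'   \code{amplitude_stats}).
#' @export
baseline_stats <- function(rec, start_s = 0, end_s = duration_s(rec)) {
  list(ipsi = amplitude_ci(extract_epoch(rec, "ipsi", start_s, end_s)),
       contra = amplitude_ci(extract_epoch(rec, "contra", start_s, end_s)))
}

# per-channel detection thresholds: gain_threshold x baseline RMS, floored
# by the baseline window's own sliding-RMS ceiling when one is given
detection_thresholds <- function(rec, baseline, rms_window_s, gain_threshold,
                                 baseline_window, ceiling_factor) {
  n <- round(rms_window_s * rec$fs)
  vapply(c("ipsi", "contra"), function(ch) {
    thr <- gain_threshold * baseline[[ch]]$rms
    if (!is.null(baseline_window)) {
      idx <- (floor(baseline_window[1L] * rec$fs) + 1L):
        floor(baseline_window[2L] * rec$fs)
      thr <- max(thr, ceiling_factor * max(moving_rms(rec[[ch]][idx], n)))
    }
    thr
  }, numeric(1))
}

channel_mask <- function(rec, channel, rms_window_s, threshold) {
  moving_rms(rec[[channel]], round(rms_window_s * rec$fs)) > threshold
}

mask_runs <- function(mask, fs, min_duration_s, merge_gap_s) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # merge sub-threshold gaps shorter than merge_gap_s between active runs
  gap <- !r$values & r$lengths < merge_gap_s * fs
  inner <- seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
  r$values[gap & inner] <- TRUE
  mask2 <- inverse.rle(r)
  r2 <- rle(mask2)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1L
  keep <- r2$values & r2$lengths >= min_duration_s * fs
  data.frame(start = starts[keep], end = ends[keep])
}

#' Detect ictal events by baseline-referenced sliding RMS
#'
#' @param rec an [eeg_recording].
#' @param baseline per-channel [baseline_stats()] computed from a
#'   non-epileptic epoch of the same subject.
#' @param rms_window_s sliding RMS window (s). The default (3 s) trades a
#'   sub-second onset smear for a stable RMS estimate on delta-dominant
#'   sleep.
#' @param gain_threshold detection threshold as a multiple of baseline RMS.
#' @param min_duration_s shortest retained event (s).
#' @param merge_gap_s sub-threshold gaps shorter than this are merged.
#' @param coverage_threshold passed to [classify_laterality()].
#' @param baseline_window optional `c(start_s, end_s)` of the baseline
#'   epoch within `rec`; when given, each channel's threshold is floored at
#'   `ceiling_factor` times the maximum sliding RMS observed there, so
#'   normal high-amplitude states do not qualify as events.
#' @param ceiling_factor multiplier on the baseline sliding-RMS ceiling
#'   (default 1.1: a finite baseline window underestimates the extreme
#'   sliding RMS of prolonged normal activity).
#' @return An object of class \code{ictal_events}: a data frame with one
#'   row per event (`subject_id`, `onset_s`, `offset_s`, `duration_s`,
#'   `onset_latency_h`, `laterality`, `rms_ratio_ipsi`, `rms_ratio_contra`,
#'   `suppression_ratio`), sorted and non-overlapping.
#' @export
detect_ictal_events <- function(rec, baseline, rms_window_s = 3,
                                gain_threshold = 2, min_duration_s = 5,
                                merge_gap_s = 2, coverage_threshold = 0.5,
                                baseline_window = NULL, ceiling_factor = 1.1) {
  if (is.null(baseline) || !all(c("ipsi", "contra") %in% names(baseline)))
    stop_input("'baseline' must provide amplitude stats for both channels (see baseline_stats)")
  fs <- rec$fs
  thr <- detection_thresholds(rec, baseline, rms_window_s, gain_threshold,
                              baseline_window, ceiling_factor)
  mi <- channel_mask(rec, "ipsi", rms_window_s, thr[["ipsi"]])
  mc <- channel_mask(rec, "contra", rms_window_s, thr[["contra"]])
  runs <- mask_runs(mi | mc, fs, min_duration_s, merge_gap_s)
  ev <- data.frame(subject_id = character(0), onset_s = numeric(0),
                   offset_s = numeric(0), duration_s = numeric(0),
                   onset_latency_h = numeric(0), laterality = character(0),
                   rms_ratio_ipsi = numeric(0), rms_ratio_contra = numeric(0),
                   suppression_ratio = numeric(0))
  for (i in seq_len(nrow(runs))) {
    onset <- (runs$start[i] - 1L) / fs
    offset <- runs$end[i] / fs
    idx <- runs$start[i]:runs$end[i]
    cov_i <- mean(mi[idx]); cov_c <- mean(mc[idx])
    lat <- if (cov_i >= coverage_threshold && cov_c >= coverage_threshold)
    "bilateral" else if (cov_i >= cov_c) "ipsilateral" else "contralateral"
    post_idx <- runs$end[i] + seq_len(min(5 * fs, length(rec$ipsi) - runs$end[i]))
    supp <- if (length(post_idx) > 0L)
      sqrt(mean(rec$ipsi[post_idx]^2)) / baseline$ipsi$rms else NA_real_
    ev <- rbind(ev, data.frame(
      subject_id = rec$subject_id, onset_s = onset, offset_s = offset,
      duration_s = offset - onset,
      onset_latency_h = (rec$t0 + onset) / 3600, laterality = lat,
      rms_ratio_ipsi = sqrt(mean(rec$ipsi[idx]^2)) / baseline$ipsi$rms,
      rms_ratio_contra = sqrt(mean(rec$contra[idx]^2)) / baseline$contra$rms,
      suppression_ratio = supp))
  }
  structure(ev, class = c("ictal_events", "data.frame"))
}

#' @export
print.ictal_events <- function(x, ...) {
  cat(sprintf("<ictal_events> %d event(s)\n", nrow(x)))
  if (nrow(x) > 0L) print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Classify the laterality of one event
#'
#' Bilateral when both channels exceed the detection criterion (sliding RMS
#' above `gain_threshold` x that channel's baseline RMS) over at least
#' `coverage_threshold` of the event; otherwise the single qualifying
#' channel.
#'
#' @param rec an [eeg_recording].
#' @param onset_s,offset_s event bounds (s).
#' @param baseline per-channel [baseline_stats()].
#' @param gain_threshold,rms_window_s detection criterion parameters.
#' @param coverage_threshold minimum fraction of the event a channel must
#'   cover (default 0.5).
#' @param baseline_window,ceiling_factor as in [detect_ictal_events()].
#' @return `"bilateral"`, `"ipsilateral"`, or `"contralateral"`.
#' @export
classify_laterality <- function(rec, onset_s, offset_s, baseline,
                                gain_threshold = 2, rms_window_s = 3,
                                coverage_threshold = 0.5,
                                baseline_window = NULL, ceiling_factor = 1.1) {
  fs <- rec$fs
  idx <- (floor(onset_s * fs) + 1L):floor(offset_s * fs)
  thr <- detection_thresholds(rec, baseline, rms_window_s, gain_threshold,
                              baseline_window, ceiling_factor)
  mi <- channel_mask(rec, "ipsi", rms_window_s, thr[["ipsi"]])[idx]
  mc <- channel_mask(rec, "contra", rms_window_s, thr[["contra"]])[idx]
  cov_i <- mean(mi); cov_c <- mean(mc)
  if (cov_i >= coverage_threshold && cov_c >= coverage_threshold) return("bilateral")
  if (cov_i < coverage_threshold && cov_c < coverage_threshold)
    stop_input("neither channel meets the detection criterion over the event")
  if (cov_i >= coverage_threshold) "ipsilateral" else "contralateral"
}

#' Detect interictal spikes by amplitude threshold
#'
#' Detections are samples whose deviation from the baseline mean strictly
#' exceeds `k` baseline standard deviations (boundary samples at exactly
#' `k` SD are excluded — deterministic tie rule). Suprathreshold samples
#' closer than `refractory_ms` are grouped into one spike, timed at the
#' largest absolute deviation in the group. The average waveform is the
#' mean of peri-spike windows aligned at that extremum.
#'
#' @param epoch a single-channel [eeg_epoch] (or vector with `fs`).
#' @param baseline an [amplitude_ci()] result from normal traces of the
#'   same channel.
#' @param k threshold in baseline SD units (default 3.5).
#' @param refractory_ms grouping window (default 100 ms).
#' @param waveform_window_ms total width of the averaged peri-spike window
#'   (default 500 ms, i.e. ±250 ms).
#' @param fs sampling rate for bare vectors.
#' @return An object of class \code{spike_train}: `times_s` (relative to
#'   the epoch start), `rate_per_min`, `average_waveform` (mV),
#'   `waveform_t_s`, `threshold_k`, `n`.
#' @export
detect_spikes <- function(epoch, baseline, k = 3.5, refractory_ms = 100,
                          waveform_window_ms = 500, fs = NULL) {
  if (k <= 0) stop_input("'k' must be > 0")
  if (!inherits(baseline, "amplitude_stats"))
    stop_input("'baseline' must be an amplitude_stats object")
  x <- epoch_matrix(epoch)
  if (ncol(x) > 1L) stop_input("detect_spikes works on one channel at a time")
  fs <- epoch_fs(epoch, fs)
  v <- x[, 1L]
  dev <- abs(v - baseline$mean)
  hits <- which(dev > k * baseline$sd)
  nref <- round(refractory_ms / 1000 * fs)
  times <- numeric(0)
  if (length(hits) > 0L) {
    grp <- cumsum(c(1L, as.integer(diff(hits) > nref)))
    times <- vapply(split(hits, grp), function(ii) ii[which.max(dev[ii])],
                    numeric(1))
    times <- unname(sort(times))
  }
  half <- round(waveform_window_ms / 2000 * fs)
  wave <- NULL
  if (length(times) > 0L) {
    ok <- times - half >= 1L & times + half <= length(v)
    if (any(ok)) {
      W <- vapply(times[ok], function(i) v[(i - half):(i + half)],
                  numeric(2L * half + 1L))
      wave <- rowMeans(W)
    }
  }
  dur_min <- length(v) / fs / 60
  structure(list(times_s = (times - 1L) / fs, rate_per_min = length(times) / dur_min,
                 average_waveform = wave,
                 waveform_t_s = if (is.null(wave)) NULL else
                   (seq(-half, half)) / fs,
                 threshold_k = k, n = length(times),
                 epoch_duration_s = length(v) / fs),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spike(s) in %.1f s (%.2f/min), threshold %.1f SD\n",
              x$n, x$epoch_duration_s, x$rate_per_min, x$threshold_k))
  invisible(x)
}

#' @export
plot.spike_train <- function(x, ...) {
  if (is.null(x$average_waveform)) {
    graphics::plot.new(); graphics::title("no spikes detected")
    return(invisible(x))
  }
  graphics::plot(x$waveform_t_s * 1000, x$average_waveform, type = "l",
                 xlab = "time from peak (ms)", ylab = "mV",
                 main = sprintf("average of %d spikes", x$n), ...)
  invisible(x)
}

#' Per-subject seizure summary
#'
#' Aggregates a subject's detected events into the tabulated per-rat
#' metrics: incidence (event count), modal laterality, total duration with
#' mean ± sample SD, onset latency of the first event (hours
#' post-injection, also formatted "H h, M min"), mean RMS ratio, and spike
#' rate when a spike train is supplied.
#'
#' @param events an `ictal_events` data frame (may be empty).
#' @param spikes optional [detect_spikes()] result.
#' @param subject_id,group metadata (defaulted from `events` when present).
#' @return An object of class \code{subject_summary}.
#' @export
summarize_subject <- function(events, spikes = NULL, subject_id = NULL,
                              group = NA_character_) {
  n <- nrow(events)
  subject_id <- subject_id %||% (if (n > 0L) events$subject_id[1L] else "S?")
  durs <- events$duration_s
  lat <- if (n == 0L) NA_character_ else {
    tb <- sort(table(events$laterality), decreasing = TRUE)
    top <- names(tb)[tb == max(tb)]
    if ("bilateral" %in% top) "bilateral" else top[1L]  # ties favor bilateral
  }
  mean_dur <- if (n > 0L) mean(durs) else 0
  sd_dur <- if (n > 1L) stats::sd(durs) else NA_real_
  onset_h <- if (n > 0L) min(events$onset_latency_h) else NA_real_
  rr <- if (n > 0L && "rms_ratio_ipsi" %in% names(events))
    events$rms_ratio_ipsi else numeric(0)
  structure(list(subject_id = subject_id, group = group, incidence = n,
                 laterality = lat, total_duration_s = sum(durs),
                 mean_duration_s = mean_dur, sd_duration_s = sd_dur,
                 duration_label = if (n > 0L)
                   format_mean_sd(sum(durs), mean_dur, sd_dur) else "0",
                 onset_latency_h = onset_h,
                 onset_label = format_latency(onset_h),
                 rms_ratio_mean = if (length(rr)) mean(rr) else NA_real_,
                 rms_ratio_sd = if (length(rr) > 1L) stats::sd(rr) else NA_real_,
                 spike_rate_per_min = if (is.null(spikes)) NA_real_ else
                   spikes$rate_per_min),
            class = "subject_summary")
}

#' @export
print.subject_summary <- function(x, ...) {
  cat(sprintf("<subject_summary> %s (%s): %d seizure(s)\n",
              x$subject_id, x$group, x$incidence))
  if (x$incidence > 0L) {
    cat(sprintf("  laterality %s, total duration %s s, onset %s\n",
                x$laterality, x$duration_label, x$onset_label))
    if (!is.na(x$rms_ratio_mean))
      cat(sprintf("  RMS ratio %.2f%s\n", x$rms_ratio_mean,
                  if (!is.na(x$rms_ratio_sd))
                    sprintf(" ± %.2f", x$rms_ratio_sd) else ""))
  }
  if (!is.na(x$spike_rate_per_min))
    cat(sprintf("  interictal spikes %.1f/min\n", x$spike_rate_per_min))
  invisible(x)
}

#' Assemble a cohort summary table (one row per subject)
#' @param summaries list of [summarize_subject()] results.
#' @return data frame in tabular (per-rat) layout.
#' @export
summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) data.frame(
    subject_id = s$subject_id, group = s$group, incidence = s$incidence,
    laterality = s$laterality %||% NA_character_,
    total_duration = s$duration_label, onset = s$onset_label %||% NA_character_,
    rms_ratio = if (is.na(s$rms_ratio_mean)) NA_character_ else
      sprintf("%.2f%s", s$rms_ratio_mean,
              if (!is.na(s$rms_ratio_sd)) sprintf(" ± %.2f", s$rms_ratio_sd) else ""),
    spike_rate_per_min = s$spike_rate_per_min,
    stringsAsFactors = FALSE)))
}
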