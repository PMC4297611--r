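# Amplitude and spectral quantification: RMS and ratios, Welch PSD with
# empirical confidence intervals, amplitude percentile intervals, and
# affected-band / power-increase calling against a baseline spectrum.

#' Root-mean-square amplitude of an epoch
#'
#' @param epoch an [eeg_epoch], numeric vector, or sample matrix (one column
#'   per channel).
#' @return RMS in mV, one value per channel (named for two-channel epochs).
#' @export
compute_rms <- function(epoch) {
  x <- epoch_matrix(epoch)
  if (nrow(x) == 0L) stop_input("epoch is empty")
  out <- sqrt(colMeans(x^2))
  if (length(out) == 1L) unname(out) else out
}

#' RMS ratio of an event epoch to a baseline epoch
#'
#' The per-event amplitude descriptor tabulated per subject: RMS of the
#' ictal trace divided by RMS of non-epileptic activity from the same
#' channel(s).
#'
#' @param event,baseline epochs with the same channel convention.
#' @return unitless ratio (per channel).
#' @export
rms_ratio <- function(event, baseline) {
  re <- compute_rms(event)
  rb <- compute_rms(baseline)
  if (length(re) != length(rb))
    stop_input("event and baseline epochs must cover the same channels")
  if (any(rb == 0)) stop_input("baseline RMS is zero; ratio undefined")
  re / rb
}

#' Per-day RMS fold change relative to a pre-injury epoch
#'
#' @param day_epochs list of epochs (e.g. days 1..3 post injury), all of the
#'   same duration as `pre_epoch` (default usage: 5-min epochs of
#'   non-epileptiform activity).
#' @param pre_epoch the day-prior (pre-injury) epoch.
#' @return numeric vector of fold changes, one per element of `day_epochs`.
#' @export
rms_fold_change <- function(day_epochs, pre_epoch) {
  if (missing(pre_epoch) || is.null(pre_epoch))
    stop_input("a pre-injury epoch is required")
  if (inherits(day_epochs, "eeg_epoch")) day_epochs <- list(day_epochs)
  vapply(day_epochs, function(e) {
    if (abs(nrow(epoch_matrix(e)) - nrow(epoch_matrix(pre_epoch))) > 1L)
      stop_input("all epochs must have the same duration")
    unname(rms_ratio(e, pre_epoch)[1L])
  }, numeric(1))
}

#' Amplitude statistics of an epoch
#'
#' RMS plus the empirical 95% interval of amplitude fluctuations (2.5th and
#' 97.5th percentiles of the sample amplitudes), together with the mean and
#' standard deviation used by threshold-based spike detection.
#'
#' @param epoch an [eeg_epoch], vector, or single-column matrix. For
#'   two-channel epochs use one channel at a time.
#' @param robust use median / scaled MAD for the centre and spread instead
#'   of mean / SD, making the statistics insensitive to sparse transients
#'   in the epoch itself (useful when thresholding an epoch against its own
#'   normal activity).
#' @return An object of class \code{amplitude_stats} with fields `rms`,
#'   `amp_ci` (mV), `mean`, `sd`, `n_samples`.
#' @export
amplitude_ci <- function(epoch, robust = FALSE) {
  x <- epoch_matrix(epoch)
  if (nrow(x) == 0L) stop_input("epoch is empty")
  if (ncol(x) > 1L)
    stop_input("amplitude_ci works on one channel at a time; extract a single channel")
  v <- x[, 1L]
  structure(list(rms = sqrt(mean(v^2)),
                 amp_ci = unname(stats::quantile(v, c(0.025, 0.975))),
                 mean = if (robust) stats::median(v) else mean(v),
                 sd = if (robust) stats::mad(v) else stats::sd(v),
                 n_samples = length(v), robust = robust),
            class = "amplitude_stats")
}

#' @export
print.amplitude_stats <- function(x, ...) {
  cat(sprintf("<amplitude_stats> n=%d, RMS %.4f mV, 95%% amplitude CI [%.4f, %.4f] mV\n",
              x$n_samples, x$rms, x$amp_ci[1], x$amp_ci[2]))
  invisible(x)
}

# Hann-windowed, per-segment demeaned segment FFTs shared by welch_psd and msc
segment_ffts <- function(x, fs, window_s, overlap_s) {
  nwin <- round(window_s * fs)
  nstep <- round((window_s - overlap_s) * fs)
  if (nstep < 1L) stop_input("'overlap_s' must be smaller than 'window_s'")
  n <- length(x)
  if (n < nwin)
    stop_input(sprintf("epoch (%g s) shorter than the analysis window (%g s)",
                       n / fs, window_s))
  K <- (n - nwin) %/% nstep + 1L
  idx <- outer(seq_len(nwin), (seq_len(K) - 1L) * nstep, "+")
  seg <- matrix(x[idx], nwin, K)
  seg <- sweep(seg, 2L, colMeans(seg))
  w <- hann_window(nwin)
  list(F = stats::mvfft(seg * w), w2 = sum(w^2), nwin = nwin, K = K)
}

onesided_bins <- function(nwin, fs) {
  nf <- nwin %/% 2L + 1L
  list(nf = nf, freq = (seq_len(nf) - 1L) * fs / nwin)
}

#' Welch power spectral density with empirical confidence intervals
#'
#' Averaged modified periodogram (Hann window, per-segment mean removal).
#' Defaults follow the study's analysis settings: 6-s windows with 2-s
#' overlap, giving 1/6-Hz frequency resolution. The per-bin 95% interval is
#' the classical chi-squared confidence interval of the Welch estimate
#' (equivalent degrees of freedom 2K for K averaged segments): an interval
#' for the underlying spectrum that tightens as segments accumulate, which
#' is what lets [power_increase()] call bands whose power differs from a
#' baseline.
#'
#' @param epoch an [eeg_epoch] (single channel), numeric vector, or
#'   single-column matrix.
#' @param window_s,overlap_s segment length and overlap in seconds.
#' @param fs sampling rate, required when `epoch` is a bare vector.
#' @return An object of class \code{psd_estimate}: `frequencies` (Hz),
#'   `power` (mV^2/Hz, one-sided), `ci_low`, `ci_high`, `window_s`,
#'   `overlap_s`, `n_segments`.
#' @export
welch_psd <- function(epoch, window_s = 6, overlap_s = 2, fs = NULL) {
  x <- epoch_matrix(epoch)
  if (ncol(x) > 1L) stop_input("welch_psd works on one channel at a time")
  fs <- epoch_fs(epoch, fs)
  sf <- segment_ffts(x[, 1L], fs, window_s, overlap_s)
  os <- onesided_bins(sf$nwin, fs)
  # one-sided density per segment: |X|^2 / (fs * sum(w^2)), doubled except at
  # DC and (for even nwin) Nyquist
  P <- Mod(sf$F[seq_len(os$nf), , drop = FALSE])^2 / (fs * sf$w2)
  dbl <- rep(2, os$nf); dbl[1L] <- 1
  if (sf$nwin %% 2L == 0L) dbl[os$nf] <- 1
  P <- P * dbl
  pow <- rowMeans(P)
  dof <- 2 * sf$K
  structure(list(frequencies = os$freq, power = pow,
                 ci_low = pow * dof / stats::qchisq(0.975, dof),
                 ci_high = pow * dof / stats::qchisq(0.025, dof),
                 window_s = window_s, overlap_s = overlap_s,
                 n_segments = sf$K, fs = fs),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins, 0-%.1f Hz (res %.4g Hz), %d segments (%g s window, %g s overlap)\n",
              length(x$frequencies), max(x$frequencies),
              x$frequencies[2] - x$frequencies[1], x$n_segments,
              x$window_s, x$overlap_s))
  cat(sprintf("  total power %.5g mV^2, peak at %.3g Hz\n",
              sum(x$power) * (x$frequencies[2] - x$frequencies[1]),
              x$frequencies[which.max(x$power)]))
  invisible(x)
}

#' @export
plot.psd_estimate <- function(x, fmax = 40, log = "y", ...) {
  keep <- x$frequencies <= fmax & x$power > 0
  graphics::plot(x$frequencies[keep], x$power[keep], type = "l", log = log,
                 xlab = "frequency (Hz)", ylab = "PSD (mV²/Hz)", ...)
  graphics::lines(x$frequencies[keep], pmax(x$ci_low[keep], min(x$power[keep])),
                  col = "grey60")
  graphics::lines(x$frequencies[keep], x$ci_high[keep], col = "grey60")
  invisible(x)
}

#' Export a spectrum as TSV
#' @param psd a [welch_psd()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psd_tsv <- function(psd, path) {
  utils::write.table(
    data.frame(frequency_hz = psd$frequencies, power_mv2_hz = psd$power,
               ci_low = psd$ci_low, ci_high = psd$ci_high),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Power change between an event spectrum and a baseline spectrum
#'
#' A frequency bin is "affected" when the baseline mean power falls outside
#' the event spectrum's 95% interval (above: power decrease; below: power
#' increase). Contiguous affected bins of the same direction are merged into
#' bands; single-bin gaps inside a band are bridged and bands shorter than
#' `min_band_bins` are discarded as noise. The total power change is the
#' band-integrated power difference (mV^2) summed over all affected bands
#' (decrease bands contribute negatively); `per_bin_sum` gives the
#' unintegrated sum of per-bin density differences instead.
#'
#' @param event,baseline [welch_psd()] results on identical frequency grids
#'   (the study compares ictal traces >= 25 s against baseline traces of
#'   equal duration).
#' @param bridge_gap_bins maximum gap (in bins) bridged inside a band.
#' @param min_band_bins minimum band width in bins.
#' @param freq_range frequencies (Hz) considered; the default 0-100 Hz is
#'   the acquisition band (the telemetry hardware low-passes at 100 Hz).
#' @param total one of `"band_integrated"` (default) or `"per_bin_sum"`.
#' @return An object of class \code{power_change}: `bands` (data frame with
#'   `f_lo`, `f_hi`, `direction`, `delta_power_mv2`), `total_increase_mv2`,
#'   and the per-bin `direction` vector (+1/-1/0).
#' @export
power_increase <- function(event, baseline, bridge_gap_bins = 1L,
                           min_band_bins = 2L, freq_range = c(0, 100),
                           total = c("band_integrated", "per_bin_sum")) {
  total <- match.arg(total)
  if (length(event$frequencies) != length(baseline$frequencies) ||
      max(abs(event$frequencies - baseline$frequencies)) > 1e-9)
    stop_input("event and baseline spectra must share the frequency grid")
  dirn <- integer(length(event$frequencies))
  dirn[baseline$power < event$ci_low] <- 1L
  dirn[baseline$power > event$ci_high] <- -1L
  dirn[event$frequencies < freq_range[1L] | event$frequencies > freq_range[2L]] <- 0L
  # bridge short gaps flanked by the same direction
  if (bridge_gap_bins > 0L) {
    r <- rle(dirn)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j] == 0L && r$lengths[j] <= bridge_gap_bins &&
          j > 1L && j < length(r$values) &&
          r$values[j - 1L] != 0L && r$values[j - 1L] == r$values[j + 1L])
        dirn[starts[j]:ends[j]] <- r$values[j - 1L]
    }
  }
  df <- event$frequencies[2L] - event$frequencies[1L]
  delta <- event$power - baseline$power
  r <- rle(dirn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L & r$lengths >= min_band_bins
  bands <- data.frame(f_lo = event$frequencies[starts[keep]],
                      f_hi = event$frequencies[ends[keep]],
                      direction = ifelse(r$values[keep] > 0L, "up", "down"),
                      delta_power_mv2 = vapply(which(keep), function(j)
                        sum(delta[starts[j]:ends[j]]) * df, numeric(1)))
  # bins outside kept bands are not affected
  mask <- logical(length(dirn))
  for (j in which(keep)) mask[starts[j]:ends[j]] <- TRUE
  dirn[!mask] <- 0L
  tot <- if (nrow(bands) == 0L) 0 else switch(total,
    band_integrated = sum(bands$delta_power_mv2),
    per_bin_sum = sum(delta[mask]))
  structure(list(bands = bands, total_increase_mv2 = tot, direction = dirn,
                 frequencies = event$frequencies, total_method = total),
            class = "power_change")
}

#' @export
print.power_change <- function(x, ...) {
  if (nrow(x$bands) == 0L) {
    cat("<power_change> no significantly affected bands\n")
  } else {
    cat(sprintf("<power_change> total %+.4g mV^2 over %d band(s):\n",
                x$total_increase_mv2, nrow(x$bands)))
    for (i in seq_len(nrow(x$bands)))
      cat(sprintf("  %s %.3g-%.3g Hz (%+.4g mV^2)\n",
                  if (x$bands$direction[i] == "up") "↑" else "↓",
                  x$bands$f_lo[i], x$bands$f_hi[i], x$bands$delta_power_mv2[i]))
  }
  invisible(x)
}

#' Compact label for affected bands, e.g. "up 1.1-6.2; down 0.5-0.9"
#' @param pc a [power_increase()] result.
#' @return character scalar (empty when no bands).
#' @export
format_bands <- function(pc) {
  if (nrow(pc$bands) == 0L) return("")
  paste(sprintf("%s %.3g-%.3g",
                ifelse(pc$bands$direction == "up", "↑", "↓"),
                pc$bands$f_lo, pc$bands$f_hi), collapse = "; ")
}
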