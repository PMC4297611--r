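# Synthetic two-channel telemetry EEG with exact ground truth.
#
# Background model: state-dependent spectrally shaped Gaussian noise.
# The awake state is a power-law ("1/f-like") spectrum; slow-wave sleep
# (SWS) is the same base with a delta-band (0.5-4 Hz) power boost and a
# higher overall amplitude, reproducing the awake (low amplitude, higher
# frequency) vs SWS (high-amplitude delta) contrast seen in rodent
# telemetry. Cross-channel coupling is a shared-component fraction c in
# [0,1]: each channel is sqrt(c) * shared + sqrt(1-c) * independent noise of
# the same spectral shape, giving true magnitude-squared coherence c^2 at
# every frequency.
#
# Ictal events are amplitude-modulated sinusoids with linear frequency
# drift (tonic-clonic-like evolution) scaled so the *total* event RMS is
# `amplitude_gain` times the local background RMS, followed by a
# multiplicative postictal suppression of the background. Interictal spikes
# are biphasic transients with a dominant negative (downward) phase.
# Everything injected is recorded in a ground-truth object.

#' Spectral profile for one behavioral state
#'
#' Power-law spectrum `S(f) ~ 1/f^alpha` (flattened below `f_lo` to keep
#' total power finite) with an optional delta-band power boost, scaled to a
#' target RMS amplitude.
#'
#' @param alpha spectral slope. Rodent EEG slopes are typically 2-3; the
#'   package default (2.5) also keeps normal background below the 3.5-SD
#'   spike threshold (fewer than ~1 spurious crossing event/min), the
#'   premise of threshold-based interictal spike detection.
#' @param rms_mv target RMS amplitude in mV.
#' @param delta_boost multiplicative power gain applied in `delta_band`.
#' @param delta_band delta band in Hz.
#' @param f_lo low-frequency flattening knee in Hz.
#' @return a list of class \code{state_profile}.
#' @export
state_profile <- function(alpha = 2.5, rms_mv = 0.1, delta_boost = 1,
                          delta_band = c(0.5, 4), f_lo = 1) {
  structure(list(alpha = alpha, rms_mv = rms_mv, delta_boost = delta_boost,
                 delta_band = delta_band, f_lo = f_lo),
            class = "state_profile")
}

#' Generator configuration
#'
#' Defaults encode the emulated study conditions: 500 Hz sampling,
#' low-amplitude awake background alternating with high-amplitude
#' delta-dominant SWS (fixed dwells), and no cross-channel coupling.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate (Hz).
#' @param coupling shared-component fraction in \[0,1\]; true MSC =
#'   `coupling^2`.
#' @param awake,sws [state_profile()]s for the two states.
#' @param dwell_awake_s,dwell_sws_s state dwell times (s); states alternate
#'   deterministically starting awake.
#' @param states `"both"` (alternating), `"awake"`, or `"sws"` (single
#'   state, stationary background).
#' @param seed integer RNG seed; a fixed seed makes generation bit
#'   reproducible.
#' @return a list of class \code{synth_config}.
#' @export
synth_config <- function(duration_s = 120, fs = 500, coupling = 0,
                         awake = state_profile(),
                         sws = state_profile(rms_mv = 0.25, delta_boost = 12),
                         dwell_awake_s = 60, dwell_sws_s = 40,
                         states = c("both", "awake", "sws"), seed = 1L) {
  check_number(duration_s, "duration_s", positive = TRUE)
  check_number(fs, "fs", positive = TRUE)
  check_number(coupling, "coupling")
  if (coupling < 0 || coupling > 1) stop_input("'coupling' must be in [0, 1]")
  structure(list(duration_s = duration_s, fs = fs, coupling = coupling,
                 awake = awake, sws = sws, dwell_awake_s = dwell_awake_s,
                 dwell_sws_s = dwell_sws_s, states = match.arg(states),
                 seed = as.integer(seed)),
            class = "synth_config")
}

profile_shape <- function(prof, f) {
  s <- 1 / pmax(f, prof$f_lo)^prof$alpha
  s[f >= prof$delta_band[1L] & f <= prof$delta_band[2L]] <-
    s[f >= prof$delta_band[1L] & f <= prof$delta_band[2L]] * prof$delta_boost
  s[f == 0] <- 0
  s
}

# Gaussian noise with spectrum prof, unit... scaled to prof$rms_mv RMS in
# expectation (fixed scale, not per-realization, so amplitude statistics
# remain honest across realizations)
shaped_noise <- function(n, fs, prof) {
  # pad to a 5-smooth length: mixed-radix FFT degrades badly on large
  # prime factors
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  f <- c(seq(0, floor(m / 2)), -seq(ceiling(m / 2) - 1, 1)) * fs / m
  g <- sqrt(profile_shape(prof, abs(f)))
  # expected mean square of Re(ifft(fft(w) * g)) is mean(g^2)
  g <- g * prof$rms_mv / sqrt(mean(g^2))
  Re(stats::fft(stats::fft(w) * g, inverse = TRUE))[seq_len(n)] / m
}

state_intervals <- function(cfg) {
  if (cfg$states != "both") {
    return(data.frame(state = cfg$states, start_s = 0, end_s = cfg$duration_s))
  }
  starts <- c(); states <- c(); t <- 0; s <- "awake"
  while (t < cfg$duration_s) {
    starts <- c(starts, t); states <- c(states, s)
    t <- t + if (s == "awake") cfg$dwell_awake_s else cfg$dwell_sws_s
    s <- if (s == "awake") "sws" else "awake"
  }
  data.frame(state = states, start_s = starts,
             end_s = c(starts[-1L], cfg$duration_s))
}

#' Generate state-modulated background EEG with ground truth
#'
#' @param cfg a [synth_config()].
#' @param subject_id,group,t0 recording metadata.
#' @return a list with components `recording` (an [eeg_recording]) and
#'   `truth` (class \code{synth_truth}: state intervals, coupling, true MSC,
#'   empty event/spike tables).
#' @export
generate_background <- function(cfg = synth_config(), subject_id = "S1",
                                group = "collagenase", t0 = 0) {
  if (!inherits(cfg, "synth_config")) stop_input("'cfg' must be a synth_config")
  set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$fs)
  if (n < 2L) stop_input("duration too short")
  iv <- state_intervals(cfg)
  c2 <- cfg$coupling
  mix <- function(shared, indep) sqrt(c2) * shared + sqrt(1 - c2) * indep
  ipsi <- numeric(n); contra <- numeric(n)
  for (st in c("awake", "sws")) {
    rows <- which(iv$state == st)
    if (length(rows) == 0L) next
    prof <- cfg[[st]]
    shared <- shaped_noise(n, cfg$fs, prof)
    n1 <- shaped_noise(n, cfg$fs, prof)
    n2 <- shaped_noise(n, cfg$fs, prof)
    mask <- numeric(n)
    for (r in rows) {
      i0 <- floor(iv$start_s[r] * cfg$fs) + 1L
      i1 <- min(n, floor(iv$end_s[r] * cfg$fs))
      mask[i0:i1] <- 1
    }
    # 0.2-s raised-cosine crossfade at state seams to avoid steps
    nramp <- round(0.2 * cfg$fs)
    if (nramp > 1L && cfg$states == "both") {
      k <- 0.5 - 0.5 * cos(pi * seq(0, 1, length.out = nramp))
      mask <- stats::filter(mask, k / sum(k), sides = 2)
      mask[is.na(mask)] <- if (st == "awake") 1 else 0
      mask <- as.numeric(mask)
    }
    ipsi <- ipsi + mask * mix(shared, n1)
    contra <- contra + mask * mix(shared, n2)
  }
  rec <- eeg_recording(ipsi, contra, fs = cfg$fs, subject_id = subject_id,
                       group = group, t0 = t0)
  truth <- structure(list(states = iv, coupling = cfg$coupling,
                          true_msc = cfg$coupling^2, seed = cfg$seed,
                          config = cfg,
                          events = data.frame(), spike_times_s = numeric(0),
                          components = list()),
                     class = "synth_truth")
  list(recording = rec, truth = truth)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf("<synth_truth> coupling %.2f (true MSC %.3f), %d state interval(s), %d event(s), %d spike(s)\n",
              x$coupling, x$true_msc, nrow(x$states),
              nrow(x$events), length(x$spike_times_s)))
  invisible(x)
}

ictal_waveform <- function(n_ev, fs, f_start, f_end, amp, ramp_s = 0.5) {
  t <- (seq_len(n_ev) - 1) / fs
  f <- f_start + (f_end - f_start) * t / max(t[n_ev], 1e-9)
  phase <- 2 * pi * cumsum(f) / fs
  env <- rep(1, n_ev)
  nr <- min(round(ramp_s * fs), floor(n_ev / 2))
  if (nr > 1L) {
    r <- 0.5 - 0.5 * cos(pi * seq(0, 1, length.out = nr))
    env[seq_len(nr)] <- r
    env[(n_ev - nr + 1L):n_ev] <- rev(r)
  }
  amp * env * sin(phase)
}

#' Inject an ictal event (rhythmic burst + postictal suppression)
#'
#' The burst is a frequency-drifting sinusoid whose amplitude is chosen so
#' that the *total* RMS over the event interval equals `amplitude_gain`
#' times a reference RMS: by default the pre-injection background RMS over
#' the event interval itself (so `amplitude_gain = 1` leaves the recording
#' unchanged), or an explicit `ref_rms` — typically the subject's baseline
#' epoch RMS, which makes the gain directly comparable to the tabulated
#' per-event RMS ratio (event RMS / non-epileptic RMS) even when the event
#' lands on a behavioral state whose amplitude differs from baseline.
#' Immediately after the burst the background is
#' multiplicatively suppressed by `suppression_factor` for `suppression_s`
#' seconds. The injected difference series is stored in the truth so the
#' background can be restored exactly.
#'
#' @param rec,truth output of [generate_background()] (or a previous
#'   injection).
#' @param onset_s,duration_s event placement in recording seconds.
#' @param burst_freq_hz,freq_end_hz oscillation frequency drifting linearly
#'   from start to end of the event (default 8 -> 4 Hz).
#' @param amplitude_gain target event/background RMS ratio (> 0).
#' @param suppression_s,suppression_factor postictal suppression length and
#'   multiplicative RMS factor (default 10 s at 0.3, i.e. RMS < 0.5 x
#'   baseline).
#' @param laterality `"bilateral"`, `"ipsilateral"`, or `"contralateral"`;
#'   the secondary channel receives `secondary_gain` of the burst amplitude
#'   for unilateral events.
#' @param secondary_gain amplitude fraction on the non-dominant channel for
#'   unilateral events (default 0).
#' @param ref_rms reference RMS in mV (length 1, or 2 for
#'   ipsi/contra); NULL (default) uses the local pre-injection background
#'   RMS over the event interval.
#' @param store_component keep the injected difference series in the truth
#'   (default TRUE; disable for large cohorts).
#' @return list(recording, truth) with the event appended to
#'   `truth$events`.
#' @export
inject_ictal_event <- function(rec, truth, onset_s, duration_s,
                               burst_freq_hz = 8, freq_end_hz = 4,
                               amplitude_gain = 4, suppression_s = 10,
                               suppression_factor = 0.3,
                               laterality = c("bilateral", "ipsilateral",
                                              "contralateral"),
                               secondary_gain = 0, ref_rms = NULL,
                               store_component = TRUE) {
  laterality <- match.arg(laterality)
  check_number(onset_s, "onset_s"); check_number(duration_s, "duration_s", positive = TRUE)
  if (amplitude_gain <= 0) stop_input("'amplitude_gain' must be > 0")
  dur <- duration_s(rec)
  end_all <- onset_s + duration_s + suppression_s
  if (onset_s < 0 || end_all > dur)
    stop_input("event (incl. suppression) must lie within the recording")
  if (nrow(truth$events) > 0L) {
    prev_lo <- truth$events$onset_s
    prev_hi <- truth$events$offset_s + truth$events$suppression_s
    if (any(onset_s < prev_hi & end_all > prev_lo))
      stop_input("event overlaps an existing injected event")
  }
  fs <- rec$fs
  i0 <- floor(onset_s * fs) + 1L
  n_ev <- floor(duration_s * fs)
  idx <- i0:(i0 + n_ev - 1L)
  gains <- switch(laterality,
                  bilateral = c(1, 1),
                  ipsilateral = c(1, secondary_gain),
                  contralateral = c(secondary_gain, 1))
  if (!is.null(ref_rms)) ref_rms <- rep_len(as.numeric(ref_rms), 2L)
  old_ipsi <- rec$ipsi; old_contra <- rec$contra
  for (ch in c("ipsi", "contra")) {
    chi <- if (ch == "ipsi") 1L else 2L
    g <- gains[chi]
    local_rms <- sqrt(mean(rec[[ch]][idx]^2))
    ref <- if (is.null(ref_rms)) local_rms else ref_rms[chi]
    eff_gain <- 1 + g * (amplitude_gain - 1)
    if (eff_gain > 1) {
      # sine RMS is A/sqrt(2): A such that the total event RMS
      # sqrt(local^2 + A^2/2) reaches eff_gain * ref
      A2 <- 2 * max(0, (eff_gain * ref)^2 - local_rms^2)
      rec[[ch]][idx] <- rec[[ch]][idx] +
        ictal_waveform(n_ev, fs, burst_freq_hz, freq_end_hz, sqrt(A2))
    }
    if (suppression_s > 0) {
      sidx <- (i0 + n_ev):min(length(rec[[ch]]), i0 + n_ev + floor(suppression_s * fs) - 1L)
      fac <- if (g > 0) suppression_factor else 1
      rec[[ch]][sidx] <- rec[[ch]][sidx] * fac
    }
  }
  ev <- data.frame(onset_s = onset_s, offset_s = onset_s + duration_s,
                   duration_s = duration_s, burst_freq_hz = burst_freq_hz,
                   freq_end_hz = freq_end_hz, amplitude_gain = amplitude_gain,
                   suppression_s = suppression_s, laterality = laterality)
  truth$events <- rbind(truth$events, ev)
  if (isTRUE(store_component)) {
    span <- i0:min(length(old_ipsi), i0 + n_ev + floor(suppression_s * fs) - 1L)
    truth$components[[length(truth$components) + 1L]] <-
      list(idx = span, ipsi = rec$ipsi[span] - old_ipsi[span],
           contra = rec$contra[span] - old_contra[span])
  }
  list(recording = rec, truth = truth)
}

spike_template <- function(fs, width_ms = 80, polarity = c("down", "up")) {
  polarity <- match.arg(polarity)
  w <- width_ms / 1000
  nspk <- max(5L, round(w * fs))
  t <- (seq_len(nspk) - 1) / fs
  s1 <- w / 6; s2 <- w / 4; d <- w / 3
  tmpl <- -exp(-((t - w / 3)^2) / (2 * s1^2)) +
    0.4 * exp(-((t - w / 3 - d)^2) / (2 * s2^2))
  tmpl <- tmpl / max(abs(tmpl))
  if (polarity == "up") tmpl <- -tmpl
  tmpl
}

#' Inject interictal spikes with exact truth times
#'
#' Biphasic transients (dominant downward phase by default) added to the
#' background at Poisson times with a refractory spacing, or at an exact
#' count in fixed-count mode. Spike amplitude is expressed in units of the
#' channel's current standard deviation.
#'
#' @param rec,truth as in [inject_ictal_event()].
#' @param rate_per_min Poisson rate (ignored in fixed-count mode).
#' @param fixed_count exact number of spikes (deterministically spread with
#'   seeded jitter) or NULL.
#' @param amplitude_sd peak amplitude in background-SD units (default 5).
#' @param width_ms spike width (default 80 ms).
#' @param polarity `"down"` (characteristic downward spiking) or `"up"`.
#' @param refractory_ms minimum spacing between spike peaks; must exceed
#'   `width_ms`.
#' @param channel `"both"`, `"ipsi"`, or `"contra"`.
#' @param window_s restrict injection to `c(lo, hi)` seconds (default whole
#'   recording).
#' @param seed integer seed for spike times.
#' @return list(recording, truth) with `truth$spike_times_s` extended.
#' @export
inject_spikes <- function(rec, truth, rate_per_min = 20, fixed_count = NULL,
                          amplitude_sd = 5, width_ms = 80,
                          polarity = c("down", "up"), refractory_ms = 200,
                          channel = c("both", "ipsi", "contra"),
                          window_s = NULL, seed = 1L) {
  polarity <- match.arg(polarity); channel <- match.arg(channel)
  if (rate_per_min < 0) stop_input("'rate_per_min' must be >= 0")
  if (width_ms >= refractory_ms)
    stop_input("'refractory_ms' must exceed the spike width")
  fs <- rec$fs
  dur <- duration_s(rec)
  if (is.null(window_s)) window_s <- c(0, dur)
  lo <- window_s[1L]; hi <- window_s[2L]
  tmpl <- spike_template(fs, width_ms, polarity)
  margin <- length(tmpl) / fs
  set.seed(seed)
  if (!is.null(fixed_count)) {
    n_spk <- as.integer(fixed_count)
    if (n_spk == 0L) return(list(recording = rec, truth = truth))
    slots <- seq(lo + margin, hi - margin, length.out = n_spk + 2L)[2:(n_spk + 1L)]
    jit <- min(diff(c(lo, slots, hi)) / 2 - refractory_ms / 2000, 1)
    times <- slots + stats::runif(n_spk, -max(jit, 0), max(jit, 0))
  } else {
    n_spk <- stats::rpois(1L, rate_per_min * (hi - lo) / 60)
    if (n_spk == 0L) return(list(recording = rec, truth = truth))
    times <- sort(stats::runif(n_spk, lo + margin, hi - margin))
    keep <- c(TRUE, diff(times) > refractory_ms / 1000)
    times <- times[keep]
  }
  times <- sort(times)
  # truth records the time of the dominant (peak) deflection, which is what
  # a threshold detector aligns on
  peak_off <- (which.max(abs(tmpl)) - 1L) / fs
  # amplitude reference: background SD within the injection window (not the
  # whole recording, which may contain ictal events)
  widx <- max(1L, floor(lo * fs) + 1L):min(length(rec$ipsi), floor(hi * fs))
  chans <- if (channel == "both") c("ipsi", "contra") else channel
  for (ch in chans) {
    amp <- amplitude_sd * stats::sd(rec[[ch]][widx])
    for (tt in times) {
      i0 <- floor(tt * fs) + 1L
      idx <- i0:(i0 + length(tmpl) - 1L)
      ok <- idx >= 1L & idx <= length(rec[[ch]])
      rec[[ch]][idx[ok]] <- rec[[ch]][idx[ok]] + amp * tmpl[ok]
    }
  }
  truth$spike_times_s <- sort(c(truth$spike_times_s, times + peak_off))
  list(recording = rec, truth = truth)
}
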