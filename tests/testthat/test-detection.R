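# ictal event delimitation, laterality, spike detection, summaries
# (make_seizure_rec lives in helper-fixtures.R)

test_that("background-only recordings yield no events", {
  bg <- generate_background(synth_config(duration_s = 400, seed = 31))
  bl <- baseline_stats(bg$recording, 0, 300)
  ev <- detect_ictal_events(bg$recording, bl, baseline_window = c(0, 300))
  expect_equal(nrow(ev), 0L)
  expect_error(detect_ictal_events(bg$recording, NULL), "baseline")
})

test_that("two injected events are recovered with sub-second accuracy", {
  f <- make_seizure_rec(32, durations = c(37, 65))
  ev <- detect_ictal_events(f$rec, f$bl, baseline_window = c(0, 300))
  expect_equal(nrow(ev), 2L)
  expect_lt(max(abs(ev$onset_s - f$truth$events$onset_s)), 1)
  expect_lt(max(abs(ev$offset_s - f$truth$events$offset_s)), 1)
  expect_equal(ev$duration_s, ev$offset_s - ev$onset_s)
  # per-subject roll-up reproduces the tabulated arithmetic on true durations
  ev$duration_s <- f$truth$events$duration_s   # exact durations for arithmetic
  s <- summarize_subject(ev)
  expect_equal(s$incidence, 2L)
  expect_equal(s$total_duration_s, 102)
  expect_identical(s$duration_label, "102 (51 ± 19.80)")
})

test_that("bursts shorter than the minimum duration are rejected", {
  f <- make_seizure_rec(33, durations = 3, duration_s = 500)
  ev <- detect_ictal_events(f$rec, f$bl, min_duration_s = 5,
                            baseline_window = c(0, 300))
  expect_equal(nrow(ev), 0L)
  ev2 <- detect_ictal_events(f$rec, f$bl, min_duration_s = 2,
                             baseline_window = c(0, 300))
  expect_equal(nrow(ev2), 1L)
})

test_that("laterality reflects which channels carry the event", {
  fb <- make_seizure_rec(34, durations = 30, duration_s = 500)
  evb <- detect_ictal_events(fb$rec, fb$bl, baseline_window = c(0, 300))
  expect_equal(evb$laterality, "bilateral")
  fi <- make_seizure_rec(35, durations = 30, lats = "ipsilateral",
                         duration_s = 500)
  evi <- detect_ictal_events(fi$rec, fi$bl, baseline_window = c(0, 300))
  expect_equal(evi$laterality, "ipsilateral")
  expect_identical(
    classify_laterality(fi$rec, evi$onset_s, evi$offset_s, fi$bl,
                        baseline_window = c(0, 300)), "ipsilateral")
  # a quiet stretch qualifies on neither channel
  expect_error(classify_laterality(fi$rec, 10, 40, fi$bl,
                                   baseline_window = c(0, 300)),
               "neither channel")
})

test_that("a weak secondary channel is not called bilateral", {
  bg <- generate_background(synth_config(duration_s = 500, seed = 36))
  bl <- baseline_stats(bg$recording, 0, 300)
  ref <- c(bl$ipsi$rms, bl$contra$rms)
  out <- inject_ictal_event(bg$recording, bg$truth, 320, 40,
                            amplitude_gain = 4, laterality = "ipsilateral",
                            secondary_gain = 0.15, ref_rms = ref,
                            store_component = FALSE)
  ev <- detect_ictal_events(out$recording, bl, baseline_window = c(0, 300))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$laterality, "ipsilateral")
})

test_that("spike threshold is strict and grouping respects the refractory", {
  baseline <- amplitude_ci(c(rep(-1, 500), rep(1, 500)))
  v <- numeric(5000)
  v[1000] <- 3.5 * baseline$sd + baseline$mean     # exactly at threshold
  st <- detect_spikes(v, baseline, fs = 500)
  expect_equal(st$n, 0L)
  v[1000] <- v[1000] + 1e-9                        # strictly beyond
  st2 <- detect_spikes(v, baseline, fs = 500)
  expect_equal(st2$n, 1L)
  # two crossings 40 ms apart collapse into one detection
  v2 <- numeric(5000)
  v2[c(2000, 2020)] <- 10
  st3 <- detect_spikes(v2, baseline, fs = 500, refractory_ms = 100)
  expect_equal(st3$n, 1L)
  v2[2200] <- -10                                  # 400 ms later: separate
  st4 <- detect_spikes(v2, baseline, fs = 500, refractory_ms = 100)
  expect_equal(st4$n, 2L)
  expect_error(detect_spikes(v, baseline, fs = 500, k = 0), "k")
})

test_that("injected 5-SD spikes are recovered at the injected rate", {
  rates <- vapply(1:10, function(s) {
    bg <- generate_background(synth_config(duration_s = 80, states = "awake",
                                           seed = 40 + s))
    out <- inject_spikes(bg$recording, bg$truth, fixed_count = 20,
                         window_s = c(10, 70), seed = s)
    bl <- amplitude_ci(extract_epoch(bg$recording, "ipsi", 10, 70))
    detect_spikes(extract_epoch(out$recording, "ipsi", 10, 70), bl)$rate_per_min
  }, numeric(1))
  expect_lt(abs(mean(rates) - 20), 1)
  # average waveform is spike-like: dominant downward deflection
  bg <- generate_background(synth_config(duration_s = 80, states = "awake",
                                         seed = 99))
  out <- inject_spikes(bg$recording, bg$truth, fixed_count = 20,
                       window_s = c(10, 70), seed = 1)
  bl <- amplitude_ci(extract_epoch(bg$recording, "ipsi", 10, 70))
  st <- detect_spikes(extract_epoch(out$recording, "ipsi", 10, 70), bl)
  expect_lt(min(st$average_waveform), -2 * bl$sd)
  expect_lt(min(st$average_waveform), -abs(max(st$average_waveform)))
})

test_that("subject summaries aggregate events as tabulated", {
  empty <- summarize_subject(data.frame())
  expect_equal(empty$incidence, 0L)
  expect_equal(empty$total_duration_s, 0)
  ev <- data.frame(subject_id = "S3", duration_s = c(20, 60, 83),
                   laterality = c("bilateral", "bilateral", "ipsilateral"),
                   onset_latency_h = c(22.117, 23, 24),
                   rms_ratio_ipsi = c(1.9, 2.0, 1.86))
  s <- summarize_subject(ev)
  expect_equal(s$incidence, 3L)
  expect_equal(s$total_duration_s, 163)
  expect_equal(s$mean_duration_s, 163 / 3)
  expect_identical(s$laterality, "bilateral")
  expect_identical(s$onset_label, "22 h, 7 min")
  expect_match(s$duration_label, "^163 \\(54\\.33")
  # laterality ties resolve to bilateral
  ev2 <- ev[1:2, ]; ev2$laterality <- c("ipsilateral", "bilateral")
  expect_identical(summarize_subject(ev2)$laterality, "bilateral")
})
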