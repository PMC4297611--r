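# synthetic generator: determinism, state contrast, coupling control,
# injection semantics, and cohort structure

test_that("generation is deterministic under a fixed seed", {
  a <- generate_background(synth_config(duration_s = 20, seed = 11))
  b <- generate_background(synth_config(duration_s = 20, seed = 11))
  expect_identical(a$recording$ipsi, b$recording$ipsi)
  expect_identical(a$recording$contra, b$recording$contra)
  c <- generate_background(synth_config(duration_s = 20, seed = 12))
  expect_false(identical(a$recording$ipsi, c$recording$ipsi))
})

test_that("slow-wave sleep segments have higher RMS than awake segments", {
  for (s in 1:3) {
    bg <- generate_background(synth_config(duration_s = 200, seed = s))
    iv <- bg$truth$states
    r <- vapply(seq_len(nrow(iv)), function(i)
      compute_rms(extract_epoch(bg$recording, "ipsi", iv$start_s[i], iv$end_s[i])),
      numeric(1))
    expect_gt(min(r[iv$state == "sws"]), max(r[iv$state == "awake"]))
  }
})

test_that("cross-channel coherence rises monotonically with coupling", {
  mean_msc <- function(cp) mean(vapply(1:20, function(s)
    mean(msc(awake_pair(27, s, cp))$coherence), numeric(1)))
  m <- vapply(c(0, 0.5, 1), mean_msc, numeric(1))
  expect_true(all(diff(m) > 0))
  expect_lt(m[1], 0.2)           # independent channels: only estimator bias
  expect_gt(m[3], 0.999)         # identical channels
})

test_that("invalid generator configs are rejected", {
  expect_error(synth_config(duration_s = 0), "duration_s")
  expect_error(synth_config(coupling = 1.5), "coupling")
})

test_that("ictal injection controls RMS, suppression, and is reversible", {
  bg <- generate_background(synth_config(duration_s = 200, states = "awake",
                                         seed = 3))
  # unity gain with no suppression is a no-op
  out0 <- inject_ictal_event(bg$recording, bg$truth, onset_s = 50,
                             duration_s = 30, amplitude_gain = 1,
                             suppression_s = 0)
  expect_equal(out0$recording$ipsi, bg$recording$ipsi)
  out <- inject_ictal_event(bg$recording, bg$truth, onset_s = 50,
                            duration_s = 40, amplitude_gain = 4,
                            suppression_s = 10, suppression_factor = 0.3)
  # suppression drops RMS well below half of baseline
  supp <- compute_rms(extract_epoch(out$recording, "ipsi", 91, 99))
  base <- compute_rms(extract_epoch(bg$recording, "ipsi", 91, 99))
  expect_lt(supp / base, 0.5)
  # removing the stored injected component restores the background exactly
  comp <- out$truth$components[[1]]
  restored <- out$recording$ipsi
  restored[comp$idx] <- restored[comp$idx] - comp$ipsi
  expect_equal(restored, bg$recording$ipsi, tolerance = 1e-12)
  # overlapping injection is rejected
  expect_error(inject_ictal_event(out$recording, out$truth, onset_s = 85,
                                  duration_s = 20), "overlaps")
  expect_error(inject_ictal_event(bg$recording, bg$truth, onset_s = 190,
                                  duration_s = 30), "within the recording")
})

test_that("a gain-4 event yields an RMS ratio near 4 across seeds", {
  rr <- vapply(1:20, function(s) {
    bg <- generate_background(synth_config(duration_s = 200, states = "awake",
                                           seed = s))
    bl <- baseline_stats(bg$recording, 0, 60)
    out <- inject_ictal_event(bg$recording, bg$truth, onset_s = 70,
                              duration_s = 60, amplitude_gain = 4,
                              ref_rms = c(bl$ipsi$rms, bl$contra$rms))
    rms_ratio(extract_epoch(out$recording, "ipsi", 70, 130),
              extract_epoch(out$recording, "ipsi", 0, 60))
  }, numeric(1))
  expect_true(all(rr > 3.5 & rr < 4.5))
})

test_that("two injected events reproduce the per-subject duration arithmetic", {
  bg <- generate_background(synth_config(duration_s = 300, seed = 4))
  out <- inject_ictal_event(bg$recording, bg$truth, 60, 37, amplitude_gain = 4,
                            store_component = FALSE)
  out <- inject_ictal_event(out$recording, out$truth, 150, 65,
                            amplitude_gain = 4, store_component = FALSE)
  d <- out$truth$events$duration_s
  expect_equal(sum(d), 102)
  expect_equal(mean(d), 51)
  expect_equal(round(sd(d), 2), 19.80)
})

test_that("spike injection honors rate, count, amplitude, and refractory rules", {
  bg <- generate_background(synth_config(duration_s = 60, states = "awake",
                                         seed = 9))
  # zero rate leaves the series untouched
  out0 <- inject_spikes(bg$recording, bg$truth, rate_per_min = 0, seed = 2)
  expect_identical(out0$recording$ipsi, bg$recording$ipsi)
  # fixed-count mode: exactly 20 truth entries in 60 s = 20/min
  out <- inject_spikes(bg$recording, bg$truth, fixed_count = 20, seed = 2)
  expect_length(out$truth$spike_times_s, 20)
  expect_true(all(diff(out$truth$spike_times_s) > 0.2))
  # injected transients peak at 5 background SD exactly; on the realized
  # trace the additive background can partially cancel an occasional peak,
  # so the 3.5-SD threshold clears at nearly (not strictly) every spike
  sdb <- sd(bg$recording$ipsi)
  delta <- out$recording$ipsi - bg$recording$ipsi
  dpeaks <- vapply(out$truth$spike_times_s, function(tt) {
    idx <- max(1, round((tt - 0.02) * 500)):min(30000, round((tt + 0.02) * 500))
    max(abs(delta[idx]))
  }, numeric(1))
  expect_equal(dpeaks, rep(5 * sdb, 20), tolerance = 1e-6)
  peaks <- vapply(out$truth$spike_times_s, function(tt) {
    idx <- max(1, round((tt - 0.02) * 500)):min(30000, round((tt + 0.02) * 500))
    max(abs(out$recording$ipsi[idx]))
  }, numeric(1))
  expect_gte(mean(peaks > 3.5 * sdb), 0.85)
  expect_error(inject_spikes(bg$recording, bg$truth, width_ms = 250,
                             refractory_ms = 200), "refractory")
})

test_that("the default cohort matches the study conditions with exact truth", {
  co <- default_cohort()
  expect_equal(unname(co$incidence_table),
               matrix(c(6L, 3L, 0L, 6L), 2, 2, byrow = TRUE))
  truths <- lapply(co$subjects, `[[`, "truth")
  counts <- vapply(truths, function(t) nrow(t$events), integer(1))
  expect_equal(unname(sort(counts[counts > 0])), c(1L, 2L, 3L, 4L, 8L, 14L))
  groups <- vapply(co$subjects, function(s) s$recording$group, "")
  expect_equal(sum(groups == "blood"), 6L)
  expect_true(all(counts[groups == "blood"] == 0L))
  for (s in co$subjects) {
    tru <- s$truth
    if (nrow(tru$events) == 0) next
    expect_true(all(tru$events$duration_s >= 5 & tru$events$duration_s <= 90))
    onset_h <- (s$recording$t0 + tru$events$onset_s[1]) / 3600
    expect_true(onset_h >= 10 && onset_h <= 36)
    lv <- lesion_volume(s$histology$ipsi, s$histology$contra)
    expect_equal(lv$lesion_mm3, s$histology$true_lesion_mm3, tolerance = 1e-9)
  }
})

test_that("cohort generation is reproducible and validates its config", {
  cfg <- cohort_config(collagenase_n = 2, blood_n = 1, seizing_n = 1,
                       event_counts = 2L, seed = 3)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects[[1]]$recording$ipsi, b$subjects[[1]]$recording$ipsi)
  expect_identical(a$subjects[[2]]$truth$events, b$subjects[[2]]$truth$events)
  expect_error(cohort_config(collagenase_n = 3, seizing_n = 4,
                             event_counts = rep(1L, 4)), "exceed")
  expect_error(cohort_config(seizing_n = 2, event_counts = 1L), "one entry")
})
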