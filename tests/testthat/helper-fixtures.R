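# shared fixture builders and independent oracles

# stationary awake-state background pair, the workhorse for estimator tests
awake_pair <- function(duration_s, seed, coupling = 0) {
  bg <- generate_background(synth_config(duration_s = duration_s,
                                         coupling = coupling,
                                         states = "awake", seed = seed))
  extract_epoch(bg$recording, "both", 0, duration_s)
}

# default synthetic cohort, built once per test run
.fixture_env <- new.env(parent = emptyenv())
default_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- generate_cohort(cohort_config())
  .fixture_env$cohort
}

# state-mixed background with ictal events referenced to the RMS of a
# 5-min baseline epoch, the way the cohort generator builds subjects
make_seizure_rec <- function(seed, durations = c(37, 65), gain = 4,
                             lats = rep("bilateral", length(durations)),
                             duration_s = 600, onsets = NULL) {
  bg <- generate_background(synth_config(duration_s = duration_s, seed = seed))
  bl <- baseline_stats(bg$recording, 0, 300)
  ref <- c(bl$ipsi$rms, bl$contra$rms)
  rec <- bg$recording; truth <- bg$truth
  if (is.null(onsets))
    onsets <- 310 + cumsum(c(0, utils::head(durations, -1) + 25))
  for (j in seq_along(durations)) {
    out <- inject_ictal_event(rec, truth, onsets[j], durations[j],
                              amplitude_gain = gain, laterality = lats[j],
                              suppression_s = 8, ref_rms = ref,
                              store_component = FALSE)
    rec <- out$recording; truth <- out$truth
  }
  list(rec = rec, truth = truth, bl = bl)
}

# independent full-enumeration oracle for the two-sided Fisher exact p:
# explicit factorial formula, explicit loop over admissible tables
fisher_oracle <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1]); c2 <- sum(m[, 2]); N <- sum(m)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  lp_tab <- function(x) {
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(N) - lfactorial(x) - lfactorial(r1 - x) -
      lfactorial(c1 - x) - lfactorial(N - r1 - c1 + x)
  }
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  lobs <- lp_tab(m[1, 1])
  p <- 0
  for (x in xs) {
    lx <- lp_tab(x)
    if (lx <= lobs + 1e-7) p <- p + exp(lx)
  }
  p
}

# brute-force Mann-Whitney U (pairwise wins + half ties) for group a
brute_U <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}
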