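# contingency and rank statistics, lesion volumetry, telemetry deltas

test_that("Fisher exact p matches the hypergeometric probability-mass sum", {
  p <- fisher_exact_2x2(matrix(c(6, 3, 0, 6), 2, byrow = TRUE))
  expect_equal(p, 139 / 5005, tolerance = 1e-12)   # = 0.02777, printed 0.028
  expect_equal(round(p, 3), 0.028)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 0), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "no observations")
})

test_that("Fisher exact agrees with enumeration oracle and fisher.test", {
  # exhaustive at moderate size here; the full N <= 20 sweep runs with the
  # acceptance checks
  for (N in 0:12) {
    for (a in 0:N) for (b in 0:(N - a)) for (cc in 0:(N - a - b)) {
      m <- matrix(c(a, b, cc, N - a - b - cc), 2, byrow = TRUE)
      if (sum(m) == 0) next
      expect_equal(fisher_exact_2x2(m), fisher_oracle(m), tolerance = 1e-10)
    }
  }
  # spot-check against the reference implementation
  set.seed(10)
  for (i in 1:50) {
    m <- matrix(rpois(4, 4), 2)
    if (sum(m) == 0) next
    expect_equal(fisher_exact_2x2(m), stats::fisher.test(m)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("Mann-Whitney U counts pairwise wins with half ties", {
  expect_equal(mann_whitney(1:4, 1:4)$statistic, 8)          # n1 n2 / 2
  expect_equal(mann_whitney(5:8, 1:4)$statistic, 16)         # full separation
  counts <- c(1, 2, 3, 4, 8, 14, 0, 0, 0)
  zeros <- rep(0, 6)
  expect_equal(mann_whitney(counts, zeros)$statistic, 45)
  expect_equal(mann_whitney(counts, zeros)$statistic, brute_U(counts, zeros))
  set.seed(11)
  for (i in 1:10) {
    a <- sample(0:5, 7, replace = TRUE); b <- sample(0:5, 5, replace = TRUE)
    expect_equal(mann_whitney(a, b)$statistic, brute_U(a, b))
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney p agrees with reference asymptotics and exact enumeration", {
  set.seed(12)
  a <- rnorm(8); b <- rnorm(10) + 0.5                       # no ties
  expect_equal(mann_whitney(a, b)$p.value,
               stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-9)
  expect_equal(mann_whitney(a, b, method = "exact")$p.value,
               stats::wilcox.test(a, b, exact = TRUE)$p.value,
               tolerance = 1e-9)
  # tie-corrected variance path
  a2 <- c(1, 1, 2, 3); b2 <- c(1, 2, 2, 4)
  expect_equal(mann_whitney(a2, b2)$p.value,
               stats::wilcox.test(a2, b2, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-9)
  # degenerate: everything tied
  expect_equal(mann_whitney(rep(1, 3), rep(1, 4))$p.value, 1)
})

test_that("lesion volume follows the section-area formula", {
  s30 <- section_series(rep(30, 40), rep(5, 40), rep(2, 40), interval_mm = 0.2)
  expect_equal(ichseizr:::hemisphere_volume(s30), (30 - 5 - 2) * 0.2 * 40) # 184
  contra <- section_series(rep(30, 40), 0, rep(2, 40), interval_mm = 0.2)
  lv <- lesion_volume(s30, contra)
  expect_equal(lv$contra_mm3, 224)
  expect_equal(lv$lesion_mm3, 224 - 184)
  expect_equal(lesion_volume(contra, contra)$lesion_mm3, 0)
  # linear in areas, invariant to section order
  set.seed(13)
  tot <- 30 + rnorm(40); dam <- runif(40, 0, 3)
  o <- sample(40)
  a <- lesion_volume(section_series(tot, dam, 1, 0.2),
                     section_series(tot, 0, 1, 0.2))
  b <- lesion_volume(section_series(tot[o], dam[o], 1, 0.2),
                     section_series(tot[o], 0, 1, 0.2))
  expect_equal(a$lesion_mm3, b$lesion_mm3)
  k <- 2.5
  a2 <- lesion_volume(section_series(k * tot, k * dam, k, 0.2),
                      section_series(k * tot, 0, k, 0.2))
  expect_equal(a2$lesion_mm3, k * a$lesion_mm3)
  expect_error(section_series(rep(10, 5), rep(8, 5), rep(3, 5)), "exceed")
  expect_error(lesion_volume(s30, section_series(rep(30, 39))), "matching")
})

test_that("peri-event deltas follow the post-minus-pre convention", {
  # constant series: all deltas zero
  ts <- telemetry_series(rep(37, 200), interval_s = 60, start_s = 0)
  pd <- peri_event_delta(ts, 4000)
  expect_true(all(abs(pd$deltas) < 1e-12))
  # -0.5 degree step at the event: every post bin reads -0.5
  v <- rep(37, 200); v[68:200] <- 36.5       # step at t = 4020 s exactly
  pd2 <- peri_event_delta(telemetry_series(v, 60, 0), 4020)
  expect_equal(unname(pd2$deltas[1, ]), rep(-0.5, 12), tolerance = 1e-9)
})

test_that("events too close together or uncovered are excluded and logged", {
  ts <- telemetry_series(rep(37, 300), interval_s = 60, start_s = 0)
  pd <- peri_event_delta(ts, c(5000, 5000 + 1800))
  expect_equal(pd$included, 5000)
  expect_equal(pd$excluded$event_s, 6800)
  expect_match(pd$excluded$reason, "preceding")
  pd2 <- peri_event_delta(ts, c(100, 17000))  # no pre-hour / beyond coverage
  expect_equal(length(pd2$included), 0)
  expect_equal(nrow(pd2$excluded), 2)
})

test_that("pure-noise series give deltas centred on zero", {
  set.seed(14)
  ts <- telemetry_series(rnorm(2000, 37, 0.2), interval_s = 60, start_s = 0)
  events <- seq(4000, 110000, by = 9000)
  pd <- peri_event_delta(ts, events)
  m <- mean(pd$deltas)
  se <- sd(pd$deltas) / sqrt(length(pd$deltas))
  expect_lt(abs(m), 2 * se + 0.02)
})
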