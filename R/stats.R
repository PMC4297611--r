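# Cohort-level statistics: exact 2x2 contingency test, Mann-Whitney U,
# lesion volumetry from serial section areas, and peri-event telemetry
# deltas.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Probability-mass definition: with margins fixed, the two-sided p-value is
#' the sum of hypergeometric probabilities of all tables whose probability
#' does not exceed that of the observed table (the convention behind the
#' usual printed p for seizure incidence contrasts, e.g.
#' `[[6,3],[0,6]]` -> 0.02797).
#'
#' @param table 2x2 matrix of non-negative integer counts (rows = model
#'   groups, columns = outcome yes/no).
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop_input("'table' must be 2x2")
  if (any(m < 0) || any(m != round(m))) stop_input("counts must be non-negative integers")
  if (sum(m) == 0L) stop_input("table has no observations")
  r1 <- sum(m[1L, ]); c1 <- sum(m[, 1L]); N <- sum(m)
  if (r1 == 0L || r1 == N || c1 == 0L || c1 == N) return(1)
  xs <- max(0L, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(xs, c1, N - c1, r1)
  pobs <- stats::dhyper(m[1L, 1L], c1, N - c1, r1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

#' Mann-Whitney U test
#'
#' U for group A counts pairwise wins plus half-ties (equivalently the
#' rank-sum formulation with midranks). The default p-value uses the
#' normal approximation with tie-corrected variance and no continuity
#' correction; `method = "exact"` enumerates the permutation distribution
#' of U (feasible for small groups, up to ~12 per group).
#'
#' @param a,b numeric vectors (both non-empty).
#' @param method `"asymptotic"` (default) or `"exact"`.
#' @return list with `statistic` (U for group `a`), `p.value`, `method`.
#' @export
mann_whitney <- function(a, b, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop_input("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  rk <- rank(c(a, b))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (method == "asymptotic") {
    ties <- table(c(a, b))
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    p <- if (sigma2 <= 0) 1 else
      2 * stats::pnorm(-abs(U - n1 * n2 / 2) / sqrt(sigma2))
    p <- min(1, p)
  } else {
    if (choose(N, n1) > 5e5)
      stop_input("exact enumeration infeasible for these group sizes; use method = 'asymptotic'")
    combs <- utils::combn(N, n1)
    us <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    dev <- abs(us - n1 * n2 / 2)
    p <- mean(dev >= abs(U - n1 * n2 / 2) - 1e-9)
  }
  list(statistic = U, p.value = p, method = method)
}

#' Serial coronal section areas for one hemisphere
#'
#' @param total_mm2 complete hemisphere section areas (mm^2).
#' @param damage_mm2,ventricle_mm2 damaged and ventricular areas per
#'   section (mm^2); `damage + ventricle <= total` section-wise.
#' @param interval_mm spacing between analyzed sections (mm).
#' @return list of class \code{section_series}.
#' @export
section_series <- function(total_mm2, damage_mm2 = 0, ventricle_mm2 = 0,
                           interval_mm = 0.2) {
  n <- length(total_mm2)
  damage_mm2 <- rep_len(damage_mm2, n)
  ventricle_mm2 <- rep_len(ventricle_mm2, n)
  check_number(interval_mm, "interval_mm", positive = TRUE)
  if (any(total_mm2 < 0) || any(damage_mm2 < 0) || any(ventricle_mm2 < 0))
    stop_input("areas must be non-negative")
  if (any(damage_mm2 + ventricle_mm2 > total_mm2 + 1e-9))
    stop_input("damage + ventricle cannot exceed the total section area")
  structure(list(total_mm2 = as.numeric(total_mm2),
                 damage_mm2 = damage_mm2, ventricle_mm2 = ventricle_mm2,
                 interval_mm = interval_mm, n_sections = n),
            class = "section_series")
}

hemisphere_volume <- function(s) {
  (mean(s$total_mm2) - mean(s$damage_mm2) - mean(s$ventricle_mm2)) *
    s$interval_mm * s$n_sections
}

#' Lesion volume from serial section areas
#'
#' Hemisphere volume = (mean complete section area − mean damage area −
#' mean ventricle area) × section interval × section count. The lesion
#' volume is reported as contralateral minus ipsilateral hemisphere volume
#' (tissue lost, capturing damage, atrophy and ventricular dilation); the
#' sign convention is this package's inference from the volumetric method,
#' which itself defines hemisphere volumes only.
#'
#' @param ipsi,contra [section_series()] for each hemisphere; section
#'   counts and intervals must match.
#' @return list with `ipsi_mm3`, `contra_mm3`, `lesion_mm3`.
#' @export
lesion_volume <- function(ipsi, contra) {
  if (!inherits(ipsi, "section_series") || !inherits(contra, "section_series"))
    stop_input("inputs must be section_series objects")
  if (ipsi$n_sections != contra$n_sections ||
      abs(ipsi$interval_mm - contra$interval_mm) > 1e-12)
    stop_input("hemispheres must have matching section counts and interval")
  vi <- hemisphere_volume(ipsi)
  vc <- hemisphere_volume(contra)
  list(ipsi_mm3 = vi, contra_mm3 = vc, lesion_mm3 = vc - vi)
}

#' Peri-event telemetry deltas
#'
#' For each event, the mean of the telemetry series over each of `n_bins`
#' post-event bins of `bin_s` seconds minus the mean over the
#' `pre_window_s` before the event (post minus pre: negative values mean a
#' drop, e.g. post-seizure hypothermia). Events with another event in their
#' preceding `pre_window_s` are excluded; events whose pre/post windows are
#' not covered by the series are skipped. Both are logged. The defaults
#' (12 five-minute bins against the prior hour) match peri-seizure
#' temperature analysis; for activity use one 1-h bin
#' (`bin_s = 3600, n_bins = 1`).
#'
#' @param series a [telemetry_series()].
#' @param event_times_s event times (seconds, same reference as
#'   `series$start_s`).
#' @param pre_window_s pre-event averaging window (default 3600 s).
#' @param bin_s,n_bins post-event bin length and count (defaults 300 s x
#'   12).
#' @return list of class \code{peri_event_delta}: `deltas` (events x bins
#'   matrix, included events only), `included`, `excluded` (data frame with
#'   reasons), `mean_delta` per bin.
#' @export
peri_event_delta <- function(series, event_times_s, pre_window_s = 3600,
                             bin_s = 300, n_bins = 12L) {
  if (!inherits(series, "telemetry_series"))
    stop_input("'series' must be a telemetry_series")
  tt <- telemetry_times(series)
  event_times_s <- sort(event_times_s)
  deltas <- NULL; included <- numeric(0)
  excluded <- data.frame(event_s = numeric(0), reason = character(0))
  for (e in event_times_s) {
    prior <- event_times_s[event_times_s < e & event_times_s >= e - pre_window_s]
    if (length(prior) > 0L) {
      excluded <- rbind(excluded, data.frame(event_s = e,
                                             reason = "event in preceding window"))
      next
    }
    pre_idx <- tt >= e - pre_window_s & tt < e
    post_ok <- tt >= e & tt < e + bin_s * n_bins
    if (!any(pre_idx) || e - pre_window_s < tt[1L] ||
        e + bin_s * n_bins > tt[length(tt)] + series$interval_s) {
      excluded <- rbind(excluded, data.frame(event_s = e,
                                             reason = "outside series coverage"))
      next
    }
    pre_mean <- mean(series$values[pre_idx])
    bins <- vapply(seq_len(n_bins), function(b) {
      bi <- tt >= e + (b - 1L) * bin_s & tt < e + b * bin_s
      if (!any(bi)) NA_real_ else mean(series$values[bi])
    }, numeric(1))
    deltas <- rbind(deltas, bins - pre_mean)
    included <- c(included, e)
  }
  if (!is.null(deltas))
    dimnames(deltas) <- list(sprintf("event_%g", included),
                             sprintf("bin%02d", seq_len(ncol(deltas))))
  structure(list(deltas = deltas, included = included, excluded = excluded,
                 bin_s = bin_s, n_bins = n_bins, pre_window_s = pre_window_s,
                 mean_delta = if (is.null(deltas)) NULL else colMeans(deltas, na.rm = TRUE)),
            class = "peri_event_delta")
}

#' @export
print.peri_event_delta <- function(x, ...) {
  cat(sprintf("<peri_event_delta> %d included, %d excluded event(s); %d x %g-s post bins\n",
              length(x$included), nrow(x$excluded), x$n_bins, x$bin_s))
  if (!is.null(x$mean_delta))
    cat("  mean delta per bin:", sprintf("%+.3f", x$mean_delta), "\n")
  invisible(x)
}
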