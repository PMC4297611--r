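# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_input(sprintf("'%s' must be a single number", name))
  if (finite && !is.finite(x))
    stop_input(sprintf("'%s' must be finite", name))
  if (positive && x <= 0)
    stop_input(sprintf("'%s' must be > 0", name))
  invisible(x)
}

# Hann window (periodic form is irrelevant at these lengths; symmetric used)
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# sample-exact moving RMS via cumulative sums, centered window, edges padded
# with the nearest valid value
moving_rms <- function(x, n) {
  n <- as.integer(n)
  if (n <= 1L) return(abs(x))
  cs <- cumsum(c(0, x^2))
  m <- length(x) - n + 1L
  if (m < 1L) return(rep(sqrt(mean(x^2)), length(x)))
  v <- (cs[(n + 1L):(length(x) + 1L)] - cs[1:m]) / n
  v[v < 0] <- 0
  r <- sqrt(v)
  lead <- (n - 1L) %/% 2L
  c(rep(r[1L], lead), r, rep(r[m], length(x) - m - lead))
}

# format "total (mean +/- sd)" the way per-subject duration summaries are
# tabulated: mean trimmed of trailing zeros at 2 decimals, sd always 2 decimals
format_mean_sd <- function(total, m, s) {
  mtxt <- as.character(round(m, 2))
  if (is.na(s)) return(sprintf("%s", as.character(round(total, 2))))
  sprintf("%s (%s ± %.2f)", as.character(round(total, 2)), mtxt, s)
}

format_latency <- function(hours) {
  if (is.na(hours)) return(NA_character_)
  h <- floor(hours)
  m <- round((hours - h) * 60)
  if (m == 60) { h <- h + 1; m <- 0 }
  sprintf("%d h, %d min", h, m)
}
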