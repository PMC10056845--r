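# Independent sort-and-interpolate quantile oracle (linear interpolation
# between order statistics), written against the textbook formula rather
# than stats::quantile so the package's gap computation has an external
# reference.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_gap <- function(x, lower = 0.05, upper = 0.95) {
  oracle_quantile(x, upper) - oracle_quantile(x, lower)
}

# A vector of length 21 whose type-7 5th and 95th percentiles land exactly
# on the 2nd and 20th order statistics, so printed percentile endpoints can
# be embedded exactly: with n = 21, h = 20 * 0.05 + 1 = 2 (and 20 for 0.95).
vector_with_endpoints <- function(p5, p95) {
  inner <- seq(p5, p95, length.out = 19)
  c(max(p5 - 1, 0), inner, min(p95 + 1, 100))
}
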