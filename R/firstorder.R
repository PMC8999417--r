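#' First-order (histogram) radiomic features
#'
#' The 15 intensity-distribution features: coefficient of variation, mean,
#' variance, skewness (standardized third moment), kurtosis (Pearson,
#' non-excess, by default), Shannon entropy of the fixed-bin histogram, and
#' nine quantiles (0.01 ... 0.99, linear interpolation on the raw values, so
#' they retain sub-bin resolution in mm^2/s).
#'
#' Zero-variance input leaves Skewness and Kurtosis undefined; they are
#' returned as `NA` (flagged, never silently zeroed). CoV is `NA` when the
#' mean is zero.
#'
#' @param adc_values Numeric vector of in-mask ADC values (>= 2 values).
#' @param spec A [discretization_spec()] for the entropy histogram.
#' @param variance_ddof 0 for population variance (default) or 1 for sample.
#' @param kurtosis `"pearson"` (non-excess, default) or `"excess"`.
#' @param entropy_base Logarithm base for entropy (default 2, bits).
#' @return Named numeric vector of the 15 first-order features.
#' @export
first_order_features <- function(adc_values, spec = discretization_spec(),
                                 variance_ddof = 0L,
                                 kurtosis = c("pearson", "excess"),
                                 entropy_base = 2) {
  kurtosis <- match.arg(kurtosis)
  x <- adc_values[is.finite(adc_values)]
  if (length(x) < 2) {
    abort("Need >= 2 finite values for first-order features.",
          class = "adc_error")
  }
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)                       # population central moments
  v <- if (variance_ddof == 0) m2 else m2 * n / (n - 1)
  s <- sqrt(v)
  cov_ <- if (m == 0) NA_real_ else s / m
  if (m2 > 0) {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2
    if (kurtosis == "excess") kurt <- kurt - 3
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  # Entropy over the fixed-bin histogram (0 log 0 = 0).
  lev <- pmin(pmax(floor((x - spec$range_min) / spec$bin_width) + 1, 1),
              spec$n_levels)
  p <- tabulate(lev, nbins = spec$n_levels) / n
  p <- p[p > 0]
  entropy <- -sum(p * log(p, base = entropy_base))
  probs <- c(0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95, 0.99)
  q <- unname(stats::quantile(x, probs = probs, type = 7))
  out <- c(CoV = cov_, Mean = m, Variance = v, Skewness = skew,
           Kurtosis = kurt, Entropy = entropy)
  names(q) <- format(probs, trim = TRUE, drop0trailing = TRUE)
  c(out, q)
}
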