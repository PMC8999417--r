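#' Construct a multi-b-value DWI series
#'
#' @param signal 4-D numeric array `(b, slices, rows, cols)`.
#' @param b_values Diffusion weightings (s/mm^2); at least two distinct
#'   values, matching the first array dimension.
#' @param mask Logical array `(slices, rows, cols)`.
#' @return A `dwi_series` object.
#' @export
dwi_series <- function(signal, b_values, mask) {
  if (length(dim(signal)) != 4 || dim(signal)[1] != length(b_values)) {
    abort("First dimension of `signal` must match `b_values`.",
          class = "adc_error")
  }
  if (length(unique(b_values)) < 2) {
    abort("Need >= 2 distinct b-values.", class = "adc_error")
  }
  if (!identical(dim(signal)[-1], dim(mask))) {
    abort("`mask` shape must match the spatial dimensions of `signal`.",
          class = "adc_error")
  }
  structure(list(signal = signal, b_values = as.numeric(b_values),
                 mask = mask), class = "dwi_series")
}

#' Average repeated DWI acquisitions
#'
#' Arithmetic mean over the repeat axis, the standard multi-repeat averaging
#' used to improve SNR before ADC fitting.
#'
#' @param repeat_stack Either a list of congruent 4-D arrays (one per repeat)
#'   or a 5-D array with repeats on the first dimension.
#' @param b_values,mask Passed through to [dwi_series()].
#' @return A `dwi_series` with the averaged signal.
#' @export
average_repeats <- function(repeat_stack, b_values, mask) {
  if (is.list(repeat_stack)) {
    dims <- lapply(repeat_stack, dim)
    if (length(repeat_stack) < 1 ||
        !all(vapply(dims, identical, TRUE, dims[[1]]))) {
      abort("Repeats must be a nonempty list of congruent arrays.",
            class = "adc_error")
    }
    avg <- Reduce(`+`, repeat_stack) / length(repeat_stack)
  } else {
    d <- dim(repeat_stack)
    if (length(d) != 5) {
      abort("Array input must be 5-D (repeat, b, slices, rows, cols).",
            class = "adc_error")
    }
    avg <- array(colMeans(matrix(repeat_stack, nrow = d[1])), dim = d[-1])
  }
  dwi_series(avg, b_values, mask)
}

#' Fit a voxelwise mono-exponential ADC map
#'
#' Ordinary least squares of `ln S` on `b` per voxel: `ADC = -slope`,
#' `S0 = exp(intercept)`. The fit is closed-form, unweighted, and uses all
#' b-values; no b = 0 image is assumed, so S0 is an extrapolated intercept.
#' Voxels with any nonpositive signal (log undefined) or a negative fitted
#' ADC are removed from the output mask rather than imputed; their count is
#' reported in a message. ADC values above 4e-3 mm^2/s are retained but
#' flagged in the `qc` element.
#'
#' @param dwi A [dwi_series()].
#' @return An `adc_map` object: list with `adc` and `s0` arrays
#'   `(slices, rows, cols)`, a logical `mask` of valid fits, and `qc` (tibble
#'   with per-map diagnostics plus an `r_squared` array).
#' @examples
#' b <- c(200, 300, 500, 700, 1000)
#' sig <- array(0, c(5, 1, 2, 2))
#' for (k in 1:5) sig[k, , , ] <- 800 * exp(-b[k] * 1.8e-3)
#' m <- fit_adc_map(dwi_series(sig, b, array(TRUE, c(1, 2, 2))))
#' range(m$adc)
#' @export
fit_adc_map <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_series"))
  b <- dwi$b_values
  dm <- dim(dwi$signal)[-1]
  idx <- which(dwi$mask)
  if (length(idx) == 0) abort("Empty mask.", class = "adc_error")
  sig <- matrix(dwi$signal, nrow = length(b))[, idx, drop = FALSE]
  pos <- colSums(sig <= 0) == 0
  if (!any(pos)) {
    abort("No voxel has positive signal at every b-value.",
          class = "adc_error")
  }
  y <- log(sig[, pos, drop = FALSE])
  bc <- b - mean(b)
  ssb <- sum(bc^2)
  slope <- as.numeric(crossprod(bc, y)) / ssb
  ybar <- colMeans(y)
  adc_v <- -slope
  s0_v <- exp(ybar - slope * mean(b))  # intercept of the log-linear fit
  # R^2 of the log-linear fit.
  fitted <- outer(bc, slope) + rep(ybar, each = length(b))
  ss_res <- colSums((y - fitted)^2)
  ss_tot <- colSums((y - rep(ybar, each = length(b)))^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, 1)

  # Tolerate roundoff around an exactly-zero slope (constant signal).
  valid <- adc_v >= -1e-12
  adc_v <- pmax(adc_v, 0)
  n_nonpos <- sum(!pos)
  n_negadc <- sum(!valid)
  if (n_nonpos + n_negadc > 0) {
    inform(sprintf(
      "fit_adc_map: dropped %d voxel(s) with nonpositive signal and %d with negative fitted ADC.",
      n_nonpos, n_negadc))
  }
  keep_idx <- idx[pos][valid]
  if (length(keep_idx) == 0) {
    abort("All voxels failed the ADC fit.", class = "adc_error")
  }
  adc <- array(NA_real_, dim = dm); s0 <- array(NA_real_, dim = dm)
  r2a <- array(NA_real_, dim = dm)
  adc[keep_idx] <- adc_v[valid]
  s0[keep_idx] <- s0_v[valid]
  r2a[keep_idx] <- r2[valid]
  mask <- array(FALSE, dim = dm); mask[keep_idx] <- TRUE
  n_flagged <- sum(adc_v[valid] > 4e-3)
  structure(list(
    adc = adc, s0 = s0, mask = mask,
    qc = list(r_squared = r2a,
              summary = tibble::tibble(
                n_voxels = length(keep_idx),
                n_dropped_nonpositive = n_nonpos,
                n_dropped_negative_adc = n_negadc,
                n_flagged_above_range = n_flagged,
                median_r_squared = stats::median(r2[valid])))
  ), class = "adc_map")
}

#' Construct an ADC map from a precomputed grid
#'
#' For workflows that ingest already-fitted parametric maps.
#'
#' @param adc Numeric array `(slices, rows, cols)` in mm^2/s.
#' @param mask Logical array of the same shape.
#' @param s0 Optional S0 array.
#' @return An `adc_map`.
#' @export
adc_map <- function(adc, mask, s0 = NULL) {
  stopifnot(identical(dim(adc), dim(mask)))
  if (!any(mask)) abort("Empty mask.", class = "adc_error")
  if (any(!is.finite(adc[mask])) || any(adc[mask] < 0)) {
    abort("In-mask ADC values must be finite and nonnegative.",
          class = "adc_error")
  }
  structure(list(adc = adc, s0 = s0, mask = mask, qc = NULL),
            class = "adc_map")
}

#' @export
print.adc_map <- function(x, ...) {
  v <- x$adc[x$mask]
  cat(sprintf("<adc_map> %d voxels; ADC median %.3g mm^2/s (range %.3g-%.3g)\n",
              length(v), stats::median(v), min(v), max(v)))
  invisible(x)
}
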