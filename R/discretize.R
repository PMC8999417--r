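#' Fixed-bin-width discretization specification
#'
#' ADC values are binned on an absolute scale: a constant bin width over a
#' fixed physical range, giving every subject the same gray-level axis
#' (default: width 4e-5 over 0 to 4e-3 mm^2/s, i.e. 100 levels).
#'
#' @param bin_width Bin width in mm^2/s.
#' @param range_min,range_max Histogram support in mm^2/s.
#' @return A `discretization_spec` with `n_levels = round((range_max -
#'   range_min) / bin_width)`.
#' @export
discretization_spec <- function(bin_width = 4e-5, range_min = 0,
                                range_max = 4e-3) {
  check_number(bin_width, "bin_width", min = .Machine$double.eps)
  if (range_max <= range_min) {
    abort("`range_max` must exceed `range_min`.", class = "adc_error")
  }
  structure(list(bin_width = bin_width, range_min = range_min,
                 range_max = range_max,
                 n_levels = as.integer(round((range_max - range_min) / bin_width))),
            class = "discretization_spec")
}

#' Discretize an ADC map to 1-based gray levels
#'
#' `level = floor((adc - range_min) / bin_width) + 1`; values at or above
#' `range_max` are clamped into the top level and values below `range_min`
#' into level 1 (the range defines the histogram support, so out-of-range
#' values are clamped, not dropped).
#'
#' @param adc_map An [adc_map()] (or list with `adc` and `mask`).
#' @param spec A [discretization_spec()].
#' @return A `label_image`: list with integer array `levels` (NA outside the
#'   mask), logical `mask`, and `n_levels`.
#' @export
discretize <- function(adc_map, spec = discretization_spec()) {
  mask <- adc_map$mask
  if (!any(mask)) abort("Empty mask.", class = "adc_error")
  v <- adc_map$adc[mask]
  lev <- floor((v - spec$range_min) / spec$bin_width) + 1
  lev <- pmin(pmax(lev, 1L), spec$n_levels)
  levels <- array(NA_integer_, dim = dim(mask))
  levels[mask] <- as.integer(lev)
  structure(list(levels = levels, mask = mask, n_levels = spec$n_levels),
            class = "label_image")
}
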