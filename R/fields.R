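# Gaussian-random-field ADC generator.

# Separable 2-D Gaussian smoothing of a matrix with reflected edges.
smooth_gaussian_2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_reflect <- function(x, r) {
    n <- length(x)
    li <- pmin(pmax(seq(r + 1, 2), 1), n)       # x[r+1] ... x[2]
    ri <- pmin(pmax(seq(n - 1, n - r), 1), n)   # x[n-1] ... x[n-r]
    c(x[li], x, x[ri])
  }
  conv1 <- function(x) {
    xp <- pad_reflect(x, r)
    as.numeric(stats::filter(xp, k, sides = 2))[(r + 1):(r + length(x))]
  }
  m <- apply(m, 2, conv1)          # smooth along rows
  t(apply(m, 1, conv1))            # then along columns
}

#' Generate a spatially correlated true-ADC field inside an ROI
#'
#' Draws white Gaussian noise on the grid, smooths it per slice with a
#' Gaussian kernel of scale `corr_length` (voxels), then affinely rescales the
#' in-mask values so their sample mean and population SD equal `mean_adc` and
#' `sd_adc` exactly (to floating-point precision). Values are finally clipped
#' to the physical range [0, 4e-3] mm^2/s; with the default parameters the
#' clipping probability is negligible, so the calibration survives in
#' practice.
#'
#' @param mask Logical array `(slices, rows, cols)`; must be nonempty.
#' @param mean_adc,sd_adc Target in-mask mean and SD (mm^2/s); `sd_adc = 0`
#'   gives a constant field.
#' @param corr_length Gaussian smoothing scale in voxels (0 = white noise).
#' @param seed Integer seed.
#' @return Numeric array of ADC values (mm^2/s), zero outside the mask.
#' @export
generate_adc_field <- function(mask, mean_adc, sd_adc, corr_length, seed = 1) {
  if (!any(mask)) abort("Empty mask.", class = "adc_error")
  check_number(mean_adc, "mean_adc")
  check_number(sd_adc, "sd_adc", min = 0)
  check_number(corr_length, "corr_length", min = 0)
  dm <- dim(mask)
  out <- array(0, dim = dm)
  if (sd_adc == 0) {
    out[mask] <- mean_adc
    return(out)
  }
  field <- with_seed(child_seed(seed, "adc_field"), {
    f <- array(stats::rnorm(prod(dm)), dim = dm)
    for (s in seq_len(dm[1])) f[s, , ] <- smooth_gaussian_2d(f[s, , ], corr_length)
    f
  })
  v <- field[mask]
  s <- sd_ddof(v, 0L)
  if (s == 0) abort("Degenerate field: zero variance after smoothing.",
                    class = "adc_error")
  v <- mean_adc + (v - mean(v)) * (sd_adc / s)
  out[mask] <- pmin(pmax(v, 0), 4e-3)
  out
}

#' Simulate an averaged multi-b-value DWI stack from a true-ADC field
#'
#' Voxelwise mono-exponential signal `S(b) = S0 * exp(-b * ADC)` with additive
#' zero-mean Gaussian noise per repeat; the returned stack is the per-b mean
#' over repeats, clipped at zero. Outside the mask the signal is zero
#' (background). Averaged multi-repeat data at these SNRs is well approximated
#' by Gaussian noise, so no Rician model is used.
#'
#' @param adc_grid Numeric array `(slices, rows, cols)` of true ADC (mm^2/s).
#' @param mask Logical array, same shape.
#' @param s0_mean Baseline signal S0 (arbitrary units).
#' @param b_values Diffusion weightings (s/mm^2).
#' @param noise_sd Per-repeat additive noise SD (signal units).
#' @param n_repeats Number of repeats averaged.
#' @param seed Integer seed.
#' @return Numeric 4-D array `(b, slices, rows, cols)`.
#' @export
synthesize_dwi <- function(adc_grid, mask, s0_mean, b_values, noise_sd,
                           n_repeats = 5, seed = 1) {
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(n_repeats, "n_repeats", min = 1, integerish = TRUE)
  dm <- dim(adc_grid)
  stopifnot(identical(dm, dim(mask)))
  nb <- length(b_values)
  sig <- array(0, dim = c(nb, dm))
  idx <- which(mask)
  nvox <- length(idx)
  with_seed(child_seed(seed, "dwi_noise"), {
    for (k in seq_len(nb)) {
      clean <- s0_mean * exp(-b_values[k] * adc_grid[idx])
      if (noise_sd > 0) {
        noise <- matrix(stats::rnorm(nvox * n_repeats, 0, noise_sd),
                        nvox, n_repeats)
        obs <- rowMeans(clean + noise)
      } else {
        obs <- clean
      }
      plane <- array(0, dim = dm)
      plane[idx] <- pmax(obs, 0)
      sig[k, , , ] <- plane
    }
  })
  sig
}
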