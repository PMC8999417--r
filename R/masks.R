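#' Generate a synthetic cortical kidney ROI mask
#'
#' Builds a C-shaped elliptical band (a stylized kidney cortex cross-section)
#' on every slice of the grid, placed in the left or right half of the image.
#' The band is connected within each slice, nonempty on all slices, and the
#' left/right masks occupy disjoint column ranges. Anatomical realism is not a
#' goal; the shape exists to give texture features a realistic support.
#'
#' @param grid_shape Integer vector `(slices, rows, cols)`.
#' @param side `"left"` or `"right"`. Left masks live entirely in columns
#'   `< cols/2`, right masks in columns `> cols/2`.
#' @param seed Integer seed controlling the small per-slice jitter of the band.
#' @param target_voxels Approximate total in-mask voxel count over all slices.
#' @return A logical array `(slices, rows, cols)`.
#' @export
generate_kidney_mask <- function(grid_shape, side = c("left", "right"),
                                 seed = 1, target_voxels = 1500) {
  side <- match.arg(side)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1)) {
    abort("`grid_shape` must be (slices, rows, cols).", class = "adc_error")
  }
  ns <- grid_shape[1]; nr <- grid_shape[2]; nc <- grid_shape[3]

  # Band geometry: inner radius 0.55, medial notch of half-angle 50 degrees.
  r_in <- 0.55
  cos_notch <- cos(50 * pi / 180)
  kept_frac <- pi * (1 - r_in^2) * (1 - 100 / 360)
  aspect <- (0.35 * nr) / (0.12 * nc)     # semi-axis ratio a/b
  b_ax <- sqrt(target_voxels / ns / kept_frac / aspect)
  a_ax <- aspect * b_ax
  # Keep the band inside its half of the image.
  a_ax <- min(a_ax, 0.45 * nr)
  b_ax <- min(b_ax, 0.22 * nc)
  if (a_ax < 1 || b_ax < 1) {
    abort("Grid too small to contain the ROI band.", class = "adc_error")
  }
  cc0 <- if (side == "left") 0.25 * nc else 0.75 * nc
  rr0 <- 0.5 * nr
  medial <- if (side == "left") 1 else -1  # +col is medial for the left kidney

  mask <- with_seed(child_seed(seed, paste0("mask_", side)), {
    out <- array(FALSE, dim = grid_shape)
    for (s in seq_len(ns)) {
      rr <- rr0 + stats::rnorm(1, 0, 0.8)
      cc <- cc0 + stats::rnorm(1, 0, 0.8)
      sa <- a_ax * stats::runif(1, 0.95, 1.05)
      sb <- b_ax * stats::runif(1, 0.95, 1.05)
      rows <- matrix(seq_len(nr), nr, nc)
      cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      u <- (rows - rr) / sa
      v <- (cols - cc) / sb
      rho <- sqrt(u^2 + v^2)
      in_band <- rho >= r_in & rho <= 1
      cosang <- ifelse(rho > 0, medial * v / rho, 0)
      sl <- in_band & cosang < cos_notch
      # Clamp to the correct image half so left/right never overlap.
      if (side == "left") sl[, seq_len(nc) >= nc / 2] <- FALSE
      else sl[, seq_len(nc) <= nc / 2] <- FALSE
      out[s, , ] <- sl
    }
    out
  })
  if (sum(mask) < 200 || any(apply(mask, 1, sum) == 0)) {
    abort("Grid too small: ROI band has fewer than 200 voxels or empty slices.",
          class = "adc_error")
  }
  mask
}
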