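# Gray level run length matrices and their 16 features.

# Maximal equal-level runs within one traversal line; NA (out of mask)
# breaks runs. Returns a 2-column matrix (level, length).
line_runs <- function(line) {
  ok <- !is.na(line)
  if (!any(ok)) return(NULL)
  seg_id <- cumsum(!ok)[ok]            # contiguous in-mask segments
  res <- lapply(split(line[ok], seg_id), function(seg) {
    r <- rle(seg)
    cbind(level = r$values, length = r$lengths)
  })
  do.call(rbind, res)
}

#' Compute a gray level run length matrix
#'
#' Counts maximal runs of equal gray level along one planar direction within
#' each slice (runs break at mask boundaries and never cross slices), summed
#' over slices.
#'
#' @param labels A `label_image` from [discretize()].
#' @param direction One of `0, 45, 90, 135` degrees (rows, anti-diagonals,
#'   columns, diagonals).
#' @return A `run_matrix`: list with count matrix `R` (n_levels x
#'   max_run_length), `direction`, `n_runs`, and `n_pixels` (in-mask voxel
#'   count).
#' @export
compute_glrlm <- function(labels, direction = 0) {
  stopifnot(inherits(labels, "label_image"))
  if (!any(labels$mask)) abort("Empty mask.", class = "adc_error")
  glcm_offset(direction)  # validates the direction
  ng <- labels$n_levels
  ns <- dim(labels$levels)[1]
  all_runs <- list()
  for (s in seq_len(ns)) {
    lev <- array(labels$levels[s, , ], dim = dim(labels$levels)[2:3])
    lines <- switch(as.character(direction),
      "0"   = lapply(seq_len(nrow(lev)), function(r) lev[r, ]),
      "90"  = lapply(seq_len(ncol(lev)), function(c) lev[, c]),
      # 45 degrees: anti-diagonals (constant row+col); 135: diagonals.
      "45"  = split(lev, row(lev) + col(lev)),
      "135" = split(lev, row(lev) - col(lev))
    )
    runs <- lapply(lines, line_runs)
    all_runs[[s]] <- do.call(rbind, runs[!vapply(runs, is.null, TRUE)])
  }
  runs <- do.call(rbind, all_runs)
  if (is.null(runs) || nrow(runs) == 0) {
    abort("No in-mask runs found.", class = "adc_error")
  }
  max_run <- max(runs[, "length"])
  R <- matrix(0, ng, max_run)
  tab <- tabulate(runs[, "level"] + (runs[, "length"] - 1) * ng,
                  nbins = ng * max_run)
  R <- matrix(tab, ng, max_run)
  structure(list(R = R, direction = direction, n_runs = sum(R),
                 n_pixels = sum(labels$mask)),
            class = "run_matrix")
}

#' The 16 GLRLM texture features
#'
#' Standard run-length statistics: with `r_i`/`r_j` the level/length
#' marginals of the count matrix `R`, `Nr` the run count, `Np` the in-mask
#' pixel count and `p = R / Nr`. Run entropy uses log base 2.
#'
#' @param runmat A `run_matrix` from [compute_glrlm()].
#' @param entropy_base Logarithm base (default 2).
#' @return Named numeric vector of 16 features (all `NA` if `n_runs` is 0).
#' @export
glrlm_features <- function(runmat, entropy_base = 2) {
  nms <- feature_names_glrlm()
  nr_runs <- runmat$n_runs
  if (is.null(nr_runs) || nr_runs == 0) {
    return(stats::setNames(rep(NA_real_, length(nms)), nms))
  }
  R <- runmat$R
  ng <- nrow(R); mj <- ncol(R)
  i <- seq_len(ng); j <- seq_len(mj)
  ri <- rowSums(R); rj <- colSums(R)
  np <- runmat$n_pixels
  p <- R / nr_runs

  sre <- sum(rj / j^2) / nr_runs
  lre <- sum(rj * j^2) / nr_runs
  glnu <- sum(ri^2) / nr_runs
  glnu_norm <- sum(ri^2) / nr_runs^2
  rlnu <- sum(rj^2) / nr_runs
  rlnu_norm <- sum(rj^2) / nr_runs^2
  run_perc <- nr_runs / np

  pi_ <- ri / nr_runs; pj_ <- rj / nr_runs
  mu_i <- sum(i * pi_)
  gl_var <- sum((i - mu_i)^2 * pi_)
  mu_j <- sum(j * pj_)
  rl_var <- sum((j - mu_j)^2 * pj_)
  pv <- p[p > 0]
  run_entr <- -sum(pv * log(pv, base = entropy_base))

  i2 <- matrix(i^2, ng, mj)
  j2 <- matrix(j^2, ng, mj, byrow = TRUE)
  lglre <- sum(R / i2) / nr_runs
  hglre <- sum(R * i2) / nr_runs
  srlgle <- sum(R / (i2 * j2)) / nr_runs
  srhgle <- sum(R * i2 / j2) / nr_runs
  lrlgle <- sum(R * j2 / i2) / nr_runs
  lrhgle <- sum(R * i2 * j2) / nr_runs

  stats::setNames(c(sre, lre, glnu, glnu_norm, rlnu, rlnu_norm, run_perc,
                    gl_var, rl_var, run_entr, lglre, hglre, srlgle, srhgle,
                    lrlgle, lrhgle), nms)
}
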