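# Gray level co-occurrence matrices and their 23 features.

glcm_offset <- function(direction) {
  switch(as.character(direction),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         abort("`direction` must be one of 0, 45, 90, 135 (degrees).",
               class = "adc_error"))
}

#' Compute a gray level co-occurrence matrix
#'
#' Counts in-mask voxel pairs at a planar offset (distance 1 by default)
#' within each slice, in both directions (symmetric), sums counts over
#' slices, and normalizes to sum 1. Texture is 2-D per slice: through-slice
#' pairs are never formed.
#'
#' @param labels A `label_image` from [discretize()].
#' @param direction One of `0, 45, 90, 135` (degrees; planar offsets
#'   `(0,1), (-1,1), (-1,0), (-1,-1)` in (row, col)).
#' @param distance Offset length in voxels.
#' @return A `cooc_matrix`: list with normalized symmetric `P`
#'   (n_levels x n_levels), `direction`, `n_pairs` (ordered pair count) and
#'   `empty` flag (no valid pairs).
#' @export
compute_glcm <- function(labels, direction = 0, distance = 1L) {
  stopifnot(inherits(labels, "label_image"))
  if (!any(labels$mask)) abort("Empty mask.", class = "adc_error")
  off <- glcm_offset(direction) * as.integer(distance)
  ng <- labels$n_levels
  counts <- matrix(0, ng, ng)
  ns <- dim(labels$levels)[1]
  for (s in seq_len(ns)) {
    lev <- array(labels$levels[s, , ], dim = dim(labels$levels)[2:3])
    nr <- nrow(lev); nc <- ncol(lev)
    r1 <- max(1, 1 - off[1]):min(nr, nr - off[1])
    c1 <- max(1, 1 - off[2]):min(nc, nc - off[2])
    if (length(r1) < 1 || length(c1) < 1) next
    a <- lev[r1, c1, drop = FALSE]
    b <- lev[r1 + off[1], c1 + off[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- tabulate(a[ok] + (b[ok] - 1L) * ng, nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng)
  }
  counts <- counts + t(counts)      # symmetric: count both orderings
  n_pairs <- sum(counts)
  P <- if (n_pairs > 0) counts / n_pairs else counts
  structure(list(P = P, direction = direction, n_pairs = n_pairs,
                 n_levels = ng, empty = n_pairs == 0),
            class = "cooc_matrix")
}

#' The 23 GLCM texture features
#'
#' Standard co-occurrence statistics on a normalized symmetric matrix `P`
#' with `Ng` gray levels: with `p_x` the row marginal, `mu = JointAvg =
#' sum(i * P)`, difference marginal `p_(x-y)` over `k = |i-j|` and sum
#' marginal `p_(x+y)` over `k = i+j`. Entropies use log base 2. The
#' normalized inverse-difference features divide by the full fixed-bin `Ng`
#' (the discretization defines an absolute scale), not the occupied range.
#'
#' @param cooc A `cooc_matrix` from [compute_glcm()].
#' @param entropy_base Logarithm base (default 2).
#' @return Named numeric vector of 23 features (`NA` for features undefined
#'   on degenerate input, e.g. GLCMCor when a marginal SD is 0; all `NA` if
#'   the matrix is empty).
#' @export
glcm_features <- function(cooc, entropy_base = 2) {
  nms <- feature_names_glcm()
  if (isTRUE(cooc$empty)) {
    return(stats::setNames(rep(NA_real_, length(nms)), nms))
  }
  P <- cooc$P
  ng <- cooc$n_levels
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  lg <- function(x) log(x, base = entropy_base)
  ent <- function(p) { p <- p[p > 0]; -sum(p * lg(p)) }

  px <- rowSums(P)                      # symmetric, so py = px
  mu <- sum(i * P)                      # joint average (= mean of p_x)
  sigx2 <- sum((seq_len(ng) - mu)^2 * px)

  joint_max <- max(P)
  joint_var <- sum((i - mu)^2 * P)
  joint_entr <- ent(P)
  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  aucor <- sum(i * j * P)
  correlation <- if (sigx2 > 0) (aucor - mu^2) / sigx2 else NA_real_

  dev <- i + j - 2 * mu
  clst_tend <- sum(dev^2 * P)
  clst_shade <- sum(dev^3 * P)
  clst_prom <- sum(dev^4 * P)

  k_diff <- abs(i - j)
  pd <- as.vector(rowsum(as.vector(P), as.vector(k_diff)))  # k = 0..Ng-1
  kd <- 0:(ng - 1)
  diff_avg <- sum(kd * pd)
  diff_var <- sum((kd - diff_avg)^2 * pd)
  diff_entr <- ent(pd)

  k_sum <- i + j
  ps <- as.vector(rowsum(as.vector(P), as.vector(k_sum)))   # k = 2..2Ng
  ks <- 2:(2 * ng)
  sum_avg <- sum(ks * ps)
  sum_ent <- ent(ps)

  inv_diff <- sum(P / (1 + k_diff))
  inv_diff_norm <- sum(P / (1 + k_diff / ng))
  inv_diff_mom <- sum(P / (1 + (i - j)^2))
  inv_diff_mom_norm <- sum(P / (1 + ((i - j) / ng)^2))
  off_diag <- k_diff > 0
  inv_var <- sum(P[off_diag] / (i[off_diag] - j[off_diag])^2)

  hx <- ent(px)
  hxy <- joint_entr
  pxy <- outer(px, px)
  pos <- P > 0
  hxy1 <- -sum(P[pos] * lg(pxy[pos]))
  pos2 <- pxy > 0
  hxy2 <- -sum(pxy[pos2] * lg(pxy[pos2]))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else NA_real_
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))

  stats::setNames(c(aucor, mu, clst_prom, clst_shade, clst_tend, contrast,
                    correlation, diff_avg, diff_entr, diff_var, asm,
                    joint_entr, imc1, imc2, inv_diff_mom, inv_diff_mom_norm,
                    inv_diff, inv_diff_norm, inv_var, joint_max, sum_avg,
                    sum_ent, joint_var), nms)
}
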