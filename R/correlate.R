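#' Spearman correlation map with strength categories
#'
#' Computes pairwise Spearman rho and two-sided p-values between two column
#' sets of a cohort table (pairwise-complete observations). Significant
#' correlations (p < alpha) are categorized by the absolute rho bands
#' strong [0.7, 1.0], moderate [0.3, 0.7), weak [0, 0.3) (closed lower
#' bounds), signed pos/neg; non-significant entries are `ns`.
#'
#' @param table A data frame (e.g. from [cohort_features()]).
#' @param columns_a Character vector of column names (rows of the map).
#' @param columns_b Column names for the map's columns; defaults to
#'   `columns_a` (a symmetric feature-feature map).
#' @param alpha Significance level (default 0.05).
#' @return A `correlation_map`: list with matrices `rho`, `p`, `category`,
#'   plus `alpha` and a `symmetric` flag. Constant columns give `NA` rho and
#'   are marked `ns` with a warning.
#' @export
spearman_map <- function(table, columns_a, columns_b = columns_a,
                         alpha = 0.05) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(unique(c(columns_a, columns_b)), names(table))
  if (length(missing_cols)) {
    abort(paste0("Columns not in table: ", paste(missing_cols, collapse = ", ")),
          class = "adc_error")
  }
  symmetric <- identical(columns_a, columns_b)
  na_ <- length(columns_a); nb_ <- length(columns_b)
  rho <- p <- matrix(NA_real_, na_, nb_, dimnames = list(columns_a, columns_b))
  warned <- FALSE
  for (ia in seq_len(na_)) {
    jb_start <- if (symmetric) ia else 1L
    for (jb in jb_start:nb_) {
      x <- table[[columns_a[ia]]]
      y <- table[[columns_b[jb]]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3) next
      if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
        warned <- TRUE
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      rho[ia, jb] <- unname(ct$estimate)
      p[ia, jb] <- ct$p.value
      if (symmetric) { rho[jb, ia] <- rho[ia, jb]; p[jb, ia] <- p[ia, jb] }
    }
  }
  if (warned) warn("Constant column(s): some correlations undefined, marked ns.")
  if (symmetric) { diag(rho) <- 1; diag(p) <- 0 }
  category <- matrix("ns", na_, nb_, dimnames = dimnames(rho))
  sig <- !is.na(p) & p < alpha & !is.na(rho)
  band <- function(r) {
    ifelse(abs(r) >= 0.7, "strong", ifelse(abs(r) >= 0.3, "moderate", "weak"))
  }
  category[sig] <- paste0(band(rho[sig]), "/",
                          ifelse(rho[sig] >= 0, "pos", "neg"))
  structure(list(rho = rho, p = p, category = category, alpha = alpha,
                 symmetric = symmetric),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cts <- categorize_counts(x)
  cat(sprintf("<correlation_map> %d x %d (%s); %d distinct pairs, %d significant at alpha = %g\n",
              nrow(x$rho), ncol(x$rho),
              if (x$symmetric) "symmetric" else "rectangular",
              attr(cts, "n_pairs"), attr(cts, "n_significant"), x$alpha))
  invisible(x)
}

#' Count significant correlations by strength category
#'
#' Counts over distinct unordered pairs only (upper triangle for a symmetric
#' map, the diagonal excluded; all cells for a rectangular map).
#'
#' @param map A [spearman_map()] result.
#' @return A tibble with `strength` (strong/moderate/weak), `sign`
#'   (pos/neg) and `n`; attributes `n_pairs` (distinct pairs evaluated) and
#'   `n_significant` (total significant).
#' @export
categorize_counts <- function(map) {
  stopifnot(inherits(map, "correlation_map"))
  cat_ <- map$category
  cells <- if (map$symmetric) cat_[upper.tri(cat_)] else as.vector(cat_)
  grid <- tidyr::expand_grid(strength = c("strong", "moderate", "weak"),
                             sign = c("pos", "neg"))
  grid$n <- purrr::map2_int(grid$strength, grid$sign, function(s, g) {
    sum(cells == paste0(s, "/", g))
  })
  structure(grid,
            n_pairs = length(cells),
            n_significant = sum(cells != "ns"))
}

#' @rdname tidiers
#' @method tidy correlation_map
#' @export
tidy.correlation_map <- function(x, ...) {
  df <- tibble::tibble(
    var_a = rep(rownames(x$rho), times = ncol(x$rho)),
    var_b = rep(colnames(x$rho), each = nrow(x$rho)),
    rho = as.vector(x$rho),
    p.value = as.vector(x$p),
    category = as.vector(x$category)
  )
  if (x$symmetric) {
    keep <- as.vector(upper.tri(x$rho))
    df <- df[keep, ]
  }
  df
}
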