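#' Correlation distance between two vectors
#'
#' `1 - Pearson correlation`: 0 for identical patterns, 1 for uncorrelated,
#' 2 for perfectly opposite patterns. Invariant to positive affine
#' transforms of either argument.
#'
#' @param u,v Numeric vectors of equal length with nonzero centered norm.
#' @return A scalar in \[0, 2\].
#' @export
correlation_distance <- function(u, v) {
  if (length(u) != length(v) || length(u) < 2) {
    abort("`u` and `v` must be equal-length vectors (length >= 2).",
          class = "adc_error")
  }
  uc <- u - mean(u); vc <- v - mean(v)
  nu <- sqrt(sum(uc^2)); nv <- sqrt(sum(vc^2))
  if (nu == 0 || nv == 0) {
    abort("Zero centered norm: correlation distance undefined.",
          class = "adc_error")
  }
  1 - sum(uc * vc) / (nu * nv)
}

# Full pairwise correlation-distance matrix over matrix rows.
correlation_dist_matrix <- function(m) {
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("Constant row(s), distance undefined: ",
                 paste(which(sds == 0), collapse = ", ")),
          class = "adc_error")
  }
  stats::as.dist(1 - stats::cor(t(m)))
}

#' Agglomerative clustering of subjects under correlation distance
#'
#' Hierarchical clustering of the Z-scored subject rows with
#' 1 - Pearson correlation as the dissimilarity (average linkage by
#' default). The two-cluster labels come from cutting at the final merge;
#' the feature columns are ordered by the same procedure applied to the
#' transposed matrix, giving the row/column orders of a cluster heat map.
#'
#' @param norm A [zscore_normalize()] result (or a numeric matrix of
#'   subjects x features).
#' @param linkage `"average"` (default), `"complete"`, `"single"`, or
#'   `"ward.D2"`.
#' @return A `phenotype_tree`: list with the subject `hclust` tree,
#'   two-cluster `labels` (in input row order), `row_order`, `col_order`,
#'   the feature tree `col_hclust`, the Z matrix, and the linkage used.
#' @export
hierarchical_cluster <- function(norm,
                                 linkage = c("average", "complete",
                                             "single", "ward.D2")) {
  linkage <- match.arg(linkage)
  z <- if (inherits(norm, "normalized_table")) norm$z else as.matrix(norm)
  if (nrow(z) < 2) abort("Need >= 2 subjects.", class = "adc_error")
  hc <- stats::hclust(correlation_dist_matrix(z), method = linkage)
  labels <- stats::cutree(hc, k = 2)
  col_hc <- if (ncol(z) >= 2) {
    stats::hclust(correlation_dist_matrix(t(z)), method = linkage)
  }
  structure(list(
    hclust = hc, labels = as.integer(labels),
    row_order = hc$order,
    col_order = if (is.null(col_hc)) seq_len(ncol(z)) else col_hc$order,
    col_hclust = col_hc, z = z, linkage = linkage
  ), class = "phenotype_tree")
}

#' @export
print.phenotype_tree <- function(x, ...) {
  cat(sprintf("<phenotype_tree> %d subjects, %s linkage; 2-cluster cut: %d / %d\n",
              nrow(x$z), x$linkage, sum(x$labels == 1), sum(x$labels == 2)))
  invisible(x)
}

#' Export the heat-map-ready matrix of a clustering
#'
#' @param tree A [hierarchical_cluster()] result.
#' @return A tibble in long format: `subject`, `feature`, `z`, with subjects
#'   and features ordered by their dendrogram orders (as factor levels).
#' @export
heatmap_matrix <- function(tree) {
  z <- tree$z[tree$row_order, tree$col_order, drop = FALSE]
  subj <- rownames(z) %||% as.character(tree$row_order)
  feat <- colnames(z) %||% as.character(tree$col_order)
  tibble::tibble(
    subject = factor(rep(subj, times = ncol(z)), levels = subj),
    feature = factor(rep(feat, each = nrow(z)), levels = feat),
    z = as.vector(z)
  )
}
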