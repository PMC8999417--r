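#' Z-score normalization of a feature table
#'
#' Column-wise standardization `Z = (x - mean) / SD`, with the population SD
#' (ddof 0) by default. The transform is stored so it can be
#' inverted with [zscore_inverse()].
#'
#' @param table A data frame or numeric matrix (subjects x features).
#' @param columns Feature columns to use when `table` is a data frame;
#'   defaults to the 54-feature registry columns present.
#' @param ddof 0 (population SD, default) or 1 (sample SD).
#' @return A `normalized_table`: list with matrix `z` (rownames = subject
#'   ids when available), and the per-feature `center` and `scale` used.
#' @export
zscore_normalize <- function(table, columns = NULL, ddof = 0L) {
  if (is.data.frame(table)) {
    if (is.null(columns)) {
      columns <- intersect(feature_registry()$feature, names(table))
    }
    m <- as.matrix(table[, columns, drop = FALSE])
    if ("subject_id" %in% names(table)) rownames(m) <- table$subject_id
  } else {
    m <- as.matrix(table)
  }
  if (nrow(m) < 2) abort("Need >= 2 subjects.", class = "adc_error")
  if (any(!is.finite(m))) {
    abort("Feature matrix contains missing/non-finite values.",
          class = "adc_error")
  }
  center <- colMeans(m)
  scale_ <- apply(m, 2, sd_ddof, ddof = as.integer(ddof))
  zero <- which(scale_ == 0)
  if (length(zero)) {
    abort(paste0("Zero-SD feature column(s): ",
                 paste(colnames(m)[zero], collapse = ", ")),
          class = "adc_error")
  }
  z <- sweep(sweep(m, 2, center), 2, scale_, "/")
  structure(list(z = z, center = center, scale = scale_, ddof = ddof),
            class = "normalized_table")
}

#' Invert a Z-score normalization
#'
#' @param norm A [zscore_normalize()] result.
#' @param z Optional matrix of Z-scores to back-transform; defaults to
#'   `norm$z`.
#' @return The matrix on the original scale.
#' @export
zscore_inverse <- function(norm, z = norm$z) {
  sweep(sweep(z, 2, norm$scale, "*"), 2, norm$center, "+")
}

#' @export
print.normalized_table <- function(x, ...) {
  cat(sprintf("<normalized_table> %d subjects x %d features (ddof %d)\n",
              nrow(x$z), ncol(x$z), x$ddof))
  invisible(x)
}
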