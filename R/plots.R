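# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   geom_vline labs scale_fill_gradient2 theme_minimal theme element_blank
#'   element_text
NULL

#' Plot a correlation map
#'
#' Heat map of Spearman rho with non-significant cells blanked, the usual
#' display for feature-feature association structure.
#'
#' @param object A [spearman_map()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot correlation_map
#' @export
autoplot.correlation_map <- function(object, ...) {
  df <- tibble::tibble(
    var_a = factor(rep(rownames(object$rho), times = ncol(object$rho)),
                   levels = rownames(object$rho)),
    var_b = factor(rep(colnames(object$rho), each = nrow(object$rho)),
                   levels = colnames(object$rho)),
    rho = as.vector(object$rho),
    significant = as.vector(object$p) < object$alpha
  )
  df$rho[!df$significant %in% TRUE] <- NA
  ggplot(df, aes(x = .data$var_b, y = .data$var_a, fill = .data$rho)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         limits = c(-1, 1), na.value = "grey92") +
    labs(x = NULL, y = NULL, fill = "Spearman ρ",
         title = sprintf("Significant correlations (p < %g)", object$alpha)) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1,
                                     size = 6),
          axis.text.y = element_text(size = 6))
}

#' Plot a BIC curve
#'
#' BIC versus the number of mixture components, with the selected minimum
#' marked.
#'
#' @param object A [gmm_bic_select()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot gmm_bic
#' @export
autoplot.gmm_bic <- function(object, ...) {
  ggplot(object$bic_curve, aes(x = .data$k, y = .data$bic)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = object$best_k, linetype = "dashed") +
    labs(x = "Number of clusters", y = "BIC",
         title = sprintf("GMM-BIC scan (best k = %d)", object$best_k)) +
    theme_minimal()
}

#' Plot the clustered Z-score heat map
#'
#' Subjects-by-features heat map in dendrogram order, the standard phenotype
#' display.
#'
#' @param object A [hierarchical_cluster()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot phenotype_tree
#' @export
autoplot.phenotype_tree <- function(object, ...) {
  df <- heatmap_matrix(object)
  ggplot(df, aes(x = .data$feature, y = .data$subject, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "#313695", mid = "white", high = "#A50026") +
    labs(x = NULL, y = NULL, fill = "Z") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1,
                                     size = 6),
          axis.text.y = element_text(size = 6))
}

#' Plot a forward-selection AUC path
#'
#' @param object A [forward_select_logistic()] trace.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot selection_trace
#' @export
autoplot.selection_trace <- function(object, ...) {
  df <- tidy.selection_trace(object)
  ggplot(df, aes(x = .data$step, y = .data$auc)) +
    geom_line() + geom_point() +
    labs(x = "Selection step", y = "In-sample AUC-ROC",
         title = paste("Forward selection:",
                       paste(object$selected, collapse = " → "))) +
    theme_minimal()
}
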