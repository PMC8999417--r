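#' Normality-routed two-group comparison
#'
#' Shapiro-Wilk on each group at `alpha_normality`; if both groups pass, a
#' Welch two-sample t-test with mean +/- SD summaries, otherwise a Wilcoxon
#' rank-sum test with median (IQR) summaries. A constant group is treated as
#' non-normal. The routing is deterministic: the same data always yields the
#' same test and p-value.
#'
#' @param table A data frame.
#' @param variable Column name of the continuous variable.
#' @param grouping Column name of a two-level grouping variable.
#' @param alpha_normality Shapiro-Wilk significance level (default 0.05).
#' @return A one-row tibble: `variable`, `test` ("t" or "wilcoxon"),
#'   `statistic`, `p.value`, per-group `n`, location and spread summaries
#'   (mean/sd under the t route, median/IQR bounds under the Wilcoxon
#'   route), and a formatted `summary_1` / `summary_2` pair.
#' @export
group_compare <- function(table, variable, grouping,
                          alpha_normality = 0.05) {
  g <- table[[grouping]]
  x <- table[[variable]]
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- as.character(g[ok])
  lev <- sort(unique(g))
  if (length(lev) != 2) {
    abort(sprintf("`%s` must have exactly two non-missing levels.", grouping),
          class = "adc_error")
  }
  x1 <- x[g == lev[1]]; x2 <- x[g == lev[2]]
  if (length(x1) < 3 || length(x2) < 3) {
    abort("Both groups need >= 3 non-missing observations.",
          class = "adc_error")
  }
  normal <- function(v) {
    if (stats::var(v) == 0 || length(v) < 3) return(FALSE)
    stats::shapiro.test(v)$p.value >= alpha_normality
  }
  use_t <- normal(x1) && normal(x2)
  if (use_t) {
    ht <- stats::t.test(x1, x2)       # Welch by default
    summ <- function(v) sprintf("%.3g ± %.3g", mean(v), stats::sd(v))
    loc <- c(mean(x1), mean(x2)); spread_lo <- c(stats::sd(x1), stats::sd(x2))
    spread_hi <- spread_lo
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x1, x2, exact = FALSE))
    iqr <- function(v) stats::quantile(v, c(0.25, 0.75), type = 7)
    summ <- function(v) {
      q <- iqr(v); sprintf("%.3g (%.3g-%.3g)", stats::median(v), q[1], q[2])
    }
    loc <- c(stats::median(x1), stats::median(x2))
    spread_lo <- c(iqr(x1)[1], iqr(x2)[1])
    spread_hi <- c(iqr(x1)[2], iqr(x2)[2])
  }
  tibble::tibble(
    variable = variable,
    test = if (use_t) "t" else "wilcoxon",
    statistic = unname(ht$statistic),
    p.value = ht$p.value,
    group_1 = lev[1], group_2 = lev[2],
    n_1 = length(x1), n_2 = length(x2),
    location_1 = loc[1], location_2 = loc[2],
    spread_lo_1 = spread_lo[1], spread_hi_1 = spread_hi[1],
    spread_lo_2 = spread_lo[2], spread_hi_2 = spread_hi[2],
    summary_1 = summ(x1), summary_2 = summ(x2)
  )
}

#' Compare many variables between two groups
#'
#' @param table A data frame.
#' @param variables Character vector of variable columns; defaults to the 54
#'   radiomic features present in the table.
#' @param grouping Grouping column name.
#' @param ... Passed to [group_compare()].
#' @return A tibble with one [group_compare()] row per variable; variables
#'   with fewer than 3 observations per group are skipped with a warning.
#' @export
group_compare_all <- function(table, variables = NULL, grouping = "group",
                              ...) {
  if (is.null(variables)) {
    variables <- intersect(feature_registry()$feature, names(table))
  }
  rows <- purrr::map(variables, function(v) {
    tryCatch(group_compare(table, v, grouping, ...),
             adc_error = function(e) {
               warn(sprintf("Skipping `%s`: %s", v, conditionMessage(e)))
               NULL
             })
  })
  dplyr::bind_rows(rows)
}

#' Per-cluster comparison of clinical and radiomic variables
#'
#' Re-uses the normality-routed [group_compare()] for every clinical and
#' radiomic variable between the two phenotype clusters, and reports each
#' cluster's size and CKD fraction. Clusters are named so that cluster 1 has
#' the lower mean eGFR.
#'
#' @param table A cohort table (from [cohort_features()]) containing a
#'   `group` column with values `healthy` / `ckd`.
#' @param labels Integer cluster labels (1/2), aligned with the table rows.
#' @return A `cluster_comparison`: list with `cluster_summary` (n, CKD
#'   fraction, mean eGFR per cluster) and `comparisons` (the per-variable
#'   tibble; flagged `NULL` rows are dropped with a warning when a cluster
#'   has < 3 members for that variable).
#' @export
cluster_compare <- function(table, labels) {
  stopifnot(nrow(table) == length(labels))
  labels <- order_clusters_by_egfr(labels, table$egfr)
  tab <- dplyr::mutate(table, .cluster = factor(labels))
  summary <- dplyr::summarise(
    dplyr::group_by(tab, .data$.cluster),
    n = dplyr::n(),
    n_ckd = sum(.data$group == "ckd"),
    ckd_fraction = mean(.data$group == "ckd"),
    mean_egfr = mean(.data$egfr, na.rm = TRUE),
    .groups = "drop"
  )
  clinical_vars <- intersect(
    c("age", "sex", "sbp", "dbp", "egfr", "bmi", "egfr_slope",
      "proteinuria", "glucose"), names(tab))
  feature_vars <- intersect(feature_registry()$feature, names(tab))
  comparisons <- suppressWarnings(
    group_compare_all(tab, c(clinical_vars, feature_vars), ".cluster"))
  structure(list(cluster_summary = summary, comparisons = comparisons),
            class = "cluster_comparison")
}

# Relabel clusters so cluster 1 has the lower mean eGFR (ties or absent
# eGFR keep the input labelling).
order_clusters_by_egfr <- function(labels, egfr = NULL) {
  lev <- sort(unique(labels))
  if (length(lev) != 2 || is.null(egfr)) return(as.integer(labels))
  m1 <- mean(egfr[labels == lev[1]], na.rm = TRUE)
  m2 <- mean(egfr[labels == lev[2]], na.rm = TRUE)
  if (is.finite(m1) && is.finite(m2) && m1 > m2) {
    ifelse(labels == lev[1], 2L, 1L)
  } else {
    ifelse(labels == lev[1], 1L, 2L)
  }
}

#' @export
print.cluster_comparison <- function(x, ...) {
  cat("<cluster_comparison>\n")
  print(x$cluster_summary)
  nsig <- sum(x$comparisons$p.value < 0.05, na.rm = TRUE)
  cat(sprintf("  %d of %d variables differ at p < 0.05\n",
              nsig, nrow(x$comparisons)))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy cluster_comparison
#' @export
tidy.cluster_comparison <- function(x, ...) x$comparisons

#' @rdname tidiers
#' @method glance cluster_comparison
#' @export
glance.cluster_comparison <- function(x, ...) {
  s <- x$cluster_summary
  tibble::tibble(
    n_cluster1 = s$n[1], n_cluster2 = s$n[2],
    ckd_fraction_1 = s$ckd_fraction[1], ckd_fraction_2 = s$ckd_fraction[2],
    n_significant = sum(x$comparisons$p.value < 0.05, na.rm = TRUE),
    n_variables = nrow(x$comparisons)
  )
}
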