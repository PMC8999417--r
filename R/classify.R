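# Forward-selection logistic regression maximizing in-sample AUC-ROC.

#' Mode imputation of missing values
#'
#' Missing entries are replaced by the most frequent non-missing value
#' (continuous values are rounded to `digits` decimal places before
#' mode-finding); ties resolve toward the smallest value.
#'
#' @param values Numeric vector, possibly with `NA`.
#' @param digits Measurement precision used for mode-finding (default 2).
#' @return The vector with `NA` replaced by the mode.
#' @export
impute_mode <- function(values, digits = 2) {
  obs <- values[!is.na(values)]
  if (!length(obs)) abort("All values missing.", class = "adc_error")
  r <- round(obs, digits)
  tab <- table(r)
  best <- as.numeric(names(tab)[tab == max(tab)])
  mode_val <- min(best)
  values[is.na(values)] <- mode_val
  values
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive scores above a random negative,
#' with ties counted one half: the exact pairwise (Mann-Whitney) AUC,
#' computed from midranks.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical or 0/1); both classes required.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) != 2) {
    abort("Both classes must be present.", class = "adc_error")
  }
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity, specificity and accuracy at a probability threshold
#'
#' @param scores Predicted probabilities (or scores).
#' @param labels Binary labels; both classes required.
#' @param threshold Call positive when `score >= threshold` (default 0.5).
#' @return A one-row tibble: `sensitivity`, `specificity`, `accuracy`,
#'   `threshold`.
#' @export
roc_metrics <- function(scores, labels, threshold = 0.5) {
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) != 2) {
    abort("Both classes must be present.", class = "adc_error")
  }
  pred <- as.integer(scores >= threshold)
  tibble::tibble(
    sensitivity = sum(pred == 1 & y == 1) / sum(y == 1),
    specificity = sum(pred == 0 & y == 0) / sum(y == 0),
    accuracy = mean(pred == y),
    threshold = threshold
  )
}

# Fit logistic regression on standardized columns; ridge fallback (glmnet,
# lambda = 1e-4) when maximum likelihood diverges on separable data.
fit_logistic <- function(x, y, ridge_lambda = 1e-4) {
  xs <- scale(x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  df <- data.frame(y = y, xs)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # Warnings alone under-detect separation (glm can converge with fitted
  # probabilities at the boundary); a huge standardized slope is the tell.
  big_coef <- any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)
  if (sep || big_coef || !fit$converged) {
    gfit <- suppressWarnings(
      glmnet::glmnet(cbind(xs, 0), y, family = "binomial",
                     alpha = 0, lambda = ridge_lambda,
                     standardize = FALSE))
    prob <- as.numeric(stats::predict(gfit, newx = cbind(xs, 0),
                                      type = "response"))
    list(prob = prob, separation = TRUE, model = gfit,
         center = attr(xs, "scaled:center"), scale = attr(xs, "scaled:scale"))
  } else {
    list(prob = stats::fitted(fit), separation = FALSE, model = fit,
         center = attr(xs, "scaled:center"), scale = attr(xs, "scaled:scale"))
  }
}

#' Forward feature selection for logistic regression by AUC-ROC
#'
#' Starts from the intercept-only model and, at each step, refits a
#' maximum-likelihood logistic regression for every remaining candidate
#' added to the current set, computing the in-sample AUC-ROC; the candidate
#' with the largest AUC is added if it improves the current AUC by more than
#' `tol`, otherwise selection stops. Ties resolve toward the candidate
#' earlier in `candidate_pool` order. Features are standardized before
#' fitting; perfect separation triggers a small ridge penalty
#' (lambda = 1e-4), which is recorded in the trace.
#'
#' In-sample selection on small cohorts is optimistic; the reported AUC
#' describes fit, not generalization.
#'
#' @param table A data frame with complete candidate columns
#'   (impute first, e.g. [impute_mode()]).
#' @param outcome Name of a binary outcome column (logical or 0/1).
#' @param candidate_pool Character vector of candidate feature columns.
#' @param tol Minimum AUC improvement to continue (default 1e-6).
#' @param threshold Probability threshold for the final report.
#' @return A `selection_trace`: list with `selected` (ordered names), `auc`
#'   (AUC after each addition), `final_auc`, `report` (one-row tibble with
#'   sensitivity/specificity/AUC/accuracy), `coefficients` (on the
#'   standardized scale), `separation` flag, and `pool`.
#' @export
forward_select_logistic <- function(table, outcome, candidate_pool,
                                    tol = 1e-6, threshold = 0.5) {
  y <- as.integer(as.logical(table[[outcome]]))
  if (length(unique(y)) != 2) {
    abort("Outcome must contain both classes.", class = "adc_error")
  }
  miss <- candidate_pool[vapply(candidate_pool,
                                function(v) anyNA(table[[v]]), TRUE)]
  if (length(miss)) {
    abort(paste0("Candidates contain missing values (impute first): ",
                 paste(miss, collapse = ", ")), class = "adc_error")
  }
  selected <- character()
  auc_path <- numeric()
  current_auc <- 0.5               # intercept-only model: no discrimination
  current_prob <- rep(mean(y), length(y))
  sep_any <- FALSE
  repeat {
    remaining <- setdiff(candidate_pool, selected)
    if (!length(remaining)) break
    cand_auc <- vapply(remaining, function(v) {
      x <- as.matrix(table[, c(selected, v), drop = FALSE])
      auc_roc(fit_logistic(x, y)$prob, y)
    }, numeric(1))
    best <- which.max(cand_auc)    # first maximum = earliest in pool order
    if (cand_auc[best] <= current_auc + tol) break
    selected <- c(selected, remaining[best])
    current_auc <- cand_auc[best]
    auc_path <- c(auc_path, current_auc)
  }
  if (length(selected)) {
    fit <- fit_logistic(as.matrix(table[, selected, drop = FALSE]), y)
    current_prob <- fit$prob
    sep_any <- fit$separation
    coefs <- if (inherits(fit$model, "glm")) stats::coef(fit$model) else {
      drop(as.matrix(stats::coef(fit$model)))
    }
  } else {
    coefs <- stats::setNames(stats::qlogis(mean(y)), "(Intercept)")
  }
  metrics <- roc_metrics(current_prob, y, threshold)
  report <- dplyr::bind_cols(
    tibble::tibble(n_selected = length(selected),
                   auc_roc = auc_roc(current_prob, y)),
    metrics
  )
  structure(list(selected = selected, auc = auc_path,
                 final_auc = report$auc_roc, report = report,
                 coefficients = coefs, separation = sep_any,
                 pool = candidate_pool, outcome = outcome,
                 prob = current_prob, labels = y),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> outcome `%s`: %d feature(s) selected, AUC %.3f\n",
              x$outcome, length(x$selected), x$final_auc))
  if (length(x$selected)) {
    cat("  ", paste(sprintf("%s (%.3f)", x$selected, x$auc), collapse = " -> "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @rdname tidiers
#' @method tidy selection_trace
#' @export
tidy.selection_trace <- function(x, ...) {
  tibble::tibble(step = seq_along(x$selected), feature = x$selected,
                 auc = x$auc)
}

#' @rdname tidiers
#' @method glance selection_trace
#' @export
glance.selection_trace <- function(x, ...) x$report

clinical_pool <- function(table) {
  intersect(c("sex", "age", "sbp", "dbp", "egfr", "bmi", "proteinuria",
              "glucose"), names(table))
}

#' Classify CKD vs healthy from radiomic features
#'
#' Forward-selection logistic regression over the 54 radiomic features with
#' CKD status as the outcome.
#'
#' @param table A cohort table from [cohort_features()].
#' @param ... Passed to [forward_select_logistic()].
#' @return A `selection_trace`.
#' @export
build_ckd_model <- function(table, ...) {
  tab <- dplyr::mutate(table, .ckd = .data$group == "ckd")
  forward_select_logistic(tab, ".ckd",
                          intersect(feature_registry()$feature, names(tab)),
                          ...)
}

#' Rapid-progression models: radiomics, clinical, and combined
#'
#' Among CKD subjects only, fits three forward-selection logistic models for
#' rapid vs non-rapid progression: the 54 radiomic features, the baseline
#' clinical features (sex, age, SBP, DBP, eGFR, BMI, mode-imputed
#' proteinuria, glucose), and the union of both.
#'
#' @param table A cohort table from [cohort_features()].
#' @param ... Passed to [forward_select_logistic()].
#' @return A `model_report_set`: list of three `selection_trace`s named
#'   `radiomics`, `clinical`, `combination`, with a `report` tibble
#'   (one row per model: selected features, sensitivity, specificity,
#'   AUC-ROC, accuracy).
#' @export
build_progression_models <- function(table, ...) {
  ckd <- dplyr::filter(table, .data$group == "ckd")
  if (!"rapid" %in% names(ckd) || anyNA(ckd$rapid)) {
    abort("CKD subjects must carry rapid labels.", class = "adc_error")
  }
  if (sum(ckd$rapid) < 3 || sum(!ckd$rapid) < 3) {
    abort("Need >= 3 rapid and >= 3 non-rapid subjects.", class = "adc_error")
  }
  ckd$proteinuria <- impute_mode(ckd$proteinuria)
  radiomic <- intersect(feature_registry()$feature, names(ckd))
  clinical <- clinical_pool(ckd)
  pools <- list(radiomics = radiomic, clinical = clinical,
                combination = c(clinical, radiomic))
  traces <- purrr::imap(pools, function(pool, nm) {
    forward_select_logistic(ckd, "rapid", pool, ...)
  })
  report <- purrr::imap_dfr(traces, function(tr, nm) {
    dplyr::bind_cols(
      tibble::tibble(model = nm,
                     features = paste(tr$selected, collapse = ", ")),
      tr$report
    )
  })
  structure(list(traces = traces, report = report),
            class = "model_report_set")
}

#' @export
print.model_report_set <- function(x, ...) {
  cat("<model_report_set>\n")
  print(x$report[, c("model", "features", "sensitivity", "specificity",
                     "auc_roc")])
  invisible(x)
}

#' @rdname tidiers
#' @method tidy model_report_set
#' @export
tidy.model_report_set <- function(x, ...) x$report
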