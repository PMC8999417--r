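# Feature registry and the 54-feature extractor.

feature_names_first_order <- function() {
  c("CoV", "Mean", "Variance", "Skewness", "Kurtosis", "Entropy",
    "0.01", "0.05", "0.1", "0.25", "0.5", "0.75", "0.9", "0.95", "0.99")
}

feature_names_glcm <- function() {
  c("AuCor", "JointAvg", "ClstProm", "ClstShade", "ClstTend", "GLCMContr",
    "GLCMCor", "DiffAvg", "DiffEntr", "DiffVar", "AngSecMom", "JointEntr",
    "FirstMeasInfoCor", "SecMeasInfoCor", "InvDiffMom", "InvDiffMomNorm",
    "InvDiff", "InvDiffNorm", "InvVar", "JointMax", "SumAvg", "SumEnt",
    "JointVar")
}

feature_names_glrlm <- function() {
  c("ShortRunEmph", "LongRunEmph", "GLNU", "GLNUnorm", "RunLenNU",
    "RunLenNUnorm", "RunPerc", "GLVar", "RunLenVar", "RunEntr",
    "LowGLRunEmph", "HighGLRunEmph", "ShortRunLowGLEmph",
    "ShortRunHighGLEmph", "LongRunLowGLEmph", "LongRunHighGLEmph")
}

#' The canonical 54-feature registry
#'
#' @return A tibble with columns `feature` and `family`
#'   (`first_order` / `glcm` / `glrlm`), in canonical extraction order
#'   (15 + 23 + 16 features).
#' @export
feature_registry <- function() {
  tibble::tibble(
    feature = c(feature_names_first_order(), feature_names_glcm(),
                feature_names_glrlm()),
    family = c(rep("first_order", 15), rep("glcm", 23), rep("glrlm", 16))
  )
}

#' Extract the 54 radiomic features from an ADC map
#'
#' First-order features are computed on the raw in-mask ADC values; GLCM and
#' GLRLM features are computed per planar direction (0, 45, 90, 135 degrees,
#' distance 1, within-slice, counts merged over slices per direction) and
#' averaged over the directions. Directions with no valid pairs/runs are
#' skipped in the average.
#'
#' @param adc_map An [adc_map()] (or the output of [fit_adc_map()]).
#' @param spec A [discretization_spec()].
#' @param distance GLCM offset length in voxels.
#' @param variance_ddof,kurtosis,entropy_base Conventions passed to the
#'   feature computations (population variance, Pearson kurtosis and log2
#'   entropies by default).
#' @return A `feature_vector`: named numeric vector of exactly 54 finite
#'   values in canonical order. A non-finite sub-feature (degenerate input)
#'   raises an error naming the features.
#' @export
extract_features <- function(adc_map, spec = discretization_spec(),
                             distance = 1L, variance_ddof = 0L,
                             kurtosis = "pearson", entropy_base = 2) {
  fo <- first_order_features(adc_map$adc[adc_map$mask], spec,
                             variance_ddof = variance_ddof,
                             kurtosis = kurtosis,
                             entropy_base = entropy_base)
  labels <- discretize(adc_map, spec)
  dirs <- c(0, 45, 90, 135)
  glcm_mat <- sapply(dirs, function(d) {
    glcm_features(compute_glcm(labels, d, distance), entropy_base)
  })
  glrlm_mat <- sapply(dirs, function(d) {
    glrlm_features(compute_glrlm(labels, d), entropy_base)
  })
  avg_dirs <- function(m) {
    ok <- colSums(is.na(m)) < nrow(m)   # drop fully flagged directions
    if (!any(ok)) m[, 1] else rowMeans(m[, ok, drop = FALSE])
  }
  out <- c(fo, avg_dirs(glcm_mat), avg_dirs(glrlm_mat))
  bad <- names(out)[!is.finite(out)]
  if (length(bad)) {
    abort(paste0("Feature extraction failed (non-finite): ",
                 paste(bad, collapse = ", ")),
          class = "adc_extraction_error")
  }
  structure(out, class = "feature_vector")
}

#' Average left and right kidney feature vectors
#'
#' Elementwise arithmetic mean of the two per-kidney feature vectors, the
#' standard bilateral combination into one representative value per subject.
#' The Spearman correlation between the two vectors across the 54 features is
#' attached as a QC value (`attr(, "qc_spearman")`); near-1 values support
#' the combination.
#'
#' @param left,right `feature_vector`s with identical feature sets.
#' @return A `feature_vector` of the means.
#' @export
combine_bilateral <- function(left, right) {
  if (!identical(names(left), names(right))) {
    abort("Left/right feature sets differ.", class = "adc_error")
  }
  out <- (unclass(left) + unclass(right)) / 2
  rho <- suppressWarnings(
    stats::cor(as.numeric(left), as.numeric(right), method = "spearman"))
  structure(out, class = "feature_vector", qc_spearman = rho)
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %d features\n", length(x)))
  print(utils::head(round(unclass(x), 6), 8))
  invisible(x)
}

#' Extract per-subject radiomic features for a whole cohort
#'
#' For each subject: fit ADC maps for both kidneys from the DWI stacks,
#' extract the 54 features per kidney, and average bilaterally. Returns the
#' cohort table used by all downstream analyses.
#'
#' @param cohort An `adc_cohort` from [generate_cohort()].
#' @param spec A [discretization_spec()].
#' @param use_true_adc If `TRUE`, skip DWI fitting and extract from the true
#'   simulated ADC fields (useful for isolating feature behaviour from fit
#'   noise). Default `FALSE`.
#' @param ... Passed to [extract_features()].
#' @return A tibble with `subject_id`, `group`, the clinical covariates, the
#'   54 feature columns in canonical order, and `lr_spearman` (left/right QC
#'   correlation).
#' @export
cohort_features <- function(cohort, spec = discretization_spec(),
                            use_true_adc = FALSE, ...) {
  cfg <- attr(cohort, "config")
  rows <- purrr::map(cohort, function(rec) {
    fv <- lapply(c("left", "right"), function(side) {
      map <- if (use_true_adc) {
        adc_map(rec[[paste0("true_adc_", side)]], rec[[paste0("mask_", side)]])
      } else {
        suppressMessages(fit_adc_map(dwi_series(rec[[paste0("dwi_", side)]],
                                                cfg$b_values,
                                                rec[[paste0("mask_", side)]])))
      }
      extract_features(map, spec, ...)
    })
    comb <- combine_bilateral(fv[[1]], fv[[2]])
    dplyr::bind_cols(
      tibble::tibble(subject_id = rec$subject_id, group = rec$group),
      rec$clinical,
      tibble::as_tibble_row(stats::setNames(as.numeric(comb), names(comb))),
      tibble::tibble(lr_spearman = attr(comb, "qc_spearman"))
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a cohort feature table to CSV with a JSON sidecar
#'
#' @param features Tibble from [cohort_features()].
#' @param path Output CSV path; a `<path>.json` sidecar records the feature
#'   families and units.
#' @return Invisibly, the two paths written.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, na = "")
  reg <- feature_registry()
  sidecar <- list(
    features = reg$feature, family = reg$family,
    units = "first-order Mean/Variance/quantiles in mm^2/s; texture features dimensionless (gray-level scale)"
  )
  jpath <- paste0(path, ".json")
  jsonlite::write_json(sidecar, jpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(path, jpath))
}
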