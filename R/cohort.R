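#' Generate a synthetic kidney DWI cohort
#'
#' Produces one record per subject: left/right 4-D DWI stacks (repeat-averaged,
#' mono-exponential signal with Gaussian noise), cortical ROI masks, the true
#' ADC fields used for simulation, and clinical covariates. Deterministic
#' given the config (per-subject child seeds are derived from `config$seed`,
#' so records do not depend on generation order).
#'
#' @param config A [cohort_config()].
#' @return An object of class `adc_cohort`: a list of subject records, each
#'   with elements `subject_id`, `group`, `dwi_left`, `dwi_right`,
#'   `mask_left`, `mask_right`, `true_adc_left`, `true_adc_right`, and
#'   `clinical` (one-row tibble).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_healthy = 1, n_ckd = 1,
#'                                         grid_shape = c(2, 32, 64),
#'                                         mask_target_voxels = 300))
#' length(cohort)
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  cfg <- config
  groups <- c(rep("healthy", cfg$n_healthy), rep("ckd", cfg$n_ckd))
  n <- length(groups)
  per_kidney <- cfg$mask_target_voxels
  records <- lapply(seq_len(n), function(i) {
    grp <- groups[i]
    sseed <- child_seed(cfg$seed, sprintf("subject_%03d", i))
    rec <- list(subject_id = sprintf("S%03d", i), group = grp)
    for (side in c("left", "right")) {
      mask <- generate_kidney_mask(cfg$grid_shape, side,
                                   seed = child_seed(sseed, side),
                                   target_voxels = per_kidney)
      adc <- generate_adc_field(mask, cfg$adc_mean[[grp]], cfg$adc_sd[[grp]],
                                cfg$corr_length[[grp]],
                                seed = child_seed(sseed, paste0("field_", side)))
      dwi <- synthesize_dwi(adc, mask, cfg$s0_mean, cfg$b_values, cfg$noise_sd,
                            cfg$n_repeats,
                            seed = child_seed(sseed, paste0("dwi_", side)))
      rec[[paste0("mask_", side)]] <- mask
      rec[[paste0("true_adc_", side)]] <- adc
      rec[[paste0("dwi_", side)]] <- dwi
    }
    rec$clinical <- generate_clinical(grp, NA, cfg, seed = sseed)
    structure(rec, class = "subject_record")
  })
  structure(records, class = "adc_cohort", config = cfg)
}

#' @export
print.adc_cohort <- function(x, ...) {
  groups <- vapply(x, `[[`, "", "group")
  cat(sprintf("<adc_cohort> %d subjects (%d healthy, %d ckd)\n",
              length(x), sum(groups == "healthy"), sum(groups == "ckd")))
  invisible(x)
}

#' Clinical covariate table of a cohort
#'
#' @param cohort An `adc_cohort`.
#' @return A tibble, one row per subject, with `subject_id`, `group` and the
#'   clinical covariates (missing values for variables not collected in
#'   healthy subjects).
#' @export
cohort_clinical <- function(cohort) {
  purrr::map_dfr(cohort, function(rec) {
    dplyr::bind_cols(
      tibble::tibble(subject_id = rec$subject_id, group = rec$group),
      rec$clinical
    )
  })
}

#' Write a cohort to disk as NIfTI volumes and a clinical CSV
#'
#' Per subject: `<id>_dwi_<side>.nii` (4-D, reordered to rows x cols x slices
#' x b for NIfTI), `<id>_mask_<side>.nii`, `<id>_adc_<side>.nii`; plus
#' `clinical.csv` (empty fields for missing values) and `b_values.txt`.
#'
#' @param cohort An `adc_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- attr(cohort, "config")
  files <- character()
  for (rec in cohort) {
    for (side in c("left", "right")) {
      base <- file.path(dir, paste0(rec$subject_id, "_"))
      dwi <- aperm(rec[[paste0("dwi_", side)]], c(3, 4, 2, 1))
      f1 <- paste0(base, "dwi_", side, ".nii")
      RNifti::writeNifti(RNifti::asNifti(dwi), f1)
      msk <- aperm(rec[[paste0("mask_", side)]] * 1L, c(2, 3, 1))
      f2 <- paste0(base, "mask_", side, ".nii")
      RNifti::writeNifti(RNifti::asNifti(msk), f2)
      adc <- aperm(rec[[paste0("true_adc_", side)]], c(2, 3, 1))
      f3 <- paste0(base, "adc_", side, ".nii")
      RNifti::writeNifti(RNifti::asNifti(adc), f3)
      files <- c(files, f1, f2, f3)
    }
  }
  clin <- cohort_clinical(cohort)
  fcsv <- file.path(dir, "clinical.csv")
  utils::write.csv(clin, fcsv, row.names = FALSE, na = "")
  fb <- file.path(dir, "b_values.txt")
  writeLines(format(cfg$b_values, trim = TRUE), fb)
  invisible(c(files, fcsv, fb))
}
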