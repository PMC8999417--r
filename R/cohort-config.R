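#' Configuration for the synthetic kidney DWI cohort
#'
#' Bundles every parameter of the synthetic-data generator: cohort composition,
#' acquisition protocol (b-values, repeats, signal level, noise), group-specific
#' cortical ADC statistics and texture correlation length, and the clinical
#' covariate distributions. Defaults emulate a study of 10 healthy volunteers
#' and 30 participants with mild-to-moderate CKD: healthy cortical ADC around
#' 1.83e-3 mm^2/s with coefficient of variation ~0.17 and coarser spatial
#' texture, CKD around 1.75e-3 mm^2/s with CoV ~0.24 and finer texture, eGFR
#' 88.6 +/- 12.6 vs 51.5 +/- 12.2 mL/min/1.73 m^2, BMI 25.8 +/- 2.7 vs
#' 32.4 +/- 7.5 kg/m^2, and an eGFR-slope mixture with a 23% rapid-progressor
#' fraction (components -5.27 +/- 2.61 and 0.92 +/- 2.57, truncated at the
#' -3 mL/min/1.73 m^2/yr threshold so labels and slopes never disagree).
#'
#' @param n_healthy,n_ckd Number of healthy / CKD subjects (n_healthy + n_ckd
#'   must be at least 2).
#' @param seed Integer seed; the cohort is bit-reproducible given the config.
#' @param grid_shape Integer vector `(slices, rows, cols)` of the voxel grid.
#' @param b_values Strictly increasing positive diffusion weightings (s/mm^2).
#' @param n_repeats Number of averaged signal repeats.
#' @param s0_mean Baseline (b = 0 extrapolated) signal level, arbitrary units.
#' @param noise_sd Additive Gaussian noise SD per repeat, signal units.
#' @param adc_mean,adc_sd Named numeric vectors with elements `healthy` and
#'   `ckd`: within-ROI mean and SD of true cortical ADC (mm^2/s).
#' @param corr_length Named numeric vector (`healthy`, `ckd`): Gaussian
#'   smoothing scale of the ADC random field, in voxels (0 = white noise).
#' @param rapid_fraction Proportion of CKD subjects that are rapid progressors.
#' @param egfr_mean,egfr_sd,bmi_mean,bmi_sd,age_mean,age_sd Named (`healthy`,
#'   `ckd`) clinical moments.
#' @param p_female Named (`healthy`, `ckd`) probability that sex = 1 (female).
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd,glucose_mean,glucose_sd CKD-only
#'   clinical moments (healthy values are generated missing).
#' @param slope_rapid_mean,slope_rapid_sd,slope_nonrapid_mean,slope_nonrapid_sd
#'   eGFR-slope mixture components (mL/min/1.73 m^2 per year).
#' @param rapid_threshold Slope at or below which a subject is a rapid
#'   progressor.
#' @param proteinuria_meanlog,proteinuria_sdlog Log-normal parameters of the
#'   nonzero 24 h urine protein component (g/day).
#' @param proteinuria_zero_frac Fraction of CKD proteinuria values that are
#'   exact zeros (the modal value).
#' @param proteinuria_missing_frac Fraction of CKD proteinuria values set
#'   missing.
#' @param mask_target_voxels Approximate in-mask voxel count per kidney,
#'   summed over slices (the cortical ROI size is not standardized; ~1500 is
#'   the default and it is a config value, never hard-coded downstream).
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_healthy = 10,
                          n_ckd = 30,
                          seed = 7,
                          grid_shape = c(5L, 64L, 128L),
                          b_values = c(200, 300, 500, 700, 1000),
                          n_repeats = 5,
                          s0_mean = 800,
                          noise_sd = 15,
                          adc_mean = c(healthy = 1.83e-3, ckd = 1.75e-3),
                          adc_sd = c(healthy = 3.1e-4, ckd = 4.2e-4),
                          corr_length = c(healthy = 3.0, ckd = 1.5),
                          rapid_fraction = 0.23,
                          egfr_mean = c(healthy = 88.6, ckd = 51.5),
                          egfr_sd = c(healthy = 12.6, ckd = 12.2),
                          bmi_mean = c(healthy = 25.8, ckd = 32.4),
                          bmi_sd = c(healthy = 2.7, ckd = 7.5),
                          age_mean = c(healthy = 58.1, ckd = 65.3),
                          age_sd = c(healthy = 9.4, ckd = 9.6),
                          p_female = c(healthy = 0.4, ckd = 0.5),
                          sbp_mean = 133.87, sbp_sd = 15.9,
                          dbp_mean = 67.9, dbp_sd = 10.6,
                          glucose_mean = 149.6, glucose_sd = 68.0,
                          slope_rapid_mean = -5.27, slope_rapid_sd = 2.61,
                          slope_nonrapid_mean = 0.92, slope_nonrapid_sd = 2.57,
                          rapid_threshold = -3,
                          proteinuria_meanlog = -1.7,
                          proteinuria_sdlog = 1.1,
                          proteinuria_zero_frac = 0.25,
                          proteinuria_missing_frac = 4 / 30,
                          mask_target_voxels = 1500) {
  cfg <- list(
    n_healthy = n_healthy, n_ckd = n_ckd, seed = seed,
    grid_shape = as.integer(grid_shape), b_values = as.numeric(b_values),
    n_repeats = n_repeats, s0_mean = s0_mean, noise_sd = noise_sd,
    adc_mean = adc_mean, adc_sd = adc_sd, corr_length = corr_length,
    rapid_fraction = rapid_fraction,
    egfr_mean = egfr_mean, egfr_sd = egfr_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    age_mean = age_mean, age_sd = age_sd, p_female = p_female,
    sbp_mean = sbp_mean, sbp_sd = sbp_sd,
    dbp_mean = dbp_mean, dbp_sd = dbp_sd,
    glucose_mean = glucose_mean, glucose_sd = glucose_sd,
    slope_rapid_mean = slope_rapid_mean, slope_rapid_sd = slope_rapid_sd,
    slope_nonrapid_mean = slope_nonrapid_mean,
    slope_nonrapid_sd = slope_nonrapid_sd,
    rapid_threshold = rapid_threshold,
    proteinuria_meanlog = proteinuria_meanlog,
    proteinuria_sdlog = proteinuria_sdlog,
    proteinuria_zero_frac = proteinuria_zero_frac,
    proteinuria_missing_frac = proteinuria_missing_frac,
    mask_target_voxels = mask_target_voxels
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  check_number(cfg$n_healthy, "n_healthy", min = 0, integerish = TRUE)
  check_number(cfg$n_ckd, "n_ckd", min = 0, integerish = TRUE)
  if (cfg$n_healthy + cfg$n_ckd < 2) {
    abort("`n_healthy` + `n_ckd` must be at least 2.",
          class = "adc_config_error")
  }
  check_number(cfg$seed, "seed", integerish = TRUE)
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 1)) {
    abort("`grid_shape` must be three positive integers (slices, rows, cols).",
          class = "adc_config_error")
  }
  b <- cfg$b_values
  if (length(b) < 2 || any(b <= 0) || any(diff(b) <= 0)) {
    abort("`b_values` must be >= 2 strictly increasing positive values.",
          class = "adc_config_error")
  }
  check_number(cfg$n_repeats, "n_repeats", min = 1, integerish = TRUE)
  check_number(cfg$s0_mean, "s0_mean", min = 0)
  check_number(cfg$noise_sd, "noise_sd", min = 0)
  check_number(cfg$rapid_fraction, "rapid_fraction", min = 0, max = 1)
  for (nm in c("adc_mean", "adc_sd", "corr_length", "egfr_mean", "egfr_sd",
               "bmi_mean", "bmi_sd", "age_mean", "age_sd", "p_female")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || !all(c("healthy", "ckd") %in% names(v))) {
      abort(sprintf("`%s` must be named with elements 'healthy' and 'ckd'.", nm),
            class = "adc_config_error")
    }
  }
  for (nm in c("adc_sd", "corr_length", "egfr_sd", "bmi_sd", "age_sd")) {
    if (any(cfg[[nm]] < 0)) {
      abort(sprintf("`%s` must be nonnegative.", nm),
            class = "adc_config_error")
    }
  }
  for (nm in c("sbp_sd", "dbp_sd", "glucose_sd", "slope_rapid_sd",
               "slope_nonrapid_sd", "proteinuria_sdlog")) {
    check_number(cfg[[nm]], nm, min = 0)
  }
  check_number(cfg$proteinuria_zero_frac, "proteinuria_zero_frac",
               min = 0, max = 1)
  check_number(cfg$proteinuria_missing_frac, "proteinuria_missing_frac",
               min = 0, max = 1)
  check_number(cfg$mask_target_voxels, "mask_target_voxels", min = 200)
  invisible(cfg)
}

#' Read a cohort configuration from a YAML or JSON file
#'
#' The file maps 1:1 onto the arguments of [cohort_config()]; missing entries
#' take the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(cohort_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(paste0("Unknown config fields: ", paste(extra, collapse = ", ")),
          class = "adc_config_error")
  }
  # Re-attach the healthy/ckd names that YAML maps preserve as sublists.
  raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  do.call(cohort_config, raw)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  subjects: %d healthy + %d ckd (seed %d)\n",
              x$n_healthy, x$n_ckd, as.integer(x$seed)))
  cat(sprintf("  grid: %s; b = %s s/mm^2; %d repeats\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$b_values, collapse = ", "), as.integer(x$n_repeats)))
  cat(sprintf("  ADC healthy %.3g +/- %.2g, ckd %.3g +/- %.2g mm^2/s\n",
              x$adc_mean[["healthy"]], x$adc_sd[["healthy"]],
              x$adc_mean[["ckd"]], x$adc_sd[["ckd"]]))
  invisible(x)
}
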