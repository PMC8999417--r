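# Clinical covariates: generation and kidney-function utilities.

# Truncated-normal draw via inverse CDF; `lower`/`upper` may be infinite.
rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

#' Generate clinical covariates for one synthetic subject
#'
#' Draws from group-conditional normal distributions (zero-inflated log-normal
#' for 24 h urine protein). For CKD subjects the annual eGFR slope is drawn
#' from the rapid or non-rapid mixture component, truncated to the correct
#' side of the rapid-progression threshold so the label and the slope can
#' never disagree. Healthy subjects mirror a typical research cohort: SBP,
#' DBP, slope, proteinuria and glucose are missing (collected only for CKD
#' patients), and the rapid label is absent.
#'
#' @param group `"healthy"` or `"ckd"`.
#' @param rapid Logical rapid-progressor label, or `NA` for healthy subjects.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A one-row tibble of clinical values (sex is 1 = female, 0 = male).
#' @export
generate_clinical <- function(group = c("healthy", "ckd"), rapid = NA,
                              config = cohort_config(), seed = 1) {
  group <- match.arg(group)
  cfg <- config
  with_seed(child_seed(seed, paste0("clinical_", group)), {
    age <- stats::rnorm(1, cfg$age_mean[[group]], cfg$age_sd[[group]])
    sex <- stats::rbinom(1, 1, cfg$p_female[[group]])
    egfr <- stats::rnorm(1, cfg$egfr_mean[[group]], cfg$egfr_sd[[group]])
    bmi <- stats::rnorm(1, cfg$bmi_mean[[group]], cfg$bmi_sd[[group]])
    if (group == "healthy") {
      tibble::tibble(
        age = age, sex = sex, egfr = egfr, bmi = bmi,
        sbp = NA_real_, dbp = NA_real_, egfr_slope = NA_real_,
        proteinuria = NA_real_, glucose = NA_real_, rapid = NA
      )
    } else {
      if (is.na(rapid)) rapid <- stats::runif(1) < cfg$rapid_fraction
      thr <- cfg$rapid_threshold
      slope <- if (rapid) {
        rtruncnorm1(1, cfg$slope_rapid_mean, cfg$slope_rapid_sd, upper = thr)
      } else {
        # Open interval above the threshold: nudge the bound by epsilon so a
        # non-rapid slope is strictly greater than thr.
        rtruncnorm1(1, cfg$slope_nonrapid_mean, cfg$slope_nonrapid_sd,
                    lower = thr + 1e-9)
      }
      prot <- if (stats::runif(1) < cfg$proteinuria_missing_frac) {
        NA_real_
      } else if (stats::runif(1) < cfg$proteinuria_zero_frac) {
        0
      } else {
        round(stats::rlnorm(1, cfg$proteinuria_meanlog, cfg$proteinuria_sdlog), 2)
      }
      tibble::tibble(
        age = age, sex = sex, egfr = egfr, bmi = bmi,
        sbp = stats::rnorm(1, cfg$sbp_mean, cfg$sbp_sd),
        dbp = stats::rnorm(1, cfg$dbp_mean, cfg$dbp_sd),
        egfr_slope = slope,
        proteinuria = prot,
        glucose = stats::rnorm(1, cfg$glucose_mean, cfg$glucose_sd),
        rapid = rapid
      )
    }
  })
}

#' Annual eGFR slope by ordinary least squares
#'
#' @param times Measurement times in years.
#' @param egfr_values eGFR values (mL/min/1.73 m^2) at those times.
#' @return The OLS slope in mL/min/1.73 m^2 per year.
#' @export
egfr_slope <- function(times, egfr_values) {
  if (length(times) != length(egfr_values) || length(times) < 2) {
    abort("Need >= 2 paired time points.", class = "adc_error")
  }
  if (stats::var(times) == 0) {
    abort("All measurement times are equal; slope undefined.",
          class = "adc_error")
  }
  unname(stats::coef(stats::lm(egfr_values ~ times))[2])
}

#' Classify rapid CKD progression from an annual eGFR slope
#'
#' Rapid progression is an eGFR loss of at least 3 mL/min/1.73 m^2 per year,
#' i.e. slope <= -3 (the threshold itself counts as rapid).
#'
#' @param slope Annual eGFR slope(s).
#' @param threshold Threshold slope; default -3.
#' @return Logical vector.
#' @export
classify_rapid <- function(slope, threshold = -3) {
  if (any(!is.finite(slope))) abort("Slope must be finite.", class = "adc_error")
  slope <= threshold
}

#' CKD-EPI 2009 creatinine-based eGFR
#'
#' The 2009 CKD Epidemiology Collaboration equation:
#' `eGFR = 141 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.209 * 0.993^age * 1.018[female]`
#' with `k = 0.7, a = -0.329` for females and `k = 0.9, a = -0.411` for males.
#' The race coefficient is not applied.
#'
#' @param creatinine Serum creatinine (mg/dL).
#' @param age Age in years.
#' @param sex 1 = female, 0 = male.
#' @return eGFR in mL/min/1.73 m^2.
#' @export
ckd_epi_egfr <- function(creatinine, age, sex) {
  if (any(creatinine <= 0) || any(age <= 0)) {
    abort("Creatinine and age must be positive.", class = "adc_error")
  }
  if (!all(sex %in% c(0, 1))) {
    abort("`sex` must be 0 (male) or 1 (female).", class = "adc_error")
  }
  kappa <- ifelse(sex == 1, 0.7, 0.9)
  alpha <- ifelse(sex == 1, -0.329, -0.411)
  ratio <- creatinine / kappa
  141 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^(-1.209) *
    0.993^age * ifelse(sex == 1, 1.018, 1)
}
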