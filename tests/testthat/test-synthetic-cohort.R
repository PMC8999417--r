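# Synthetic cohort generator: structure, determinism, calibration.

test_that("cohort has the configured composition and is reproducible", {
  cfg <- test_config(seed = 7, n_healthy = 3, n_ckd = 5)
  co <- generate_cohort(cfg)
  expect_length(co, 8)
  groups <- vapply(co, `[[`, "", "group")
  expect_equal(sum(groups == "ckd"), 5)
  expect_equal(sum(groups == "healthy"), 3)
  rec <- co[[1]]
  expect_equal(dim(rec$dwi_left), c(5, cfg$grid_shape))
  expect_true(all(rec$dwi_left >= 0))
  expect_true(all(rec$true_adc_left[rec$mask_left] >= 0 &
                    rec$true_adc_left[rec$mask_left] <= 4e-3))
  co2 <- generate_cohort(cfg)
  expect_identical(co, co2)
})

test_that("degenerate group sizes are handled and invalid configs rejected", {
  co <- generate_cohort(test_config(n_healthy = 0, n_ckd = 2))
  expect_length(co, 2)
  expect_true(all(vapply(co, `[[`, "", "group") == "ckd"))
  expect_error(cohort_config(n_healthy = 0, n_ckd = 1), "n_healthy")
  expect_error(cohort_config(b_values = c(500, 300)), "b_values")
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(cohort_config(rapid_fraction = 1.5), "rapid_fraction")
})

test_that("rapid labels follow the configured Bernoulli fraction", {
  cfg <- cohort_config(rapid_fraction = 0.23)
  rapid <- vapply(seq_len(1000), function(i) {
    generate_clinical("ckd", NA, cfg, seed = i)$rapid
  }, TRUE)
  expect_lt(abs(mean(rapid) - 0.23), 0.03)
})

test_that("kidney masks respect side convention, determinism and disjointness", {
  shape <- c(5, 64, 128)
  left <- generate_kidney_mask(shape, "left", seed = 3)
  right <- generate_kidney_mask(shape, "right", seed = 3)
  expect_gt(sum(left), 200)
  cols_hit <- apply(left, 3, any)
  expect_true(all(which(cols_hit) < 64))
  expect_equal(sum(left & right), 0)
  expect_true(all(apply(left, 1, sum) > 0))    # present on every slice
  expect_identical(left, generate_kidney_mask(shape, "left", seed = 3))
  expect_error(generate_kidney_mask(c(1, 4, 4), "left"), "too small")
})

test_that("ADC fields hit their target moments exactly and clip to range", {
  mask <- generate_kidney_mask(c(4, 32, 64), "left", seed = 1,
                               target_voxels = 400)
  f <- generate_adc_field(mask, 1.83e-3, 3.1e-4, 3, seed = 2)
  v <- f[mask]
  pop_sd <- sqrt(mean((v - mean(v))^2))
  expect_equal(mean(v), 1.83e-3, tolerance = 1e-12)
  expect_equal(pop_sd, 3.1e-4, tolerance = 1e-12)
  expect_equal(pop_sd / mean(v), 0.169, tolerance = 0.005)
  const <- generate_adc_field(mask, 1.5e-3, 0, 3, seed = 2)
  expect_true(all(const[mask] == 1.5e-3))
  expect_error(generate_adc_field(array(FALSE, c(1, 4, 4)), 1e-3, 1e-4, 1),
               "Empty mask")
})

test_that("shorter correlation length produces higher GLCM contrast", {
  mask <- generate_kidney_mask(c(4, 32, 64), "left", seed = 1,
                               target_voxels = 400)
  contrast_of <- function(cl) {
    f <- generate_adc_field(mask, 1.8e-3, 3e-4, cl, seed = 5)
    fv <- extract_features(adc_map(f, mask))
    fv[["GLCMContr"]]
  }
  expect_gt(contrast_of(0), contrast_of(4))
})

test_that("DWI synthesis follows the mono-exponential model", {
  mask <- array(TRUE, c(1, 10, 10))
  adc <- array(1e-3, c(1, 10, 10))
  sig <- synthesize_dwi(adc, mask, 1000, c(1000), 0, 5, seed = 1)
  expect_equal(as.vector(sig), rep(1000 * exp(-1), 100), tolerance = 1e-12)
  sig0 <- synthesize_dwi(adc, mask, 1000, c(0), 0, 5, seed = 1)
  expect_equal(as.vector(sig0), rep(1000, 100))
  # averaging five repeats scales the noise SD by 1/sqrt(5)
  mask2 <- array(TRUE, c(1, 100, 100))
  adc2 <- array(0, c(1, 100, 100))
  sign <- synthesize_dwi(adc2, mask2, 1000, c(500), 20, 5, seed = 2)
  expect_equal(sd(as.vector(sign)), 20 / sqrt(5), tolerance = 0.05 * 20)
  expect_error(synthesize_dwi(adc, mask, 1000, c(500), -1, 5), "noise_sd")
})

test_that("clinical draws match the configured group distributions", {
  cfg <- cohort_config()
  healthy <- do.call(rbind, lapply(1:600, function(i) {
    generate_clinical("healthy", NA, cfg, seed = i)
  }))
  expect_lt(abs(mean(healthy$egfr) - 88.6), 2)
  expect_true(all(is.na(healthy$sbp)))
  expect_true(all(is.na(healthy$egfr_slope)))
  expect_true(all(is.na(healthy$rapid)))
  # truncation contract: rapid slopes never cross the threshold
  rapid_slopes <- vapply(1:200, function(i) {
    generate_clinical("ckd", TRUE, cfg, seed = i)$egfr_slope
  }, 1)
  expect_true(all(rapid_slopes <= -3))
  nonrapid_slopes <- vapply(1:200, function(i) {
    generate_clinical("ckd", FALSE, cfg, seed = i)$egfr_slope
  }, 1)
  expect_true(all(nonrapid_slopes > -3))
})

test_that("eGFR slope mixture mean matches the two-component arithmetic", {
  cfg <- cohort_config()
  slopes <- vapply(seq_len(10000), function(i) {
    generate_clinical("ckd", NA, cfg, seed = i)$egfr_slope
  }, 1)
  target <- 0.23 * (-5.27) + 0.77 * 0.92
  expect_lt(abs(mean(slopes) - target), 0.4)
})

test_that("generated rapid labels agree with classify_rapid on the slopes", {
  cfg <- cohort_config()
  clin <- do.call(rbind, lapply(1:300, function(i) {
    generate_clinical("ckd", NA, cfg, seed = i)
  }))
  expect_identical(classify_rapid(clin$egfr_slope), clin$rapid)
})

test_that("extracted CoV separates groups in the configured direction", {
  co <- generate_cohort(test_config(seed = 11, n_healthy = 5, n_ckd = 8))
  ft <- cohort_features(co)
  expect_gt(median(ft$CoV[ft$group == "ckd"]),
            median(ft$CoV[ft$group == "healthy"]))
})

test_that("config round-trips through YAML", {
  cfg <- test_config(seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(unclass(cfg), function(x) {
    if (!is.null(names(x))) as.list(x) else x
  }), path, precision = 12)
  cfg2 <- read_cohort_config(path)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-9,
               ignore_attr = TRUE)
})
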