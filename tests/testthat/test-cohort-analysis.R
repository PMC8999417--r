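# Spearman maps, normality-routed comparisons, eGFR utilities.

test_that("spearman map identities hold and categories follow the bands", {
  set.seed(2)
  tab <- tibble::tibble(a = rnorm(30), b = rnorm(30))
  tab$c <- tab$a + rnorm(30, 0, 0.05)        # strong positive
  tab$d <- -tab$a                            # perfect negative
  m <- spearman_map(tab, c("a", "b", "c", "d"))
  expect_equal(unname(diag(m$rho)), rep(1, 4))
  expect_equal(m$rho["a", "d"], -1)
  expect_equal(m$category["a", "d"], "strong/neg")
  expect_equal(m$category["a", "c"], "strong/pos")
  expect_true(isSymmetric(m$rho))
  # rank reversal gives rho -1 regardless of spacing
  tab2 <- tibble::tibble(x = c(1, 2, 3, 4, 5), y = c(100, 9, 8, 0.5, -2))
  m2 <- spearman_map(tab2, c("x", "y"))
  expect_equal(m2$rho["x", "y"], -1)
  # invariance under strictly monotone transforms
  tab3 <- tibble::tibble(u = rexp(25), v = rnorm(25))
  m3 <- spearman_map(tab3, c("u", "v"))
  tab4 <- tibble::tibble(u = log(tab3$u), v = tab3$v^3)
  m4 <- spearman_map(tab4, c("u", "v"))
  expect_equal(m3$rho["u", "v"], m4$rho["u", "v"])
})

test_that("54 feature columns give 1431 distinct unordered pairs", {
  set.seed(3)
  reg <- feature_registry()
  tab <- tibble::as_tibble(matrix(rnorm(40 * 54), 40, 54,
                                  dimnames = list(NULL, reg$feature)),
                           .name_repair = "minimal")
  m <- spearman_map(tab, reg$feature)
  cts <- categorize_counts(m)
  expect_equal(attr(cts, "n_pairs"), choose(54, 2))
  expect_equal(attr(cts, "n_pairs"), 1431)
  expect_lte(attr(cts, "n_significant"), 1431)
})

test_that("category counts equal a brute-force recount of rho and p", {
  co <- generate_cohort(test_config(seed = 5, n_healthy = 5, n_ckd = 7))
  ft <- cohort_features(co)
  m <- spearman_map(ft, feature_registry()$feature)
  cts <- categorize_counts(m)
  # independent recount from the matrices
  n <- nrow(m$rho)
  recount <- c(strong = 0, moderate = 0, weak = 0)
  total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (!is.na(m$p[i, j]) && m$p[i, j] < 0.05) {
      total <- total + 1
      r <- abs(m$rho[i, j])
      band <- if (r >= 0.7) "strong" else if (r >= 0.3) "moderate" else "weak"
      recount[band] <- recount[band] + 1
    }
  }
  expect_equal(attr(cts, "n_significant"), unname(total))
  agg <- tapply(cts$n, cts$strength, sum)
  expect_equal(as.numeric(agg[c("strong", "moderate", "weak")]),
               as.numeric(recount))
})

test_that("constant columns are flagged ns with a warning", {
  tab <- tibble::tibble(a = rnorm(10), b = rep(1, 10))
  expect_warning(m <- spearman_map(tab, c("a", "b")), "Constant")
  expect_equal(m$category["a", "b"], "ns")
})

test_that("normality routing picks t for normal and wilcoxon for skewed data", {
  set.seed(7)
  tab <- tibble::tibble(x = c(rnorm(50, 0), rnorm(50, 1)),
                        g = rep(c("a", "b"), each = 50))
  cmp <- group_compare(tab, "x", "g")
  expect_equal(cmp$test, "t")
  expect_lt(cmp$p.value, 0.001)
  set.seed(8)
  tab2 <- tibble::tibble(x = c(rlnorm(60, 0, 1.5), rlnorm(60, 0.2, 1.5)),
                         g = rep(c("a", "b"), each = 60))
  cmp2 <- group_compare(tab2, "x", "g")
  expect_equal(cmp2$test, "wilcoxon")
  # identical groups show no effect under either route
  tab3 <- tibble::tibble(x = rep(c(1.2, 3.4, 2.2, 5.1, 0.7), 2),
                         g = rep(c("a", "b"), each = 5))
  cmp3 <- group_compare(tab3, "x", "g")
  expect_gt(cmp3$p.value, 0.99)
  # routing is deterministic
  expect_identical(group_compare(tab2, "x", "g"), cmp2)
  expect_error(group_compare(tab2[tab2$g == "a", ], "x", "g"), "two")
})

test_that("eGFR slope is the OLS slope and rapid labels use the -3 boundary", {
  expect_equal(egfr_slope(c(0, 1, 2), c(60, 57, 54)), -3)
  expect_equal(egfr_slope(c(0, 1, 2, 3), rep(70, 4)), 0)
  expect_error(egfr_slope(c(1, 1), c(60, 55)), "equal")
  set.seed(10)
  slopes <- replicate(2000, {
    t <- 0:4
    egfr_slope(t, 80 - 2 * t + rnorm(5, 0, 3))
  })
  expect_lt(abs(mean(slopes) + 2), 3 * sd(slopes) / sqrt(2000))
  expect_true(classify_rapid(-3))
  expect_true(classify_rapid(-5.27))
  expect_false(classify_rapid(0))
  expect_false(classify_rapid(-2.999))
})

test_that("CKD-EPI 2009 equation matches an independent transcription", {
  expect_gt(ckd_epi_egfr(1.0, 40, 0), ckd_epi_egfr(1.0, 70, 0))
  # continuity at the sex-specific knots
  for (sex in c(0, 1)) {
    kappa <- if (sex == 1) 0.7 else 0.9
    lo <- ckd_epi_egfr(kappa - 1e-9, 55, sex)
    hi <- ckd_epi_egfr(kappa + 1e-9, 55, sex)
    expect_equal(lo, hi, tolerance = 1e-6)
  }
  set.seed(11)
  scr <- runif(20, 0.4, 3)
  age <- runif(20, 20, 85)
  sex <- rbinom(20, 1, 0.5)
  expect_equal(ckd_epi_egfr(scr, age, sex), ckd_epi_oracle(scr, age, sex),
               tolerance = 1e-9)
  expect_error(ckd_epi_egfr(-1, 50, 0), "positive")
})
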