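# Mode imputation, AUC-ROC, confusion metrics, forward selection.

test_that("mode imputation fills with the most frequent value, ties low", {
  expect_equal(impute_mode(c(0, 0, 0.16, NA)), c(0, 0, 0.16, 0))
  x <- c(1.2, 3.4)
  expect_equal(impute_mode(x), x)
  expect_equal(impute_mode(c(1, 1, 2, 2, NA)), c(1, 1, 2, 2, 1))
  expect_error(impute_mode(c(NA_real_, NA_real_)), "All values missing")
})

test_that("AUC matches its closed forms and the pairwise oracle", {
  expect_equal(auc_roc(c(1, 2, 10, 20), c(0, 0, 1, 1)), 1)
  expect_equal(auc_roc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auc_roc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(1)
  for (rep in 1:25) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    expect_identical(auc_roc(s, y), auc_oracle(s, y))
  }
  # invariance under strictly increasing transforms
  set.seed(2)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  expect_equal(auc_roc(exp(s), y), auc_roc(s, y))
  expect_equal(auc_roc(qlogis(plogis(s)), y), auc_roc(s, y), tolerance = 1e-12)
  expect_error(auc_roc(s, rep(1, 40)), "Both classes")
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  for (i in 1:5) {
    s <- rnorm(30)
    y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
    ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
    expect_equal(auc_roc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("confusion metrics behave correctly across thresholds", {
  s <- c(0.1, 0.4, 0.35, 0.8); y <- c(0, 0, 1, 1)
  m <- roc_metrics(s, y, 0.5)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1)
  expect_equal(roc_metrics(s, y, 0)$sensitivity, 1)
  expect_equal(roc_metrics(s, y, 1 + 1e-9)$specificity, 1)
  # sensitivity non-increasing, specificity non-decreasing in the threshold
  set.seed(3)
  s2 <- runif(50); y2 <- rbinom(50, 1, 0.4); y2[1:2] <- c(0, 1)
  ths <- seq(0, 1, by = 0.1)
  sens <- sapply(ths, function(t) roc_metrics(s2, y2, t)$sensitivity)
  spec <- sapply(ths, function(t) roc_metrics(s2, y2, t)$specificity)
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spec) >= -1e-12))
})

test_that("a perfect separator is selected first and selection stops", {
  set.seed(4)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  tab <- tibble::tibble(
    y = y,
    good = y * 10 + rnorm(n, 0, 0.1),    # separates perfectly
    noise1 = rnorm(n), noise2 = rnorm(n)
  )
  tr <- forward_select_logistic(tab, "y", c("noise1", "good", "noise2"))
  expect_equal(tr$selected[1], "good")
  expect_equal(tr$final_auc, 1)
  expect_length(tr$selected, 1)          # AUC 1 cannot improve
  expect_true(tr$separation)             # ridge fallback engaged
  # the AUC path is strictly increasing
  expect_true(all(diff(c(0.5, tr$auc)) > 1e-6))
})

test_that("an informative feature beats its correlated shadows", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 40
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(2.5 * x))
    if (length(unique(y)) < 2) next
    tab <- tibble::tibble(y = y, signal = x,
                          shadow1 = x + rnorm(n, 0, 1.5),
                          shadow2 = x + rnorm(n, 0, 1.5))
    tr <- forward_select_logistic(tab, "y",
                                  c("shadow1", "signal", "shadow2"))
    hits <- hits + (tr$selected[1] == "signal")
  }
  expect_gte(hits, 16)
})

test_that("progression models produce the three-row report", {
  co <- generate_cohort(test_config(seed = 17))
  ft <- cohort_features(co)
  reps <- build_progression_models(ft)
  expect_equal(nrow(reps$report), 3)
  expect_equal(reps$report$model, c("radiomics", "clinical", "combination"))
  expect_true(all(c("sensitivity", "specificity", "auc_roc", "accuracy")
                  %in% names(reps$report)))
  expect_true(all(reps$report$auc_roc >= 0 & reps$report$auc_roc <= 1))
  expect_true(all(reps$report$sensitivity >= 0 &
                    reps$report$sensitivity <= 1))
  # radiomics pool never selects clinical variables and vice versa
  expect_false(any(reps$traces$radiomics$selected %in%
                     c("sex", "age", "egfr", "bmi")))
  expect_true(all(reps$traces$clinical$selected %in%
                    reps$traces$clinical$pool))
  # too few rapid progressors is an error
  small <- ft[ft$group == "ckd", ][1:6, ]
  small$rapid <- c(TRUE, rep(FALSE, 5))
  small$group <- "ckd"
  expect_error(build_progression_models(small), ">= 3 rapid")
})

test_that("a proteinuria-driven outcome selects proteinuria first", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 30
    tab <- tibble::tibble(
      group = "ckd",
      sex = rbinom(n, 1, 0.5), age = rnorm(n, 65, 9),
      sbp = rnorm(n, 134, 16), dbp = rnorm(n, 68, 10),
      egfr = rnorm(n, 51, 12), bmi = rnorm(n, 32, 7),
      proteinuria = round(rlnorm(n, -1.7, 1.1), 2),
      glucose = rnorm(n, 150, 60)
    )
    tab$rapid <- runif(n) < plogis(4 * scale(tab$proteinuria)[, 1])
    if (sum(tab$rapid) < 3 || sum(!tab$rapid) < 3) next
    tr <- forward_select_logistic(tab, "rapid", clinical_pool <- c(
      "sex", "age", "sbp", "dbp", "egfr", "bmi", "proteinuria", "glucose"))
    hits <- hits + (tr$selected[1] == "proteinuria")
  }
  expect_gte(hits, 7)
})
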