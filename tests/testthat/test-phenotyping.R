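# Z-scores, correlation-distance clustering, GMM-BIC selection.

test_that("Z-score normalization is exact and invertible", {
  m <- matrix(c(1, 2, 3, 10, 20, 60), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  norm <- zscore_normalize(m)
  expect_equal(unname(norm$z[, "a"]),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  norm1 <- zscore_normalize(m, ddof = 1)
  expect_equal(unname(norm1$z[, "a"]), c(-1, 0, 1), tolerance = 1e-12)
  set.seed(1)
  big <- matrix(rnorm(200), 20, 10)
  nb <- zscore_normalize(big)
  expect_lt(max(abs(colMeans(nb$z))), 1e-10)
  popsd <- apply(nb$z, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_lt(max(abs(popsd - 1)), 1e-10)
  expect_equal(zscore_inverse(nb), big, tolerance = 1e-10, ignore_attr = TRUE)
  const <- cbind(big, bad = 1)
  expect_error(zscore_normalize(const), "bad")
})

test_that("correlation distance hits its three analytic anchors", {
  u <- c(1, 3, 2, 5, 4)
  expect_equal(correlation_distance(u, u), 0, tolerance = 1e-12)
  expect_equal(correlation_distance(u, -u + 10), 2, tolerance = 1e-12)
  v <- c(1, -1, 0, 0, 0); w <- c(0, 0, 1, -1, 0)
  expect_equal(correlation_distance(v, w), 1, tolerance = 1e-12)
  # invariance to positive affine transforms
  set.seed(2)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(correlation_distance(3 * a + 7, b),
               correlation_distance(a, b), tolerance = 1e-12)
  expect_error(correlation_distance(rep(1, 5), u), "Zero centered")
})

test_that("identical patterns merge first and heights are monotone", {
  base <- c(1, 2, 3, 4, 5, 4, 3, 2)
  m <- rbind(s1 = base, s2 = base + 10, s3 = -base)
  tree <- hierarchical_cluster(m)
  # the two zero-distance copies merge first
  expect_equal(sort(tree$hclust$merge[1, ]), c(-2, -1))
  expect_equal(tree$hclust$height[1], 0, tolerance = 1e-12)
  expect_equal(tree$labels[1], tree$labels[2])
  expect_false(tree$labels[1] == tree$labels[3])
  set.seed(3)
  rand <- matrix(rnorm(30 * 12), 30, 12)
  tr <- hierarchical_cluster(rand, linkage = "average")
  expect_true(all(diff(tr$hclust$height) >= -1e-12))
})

test_that("a planted two-pattern cohort is recovered by the 2-cluster cut", {
  set.seed(4)
  p1 <- sin(seq(0, 3, length.out = 20))
  p2 <- cos(seq(0, 3, length.out = 20))
  m <- rbind(
    t(replicate(10, p1 + rnorm(20, 0, 0.2))),
    t(replicate(10, p2 + rnorm(20, 0, 0.2)))
  )
  tree <- hierarchical_cluster(m)
  truth <- rep(1:2, each = 10)
  agree <- max(mean(tree$labels == truth), mean(tree$labels == 3 - truth))
  expect_equal(agree, 1)
  # invariance to row order up to label permutation
  perm <- sample(20)
  tree2 <- hierarchical_cluster(m[perm, ])
  l1 <- tree$labels[perm]; l2 <- tree2$labels
  expect_true(all(l1 == l2) || all(l1 == 3 - l2))
})

test_that("GMM-BIC recovers the planted component count", {
  set.seed(5)
  one <- matrix(rnorm(200 * 3), 200, 3)
  g1 <- gmm_bic_select(one, k_max = 4, seed = 1, var_explained = 1)
  expect_equal(g1$best_k, 1)
  two <- rbind(matrix(rnorm(100 * 3), 100, 3),
               matrix(rnorm(100 * 3, mean = 6), 100, 3))
  g2 <- gmm_bic_select(two, k_max = 5, seed = 1, var_explained = 1)
  expect_equal(g2$best_k, 2)
  # hard assignment separates the planted halves
  lab <- g2$labels
  expect_true(all(lab[1:100] == lab[1]) && all(lab[101:200] == lab[101]) &&
                lab[1] != lab[101])
})

test_that("the BIC curve is reproducible bitwise given the seed", {
  set.seed(6)
  x <- rbind(matrix(rnorm(60 * 4), 60, 4),
             matrix(rnorm(60 * 4, 4), 60, 4))
  a <- gmm_bic_select(x, k_max = 4, seed = 42)
  b <- gmm_bic_select(x, k_max = 4, seed = 42)
  expect_identical(a$bic_curve, b$bic_curve)
})

test_that("the EM log-likelihood matches the mclust oracle", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(7)
  x <- rbind(matrix(rnorm(80 * 2), 80, 2),
             matrix(rnorm(80 * 2, 5), 80, 2))
  mine <- gmm_bic_select(x, k_max = 3, seed = 1, var_explained = 1,
                         cov_floor = 1e-12)
  mc <- mclust::Mclust(x, G = 1:3, modelNames = "VVV", verbose = FALSE)
  # same selected k, and log-likelihoods agree closely for k = best
  expect_equal(mine$best_k, mc$G)
  mc_ll <- mc$loglik
  my_ll <- mine$bic_curve$loglik[mine$best_k]
  expect_equal(my_ll, mc_ll, tolerance = 1e-3)
})

test_that("cluster comparison reports CKD fractions and eGFR ordering", {
  co <- generate_cohort(test_config(seed = 9, n_healthy = 6, n_ckd = 8))
  ft <- cohort_features(co)
  labels <- ifelse(ft$group == "ckd", 1L, 2L)
  cc <- cluster_compare(ft, labels)
  s <- cc$cluster_summary
  expect_equal(sort(s$ckd_fraction), c(0, 1))
  # cluster 1 is the lower-eGFR cluster by construction of the labelling
  expect_lt(s$mean_egfr[s$.cluster == 1], s$mean_egfr[s$.cluster == 2])
  expect_true(all(c("egfr", "CoV") %in% cc$comparisons$variable))
})

test_that("random labels on null data stay near the type-I error rate", {
  set.seed(10)
  pvals <- replicate(40, {
    tab <- tibble::tibble(x = rnorm(30), g = rep(c("a", "b"), 15))
    group_compare(tab, "x", "g")$p.value
  })
  expect_lt(mean(pvals < 0.05), 0.2)
})
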