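# Full-covariance Gaussian mixtures with BIC model selection.

log_dmvnorm <- function(x, mean, chol_up) {
  d <- ncol(x)
  logdet <- 2 * sum(log(diag(chol_up)))
  dev <- t(x) - mean
  quad <- colSums(backsolve(chol_up, dev, transpose = TRUE)^2)
  -0.5 * (d * log(2 * pi) + logdet + quad)
}

# Eigenvalue floor keeps every component covariance positive definite.
floor_cov <- function(S, floor) {
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values >= floor)) return(list(S = S, regularized = FALSE))
  vals <- pmax(e$values, floor)
  list(S = e$vectors %*% (vals * t(e$vectors)), regularized = TRUE)
}

fit_gmm_em <- function(x, k, init_labels, cov_floor = 1e-6,
                       max_iter = 500, tol = 1e-8) {
  n <- nrow(x); d <- ncol(x)
  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), init_labels)] <- 1
  ll_old <- -Inf
  regularized <- FALSE
  for (iter in seq_len(max_iter)) {
    nk <- colSums(resp)
    if (any(nk < 1e-10)) stop("empty component")
    w <- nk / n
    means <- lapply(seq_len(k), function(j) colSums(resp[, j] * x) / nk[j])
    chols <- vector("list", k)
    for (j in seq_len(k)) {
      dev <- sweep(x, 2, means[[j]])
      S <- crossprod(dev * sqrt(resp[, j])) / nk[j]
      fc <- floor_cov(S, cov_floor)
      regularized <- regularized || fc$regularized
      chols[[j]] <- chol(fc$S)
    }
    logp <- vapply(seq_len(k), function(j) {
      log(w[j]) + log_dmvnorm(x, means[[j]], chols[[j]])
    }, numeric(n))
    logp <- matrix(logp, n, k)
    m <- apply(logp, 1, max)
    lse <- m + log(rowSums(exp(logp - m)))
    ll <- sum(lse)
    resp <- exp(logp - lse)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  # Degeneracy diagnostics of the converged solution: a component whose
  # covariance sits at the floor, or with fewer effective members than
  # dimensions, marks a spiky solution whose likelihood is an artifact of
  # the floor rather than a maximum-likelihood fit.
  nk <- colSums(resp)
  min_eig <- min(vapply(seq_len(k), function(j) {
    dev <- sweep(x, 2, means[[j]])
    S <- crossprod(dev * sqrt(resp[, j])) / max(nk[j], 1e-10)
    min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1)))
  list(loglik = ll, weights = w, means = means, resp = resp,
       labels = max.col(resp), regularized = regularized,
       min_eig = min_eig, min_nk = min(nk),
       degenerate = min_eig <= cov_floor * 10 || min(nk) < d + 1)
}

#' Select the number of phenotype clusters with a GMM-BIC scan
#'
#' Fits full-covariance Gaussian mixtures with 1 to `k_max` components by EM
#' (k-means initialization, multiple restarts, eigenvalue floor on component
#' covariances) and selects the component count minimizing
#' `BIC = p * ln(n) - 2 * ln(L)`, where `p = (k-1) + k*d + k*d*(d+1)/2` is
#' the free-parameter count. Ties resolve toward the smaller k.
#'
#' A full-covariance mixture on more features than subjects is ill-posed, so
#' the mixture is fitted on the top principal components capturing at least
#' `var_explained` of the variance (the retained count is reported).
#'
#' With unequal component covariances the likelihood is unbounded: EM can
#' drive one component's covariance to the floor around a handful of nearly
#' coincident points. Such converged solutions (floor-level covariance, or a
#' component with fewer effective members than dimensions) are rejected as
#' degenerate rather than scored; if no restart survives for some k, that
#' BIC entry is flagged `NA` with a warning.
#'
#' @param norm A [zscore_normalize()] result or a numeric matrix
#'   (subjects x features).
#' @param k_max Maximum number of components (default 10).
#' @param seed Integer seed (k-means restarts).
#' @param var_explained Variance fraction retained by the PCA safeguard.
#' @param n_restarts EM restarts per k (default 10).
#' @param cov_floor Eigenvalue floor for component covariances.
#' @return A `gmm_bic`: list with `bic_curve` (tibble: k, bic, loglik,
#'   n_params, regularized, failed), `best_k`, `labels` (hard assignment
#'   under the best model), `n_dims` (PCA components used) and `scores`
#'   (the PCA scores the mixture was fitted on).
#' @export
gmm_bic_select <- function(norm, k_max = 10, seed = 1,
                           var_explained = 0.95, n_restarts = 10,
                           cov_floor = 1e-6) {
  seed <- check_number(seed, "seed", integerish = TRUE)
  z <- if (inherits(norm, "normalized_table")) norm$z else as.matrix(norm)
  n <- nrow(z)
  pca <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  d <- which(cum >= var_explained)[1]
  d <- max(1L, min(d, n - 2L))
  x <- pca$x[, seq_len(d), drop = FALSE]
  if (n <= d) abort("Need more subjects than retained dimensions.",
                    class = "adc_error")

  fits <- vector("list", k_max)
  rows <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    best <- NULL
    reg <- FALSE
    for (r in seq_len(n_restarts)) {
      fit <- try(with_seed(child_seed(seed, sprintf("gmm_k%d_r%d", k, r)), {
        init <- if (k == 1) rep(1L, n) else {
          km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 1,
                                               iter.max = 50))
          km$cluster
        }
        fit_gmm_em(x, k, init, cov_floor = cov_floor)
      }), silent = TRUE)
      if (!inherits(fit, "try-error") && is.finite(fit$loglik) &&
          !fit$degenerate) {
        reg <- reg || fit$regularized
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
      if (k == 1) break   # deterministic: one restart suffices
    }
    n_params <- (k - 1) + k * d + k * d * (d + 1) / 2
    if (is.null(best)) {
      warn(sprintf(
        "GMM with %d components found no non-degenerate fit; BIC flagged NA.",
        k))
      rows[[k]] <- tibble::tibble(k = k, bic = NA_real_, loglik = NA_real_,
                                  n_params = n_params, regularized = NA,
                                  failed = TRUE)
    } else {
      fits[[k]] <- best
      if (reg) inform(sprintf(
        "GMM k = %d: covariance floor regularization applied.", k))
      rows[[k]] <- tibble::tibble(
        k = k, bic = n_params * log(n) - 2 * best$loglik,
        loglik = best$loglik, n_params = n_params,
        regularized = reg, failed = FALSE)
    }
  }
  curve <- dplyr::bind_rows(rows)
  ok <- which(!curve$failed)
  if (!length(ok)) abort("All GMM fits failed.", class = "adc_error")
  best_k <- ok[which.min(curve$bic[ok])]   # which.min takes the first tie
  structure(list(
    bic_curve = curve, best_k = as.integer(best_k),
    labels = fits[[best_k]]$labels, n_dims = d,
    scores = x
  ), class = "gmm_bic")
}

#' @export
print.gmm_bic <- function(x, ...) {
  cat(sprintf("<gmm_bic> best k = %d (scan 1-%d on %d PCA dims)\n",
              x$best_k, max(x$bic_curve$k), x$n_dims))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy gmm_bic
#' @export
tidy.gmm_bic <- function(x, ...) x$bic_curve

#' @rdname tidiers
#' @method glance gmm_bic
#' @export
glance.gmm_bic <- function(x, ...) {
  tibble::tibble(best_k = x$best_k, n_dims = x$n_dims,
                 min_bic = min(x$bic_curve$bic, na.rm = TRUE))
}
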