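# Independent brute-force oracles used to validate the implementation.
# These re-derive every quantity from first principles (explicit loops,
# literal formulas) and share no code with the package internals.

# Build a label_image from a 3-D integer array (NA = outside mask).
label_image_from_array <- function(lev, n_levels = max(lev, na.rm = TRUE)) {
  structure(list(levels = lev, mask = !is.na(lev),
                 n_levels = as.integer(n_levels)),
            class = "label_image")
}

oracle_offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                       `90` = c(-1L, 0L), `135` = c(-1L, -1L))

# Exhaustive pair enumeration for the GLCM.
glcm_oracle <- function(lev, n_levels, direction) {
  off <- oracle_offsets[[as.character(direction)]]
  C <- matrix(0, n_levels, n_levels)
  ns <- dim(lev)[1]; nr <- dim(lev)[2]; nc <- dim(lev)[3]
  for (s in seq_len(ns)) for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    a <- lev[s, r, c]; b <- lev[s, r2, c2]
    if (is.na(a) || is.na(b)) next
    C[a, b] <- C[a, b] + 1
    C[b, a] <- C[b, a] + 1
  }
  n_pairs <- sum(C)
  list(P = if (n_pairs > 0) C / n_pairs else C, n_pairs = n_pairs)
}

# Exhaustive run scan for the GLRLM: walk every line from its start cell.
glrlm_oracle <- function(lev, n_levels, direction) {
  off <- oracle_offsets[[as.character(direction)]]
  ns <- dim(lev)[1]; nr <- dim(lev)[2]; nc <- dim(lev)[3]
  runs <- list()
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc
  for (s in seq_len(ns)) for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    # a line start has no predecessor cell along the offset
    if (inside(r0 - off[1], c0 - off[2])) next
    r <- r0; c <- c0
    cur <- NA; len <- 0
    while (inside(r, c)) {
      v <- lev[s, r, c]
      if (is.na(v)) {
        if (len > 0) runs[[length(runs) + 1]] <- c(cur, len)
        cur <- NA; len <- 0
      } else if (!is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (len > 0) runs[[length(runs) + 1]] <- c(cur, len)
        cur <- v; len <- 1
      }
      r <- r + off[1]; c <- c + off[2]
    }
    if (len > 0) runs[[length(runs) + 1]] <- c(cur, len)
  }
  if (!length(runs)) return(list(R = matrix(0, n_levels, 1), n_runs = 0))
  rm_ <- do.call(rbind, runs)
  R <- matrix(0, n_levels, max(rm_[, 2]))
  for (k in seq_len(nrow(rm_))) {
    R[rm_[k, 1], rm_[k, 2]] <- R[rm_[k, 1], rm_[k, 2]] + 1
  }
  list(R = R, n_runs = nrow(rm_))
}

# Literal-formula GLCM features: every sum written as an explicit loop.
glcm_feature_oracle <- function(P) {
  ng <- nrow(P)
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j]
  }
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px)); sy <- sqrt(sum(((1:ng) - muy)^2 * py))
  acc <- function(f) {
    tot <- 0
    for (i in 1:ng) for (j in 1:ng) tot <- tot + f(i, j, P[i, j])
    tot
  }
  l2 <- function(x) ifelse(x > 0, log2(x), 0)
  pd <- numeric(ng); psum <- numeric(2 * ng)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    psum[i + j] <- psum[i + j] + P[i, j]
  }
  da <- sum((0:(ng - 1)) * pd)
  sa <- sum((1:(2 * ng)) * psum)
  hxy <- -acc(function(i, j, p) p * l2(p))
  hxy1 <- -acc(function(i, j, p) p * l2(px[i] * py[j]))
  hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    hxy2 <- hxy2 - px[i] * py[j] * l2(px[i] * py[j])
  }
  hx <- -sum(px * l2(px)); hy <- -sum(py * l2(py))
  c(
    AuCor = acc(function(i, j, p) i * j * p),
    JointAvg = acc(function(i, j, p) i * p),
    ClstProm = acc(function(i, j, p) (i + j - mux - muy)^4 * p),
    ClstShade = acc(function(i, j, p) (i + j - mux - muy)^3 * p),
    ClstTend = acc(function(i, j, p) (i + j - mux - muy)^2 * p),
    GLCMContr = acc(function(i, j, p) (i - j)^2 * p),
    GLCMCor = (acc(function(i, j, p) i * j * p) - mux * muy) / (sx * sy),
    DiffAvg = da,
    DiffEntr = -sum(pd * l2(pd)),
    DiffVar = sum(((0:(ng - 1)) - da)^2 * pd),
    AngSecMom = acc(function(i, j, p) p^2),
    JointEntr = hxy,
    FirstMeasInfoCor = (hxy - hxy1) / max(hx, hy),
    SecMeasInfoCor = sqrt(1 - exp(-2 * (hxy2 - hxy))),
    InvDiffMom = acc(function(i, j, p) p / (1 + (i - j)^2)),
    InvDiffMomNorm = acc(function(i, j, p) p / (1 + ((i - j) / ng)^2)),
    InvDiff = acc(function(i, j, p) p / (1 + abs(i - j))),
    InvDiffNorm = acc(function(i, j, p) p / (1 + abs(i - j) / ng)),
    InvVar = acc(function(i, j, p) if (i != j) p / (i - j)^2 else 0),
    JointMax = max(P),
    SumAvg = sa,
    SumEnt = -sum(psum * l2(psum)),
    JointVar = acc(function(i, j, p) (i - mux)^2 * p)
  )
}

# Literal-formula GLRLM features.
glrlm_feature_oracle <- function(R, n_pixels) {
  ng <- nrow(R); mj <- ncol(R)
  nr_ <- sum(R)
  acc <- function(f) {
    tot <- 0
    for (i in 1:ng) for (j in 1:mj) tot <- tot + f(i, j, R[i, j])
    tot
  }
  l2 <- function(x) ifelse(x > 0, log2(x), 0)
  mu_i <- acc(function(i, j, r) i * r / nr_)
  mu_j <- acc(function(i, j, r) j * r / nr_)
  c(
    ShortRunEmph = acc(function(i, j, r) r / j^2) / nr_,
    LongRunEmph = acc(function(i, j, r) r * j^2) / nr_,
    GLNU = sum(rowSums(R)^2) / nr_,
    GLNUnorm = sum(rowSums(R)^2) / nr_^2,
    RunLenNU = sum(colSums(R)^2) / nr_,
    RunLenNUnorm = sum(colSums(R)^2) / nr_^2,
    RunPerc = nr_ / n_pixels,
    GLVar = acc(function(i, j, r) (i - mu_i)^2 * r / nr_),
    RunLenVar = acc(function(i, j, r) (j - mu_j)^2 * r / nr_),
    RunEntr = -acc(function(i, j, r) (r / nr_) * l2(r / nr_)),
    LowGLRunEmph = acc(function(i, j, r) r / i^2) / nr_,
    HighGLRunEmph = acc(function(i, j, r) r * i^2) / nr_,
    ShortRunLowGLEmph = acc(function(i, j, r) r / (i^2 * j^2)) / nr_,
    ShortRunHighGLEmph = acc(function(i, j, r) r * i^2 / j^2) / nr_,
    LongRunLowGLEmph = acc(function(i, j, r) r * j^2 / i^2) / nr_,
    LongRunHighGLEmph = acc(function(i, j, r) r * i^2 * j^2) / nr_
  )
}

# Pairwise Mann-Whitney AUC.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# Independent piecewise transcription of the CKD-EPI 2009 equation
# (sex-specific branches written out; 143.538 = 141 * 1.018).
ckd_epi_oracle <- function(scr, age, sex) {
  mapply(function(s, a, f) {
    if (f == 1) {
      if (s <= 0.7) 143.538 * (s / 0.7)^(-0.329) * 0.993^a
      else          143.538 * (s / 0.7)^(-1.209) * 0.993^a
    } else {
      if (s <= 0.9) 141 * (s / 0.9)^(-0.411) * 0.993^a
      else          141 * (s / 0.9)^(-1.209) * 0.993^a
    }
  }, scr, age, sex)
}

# Coarse-to-fine grid search over (S0, ADC) minimizing signal-domain SSE.
adc_grid_oracle <- function(signal, b) {
  s0_lo <- max(signal) * 0.5; s0_hi <- max(signal) * 4
  adc_lo <- 0; adc_hi <- 4e-3
  for (pass in 1:6) {
    s0s <- seq(s0_lo, s0_hi, length.out = 25)
    adcs <- seq(adc_lo, adc_hi, length.out = 25)
    sse <- outer(s0s, adcs, Vectorize(function(s0, adc) {
      sum((signal - s0 * exp(-b * adc))^2)
    }))
    ix <- which(sse == min(sse), arr.ind = TRUE)[1, ]
    ds <- diff(s0s)[1]; da <- diff(adcs)[1]
    s0_lo <- s0s[ix[1]] - ds; s0_hi <- s0s[ix[1]] + ds
    adc_lo <- max(0, adcs[ix[2]] - da); adc_hi <- adcs[ix[2]] + da
  }
  c(s0 = s0s[ix[1]], adc = adcs[ix[2]])
}

# Small reduced-size cohort config for tests (study conditions preserved;
# grid and ROI size scaled down for speed).
test_config <- function(seed = 1, n_healthy = 10, n_ckd = 30, ...) {
  cohort_config(seed = seed, n_healthy = n_healthy, n_ckd = n_ckd,
                grid_shape = c(4, 32, 64), mask_target_voxels = 400, ...)
}

random_label_image <- function(seed, ns = 1, nr = 8, nc = 8, ng = 5,
                               na_frac = 0.2) {
  set.seed(seed)
  lev <- array(sample.int(ng, ns * nr * nc, replace = TRUE), c(ns, nr, nc))
  lev[array(runif(length(lev)) < na_frac, dim(lev))] <- NA
  if (all(is.na(lev))) lev[1, 1, 1] <- 1L
  label_image_from_array(lev, ng)
}
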