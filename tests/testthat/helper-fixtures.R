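# shared fixtures and independent oracles (kept free of package internals)

tinyMontage <- function(n = 4) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  Montage(paste0("ch", seq_len(n)), cbind(sin(ang), cos(ang)) * 0.8)
}

# structured peak maps: K unit templates, random polarity and amplitude,
# white noise at the given snr
structuredPeaks <- function(n, C, K, snr = 3, seed = 1) {
  set.seed(seed)
  nrm <- function(v) { v <- v - mean(v); v / sqrt(sum(v^2)) }
  Tm <- t(apply(matrix(rnorm(K * C), K, C), 1, nrm))
  lab <- sample.int(K, n, replace = TRUE)
  S <- Tm[lab, , drop = FALSE] * runif(n, 0.5, 1.5) *
    sample(c(-1, 1), n, replace = TRUE)
  X <- S + matrix(rnorm(n * C, 0, sqrt(mean(S^2)) / snr), n, C)
  X <- X - rowMeans(X)
  list(maps = X, templates = Tm, labels = lab)
}

asTopographySet <- function(M, subjectId = "fix") {
  new("TopographySet", maps = M - rowMeans(M),
      sourceIndices = seq_len(nrow(M)), subjectId = subjectId)
}

# Exhaustive polarity-invariant GEV optimum over all assignments of peaks
# to K clusters, with the GEV-optimal (dominant eigenvector) template per
# cluster. Enumerates K^n assignments; keep n small.
exhaustiveGEVOptimum <- function(M, K) {
  Xc <- M - rowMeans(M)
  norms <- sqrt(rowSums(Xc^2))
  Xn <- Xc / norms
  gfp <- norms / sqrt(ncol(M))
  denom <- sum(gfp^2)
  n <- nrow(M)
  asn <- rep(1L, n)
  best <- -Inf
  repeat {
    if (length(unique(asn)) == K) {
      tot <- 0
      for (k in seq_len(K)) {
        sel <- asn == k
        Mk <- crossprod(Xn[sel, , drop = FALSE] * gfp[sel])
        tot <- tot + eigen(Mk, symmetric = TRUE, only.values = TRUE)$values[1]
      }
      g <- tot / denom
      if (g > best) best <- g
    }
    i <- 1L
    while (i <= n) {
      asn[i] <- asn[i] + 1L
      if (asn[i] <= K) break
      asn[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
  }
  best
}

# exhaustive best permutation matching templates to a reference by total
# absolute correlation (independent of the package's implementation)
bruteBestPermutation <- function(Tm, Rf) {
  nrmRows <- function(M) {
    M <- M - rowMeans(M)
    M / sqrt(rowSums(M^2))
  }
  Rho <- abs(nrmRows(Tm) %*% t(nrmRows(Rf)))
  K <- nrow(Tm)
  perms <- asplit(as.matrix(expand.grid(rep(list(seq_len(K)), K))), 1)
  perms <- Filter(function(p) length(unique(p)) == K, perms)
  scores <- vapply(perms, function(p) sum(Rho[cbind(p, seq_len(K))]), 0)
  list(perm = as.integer(perms[[which.max(scores)]]),
       score = max(scores))
}

# minimal Segmentation builder for label vectors
segFromLabels <- function(lab, fs = 125, K = max(lab), id = "s1") {
  new("Segmentation", labels = as.integer(lab),
      corr = rep(1, length(lab)), stateNames = LETTERS[seq_len(K)],
      fs = fs, subjectId = id)
}

flatGFP <- function(n, fs = 125) {
  new("GFPSeries", values = rep(1, n), peakIndices = integer(0),
      excludedPeakIndices = integer(0), fs = fs)
}

# metrics for a whole simulated cohort from the ground-truth label
# sequences (no EEG synthesis; used for statistical calibration tests)
metricsFromTruth <- function(cfg, sim) {
  mets <- list()
  for (id in names(sim$truth@labelSequences)) {
    lab <- sim$truth@labelSequences[[id]]
    seg <- segFromLabels(lab, fs = cfg@fs, K = cfg@KTrue, id = id)
    grp <- sim$subjects$group[match(id, sim$subjects$subject_id)]
    mets[[id]] <- computeMetrics(seg, flatGFP(length(lab), cfg@fs),
                                 sim$truth@templates, group = grp)
  }
  mets
}
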