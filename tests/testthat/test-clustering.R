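test_that("spatial correlation behaves as a polarity-aware similarity", {
  u <- c(1, 0, -1, 0)
  expect_equal(spatialCorrelation(u, u), 1)
  expect_equal(spatialCorrelation(u, -u), -1)
  expect_equal(spatialCorrelation(u, c(0, 1, 0, -1)), 0)
  expect_error(spatialCorrelation(u, rep(2, 4)), "flat")
  expect_error(spatialCorrelation(u, c(1, 2)), "equal channel")
})

test_that("noise-free peaks are recovered exactly with GEV = 1", {
  fix <- structuredPeaks(60, 8, 3, snr = 1e12, seed = 21)
  res <- modifiedKMeans(asTopographySet(fix$maps), 3, nRestarts = 20, seed = 1)
  expect_equal(res@gevTotal, 1, tolerance = 1e-9)
  # recovered templates match truth at |rho| = 1 up to permutation
  Rho <- abs(maps(res@templates) %*% t(fix$templates))
  expect_equal(sort(apply(Rho, 1, max)), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(res@converged)
})

test_that("degenerate K = 1 reduces to the direct GEV formula", {
  fix <- structuredPeaks(20, 4, 2, snr = 3, seed = 3)
  res <- modifiedKMeans(asTopographySet(fix$maps), 1, nRestarts = 5, seed = 2)
  X <- fix$maps - rowMeans(fix$maps)
  gfp <- sqrt(rowMeans(X^2))
  rho <- vapply(seq_len(nrow(X)), function(i)
    spatialCorrelation(X[i, ], maps(res@templates)[1, ]), 0)
  expect_equal(res@gevTotal, sum((gfp * rho)^2) / sum(gfp^2),
               tolerance = 1e-9)
})

test_that("eigen-update K-means attains the exhaustive-search GEV optimum", {
  for (cse in list(list(n = 9, K = 2, seed = 5), list(n = 8, K = 3, seed = 6))) {
    fix <- structuredPeaks(cse$n, 4, cse$K, snr = 3, seed = cse$seed)
    res <- modifiedKMeans(asTopographySet(fix$maps), cse$K, nRestarts = 50,
                          seed = 1, templateUpdate = "eigen", tol = 1e-12)
    opt <- exhaustiveGEVOptimum(fix$maps, cse$K)
    expect_equal(res@gevTotal, opt, tolerance = 1e-9)
    # the mean-update heuristic can never beat the exhaustive optimum
    resMean <- modifiedKMeans(asTopographySet(fix$maps), cse$K,
                              nRestarts = 50, seed = 1)
    expect_lte(resMean@gevTotal, opt + 1e-9)
  }
})

test_that("GEV decomposes exactly and is polarity/permutation invariant", {
  fix <- structuredPeaks(40, 6, 3, snr = 3, seed = 7)
  tset <- asTopographySet(fix$maps)
  res <- modifiedKMeans(tset, 3, nRestarts = 20, seed = 4)
  expect_equal(sum(res@gevPerTemplate), res@gevTotal, tolerance = 1e-12)

  # flipping any subset of peak maps leaves GEV and templates (up to sign)
  # unchanged under the same restart stream
  set.seed(99)
  flip <- sample(c(-1, 1), nrow(fix$maps), replace = TRUE)
  resF <- modifiedKMeans(asTopographySet(fix$maps * flip), 3,
                         nRestarts = 20, seed = 4)
  expect_equal(resF@gevTotal, res@gevTotal, tolerance = 1e-9)
  agree <- abs(maps(resF@templates) %*% t(maps(res@templates)))
  expect_equal(sort(apply(agree, 1, max)), rep(1, 3), tolerance = 1e-6,
               ignore_attr = TRUE)

  # relabeling templates leaves total GEV untouched
  ref <- new("TemplateSet",
             maps = maps(res@templates)[c(2, 3, 1), ],
             labels = c("A", "B", "C"))
  rel <- canonicalLabeling(res, ref)
  expect_equal(rel@gevTotal, res@gevTotal, tolerance = 1e-12)
})

test_that("the CV criterion selects the generating K on separable data", {
  # algebraic penalty monotonicity
  C <- 64
  pen <- ((C - 1) / (C - 1 - (1:10)))^2
  expect_true(all(diff(pen) > 0))

  # exactly noise-free single-template data: residual variance 0 at K = 1
  set.seed(8)
  tpl <- c(scale(rnorm(6), scale = FALSE))
  tpl <- tpl / sqrt(sum(tpl^2))
  M1 <- outer(runif(30, 0.5, 1.5) * sample(c(-1, 1), 30, TRUE), tpl)
  sk1 <- selectK(asTopographySet(M1), kRange = 1:3, nRestarts = 5, seed = 1)
  expect_equal(sk1$chosenK, 1L)
  expect_lt(sk1$table$cv[1], 1e-12)

  # four well-separated templates at snr = 3
  fix4 <- structuredPeaks(400, 16, 4, snr = 3, seed = 9)
  sk4 <- selectK(asTopographySet(fix4$maps), kRange = 2:6, nRestarts = 10,
                 seed = 2)
  expect_equal(sk4$chosenK, 4L)

  expect_error(selectK(asTopographySet(fix4$maps), kRange = integer(0)),
               "non-empty")
  expect_error(selectK(asTopographySet(fix4$maps), kRange = 2:15),
               "channel count")
})

test_that("canonical labeling equals the exhaustive permutation optimum", {
  mont <- standardMontage()
  ref <- canonicalTemplates(mont)
  fix <- structuredPeaks(80, 64, 4, snr = 5, seed = 10)
  res <- modifiedKMeans(asTopographySet(fix$maps), 4, nRestarts = 20, seed = 3)
  lab <- canonicalLabeling(res, ref)
  bb <- bruteBestPermutation(maps(res@templates), maps(ref))
  # same ordering as the brute-force matching, rows equal up to sign
  expect_identical(lab@assignments, match(res@assignments, bb$perm))
  expect_equal(lab@gevPerTemplate, res@gevPerTemplate[bb$perm])
  rowAgree <- abs(rowSums(maps(lab@templates) *
                            maps(res@templates)[bb$perm, ]))
  expect_equal(rowAgree, rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)

  # identity and swap behaviour: per-peak state names are equivariant under
  # a permuted reference
  resAsRef <- canonicalLabeling(res, res@templates)
  expect_identical(resAsRef@assignments, res@assignments)
  perm <- c(2L, 1L, 4L, 3L)
  swapped <- new("TemplateSet", maps = maps(ref)[perm, ],
                 labels = stateLabels(ref)[perm])
  labSw <- canonicalLabeling(res, swapped)
  expect_identical(stateLabels(labSw@templates)[labSw@assignments],
                   stateLabels(lab@templates)[lab@assignments])
})

test_that("TANOVA matches exact enumeration and is polarity invariant", {
  set.seed(12)
  A <- matrix(rnorm(4 * 4), 4, 4)
  B <- matrix(rnorm(4 * 4), 4, 4) + rep(c(1, -1, 1, -1), each = 4)
  tA <- asTopographySet(A); tB <- asTopographySet(B)
  res <- tanova(tA, tB, nPerm = 1e5, seed = 1)
  expect_true(res$exact)

  # independent enumeration over all C(8,4) splits
  X <- rbind(maps(tA), maps(tB))
  dissFun <- function(idx) {
    u <- colMeans(X[idx, ]); w <- colMeans(X[-idx, ])
    u <- u - mean(u); w <- w - mean(w)
    u <- u / sqrt(mean(u^2)); w <- w / sqrt(mean(w^2))
    if (sum(u * w) < 0) w <- -w
    sqrt(mean((u - w)^2))
  }
  obs <- dissFun(1:4)
  cnt <- 0L; tot <- 0L
  for (cmb in utils::combn(8, 4, simplify = FALSE)) {
    tot <- tot + 1L
    if (dissFun(cmb) >= obs - 1e-12) cnt <- cnt + 1L
  }
  expect_equal(res$p, cnt / tot, tolerance = 1e-12)
  expect_equal(res$diss, obs, tolerance = 1e-12)

  # identical groups: DISS 0, p 1; opposite polarity: DISS 0
  same <- tanova(tA, tA, nPerm = 1e5)
  expect_equal(same$diss, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  flip <- asTopographySet(-A)
  expect_lt(tanova(tA, flip, nPerm = 10)$diss, 1e-12)
})
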