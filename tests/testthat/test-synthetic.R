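test_that("generated templates are normalized, distinct and deterministic", {
  mont <- standardMontage()
  for (K in c(2, 4, 6)) {
    tmpl <- makeTemplates(mont, K, seed = 11)
    M <- maps(tmpl)
    expect_equal(nrow(M), K)
    expect_lt(max(abs(rowMeans(M))), 1e-9)
    expect_lt(max(abs(sqrt(rowSums(M^2)) - 1)), 1e-9)
    cc <- M %*% t(M)
    expect_lte(max(abs(cc[upper.tri(cc)])), 0.7 + 1e-12)
  }
  expect_identical(maps(makeTemplates(mont, 6, seed = 5)),
                   maps(makeTemplates(mont, 6, seed = 5)))
  expect_error(makeTemplates(tinyMontage(4), K = 4), "channel count")
  expect_error(makeTemplates(mont, K = 1), ">= 2")
})

test_that("the packaged canonical template TSV matches the computed maps", {
  a <- maps(packagedCanonicalTemplates())
  b <- maps(canonicalTemplates(standardMontage()))
  expect_identical(dim(a), dim(b))
  expect_lt(max(abs(a - b)), 1e-7)
})

test_that("dwell times converge to the configured means", {
  # single long sequence: >= 1e5 runs, empirical mean within 2% of 12.5
  cfg <- simConfig(durationS = 12000, KTrue = 4,
                   meanDurationMs = matrix(100, 2, 4,
                     dimnames = list(c("patient", "control"), LETTERS[1:4])))
  lab <- simulateLabels(cfg, "control", seed = 42)
  r <- rle(lab)
  expect_gt(length(r$lengths), 1e5)
  expect_lt(abs(mean(r$lengths) - 12.5) / 12.5, 0.02)
})

test_that("label simulation validates durations and alternates when K = 2", {
  bad <- simConfig(durationS = 1, meanDurationMs = matrix(
    c(5, rep(100, 7)), 2, 4,
    dimnames = list(c("patient", "control"), LETTERS[1:4])))
  expect_error(simulateLabels(bad, "patient"), "sample period")

  cfg2 <- simConfig(durationS = 5, KTrue = 2, meanDurationMs = matrix(
    100, 2, 2, dimnames = list(c("patient", "control"), c("A", "B"))))
  lab <- simulateLabels(cfg2, "control", seed = 1)
  r <- rle(lab)
  expect_true(all(r$values[-1] != r$values[-length(r$values)]))
  expect_setequal(unique(lab), 1:2)
})

test_that("a configured transition kernel drives next-state choices", {
  # state 1 always goes to 2, 2 to 3, 3 to 1
  P <- matrix(0, 3, 3)
  P[cbind(1:3, c(2, 3, 1))] <- 1
  cfg <- simConfig(durationS = 20, KTrue = 3, transitionKernel = P,
                   meanDurationMs = matrix(60, 2, 3,
                     dimnames = list(c("patient", "control"), LETTERS[1:3])),
                   coupling = matrix(0, 3, 15))
  r <- rle(simulateLabels(cfg, "control", seed = 2))
  from <- r$values[-length(r$values)]
  to <- r$values[-1]
  expect_true(all(to == c(2, 3, 1)[from]))
})

test_that("simulated EEG is average-referenced, seeded, and carries the template", {
  mont <- standardMontage()
  cfg <- simConfig(durationS = 20, nSubjectsPerGroup = 1)
  sim <- simulateCohort(cfg, seed = 9, keepEEG = FALSE)
  rec1 <- simulateEEG(cfg, sim$truth, "pat01", seed = 4)
  rec2 <- simulateEEG(cfg, sim$truth, "pat01", seed = 4)
  expect_identical(eegData(rec1), eegData(rec2))
  expect_lt(max(abs(colMeans(eegData(rec1)))), 1e-9)

  # noise-free limit: at every retained GFP peak the topography matches the
  # active template exactly (up to sign)
  cfg0 <- simConfig(durationS = 20, nSubjectsPerGroup = 1, snr = 1e12)
  rec0 <- simulateEEG(cfg0, sim$truth, "pat01", seed = 4)
  pt <- peakTopographies(rec0)
  Tm <- maps(sim$truth@templates)
  lab <- sim$truth@labelSequences[["pat01"]]
  rho0 <- vapply(seq_along(peakIndices(pt$gfp)), function(i) {
    idx <- peakIndices(pt$gfp)[i]
    abs(spatialCorrelation(maps(pt$topos)[i, ], Tm[lab[idx], ]))
  }, 0)
  expect_gt(min(rho0), 1 - 1e-9)

  # at the generator snr of 3, peak topographies stay close to the truth
  rec3 <- simulateEEG(cfg, sim$truth, "pat01", seed = 4)
  pt3 <- peakTopographies(rec3)
  rho3 <- vapply(seq_along(peakIndices(pt3$gfp)), function(i) {
    idx <- peakIndices(pt3$gfp)[i]
    abs(spatialCorrelation(maps(pt3$topos)[i, ], Tm[lab[idx], ]))
  }, 0)
  expect_gte(mean(rho3 >= 0.9), 0.95)
})

test_that("RSN time courses follow the coupling matrix", {
  cfg <- simConfig(durationS = 600, nSubjectsPerGroup = 1)
  sim <- simulateCohort(cfg, seed = 13, keepEEG = FALSE)
  lab <- sim$truth@labelSequences[["pat01"]]
  seg <- segFromLabels(lab, fs = cfg@fs, K = 4)
  regs <- buildRegressors(seg, cfg@trS, cfg@nVolumes)

  # noiseless identity: coupling A->comp2 = 1 reproduces the regressor
  cp <- matrix(0, 4, 15); cp[1, 2] <- 1
  cfgId <- simConfig(durationS = 600, nSubjectsPerGroup = 1, coupling = cp,
                     rsnSnr = 1e12)
  truthId <- new("GroundTruth", templates = sim$truth@templates,
                 labelSequences = sim$truth@labelSequences,
                 coupling = cp, subjects = sim$subjects)
  rsnId <- simulateRSNTimecourses(cfgId, truthId, "pat01", seed = 2)
  slopes <- sortComponents(regs, rsnId)
  expect_lt(abs(slopes["A", "comp2"] - 1), 1e-6)
  expect_lt(max(abs(slopes[, -2])), 1e-6)

  # zero coupling: pure AR(1) noise, slopes near zero
  cfg0 <- simConfig(durationS = 600, nSubjectsPerGroup = 1,
                    coupling = matrix(0, 4, 15))
  truth0 <- new("GroundTruth", templates = sim$truth@templates,
                labelSequences = sim$truth@labelSequences,
                coupling = cfg0@coupling, subjects = sim$subjects)
  rsn0 <- simulateRSNTimecourses(cfg0, truth0, "pat01", seed = 3)
  s0 <- sortComponents(regs, rsn0)
  # standardized coefficients of pure noise on 270 volumes: all small
  std <- s0 * apply(regs, 1, stats::sd) /
    rep(apply(rsn0@timecourses, 1, stats::sd), each = nrow(s0))
  expect_lt(max(abs(std)), 0.3)
})

test_that("two-group defaults reproduce the published duration ordering", {
  cfg <- simConfig(durationS = 200, nSubjectsPerGroup = 4)
  sim <- simulateCohort(cfg, seed = 17, keepEEG = FALSE)
  mets <- metricsFromTruth(cfg, sim)
  tab <- combineMetrics(mets)
  md <- tapply(tab$mean_duration_ms, list(tab$group, tab$state), mean)
  expect_gt(md["control", "A"], md["patient", "A"])
  expect_gt(md["patient", "B"], md["control", "B"])
  expect_gt(md["patient", "C"], md["control", "C"])
})
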