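# build a metrics table directly from a subjects x states value matrix
tableFromValues <- function(Y, subjects) {
  rows <- lapply(seq_len(nrow(Y)), function(i) {
    data.frame(subject_id = subjects$subject_id[i],
               group = subjects$group[i],
               state = colnames(Y), mean_duration_ms = Y[i, ],
               occurrence_per_s = 1, ratio_total_time = 1 / ncol(Y),
               gev = Y[i, ] / sum(Y[i, ]), visited = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

mkSubjects <- function(n) {
  data.frame(subject_id = sprintf("s%02d", seq_len(2 * n)),
             group = rep(c("control", "patient"), each = n),
             age = rep(seq(13, 20, length.out = n), 2),
             gender = rep(c("F", "M"), n), stringsAsFactors = FALSE)
}

test_that("identical groups give null post hoc statistics", {
  subj <- mkSubjects(6)
  set.seed(1)
  half <- matrix(rnorm(6 * 4, 80, 5), 6, 4,
                 dimnames = list(NULL, LETTERS[1:4]))
  Y <- rbind(half, half)  # patient block duplicates control block
  tab <- tableFromValues(Y, subj)
  ph <- posthocResidualT(tab, subj, "mean_duration")
  expect_equal(ph$t, rep(0, 4), tolerance = 1e-9)
  expect_equal(ph$p, rep(1, 4), tolerance = 1e-9)
})

test_that("with covariates orthogonal to group and outcome, residual t equals the plain t", {
  subj <- mkSubjects(8)
  set.seed(2)
  Y <- matrix(rnorm(16 * 4, 80, 5), 16, 4,
              dimnames = list(NULL, LETTERS[1:4]))
  Y[subj$group == "patient", 1] <- Y[subj$group == "patient", 1] + 10
  # make age/gender exactly orthogonal to each outcome column and to group:
  # both covariates repeat identically across the two groups, and we remove
  # their fitted effect from Y so the residualization is a no-op
  for (j in seq_len(4)) {
    fit <- lm(Y[, j] ~ age + gender, data = subj)
    adj <- fitted(fit) - mean(fitted(fit))
    Y[, j] <- Y[, j] - adj
  }
  tab <- tableFromValues(Y, subj)
  ph <- posthocResidualT(tab, subj, "mean_duration")
  for (j in seq_len(4)) {
    plain <- t.test(Y[subj$group == "control", j],
                    Y[subj$group == "patient", j], var.equal = TRUE)
    expect_equal(ph$t[j], unname(plain$statistic), tolerance = 1e-8)
    expect_equal(ph$p[j], plain$p.value, tolerance = 1e-8)
  }
})

test_that("complete separation reports a below-minimum p", {
  subj <- mkSubjects(4)
  # parameter constant within each group; covariates balanced across
  # groups, so residualization leaves the separation intact
  Y <- matrix(rep(c(100, 80), each = 4), 8, 4,
              dimnames = list(NULL, LETTERS[1:4]))
  tab <- tableFromValues(Y, subj)
  ph <- posthocResidualT(tab, subj, "mean_duration")
  expect_true(all(ph$p < .Machine$double.eps))
  expect_true(all(abs(ph$t) > 1e6))
})

test_that("rmAnova recovers a planted interaction; Wilks matches the SSP identity", {
  cfg <- simConfig(durationS = 150, nSubjectsPerGroup = 8)
  sim <- simulateCohort(cfg, seed = 51, keepEEG = FALSE)
  tab <- combineMetrics(metricsFromTruth(cfg, sim))
  res <- rmAnova(tab, sim$subjects, "mean_duration")
  expect_identical(res@degenerate, "")
  expect_lt(res@pMultivariate, 0.05)
  expect_true(res@wilksLambda > 0 && res@wilksLambda <= 1)
  # degrees of freedom of the one-between-factor Wilks F with covariates
  expect_equal(res@dfNum, 3)
  expect_equal(res@dfDen, 16 - 4 - 3 + 1)

  # independent route: Wilks = det(E) / det(E + H) from the SSP matrices of
  # the difference scores, H taken as the extra residual SSP of the model
  # without the group term
  Y <- sapply(LETTERS[1:4], function(s)
    tab$mean_duration_ms[tab$state == s])
  D <- Y[, -1] - Y[, 1]
  ids <- unique(tab$subject_id)
  cov <- data.frame(
    group = factor(sim$subjects$group[match(ids, sim$subjects$subject_id)]),
    age = sim$subjects$age[match(ids, sim$subjects$subject_id)],
    gender = factor(sim$subjects$gender[match(ids, sim$subjects$subject_id)]))
  E <- crossprod(resid(lm(D ~ age + gender + group, data = cov)))
  H <- crossprod(resid(lm(D ~ age + gender, data = cov))) - E
  wilks <- det(E) / det(E + H)
  expect_equal(res@wilksLambda, wilks, tolerance = 1e-9)
  # Rao F for a single-df hypothesis: F = (1 - L)/L * (dfe - p + 1)/p
  p <- ncol(D); dfe <- nrow(D) - 4
  expect_equal(res@F, (1 - wilks) / wilks * (dfe - p + 1) / p,
               tolerance = 1e-9)
})

test_that("group statistics are invariant to subject order and constant shifts", {
  cfg <- simConfig(durationS = 100, nSubjectsPerGroup = 5)
  sim <- simulateCohort(cfg, seed = 52, keepEEG = FALSE)
  tab <- combineMetrics(metricsFromTruth(cfg, sim))
  res <- rmAnova(tab, sim$subjects, "mean_duration")

  tabShift <- tab
  tabShift$mean_duration_ms <- tabShift$mean_duration_ms + 500
  resShift <- rmAnova(tabShift, sim$subjects, "mean_duration")
  expect_equal(resShift@wilksLambda, res@wilksLambda, tolerance = 1e-9)
  expect_equal(resShift@posthoc$t, res@posthoc$t, tolerance = 1e-9)

  perm <- sample(nrow(tab))
  resPerm <- rmAnova(tab[perm, ], sim$subjects, "mean_duration")
  expect_equal(resPerm@wilksLambda, res@wilksLambda, tolerance = 1e-9)
  expect_equal(resPerm@pMultivariate, res@pMultivariate, tolerance = 1e-9)
})

test_that("degenerate designs are reported, empty groups are an error", {
  subj <- mkSubjects(4)
  set.seed(3)
  Y <- matrix(rnorm(8 * 4, 80, 5), 8, 4, dimnames = list(NULL, LETTERS[1:4]))
  tab <- tableFromValues(Y, subj)
  subjOne <- subj
  subjOne$group <- "control"
  expect_error(rmAnova(tab, subjOne, "mean_duration"), "two groups")

  # constant outcome differences make the multivariate test singular
  Yc <- matrix(80, 8, 4, dimnames = list(NULL, LETTERS[1:4]))
  resDeg <- rmAnova(tableFromValues(Yc, subj), subj, "mean_duration")
  expect_true(nzchar(resDeg@degenerate))
})

test_that("transition probabilities enter as off-diagonal vectors", {
  cfg <- simConfig(durationS = 100, nSubjectsPerGroup = 8)
  sim <- simulateCohort(cfg, seed = 53, keepEEG = FALSE)
  tab <- combineMetrics(metricsFromTruth(cfg, sim))
  expect_equal(sum(grepl("^trans_", names(tab))), 12)
  res <- rmAnova(tab, sim$subjects, "transition")
  expect_identical(res@degenerate, "")
  expect_equal(res@dfNum, 11)
  expect_gt(res@pMultivariate, 0)
})
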