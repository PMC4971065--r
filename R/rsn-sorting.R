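#' Canonical double-gamma hemodynamic response function
#'
#' \eqn{h(t) = g(t; 6, 1) - g(t; 16, 1)/6} (gamma densities; peak at ~6 s,
#' undershoot at ~16 s, peak-to-undershoot ratio 6), truncated at 32 s.
#'
#' @param t time points in seconds.
#' @param peak,undershoot gamma shape parameters (seconds to peak /
#'   undershoot for unit rate).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param length response duration in seconds (zero beyond).
#' @return h(t), unit-less.
#' @export
canonicalHRF <- function(t, peak = 6, undershoot = 16, ratio = 6,
                         length = 32) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  h[t < 0 | t > length] <- 0
  h
}

# occupancy boxcars on a fine grid, HRF convolution, volume sampling
.regressorsFromLabels <- function(labels, fs, K, trS, nVolumes,
                                  gridHz = 100, hrfParams = list(),
                                  center = TRUE) {
  scanS <- nVolumes * trS
  if (length(labels) / fs < scanS - 1e-9)
    stop("segmentation is shorter than the scan")
  nGrid <- as.integer(ceiling(scanS * gridHz))
  tGrid <- (seq_len(nGrid) - 1) / gridHz
  srcIdx <- pmin(length(labels), floor(tGrid * fs) + 1L)
  labGrid <- labels[srcIdx]
  hrf <- do.call(canonicalHRF,
                 c(list(t = seq(0, 32, by = 1 / gridHz)), hrfParams))
  volIdx <- pmin(nGrid, as.integer(round((seq_len(nVolumes) - 1) * trS * gridHz)) + 1L)
  regs <- matrix(0, K, nVolumes)
  for (k in seq_len(K)) {
    box <- as.numeric(labGrid == k)
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(nGrid)] / gridHz
    regs[k, ] <- conv[volIdx]
  }
  rownames(regs) <- .stateNamesFor(K)
  if (center) regs <- regs - rowMeans(regs)
  regs
}

#' Build HRF-convolved microstate regressors at the fMRI TR
#'
#' The run onsets/durations of each microstate are expressed as an
#' occupancy boxcar on a fine grid (default 100 Hz, preserving the sub-TR
#' ~100 ms runs), convolved with the canonical double-gamma HRF, sampled at
#' the volume times \eqn{t_v = (v-1) TR}, and mean-centered.
#'
#' @param seg a [Segmentation-class] spanning at least
#'   \code{nVolumes * trS} seconds.
#' @param trS repetition time (s).
#' @param nVolumes number of volumes.
#' @param hrfParams optional list of [canonicalHRF()] parameter overrides.
#' @param gridHz fine-grid rate for the boxcars (Hz).
#' @param center mean-center each regressor (default TRUE).
#' @return microstates x volumes numeric matrix.
#' @export
buildRegressors <- function(seg, trS = 2.2, nVolumes = 270,
                            hrfParams = list(), gridHz = 100, center = TRUE) {
  regs <- .regressorsFromLabels(seg@labels, seg@fs, length(seg@stateNames),
                                trS, nVolumes, gridHz = gridHz,
                                hrfParams = hrfParams, center = center)
  rownames(regs) <- seg@stateNames
  regs
}

#' Regress RSN component time courses on the microstate regressors
#'
#' Per component, ordinary least squares of the component time course on
#' all K microstate regressors jointly, plus an intercept; the returned
#' slopes are the per-(microstate, component) regression coefficients.
#' Rank-deficient designs yield NA slopes for the aliased regressors.
#'
#' @param regs microstates x volumes regressor matrix ([buildRegressors()]).
#' @param rsn an [RSNTimecourseSet-class] with the same number of volumes.
#' @return microstates x components slope matrix.
#' @export
sortComponents <- function(regs, rsn) {
  Y <- rsn@timecourses
  if (ncol(Y) != ncol(regs)) stop("volume counts differ")
  X <- cbind(1, t(regs))
  fit <- stats::lm.fit(X, t(Y))
  coefs <- fit$coefficients[-1, , drop = FALSE]
  slopes <- matrix(coefs, nrow(regs), nrow(Y),
                   dimnames = list(rownames(regs), rsn@componentNames))
  slopes
}

#' Aggregate per-subject slopes into group Z maps
#'
#' Slopes are averaged per (microstate, component) within each group, then
#' standardized to Z-scores across the components within each
#' (microstate, group) cell -- so Z answers "which components stand out for
#' this microstate in this group". Cells with zero variance across
#' components get an all-zero Z row. Pairings with Z >= 1 (positive only)
#' are flagged for interpretation.
#'
#' @param slopes named list of per-subject microstates x components slope
#'   matrices ([sortComponents()]).
#' @param subjects subject table with \code{subject_id} and \code{group};
#'   both groups need >= 2 subjects.
#' @return A [SortingResult-class].
#' @export
aggregateZ <- function(slopes, subjects) {
  ids <- names(slopes)
  m <- match(ids, subjects$subject_id)
  if (anyNA(m)) stop("slopes contain subjects missing from the subject table")
  groups <- subjects$group[m]
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need at least 2 subjects in each group")
  d <- dim(slopes[[1]])
  arr <- array(NA_real_, c(length(ids), d[1], d[2]),
               dimnames = list(ids, rownames(slopes[[1]]),
                               colnames(slopes[[1]])))
  for (i in seq_along(ids)) arr[i, , ] <- slopes[[i]]
  groupMean <- list(); zMap <- list()
  flagged <- data.frame(group = character(0), state = character(0),
                        component = character(0), z = numeric(0),
                        stringsAsFactors = FALSE)
  for (g in sort(unique(groups))) {
    sub <- arr[groups == g, , , drop = FALSE]
    gm <- apply(sub, c(2, 3), mean)
    z <- gm
    for (k in seq_len(nrow(gm))) {
      s <- stats::sd(gm[k, ])
      z[k, ] <- if (is.finite(s) && s > 0) (gm[k, ] - mean(gm[k, ])) / s
                else 0
    }
    groupMean[[g]] <- gm
    zMap[[g]] <- z
    hit <- which(z >= 1, arr.ind = TRUE)
    if (nrow(hit))
      flagged <- rbind(flagged, data.frame(
        group = g, state = rownames(z)[hit[, 1]],
        component = colnames(z)[hit[, 2]], z = z[hit],
        stringsAsFactors = FALSE))
  }
  new("SortingResult", slopes = arr, groupMeanSlopes = groupMean,
      zMap = zMap, flagged = flagged)
}
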