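#' Simulation configuration
#'
#' Holds the generative conditions for the two-group synthetic cohort:
#' 64-channel EEG at 125 Hz, 10 minutes per subject, four microstates whose
#' group-wise mean dwell times default to the published patient/control
#' values (A 87.58/101.44, B 90.47/80.02, C 75.92/72.92, D 61.14/61.54 ms),
#' gamma-distributed dwell times, a rectified 10 Hz amplitude carrier, and
#' 15 RSN component time courses at TR 2.2 s over 270 volumes driven by a
#' known microstate-to-component coupling matrix.
#'
#' @slot nChannels,fs,durationS,KTrue basic EEG geometry.
#' @slot meanDurationMs groups x states matrix of mean dwell times (ms).
#' @slot durationShape gamma shape of the dwell-time distribution.
#' @slot carrierFreqHz,carrierAmplitude,phaseDriftHz amplitude-carrier
#'   parameters (rectified sinusoid, slow phase drift).
#' @slot snr ratio of state-signal RMS to noise RMS.
#' @slot transitionKernel optional K x K next-state kernel (zero diagonal,
#'   rows sum to 1); empty matrix means uniform over the other K-1 states.
#' @slot nSubjectsPerGroup,nComponents,trS,nVolumes fMRI-side geometry.
#' @slot coupling K x nComponents microstate-to-component slope matrix.
#' @slot ar1NoiseCoef AR(1) coefficient of the RSN noise.
#' @slot rsnSnr ratio of RSN signal SD to noise SD.
#' @slot seed default seed used by [simulateCohort()].
#'
#' @exportClass SimConfig
setClass("SimConfig",
  representation(nChannels = "numeric", fs = "numeric", durationS = "numeric",
    KTrue = "numeric", meanDurationMs = "matrix", durationShape = "numeric",
    carrierFreqHz = "numeric", carrierAmplitude = "numeric",
    phaseDriftHz = "numeric", snr = "numeric", transitionKernel = "matrix",
    nSubjectsPerGroup = "numeric", nComponents = "numeric", trS = "numeric",
    nVolumes = "numeric", coupling = "matrix", ar1NoiseCoef = "numeric",
    rsnSnr = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@KTrue < 2) msg <- c(msg, "KTrue must be >= 2")
    if (any(object@meanDurationMs <= 0)) msg <- c(msg, "durations must be > 0")
    if (object@snr <= 0) msg <- c(msg, "snr must be > 0")
    if (!all(is.finite(object@coupling))) msg <- c(msg, "coupling must be finite")
    if (nrow(object@coupling) != object@KTrue)
      msg <- c(msg, "coupling must have KTrue rows")
    if (length(msg)) msg else TRUE
  })

#' Default microstate-to-RSN coupling matrix
#'
#' States x components slope matrix: microstate A drives components 2 and 10
#' (the posterior and anterior default-mode components in the emulated
#' layout), B drives component 7, C components 4 and 9, D component 6.
#'
#' @param K number of states (extra states beyond 4 get zero rows).
#' @param nComponents number of RSN components.
#' @return K x nComponents numeric matrix.
#' @export
defaultCoupling <- function(K = 4, nComponents = 15) {
  cp <- matrix(0, K, nComponents,
               dimnames = list(.stateNamesFor(K), paste0("comp", seq_len(nComponents))))
  set1 <- function(st, comps, v) {
    if (st <= K) cp[st, comps] <<- v
  }
  set1(1L, c(2L, 10L), 1.0)
  set1(2L, 7L, 1.0)
  set1(3L, c(4L, 9L), 0.8)
  set1(4L, 6L, 1.0)
  cp
}

#' Build a simulation configuration
#'
#' All arguments default to the emulated study conditions; see
#' [SimConfig-class].
#'
#' @param nChannels,fs,durationS,KTrue EEG geometry.
#' @param meanDurationMs groups x states matrix (rows "patient", "control").
#' @param durationShape gamma shape for dwell times.
#' @param carrierFreqHz,carrierAmplitude,phaseDriftHz amplitude carrier.
#' @param snr state-signal RMS over noise RMS.
#' @param transitionKernel optional K x K next-state kernel; NULL = uniform.
#' @param nSubjectsPerGroup,nComponents,trS,nVolumes fMRI-side geometry.
#' @param coupling K x nComponents slope matrix.
#' @param ar1NoiseCoef,rsnSnr RSN noise model.
#' @param seed default cohort seed.
#' @return A validated [SimConfig-class].
#' @export
#' @examples
#' cfg <- simConfig(durationS = 10, nSubjectsPerGroup = 2)
#' cfg@meanDurationMs
simConfig <- function(nChannels = 64, fs = 125, durationS = 600, KTrue = 4,
                      meanDurationMs = NULL, durationShape = 2,
                      carrierFreqHz = 10, carrierAmplitude = 80,
                      phaseDriftHz = 0.5, snr = 3, transitionKernel = NULL,
                      nSubjectsPerGroup = 16, nComponents = 15, trS = 2.2,
                      nVolumes = 270, coupling = NULL, ar1NoiseCoef = 0.3,
                      rsnSnr = 1, seed = 1) {
  if (is.null(meanDurationMs)) {
    meanDurationMs <- rbind(
      patient = c(87.58, 90.47, 75.92, 61.14),
      control = c(101.44, 80.02, 72.92, 61.54))[, seq_len(min(4, KTrue)),
                                                drop = FALSE]
    if (KTrue > 4)
      meanDurationMs <- cbind(meanDurationMs,
                              matrix(80, 2, KTrue - 4))
    colnames(meanDurationMs) <- .stateNamesFor(KTrue)
  }
  if (is.null(coupling)) coupling <- defaultCoupling(KTrue, nComponents)
  if (is.null(transitionKernel)) transitionKernel <- matrix(0, 0, 0)
  new("SimConfig", nChannels = nChannels, fs = fs, durationS = durationS,
      KTrue = KTrue, meanDurationMs = meanDurationMs,
      durationShape = durationShape, carrierFreqHz = carrierFreqHz,
      carrierAmplitude = carrierAmplitude, phaseDriftHz = phaseDriftHz,
      snr = snr, transitionKernel = transitionKernel,
      nSubjectsPerGroup = nSubjectsPerGroup, nComponents = nComponents,
      trS = trS, nVolumes = nVolumes, coupling = coupling,
      ar1NoiseCoef = ar1NoiseCoef, rsnSnr = rsnSnr, seed = seed)
}

#' Ground truth of a simulated cohort
#'
#' @slot templates the generating [TemplateSet-class].
#' @slot labelSequences named list of per-subject per-sample state labels.
#' @slot coupling the microstate x component slope matrix used.
#' @slot subjects subject table (subject_id, group, age, gender).
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(templates = "TemplateSet", labelSequences = "list",
                 coupling = "matrix", subjects = "data.frame"))

# geometric base patterns mimicking the four canonical map classes
.canonicalRaw <- function(montage) {
  x <- montage@positions[, 1]
  y <- montage@positions[, 2]
  rbind(A = -(0.8 * x + 0.6 * y),            # left-posterior / right-anterior
        B = 0.8 * x - 0.6 * y,               # right-posterior / left-anterior
        C = y,                               # occipital-frontal gradient
        D = exp(-(x^2 + (y - 0.25)^2) / 0.35))  # fronto-central focus
}

# shrink rows against earlier rows until all pairwise |cor| <= maxAbsCor
.decorrelateRows <- function(M, maxAbsCor = 0.7, target = 0.65) {
  M <- t(apply(M, 1, .unitMap))
  for (pass in 1:50) {
    done <- TRUE
    for (i in seq_len(nrow(M))[-1]) for (j in seq_len(i - 1)) {
      r <- sum(M[i, ] * M[j, ])
      if (abs(r) > maxAbsCor) {
        done <- FALSE
        # remove enough of the shared component to land at |cor| = target
        lam <- (abs(r) - target) / (abs(r) * (1 - target * abs(r)))
        M[i, ] <- .unitMap(M[i, ] - lam * r * M[j, ])
      }
    }
    if (done) return(M)
  }
  stop("could not decorrelate template maps below |cor| = ", maxAbsCor)
}

#' Canonical A-D reference topographies
#'
#' Idealized, geometry-derived stand-ins for the four map classes reported
#' throughout the resting-state microstate literature: A (left-posterior to
#' right-anterior gradient), B (right-posterior to left-anterior), C
#' (occipital-frontal), D (fronto-central focus). Synthetic constructions,
#' not measured grand-average maps; used as the fixed reference for
#' canonical labeling and as the base maps of the generator.
#'
#' @param montage a [Montage-class].
#' @return A [TemplateSet-class] with labels A-D.
#' @export
canonicalTemplates <- function(montage) {
  maps <- .decorrelateRows(.canonicalRaw(montage))
  colnames(maps) <- montage@channelNames
  new("TemplateSet", maps = maps, labels = rownames(maps))
}

#' Packaged canonical reference maps for the built-in 64-channel montage
#'
#' Reads the copy of [canonicalTemplates()] for [standardMontage()] shipped
#' as a TSV in \code{extdata} (file name marks it as synthetic). Useful for
#' interoperability with external tools; within R, [canonicalTemplates()]
#' computes the same maps directly.
#'
#' @return A [TemplateSet-class] with labels A-D over 64 channels.
#' @export
packagedCanonicalTemplates <- function() {
  path <- system.file("extdata", "canonical_templates_synthetic_64.tsv",
                      package = "EEGmicrostates", mustWork = TRUE)
  df <- utils::read.delim(path)
  maps <- t(as.matrix(df[, -1]))
  colnames(maps) <- df$channel
  maps <- t(apply(maps, 1, .unitMap))   # re-normalize after 9-digit text
  new("TemplateSet", maps = maps, labels = rownames(maps))
}

#' Generate ground-truth microstate topographies
#'
#' The first four maps are the canonical A-D patterns of
#' [canonicalTemplates()]; additional maps (K > 4) are seeded smooth random
#' fields (RBF-weighted over electrode positions). All maps are
#' average-referenced, unit-norm, and pairwise |spatial correlation| <= 0.7.
#'
#' @param montage a [Montage-class].
#' @param K number of templates (2 <= K < number of channels).
#' @param seed RNG seed (only consumed when K > 4).
#' @return A [TemplateSet-class].
#' @export
makeTemplates <- function(montage, K = 4, seed = 1) {
  C <- nChannels(montage)
  if (K < 2) stop("K must be >= 2")
  if (K >= C) stop("K must be smaller than the channel count")
  base <- maps(canonicalTemplates(montage))
  maps <- base[seq_len(min(K, 4L)), , drop = FALSE]
  if (K > 4) {
    set.seed(seed)
    pos <- montage@positions
    D2 <- as.matrix(stats::dist(pos))^2
    Kern <- exp(-D2 / (2 * 0.35^2))
    for (k in 5:K) {
      for (try in 1:200) {
        cand <- .unitMap(drop(Kern %*% stats::rnorm(C)))
        if (max(abs(maps %*% cand)) <= 0.7) break
        if (try == 200) stop("could not draw a sufficiently distinct map")
      }
      maps <- rbind(maps, cand)
    }
  }
  rownames(maps) <- .stateNamesFor(K)
  colnames(maps) <- montage@channelNames
  new("TemplateSet", maps = maps, labels = rownames(maps))
}

#' Simulate a semi-Markov microstate label sequence
#'
#' Run lengths are gamma-distributed (shape \code{cfg@durationShape}) with
#' the configured per-state mean for the given group, rounded to at least
#' one sample; the next state is drawn uniformly among the other K-1 states
#' unless \code{cfg@transitionKernel} is set.
#'
#' @param cfg a [SimConfig-class].
#' @param group \code{"patient"} or \code{"control"} (a row of
#'   \code{cfg@meanDurationMs}).
#' @param seed RNG seed; NULL continues the current RNG stream.
#' @return Integer vector of length \code{fs * durationS} with values 1..K.
#' @export
simulateLabels <- function(cfg, group = "control", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- as.integer(cfg@KTrue)
  fs <- cfg@fs
  n <- as.integer(round(cfg@fs * cfg@durationS))
  mean_ms <- cfg@meanDurationMs[group, ]
  if (any(mean_ms < 1000 / fs))
    stop("mean duration below one sample period for group ", group)
  shape <- cfg@durationShape
  uniformKernel <- length(cfg@transitionKernel) == 0
  m <- as.integer(ceiling(n / (fs * min(mean_ms) / 1000) * 1.5) + 50L)
  repeat {
    if (uniformKernel) {
      # modular walk with uniform steps in 1..K-1 == uniform over other states
      s1 <- sample.int(K, 1L)
      u <- sample.int(K - 1L, m - 1L, replace = TRUE)
      states <- 1L + (s1 - 1L + c(0L, cumsum(u))) %% K
    } else {
      P <- cfg@transitionKernel
      states <- integer(m)
      states[1L] <- sample.int(K, 1L)
      for (i in 2:m) states[i] <- sample.int(K, 1L, prob = P[states[i - 1L], ])
    }
    lens_s <- stats::rgamma(m, shape = shape,
                            scale = (mean_ms[states] / 1000) / shape)
    lens <- pmax(1L, as.integer(round(lens_s * fs)))
    if (sum(lens) >= n) break
    m <- as.integer(m * 1.5)
  }
  rep(states, lens)[seq_len(n)]
}

#' Simulate a multichannel EEG recording from ground truth
#'
#' Each sample is the active state's template scaled by a rectified-sinusoid
#' amplitude carrier (frequency \code{carrierFreqHz}, slow random phase
#' drift), plus spatially white Gaussian noise scaled so that state-signal
#' RMS over noise RMS equals \code{cfg@snr}; the output is average-referenced
#' per sample.
#'
#' @param cfg a [SimConfig-class].
#' @param truth a [GroundTruth-class] holding the subject's label sequence.
#' @param subjectId which subject to synthesize.
#' @param seed RNG seed; NULL continues the current stream.
#' @param montage montage for the recording (defaults to the 64-channel
#'   built-in layout; must match \code{cfg@nChannels}).
#' @return An [EEGRecording-class] (channels x samples).
#' @export
simulateEEG <- function(cfg, truth, subjectId, seed = NULL,
                        montage = standardMontage()) {
  if (!is.null(seed)) set.seed(seed)
  labels <- truth@labelSequences[[subjectId]]
  if (is.null(labels)) stop("no label sequence for subject ", subjectId)
  Tm <- maps(truth@templates)
  if (ncol(Tm) != nChannels(montage))
    stop("montage channel count does not match the templates")
  n <- length(labels)
  C <- ncol(Tm)
  tt <- (seq_len(n) - 1) / cfg@fs
  phase <- cumsum(stats::rnorm(n, 0, 2 * pi * cfg@phaseDriftHz / cfg@fs))
  amp <- cfg@carrierAmplitude * abs(sin(2 * pi * cfg@carrierFreqHz * tt + phase))
  S <- Tm[labels, , drop = FALSE] * amp
  sigma <- sqrt(mean(S^2)) / cfg@snr
  X <- S + matrix(stats::rnorm(n * C, 0, sigma), n, C)
  X <- X - rowMeans(X)
  grp <- truth@subjects$group[match(subjectId, truth@subjects$subject_id)]
  if (is.na(grp)) grp <- "control"
  EEGRecording(t(X), fs = cfg@fs, montage = montage, subjectId = subjectId,
               group = grp)
}

#' Simulate RSN component time courses coupled to the microstate sequence
#'
#' Each component time course is the coupling-weighted sum of the
#' HRF-convolved state regressors (built from the subject's ground-truth
#' label sequence, sampled at the volume times) plus AR(1) Gaussian noise
#' with marginal SD = signal SD / \code{cfg@rsnSnr}.
#'
#' @inheritParams simulateEEG
#' @return An [RSNTimecourseSet-class] (components x volumes).
#' @export
simulateRSNTimecourses <- function(cfg, truth, subjectId, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- truth@labelSequences[[subjectId]]
  if (is.null(labels)) stop("no label sequence for subject ", subjectId)
  if (length(labels) < cfg@nVolumes * cfg@trS * cfg@fs)
    stop("label sequence does not cover the scan duration")
  cp <- truth@coupling
  if (nrow(cp) != cfg@KTrue || ncol(cp) != cfg@nComponents)
    stop("coupling matrix shape does not match the configuration")
  regs <- .regressorsFromLabels(labels, cfg@fs, cfg@KTrue, cfg@trS,
                                cfg@nVolumes)
  signal <- t(cp) %*% regs                     # components x volumes
  sds <- apply(signal, 1, stats::sd)
  sdRef <- if (any(sds > 0)) mean(sds[sds > 0]) else 1
  sigma <- sdRef / cfg@rsnSnr
  phi <- cfg@ar1NoiseCoef
  V <- cfg@nVolumes
  innov <- matrix(stats::rnorm(cfg@nComponents * V), cfg@nComponents, V)
  noise <- matrix(0, cfg@nComponents, V)
  noise[, 1] <- innov[, 1]
  for (v in 2:V) noise[, v] <- phi * noise[, v - 1] + sqrt(1 - phi^2) * innov[, v]
  tc <- signal + sigma * noise
  rownames(tc) <- paste0("comp", seq_len(cfg@nComponents))
  new("RSNTimecourseSet", timecourses = tc, trS = cfg@trS,
      componentNames = rownames(tc), subjectId = subjectId)
}

#' Simulate a full two-group cohort
#'
#' Draws a subject table (ages uniform 13-20, genders balanced), per-subject
#' ground-truth label sequences with the group-specific dwell-time means,
#' and optionally the EEG recordings and RSN time courses.
#'
#' @param cfg a [SimConfig-class].
#' @param seed cohort seed (defaults to \code{cfg@seed}).
#' @param montage montage matching \code{cfg@nChannels}.
#' @param keepEEG,keepRSN generate and keep the heavyweight per-subject data
#'   (set FALSE to obtain only the ground truth, e.g. when streaming
#'   subjects one at a time via [simulateEEG()]).
#' @return A list with elements \code{truth} ([GroundTruth-class]),
#'   \code{recordings} (named list of [EEGRecording-class] or NULL), and
#'   \code{rsn} (named list of [RSNTimecourseSet-class] or NULL).
#' @export
simulateCohort <- function(cfg, seed = cfg@seed, montage = standardMontage(),
                           keepEEG = TRUE, keepRSN = FALSE) {
  set.seed(seed)
  if (nChannels(montage) != cfg@nChannels)
    stop("montage channel count does not match cfg@nChannels")
  nG <- cfg@nSubjectsPerGroup
  ids <- c(sprintf("pat%02d", seq_len(nG)), sprintf("ctl%02d", seq_len(nG)))
  groups <- rep(c("patient", "control"), each = nG)
  subjects <- data.frame(
    subject_id = ids, group = groups,
    age = round(stats::runif(2 * nG, 13, 20), 1),
    gender = sample(c("F", "M"), 2 * nG, replace = TRUE),
    stringsAsFactors = FALSE)
  tmpl <- makeTemplates(montage, cfg@KTrue,
                        seed = sample.int(.Machine$integer.max, 1))
  subseeds <- sample.int(.Machine$integer.max - 1L, 3L * 2L * nG)
  labelSequences <- stats::setNames(vector("list", 2 * nG), ids)
  for (i in seq_along(ids))
    labelSequences[[i]] <- simulateLabels(cfg, groups[i], seed = subseeds[i])
  truth <- new("GroundTruth", templates = tmpl,
               labelSequences = labelSequences, coupling = cfg@coupling,
               subjects = subjects)
  recordings <- NULL
  if (keepEEG) {
    recordings <- stats::setNames(vector("list", 2 * nG), ids)
    for (i in seq_along(ids))
      recordings[[i]] <- simulateEEG(cfg, truth, ids[i],
                                     seed = subseeds[2 * nG + i],
                                     montage = montage)
  }
  rsn <- NULL
  if (keepRSN) {
    rsn <- stats::setNames(vector("list", 2 * nG), ids)
    for (i in seq_along(ids))
      rsn[[i]] <- simulateRSNTimecourses(cfg, truth, ids[i],
                                         seed = subseeds[4 * nG + i])
  }
  list(truth = truth, recordings = recordings, rsn = rsn,
       subjects = subjects)
}
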