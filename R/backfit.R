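#' Competitively backfit templates to a continuous recording
#'
#' Assigns every sample to the template with the largest absolute spatial
#' correlation (ties broken by the lowest template index). Samples whose
#' GFP falls below \code{gfpFloorFrac * median(GFP)} carry no usable
#' topographic information and inherit the previous sample's label (leading
#' low-GFP samples take the first valid label), preserving the
#' quasi-stability of the state sequence across amplitude troughs.
#'
#' @param rec an [EEGRecording-class].
#' @param templates a [TemplateSet-class] with matching channel count.
#' @param gfpFloorFrac fraction of the median GFP below which a sample
#'   inherits the previous label (default 0.5; see the methods vignette for
#'   the rationale).
#' @return A [Segmentation-class].
#' @export
backfit <- function(rec, templates, gfpFloorFrac = 0.5) {
  Tm <- maps(templates)
  if (ncol(Tm) != nrow(rec@data))
    stop("template channel count does not match the recording")
  X <- t(rec@data)                       # samples x channels
  Xc <- .centerRows(X)
  norms <- sqrt(rowSums(Xc^2))
  gfp <- norms / sqrt(ncol(Xc))
  safe <- pmax(norms, .Machine$double.xmin)
  Xn <- Xc / safe
  A <- abs(Xn %*% t(.unitRows(Tm)))
  lab <- max.col(A, ties.method = "first")
  corr <- A[cbind(seq_along(lab), lab)]
  low <- gfp < gfpFloorFrac * stats::median(gfp)
  if (any(low)) {
    lab[low] <- NA_integer_
    lab <- .locf(lab)
    corr[low] <- 0
  }
  new("Segmentation", labels = as.integer(lab), corr = pmin(corr, 1),
      stateNames = templates@labels, fs = rec@fs, subjectId = rec@subjectId)
}

#' Temporal microstate parameters from a segmentation
#'
#' Computes, per state: mean duration (mean run length in ms), occurrence
#' (runs per second), ratio of total time (fraction of samples), and
#' GFP-weighted GEV over all samples; plus the sample-to-sample transition
#' matrix (self-transitions on the diagonal, rows sum to 1) and a run-level
#' transition matrix (self-transitions excluded). States never visited get
#' zero duration/occurrence and are flagged \code{visited = FALSE}.
#'
#' @param seg a [Segmentation-class].
#' @param g the matching [GFPSeries-class] (GFP weights for GEV).
#' @param templates the [TemplateSet-class] used for the backfit.
#' @param group group label stored in the result.
#' @param trimEdges drop the first and last run before computing duration,
#'   occurrence and coverage (removes boundary truncation; default FALSE).
#' @return A [MicrostateMetrics-class].
#' @export
computeMetrics <- function(seg, g, templates, group = "control",
                           trimEdges = FALSE) {
  lab <- seg@labels
  if (length(lab) != length(g@values))
    stop("segmentation and GFP series lengths differ")
  K <- nrow(maps(templates))
  fs <- seg@fs
  r <- rle(lab)
  keepRuns <- seq_along(r$values)
  keepSamples <- rep(TRUE, length(lab))
  if (trimEdges && length(r$values) > 2) {
    keepRuns <- keepRuns[-c(1L, length(r$values))]
    drop1 <- seq_len(r$lengths[1L])
    dropN <- seq.int(length(lab) - r$lengths[length(r$lengths)] + 1L,
                     length(lab))
    keepSamples[c(drop1, dropN)] <- FALSE
  }
  vals <- r$values[keepRuns]
  lens <- r$lengths[keepRuns]
  totalSamples <- sum(keepSamples)
  stats <- data.frame(state = templates@labels,
                      mean_duration_ms = 0, occurrence_per_s = 0,
                      ratio_total_time = 0, gev = 0, visited = FALSE,
                      stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    sel <- vals == k
    if (any(sel)) {
      stats$visited[k] <- TRUE
      stats$mean_duration_ms[k] <- mean(lens[sel]) * 1000 / fs
      stats$occurrence_per_s[k] <- sum(sel) / (totalSamples / fs)
      stats$ratio_total_time[k] <- sum(lens[sel]) / totalSamples
    }
  }
  w2 <- g@values^2
  denom <- sum(w2)
  num <- w2 * seg@corr^2
  for (k in seq_len(K)) stats$gev[k] <- sum(num[lab == k]) / denom
  # sample-to-sample transitions (diagonal included)
  TM <- matrix(0, K, K, dimnames = list(templates@labels, templates@labels))
  from <- lab[-length(lab)]
  to <- lab[-1L]
  for (k in seq_len(K)) {
    sel <- from == k
    if (any(sel)) TM[k, ] <- tabulate(to[sel], K) / sum(sel)
  }
  # run-level transitions (self-transitions structurally absent)
  TR <- matrix(0, K, K, dimnames = dimnames(TM))
  if (length(r$values) > 1) {
    rf <- r$values[-length(r$values)]
    rt <- r$values[-1L]
    for (k in seq_len(K)) {
      sel <- rf == k
      if (any(sel)) TR[k, ] <- tabulate(rt[sel], K) / sum(sel)
    }
  }
  new("MicrostateMetrics", stats = stats, transitionMatrix = TM,
      transitionMatrixRuns = TR, subjectId = seg@subjectId, group = group)
}

#' Combine per-subject metrics into one long table
#'
#' @param metricsList list of [MicrostateMetrics-class] objects.
#' @return data.frame with columns subject_id, group, state, the four
#'   temporal parameters, and the flattened off-diagonal transition
#'   probabilities in wide companion columns (one \code{trans_<i>_<j>}
#'   column per ordered state pair).
#' @export
combineMetrics <- function(metricsList) {
  rows <- lapply(metricsList, function(mm) {
    df <- mm@stats
    df$subject_id <- mm@subjectId
    df$group <- mm@group
    TM <- mm@transitionMatrix
    K <- nrow(TM)
    for (i in seq_len(K)) for (j in seq_len(K)) if (i != j)
      df[[paste0("trans_", rownames(TM)[i], "_", colnames(TM)[j])]] <- TM[i, j]
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("subject_id", "group",
          setdiff(names(out), c("subject_id", "group")))]
}
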