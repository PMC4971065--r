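#' Band-pass filter, resample and average-reference a recording
#'
#' Zero-phase (forward-backward Butterworth) band-pass -- a 2nd-order
#' high-pass at \code{band[1]} cascaded with an 8th-order low-pass at
#' \code{band[2]} -- followed by decimation to \code{targetFs} and per-sample
#' average referencing. Zero-phase filtering keeps GFP peak latencies in
#' place; the steep low-pass gives < 5\% leakage one quarter-octave above
#' the band edge.
#'
#' @param rec an [EEGRecording-class].
#' @param band numeric length-2, band edges in Hz (low, high).
#' @param targetFs output sampling rate; \code{rec} rate must be an integer
#'   multiple.
#' @return A filtered, resampled, average-referenced [EEGRecording-class].
#' @export
preprocess <- function(rec, band = c(1, 40), targetFs = 125) {
  fs <- rec@fs
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < targetFs / 2 &&
        targetFs <= fs))
    stop("band must satisfy 0 < low < high < targetFs/2 <= fs/2")
  hp <- signal::butter(2, band[1] / (fs / 2), type = "high")
  lp <- signal::butter(8, band[2] / (fs / 2), type = "low")
  X <- rec@data
  for (ch in seq_len(nrow(X))) {
    v <- signal::filtfilt(hp, X[ch, ])
    X[ch, ] <- signal::filtfilt(lp, v)
  }
  fac <- fs / targetFs
  if (abs(fac - round(fac)) > 1e-9)
    stop("rec sampling rate must be an integer multiple of targetFs")
  fac <- as.integer(round(fac))
  if (fac > 1L) X <- X[, seq(1L, ncol(X), by = fac), drop = FALSE]
  X <- sweep(X, 2L, colMeans(X))
  EEGRecording(X, fs = targetFs, montage = rec@montage,
               subjectId = rec@subjectId, group = rec@group)
}

#' Compute the global field power series
#'
#' GFP at each sample is the population (divide-by-C) standard deviation of
#' the average-referenced topography across channels -- the conventional
#' definition of field strength.
#'
#' @param rec an [EEGRecording-class] with at least 2 channels.
#' @return A [GFPSeries-class] with empty peak slots (see [findGFPPeaks()]).
#' @export
#' @examples
#' m <- Montage(paste0("ch", 1:4), cbind(c(-1, 0, 1, 0), c(0, 1, 0, -1)))
#' rec <- EEGRecording(matrix(c(2, 0, -2, 0), 4, 1), 125, m)
#' gfpValues(computeGFP(rec))  # sqrt(2)
computeGFP <- function(rec) {
  if (nrow(rec@data) < 2L) stop("GFP needs at least two channels")
  Xc <- sweep(rec@data, 2L, colMeans(rec@data))
  vals <- sqrt(colMeans(Xc^2))
  new("GFPSeries", values = vals, peakIndices = integer(0),
      excludedPeakIndices = integer(0), fs = rec@fs)
}

#' Identify GFP peaks with an automated amplitude-exclusion rule
#'
#' Retains interior strict local maxima (for plateaus, the first sample of
#' the plateau); endpoints are never peaks. Peaks whose GFP exceeds
#' \code{median + exclusionZ * MAD} of the peak amplitudes are moved to the
#' excluded set -- a deterministic surrogate for the visual rejection of
#' noisy high-amplitude peaks.
#'
#' @param g a [GFPSeries-class] with >= 3 samples.
#' @param exclusionZ robust-Z threshold for amplitude outliers (default 5).
#' @return The series with \code{peakIndices} / \code{excludedPeakIndices}
#'   filled in.
#' @export
findGFPPeaks <- function(g, exclusionZ = 5) {
  v <- g@values
  n <- length(v)
  if (n < 3L) stop("need at least 3 samples to find peaks")
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) {
        peaks <- c(peaks, i)
        i <- j + 1L
        next
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  excluded <- integer(0)
  if (length(peaks) >= 2L && is.finite(exclusionZ)) {
    pv <- v[peaks]
    thr <- stats::median(pv) + exclusionZ * stats::mad(pv)
    excluded <- peaks[pv > thr]
    peaks <- setdiff(peaks, excluded)
  }
  new("GFPSeries", values = v, peakIndices = as.integer(peaks),
      excludedPeakIndices = as.integer(excluded), fs = g@fs)
}

#' Extract average-referenced topographies at retained GFP peaks
#'
#' @param rec the [EEGRecording-class] the GFP series came from.
#' @param g a [GFPSeries-class] with identified peaks.
#' @return A [TopographySet-class], one row per retained peak, in temporal
#'   order.
#' @export
extractTopographies <- function(rec, g) {
  if (!length(g@peakIndices)) stop("no retained GFP peaks to extract")
  M <- t(rec@data[, g@peakIndices, drop = FALSE])
  M <- .centerRows(M)
  colnames(M) <- rec@montage@channelNames
  new("TopographySet", maps = M, sourceIndices = g@peakIndices,
      subjectId = rec@subjectId)
}

#' Concatenate topography sets
#'
#' Stacks peak maps across subjects (the pooled-group clustering input).
#'
#' @param ... [TopographySet-class] objects, or a single list of them.
#' @return A single [TopographySet-class] with subjectId "" and source
#'   indices re-used from the inputs.
#' @export
concatTopographies <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !is(sets[[1L]], "TopographySet"))
    sets <- sets[[1L]]
  maps <- do.call(rbind, lapply(sets, maps))
  idx <- unlist(lapply(sets, function(s) s@sourceIndices))
  new("TopographySet", maps = maps, sourceIndices = as.integer(idx),
      subjectId = "")
}
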