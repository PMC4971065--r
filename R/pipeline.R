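#' GFP peaks and topographies for one recording
#'
#' Convenience wrapper: GFP series, peak detection with the amplitude
#' exclusion rule, and topography extraction.
#'
#' @param rec an [EEGRecording-class] (already preprocessed).
#' @param exclusionZ robust-Z amplitude threshold for [findGFPPeaks()].
#' @return list with \code{gfp} ([GFPSeries-class]) and \code{topos}
#'   ([TopographySet-class]).
#' @export
peakTopographies <- function(rec, exclusionZ = 5) {
  g <- findGFPPeaks(computeGFP(rec), exclusionZ = exclusionZ)
  list(gfp = g, topos = extractTopographies(rec, g))
}

#' Full microstate analysis of a cohort of recordings
#'
#' Extracts GFP-peak topographies per subject, concatenates them across the
#' whole cohort (both groups pooled, so between-group comparisons use a
#' common template set), clusters with [modifiedKMeans()], relabels against
#' the canonical A-D reference, backfits every subject, and computes the
#' temporal parameters.
#'
#' @param recordings named list of [EEGRecording-class] (one per subject).
#' @param subjects subject table (subject_id, group, age, gender).
#' @param K number of microstate classes (default 4).
#' @param nRestarts,seed,templateUpdate clustering options.
#' @param exclusionZ GFP-peak amplitude exclusion threshold.
#' @param gfpFloorFrac backfit GFP floor (see [backfit()]).
#' @param reference template reference for canonical labeling; NULL uses
#'   [canonicalTemplates()] on the first recording's montage (only for
#'   K <= 4).
#' @return list: \code{clustering} ([ClusteringResult-class], canonically
#'   labeled), \code{segmentations}, \code{metrics} (per-subject
#'   [MicrostateMetrics-class]), \code{metricsTable} (long data.frame).
#' @export
microstatePipeline <- function(recordings, subjects, K = 4, nRestarts = 50,
                               seed = 1, templateUpdate = "mean",
                               exclusionZ = 5, gfpFloorFrac = 0.5,
                               reference = NULL) {
  peaks <- lapply(recordings, peakTopographies, exclusionZ = exclusionZ)
  pooled <- concatTopographies(lapply(peaks, `[[`, "topos"))
  cl <- modifiedKMeans(pooled, K, nRestarts = nRestarts, seed = seed,
                       templateUpdate = templateUpdate)
  if (is.null(reference) && K <= 4) {
    ref <- canonicalTemplates(recordings[[1]]@montage)
    ref <- new("TemplateSet", maps = maps(ref)[seq_len(K), , drop = FALSE],
               labels = ref@labels[seq_len(K)])
    cl <- canonicalLabeling(cl, ref)
  } else if (!is.null(reference)) {
    cl <- canonicalLabeling(cl, reference)
  }
  segs <- list(); mets <- list()
  for (id in names(recordings)) {
    seg <- backfit(recordings[[id]], cl@templates,
                   gfpFloorFrac = gfpFloorFrac)
    grp <- subjects$group[match(id, subjects$subject_id)]
    mets[[id]] <- computeMetrics(seg, peaks[[id]]$gfp, cl@templates,
                                 group = grp)
    segs[[id]] <- seg
  }
  list(clustering = cl, segmentations = segs, metrics = mets,
       metricsTable = combineMetrics(mets))
}
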