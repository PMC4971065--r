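#' Construct an EEG recording
#'
#' @param data channels x samples numeric matrix (microvolts), rows in
#'   montage channel order.
#' @param fs sampling rate in Hz.
#' @param montage a [Montage-class].
#' @param subjectId,group subject metadata.
#' @return An [EEGRecording-class].
#' @export
EEGRecording <- function(data, fs, montage, subjectId = "subject",
                         group = "control") {
  rownames(data) <- montage@channelNames
  new("EEGRecording", data = data, fs = fs, subjectId = subjectId,
      group = group, montage = montage)
}

.matchChannels <- function(data, labels, montage) {
  keep <- match(montage@channelNames, labels)
  if (all(is.na(keep))) stop("zero channels matched the montage")
  if (anyNA(keep))
    stop("montage channels missing from file: ",
         paste(montage@channelNames[is.na(keep)], collapse = ", "))
  dropped <- setdiff(labels, montage@channelNames)
  if (length(dropped))
    warning("dropping ", length(dropped),
            " channel(s) not in montage: ", paste(dropped, collapse = ", "))
  data[keep, , drop = FALSE]
}

#' Read an EEG recording, matching channels to a montage
#'
#' Accepts an EDF file or a delimited numeric matrix (TSV with a header of
#' channel names, one row per sample; \code{fs} must then be supplied).
#' File channels are matched to the montage by name, in montage order;
#' channels absent from the montage (e.g. ECG) are dropped with a warning.
#'
#' @param path path to the EDF or delimited file.
#' @param montage a [Montage-class].
#' @param fs sampling rate in Hz, required for delimited input; ignored
#'   for EDF (taken from the header).
#' @param subjectId,group subject metadata.
#' @return An [EEGRecording-class] with one row per montage channel.
#' @export
readEEG <- function(path, montage, fs = NULL, subjectId = "subject",
                    group = "control") {
  if (!file.exists(path)) stop("EEG file not found: ", path)
  magic <- readBin(path, "raw", 8L)
  isEDF <- grepl("\\.edf$", path, ignore.case = TRUE) ||
    identical(rawToChar(magic), "0       ")
  if (isEDF) {
    edf <- readEDF(path)
    data <- .matchChannels(edf$data, edf$labels, montage)
    fs <- unname(edf$fs)
  } else {
    if (is.null(fs)) stop("fs must be supplied for delimited EEG input")
    df <- utils::read.delim(path, check.names = FALSE)
    if (!all(vapply(df, is.numeric, TRUE)))
      stop("non-numeric values in delimited EEG file: ", path)
    data <- .matchChannels(t(as.matrix(df)), colnames(df), montage)
  }
  EEGRecording(data, fs = fs, montage = montage, subjectId = subjectId,
               group = group)
}

#' Write an EEG recording as a delimited matrix
#'
#' One row per sample, one column per channel (header = channel names);
#' the plain-text companion to [writeEDF()].
#'
#' @param rec an [EEGRecording-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEEGMatrix <- function(rec, path) {
  df <- as.data.frame(t(rec@data))
  colnames(df) <- rec@montage@channelNames
  utils::write.table(format(df, digits = 9, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subject table
#'
#' TSV with columns \code{subject_id}, \code{group}, \code{age},
#' \code{gender}.
#'
#' @param path file path.
#' @return data.frame with the four columns; subject ids are checked unique.
#' @export
readSubjectTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "gender")
  if (!all(need %in% names(df)))
    stop("subject table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$subject_id)) stop("duplicate subject ids")
  df
}

#' Read/write RSN component time courses
#'
#' The TSV layout is one row per volume, one column per component (header =
#' component names).
#'
#' @param path file path.
#' @param trS repetition time in seconds.
#' @param subjectId subject label.
#' @return An [RSNTimecourseSet-class].
#' @export
readTimecourses <- function(path, trS, subjectId = "subject") {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(vapply(df, is.numeric, TRUE)))
    stop("non-numeric values in time-course file: ", path)
  tc <- t(as.matrix(df))
  new("RSNTimecourseSet", timecourses = tc, trS = trS,
      componentNames = rownames(tc), subjectId = subjectId)
}

#' @param rsn an [RSNTimecourseSet-class].
#' @rdname readTimecourses
#' @export
writeTimecourses <- function(rsn, path) {
  df <- as.data.frame(t(rsn@timecourses))
  colnames(df) <- rsn@componentNames
  utils::write.table(format(df, digits = 9, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write result tables with a JSON manifest
#'
#' Writes one TSV per named table (matrices keep row names as a leading
#' \code{row} column), with floats at 9 significant digits and deterministic
#' column order, plus a \code{manifest.json} listing the files and an MD5
#' hash of the configuration.
#'
#' @param tables non-empty named list of data.frames or matrices.
#' @param outDir output directory (created if needed).
#' @param config optional list describing the run configuration; hashed
#'   into the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
writeResults <- function(tables, outDir, config = list()) {
  if (!length(tables) || is.null(names(tables)) || any(names(tables) == ""))
    stop("'tables' must be a non-empty named list")
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  files <- character(0)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (is.matrix(tb)) {
      df <- data.frame(row = if (is.null(rownames(tb)))
        seq_len(nrow(tb)) else rownames(tb), as.data.frame(tb),
        check.names = FALSE)
    } else df <- as.data.frame(tb)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) format(x, digits = 9, trim = TRUE))
    fn <- paste0(nm, ".tsv")
    utils::write.table(df, file.path(outDir, fn), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, fn)
  }
  cfgFile <- tempfile()
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), cfgFile)
  hash <- unname(tools::md5sum(cfgFile))
  unlink(cfgFile)
  manifest <- list(files = files, config_md5 = hash)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(outDir, "manifest.json"))
  invisible(manifest)
}
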