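# Minimal EDF (European Data Format) I/O.
#
# Implements the standard EDF layout: a 256-byte ASCII header, 256 bytes of
# per-signal ASCII fields, then data records of little-endian 16-bit integers
# scaled linearly between the digital and physical ranges. Continuous
# multichannel recordings with a common sampling rate only; EDF+ annotation
# channels are passed through as ordinary signals (callers drop them by name).

.edfField <- function(x, width) {
  x <- substr(format(x, width = width), 1, width)
  formatC(x, width = width, flag = "-")
}

.edfNum <- function(raw, offset, width, n = 1L) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- rawToChar(raw[(offset + (i - 1L) * width + 1L):(offset + i * width)])
    out[i] <- as.numeric(trimws(s))
  }
  out
}

.edfStr <- function(raw, offset, width, n = 1L) {
  out <- character(n)
  for (i in seq_len(n)) {
    s <- rawToChar(raw[(offset + (i - 1L) * width + 1L):(offset + i * width)])
    out[i] <- trimws(s)
  }
  out
}

#' Read an EDF file
#'
#' Returns the raw signal matrix and header metadata; see [readEEG()] for the
#' montage-matched high-level interface.
#'
#' @param path path to an EDF file.
#' @return A list with \code{data} (signals x samples matrix, physical
#'   units), \code{labels}, \code{fs} (per-signal sampling rate, Hz),
#'   and \code{recordDuration}.
#' @export
readEDF <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  if (length(hdr) < 256L) stop("not an EDF file (truncated header): ", path)
  nRecords <- .edfNum(hdr, 236L, 8L)
  recDur <- .edfNum(hdr, 244L, 8L)
  ns <- as.integer(.edfNum(hdr, 252L, 4L))
  if (!is.finite(ns) || ns < 1L) stop("not an EDF file (bad signal count)")
  sig <- readBin(con, "raw", 256L * ns)
  off <- 0L
  labels <- .edfStr(sig, off, 16L, ns); off <- off + 16L * ns
  off <- off + 80L * ns                       # transducer
  off <- off + 8L * ns                        # physical dimension
  physMin <- .edfNum(sig, off, 8L, ns); off <- off + 8L * ns
  physMax <- .edfNum(sig, off, 8L, ns); off <- off + 8L * ns
  digMin <- .edfNum(sig, off, 8L, ns); off <- off + 8L * ns
  digMax <- .edfNum(sig, off, 8L, ns); off <- off + 8L * ns
  off <- off + 80L * ns                       # prefilter
  spr <- as.integer(.edfNum(sig, off, 8L, ns))
  if (length(unique(spr)) != 1L)
    stop("EDF signals with differing samples-per-record are not supported")
  spr1 <- spr[1L]
  total <- as.integer(nRecords) * spr1
  raw <- readBin(con, "integer", n = as.integer(nRecords) * ns * spr1,
                 size = 2L, signed = TRUE, endian = "little")
  if (length(raw) < as.integer(nRecords) * ns * spr1)
    stop("EDF data shorter than header declares")
  # records x (signal-major blocks of spr samples)
  data <- matrix(NA_real_, ns, total)
  dim(raw) <- c(spr1, ns, as.integer(nRecords))
  for (s in seq_len(ns)) {
    dig <- as.numeric(raw[, s, ])
    scale <- (physMax[s] - physMin[s]) / (digMax[s] - digMin[s])
    data[s, ] <- (dig - digMin[s]) * scale + physMin[s]
  }
  rownames(data) <- labels
  list(data = data, labels = labels, fs = spr1 / recDur,
       recordDuration = recDur)
}

#' Write an EDF file
#'
#' @param data signals x samples numeric matrix with row names as channel
#'   labels (physical units, e.g. microvolts).
#' @param fs sampling rate in Hz.
#' @param path output path.
#' @param patient,recording free-text header fields.
#' @return \code{path}, invisibly. Values are quantized to the EDF 16-bit
#'   range per channel, so the round trip is exact only to about
#'   \code{range/65534} per channel.
#' @export
writeEDF <- function(data, fs, path, patient = "X", recording = "X") {
  stopifnot(is.matrix(data), fs > 0)
  ns <- nrow(data)
  n <- ncol(data)
  if (is.null(rownames(data))) stop("data must have channel row names")
  if (n %% round(fs) == 0 && abs(fs - round(fs)) < 1e-9) {
    spr <- as.integer(round(fs)); recDur <- 1
  } else {
    spr <- n; recDur <- n / fs
  }
  nRecords <- as.integer(n / spr)
  physMin <- apply(data, 1, min)
  physMax <- apply(data, 1, max)
  flat <- physMax - physMin <= 0
  physMax[flat] <- physMin[flat] + 1
  digMin <- rep(-32768L, ns); digMax <- rep(32767L, ns)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfField("0", 8L), .edfField(patient, 80L), .edfField(recording, 80L),
    .edfField("01.01.00", 8L), .edfField("00.00.00", 8L),
    .edfField(256L * (1L + ns), 8L), .edfField("", 44L),
    .edfField(nRecords, 8L), .edfField(format(recDur, digits = 7), 8L),
    .edfField(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste0(vapply(vals, .edfField, "", width = width),
                     collapse = ""), con, eos = NULL)
  fld(rownames(data), 16L)
  fld(rep("", ns), 80L)
  fld(rep("uV", ns), 8L)
  fld(format(physMin, digits = 7), 8L)
  fld(format(physMax, digits = 7), 8L)
  fld(digMin, 8L)
  fld(digMax, 8L)
  fld(rep("", ns), 80L)
  fld(rep(spr, ns), 8L)
  fld(rep("", ns), 32L)
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRecords)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((data[s, cols] - physMin[s]) / scale[s] + digMin[s])
      dig <- pmin(pmax(dig, digMin[s]), digMax[s])
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
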