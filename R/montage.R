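#' Construct a montage
#'
#' @param channelNames character vector of unique channel labels.
#' @param positions numeric matrix (channels x 2) of 2-D scalp positions,
#'   head seen from above, nose up.
#' @return A [Montage-class].
#' @export
#' @examples
#' m <- Montage(c("Cz", "Pz"), rbind(c(0, 0), c(0, -0.45)))
#' nChannels(m)
Montage <- function(channelNames, positions) {
  positions <- as.matrix(positions)
  dimnames(positions) <- list(channelNames, c("x", "y"))
  new("Montage", channelNames = as.character(channelNames),
      positions = positions)
}

# 64-channel extended 10-20 layout: row letters fix the anterior-posterior
# coordinate, electrodes are spread evenly along each row's chord of the
# (unit-radius) head disc. Positions are schematic, adequate for the spatial
# patterns used here; they are not digitized electrode coordinates.
.rows1020 <- list(
  Fp = c("Fp1", "Fpz", "Fp2"),
  AF = c("AF7", "AF3", "AFz", "AF4", "AF8"),
  F  = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
  FC = c("FT9", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
         "FT8", "FT10"),
  C  = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
  CP = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
  P  = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
  PO = c("PO7", "PO3", "POz", "PO4", "PO8"),
  O  = c("O1", "Oz", "O2"),
  I  = "Iz")

.rowY1020 <- c(Fp = 0.85, AF = 0.65, F = 0.45, FC = 0.22, C = 0,
               CP = -0.22, P = -0.45, PO = -0.65, O = -0.85, I = -0.98)

#' Built-in standard montages
#'
#' \code{"standard-10-20-64"} is a 64-channel extended 10-20 layout
#' (Fp1..Iz) with schematic 2-D head-top coordinates, available without any
#' montage file.
#'
#' @param name montage name; currently only \code{"standard-10-20-64"}.
#' @return A [Montage-class].
#' @export
#' @examples
#' nChannels(standardMontage())
standardMontage <- function(name = "standard-10-20-64") {
  if (!identical(name, "standard-10-20-64"))
    stop("unknown built-in montage: ", name)
  nm <- character(0); xx <- numeric(0); yy <- numeric(0)
  for (r in names(.rows1020)) {
    lab <- .rows1020[[r]]
    n <- length(lab)
    y <- .rowY1020[[r]]
    halfw <- 0.95 * sqrt(max(0, 1 - (y / 1.05)^2))
    x <- if (n == 1) 0 else seq(-halfw, halfw, length.out = n)
    nm <- c(nm, lab); xx <- c(xx, x); yy <- c(yy, rep(y, n))
  }
  Montage(nm, cbind(xx, yy))
}

#' Read a montage from a delimited file
#'
#' Expects a tab- or whitespace-delimited file with three columns
#' (channel name, x, y) and no header, or the name of a built-in montage
#' (see [standardMontage()]).
#'
#' @param path file path, or a built-in montage name.
#' @return A [Montage-class].
#' @export
readMontage <- function(path) {
  if (identical(path, "standard-10-20-64")) return(standardMontage(path))
  if (!file.exists(path)) stop("montage file not found: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("malformed montage file: need name, x, y columns")
  if (!is.numeric(df[[2]]) || !is.numeric(df[[3]]))
    stop("malformed montage file: coordinates must be numeric")
  if (anyDuplicated(df[[1]]))
    stop("duplicate channel names in montage file: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  Montage(df[[1]], cbind(df[[2]], df[[3]]))
}

#' Write a montage to a delimited file
#'
#' @param montage a [Montage-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMontage <- function(montage, path) {
  df <- data.frame(name = montage@channelNames,
                   x = format(montage@positions[, 1], digits = 9),
                   y = format(montage@positions[, 2], digits = 9))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
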