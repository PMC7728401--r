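## Delimited-text readers and writers. Traces are neurons-as-rows; frame
## indices in files are 0-based. Auto-transposing is refused: an explicitly
## mis-oriented file must be fixed or read with transpose = TRUE.

#' Read a fluorescence trace matrix from delimited text
#'
#' Expects a numeric neurons x frames matrix (CSV/TSV by extension, header
#' optional and auto-detected). Any non-finite entry is rejected with its
#' (row, column) location. The orientation is taken as-is; set
#' `transpose = TRUE` explicitly for frames-as-rows files.
#'
#' @param path file path
#' @param fs imaging rate in Hz (required; not stored in the file)
#' @param transpose set TRUE only for frames x neurons files
#' @return a \linkS4class{FluorescenceSet}
#' @export
readTraces <- function(path, fs, transpose = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  first <- readLines(path, n = 1)
  hasHeader <- anyNA(suppressWarnings(
    as.numeric(strsplit(first, sep, fixed = TRUE)[[1]])))
  df <- utils::read.table(path, sep = sep, header = hasHeader,
                          colClasses = "numeric")
  M <- as.matrix(df)
  dimnames(M) <- NULL
  bad <- which(!is.finite(M), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite entry at row ", bad[1, 1], ", column ", bad[1, 2])
  if (transpose) M <- t(M)
  FluorescenceSet(M, fs = fs)
}

#' Read a stimulus specification
#'
#' Two accepted formats, distinguished by shape: a binary K x T design
#' matrix (entries 0/1 only), or a two-column onset table with 0-based
#' frame index and stimulus label. Onset tables are expanded to
#' single-frame onsets; duplicate (frame, stimulus) pairs are collapsed
#' with a warning. `shiftCount > 0` appends time-shifted copies of each
#' stimulus row (shifted by 1..shiftCount frames).
#'
#' @param path file path (CSV/TSV)
#' @param T total number of frames (required for onset tables)
#' @param shiftCount number of shifted copies to append
#' @return a \linkS4class{StimulusDesign}
#' @export
readStimulus <- function(path, T = NULL, shiftCount = 0L) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  first <- readLines(path, n = 1)
  hasHeader <- anyNA(suppressWarnings(
    as.numeric(strsplit(first, sep, fixed = TRUE)[[1]][1])))
  df <- utils::read.table(path, sep = sep, header = hasHeader)
  if (ncol(df) == 2) {
    if (is.null(T)) stop("T must be supplied with an onset table")
    frames <- as.integer(df[[1]])
    labels <- as.character(df[[2]])
    if (any(frames < 0 | frames >= T)) stop("onset frame out of range [0, T)")
    dup <- duplicated(paste(frames, labels))
    if (any(dup)) {
      warning("collapsing ", sum(dup), " duplicate (frame, stimulus) pair(s)")
      frames <- frames[!dup]; labels <- labels[!dup]
    }
    lev <- unique(labels)
    design <- matrix(0, length(lev), T)
    for (i in seq_along(frames))
      design[match(labels[i], lev), frames[i] + 1L] <- 1
    S <- StimulusDesign(design, stimLabels = lev)
  } else {
    M <- as.matrix(df)
    dimnames(M) <- NULL
    if (!all(M %in% c(0, 1))) stop("design matrix entries must be 0 or 1")
    S <- StimulusDesign(M)
  }
  if (shiftCount > 0) S <- expandShiftedCopies(S, shiftCount) else S
}

#' Append time-shifted copies of each stimulus row
#'
#' Models temporally extended responses: each stimulus contributes
#' `shiftCount` extra rows, shifted right by 1..shiftCount frames, growing
#' K rows to (shiftCount + 1) K.
#'
#' @param S a \linkS4class{StimulusDesign}
#' @param shiftCount number of single-frame shifts (>= 1)
#' @return an expanded \linkS4class{StimulusDesign}
#' @export
expandShiftedCopies <- function(S, shiftCount) {
  stopifnot2(shiftCount >= 1, "shiftCount must be >= 1")
  d <- S@design
  Tt <- ncol(d)
  rows <- list()
  labels <- character(0)
  for (i in seq_len(nrow(d))) for (s in 0:shiftCount) {
    r <- rep(0, Tt)
    if (s < Tt) r[(1 + s):Tt] <- d[i, seq_len(Tt - s)]
    rows[[length(rows) + 1L]] <- r
    labels <- c(labels, if (s == 0) S@stimLabels[i] else
      paste0(S@stimLabels[i], "+", s))
  }
  StimulusDesign(do.call(rbind, rows), stimLabels = labels,
                 shiftCount = as.integer(shiftCount))
}

#' Write a trace matrix as CSV
#'
#' @param F a \linkS4class{FluorescenceSet} or bare matrix
#' @param path output path
#' @return invisibly, the path
#' @export
writeTraces <- function(F, path) {
  M <- if (is(F, "FluorescenceSet")) F@traces else as.matrix(F)
  utils::write.table(M, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
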