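# MAF parsing for split-read alignments, gap extraction, and the
# gentle-masking maximal-segment score used to discard alignments made
# almost entirely of soft-masked simple sequence.
#
# The dialect is the split-aligner convention: each block has an "a"
# line (score=..., mismap=...) and exactly two "s" lines, reference row
# first, read row second.  Lowercase letters are soft-masking and are
# preserved.  Read-row coordinates are strand-local per the MAF standard
# and are converted to forward-read orientation on input.

#' Alignment scoring parameters
#'
#' Substitution and affine-gap parameters used only for the
#' gentle-masking filter.  Defaults are of the order produced by score
#' training on long reads; they are deliberately harsh on mismatches so
#' that only a run of confidently aligned, unmasked bases can reach the
#' threshold.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0).
#' @param gap_open,gap_extend affine gap penalties, given as positive
#'   costs; a gap run of length k costs gap_open + k * gap_extend.
#' @param threshold minimal maximal-segment score an alignment must
#'   retain under gentle masking to be kept.
#' @return object of class \code{tg_scoring}.
#' @export
tg_scoring <- function(match = 6, mismatch = -18, gap_open = 21,
                       gap_extend = 9, threshold = 180) {
  stopifnot(match > 0, mismatch <= 0, gap_open >= 0, gap_extend >= 0,
            threshold > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, threshold = threshold),
            class = "tg_scoring")
}

#' Read split-read alignments from a MAF file
#'
#' @param path file path or connection.
#' @return a \code{tg_alignments} data frame, one row per alignment part,
#'   ordered by read and then 5'-to-3' position in the read.  Columns:
#'   readName, readStrand, refName, refSize, refStart, refEnd, readStart,
#'   readEnd (forward-read orientation), readSize, mismap, score,
#'   refText, readText.  Header comment lines are kept in attribute
#'   \code{"comments"}.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  comments <- lines[startsWith(lines, "#")]
  aIdx <- grep("^a( |$)", lines)
  sIdx <- grep("^s ", lines)
  empty <- data.frame(readName = character(), readStrand = character(),
                      refName = character(), refSize = integer(),
                      refStart = integer(), refEnd = integer(),
                      readStart = integer(), readEnd = integer(),
                      readSize = integer(), mismap = numeric(),
                      score = numeric(), refText = character(),
                      readText = character(), stringsAsFactors = FALSE)
  if (length(aIdx) == 0L) {
    class(empty) <- c("tg_alignments", "data.frame")
    attr(empty, "comments") <- comments
    return(empty)
  }
  block <- findInterval(sIdx, aIdx)
  if (any(block == 0L))
    stop("MAF 's' line before any 'a' line", call. = FALSE)
  cnt <- tabulate(block, nbins = length(aIdx))
  if (any(cnt != 2L))
    stop("MAF block ", which(cnt != 2L)[1L], " has ", cnt[cnt != 2L][1L],
         " 's' lines, expected 2", call. = FALSE)
  sf <- strsplit(trimws(lines[sIdx]), "[ \t]+")
  if (any(lengths(sf) != 7L))
    stop("malformed MAF 's' line", call. = FALSE)
  sm <- matrix(unlist(sf), ncol = 7L, byrow = TRUE)
  refRow <- seq(1L, nrow(sm), by = 2L)
  readRow <- refRow + 1L
  aLines <- lines[aIdx]
  getnum <- function(key, default) {
    m <- regmatches(aLines, regexpr(paste0(key, "=[^ \t]+"), aLines))
    v <- rep(default, length(aLines))
    hit <- grepl(paste0(key, "="), aLines)
    v[hit] <- as.numeric(sub(paste0(key, "="), "", m))
    v
  }
  score <- getnum("score", NA_real_)
  mismap <- getnum("mismap", 0)

  refText <- sm[refRow, 7L]
  readText <- sm[readRow, 7L]
  if (any(nchar(refText) != nchar(readText)))
    stop("MAF block ", which(nchar(refText) != nchar(readText))[1L],
         ": row lengths differ", call. = FALSE)
  refStart <- as.integer(sm[refRow, 3L])
  refLen <- as.integer(sm[refRow, 4L])
  readStartLocal <- as.integer(sm[readRow, 3L])
  readLen <- as.integer(sm[readRow, 4L])
  readSize <- as.integer(sm[readRow, 6L])
  strand <- sm[readRow, 5L]
  # strand-local -> forward-read coordinates
  readStart <- ifelse(strand == "-", readSize - (readStartLocal + readLen),
                      readStartLocal)
  df <- data.frame(readName = sm[readRow, 2L],
                   readStrand = strand,
                   refName = sm[refRow, 2L],
                   refSize = as.integer(sm[refRow, 6L]),
                   refStart = refStart,
                   refEnd = refStart + refLen,
                   readStart = as.integer(readStart),
                   readEnd = as.integer(readStart + readLen),
                   readSize = readSize,
                   mismap = mismap,
                   score = score,
                   refText = refText,
                   readText = readText,
                   stringsAsFactors = FALSE)
  df <- df[order(df$readName, df$readStart), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("tg_alignments", "data.frame")
  attr(df, "comments") <- comments
  df
}

#' Write alignments back to MAF
#'
#' Inverse of [read_maf()] for round-trip testing and for the synthetic
#' generator.
#'
#' @param parts a \code{tg_alignments} data frame.
#' @param path output file path or connection.
#' @export
write_maf <- function(parts, path) {
  out <- character(0L)
  cm <- attr(parts, "comments")
  if (!is.null(cm)) out <- cm
  for (k in seq_len(nrow(parts))) {
    p <- parts[k, ]
    a <- if (is.na(p$score)) "a" else sprintf("a score=%s", format(p$score))
    a <- paste0(a, sprintf(" mismap=%g", p$mismap))
    localStart <- if (p$readStrand == "-") p$readSize - p$readEnd else p$readStart
    out <- c(out, a,
             sprintf("s %s %d %d + %d %s", p$refName, p$refStart,
                     p$refEnd - p$refStart, p$refSize, p$refText),
             sprintf("s %s %d %d %s %d %s", p$readName, localStart,
                     p$readEnd - p$readStart, p$readStrand, p$readSize,
                     p$readText),
             "")
  }
  writeLines(out, path)
}

#' Extract gap runs from one alignment
#'
#' Each maximal run of consecutive columns holding a "-" in either row
#' becomes one gap: d unaligned reference bases and i unaligned read
#' bases (adjacent deletion and insertion columns merge into one run).
#' The run's unaligned reference bases occupy the reference interval
#' [refLo, refHi), with refLo == refHi for a pure insertion point.
#'
#' @param refText,readText equal-length gapped rows.
#' @param refStart reference coordinate of the first aligned column.
#' @return data frame with columns d, i, refLo, refHi.
#' @export
alignment_gaps <- function(refText, readText, refStart) {
  rc <- strsplit(refText, "", fixed = TRUE)[[1L]]
  qc <- strsplit(readText, "", fixed = TRUE)[[1L]]
  isGap <- rc == "-" | qc == "-"
  empty <- data.frame(d = integer(), i = integer(),
                      refLo = integer(), refHi = integer())
  if (!any(isGap)) return(empty)
  r <- rle(isGap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gapRuns <- which(r$values)
  # reference coordinate before each column
  refPos <- refStart + c(0L, cumsum(rc != "-"))
  out <- data.frame(
    d = vapply(gapRuns, function(g) sum(qc[starts[g]:ends[g]] == "-"), integer(1L)),
    i = vapply(gapRuns, function(g) sum(rc[starts[g]:ends[g]] == "-"), integer(1L)),
    refLo = refPos[starts[gapRuns]]
  )
  out$refHi <- out$refLo + out$d
  out
}

# gaps for a row of a tg_alignments data frame, honoring a precomputed
# list column "gaps" (present after colinear joining drops the texts)
part_gaps <- function(parts, k) {
  if (!is.null(parts$gaps)) {
    g <- parts$gaps[[k]]
    if (!is.null(g)) return(g)
  }
  alignment_gaps(parts$refText[k], parts$readText[k], parts$refStart[k])
}

#' Maximal contiguous-segment score under gentle masking
#'
#' Scores each alignment column (substitution scores on aligned columns,
#' affine gap costs across gap runs), caps every column in which either
#' letter is lowercase at a non-positive contribution, and returns the
#' maximum over all contiguous column segments (0 for an alignment that
#' is masked throughout).  An alignment of mostly soft-masked simple
#' sequence cannot reach the aligner's score threshold under this
#' rescoring and is discarded by [filter_alignments()].
#'
#' @inheritParams alignment_gaps
#' @param params a [tg_scoring()] object.
#' @return maximal segment score (numeric, >= 0).
#' @export
gentle_masked_max_segment <- function(refText, readText, params = tg_scoring()) {
  rc <- strsplit(refText, "", fixed = TRUE)[[1L]]
  qc <- strsplit(readText, "", fixed = TRUE)[[1L]]
  n <- length(rc)
  if (n == 0L) return(0)
  lower <- (rc != toupper(rc)) | (qc != toupper(qc))
  isGap <- rc == "-" | qc == "-"
  ru <- toupper(rc); qu <- toupper(qc)
  known <- c("A", "C", "G", "T")
  sc <- numeric(n)
  aligned <- !isGap
  ok <- aligned & ru %in% known & qu %in% known
  sc[aligned] <- ifelse(ru[aligned] == qu[aligned], params$match, params$mismatch)
  if (any(aligned & !ok)) {
    warning("unknown letters in alignment scored as mismatches")
    sc[aligned & !ok] <- params$mismatch
  }
  if (any(isGap)) {
    # first column of each gap run carries the open cost
    newRun <- isGap & !c(FALSE, isGap[-n])
    sc[isGap] <- -params$gap_extend
    sc[newRun] <- sc[newRun] - params$gap_open
  }
  sc[lower] <- pmin(sc[lower], 0)
  # Kadane via prefix sums: max over segments of cumsum difference
  cs <- cumsum(sc)
  best <- max(cs - cummin(c(0, cs[-n])))
  max(best, 0)
}
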