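# Readers for tandem-repeat and gene annotations, and the gene-context
# classifier used by the prioritization score.
#
# All coordinates are 0-based half-open throughout the package, matching
# the UCSC table conventions of the input files.

#' Region multipliers used by the priority score
#'
#' Ad hoc weights per genomic context: 50 for coding sequence, 20 for
#' UTR, 15 for promoter, 15 for an exon of a non-protein-coding RNA,
#' 5 for intron and 1 for intergenic.  They can be overridden wholesale
#' by passing a modified copy to [classify_region()].
#'
#' @export
region_multipliers <- c(coding = 50, UTR = 20, ncRNA_exon = 15,
                        promoter = 15, intron = 5, intergenic = 1)

new_tg_repeats <- function(chrom, start, end, unit, name, source) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   unit = toupper(as.character(unit)),
                   name = as.character(name),
                   source = rep_len(source, length(chrom)),
                   stringsAsFactors = FALSE)
  df$u <- nchar(df$unit)
  class(df) <- c("tg_repeats", "data.frame")
  df
}

#' Read tandem repeats from a UCSC RepeatMasker table (rmsk.txt)
#'
#' Keeps rows whose \code{repName} has the form \code{(UNIT)n}; the unit
#' is extracted from the parentheses, uppercased, and reverse-complemented
#' to the reference forward strand when the row is annotated on "-".
#' Rows naming transposable elements or other non-simple repeats carry no
#' usable unit and are skipped (the skip count is attached as attribute
#' \code{"skipped"}).
#'
#' @param path file path or connection to an rmsk.txt-style table
#'   (16 or 17 tab-separated columns; 17 when the leading UCSC bin
#'   column is present).
#' @param min_unit minimum repeat-unit length to keep; the conventional
#'   default 2 excludes homopolymers, pass 1 to include them.
#' @return a \code{tg_repeats} data frame with columns chrom, start, end,
#'   unit, u, name, source.
#' @export
read_rmsk <- function(path, min_unit = 2L) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  n <- length(lines)
  if (n == 0L) return(new_tg_repeats(character(), integer(), integer(),
                                     character(), character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  out <- vector("list", n)
  skipped <- 0L
  for (k in seq_len(n)) {
    f <- fields[[k]]
    # UCSC dumps have a leading bin column (17 cols); tolerate its absence
    if (length(f) < 13L)
      stop_line(lineno[k], "rmsk row has ", length(f), " columns, expected >= 13")
    off <- if (length(f) >= 17L) 1L else 0L
    genoName <- f[5L + off]
    genoStart <- suppressWarnings(as.integer(f[6L + off]))
    genoEnd <- suppressWarnings(as.integer(f[7L + off]))
    strand <- f[9L + off]
    repName <- f[10L + off]
    if (is.na(genoStart) || is.na(genoEnd))
      stop_line(lineno[k], "non-integer coordinates in rmsk row")
    m <- regmatches(repName, regexec("^\\(([ACGTNacgtn]+)\\)n$", repName))[[1L]]
    if (length(m) < 2L) { skipped <- skipped + 1L; next }
    unit <- toupper(m[2L])
    if (identical(strand, "-")) unit <- revcomp(unit)
    if (nchar(unit) < min_unit) { skipped <- skipped + 1L; next }
    out[[k]] <- list(chrom = genoName, start = genoStart, end = genoEnd,
                     unit = unit, name = repName)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  res <- new_tg_repeats(
    chrom = vapply(out, `[[`, "", "chrom"),
    start = vapply(out, function(x) x$start, integer(1L)),
    end = vapply(out, function(x) x$end, integer(1L)),
    unit = vapply(out, `[[`, "", "unit"),
    name = vapply(out, `[[`, "", "name"),
    source = "rmsk")
  attr(res, "skipped") <- skipped
  res
}

#' Read tandem repeats from a BED-like custom file
#'
#' Format: tab-separated \code{chrom start end unit [name ...]} with
#' 0-based half-open coordinates and "#" comment lines, as in custom
#' disease-locus files.
#'
#' @inheritParams read_rmsk
#' @return a \code{tg_repeats} data frame.
#' @export
read_bed_repeats <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  n <- length(lines)
  chrom <- character(n); start <- integer(n); end <- integer(n)
  unit <- character(n); name <- character(n)
  for (k in seq_len(n)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 4L)
      stop_line(lineno[k], "BED-like repeat row needs >= 4 columns")
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e))
      stop_line(lineno[k], "non-integer coordinates")
    if (e <= s) stop_line(lineno[k], "end <= start")
    if (!nzchar(f[4L])) stop_line(lineno[k], "empty repeat unit")
    chrom[k] <- f[1L]; start[k] <- s; end[k] <- e
    unit[k] <- f[4L]
    name[k] <- if (length(f) >= 5L) f[5L] else ""
  }
  new_tg_repeats(chrom, start, end, unit, name, source = "bed")
}

#' Read gene models from a UCSC refFlat table
#'
#' Standard 11-column refFlat: geneName, name, chrom, strand, txStart,
#' txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds.  Exon lists
#' are comma-separated with a UCSC trailing comma.  A transcript is
#' coding iff cdsStart < cdsEnd.
#'
#' @inheritParams read_rmsk
#' @return a \code{tg_genes} data frame with list columns exonStarts and
#'   exonEnds.
#' @export
read_refflat <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  n <- length(lines)
  geneName <- character(n); chrom <- character(n); strand <- character(n)
  txStart <- integer(n); txEnd <- integer(n)
  cdsStart <- integer(n); cdsEnd <- integer(n)
  exonStarts <- vector("list", n); exonEnds <- vector("list", n)
  for (k in seq_len(n)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L)
      stop_line(lineno[k], "refFlat row has ", length(f), " columns, expected 11")
    es <- as.integer(strsplit(sub(",$", "", f[10L]), ",", fixed = TRUE)[[1L]])
    ee <- as.integer(strsplit(sub(",$", "", f[11L]), ",", fixed = TRUE)[[1L]])
    cnt <- as.integer(f[9L])
    if (length(es) != cnt || length(ee) != cnt)
      stop_line(lineno[k], "exon list length disagrees with exonCount")
    geneName[k] <- f[1L]; chrom[k] <- f[3L]; strand[k] <- f[4L]
    txStart[k] <- as.integer(f[5L]); txEnd[k] <- as.integer(f[6L])
    cdsStart[k] <- as.integer(f[7L]); cdsEnd[k] <- as.integer(f[8L])
    exonStarts[[k]] <- es; exonEnds[[k]] <- ee
  }
  df <- data.frame(geneName = geneName, chrom = chrom, strand = strand,
                   txStart = txStart, txEnd = txEnd,
                   cdsStart = cdsStart, cdsEnd = cdsEnd,
                   stringsAsFactors = FALSE)
  df$coding <- df$cdsStart < df$cdsEnd
  df$exonStarts <- exonStarts
  df$exonEnds <- exonEnds
  class(df) <- c("tg_genes", "data.frame")
  df
}

overlaps <- function(aStart, aEnd, bStart, bEnd) aStart < bEnd & aEnd > bStart

# context of one repeat against one transcript; NULL when unrelated
transcript_context <- function(start, end, g, promoter_bp) {
  inTx <- overlaps(start, end, g$txStart, g$txEnd)
  if (inTx) {
    exHit <- any(overlaps(start, end, g$exonStarts[[1L]], g$exonEnds[[1L]]))
    if (exHit && g$coding) {
      # coding if the repeat touches the exonic part of the CDS interval
      cdsEx <- overlaps(start, end,
                        pmax(g$exonStarts[[1L]], g$cdsStart),
                        pmin(g$exonEnds[[1L]], g$cdsEnd))
      cdsEx <- cdsEx & g$exonStarts[[1L]] < g$cdsEnd & g$exonEnds[[1L]] > g$cdsStart
      if (any(cdsEx)) return("coding")
      return("UTR")
    }
    if (exHit) return("ncRNA_exon")
  }
  promStart <- if (g$strand == "-") g$txEnd else g$txStart - promoter_bp
  promEnd <- if (g$strand == "-") g$txEnd + promoter_bp else g$txStart
  if (overlaps(start, end, promStart, promEnd)) return("promoter")
  if (inTx) return("intron")
  NULL
}

#' Classify the genomic context of a tandem repeat
#'
#' Evaluates every transcript overlapping the repeat (or whose
#' strand-aware promoter window does) and returns the context with the
#' largest multiplier.  Ties between promoter and ncRNA exon (both 15)
#' go to the ncRNA exon, the more specific evidence.
#'
#' @param chrom,start,end repeat interval (0-based half-open).
#' @param genes a \code{tg_genes} data frame from [read_refflat()].
#' @param promoter_bp promoter window size upstream of txStart (default
#'   1000 bp, strand-aware).
#' @param multipliers named multiplier vector, see [region_multipliers].
#' @return list with elements \code{category}, \code{geneName} and
#'   \code{multiplier}.
#' @export
classify_region <- function(chrom, start, end, genes, promoter_bp = 1000L,
                            multipliers = region_multipliers) {
  best <- list(category = "intergenic", geneName = "",
               multiplier = unname(multipliers[["intergenic"]]))
  if (is.null(genes) || nrow(genes) == 0L) return(best)
  cand <- which(genes$chrom == chrom &
                  overlaps(start, end,
                           genes$txStart - promoter_bp,
                           genes$txEnd + promoter_bp))
  # category precedence when multipliers tie (ncRNA_exon over promoter)
  prec <- c(coding = 1L, UTR = 2L, ncRNA_exon = 3L, promoter = 4L,
            intron = 5L, intergenic = 6L)
  bestPrec <- prec[["intergenic"]]
  for (j in cand) {
    cat <- transcript_context(start, end, genes[j, , drop = FALSE], promoter_bp)
    if (is.null(cat)) next
    m <- unname(multipliers[[cat]])
    if (m > best$multiplier ||
        (m == best$multiplier && prec[[cat]] < bestPrec)) {
      best <- list(category = cat, geneName = genes$geneName[j], multiplier = m)
      bestPrec <- prec[[cat]]
    }
  }
  best
}

#' Annotate a repeat table with gene context
#'
#' @param repeats a \code{tg_repeats} data frame.
#' @inheritParams classify_region
#' @return \code{repeats} with added columns category, geneName and
#'   multiplier.
#' @export
classify_repeats <- function(repeats, genes, promoter_bp = 1000L,
                             multipliers = region_multipliers) {
  n <- nrow(repeats)
  category <- character(n); geneName <- character(n); mult <- numeric(n)
  byChrom <- if (!is.null(genes) && nrow(genes) > 0L)
    split(seq_len(nrow(genes)), genes$chrom) else list()
  for (k in seq_len(n)) {
    idx <- byChrom[[repeats$chrom[k]]]
    ctx <- classify_region(repeats$chrom[k], repeats$start[k], repeats$end[k],
                           if (is.null(idx)) NULL else genes[idx, , drop = FALSE],
                           promoter_bp, multipliers)
    category[k] <- ctx$category
    geneName[k] <- ctx$geneName
    mult[k] <- ctx$multiplier
  }
  repeats$category <- category
  repeats$geneName <- geneName
  repeats$multiplier <- mult
  repeats
}
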