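# Synthetic fixture generator: tandem-repeat loci, long reads with
# planted copy-number changes, sequencing-error models (including the
# strand-systematic motif conversion seen in nanopore data), and
# ground-truth MAF emitted from edit scripts.  This stands in for an
# external aligner so the genotyping logic is testable in isolation;
# externally produced MAF can of course still be fed to read_maf().

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA flank free of the repeat unit
#'
#' Draws a uniform-random DNA string and redraws until it contains no
#' occurrence of the unit repeated three times, keeping the repeat
#' boundary unambiguous.
#'
#' @param len flank length.
#' @param unit repeat unit to avoid.
#' @return DNA string.
#' @export
random_flank <- function(len, unit) {
  forbidden <- strrep(toupper(unit), 3L)
  repeat {
    s <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    if (!grepl(forbidden, s, fixed = TRUE)) return(s)
  }
}

#' Build a reference locus: flank + unit x copies + flank
#'
#' @param left_flank,right_flank DNA flanks; neither may contain the
#'   unit repeated three times.
#' @param unit repeat unit.
#' @param ref_copies reference copy count (>= 1).
#' @param chrom chromosome label of the construct.
#' @param offset genomic coordinate at which the construct starts.
#' @return list of class \code{tg_locus}: seq (the construct), chrom,
#'   offset, leftLen, rightLen, unit, u, ref_copies, refSize, and
#'   annotation (a one-row \code{tg_repeats}).
#' @export
make_locus <- function(left_flank, right_flank, unit, ref_copies,
                       chrom = "construct", offset = 0L) {
  unit <- toupper(unit)
  if (ref_copies < 1L) stop("ref_copies must be >= 1", call. = FALSE)
  bad <- strrep(unit, 3L)
  if (grepl(bad, left_flank, fixed = TRUE) ||
      grepl(bad, right_flank, fixed = TRUE))
    stop("flank contains the repeat unit three times in a row",
         call. = FALSE)
  u <- nchar(unit)
  seqv <- paste0(left_flank, strrep(unit, ref_copies), right_flank)
  ann <- new_tg_repeats(chrom,
                        offset + nchar(left_flank),
                        offset + nchar(left_flank) + u * ref_copies,
                        unit, sprintf("(%s)n", unit), "synthetic")
  structure(list(seq = seqv, chrom = chrom, offset = as.integer(offset),
                 leftLen = nchar(left_flank), rightLen = nchar(right_flank),
                 unit = unit, u = u, ref_copies = as.integer(ref_copies),
                 refSize = as.integer(offset + nchar(seqv)),
                 annotation = ann),
            class = "tg_locus")
}

#' Sequencing-error models
#'
#' \code{error_none()} leaves reads exact.  \code{error_uniform()}
#' applies i.i.d. substitutions and single-base indels at the given
#' per-base rates, over the whole read or confined to the flanks.
#' \code{error_strand_systematic()} converts every repeat unit of reads
#' from one strand into a target motif (motifs given in
#' reference-forward orientation); the converted tract no longer matches
#' the reference repeat, so its alignment degrades to one unaligned
#' run, the way a real aligner treats a systematically miscalled repeat.
#'
#' @param sub,indel per-base substitution and indel probabilities.
#' @param region "flanks" or "all".
#' @param strand the strand ("+" or "-") whose reads suffer the error.
#' @param to target motif the unit is converted to.
#' @name error_models
NULL

#' @rdname error_models
#' @export
error_none <- function() list(type = "none")

#' @rdname error_models
#' @export
error_uniform <- function(sub = 0.05, indel = 0.05, region = "all") {
  stopifnot(region %in% c("all", "flanks"))
  list(type = "uniform", sub = sub, indel = indel, region = region)
}

#' @rdname error_models
#' @export
error_strand_systematic <- function(strand, to) {
  stopifnot(strand %in% c("+", "-"))
  list(type = "strand_systematic", strand = strand, to = toupper(to))
}

# columns representation of one alignment block: refCols/readCols with
# "-" for gaps; used internally while building a read, then compressed
# into the ops-based edit script
cols_to_ops <- function(refCols, readCols) {
  op <- ifelse(refCols == "-", "I", ifelse(readCols == "-", "D", "M"))
  r <- rle(op)
  data.frame(op = r$values, len = r$lengths, stringsAsFactors = FALSE)
}

#' Generate a read with a planted copy-number change
#'
#' The read carries unit x (ref_copies + delta_copies) between the
#' locus flanks; the insertion or deletion is placed after
#' \code{insert_at} reference copies.  The returned edit script has one
#' block per aligned segment (two when \code{split = TRUE}, emulating an
#' expansion whose middle fails to align and leaves two flanking
#' alignments) and maps every read base to a reference operation.
#' Reads from the "-" strand are reverse-complemented; the script stays
#' in reference-forward orientation.
#'
#' @param locus a [make_locus()] object.
#' @param delta_copies signed copy-number change; ref_copies +
#'   delta_copies must be >= 0.
#' @param strand "+" or "-".
#' @param error an error model from [error_models].
#' @param insert_at copy index after which the change is placed
#'   (default: the middle of the tract).
#' @param split emit the expansion as an unaligned read segment between
#'   two alignment blocks instead of an insertion gap.
#' @return list of class \code{tg_read_spec}: read (the oriented read
#'   sequence), strand, delta_copies, and script — a list of blocks,
#'   each with refStart, readStart (construct-local, forward-read
#'   orientation) and an ops data frame (op in M/I/D, len).
#' @export
make_read <- function(locus, delta_copies, strand = "+",
                      error = error_none(), insert_at = NULL,
                      split = FALSE) {
  u <- locus$u
  nc <- locus$ref_copies + delta_copies
  if (nc < 0L) stop("ref_copies + delta_copies must be >= 0", call. = FALSE)
  if (is.null(insert_at))
    insert_at <- if (delta_copies >= 0L) locus$ref_copies %/% 2L
                 else min(locus$ref_copies %/% 2L, nc)
  L <- locus$leftLen
  refChars <- strsplit(locus$seq, "", fixed = TRUE)[[1L]]
  repLen <- u * locus$ref_copies

  if (identical(error$type, "strand_systematic") &&
      identical(error$strand, strand)) {
    tract <- strsplit(strrep(error$to, nc), "", fixed = TRUE)[[1L]]
    refCols <- c(refChars[seq_len(L)],
                 refChars[L + seq_len(repLen)],
                 rep("-", length(tract)),
                 refChars[(L + repLen + 1L):length(refChars)])
    readCols <- c(refChars[seq_len(L)],
                  rep("-", repLen),
                  tract,
                  refChars[(L + repLen + 1L):length(refChars)])
  } else {
    ins <- delta_copies > 0L
    nIns <- if (ins) u * delta_copies else 0L
    nDel <- if (ins) 0L else -u * delta_copies
    at <- L + u * insert_at
    refCols <- c(refChars[seq_len(at)],
                 if (ins) rep("-", nIns),
                 refChars[(at + 1L):length(refChars)])
    readCols <- c(refChars[seq_len(at)],
                  if (ins) strsplit(strrep(locus$unit, delta_copies),
                                    "", fixed = TRUE)[[1L]],
                  if (nDel > 0L) rep("-", nDel),
                  refChars[(at + nDel + 1L):length(refChars)])
  }

  if (identical(error$type, "uniform")) {
    n <- length(refCols)
    refPos <- cumsum(refCols != "-")   # 1-based ref coordinate per column
    inFlank <- refPos <= L | refPos > L + repLen
    eligible <- if (identical(error$region, "flanks")) which(inFlank)
                else seq_len(n)
    eligible <- eligible[readCols[eligible] != "-" & refCols[eligible] != "-"]
    nSub <- stats::rbinom(1L, length(eligible), error$sub)
    if (nSub > 0L) {
      at <- eligible[sample.int(length(eligible), nSub)]
      readCols[at] <- vapply(readCols[at], function(b)
        sample(setdiff(DNA_BASES, toupper(b)), 1L), character(1L))
    }
    nInd <- stats::rbinom(1L, length(eligible), error$indel)
    if (nInd > 0L) {
      at <- sort(eligible[sample.int(length(eligible), nInd)],
                 decreasing = TRUE)
      for (j in at) {
        if (stats::runif(1L) < 0.5) {       # deletion of one read base
          readCols[j] <- "-"
        } else {                            # insertion of one read base
          refCols <- append(refCols, "-", after = j)
          readCols <- append(readCols, sample(DNA_BASES, 1L), after = j)
        }
      }
    }
  }

  readF <- paste(readCols[readCols != "-"], collapse = "")
  if (split && delta_copies > 0L &&
      !identical(error$type, "strand_systematic")) {
    # two blocks flanking an unaligned read segment over the expansion
    at <- L + u * insert_at
    script <- list(
      list(refStart = 0L, readStart = 0L,
           ops = data.frame(op = "M", len = at, stringsAsFactors = FALSE)),
      list(refStart = at, readStart = at + u * delta_copies,
           ops = data.frame(op = "M", len = nchar(locus$seq) - at,
                            stringsAsFactors = FALSE)))
  } else {
    script <- list(list(refStart = 0L, readStart = 0L,
                        ops = cols_to_ops(refCols, readCols)))
  }
  read <- if (strand == "-") revcomp(readF) else readF
  structure(list(read = read, strand = strand,
                 delta_copies = as.integer(delta_copies), script = script),
            class = "tg_read_spec")
}

#' Render an edit script as MAF text
#'
#' Walks the script's blocks over the reference construct and the read,
#' producing one MAF block per script block, with optional lowercase
#' soft-masking over reference coordinate ranges and a mismap
#' probability on each block.  The script must consume consistent
#' lengths of both sequences.
#'
#' @param locus a [make_locus()] object.
#' @param read_spec a [make_read()] object.
#' @param read_name read identifier.
#' @param mismap mismap probability written on each block.
#' @param mask_ranges optional data frame (lo, hi) of construct-local
#'   reference ranges to lowercase on both rows.
#' @return character vector of MAF lines.
#' @export
edit_script_to_maf <- function(locus, read_spec, read_name,
                               mismap = 1e-10, mask_ranges = NULL) {
  readF <- if (read_spec$strand == "-") revcomp(read_spec$read)
           else read_spec$read
  refChars <- strsplit(locus$seq, "", fixed = TRUE)[[1L]]
  readChars <- strsplit(readF, "", fixed = TRUE)[[1L]]
  readSize <- length(readChars)
  out <- character(0L)
  for (b in read_spec$script) {
    rpos <- b$refStart; qpos <- b$readStart
    refCols <- character(0L); readCols <- character(0L)
    for (k in seq_len(nrow(b$ops))) {
      op <- b$ops$op[k]; len <- b$ops$len[k]
      if (op == "M") {
        if (rpos + len > length(refChars) || qpos + len > readSize)
          stop("edit script overruns a sequence", call. = FALSE)
        refCols <- c(refCols, refChars[rpos + seq_len(len)])
        readCols <- c(readCols, readChars[qpos + seq_len(len)])
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "I") {
        refCols <- c(refCols, rep("-", len))
        readCols <- c(readCols, readChars[qpos + seq_len(len)])
        qpos <- qpos + len
      } else if (op == "D") {
        refCols <- c(refCols, refChars[rpos + seq_len(len)])
        readCols <- c(readCols, rep("-", len))
        rpos <- rpos + len
      } else stop("unknown edit op: ", op, call. = FALSE)
    }
    if (!is.null(mask_ranges) && nrow(mask_ranges) > 0L) {
      refPos <- b$refStart + cumsum(refCols != "-") - (refCols != "-")
      masked <- rep(FALSE, length(refCols))
      for (m in seq_len(nrow(mask_ranges)))
        masked <- masked | (refPos >= mask_ranges$lo[m] &
                              refPos < mask_ranges$hi[m] & refCols != "-")
      refCols[masked] <- tolower(refCols[masked])
      readCols[masked & readCols != "-"] <-
        tolower(readCols[masked & readCols != "-"])
    }
    nRef <- rpos - b$refStart
    nRead <- qpos - b$readStart
    # for "-" alignments MAF read coordinates live on the reverse
    # complement of the read, which is exactly the construct-forward
    # orientation the script is written in
    localStart <- b$readStart
    out <- c(out,
             sprintf("a score=%d mismap=%g",
                     as.integer(6L * sum(refCols == readCols)), mismap),
             sprintf("s %s %d %d + %d %s", locus$chrom,
                     locus$offset + b$refStart, nRef, locus$refSize,
                     paste(refCols, collapse = "")),
             sprintf("s %s %d %d %s %d %s", read_name, localStart, nRead,
                     read_spec$strand, readSize,
                     paste(readCols, collapse = "")),
             "")
  }
  out
}

#' Replace the repeat region of a read with donor sequence
#'
#' Emulates chimeric reads built from a host read whose repeat tract is
#' swapped for the (possibly expanded) tract of another molecule.
#'
#' @param host_read read sequence.
#' @param lo,hi 0-based half-open interval of the tract within the read.
#' @param donor replacement sequence (may be empty: a pure deletion
#'   chimera).
#' @return the chimeric read.
#' @export
make_chimeric_read <- function(host_read, lo, hi, donor = "") {
  stopifnot(lo >= 0L, hi >= lo, hi <= nchar(host_read))
  paste0(substr(host_read, 1L, lo), donor,
         substr(host_read, hi + 1L, nchar(host_read)))
}

#' Generate a background genome of annotated repeats with reads
#'
#' Builds \code{n_repeats} independent loci (one per synthetic
#' chromosome), each with random unit, copy count and flanks, covered by
#' \code{coverage} reads whose copy changes are drawn from
#' \code{copy_noise}.  A fraction of loci get a synthetic gene so
#' intronic and coding contexts occur.  Pure function of its arguments
#' and the RNG state: call \code{set.seed()} first for reproducibility.
#'
#' @param n_repeats number of loci.
#' @param unit_lengths unit lengths to sample from.
#' @param copy_noise function(n) returning n signed integer copy
#'   changes; default uniform on -2..2.
#' @param coverage reads per locus (alternating strands).
#' @param flank_len flank length per side; must exceed the "far"
#'   distance for reads to qualify.
#' @param copies_range range of reference copy counts.
#' @param gene_fraction fraction of loci covered by a synthetic gene
#'   (split between intron and coding-exon placements).
#' @param plant optional list(index, delta_copies, unit, category) to
#'   plant a specific repeat at one locus; category "coding" wraps it
#'   in a single-exon coding gene.
#' @param loci optional locus set returned by a previous call (element
#'   \code{loci}); reusing it keeps the reference genome and annotations
#'   fixed while drawing a fresh read set, which is how independent
#'   case/control datasets over one genome are simulated.
#' @return list with elements loci (reusable locus list), repeats
#'   (\code{tg_repeats}), genes (\code{tg_genes}), maf (character
#'   lines), truth (data frame: chrom, read, strand, delta).
#' @export
make_background_genome <- function(n_repeats, unit_lengths = 2:6,
                                   copy_noise = function(n)
                                     sample(-2:2, n, replace = TRUE),
                                   coverage = 4L, flank_len = 120L,
                                   copies_range = c(8L, 20L),
                                   gene_fraction = 0.2,
                                   plant = NULL, loci = NULL) {
  stopifnot(n_repeats >= 1L)
  if (is.null(loci)) {
    loci <- vector("list", n_repeats)
    for (k in seq_len(n_repeats)) {
      chrom <- sprintf("bg%06d", k)
      planted <- !is.null(plant) && k == plant$index
      unit <- if (planted) plant$unit
              else paste(sample(DNA_BASES, sample(unit_lengths, 1L),
                                replace = TRUE), collapse = "")
      copies <- sample(seq(copies_range[1L], copies_range[2L]), 1L)
      loc <- make_locus(random_flank(flank_len, unit),
                        random_flank(flank_len, unit),
                        unit, copies, chrom = chrom)
      loc$geneCat <- if (planted) plant$category
                     else if (stats::runif(1L) < gene_fraction)
                       sample(c("intron", "coding"), 1L,
                              prob = c(0.7, 0.3))
                     else NA_character_
      loci[[k]] <- loc
    }
  } else {
    stopifnot(length(loci) == n_repeats)
  }
  repList <- vector("list", n_repeats)
  geneRows <- list()
  mafChunks <- vector("list", n_repeats)
  truthChunks <- vector("list", n_repeats)
  for (k in seq_len(n_repeats)) {
    loc <- loci[[k]]
    chrom <- loc$chrom
    repList[[k]] <- loc$annotation
    if (!is.na(loc$geneCat)) {
      len <- nchar(loc$seq)
      ex <- if (loc$geneCat == "coding")
        list(starts = 5L, ends = len - 5L)
      else list(starts = c(5L, len - 25L), ends = c(25L, len - 5L))
      geneRows[[length(geneRows) + 1L]] <- data.frame(
        geneName = sprintf("GENE%06d", k), chrom = chrom, strand = "+",
        txStart = 5L, txEnd = len - 5L, cdsStart = 5L, cdsEnd = len - 5L,
        coding = TRUE, stringsAsFactors = FALSE,
        exonStarts = I(list(ex$starts)), exonEnds = I(list(ex$ends)))
    }
    planted <- !is.null(plant) && k == plant$index
    deltas <- if (planted) rep(plant$delta_copies, coverage)
              else pmax(copy_noise(coverage), -loc$ref_copies)
    strands <- rep(c("+", "-"), length.out = coverage)
    maf <- character(0L)
    for (j in seq_len(coverage)) {
      rs <- make_read(loc, deltas[j], strands[j])
      maf <- c(maf, edit_script_to_maf(loc, rs, sprintf("%s_read%d", chrom, j)))
    }
    mafChunks[[k]] <- maf
    truthChunks[[k]] <- data.frame(chrom = chrom,
                                   read = sprintf("%s_read%d", chrom,
                                                  seq_len(coverage)),
                                   strand = strands, delta = deltas,
                                   stringsAsFactors = FALSE)
  }
  repeats <- do.call(rbind, repList)
  class(repeats) <- c("tg_repeats", "data.frame")
  genes <- if (length(geneRows)) do.call(rbind, geneRows) else NULL
  if (!is.null(genes)) class(genes) <- c("tg_genes", "data.frame")
  list(loci = loci, repeats = repeats, genes = genes,
       maf = unlist(mafChunks), truth = do.call(rbind, truthChunks))
}

#' Write a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
}

#' Write a refFlat table for synthetic genes
#'
#' @param genes a \code{tg_genes} data frame.
#' @param path output path.
#' @export
write_refflat <- function(genes, path) {
  rows <- vapply(seq_len(nrow(genes)), function(k) {
    paste(genes$geneName[k], genes$geneName[k], genes$chrom[k],
          genes$strand[k], genes$txStart[k], genes$txEnd[k],
          genes$cdsStart[k], genes$cdsEnd[k],
          length(genes$exonStarts[[k]]),
          paste0(paste(genes$exonStarts[[k]], collapse = ","), ","),
          paste0(paste(genes$exonEnds[[k]], collapse = ","), ","),
          sep = "\t")
  }, character(1L))
  writeLines(rows, path)
}

#' Write a BED-like repeat annotation file
#'
#' @param repeats a \code{tg_repeats} data frame.
#' @param path output path.
#' @export
write_bed_repeats <- function(repeats, path) {
  writeLines(paste(repeats$chrom, repeats$start, repeats$end, repeats$unit,
                   repeats$name, sep = "\t"), path)
}
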