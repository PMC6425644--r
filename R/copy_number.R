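# Core genotyping algorithm: per-read copy-number-change prediction at
# annotated tandem repeats, from filtered and joined split alignments.
#
# Pipeline per read: (1) drop alignments with mismap probability above
# the cutoff, (2) drop alignments that keep no segment scoring at least
# the threshold under gentle masking, (3) join consecutive colinear
# alignments, (4) per repeat, predict from the single overlapping
# alignment's gaps or from the flanking pair of alignments.

#' Prediction configuration
#'
#' @param mismap_max discard alignments with mismap probability strictly
#'   greater than this (default 1e-6).
#' @param join_gap_max maximal reference separation, in bases, for
#'   joining consecutive colinear alignments (default 1e6).
#' @param far_floor,near_floor floors of the ad hoc "far" and "near"
#'   distances: f = max(far_floor, u), n = max(near_floor, u).  f
#'   controls the required flank coverage and the give-up rules, n
#'   bounds which gaps count toward the repeat.
#' @param min_unit minimal repeat-unit length of annotations to
#'   genotype; default 2 excludes homopolymers.
#' @param scoring a [tg_scoring()] object for the gentle-masking filter.
#' @return object of class \code{tg_config}.
#' @export
tg_config <- function(mismap_max = 1e-6, join_gap_max = 1e6,
                      far_floor = 100L, near_floor = 60L, min_unit = 2L,
                      scoring = tg_scoring()) {
  stopifnot(mismap_max > 0, join_gap_max > 0, far_floor > 0,
            near_floor > 0, min_unit >= 1, near_floor <= far_floor)
  structure(list(mismap_max = mismap_max, join_gap_max = join_gap_max,
                 far_floor = far_floor, near_floor = near_floor,
                 min_unit = min_unit, scoring = scoring),
            class = "tg_config")
}

#' "Far" and "near" distances for a repeat
#'
#' f = max(far_floor, u) truncated, per side, at the edge of the
#' reference sequence; n = max(near_floor, u).  With default floors and
#' u = 3 this is f = 100, n = 60.  Truncation matters for constructs
#' with little flanking sequence, where the full f cannot fit.
#'
#' @param u repeat-unit length.
#' @param edge_left,edge_right distance from the repeat's boundaries to
#'   the start and end of the reference sequence (Inf when unknown).
#' @param config a [tg_config()].
#' @return list with elements f_left, f_right, n.
#' @export
far_near <- function(u, edge_left = Inf, edge_right = Inf,
                     config = tg_config()) {
  f <- max(config$far_floor, u)
  list(f_left = min(f, edge_left), f_right = min(f, edge_right),
       n = max(config$near_floor, u))
}

#' Filter alignments by mismap probability and gentle masking
#'
#' Removes parts with mismap strictly above \code{config$mismap_max} and
#' parts whose [gentle_masked_max_segment()] falls below the scoring
#' threshold.  5'-to-3' order within each read is preserved.
#'
#' @param parts a \code{tg_alignments} data frame.
#' @param config a [tg_config()].
#' @return the surviving rows.
#' @export
filter_alignments <- function(parts, config = tg_config()) {
  if (nrow(parts) == 0L) return(parts)
  keep <- parts$mismap <= config$mismap_max
  if (any(keep)) {
    seg <- vapply(which(keep), function(k)
      gentle_masked_max_segment(parts$refText[k], parts$readText[k],
                                config$scoring), numeric(1L))
    keep[keep] <- seg >= config$scoring$threshold
  }
  out <- parts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Join consecutive colinear alignments of one read
#'
#' Adjacent parts (in 5'-to-3' read order) are merged, transitively from
#' left to right, when they lie on the same strand of the same reference
#' sequence, both the read and reference intervals advance in the
#' strand-consistent direction without overlap, and the reference
#' separation is at most \code{config$join_gap_max}.  The bridged region
#' becomes an ordinary gap run (d = reference gap, i = read gap) so it
#' flows through the single-alignment gap rules.  Merged rows keep their
#' gaps in a list column \code{gaps}; texts are dropped.
#'
#' @param parts alignments of ONE read, ordered 5' to 3'.
#' @param config a [tg_config()].
#' @return a \code{tg_alignments} data frame with a \code{gaps} list
#'   column.
#' @export
join_colinear <- function(parts, config = tg_config()) {
  n <- nrow(parts)
  if (is.null(parts$gaps))
    parts$gaps <- lapply(seq_len(n), function(k) part_gaps(parts, k))
  if (n <= 1L) return(parts)
  acc <- list(parts[1L, , drop = FALSE])
  for (k in 2L:n) {
    p <- acc[[length(acc)]]               # read-earlier part
    q <- parts[k, , drop = FALSE]         # read-later part
    readGap <- q$readStart - p$readEnd
    refGap <- if (identical(p$readStrand, "+")) q$refStart - p$refEnd
              else p$refStart - q$refEnd
    mergeable <- identical(p$refName, q$refName) &&
      identical(p$readStrand, q$readStrand) &&
      !is.na(refGap) && readGap >= 0 && refGap >= 0 &&
      refGap <= config$join_gap_max
    if (mergeable) {
      bridge <- if (readGap + refGap > 0) {
        lo <- if (identical(p$readStrand, "+")) p$refEnd else q$refEnd
        data.frame(d = as.integer(refGap), i = as.integer(readGap),
                   refLo = as.integer(lo), refHi = as.integer(lo + refGap))
      } else NULL
      m <- p
      m$refStart <- min(p$refStart, q$refStart)
      m$refEnd <- max(p$refEnd, q$refEnd)
      m$readEnd <- q$readEnd
      m$mismap <- max(p$mismap, q$mismap)
      m$score <- if (is.na(p$score) || is.na(q$score)) NA_real_
                 else p$score + q$score
      m$refText <- NA_character_
      m$readText <- NA_character_
      gl <- if (identical(p$readStrand, "+"))
        list(p$gaps[[1L]], bridge, q$gaps[[1L]])
      else list(q$gaps[[1L]], bridge, p$gaps[[1L]])
      m$gaps <- list(do.call(rbind, gl[!vapply(gl, is.null, logical(1L))]))
      acc[[length(acc)]] <- m
    } else {
      acc <- c(acc, list(q))
    }
  }
  acc <- do.call(rbind, acc)
  rownames(acc) <- NULL
  acc
}

#' Round to the nearest multiple of the unit length
#'
#' Exact midpoints are rounded toward zero, so e.g. 9 with u = 6 gives
#' 6, and -9 gives -6.
#'
#' @param D signed base count.
#' @param u unit length (>= 1).
#' @return signed multiple of u nearest to D.
#' @export
round_to_unit <- function(D, u) {
  q <- D / u
  lo <- floor(q) * u
  hi <- ceiling(q) * u
  dlo <- abs(D - lo); dhi <- abs(hi - D)
  ifelse(dlo < dhi, lo,
         ifelse(dhi < dlo, hi, ifelse(abs(lo) <= abs(hi), lo, hi)))
}

#' Net deletion size of a gap
#'
#' D = min(d - i, r): deleted reference bases net of inserted read
#' bases, capped by r, the unaligned reference bases that fall inside
#' the repeat.  Pure insertions give negative D (an expansion).
#'
#' @param d,i unaligned reference / read bases of the gap.
#' @param r unaligned reference bases of the gap inside the repeat.
#' @return signed base count.
#' @export
net_deletion <- function(d, i, r) pmin(d - i, r)

# distance of each unaligned reference base (or, for d == 0, of the
# insertion point) to the repeat interval; bases touching the repeat
# have distance 0
gap_distances <- function(gap, rstart, rend) {
  if (gap$d > 0L) {
    pos <- gap$refLo:(gap$refHi - 1L)
    pmax(rstart - 1L - pos, pos - rend, 0L)
  } else {
    max(rstart - gap$refLo, gap$refLo - rend, 0L)
  }
}

gap_overlaps_repeat <- function(gap, rstart, rend) {
  if (gap$d > 0L) gap$refLo < rend && gap$refHi > rstart
  else gap$refLo >= rstart && gap$refLo < rend
}

#' Predict the copy change from a single overlapping alignment
#'
#' Gives up unless the alignment extends beyond both sides of the repeat
#' by at least f.  Each gap is then tested against four rules, in order:
#' (1) not overlapping the repeat with i <= u/2: ignore; (2) wholly >= f
#' away: ignore; (3) partly >= f away: give up; (4) wholly > n away:
#' ignore.  A surviving gap contributes -round_to_unit(min(d - i, r), u)
#' / u copies; contributions are rounded per gap and summed.
#'
#' @param parts one-row \code{tg_alignments} (possibly joined).
#' @param k row index of the alignment.
#' @param rstart,rend repeat interval.
#' @param u unit length.
#' @param fn list from [far_near()].
#' @return list(status, copyChange, strand).
#' @export
predict_single <- function(parts, k, rstart, rend, u, fn) {
  p <- parts[k, , drop = FALSE]
  if (!(p$refStart <= rstart - fn$f_left && p$refEnd >= rend + fn$f_right))
    return(list(status = "gave_up", copyChange = NA_integer_,
                strand = p$readStrand))
  gaps <- part_gaps(parts, k)
  total <- 0L
  if (!is.null(gaps) && nrow(gaps) > 0L) {
    for (g in seq_len(nrow(gaps))) {
      gap <- gaps[g, ]
      ov <- gap_overlaps_repeat(gap, rstart, rend)
      if (!ov && gap$i <= u / 2) next
      dist <- gap_distances(gap, rstart, rend)
      # each position is compared against the f of its own side, so a
      # truncated f on one flank does not leak to the other
      pos <- if (gap$d > 0L) gap$refLo:(gap$refHi - 1L) else gap$refLo
      f <- ifelse(pos < rstart, fn$f_left, fn$f_right)
      if (all(dist >= f)) next
      if (any(dist >= f)) return(list(status = "gave_up",
                                      copyChange = NA_integer_,
                                      strand = p$readStrand))
      if (all(dist > fn$n)) next
      r <- max(0L, min(gap$refHi, rend) - max(gap$refLo, rstart))
      D <- net_deletion(gap$d, gap$i, r)
      total <- total - round_to_unit(D, u) %/% u
    }
  }
  list(status = "predicted", copyChange = as.integer(total),
       strand = p$readStrand)
}

#' Predict the copy change from multiple overlapping alignments
#'
#' For two or more overlapping alignments (typically an expansion whose
#' middle does not align, leaving two flanking parts): they must be
#' consecutive in the read and on one strand; the reference-leftmost
#' ("left") alignment must extend >= f left of the repeat and of every
#' other overlapping alignment, while no other alignment extends >= f
#' left of the repeat; mirror conditions on the right.  The copy change
#' is the read-minus-reference base count between the left alignment's
#' end and the right alignment's start, rounded to units.
#'
#' @param parts all (joined) alignments of the read, in read order.
#' @param ov indices (into parts) of alignments overlapping the repeat.
#' @inheritParams predict_single
#' @return list(status, copyChange, strand).
#' @export
predict_multi <- function(parts, ov, rstart, rend, u, fn) {
  strand <- parts$readStrand[ov[1L]]
  giveup <- list(status = "gave_up", copyChange = NA_integer_,
                 strand = strand)
  consecutive <- all(diff(sort(ov)) == 1L)
  sameStrand <- length(unique(parts$readStrand[ov])) == 1L &&
    length(unique(parts$refName[ov])) == 1L
  if (!consecutive || !sameStrand) return(giveup)
  ov <- sort(ov)
  leftIdx <- if (strand == "+") ov[1L] else ov[length(ov)]
  rightIdx <- if (strand == "+") ov[length(ov)] else ov[1L]
  others <- setdiff(ov, leftIdx)
  L <- parts[leftIdx, ]; R <- parts[rightIdx, ]
  # left alignment: extends >= f left of the repeat and of the others;
  # the others must not extend >= f left of the repeat
  okL <- L$refStart <= rstart - fn$f_left &&
    all(L$refStart <= parts$refStart[others] - fn$f_left) &&
    all(parts$refStart[others] > rstart - fn$f_left)
  othersR <- setdiff(ov, rightIdx)
  okR <- R$refEnd >= rend + fn$f_right &&
    all(R$refEnd >= parts$refEnd[othersR] + fn$f_right) &&
    all(parts$refEnd[othersR] < rend + fn$f_right)
  if (!okL || !okR) return(giveup)
  readGap <- if (strand == "+") R$readStart - L$readEnd
             else L$readStart - R$readEnd
  refGap <- R$refStart - L$refEnd
  insertion <- readGap - refGap
  list(status = "predicted",
       copyChange = as.integer(round_to_unit(insertion, u) %/% u),
       strand = strand)
}

#' Genotype one repeat across all reads
#'
#' Orchestrates the per-read pipeline over already filtered-and-joined
#' alignments: reads with no overlapping alignment get status
#' no_coverage; one overlapping alignment goes through
#' [predict_single()], several through [predict_multi()].
#'
#' @param parts filtered, joined \code{tg_alignments} for the repeat's
#'   reference sequence (all reads).
#' @param rep1 one-row \code{tg_repeats}.
#' @param config a [tg_config()].
#' @return list of class \code{tg_repeat_result}: repeat fields,
#'   forwardChanges, reverseChanges, and a per-read data frame
#'   \code{reads} (read, strand, status, copyChange).
#' @export
predict_repeat <- function(parts, rep1, config = tg_config()) {
  rstart <- rep1$start; rend <- rep1$end; u <- rep1$u
  readIdx <- split(seq_len(nrow(parts)), parts$readName)
  rows <- vector("list", length(readIdx))
  for (j in seq_along(readIdx)) {
    idx <- readIdx[[j]]
    sub <- parts[idx, , drop = FALSE]
    refSize <- sub$refSize[match(rep1$chrom, sub$refName)]
    fn <- far_near(u,
                   edge_left = if (is.na(refSize)) Inf else rstart,
                   edge_right = if (is.na(refSize)) Inf else refSize - rend,
                   config = config)
    ov <- which(sub$refName == rep1$chrom &
                  sub$refStart < rend & sub$refEnd > rstart)
    res <- if (length(ov) == 0L)
      list(status = "no_coverage", copyChange = NA_integer_,
           strand = NA_character_)
    else if (length(ov) == 1L)
      predict_single(sub, ov, rstart, rend, u, fn)
    else predict_multi(sub, ov, rstart, rend, u, fn)
    rows[[j]] <- data.frame(read = names(readIdx)[j], strand = res$strand,
                            status = res$status, copyChange = res$copyChange,
                            stringsAsFactors = FALSE)
  }
  reads <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read = character(), strand = character(),
               status = character(), copyChange = integer(),
               stringsAsFactors = FALSE)
  pred <- reads[reads$status == "predicted", , drop = FALSE]
  structure(list(chrom = rep1$chrom, start = rstart, end = rend,
                 unit = rep1$unit, u = u, name = rep1$name,
                 forwardChanges = pred$copyChange[pred$strand == "+"],
                 reverseChanges = pred$copyChange[pred$strand == "-"],
                 reads = reads),
            class = "tg_repeat_result")
}

#' Genotype all repeats against a set of alignments
#'
#' Runs the full per-read pipeline (mismap filter, gentle-masking
#' filter, colinear joining) once, then predicts every repeat whose unit
#' length is at least \code{config$min_unit}.
#'
#' @param repeats a \code{tg_repeats} data frame.
#' @param parts a \code{tg_alignments} data frame from [read_maf()].
#' @param config a [tg_config()].
#' @param genes optional \code{tg_genes}; when given, gene context is
#'   attached for prioritization.
#' @param promoter_bp promoter window for [classify_repeats()].
#' @return a \code{tg_results} data frame: repeat columns plus list
#'   columns forwardChanges and reverseChanges, and context columns when
#'   genes were supplied.
#' @export
tg_genotype <- function(repeats, parts, config = tg_config(), genes = NULL,
                        promoter_bp = 1000L) {
  repeats <- repeats[repeats$u >= config$min_unit, , drop = FALSE]
  parts <- filter_alignments(parts, config)
  if (nrow(parts) > 0L) {
    parts$gaps <- lapply(seq_len(nrow(parts)), function(k) part_gaps(parts, k))
    byRead <- split(seq_len(nrow(parts)), parts$readName)
    joined <- lapply(byRead, function(idx)
      join_colinear(parts[idx, , drop = FALSE], config))
    parts <- do.call(rbind, joined)
    rownames(parts) <- NULL
  }
  byChrom <- split(seq_len(nrow(parts)), parts$refName)
  fwd <- vector("list", nrow(repeats))
  rev <- vector("list", nrow(repeats))
  nGaveUp <- integer(nrow(repeats)); nNoCov <- integer(nrow(repeats))
  for (k in seq_len(nrow(repeats))) {
    idx <- byChrom[[repeats$chrom[k]]]
    if (is.null(idx)) {
      fwd[[k]] <- integer(0L); rev[[k]] <- integer(0L)
      next
    }
    rr <- predict_repeat(parts[idx, , drop = FALSE],
                         repeats[k, , drop = FALSE], config)
    fwd[[k]] <- rr$forwardChanges
    rev[[k]] <- rr$reverseChanges
    nGaveUp[k] <- sum(rr$reads$status == "gave_up")
    nNoCov[k] <- sum(rr$reads$status == "no_coverage")
  }
  res <- as.data.frame(repeats)
  res$forwardChanges <- fwd
  res$reverseChanges <- rev
  res$nGaveUp <- nGaveUp
  res$nNoCoverage <- nNoCov
  if (!is.null(genes)) {
    cls <- class(res)
    res <- classify_repeats(res, genes, promoter_bp)
    class(res) <- cls
  }
  class(res) <- c("tg_results", "data.frame")
  attr(res, "config") <- config
  res
}
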