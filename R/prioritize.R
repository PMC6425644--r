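# Prioritization of copy-number changes: a per-repeat score built from
# the most extreme remaining change, the gene-context multiplier, and a
# polyglutamine/polyalanine bonus; plus the cubic-mean case/control
# joint score for multi-dataset ranking.

#' Select the "most extreme remaining change" of a repeat
#'
#' When the dataset's average number of predictions per covered repeat
#' is at least 3, one copy of the maximum and one copy of the minimum
#' change are dropped first (guarding against single outlier reads);
#' with fewer than 3 — e.g. an assembled genome contributing one
#' prediction per repeat — nothing is dropped.  A value is only dropped
#' while at least two remain.  Of the remainder, the change with the
#' largest absolute base length is returned; a +/- tie prefers the
#' expansion.
#'
#' @param changes pooled forward- and reverse-strand copy changes.
#' @param u unit length.
#' @param dataset_mean_predictions average prediction count per repeat
#'   with >= 1 prediction, over the whole dataset.
#' @return list(copies, bases) or NULL for an empty change list.
#' @export
select_top_change <- function(changes, u, dataset_mean_predictions) {
  if (length(changes) == 0L) return(NULL)
  if (dataset_mean_predictions >= 3) {
    if (length(changes) >= 2L) changes <- changes[-which.max(changes)]
    if (length(changes) >= 2L) changes <- changes[-which.min(changes)]
  }
  best <- changes[order(-abs(changes), -changes)][1L]
  list(copies = best, bases = best * u)
}

#' Does a repeat unit encode polyglutamine or polyalanine?
#'
#' TRUE iff the infinite repetition of the unit, in one of the 6 reading
#' frames (3 frames x 2 strands), consists solely of glutamine codons
#' (CAA/CAG) or solely of alanine codons (GCA/GCC/GCG/GCT).  The codon
#' cycle of a frame has period lcm(u, 3) / 3 codons, all of which must
#' match.
#'
#' @param unit repeat unit (DNA string).
#' @return logical.
#' @export
is_polyq_or_polya <- function(unit) {
  unit <- toupper(unit)
  u <- nchar(unit)
  gln <- c("CAA", "CAG")
  ala <- c("GCA", "GCC", "GCG", "GCT")
  period <- lcm2(u, 3L) %/% 3L  # codons per cycle
  for (seqStrand in c(unit, revcomp(unit))) {
    big <- strrep(seqStrand, ceiling((3L * period + 2L) / u) + 1L)
    for (frame in 0:2) {
      codons <- substring(big, frame + 1L + 3L * (0:(period - 1L)),
                          frame + 3L * (1:period))
      if (all(codons %in% gln) || all(codons %in% ala)) return(TRUE)
    }
  }
  FALSE
}

#' Priority score of one repeat
#'
#' score = topChangeBases / (refLen + 30) * multiplier, doubled for
#' coding repeats whose unit encodes polyglutamine or polyalanine.  The
#' +30 damps scores of dubiously short annotations.  Contractions give
#' negative scores; ranking uses the absolute value.
#'
#' @param top_change_bases signed change in bases.
#' @param ref_len annotated reference repeat length in bases.
#' @param category gene context category (see [classify_region()]).
#' @param multiplier gene context multiplier.
#' @param unit repeat unit.
#' @return signed real score.
#' @export
priority_score <- function(top_change_bases, ref_len, category, multiplier,
                           unit) {
  s <- top_change_bases / (ref_len + 30) * multiplier
  if (identical(category, "coding") && is_polyq_or_polya(unit)) s <- 2 * s
  s
}

#' Score and rank genotyped repeats
#'
#' Computes the dataset's mean prediction count, selects each repeat's
#' top change, scores it against its gene context, and ranks by
#' descending absolute score (ties: larger absolute base change, then
#' chromosome and start for determinism).  Repeats without predictions
#' are dropped.
#'
#' @param results a \code{tg_results} data frame from [tg_genotype()]
#'   (context columns present when genes were supplied; otherwise all
#'   repeats count as intergenic with multiplier 1).
#' @return a \code{tg_priority} data frame with columns of the repeat,
#'   topChangeCopies, topChangeBases, score and rank, ordered by rank.
#' @export
tg_prioritize <- function(results) {
  if (is.null(results$category)) {
    results$category <- "intergenic"
    results$geneName <- ""
    results$multiplier <- 1
  }
  counts <- lengths(results$forwardChanges) + lengths(results$reverseChanges)
  covered <- counts > 0L
  meanPred <- if (any(covered)) mean(counts[covered]) else 0
  res <- results[covered, , drop = FALSE]
  n <- nrow(res)
  copies <- integer(n); bases <- integer(n); score <- numeric(n)
  for (k in seq_len(n)) {
    top <- select_top_change(c(res$forwardChanges[[k]],
                               res$reverseChanges[[k]]),
                             res$u[k], meanPred)
    copies[k] <- top$copies
    bases[k] <- top$bases
    score[k] <- priority_score(top$bases, res$end[k] - res$start[k],
                               res$category[k], res$multiplier[k], res$unit[k])
  }
  res$topChangeCopies <- copies
  res$topChangeBases <- bases
  res$score <- score
  res <- rank_records(res)
  attr(res, "meanPredictions") <- meanPred
  res
}

#' Rank scored records by absolute priority score
#'
#' @param records data frame with columns score, topChangeBases, chrom,
#'   start.
#' @return records ordered by descending |score| with a 1-based
#'   \code{rank} column.
#' @export
rank_records <- function(records) {
  o <- order(-abs(records$score), -abs(records$topChangeBases),
             records$chrom, records$start, method = "radix")
  records <- records[o, , drop = FALSE]
  records$rank <- seq_len(nrow(records))
  rownames(records) <- NULL
  class(records) <- unique(c("tg_priority", class(records)))
  records
}

#' Cubic mean
#'
#' Cube root of the mean of cubes, sign-preserving; emphasizes large
#' values so that one large control expansion strongly de-prioritizes a
#' repeat.
#'
#' @param xs numeric vector (non-empty).
#' @return real.
#' @export
cubic_mean <- function(xs) {
  stopifnot(length(xs) > 0L)
  m <- mean(xs^3)
  sign(m) * abs(m)^(1 / 3)
}

#' Joint case/control priority score
#'
#' d = cubic mean of case scores, h = cubic mean of control scores (0
#' with no controls); if d < 0 both are negated; the joint score is
#' max(d - max(h, 0), 0).
#'
#' @param case_scores per-case-dataset priority scores (non-empty).
#' @param control_scores per-control-dataset priority scores (may be
#'   empty).
#' @return list(d, h, jointScore).
#' @export
joint_priority <- function(case_scores, control_scores = numeric(0L)) {
  d <- cubic_mean(case_scores)
  h <- if (length(control_scores)) cubic_mean(control_scores) else 0
  if (d < 0) { d <- -d; h <- -h }
  list(d = d, h = h, jointScore = max(d - max(h, 0), 0))
}

#' Join per-dataset results into a case/control ranking
#'
#' Recomputes each dataset's priority scores from its genotyping results
#' (each dataset gets its own mean-prediction gate), then combines them
#' per repeat: a repeat absent from a dataset contributes score 0 for
#' that dataset.  Records are ranked by descending joint score.
#'
#' @param cases list of \code{tg_results} (or file paths readable with
#'   [read_results()]) for diseased individuals.
#' @param controls likewise for non-diseased individuals; may be empty.
#' @return a \code{tg_join} data frame with columns chrom, start, end,
#'   unit, geneName, category, d, h, jointScore, rank.
#' @export
tg_join <- function(cases, controls = list()) {
  load1 <- function(x) {
    if (is.character(x)) x <- read_results(x)
    tg_prioritize(x)
  }
  caseRec <- lapply(cases, load1)
  ctrlRec <- lapply(controls, load1)
  all <- c(caseRec, ctrlRec)
  key <- unique(do.call(rbind, lapply(all, function(r)
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               unit = r$unit, stringsAsFactors = FALSE))))
  kid <- paste(key$chrom, key$start, key$end, sep = ":")
  scoresOf <- function(rec) {
    v <- numeric(nrow(key))
    m <- match(kid, paste(rec$chrom, rec$start, rec$end, sep = ":"))
    hit <- !is.na(m)
    v[hit] <- rec$score[m[hit]]
    v
  }
  caseMat <- vapply(caseRec, scoresOf, numeric(nrow(key)))
  ctrlMat <- if (length(ctrlRec))
    vapply(ctrlRec, scoresOf, numeric(nrow(key))) else NULL
  caseMat <- matrix(caseMat, nrow = nrow(key))
  if (!is.null(ctrlMat)) ctrlMat <- matrix(ctrlMat, nrow = nrow(key))
  d <- numeric(nrow(key)); h <- numeric(nrow(key)); js <- numeric(nrow(key))
  for (k in seq_len(nrow(key))) {
    jp <- joint_priority(caseMat[k, ],
                         if (is.null(ctrlMat)) numeric(0L) else ctrlMat[k, ])
    d[k] <- jp$d; h[k] <- jp$h; js[k] <- jp$jointScore
  }
  first <- caseRec[[1L]]
  m <- match(kid, paste(first$chrom, first$start, first$end, sep = ":"))
  out <- key
  out$geneName <- ifelse(is.na(m), "", first$geneName[m])
  out$category <- ifelse(is.na(m), "intergenic", first$category[m])
  out$d <- d; out$h <- h; out$jointScore <- js
  o <- order(-out$jointScore, -abs(out$d), out$chrom, out$start,
             method = "radix")
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("tg_join", "data.frame")
  out
}
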