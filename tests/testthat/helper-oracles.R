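# Independent brute-force oracles and fixture builders.  These
# deliberately re-derive results by literal enumeration, not by calling
# the implementation under test.

# literal per-column scan: gap runs from gapped rows
oracle_gaps <- function(refText, readText, refStart) {
  rc <- strsplit(refText, "")[[1]]
  qc <- strsplit(readText, "")[[1]]
  runs <- list()
  refPos <- refStart
  inRun <- FALSE
  for (j in seq_along(rc)) {
    if (rc[j] == "-" || qc[j] == "-") {
      if (!inRun) {
        runs[[length(runs) + 1]] <- list(d = 0L, i = 0L, refLo = refPos)
        inRun <- TRUE
      }
      r <- runs[[length(runs)]]
      if (qc[j] == "-") r$d <- r$d + 1L
      if (rc[j] == "-") r$i <- r$i + 1L
      runs[[length(runs)]] <- r
    } else inRun <- FALSE
    if (rc[j] != "-") refPos <- refPos + 1L
  }
  if (!length(runs))
    return(data.frame(d = integer(), i = integer(),
                      refLo = integer(), refHi = integer()))
  out <- do.call(rbind, lapply(runs, as.data.frame))
  out$refHi <- out$refLo + out$d
  out
}

# per-column gentle-masked scores, re-derived independently
oracle_column_scores <- function(refText, readText, params) {
  rc <- strsplit(refText, "")[[1]]
  qc <- strsplit(readText, "")[[1]]
  sc <- numeric(length(rc))
  prevGap <- FALSE
  for (j in seq_along(rc)) {
    if (rc[j] == "-" || qc[j] == "-") {
      sc[j] <- -params$gap_extend - if (!prevGap) params$gap_open else 0
      prevGap <- TRUE
    } else {
      sc[j] <- if (toupper(rc[j]) == toupper(qc[j])) params$match
               else params$mismatch
      prevGap <- FALSE
    }
    if (rc[j] %in% letters || qc[j] %in% letters) sc[j] <- min(sc[j], 0)
  }
  sc
}

# O(n^2) max over all contiguous segments (empty segment scores 0)
oracle_max_segment <- function(refText, readText, params) {
  sc <- oracle_column_scores(refText, readText, params)
  best <- 0
  for (a in seq_along(sc)) for (b in a:length(sc))
    best <- max(best, sum(sc[a:b]))
  best
}

# nearest multiple of u, ties toward zero, by enumeration
oracle_round <- function(D, u) {
  cand <- u * ((floor(D / u) - 1):(ceiling(D / u) + 1))
  dist <- abs(cand - D)
  cand <- cand[dist == min(dist)]
  cand[which.min(abs(cand))]
}

# literal re-application of the single-alignment prediction rules
oracle_predict_single <- function(alnStart, alnEnd, gaps, rstart, rend,
                                  u, f, n) {
  if (!(alnStart <= rstart - f && alnEnd >= rend + f))
    return(list(status = "gave_up", change = NA))
  total <- 0
  for (k in seq_len(nrow(gaps))) {
    d <- gaps$d[k]; i <- gaps$i[k]
    lo <- gaps$refLo[k]; hi <- gaps$refHi[k]
    if (d > 0) {
      pos <- lo:(hi - 1)
      ov <- lo < rend && hi > rstart
    } else {
      pos <- lo
      ov <- lo >= rstart && lo < rend
    }
    dist <- vapply(pos, function(x) max(rstart - 1 - x, x - rend, 0), 0)
    if (d == 0) dist <- max(rstart - lo, lo - rend, 0)
    if (!ov && i <= u / 2) next
    if (all(dist >= f)) next
    if (any(dist >= f)) return(list(status = "gave_up", change = NA))
    if (all(dist > n)) next
    r <- max(0, min(hi, rend) - max(lo, rstart))
    total <- total - oracle_round(min(d - i, r), u) / u
  }
  list(status = "predicted", change = total)
}

# one-row tg_alignments with an explicit gap table (no texts)
make_part <- function(refStart, refEnd, gaps = NULL, readStrand = "+",
                      refName = "chr", readName = "read",
                      readStart = 0L, readEnd = NULL, refSize = 10000000L,
                      readSize = 100000L, mismap = 0) {
  if (is.null(readEnd)) readEnd <- readStart + (refEnd - refStart)
  df <- data.frame(readName = readName, readStrand = readStrand,
                   refName = refName, refSize = refSize,
                   refStart = refStart, refEnd = refEnd,
                   readStart = readStart, readEnd = readEnd,
                   readSize = readSize, mismap = mismap, score = NA_real_,
                   refText = NA_character_, readText = NA_character_,
                   stringsAsFactors = FALSE)
  df$gaps <- list(if (is.null(gaps))
    data.frame(d = integer(), i = integer(),
               refLo = integer(), refHi = integer()) else gaps)
  class(df) <- c("tg_alignments", "data.frame")
  df
}

# random single-alignment prediction case (far from sequence edges so
# the left/right f are equal and the oracle can use one f)
random_single_case <- function() {
  u <- sample(c(2:6, 10), 1)
  rstart <- 5000L
  rend <- rstart + u * sample(3:30, 1)
  f <- max(100, u); n <- max(60, u)
  alnStart <- rstart - sample(c(0:50, f:(f + 300)), 1)
  alnEnd <- rend + sample(c(0:50, f:(f + 300)), 1)
  nGaps <- sample(0:5, 1)
  gaps <- NULL
  if (nGaps > 0 && alnEnd - alnStart > 10) {
    lo <- sort(sample(alnStart:(alnEnd - 1), nGaps))
    d <- sample(0:30, nGaps, replace = TRUE)
    i <- ifelse(d == 0, sample(1:30, nGaps, replace = TRUE),
                sample(0:30, nGaps, replace = TRUE))
    hi <- lo + d
    keep <- hi <= alnEnd & c(hi[-nGaps] < lo[-1], TRUE)
    gaps <- data.frame(d = d, i = i, refLo = lo, refHi = hi)[keep, ]
  }
  list(u = u, rstart = rstart, rend = rend, f = f, n = n,
       alnStart = alnStart, alnEnd = alnEnd, gaps = gaps)
}

run_single_case <- function(cs) {
  part <- make_part(cs$alnStart, cs$alnEnd, cs$gaps)
  fn <- list(f_left = cs$f, f_right = cs$f, n = cs$n)
  got <- predict_single(part, 1L, cs$rstart, cs$rend, cs$u, fn)
  exp <- oracle_predict_single(cs$alnStart, cs$alnEnd,
                               if (is.null(cs$gaps))
                                 data.frame(d = integer(), i = integer(),
                                            refLo = integer(),
                                            refHi = integer())
                               else cs$gaps,
                               cs$rstart, cs$rend, cs$u, cs$f, cs$n)
  identical(got$status, exp$status) &&
    (got$status != "predicted" || got$copyChange == exp$change)
}

# full pipeline on a fresh locus: returns per-read predictions
genotype_locus <- function(loc, deltas, strands, error = error_none(),
                           split = FALSE, mismap = 1e-10,
                           mask_ranges = NULL) {
  maf <- character(0)
  for (j in seq_along(deltas)) {
    rs <- make_read(loc, deltas[j], strands[j], error = error,
                    split = split)
    maf <- c(maf, edit_script_to_maf(loc, rs, sprintf("r%03d", j),
                                     mismap = mismap,
                                     mask_ranges = mask_ranges))
  }
  tf <- tempfile(fileext = ".maf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(maf, tf)
  tg_genotype(loc$annotation, read_maf(tf))
}
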