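# Core prediction algorithm: far/near, rounding, net deletion, the
# filter/join steps, and the single- and multi-alignment predictors.

test_that("far_near applies floors, the unit length, and edge truncation", {
  fn <- far_near(3)
  expect_equal(c(fn$f_left, fn$f_right, fn$n), c(100, 100, 60))
  fn <- far_near(200)
  expect_equal(c(fn$f_left, fn$f_right, fn$n), c(200, 200, 200))
  # only 10 bases of sequence upstream: f truncates on that side
  fn <- far_near(3, edge_left = 10, edge_right = 5000)
  expect_equal(fn$f_left, 10)
  expect_equal(fn$f_right, 100)
})

test_that("round_to_unit rounds to nearest multiple, midpoints toward 0", {
  expect_equal(round_to_unit(7, 3), 6)
  expect_equal(round_to_unit(9, 6), 6)
  expect_equal(round_to_unit(-9, 6), -6)
  expect_equal(round_to_unit(0, 5), 0)
  set.seed(1)
  D <- sample(-500:500, 300)
  u <- sample(1:12, 300, replace = TRUE)
  for (k in seq_along(D))
    expect_equal(round_to_unit(D[k], u[k]), oracle_round(D[k], u[k]),
                 info = sprintf("D=%d u=%d", D[k], u[k]))
})

test_that("net_deletion caps deletions at in-repeat reference bases", {
  expect_equal(net_deletion(0, 147, 0), -147)
  expect_equal(net_deletion(50, 0, 40), 40)
  expect_equal(net_deletion(10, 10, 10), 0)
})

test_that("filter_alignments applies the strict mismap cutoff and the
           gentle-masking test", {
  txt <- strrep("A", 50)           # scores 300 >= threshold 180
  mk <- function(mismap, refText = txt, readText = txt) {
    p <- make_part(0L, nchar(gsub("-", "", refText)), mismap = mismap)
    p$refText <- refText; p$readText <- readText
    p$gaps <- NULL
    p
  }
  cfg <- tg_config()
  expect_equal(nrow(filter_alignments(mk(1e-5), cfg)), 0L)   # > 1e-6: out
  expect_equal(nrow(filter_alignments(mk(1e-6), cfg)), 1L)   # == 1e-6: kept
  expect_equal(nrow(filter_alignments(mk(0, strrep("a", 50),
                                         strrep("a", 50)), cfg)), 0L)
  expect_equal(nrow(filter_alignments(mk(0, strrep("A", 20),
                                         strrep("A", 20)), cfg)), 0L)
  expect_equal(nrow(filter_alignments(mk(0)[0, ], cfg)), 0L)  # empty in/out
})

test_that("join_colinear merges colinear neighbors into one part with a
           bridge gap", {
  p1 <- make_part(1000L, 2000L, readStart = 0L, readEnd = 1000L)
  p2 <- make_part(2500L, 3000L, readStart = 1350L, readEnd = 1850L)
  both <- rbind(p1, p2)
  class(both) <- class(p1)
  j <- join_colinear(both, tg_config())
  expect_equal(nrow(j), 1L)
  expect_equal(c(j$refStart, j$refEnd), c(1000L, 3000L))
  expect_equal(c(j$readStart, j$readEnd), c(0L, 1850L))
  expect_equal(j$gaps[[1]], data.frame(d = 500L, i = 350L, refLo = 2000L,
                                       refHi = 2500L))
  # beyond the join distance: kept separate
  far <- make_part(2000000L + 2000L, 2000000L + 2500L,
                   readStart = 1350L, readEnd = 1850L)
  both2 <- rbind(p1, far); class(both2) <- class(p1)
  expect_equal(nrow(join_colinear(both2, tg_config())), 2L)
  # opposite strands: kept separate
  p2m <- make_part(2500L, 3000L, readStrand = "-", readStart = 1350L,
                   readEnd = 1850L)
  both3 <- rbind(p1, p2m); class(both3) <- class(p1)
  expect_equal(nrow(join_colinear(both3, tg_config())), 2L)
})

test_that("join_colinear chains more than two parts transitively", {
  ps <- rbind(make_part(0L, 100L, readStart = 0L, readEnd = 100L),
              make_part(150L, 250L, readStart = 120L, readEnd = 220L),
              make_part(300L, 400L, readStart = 240L, readEnd = 340L))
  class(ps) <- c("tg_alignments", "data.frame")
  j <- join_colinear(ps, tg_config())
  expect_equal(nrow(j), 1L)
  expect_equal(nrow(j$gaps[[1]]), 2L)
})

test_that("join_colinear joins minus-strand colinear parts
           (reference decreasing along the read)", {
  p1 <- make_part(3000L, 4000L, readStrand = "-", readStart = 0L,
                  readEnd = 1000L)
  p2 <- make_part(1000L, 2900L, readStrand = "-", readStart = 1050L,
                  readEnd = 2950L)
  both <- rbind(p1, p2); class(both) <- class(p1)
  j <- join_colinear(both, tg_config())
  expect_equal(nrow(j), 1L)
  expect_equal(j$gaps[[1]]$d, 100L)
  expect_equal(j$gaps[[1]]$i, 50L)
  expect_equal(c(j$gaps[[1]]$refLo, j$gaps[[1]]$refHi), c(2900L, 3000L))
})

test_that("predict_single reproduces the worked expansion case", {
  # CAG x 21 (63 bases), alignment spanning the repeat by 200 each side,
  # one pure-insertion gap of 147 bases inside the repeat -> +49 copies
  rstart <- 1000L; rend <- 1063L
  part <- make_part(rstart - 200L, rend + 200L,
                    gaps = data.frame(d = 0L, i = 147L, refLo = 1030L,
                                      refHi = 1030L))
  fn <- far_near(3)
  res <- predict_single(part, 1L, rstart, rend, 3L, fn)
  expect_equal(res$status, "predicted")
  expect_equal(res$copyChange, 49L)
  # no gaps near the repeat -> change 0
  res0 <- predict_single(make_part(rstart - 200L, rend + 200L), 1L,
                         rstart, rend, 3L, fn)
  expect_equal(res0$copyChange, 0L)
  # insufficient flank extension -> give up
  short <- make_part(rstart - 50L, rend + 200L)
  expect_equal(predict_single(short, 1L, rstart, rend, 3L, fn)$status,
               "gave_up")
  # gap straddling the f boundary (i > u/2 so rule 1 passes it on):
  # partly >= f away -> give up
  strad <- make_part(rstart - 200L, rend + 200L,
                     gaps = data.frame(d = 30L, i = 10L, refLo = 1063L + 80L,
                                       refHi = 1063L + 110L))
  expect_equal(predict_single(strad, 1L, rstart, rend, 3L, fn)$status,
               "gave_up")
})

test_that("gap rule order is pinned: first matching rule wins", {
  rstart <- 1000L; rend <- 1030L
  fn <- far_near(3)  # f = 100, n = 60
  # a gap not overlapping, with i <= u/2, that is also wholly > n away:
  # ignored by rule 1 (and would be by rule 4 too) -> predicted 0
  g1 <- make_part(rstart - 200L, rend + 200L,
                  gaps = data.frame(d = 2L, i = 1L, refLo = rend + 70L,
                                    refHi = rend + 72L))
  expect_equal(predict_single(g1, 1L, rstart, rend, 3L, fn)$copyChange, 0L)
  # same position but i > u/2: rules 2-3 do not fire (< f), rule 4 does
  g2 <- make_part(rstart - 200L, rend + 200L,
                  gaps = data.frame(d = 0L, i = 30L, refLo = rend + 70L,
                                    refHi = rend + 70L))
  expect_equal(predict_single(g2, 1L, rstart, rend, 3L, fn)$copyChange, 0L)
  # within n: the insertion counts
  g3 <- make_part(rstart - 200L, rend + 200L,
                  gaps = data.frame(d = 0L, i = 30L, refLo = rend + 40L,
                                    refHi = rend + 40L))
  expect_equal(predict_single(g3, 1L, rstart, rend, 3L, fn)$copyChange, 10L)
})

test_that("predict_single matches the literal brute-force oracle on
           random cases", {
  set.seed(20240601)
  ok <- vapply(1:300, function(k) run_single_case(random_single_case()),
               logical(1))
  expect_true(all(ok))
})

test_that("predict_multi measures the read-minus-reference gap between
           flanking alignments", {
  # repeat spanning the junction: left part ends ref 1000 / read 1000,
  # right part starts ref 1020 / read 1520 -> insertion 500, u = 5
  rstart <- 950L; rend <- 1050L
  fn <- far_near(5)
  parts <- rbind(
    make_part(800L, 1000L, readStart = 800L, readEnd = 1000L),
    make_part(1020L, 2200L, readStart = 1520L, readEnd = 2700L))
  class(parts) <- c("tg_alignments", "data.frame")
  res <- predict_multi(parts, c(1L, 2L), rstart, rend, 5L, fn)
  expect_equal(res$status, "predicted")
  expect_equal(res$copyChange, 100L)
  # negative insertion size: read gap 0, reference gap 30 -> -10 at u=3
  rstart2 <- 1500L; rend2 <- 1600L
  parts2 <- rbind(
    make_part(800L, 1550L, readStart = 800L, readEnd = 1550L),
    make_part(1580L, 2200L, readStart = 1550L, readEnd = 2170L))
  class(parts2) <- c("tg_alignments", "data.frame")
  res2 <- predict_multi(parts2, c(1L, 2L), rstart2, rend2, 3L, far_near(3))
  expect_equal(res2$copyChange, -10L)
  # a middle part extending >= f beyond the repeat's left edge: give up
  parts3 <- rbind(
    make_part(800L, 1550L, readStart = 800L, readEnd = 1550L),
    make_part(1300L, 1550L, readStart = 1560L, readEnd = 1810L),
    make_part(1580L, 2200L, readStart = 1830L, readEnd = 2450L))
  class(parts3) <- c("tg_alignments", "data.frame")
  res3 <- predict_multi(parts3, c(1L, 2L, 3L), rstart2, rend2, 5L,
                        far_near(5))
  expect_equal(res3$status, "gave_up")
  # opposite strands among overlapping parts: give up
  parts4 <- parts
  parts4$readStrand[2] <- "-"
  expect_equal(predict_multi(parts4, c(1L, 2L), rstart, rend, 5L,
                             fn)$status, "gave_up")
})

test_that("strand and mirror symmetry hold on error-free reads", {
  set.seed(14)
  loc <- make_locus(random_flank(150, "CAG"), random_flank(150, "CAG"),
                    "CAG", 12, chrom = "sym")
  for (delta in c(-5L, 0L, 8L, 40L)) {
    rs <- genotype_locus(loc, c(delta, delta), c("+", "-"))
    expect_equal(rs$forwardChanges[[1]], delta)
    expect_equal(rs$reverseChanges[[1]], delta)
  }
  # mirrored locus (reverse-complemented construct) preserves |change|
  mir <- make_locus(revcomp(random_flank(150, "CTG")),
                    revcomp(random_flank(150, "CTG")), "CTG", 12,
                    chrom = "mir")
  rs <- genotype_locus(mir, 8L, "+")
  expect_equal(abs(rs$forwardChanges[[1]]), 8L)
})

test_that("tg_genotype reports no_coverage and the multi-alignment path", {
  set.seed(15)
  loc <- make_locus(random_flank(140, "CTTG"), random_flank(140, "CTTG"),
                    "CTTG", 9, chrom = "cov")
  # a read aligned only to the left flank: no coverage of the repeat
  rs <- make_read(loc, 0L, "+")
  rs$script[[1]]$ops <- data.frame(op = "M", len = 100L)
  maf <- edit_script_to_maf(loc, rs, "flankonly")
  # plus split reads through the multi path, both strands
  maf <- c(maf,
           edit_script_to_maf(loc, make_read(loc, 25L, "+", split = TRUE),
                              "sp1"),
           edit_script_to_maf(loc, make_read(loc, 25L, "-", split = TRUE),
                              "sp2"))
  tf <- tempfile(); writeLines(maf, tf)
  parts <- read_maf(tf)
  res <- tg_genotype(loc$annotation, parts)
  expect_equal(res$forwardChanges[[1]], 25L)
  expect_equal(res$reverseChanges[[1]], 25L)
  expect_equal(res$nNoCoverage, 1L)
  unlink(tf)
})

test_that("min_unit excludes short-unit annotations from genotyping", {
  set.seed(16)
  loc <- make_locus(random_flank(140, "AT"), random_flank(140, "AT"),
                    "AT", 15, chrom = "mu")
  homo <- loc$annotation
  homo$unit <- "A"; homo$u <- 1L
  reps <- rbind(loc$annotation, homo)
  class(reps) <- c("tg_repeats", "data.frame")
  tf <- tempfile()
  writeLines(edit_script_to_maf(loc, make_read(loc, 3L, "+"), "r1"), tf)
  res <- tg_genotype(reps, read_maf(tf), tg_config(min_unit = 2L))
  expect_equal(nrow(res), 1L)
  expect_equal(res$u, 2L)
  unlink(tf)
})
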