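---
title: "Genotyping tandem repeat copy-number changes from long-read split alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping tandem repeat copy-number changes from long-read split alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemcn)
```

## The model

A tandem repeat locus is an interval `[start, end)` on the reference
with a repeating unit of length `u`; the interval length need not be a
multiple of `u`. A long read spanning the locus carries the
individual's allele, and the difference between the read's and the
reference's copy count shows up in the read-to-genome alignment as
unaligned bases. `tandemcn` estimates, per read, the signed integer
copy-number change relative to the reference annotation (expansions
positive), and aggregates the per-read changes by sequencing strand.

The estimate is purely alignment-arithmetic — there is no HMM, no
motif decomposition, and no allele clustering. That makes it fast,
transparent, and robust to very large expansions (the inserted
sequence never needs to align), at the price of inheriting whatever
biases the aligner has. Reporting the two strands separately is part
of the design: systematic basecalling errors tend to convert a repeat
motif consistently on one strand, and a locus where the forward- and
reverse-strand distributions disagree should be treated with
suspicion rather than averaged.

## Per-read pipeline

1. **Mismap filter.** Alignments with mismap probability strictly
   greater than `mismap_max` (default `1e-6`) are discarded. An absent
   mismap field is read as 0, i.e. alignments without the annotation
   are trusted.
2. **Gentle-masking filter.** Simple sequence is soft-masked
   (lowercase) by the aligner's pipeline. Each alignment is rescored
   column-wise — substitution scores on aligned columns, affine gap
   costs across gap runs, and any column in which *either* letter is
   lowercase contributes at most 0 — and discarded unless some
   contiguous segment reaches the score threshold. This removes
   alignments consisting almost entirely of simple sequence. The
   scoring defaults (match +6, mismatch −18, gap open 21, gap extend
   9, threshold 180) stand in for aligner-trained parameters, which
   are outside this package's scope; all are exposed via
   `tg_scoring()`. Whether masking should consider the reference row,
   the read row, or both is not prescribed anywhere we could find;
   both-sides is used because either row's lowercase marks the same
   simple-sequence column.
3. **Colinear joining.** Consecutive alignments of one read on the
   same strand of the same chromosome, advancing without overlap in
   both coordinates and separated by ≤ `1e6` reference bases, are
   merged left-to-right, transitively (chains longer than two are
   allowed; the limit is not stated and transitive merging is the
   natural reading). The bridged region becomes an ordinary gap run,
   so it flows through the same gap rules as aligner-produced gaps.
4. **Prediction.** For each annotated repeat, the read's joined
   alignments overlapping the repeat interval are counted: none →
   no coverage; one → single-alignment path; several →
   multi-alignment path.

### Distances

`f = max(100, u)` and `n = max(60, u)`. `f` is the flank extension an
alignment must have beyond both repeat boundaries, and the radius of
the give-up rules; `n` bounds which gaps count toward the repeat. `f`
is truncated, per side, at the edge of the reference sequence — a
construct with only 10 bp upstream of the repeat has an upstream `f`
of 10. Both floors are configurable (`tg_config(far_floor=,
near_floor=)`).

### Single-alignment path

The alignment must extend ≥ `f` beyond both sides of the repeat, else
the read gives up at this repeat. Every gap run (d unaligned
reference bases, i unaligned read bases, merged across adjacent
columns) is tested against four rules **in order**: not overlapping
the repeat with `i ≤ u/2` → ignore; wholly ≥ `f` away → ignore;
partly ≥ `f` away → give up; wholly > `n` away → ignore. The order is
semantic: a tiny gap far from the repeat is ignored by the first rule
before the distance rules are consulted. A surviving gap contributes
`-round_u(min(d - i, r))/u` copies, where `r` is the count of the
gap's unaligned reference bases inside the repeat and `round_u`
rounds to the nearest multiple of `u` with ties toward zero. Each gap
is rounded independently and the contributions summed.

Two geometric conventions had to be fixed. A pure insertion (`d = 0`)
is a zero-length point at its reference position; it overlaps the
repeat iff the point lies in `[start, end)`. A point at exactly `end`
is not an overlap but has distance 0, is within `n`, and therefore
still contributes (`r = 0`, so `D = -i`): boundary insertions are
counted either way, and nothing depends on the overlap call itself.
Second, in the "partly ≥ f away" test each unaligned reference
position is compared against the `f` of its own side, so a truncated
`f` on one flank does not affect gaps on the other.

### Multi-alignment path

An expansion too divergent to align in the middle leaves two
alignments flanking it. All overlapping alignments must be
consecutive in the read and on one strand. The reference-leftmost
("left") alignment must extend ≥ `f` left of the repeat and of every
other overlapping alignment, while no other overlapping alignment
extends ≥ `f` left of the repeat; mirror conditions apply on the
right. The change is then (read bases between the left alignment's
end and the right alignment's start) − (reference bases between
them), rounded to units — negative values (contractions) pass
through. Whenever a give-up condition and a prediction are both
arguable, the give-up wins.

Predictions more negative than the annotated reference copy count are
not clamped: the annotation boundary may be wrong, and the raw value
is more informative than a floor.

## Prioritization

Per repeat the "top" change is selected from the pooled strand lists:
if the dataset's mean prediction count over covered repeats is ≥ 3,
one copy of the maximum and one of the minimum are dropped first
(outlier-read protection; an assembled genome contributing one
prediction per repeat — mean < 3 — skips the dropping). A value is
only dropped while at least two remain. Of the remainder the largest
absolute base change wins, ties preferring the expansion. The score is
`bases/(refLen + 30) × multiplier`, doubled for coding polyglutamine/
polyalanine units (all 6 reading frames of the infinite unit
repetition are checked; the codon cycle has period `lcm(u,3)/3`).
Ranking is by descending absolute score, ties broken by absolute base
change then coordinates, so output order is deterministic.

The intergenic multiplier is 1 — no value is prescribed, and a
neutral baseline keeps scores comparable across annotated and
unannotated loci. The promoter window is 1000 bp upstream of
`txStart`, strand-aware: "promoter" is conventionally vague, 1 kb is
the common default, and the value is a `classify_region()` argument.
When several transcripts overlap a repeat the largest multiplier
wins; the 15/15 tie between promoter and ncRNA exon goes to the exon,
which is the more specific evidence.

For case/control joining, per-dataset scores are recomputed from each
result file (each dataset gets its own mean-prediction gate), missing
repeats contribute 0 for that dataset, and the joint score is
`max(d - max(h, 0), 0)` on cubic means, with both negated first when
`d < 0`. The cubic mean makes one large control expansion nearly as
de-prioritizing as three.

## The synthetic generator, and what a green test establishes

`make_locus()` builds flank + unit×copies + flank, with flanks
rejected while they contain the unit three times in a row, so the
repeat boundary is unambiguous. `make_read()` plants a signed copy
change mid-tract and records the exact edit script;
`edit_script_to_maf()` renders the script as MAF (optionally split
into two blocks around the expansion, reproducing the
two-flanking-alignments geometry, and optionally soft-masked over
given reference ranges). `make_background_genome()` scales this to
thousands of independent loci — units of 2–6 bp, 8–20 reference
copies, 120 bp flanks, coverage 4 alternating strands, background
noise uniform on ±2 copies, and about 20% of loci wrapped in a
synthetic gene so genic contexts occur. These defaults are the
stated experimental world of the validation suite; they are not tuned
per test.

Error models: `error_uniform()` applies i.i.d. per-base substitutions
and single-base indels (optionally confined to the flanks);
`error_strand_systematic()` converts every repeat unit of one
strand's reads into a target motif. Because this package also
*generates* the alignments, the converted tract is emitted as one
unaligned run (reference repeat deleted, converted tract inserted) —
the way a real aligner treats a tract that no longer matches the
reference. With an equal-length target motif the gap arithmetic then
cancels exactly, so the strand-bias demonstrations use a shorter
target (`GGGGCC → GGCC`, a deletion-type systematic miscall); the
asserted property is qualitative — the gated strand's mode moves, the
ungated strand's does not, and error-free strands coincide.

What the generator does **not** emulate: signal-level nanopore error
structure, homopolymer-length miscalls, context-dependent indel
rates, mismap ambiguity from genomic repeat families, and real
aligner behaviour on divergent tracts (partial alignments of a
converted repeat, boundary wobble). A green synthetic test therefore
establishes that the *genotyping arithmetic* is correct given the
alignments, not that any aligner will produce such alignments; the
MAF reader accepts externally produced files for that purpose. The
SCA10-scale benchmark against public sequencing runs requires
downloads and an external aligner and is deliberately outside the
test suite.

## Numerical and degenerate-input choices

* Midpoint rounding is toward zero in both directions
  (`round_to_unit(9, 6) = 6`, `round_to_unit(-9, 6) = -6`).
* The mismap cutoff is strict (`>`): a mismap of exactly `1e-6` is
  kept.
* `-u`/`min_unit` defaults to 2 (homopolymers excluded; pass 1 to
  include them). It filters annotations only and never enters the gap
  arithmetic.
* An empty control set, or controls whose scores are all ≤ 0, leave
  the joint score equal to `|d|`; single-dataset ranking equals
  joining with no controls.
* Empty change lists produce no priority record; with `--all` the
  repeat still appears in the result file with empty fields.
* Unknown letters in alignments score as mismatches (with a warning);
  all-masked alignments score 0 and are discarded.

## Known limitations

Interrupted repeats are treated as their annotation says, so an
interruption inside the tract is invisible; gap placement within the
repeat is trusted from the aligner; no allele clustering is done —
the per-read distribution is the output, and a heterozygous expansion
appears as bimodality, not as two genotype calls; and the priority
score is an ad hoc screen, not a statistical test — no significance
is attached to ranks.
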