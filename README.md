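# tandemcn

Tandem repeat copy-number genotyping from long-read split alignments.

## The problem

Copy-number changes at tandem repeats — adjacent copies of a short DNA
unit such as CAG — cause more than 30 human diseases, from a few extra
copies (polyglutamine disorders like Huntington's disease) to thousands
(intronic expansions like SCA10 or BAFME). Long reads can span an entire
expanded allele, but the expansion appears only indirectly in the read's
alignment to the reference genome: as a large insertion gap inside one
alignment, or as a split into two alignments flanking an unalignable
middle. `tandemcn` turns such split alignments (MAF format, with
per-alignment mismap probabilities and lowercase soft-masking) plus a
repeat annotation into **per-read integer copy-number changes**, reported
separately for forward- and reverse-strand reads — because systematic
strand-specific sequencing errors make the two distributions disagree at
problem loci, and seeing that disagreement is diagnostic.

It is aimed at people analysing nanopore/PacBio whole-genome or targeted
data who want to screen ~1 million annotated repeats and shortlist the
handful worth looking at.

## The method

For each read: discard alignments with mismap probability > 10⁻⁶;
discard alignments that keep no segment scoring ≥ the aligner threshold
under *gentle masking* (columns over soft-masked letters contribute at
most 0); join consecutive colinear alignments separated by ≤ 10⁶ bp.
Two ad hoc distances are defined per repeat with unit length *u*:
*f* = max(100, *u*) (truncated at sequence edges) and *n* = max(60, *u*).

With **one** alignment overlapping the repeat, it must extend ≥ *f*
beyond both sides; each alignment gap (d unaligned reference bases, i
unaligned read bases) is then either ignored, counted, or triggers a
give-up according to its distance from the repeat, and a counted gap
contributes

    -round_u( min(d - i, r) ) / u    copies,

where *r* is the number of unaligned reference bases inside the repeat
and round_u rounds to the nearest multiple of *u*, ties toward zero.
With **several** overlapping alignments (the split-expansion geometry),
the change is the read-minus-reference base count between the two
flanking alignments, rounded the same way.

Repeats are ranked by the absolute **priority score**

    (change in bases) / (reference repeat length + 30) × M × P,

with region multiplier M = 50 coding / 20 UTR / 15 promoter / 15 ncRNA
exon / 5 intron / 1 intergenic, and P = 2 for coding repeats whose unit
encodes polyglutamine or polyalanine in any of the 6 reading frames.
Case and control datasets are joined per repeat via cubic means
(d = ∛mean(case scores³), h likewise for controls; negate both if d < 0):

    joint score = max(d - max(h, 0), 0),

so one large control expansion strongly de-prioritizes a repeat.

A synthetic module generates loci, reads with planted copy changes,
uniform and strand-systematic error models, chimeric reads, and
ground-truth MAF from edit scripts, so the whole pipeline is testable
with no aligner and no downloads.

## Worked example

An HTT-like locus — CAG×21 in the reference, six error-free reads
carrying 70 copies (the Huntington chimera design; expected change +49):

```r
library(tandemcn)
set.seed(2026)
loc <- make_locus(random_flank(150, "CAG"), random_flank(150, "CAG"),
                  "CAG", 21, chrom = "chr4")
maf <- unlist(lapply(1:6, function(j)
  edit_script_to_maf(loc, make_read(loc, 49, c("+", "-")[1 + j %% 2]),
                     paste0("read", j))))
writeLines(maf, "example.maf")
res <- tg_genotype(loc$annotation, read_maf("example.maf"))
res$category <- "coding"; res$geneName <- "HTT"; res$multiplier <- 50
pr <- tg_prioritize(res)
pr[, c("chrom", "start", "end", "unit", "geneName",
       "topChangeCopies", "score", "rank")]
#>   chrom start end unit geneName topChangeCopies    score rank
#> 1  chr4   150 213  CAG      HTT              49 158.0645    1
write_results(res, stdout(), ranked = pr)
#> #tandemcn 0.1.0
#> #mismap_max=1e-06
#> #far_floor=100 near_floor=60
#> #min_unit=2
#> #multipliers=coding:50,UTR:20,ncRNA_exon:15,promoter:15,intron:5,intergenic:1
#> chr4	150	213	CAG	HTT:coding	49,49,49	49,49,49	158.065
```

Every read on both strands recovers +49 copies. The score is
49×3 bases / (63 + 30) × 50 (coding) × 2 (polyglutamine) ≈ 158.06.

The same steps from a shell, on real files (UCSC `rmsk.txt` or a BED-like
`chrom start end unit [name]` file, `refFlat.txt`, and MAF from a
split-read aligner):

```sh
Rscript -e 'tandemcn::tg_main()' copy -u 1 -g refFlat.txt rmsk.txt alns.maf
Rscript -e 'tandemcn::tg_main()' join case.txt : ctrl1.txt ctrl2.txt ctrl3.txt
Rscript -e 'tandemcn::tg_main()' plot -n 10 results.txt
```

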