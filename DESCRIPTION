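Package: tandemcn
Title: Tandem Repeat Copy-Number Genotyping from Long-Read Split Alignments
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts per-read copy-number changes at annotated tandem
    repeats from split long-read alignments in MAF format, reports the
    changes separately for forward- and reverse-strand reads, ranks
    repeats genome-wide by a pathogenicity-oriented priority score, and
    joins multiple datasets with a cubic-mean case/control score to
    de-prioritize benign variation.  Includes readers for UCSC
    RepeatMasker (rmsk.txt), BED-like custom repeat files and refFlat
    gene models, a gene-context classifier, and a synthetic long-read
    generator that emits ground-truth MAF from edit scripts so the whole
    pipeline is testable without an aligner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
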