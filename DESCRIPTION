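Package: tailforge
Title: Poly(A) Tail Profiling and RNA Turnover Kinetics from Long-Read Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls poly(A) tails from terminal soft clips of splice-aware
    long-read alignments (85% adenine rule), summarizes tail-length
    distributions per gene and per splice isoform, tests for differential
    tail length between conditions (Mann-Whitney U with Benjamini-Hochberg
    correction), profiles positional non-A nucleotide composition within
    tails, estimates RNA turnover kinetics (fraction-new, degradation and
    synthesis rate constants) from nucleotide-recoding metabolic-labeling
    data via a two-binomial mixture, and fits hyperbolic filter-binding
    curves. Includes a fully seeded synthetic-data generator (genome,
    annotation, SAM alignments with known tails, mutation tables, binding
    curves) so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    GenomeInfoDb,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
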