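# tailforge

Poly(A) tail profiling and RNA turnover kinetics from long-read alignments.

## What it does, and for whom

When spliced long reads (e.g. PacBio HiFi CCS) are mapped splice-aware to a
genome, the untemplated poly(A) tail cannot align and is left as a terminal
**soft clip** in the CIGAR string. `tailforge` is for transcriptomics groups
who want to turn such alignments into per-gene and per-isoform tail-length
biology without writing one-off scripts:

* **Tail calling** — the transcript-3′ soft clip of each primary alignment
  is extracted (reverse-complemented for minus-strand reads) and called a
  tail when at least 85% of its bases are adenosine (inclusive boundary)
  and it is at least 5 nt long. The reported length is the full clip,
  non-A bases included.
* **Tail statistics** — reads are assigned to the same-strand gene with
  maximal overlap; per gene and per splice isoform the package reports
  *n*, mean, median, quartiles, and Pearson's second skewness coefficient
  3(mean − median)/s.
* **Differential tail length** — per-group two-condition testing with the
  Mann–Whitney U test and Benjamini–Hochberg correction (default
  FDR < 0.05, ≥ 100 reads per condition per group), with the direction of
  the median difference.
* **Tail composition** — positional counts of A/C/G/U within called tails,
  anchored either at the cleavage site or at the tail 3′ end, with a
  per-position Welch t-test on per-read non-A indicators between
  conditions.
* **Turnover kinetics** — for nucleotide-recoding metabolic labeling data
  (s⁴U/TimeLapse chemistry), filtered T→C conversion counting (base
  quality ≥ 40, 5-nt end trim, SNP mask), a two-binomial mixture EM for
  the fraction of newly synthesized reads θ, and conversion to rate
  constants:

  ```
  k_deg = -ln(1 - θ) / t_label        (first-order decay, t_label = 2 h)
  k_syn = k_deg × steady-state level  (steady-state assumption)
  ```

* **Filter binding** — fraction bound = nitro/(nitro + nylon) and
  Levenberg–Marquardt fitting of the single-site hyperbola
  `f(c) = f_max·c/(c + K_d)` with multi-start initialization.

A fully seeded synthetic-data generator (genome, annotation, SAM
alignments with known tails, mutation tables, binding curves) provides
ground truth for every stage, so the whole pipeline is testable offline.

## Worked example

```r
library(tailforge)

ref   <- generate_reference(20, seed = 1)
truth <- simulation_truth(ref, conditions = c("A", "B"), effect_size = 1.2,
                          prop_affected = 0.5, reads_per_gene = 150L, seed = 2)
tails <- lapply(c(A = "A", B = "B"), function(cond) {
  reads <- simulate_tailed_reads(truth[truth$condition == cond, ], ref,
                                 seed = 3 + (cond == "B"))
  sam <- tempfile(fileext = ".sam")
  write_alignments(reads, ref, sam)
  assign_to_genes(tail_table(read_alignments(sam, sample = cond)),
                  ref$annotation)
})
head(summarize_by_gene(tails$A), 3)
#>    gene_id sample n_reads     mean median q25 q75 pearson_skew
#> 1 gene0001      A     150 92.64667   92.5  75 108   0.01930796
#> 2 gene0002      A     150 93.78000   92.0  78 110   0.23125050
#> 3 gene0003      A     150 88.19333   88.0  73 101   0.02765645

diff <- compare_conditions(tails$A, tails$B, min_reads = 100)
head(diff[, c("group_id", "median_a", "median_b", "q_value", "direction")], 3)
#>   group_id median_a median_b      q_value   direction
#> 1 gene0009     92.5      111 8.144359e-11 longer_in_B
#> 2 gene0001     92.5      111 3.601134e-10 longer_in_B
#> 3 gene0019     90.0      109 9.353825e-10 longer_in_B
```

Gene 0009's median tail grows from 92.5 to 111 nt (the simulated 20%
lengthening); the q-values are Benjamini–Hochberg-adjusted Mann–Whitney
p-values, and `direction` names the condition with the longer tails.

Binding-curve fitting:

```r
fit <- fit_binding(simulate_binding(kd = 100, f_max = 0.9, noise_sd = 0))
fit
#> Hyperbolic binding fit: f(c) = f_max * c / (c + Kd)
#>   Kd:    100 nM
#>   f_max: 0.9000
#>   rss:   0 over 7 points
```

An end-to-end run from a YAML config (`run_pipeline("config.yaml")`)
writes one TSV per stage plus a JSON manifest; a thin command-line wrapper
lives at `inst/scripts/tailforge.R`.

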