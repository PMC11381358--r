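---
title: "Methods: poly(A) tail profiling, differential tail statistics, and turnover kinetics"
author: "tailforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poly(A) tail profiling, differential tail statistics, and turnover kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailforge)
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, the tunable parameters, what the synthetic
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## 1. Tail calling from soft clips

Splice-aware mapping of long reads leaves the untemplated poly(A) tail as
a terminal soft clip (CIGAR `S`). The caller extracts, per primary mapped
record, the clip at the transcript 3′ end: the trailing clip as stored for
forward reads, the leading clip reverse-complemented for reverse-flagged
reads. Hard clips are ignored. Secondary and supplementary records are
dropped, matching upstream mapping with secondary output disabled.

A clip is called a tail when

* `frac_A >= min_frac_A` (default **0.85**, inclusive) computed over the
  whole clip, and
* `clip_length >= min_len` (default **5 nt**).

Choices worth spelling out:

* **Inclusive boundary.** An 85% adenine requirement leaves the boundary
  case unstated; we treat `frac_A = 0.85` (e.g. 17 of 20) as a tail. The
  boundary is exercised explicitly in the tests.
* **Length includes non-A bases.** Called tails genuinely contain C/G/U
  residues near their 3′ ends; truncating at the first non-A base would
  bias both length and composition. The reported length is the full clip.
* **Minimum length 5 nt.** A floor suppresses 1–2 nt clip noise from
  imperfect end trimming; it is configurable and its effect is visible in
  the output table because failing rows are retained with
  `is_tail = FALSE`.
* **No adapter trimming inside clips.** Adapter removal is assumed
  upstream; residual adapter would fail the A-content rule in any case.

## 2. Gene and isoform assignment, summaries

Reads are assigned by intersecting the full reference span of each read
with same-strand gene intervals and keeping the gene with maximal overlap.
Ties are dropped rather than double-counted so per-gene distributions stay
disjoint; opposite-strand overlaps never match. The overlap is bed-style
(read span vs gene span), not exon-aware — introns retained in a read do
not change its assignment, which is the behaviour wanted when
intron-retained transcripts are of interest.

Per (gene, condition) and per (isoform, condition) the package reports n,
mean, median, quartiles, and **Pearson's second skewness coefficient**
`3 * (mean - median) / s` with the sample (n−1) standard deviation,
undefined for n < 2 or s = 0. Quartiles use linear interpolation between
order statistics (R's default type 7), stated here so results are
reproducible bit for bit. Isoform assignment tables come from an upstream
isoform-discovery tool as a read → isoform TSV with an intron-retention
flag; conflicting duplicate read assignments are a hard error naming the
offending reads.

## 3. Differential tail length

For each group with at least `min_reads` (default **100**) called tails in
both conditions, the two tail-length samples (replicates pooled within
condition) are compared with the Mann–Whitney U test — the tie-corrected
normal approximation with continuity correction, appropriate at these
group sizes; exact enumeration appears only as a test oracle. P-values are
Benjamini–Hochberg adjusted across tested groups; `significant` means
`q < fdr` (default **0.05**), and `direction` is the sign of the median
difference for significant groups. The 100-read filter matches the depth
at which per-gene tail medians become stable in this kind of data; it is
configurable because published gene counts are sensitive to it.

## 4. Positional tail composition

Called tails are aligned at either the **cleavage site** (position 0 =
first tail base, counting 3′-ward; default range 400 positions) or the
**tail 3′ end** (position 0 = terminal base, counting 5′-ward; default 50
positions). At each position the A/C/G/U counts over covering tails are
reported (T is reported as U; N bases are excluded from numerator and
denominator). For condition comparisons, each position gets a Welch
two-sample t-test on the per-read binary non-A indicator, computed in
closed form from the counts and cross-checked against `t.test` in the
suite. Per-read indicators (rather than replicate-level proportions, n = 2)
were chosen for power and determinism; a replicate-level alternative is a
straightforward aggregation of the same profile table. No correction is
applied across positions; the p = 0.05 line is presentation only.

## 5. Turnover kinetics

Metabolic labeling with s⁴U followed by chemical recoding marks newly
synthesized RNA with apparent T→C conversions. Conversion counting applies
the standard filters: base quality ≥ **40**, sites within **5 nt** of
either read end ignored, SNP-mask positions ignored; on minus-strand
transcripts genomic A→G is counted as T→C in transcript space. Per-base
reference identity comes from the MD tag when present, else from a
reference FASTA; both routes are tested against a brute-force
re-alignment oracle.

Per gene, read-level counts (k conversions among n T sites) are modeled as
a two-component binomial mixture,

$$\ell(\theta, p_{new}, p_{old}) = \sum_i \log\left[\theta\,
\mathrm{Bin}(k_i \mid n_i, p_{new}) + (1-\theta)\,
\mathrm{Bin}(k_i \mid n_i, p_{old})\right],$$

maximized by EM (log-sum-exp arithmetic; monotone log-likelihood asserted
in tests; convergence at Δll < 1e-8 or 500 iterations). This is a
deliberately simplified estimator: it ignores replicate hierarchy and
per-site effects, trading them for a closed, simulation-testable contract
on θ.

Numerical choices:

* **Background rate.** Free co-estimation of \(p_{old}\) is weakly
  identifiable when most reads are labeled: the global MLE can collapse
  \(p_{old}\) toward 0 and inflate θ by a few percent. The default
  workflow therefore estimates the background globally from an unlabeled
  control (`background_rate()`, the no-label replicates every such
  experiment carries) and fixes it per gene via `fix_p_old`. Free
  co-estimation remains available.
* **Identifiability floor.** The M-step keeps
  \(p_{new} \ge p_{old} + 10^{-4}\) so the components cannot collapse; and
  when no conversions are observed at all the fit resolves the flat
  likelihood ridge to the boundary θ = 0.
* **Clamping.** θ is clamped to \(1 - 10^{-6}\) before
  \(k_{deg} = -\ln(1-\theta)/t\) (labeling time default **2 h**), with a
  message when triggered. \(k_{syn} = k_{deg} \times\) steady-state level,
  with abundances supplied externally (TPM or normalized counts); the
  package does no quantification of its own.

Cross-condition comparison reports per-gene log2 fold changes of k_deg,
k_syn and median tail length, Pearson correlations among them, and median
k_deg per median-tail-length bin (default width **50 nt**, matching the
short/long regimes of interest below 50 and above 150 nt).

## 6. Binding curves

Fraction bound is nitro/(nitro + nylon). The single-site hyperbola
\(f(c) = f_{max}\, c/(c + K_d)\) is fit by Levenberg–Marquardt least
squares with three starts (K_d at the minimum, geometric mean, and maximum
of the concentration series; f_max at the largest observed fraction),
keeping the lowest-RSS converged fit. \(f_{max}\) is bounded in (0, 1.2]
to tolerate normalization noise; constant fraction-bound input has no
curvature and is a hard error. The default simulated design is the
two-fold dilution series from 4000 nM to 62.5 nM.

## 7. The synthetic generator: what it does and does not emulate

The generator builds a single chromosome of non-overlapping single-exon
genes on alternating strands, then reads consisting of the 3′ portion of
the gene body plus a tail:

* **Tail lengths** are negative binomial, parameterized by the *median*
  (the mean is solved by root-finding on the CDF so the requested median
  is exact) and a dispersion φ with variance μ + φμ². Defaults: baseline
  median **90 nt**, φ = **0.05** (sd ≈ 22 nt at μ ≈ 90, an overdispersed
  spread typical of per-gene tail distributions), a **1.2×** median
  lengthening (the ~20% effect size of interest) applied to a configurable
  fraction of genes (default 10%). The empirical tail-length family of
  real data is not known in closed form; any overdispersed count family
  would do, and the negative binomial is the conventional choice.
* **Non-A bases** are substituted uniformly among C/G/U within the
  terminal **k = 10** tail positions at rate **0.1** per position by
  default, emulating the 3′-anchored non-A signal in real tails.
* **SAM encoding** writes gene bodies as `M` and the entire tail as a
  terminal soft clip; minus-strand genes are emitted reverse-complemented
  with a leading clip of T's, chosen deliberately to exercise strand
  handling.
* **Labeling data** follow the two-binomial structure exactly
  (θ = 0.3, p_new = 0.05, p_old = 0.002, ~40 T sites/read by default).
* **Binding data** evaluate the hyperbola with optional Gaussian noise,
  clipped to [0, 1].

Not emulated: sequencing error in gene bodies, splicing structure
(isoform tables are consumed as plain TSVs), adapter/UMI chemistry,
per-site conversion-rate variation, and coverage biases. Passing tests on
generator output therefore demonstrate correctness of the *computations*
— clip extraction, counting, testing, estimation — under a known model;
they do not certify robustness to mapping artifacts or chemistry-specific
biases in real libraries, which should be assessed with the usual QC on
real data.

All generator entry points take an explicit integer seed and restore the
caller's RNG state; identical seeds give byte-identical files.

## 8. Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data at
desk scale: 10,000-read SAM round trips for the tail caller; 1000 random
vectors against brute-force summary oracles; 2000 null genes at 100 reads
per condition for false-discovery control; 200 genes at 200
reads/condition (10% of genes lengthened 20%) for detection power; 2000
tails per condition for composition; 5000 reads per θ for mixture
recovery over θ ∈ {0.1, 0.3, 0.5, 0.8}; and the 4 μM → 62.5 nM series for
binding. These sizes make every property cheap to recompute while keeping
Monte-Carlo error well inside the asserted tolerances.

## 9. Known limitations

* Gene assignment is span-based, not exon-aware; reads bridging adjacent
  genes resolve by maximal overlap or drop out on ties.
* The mixture estimator is per-gene and replicate-blind; uncertainty in θ
  is not propagated into k_deg.
* Tail calling trusts the aligner's clip boundaries; internal priming and
  poly(A)-site clustering are out of scope.
* The composition t-test treats reads as independent units; replicate
  structure is not modeled.
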