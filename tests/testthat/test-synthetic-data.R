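test_that("reference generation respects contracts and is deterministic", {
  ref <- generate_reference(1, gene_length_range = c(1000L, 1000L), seed = 7)
  expect_equal(nrow(ref$genes), 1L)
  expect_equal(ref$genes$end - ref$genes$start, 1000L)
  expect_lte(max(ref$genes$end), sum(Biostrings::width(ref$genome)))

  d1 <- tempfile(); d2 <- tempfile()
  r1 <- generate_reference(50, seed = 7)
  r2 <- generate_reference(50, seed = 7)
  write_reference(r1, d1)
  write_reference(r2, d2)
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))
  expect_identical(readLines(file.path(d1, "genes.bed")),
                   readLines(file.path(d2, "genes.bed")))

  # brute-force all-pairs overlap check
  g <- r1$genes
  for (i in seq_len(nrow(g) - 1)) {
    for (j in (i + 1):nrow(g)) {
      expect_lte(min(g$end[i], g$end[j]) - max(g$start[i], g$start[j]), 0)
    }
  }
  expect_error(generate_reference(5, gene_length_range = c(500, 300), seed = 1),
               "min <= max")
})

test_that("annotation round-trips through BED and GTF on disk", {
  ref <- make_tiny_ref()
  d <- tempfile()
  paths <- write_reference(ref, d)
  bed <- read_annotation(paths["bed"])
  expect_equal(sort(bed$gene_id), sort(ref$genes$gene_id))
  m <- match(ref$genes$gene_id, bed$gene_id)
  expect_equal(GenomicRanges::start(bed)[m] - 1L, ref$genes$start)
  expect_equal(GenomicRanges::end(bed)[m], ref$genes$end)
  expect_equal(as.character(GenomicRanges::strand(bed))[m], ref$genes$strand)
  gtf <- read_annotation(paths["gtf"])
  m2 <- match(ref$genes$gene_id, gtf$gene_id)
  expect_equal(GenomicRanges::start(gtf)[m2] - 1L, ref$genes$start)
})

test_that("simulated tails honour the tail model and composition settings", {
  ref <- generate_reference(1, gene_length_range = c(1000L, 1000L), seed = 3)
  pure <- simulation_truth(ref, conditions = "A", nonA_rate_3prime = 0,
                           reads_per_gene = 500L, seed = 4)
  reads <- simulate_tailed_reads(pure, ref, seed = 5)
  expect_true(all(grepl("^A*$", reads$tail_seq)))
  expect_equal(nchar(reads$tail_seq), reads$tail_length)

  none <- simulation_truth(ref, conditions = "A", reads_per_gene = 0L, seed = 4)
  expect_equal(nrow(simulate_tailed_reads(none, ref, seed = 5)), 0L)

  # condition medians 100 and 120 recovered within +/- 2 nt at 10k reads
  truth <- simulation_truth(ref, conditions = c("A", "B"),
                            baseline_median = 100, effect_size = 1.2,
                            prop_affected = 1, reads_per_gene = 10000L,
                            seed = 6)
  rd <- simulate_tailed_reads(truth, ref, seed = 7)
  med <- tapply(rd$tail_length, rd$sample, median)
  expect_lt(abs(med[["A"]] - 100), 2)
  expect_lt(abs(med[["B"]] - 120), 2)

  expect_error(simulate_tailed_reads(truth, ref, tail_model = "zeta", seed = 1),
               "unknown tail length model")
})

test_that("SAM encoding follows the soft-clip and strand conventions", {
  ref <- generate_reference(2, gene_length_range = c(1000L, 1000L), seed = 9)
  # gene0001 is plus strand, gene0002 minus strand by construction
  g <- ref$genes
  chrom <- as.character(ref$genome[[1]])
  body_plus <- substring(chrom, g$end[1] - 200 + 1, g$end[1])
  body_minus <- paste(rev(strsplit(chartr("ACGT", "TGCA",
    substring(chrom, g$start[2] + 1, g$start[2] + 200)), "")[[1]]),
    collapse = "")
  reads <- data.frame(
    read_id = c("p1", "m1"),
    gene_id = g$gene_id,
    sample = "A",
    chrom = g$chrom,
    strand = c("+", "-"),
    body_start = c(g$end[1] - 200L, g$start[2]),
    body_end = c(g$end[1], g$start[2] + 200L),
    body_seq = c(body_plus, body_minus),
    tail_seq = strrep("A", 50),
    tail_length = 50L,
    stringsAsFactors = FALSE
  )
  sam <- tempfile(fileext = ".sam")
  write_alignments(reads, ref, sam)
  rec <- grep("^@", readLines(sam), invert = TRUE, value = TRUE)
  f1 <- strsplit(rec[1], "\t")[[1]]
  f2 <- strsplit(rec[2], "\t")[[1]]
  expect_equal(f1[6], "200M50S")
  expect_equal(f2[6], "50S200M")
  expect_equal(as.integer(f2[2]), 16L)
  # minus-strand leading clip stores the reverse complement: 50 T's
  expect_equal(substr(f2[10], 1, 50), strrep("T", 50))

  empty <- reads[0, ]
  sam2 <- tempfile(fileext = ".sam")
  write_alignments(empty, ref, sam2)
  expect_true(all(startsWith(readLines(sam2), "@")))
})

test_that("read conservation: one SAM record per simulated read, per gene", {
  ref <- make_tiny_ref()
  truth <- simulation_truth(ref, conditions = "A", reads_per_gene = 37L,
                            seed = 2)
  reads <- simulate_tailed_reads(truth, ref, seed = 3)
  expect_equal(nrow(reads), sum(truth$reads_per_gene))
  expect_equal(unname(table(reads$gene_id)[truth$gene_id]),
               as.array(truth$reads_per_gene), ignore_attr = TRUE)
  sam <- tempfile(fileext = ".sam")
  write_alignments(reads, ref, sam)
  n_rec <- sum(!startsWith(readLines(sam), "@"))
  expect_equal(n_rec, nrow(reads))
})

test_that("timelapse mixture has the closed-form pooled conversion rate", {
  ref <- generate_reference(1, seed = 1)
  tr <- simulation_truth(ref, conditions = "A", theta_true = 0.3,
                         p_new = 0.05, p_old = 0.002,
                         reads_per_gene = 5000L, seed = 2)
  tl <- simulate_timelapse(tr, read_T_content = 40, seed = 3)
  rate <- sum(tl$n_TC) / sum(tl$n_T)
  expected <- 0.3 * 0.05 + 0.7 * 0.002
  se <- sqrt(expected * (1 - expected) / sum(tl$n_T))
  expect_lt(abs(rate - expected), 3 * se)

  tr0 <- simulation_truth(ref, conditions = "A", theta_true = 0,
                          reads_per_gene = 2000L, seed = 2)
  tl0 <- simulate_timelapse(tr0, seed = 3)
  expect_lt(abs(sum(tl0$n_TC) / sum(tl0$n_T) - 0.002), 0.002)
  tr1 <- simulation_truth(ref, conditions = "A", theta_true = 1,
                          reads_per_gene = 2000L, seed = 2)
  tl1 <- simulate_timelapse(tr1, seed = 3)
  expect_lt(abs(sum(tl1$n_TC) / sum(tl1$n_T) - 0.05), 0.004)
})

test_that("binding simulation evaluates the hyperbola", {
  obs <- simulate_binding(kd = 250, f_max = 0.8, concentrations = 250,
                          noise_sd = 0)
  expect_equal(obs$fraction_bound, 0.4)
  expect_equal(simulate_binding(100, 0.9, concentrations = 1e-9,
                                noise_sd = 0)$fraction_bound, 0,
               tolerance = 1e-8)
  expect_equal(simulate_binding(250, 0.8, concentrations = 4000,
                                noise_sd = 0)$fraction_bound,
               0.8 * 4000 / 4250, tolerance = 1e-12)
  noisy <- simulate_binding(250, 0.8, noise_sd = 0.05, replicates = 3,
                            seed = 4)
  expect_true(all(noisy$fraction_bound >= 0 & noisy$fraction_bound <= 1))
  expect_equal(noisy$fraction_bound,
               fraction_bound(noisy$intensity_nitro, noisy$intensity_nylon))
})
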