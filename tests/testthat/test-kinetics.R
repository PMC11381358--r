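test_that("mutation calling applies quality, end-trim and SNP filters", {
  # 30-nt read, all M; reference = read except where stated
  seq <- "ACGTACGTACGTACGTACGTACGTACGTAC"   # T at 1-based 4,8,12,16,20,24,28
  qual <- strrep("K", 30)                   # Phred 42
  base <- list(read_id = "r", seq = seq, qual = qual, cigar = "30M",
               ref_start = 0L, reference_name = "chr1", md = "30",
               is_reverse = FALSE)
  # perfect match: T's at 5 < pos <= 25 are eligible -> 8,12,16,20,24
  out <- call_mutations(base)
  expect_equal(out$n_T, 5L)
  expect_equal(out$n_TC, 0L)

  # T->C at read position 8 (MD says ref T where read has C)
  mut <- base
  substr(mut$seq, 8, 8) <- "C"
  mut$md <- "7T22"
  out2 <- call_mutations(mut)
  expect_equal(out2$n_T, 5L)
  expect_equal(out2$n_TC, 1L)

  # same conversion at read position 4: inside the 5-nt end trim
  end <- base
  substr(end$seq, 4, 4) <- "C"
  end$md <- "3T26"
  out3 <- call_mutations(end)
  expect_equal(out3$n_TC, 0L)
  expect_equal(out3$n_T, 5L)   # the trimmed site does not count as a T site

  # base quality 39 vs 40 at the converted site
  q39 <- mut
  substr(q39$qual, 8, 8) <- "H"   # Phred 39
  expect_equal(call_mutations(q39, min_qual = 40)$n_TC, 0L)
  q40 <- mut
  substr(q40$qual, 8, 8) <- "I"   # Phred 40
  expect_equal(call_mutations(q40, min_qual = 40)$n_TC, 1L)

  # SNP mask removes the site entirely
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8, 8))
  masked <- call_mutations(mut, snp_mask = mask)
  expect_equal(masked$n_T, 4L)
  expect_equal(masked$n_TC, 0L)

  # minus-strand transcript: genomic A->G counts as T->C
  minus <- base
  substr(minus$seq, 9, 9) <- "G"  # ref A at pos 9
  minus$md <- "8A21"
  m_out <- call_mutations(minus, transcript_strand = "-")
  expect_equal(m_out$n_TC, 1L)
  expect_gt(m_out$n_T, 0L)

  noqual <- base
  noqual$qual <- "*"
  expect_error(call_mutations(noqual), "qualities")
  noref <- base
  noref$md <- NA_character_
  expect_error(call_mutations(noref), "reference")
})

test_that("MD-tag and reference-sequence routes agree with a re-alignment oracle", {
  set.seed(19)
  chrom <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                 collapse = "")
  reference <- Biostrings::DNAStringSet(stats::setNames(chrom, "chr1"))
  for (i in 1:25) {
    start <- sample(0:400, 1)
    len <- sample(40:120, 1)
    read_seq <- substring(chrom, start + 1, start + len)
    # sprinkle mismatches
    nmut <- sample(0:4, 1)
    pos <- sample(seq_len(len), nmut)
    for (p in pos) {
      substr(read_seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                               substr(read_seq, p, p)), 1)
    }
    qual <- paste(sample(strsplit("FGHIJK", "")[[1]], len, replace = TRUE),
                  collapse = "")
    rd <- list(read_id = "r", seq = read_seq, qual = qual,
               cigar = paste0(len, "M"), ref_start = start,
               reference_name = "chr1", md = NA_character_,
               is_reverse = FALSE)
    via_ref <- call_mutations(rd, reference = reference)
    oracle <- oracle_mutations(read_seq, qual, rd$cigar, start, chrom)
    expect_equal(via_ref$n_T, oracle$n_T)
    expect_equal(via_ref$n_TC, oracle$n_TC)
  }

  # soft clips and deletions: MD route vs reference route on a crafted record
  start <- 100L
  body <- substring(chrom, start + 1, start + 40)
  rd2 <- list(read_id = "r2", seq = paste0(body, strrep("A", 10)),
              qual = strrep("K", 50), cigar = "40M10S",
              ref_start = start, reference_name = "chr1",
              md = "40", is_reverse = FALSE)
  expect_equal(call_mutations(rd2, reference = reference),
               call_mutations(rd2))
})

test_that("mixture EM recovers parameters with monotone log-likelihood", {
  ref <- generate_reference(1, seed = 1)
  tr <- simulation_truth(ref, conditions = "A", theta_true = 0.3,
                         p_new = 0.05, p_old = 0.002,
                         reads_per_gene = 5000L, seed = 41)
  tl <- simulate_timelapse(tr, read_T_content = 40, seed = 42)
  fit <- fit_binomial_mixture(tl)
  expect_lt(abs(fit$theta - 0.3), 0.03)
  expect_true(all(diff(fit$ll_trace) >= -1e-8))
  expect_true(fit$p_old <= fit$p_new)
  expect_true(fit$theta >= 0 && fit$theta <= 1)
  expect_equal(length(fit$posterior_new), fit$n_reads)

  # theta = 1 boundary
  tr1 <- simulation_truth(ref, conditions = "A", theta_true = 1,
                          reads_per_gene = 2000L, seed = 43)
  tl1 <- simulate_timelapse(tr1, seed = 44)
  fit1 <- fit_binomial_mixture(tl1, fix_p_old = 0.002)
  expect_gte(fit1$theta, 0.97)

  # all reads mutation-free with the background fixed at zero
  clean <- data.frame(n_T = rep(30L, 100), n_TC = 0L)
  fit0 <- fit_binomial_mixture(clean, fix_p_old = 0)
  expect_lt(fit0$theta, 0.01)

  expect_error(fit_binomial_mixture(data.frame(n_T = rep(5L, 10), n_TC = 0L)),
               "insufficient")
})

test_that("rate-constant conversions follow the first-order model", {
  expect_equal(kdeg_from_theta(0), 0)
  expect_equal(kdeg_from_theta(0.5, 2), log(2) / 2)
  expect_equal(kdeg_from_theta(0.99, 2), -log(0.01) / 2)
  expect_message(k1 <- kdeg_from_theta(1, 2), "clamped")
  expect_true(is.finite(k1))
  th <- seq(0, 0.999, length.out = 50)
  expect_true(all(diff(kdeg_from_theta(th)) > 0))   # strictly increasing

  expect_equal(ksyn_from_kdeg(0, 100), 0)
  expect_equal(ksyn_from_kdeg(0.2, 100), 20)
  # bookkeeping identity on a known triple
  k_deg <- 0.35; level <- 42
  expect_equal(ksyn_from_kdeg(k_deg, level) / level, k_deg)
})

test_that("per-gene estimation and cross-condition comparison", {
  ref <- generate_reference(12, seed = 45)
  tr <- simulation_truth(ref, conditions = "A", theta_true = 0.4,
                         reads_per_gene = 400L, seed = 46)
  tl <- simulate_timelapse(tr, seed = 47)
  expr <- data.frame(gene_id = ref$genes$gene_id,
                     level = seq(10, 120, length.out = 12))
  kin <- estimate_kinetics(tl, t_label = 2, fix_p_old = 0.002,
                           expression = expr)
  expect_equal(nrow(kin), 12L)
  expect_true(all(abs(kin$theta - 0.4) < 0.12))
  expect_equal(kin$k_syn, kin$k_deg * kin$expression_level)

  # identical conditions: zero fold changes, undefined correlations
  same <- compare_kinetics(kin, kin)
  expect_true(all(same$fold_changes$lfc_kdeg == 0))
  expect_true(is.na(same$correlations$r[1]))

  # coupled synthesis/degradation changes give a strong positive r
  set.seed(48)
  n <- 300
  lk_a <- runif(n, 0.1, 0.6)
  ratio <- 2^rnorm(n, 0, 0.5)
  kin_a <- data.frame(gene_id = sprintf("g%03d", 1:n), k_deg = lk_a * ratio,
                      k_syn = lk_a * ratio * 2^rnorm(n, 0, 0.1) * 50)
  kin_b <- data.frame(gene_id = sprintf("g%03d", 1:n), k_deg = lk_a,
                      k_syn = lk_a * 50)
  cmp <- compare_kinetics(kin_a, kin_b)
  r <- cmp$correlations$r[cmp$correlations$comparison == "kdeg_vs_ksyn"]
  expect_gt(r, 0.9)

  # tail changes independent of degradation changes: near-zero r,
  # binned k_deg summaries cover the tail-length range
  tails <- data.frame(gene_id = sprintf("g%03d", 1:n),
                      median_a = sample(30:250, n, replace = TRUE),
                      median_b = sample(30:250, n, replace = TRUE))
  cmp2 <- compare_kinetics(kin_a, kin_b, tails = tails, bin_width = 50)
  r2 <- cmp2$correlations$r[cmp2$correlations$comparison == "tail_vs_kdeg"]
  expect_lt(abs(r2), 0.15)
  expect_true(all(cmp2$kdeg_by_bin$n_genes > 0))
  expect_true(all(is.finite(cmp2$kdeg_by_bin$median_kdeg)))
})
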