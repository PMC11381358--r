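#' Generate a synthetic reference genome and gene annotation
#'
#' Builds a single synthetic chromosome carrying `n_genes` non-overlapping,
#' single-exon genes of random sequence, alternating between the plus and
#' minus strands, separated by intergenic gaps. Coordinates are 0-based
#' half-open internally; use [write_reference()] to emit FASTA/BED12/GTF.
#'
#' @param n_genes Number of genes (>= 1).
#' @param gene_length_range Length-two integer vector, min/max gene length in
#'   nucleotides (min >= 200).
#' @param intergenic_gap Gap between consecutive genes, nucleotides.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param chrom Chromosome name.
#'
#' @return A list with elements `genome` (a [Biostrings::DNAStringSet] of one
#'   chromosome), `annotation` (a [GenomicRanges::GRanges] with a `gene_id`
#'   column), and `genes` (data.frame with `gene_id`, `chrom`, `start`, `end`
#'   in 0-based half-open coordinates, `strand`, `length`).
#' @export
generate_reference <- function(n_genes,
                               gene_length_range = c(800L, 2000L),
                               intergenic_gap = 500L,
                               seed,
                               chrom = "chrS") {
  stopifnot(n_genes >= 1L, intergenic_gap >= 0L)
  if (length(gene_length_range) != 2L || gene_length_range[1] > gene_length_range[2]) {
    stop("`gene_length_range` must be c(min, max) with min <= max", call. = FALSE)
  }
  if (gene_length_range[1] < 200L) {
    stop("gene lengths must be >= 200 nt", call. = FALSE)
  }
  with_seed(seed, {
    lens <- if (gene_length_range[1] == gene_length_range[2]) {
      rep(gene_length_range[1], n_genes)
    } else {
      sample(gene_length_range[1]:gene_length_range[2], n_genes, replace = TRUE)
    }
    starts <- integer(n_genes)
    pos <- intergenic_gap
    for (i in seq_len(n_genes)) {
      starts[i] <- pos
      pos <- pos + lens[i] + intergenic_gap
    }
    genome_len <- pos
    genome_seq <- paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
                        collapse = "")
    genes <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      chrom = chrom,
      start = starts,
      end = starts + lens,
      strand = rep_len(c("+", "-"), n_genes),
      length = lens,
      stringsAsFactors = FALSE
    )
    genome <- Biostrings::DNAStringSet(stats::setNames(genome_seq, chrom))
    anno <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
      strand = genes$strand,
      gene_id = genes$gene_id,
      seqlengths = stats::setNames(genome_len, chrom)
    )
    names(anno) <- genes$gene_id
    list(genome = genome, annotation = anno, genes = genes)
  })
}

#' Write a synthetic reference to FASTA, BED12 and GTF
#'
#' @param ref Output of [generate_reference()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, named paths of the files written.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  bed <- file.path(dir, "genes.bed")
  gtf <- file.path(dir, "genes.gtf")
  Biostrings::writeXStringSet(ref$genome, fasta)
  anno <- ref$annotation
  anno$name <- anno$gene_id
  anno$score <- 0L
  anno$thick <- IRanges::ranges(anno)
  anno$blocks <- IRanges::IRangesList(
    stats::setNames(
      lapply(GenomicRanges::width(anno),
             function(w) IRanges::IRanges(start = 1L, width = w)),
      anno$gene_id
    )
  )
  rtracklayer::export(anno, bed, format = "bed")
  gr <- ref$annotation
  gr$type <- "exon"
  gr$source <- "tailforge"
  rtracklayer::export(gr, gtf, format = "gtf")
  invisible(c(fasta = fasta, bed = bed, gtf = gtf))
}

#' Build a per-gene, per-condition simulation truth table
#'
#' Attaches tail-length, tail-composition and metabolic-labeling parameters
#' to every gene of a synthetic reference, for each condition. Defaults
#' emulate the measured regime: a baseline median tail of 90 nt with a 1.2x
#' (~20%) lengthening in the second condition for a subset of genes,
#' position-restricted non-A incorporation near tail 3' ends, and a
#' two-binomial T->C mutation structure for labeling.
#'
#' @param ref Output of [generate_reference()].
#' @param conditions Character vector of condition labels.
#' @param baseline_median Baseline median tail length, nt.
#' @param effect_size Multiplicative median-tail change applied to affected
#'   genes in every condition after the first (1.2 = 20% longer).
#' @param prop_affected Fraction of genes receiving the effect.
#' @param tail_dispersion Negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2).
#' @param nonA_rate_3prime Per-position substitution probability for non-A
#'   bases within the terminal `nonA_k` tail positions.
#' @param nonA_k Number of terminal tail positions subject to substitution.
#' @param theta_true Fraction-new per gene (labeling window).
#' @param p_new,p_old T->C conversion rate per T site in new / old reads.
#' @param reads_per_gene Reads simulated per gene per condition.
#' @param seed Integer seed (selects which genes are affected).
#'
#' @return data.frame with one row per gene x condition, carrying all
#'   simulation parameters plus `true_median_tail` and `affected`.
#' @export
simulation_truth <- function(ref,
                             conditions = c("A", "B"),
                             baseline_median = 90,
                             effect_size = 1.2,
                             prop_affected = 0.1,
                             tail_dispersion = 0.05,
                             nonA_rate_3prime = 0.1,
                             nonA_k = 10L,
                             theta_true = 0.3,
                             p_new = 0.05,
                             p_old = 0.002,
                             reads_per_gene = 200L,
                             seed) {
  stopifnot(theta_true >= 0, theta_true <= 1, p_old >= 0, p_old < p_new,
            p_new <= 1, baseline_median >= 0, reads_per_gene >= 0)
  genes <- ref$genes
  n <- nrow(genes)
  affected <- with_seed(seed, {
    idx <- sample(n, size = round(prop_affected * n))
    seq_len(n) %in% idx
  })
  out <- do.call(rbind, lapply(seq_along(conditions), function(ci) {
    cond <- conditions[ci]
    med <- ifelse(ci > 1L & affected,
                  round(baseline_median * effect_size), baseline_median)
    data.frame(
      gene_id = genes$gene_id,
      condition = cond,
      true_median_tail = med,
      tail_dispersion = tail_dispersion,
      nonA_rate_3prime = nonA_rate_3prime,
      nonA_k = as.integer(nonA_k),
      theta_true = theta_true,
      p_new = p_new,
      p_old = p_old,
      reads_per_gene = as.integer(reads_per_gene),
      affected = affected,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

# Solve for the negative-binomial mean giving a target median at fixed size.
# pnbinom(m, size, mu) is continuous and decreasing in mu; the root of
# P(X <= m) = 0.5 makes m the distribution's median.
nbinom_mu_for_median <- function(median_target, size) {
  if (median_target <= 0) return(1e-8)
  f <- function(mu) pnbinom(median_target, size = size, mu = mu) - 0.5
  hi <- max(10, 5 * median_target)
  while (f(hi) > 0) hi <- hi * 2
  uniroot(f, c(1e-8, hi), tol = 1e-10)$root
}

draw_tail_lengths <- function(n, median_target, dispersion, model = "nbinom") {
  if (n == 0L) return(integer(0))
  switch(model,
    nbinom = {
      size <- 1 / max(dispersion, 1e-8)
      mu <- nbinom_mu_for_median(median_target, size)
      rnbinom(n, size = size, mu = mu)
    },
    poisson = {
      lam <- if (median_target <= 0) 1e-8 else {
        f <- function(l) stats::ppois(median_target, l) - 0.5
        hi <- max(10, 5 * median_target)
        while (f(hi) > 0) hi <- hi * 2
        uniroot(f, c(1e-8, hi), tol = 1e-10)$root
      }
      rpois(n, lam)
    },
    stop("unknown tail length model: ", model, call. = FALSE)
  )
}

# Apply non-A substitutions to an all-A tail: each of the terminal k
# positions is replaced with C/G/T independently with probability `rate`.
substitute_tail <- function(len, rate, k) {
  if (len == 0L) return("")
  tail <- rep("A", len)
  if (rate > 0 && k > 0L) {
    zone <- max(1L, len - k + 1L):len
    hit <- runif(length(zone)) < rate
    if (any(hit)) {
      tail[zone[hit]] <- sample(c("C", "G", "T"), sum(hit), replace = TRUE)
    }
  }
  paste(tail, collapse = "")
}

#' Simulate long reads with known poly(A) tails
#'
#' Each read is the 3'-most portion of its gene body plus an appended tail
#' whose length is drawn from the configured distribution; non-A bases are
#' substituted into the terminal `nonA_k` tail positions at the per-gene
#' rate. The returned table is the per-read ground truth; pass it to
#' [write_alignments()] to obtain a SAM file.
#'
#' @param truth Truth table from [simulation_truth()].
#' @param ref Output of [generate_reference()] (provides sequences/strands).
#' @param tail_model Name of the tail-length distribution: `"nbinom"`
#'   (default, median/dispersion-parameterized) or `"poisson"`.
#' @param body_length_range Min/max gene-body nucleotides carried per read
#'   (capped at gene length).
#' @param seed Integer seed.
#'
#' @return data.frame, one row per read: `read_id`, `gene_id`, `sample`,
#'   `chrom`, `strand`, `body_start`/`body_end` (0-based half-open reference
#'   span), `body_seq` and `tail_seq` in transcript 5'->3' orientation, and
#'   `tail_length`.
#' @export
simulate_tailed_reads <- function(truth, ref,
                                  tail_model = "nbinom",
                                  body_length_range = c(150L, 600L),
                                  seed) {
  if (!tail_model %in% c("nbinom", "poisson")) {
    stop("unknown tail length model: ", tail_model, call. = FALSE)
  }
  genes <- ref$genes
  gmap <- match(truth$gene_id, genes$gene_id)
  if (anyNA(gmap)) stop("truth table names genes absent from the reference", call. = FALSE)
  chrom_seq <- as.character(ref$genome[[1]])
  with_seed(seed, {
    rows <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      g <- genes[gmap[i], ]
      n <- tr$reads_per_gene
      if (n == 0L) next
      lens <- draw_tail_lengths(n, tr$true_median_tail, tr$tail_dispersion, tail_model)
      body_len <- sample(seq(min(body_length_range[1], g$length),
                             min(body_length_range[2], g$length)),
                         n, replace = TRUE)
      if (g$strand == "+") {
        bstart <- g$end - body_len
        bend <- rep(g$end, n)
        body <- substring(chrom_seq, bstart + 1L, bend)
      } else {
        bstart <- rep(g$start, n)
        bend <- g$start + body_len
        body <- revcomp(substring(chrom_seq, bstart + 1L, bend))
      }
      tails <- vapply(lens, substitute_tail, character(1),
                      rate = tr$nonA_rate_3prime, k = tr$nonA_k)
      rows[[i]] <- data.frame(
        read_id = sprintf("%s_%s_r%05d", tr$gene_id, tr$condition, seq_len(n)),
        gene_id = tr$gene_id,
        sample = tr$condition,
        chrom = g$chrom,
        strand = g$strand,
        body_start = bstart,
        body_end = bend,
        body_seq = body,
        tail_seq = tails,
        tail_length = as.integer(lens),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(read_id = character(0), gene_id = character(0),
                        sample = character(0), chrom = character(0),
                        strand = character(0), body_start = integer(0),
                        body_end = integer(0), body_seq = character(0),
                        tail_seq = character(0), tail_length = integer(0),
                        stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    out
  })
}

#' Write simulated reads as a SAM file
#'
#' Gene-body bases are encoded as CIGAR `M`; the tail is carried entirely in
#' a terminal soft clip (`S`). Plus-strand reads store the transcript
#' sequence as-is with a trailing clip; minus-strand reads are stored
#' reverse-complemented with the reverse flag set, so the tail becomes a
#' leading soft clip of T's. The tail caller applied to this file recovers
#' every true tail length exactly whenever the clip passes the A-content
#' rule.
#'
#' @param reads Read table from [simulate_tailed_reads()] (or one crafted
#'   with the same columns).
#' @param ref Output of [generate_reference()] (supplies sequence lengths
#'   for the header).
#' @param path Output SAM path.
#' @param qual_char Single character used as the uniform per-base quality.
#' @return Invisibly, `path`.
#' @export
write_alignments <- function(reads, ref, path, qual_char = "K") {
  sq <- sprintf("@SQ\tSN:%s\tLN:%d", names(ref$genome),
                Biostrings::width(ref$genome))
  header <- c("@HD\tVN:1.6\tSO:unsorted", sq,
              "@PG\tID:tailforge\tPN:tailforge")
  if (nrow(reads) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  known <- reads$chrom %in% names(ref$genome)
  if (!all(known)) stop("reads reference sequences absent from the genome", call. = FALSE)
  body_len <- reads$body_end - reads$body_start
  tail_len <- nchar(reads$tail_seq)
  fwd <- reads$strand == "+"
  cigar <- ifelse(fwd,
                  paste0(body_len, "M", ifelse(tail_len > 0L, paste0(tail_len, "S"), "")),
                  paste0(ifelse(tail_len > 0L, paste0(tail_len, "S"), ""), body_len, "M"))
  tx_seq <- paste0(reads$body_seq, reads$tail_seq)
  seq_stored <- ifelse(fwd, tx_seq, revcomp(tx_seq))
  flag <- ifelse(fwd, 0L, 16L)
  qual <- vapply(nchar(seq_stored), function(n) strrep(qual_char, n), character(1))
  rec <- paste(reads$read_id, flag, reads$chrom, reads$body_start + 1L, 60L,
               cigar, "*", 0L, 0L, seq_stored, qual, sep = "\t")
  writeLines(c(header, rec), path)
  invisible(path)
}

#' Simulate nucleotide-recoding (T->C) mutation counts
#'
#' Per read: the number of reference-T sites is Poisson around
#' `read_T_content`; with probability `theta_true` the read is "new" and its
#' T->C count is Binomial(n_T, p_new), otherwise Binomial(n_T, p_old). The
#' hidden new/old label is retained as ground truth.
#'
#' @param truth Truth table from [simulation_truth()] (uses `theta_true`,
#'   `p_new`, `p_old`, and `reads_per_gene` unless overridden).
#' @param reads_per_gene Optional count overriding the truth table.
#' @param read_T_content Mean number of T sites per read.
#' @param seed Integer seed.
#'
#' @return data.frame: `read_id`, `gene_id`, `sample`, `n_T`, `n_TC`,
#'   `is_new`.
#' @export
simulate_timelapse <- function(truth, reads_per_gene = NULL,
                               read_T_content = 40, seed) {
  stopifnot(all(truth$p_old < truth$p_new))
  with_seed(seed, {
    rows <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      n <- reads_per_gene %||% tr$reads_per_gene
      if (n == 0L) next
      n_T <- rpois(n, read_T_content)
      is_new <- runif(n) < tr$theta_true
      n_TC <- rbinom(n, n_T, ifelse(is_new, tr$p_new, tr$p_old))
      rows[[i]] <- data.frame(
        read_id = sprintf("%s_%s_t%05d", tr$gene_id, tr$condition, seq_len(n)),
        gene_id = tr$gene_id,
        sample = tr$condition,
        n_T = n_T,
        n_TC = n_TC,
        is_new = is_new,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(read_id = character(0), gene_id = character(0),
                        sample = character(0), n_T = integer(0),
                        n_TC = integer(0), is_new = logical(0))
    }
    rownames(out) <- NULL
    out
  })
}

#' Simulate an equilibrium filter-binding concentration series
#'
#' Fraction bound follows the single-site hyperbola
#' f(c) = f_max * c / (c + kd), plus optional Gaussian noise, clipped to
#' `[0, 1]`. Membrane intensities consistent with each fraction are also
#' emitted. The default series is a two-fold dilution from 4000 nM down to
#' 62.5 nM.
#'
#' @param kd Dissociation constant, nM (> 0).
#' @param f_max Maximal fraction bound, in (0, 1].
#' @param concentrations Protein concentrations, nM.
#' @param noise_sd Gaussian noise SD on the fraction scale.
#' @param replicates Number of replicate series.
#' @param total_intensity Summed membrane intensity per reaction.
#' @param seed Integer seed (required when `noise_sd > 0`).
#'
#' @return data.frame: `replicate`, `protein_conc_nM`, `intensity_nitro`,
#'   `intensity_nylon`, `fraction_bound`.
#' @export
simulate_binding <- function(kd, f_max,
                             concentrations = 4000 / 2^(0:6),
                             noise_sd = 0, replicates = 1L,
                             total_intensity = 10000, seed = 1L) {
  stopifnot(kd > 0, f_max > 0, f_max <= 1, noise_sd >= 0)
  with_seed(seed, {
    conc <- rep(concentrations, times = replicates)
    repl <- rep(seq_len(replicates), each = length(concentrations))
    f <- f_max * conc / (conc + kd)
    if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
    f <- pmin(pmax(f, 0), 1)
    data.frame(
      replicate = repl,
      protein_conc_nM = conc,
      intensity_nitro = f * total_intensity,
      intensity_nylon = (1 - f) * total_intensity,
      fraction_bound = f
    )
  })
}
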