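# Aligned (query, reference) base pairs for one record. Returns a
# data.frame with qpos/rpos (1-based), read_base, and ref_base resolved
# from either the reference sequence or the MD tag.
aligned_pairs <- function(cigar, seq, ref_start, md = NA_character_,
                          reference = NULL, reference_name = NULL) {
  ops <- parse_cigar(cigar)
  qpos <- integer(0)
  rpos <- integer(0)
  q <- 1L
  r <- ref_start + 1L   # 1-based genomic
  for (i in seq_len(nrow(ops))) {
    len <- ops$length[i]
    op <- ops$op[i]
    if (op %in% c("M", "=", "X")) {
      qpos <- c(qpos, q:(q + len - 1L))
      rpos <- c(rpos, r:(r + len - 1L))
      q <- q + len
      r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      r <- r + len
    }
  }
  read_base <- substring(seq, qpos, qpos)
  if (!is.null(reference)) {
    chrom <- as.character(reference[[reference_name]])
    ref_base <- substring(chrom, rpos, rpos)
  } else if (!is.na(md)) {
    ref_base <- md_reference_bases(md, read_base)
  } else {
    stop("per-base reference needs either a reference sequence or an MD tag",
         call. = FALSE)
  }
  data.frame(qpos = qpos, rpos = rpos, read_base = read_base,
             ref_base = ref_base, stringsAsFactors = FALSE)
}

# Reconstruct reference bases over aligned (M/=/X) positions from an MD
# tag. Deletion runs (^...) consume reference but no aligned position.
md_reference_bases <- function(md, read_base) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  out <- character(length(read_base))
  i <- 1L
  for (tk in toks) {
    if (grepl("^[0-9]+$", tk)) {
      n <- as.integer(tk)
      if (n > 0L) {
        out[i:(i + n - 1L)] <- read_base[i:(i + n - 1L)]
        i <- i + n
      }
    } else if (startsWith(tk, "^")) {
      # deleted reference bases: not aligned to the query, skip
    } else {
      out[i] <- toupper(tk)
      i <- i + 1L
    }
  }
  if (i != length(read_base) + 1L) {
    stop("MD tag inconsistent with CIGAR-aligned length", call. = FALSE)
  }
  out
}

#' Count filtered T->C mutations in one alignment
#'
#' Counts transcript-strand T sites and T->C conversions, applying the
#' standard nucleotide-recoding filters: a site contributes only when its
#' base quality is at least `min_qual`, it lies more than `end_trim`
#' nucleotides from both read ends, and it is not inside the SNP mask.
#' For minus-strand transcripts, genomic A->G substitutions are counted as
#' T->C in transcript space.
#'
#' @param read One-row data.frame (or list) with `seq`, `qual`, `cigar`,
#'   `ref_start`, `reference_name` and optionally `md`, as produced by
#'   [read_alignments()].
#' @param reference Optional [Biostrings::DNAStringSet] (used when no MD
#'   tag is available; one of the two must be present).
#' @param snp_mask Optional [GenomicRanges::GRanges] of positions to
#'   exclude.
#' @param min_qual Minimum Phred base quality (default 40; sites below are
#'   not considered).
#' @param end_trim Exclusion zone at both read ends, nt (default 5).
#' @param transcript_strand `"+"` or `"-"`; the annotated strand of the
#'   transcript the read derives from.
#'
#' @return List with `n_T` (filtered T sites) and `n_TC` (filtered T->C
#'   conversions), `n_TC <= n_T`.
#' @export
call_mutations <- function(read, reference = NULL, snp_mask = NULL,
                           min_qual = 40L, end_trim = 5L,
                           transcript_strand = "+") {
  if (is.data.frame(read)) read <- as.list(read[1, ])
  if (is.null(read$qual) || is.na(read$qual) || read$qual == "*") {
    stop("read has no base qualities", call. = FALSE)
  }
  md <- read$md %||% NA_character_
  if (is.null(reference) && is.na(md)) {
    stop("per-base reference needs either a reference sequence or an MD tag",
         call. = FALSE)
  }
  ap <- aligned_pairs(read$cigar, read$seq, read$ref_start, md = md,
                      reference = reference,
                      reference_name = read$reference_name)
  qlen <- nchar(read$seq)
  quals <- utf8ToInt(read$qual) - 33L
  ok <- quals[ap$qpos] >= min_qual &
    ap$qpos > end_trim & ap$qpos <= qlen - end_trim
  if (!is.null(snp_mask)) {
    mask <- snp_mask[GenomeInfoDb::seqnames(snp_mask) == read$reference_name]
    if (length(mask) > 0L) {
      masked <- IRanges::overlapsAny(
        IRanges::IRanges(start = ap$rpos, width = 1L),
        IRanges::ranges(mask))
      ok <- ok & !masked
    }
  }
  ref_t <- if (transcript_strand == "+") "T" else "A"
  mut_to <- if (transcript_strand == "+") "C" else "G"
  t_site <- ok & ap$ref_base == ref_t
  list(n_T = sum(t_site),
       n_TC = sum(t_site & ap$read_base == mut_to))
}

#' Tabulate filtered mutation counts for a set of alignments
#'
#' Applies [call_mutations()] to every record, taking the transcript strand
#' from the alignment orientation (sense-stranded long reads map to the
#' gene strand).
#'
#' @inheritParams call_mutations
#' @param alignments data.frame from [read_alignments()].
#' @param gene_ids Optional per-read gene assignment vector.
#' @return data.frame: `read_id`, `gene_id`, `sample`, `n_T`, `n_TC`.
#' @export
mutation_table <- function(alignments, reference = NULL, snp_mask = NULL,
                           min_qual = 40L, end_trim = 5L, gene_ids = NULL) {
  counts <- lapply(seq_len(nrow(alignments)), function(i) {
    call_mutations(as.list(alignments[i, ]), reference = reference,
                   snp_mask = snp_mask, min_qual = min_qual,
                   end_trim = end_trim,
                   transcript_strand = if (alignments$is_reverse[i]) "-" else "+")
  })
  data.frame(
    read_id = alignments$read_id,
    gene_id = gene_ids %||% rep(NA_character_, nrow(alignments)),
    sample = alignments$sample,
    n_T = vapply(counts, `[[`, integer(1), "n_T"),
    n_TC = vapply(counts, `[[`, integer(1), "n_TC"),
    stringsAsFactors = FALSE
  )
}

#' Pooled background conversion rate
#'
#' Overall T->C rate of an unlabeled control sample, used to fix the
#' old-read mutation rate of the mixture model.
#'
#' @param counts data.frame with `n_T`, `n_TC` columns.
#' @return Scalar rate in `[0, 1]`.
#' @export
background_rate <- function(counts) {
  if (sum(counts$n_T) == 0) stop("no T sites in control counts", call. = FALSE)
  sum(counts$n_TC) / sum(counts$n_T)
}

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m[m == -Inf] <- 0
  m + log(exp(a - m) + exp(b - m))
}

#' Fit a two-component binomial mixture of conversion counts
#'
#' Maximizes the mixture likelihood
#' \deqn{\sum_i \log[\theta \mathrm{Bin}(k_i \mid n_i, p_{new}) +
#'   (1-\theta) \mathrm{Bin}(k_i \mid n_i, p_{old})]}
#' by EM, estimating the fraction of newly synthesized reads
#' \eqn{\theta} and the per-T conversion rates of new and old reads. The
#' log-likelihood is non-decreasing across iterations; convergence when the
#' improvement falls below `tol` or after `max_iter` iterations.
#'
#' @param counts data.frame with `n_T` and `n_TC` columns (per read), or a
#'   numeric vector of `n_T` with `n_TC` supplied separately.
#' @param n_TC Conversion counts when `counts` is a vector.
#' @param fix_p_old Optional fixed background rate (e.g. from
#'   [background_rate()] of an unlabeled control).
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param max_iter Maximum EM iterations.
#' @param min_reads Minimum number of reads with `n_T >= 1`.
#'
#' @return An object of class `"binom_mixture"`: components `theta`,
#'   `p_new`, `p_old`, `logLik`, `ll_trace`, `n_reads`, `iterations`,
#'   `converged`, `posterior_new` (per-read probability of being new).
#' @export
fit_binomial_mixture <- function(counts, n_TC = NULL, fix_p_old = NULL,
                                 tol = 1e-8, max_iter = 500L,
                                 min_reads = 20L) {
  if (is.data.frame(counts)) {
    n <- counts$n_T
    k <- counts$n_TC
  } else {
    n <- counts
    k <- n_TC
  }
  keep <- n >= 1L
  n <- as.numeric(n[keep])
  k <- as.numeric(k[keep])
  if (length(n) < min_reads) {
    stop("insufficient data: need >= ", min_reads, " reads with n_T >= 1, got ",
         length(n), call. = FALSE)
  }
  if (any(k > n)) stop("n_TC exceeds n_T", call. = FALSE)

  if (sum(k) == 0) {
    # no conversions anywhere: the likelihood ridge is resolved to the
    # boundary theta = 0 (nothing labeled)
    p_old <- fix_p_old %||% 0
    ll <- sum(stats::dbinom(k, n, p_old, log = TRUE))
    return(structure(
      list(theta = 0, p_new = p_old, p_old = p_old, logLik = ll,
           ll_trace = ll, n_reads = length(n), iterations = 0L,
           converged = TRUE, posterior_new = rep(0, length(n)),
           p_old_fixed = !is.null(fix_p_old)),
      class = "binom_mixture"))
  }

  r <- k / n
  p_old <- if (!is.null(fix_p_old)) fix_p_old else
    min(max(unname(stats::quantile(r, 0.1)), 1e-5), 0.5)
  p_new <- max(unname(stats::quantile(r, 0.9)), p_old * 5 + 1e-3)
  p_new <- min(p_new, 1 - 1e-9)
  theta <- 0.5
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    l1 <- stats::dbinom(k, n, p_new, log = TRUE)
    l0 <- stats::dbinom(k, n, p_old, log = TRUE)
    la <- log(theta) + l1
    lb <- log(1 - theta) + l0
    lse <- logsumexp2(la, lb)
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    w <- exp(la - lse)
    w[is.nan(w)] <- 0
    if (is.finite(ll) && ll - ll_old < tol && iter > 1L) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    theta <- mean(w)
    sw <- sum(w * n)
    p_new <- if (sw > 0) sum(w * k) / sw else p_new
    if (is.null(fix_p_old)) {
      s0 <- sum((1 - w) * n)
      p_old <- if (s0 > 0) sum((1 - w) * k) / s0 else p_old
    }
    p_old <- min(max(p_old, 0), 1 - 1e-12)
    # identifiability floor: keep the labeled component's rate strictly
    # above background so the mixture cannot collapse onto one component
    p_new <- min(max(p_new, p_old + 1e-4), 1 - 1e-12)
  }
  if (p_old > p_new) {   # relabel so "new" is the high-rate component
    tmp <- p_old; p_old <- p_new; p_new <- tmp
    theta <- 1 - theta
    w <- 1 - w
  }
  structure(
    list(theta = theta, p_new = p_new, p_old = p_old,
         logLik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
         n_reads = length(n), iterations = iter, converged = converged,
         posterior_new = w, p_old_fixed = !is.null(fix_p_old)),
    class = "binom_mixture"
  )
}

#' @export
print.binom_mixture <- function(x, ...) {
  cat("Two-component binomial mixture (EM)\n")
  cat(sprintf("  reads: %d   iterations: %d   converged: %s\n",
              x$n_reads, x$iterations, x$converged))
  cat(sprintf("  theta (fraction new): %.4f\n", x$theta))
  cat(sprintf("  p_new: %.5f   p_old: %.5f%s\n", x$p_new, x$p_old,
              if (x$p_old_fixed) " (fixed)" else ""))
  cat(sprintf("  log-likelihood: %.3f\n", x$logLik))
  invisible(x)
}

#' @export
coef.binom_mixture <- function(object, ...) {
  c(theta = object$theta, p_new = object$p_new, p_old = object$p_old)
}

#' @export
logLik.binom_mixture <- function(object, ...) {
  structure(object$logLik, df = if (object$p_old_fixed) 2 else 3,
            nobs = object$n_reads, class = "logLik")
}

#' @export
summary.binom_mixture <- function(object, ...) {
  out <- c(coef(object),
           k_deg_2h = kdeg_from_theta(object$theta, 2),
           logLik = object$logLik, n_reads = object$n_reads)
  class(out) <- "summary.binom_mixture"
  out
}

#' @export
print.summary.binom_mixture <- function(x, ...) {
  print(unclass(x)); invisible(x)
}

#' Degradation rate constant from fraction-new
#'
#' Under first-order decay over a labeling window of `t_label` hours,
#' `k_deg = -log(1 - theta) / t_label`. Theta is clamped to
#' `1 - 1e-6` before the logarithm so the rate stays finite; clamping is
#' reported with a message.
#'
#' @param theta Fraction-new, in `[0, 1]` (vectorized).
#' @param t_label Labeling time in hours (default 2).
#' @return Degradation rate constant(s), 1/h.
#' @export
kdeg_from_theta <- function(theta, t_label = 2) {
  stopifnot(t_label > 0, all(theta >= 0 & theta <= 1))
  clamped <- theta > 1 - 1e-6
  if (any(clamped)) {
    message(sum(clamped), " theta value(s) clamped to 1 - 1e-6")
    theta <- pmin(theta, 1 - 1e-6)
  }
  -log(1 - theta) / t_label
}

#' Synthesis rate constant from degradation rate and abundance
#'
#' At steady state, `k_syn = k_deg * expression_level`.
#'
#' @param k_deg Degradation rate constant, 1/h (>= 0).
#' @param expression_level Relative steady-state abundance (>= 0), e.g. TPM.
#' @return Synthesis rate constant(s), abundance units per hour.
#' @export
ksyn_from_kdeg <- function(k_deg, expression_level) {
  stopifnot(all(k_deg >= 0), all(expression_level >= 0))
  k_deg * expression_level
}

#' Per-gene turnover kinetics from mutation counts
#'
#' Fits the two-binomial mixture per gene and converts fraction-new to
#' degradation (and, when abundances are given, synthesis) rate constants.
#'
#' @param counts data.frame with `gene_id`, `n_T`, `n_TC` (per read).
#' @param t_label Labeling time, hours.
#' @param fix_p_old Optional fixed background conversion rate.
#' @param expression Optional data.frame `gene_id`, `level` for `k_syn`.
#' @param min_reads Minimum informative reads per gene; genes below are
#'   skipped (count reported via message).
#'
#' @return data.frame: `gene_id`, `n_reads`, `theta`, `p_new`, `p_old`,
#'   `k_deg`, `expression_level`, `k_syn`, `converged`.
#' @export
estimate_kinetics <- function(counts, t_label = 2, fix_p_old = NULL,
                              expression = NULL, min_reads = 20L) {
  by_gene <- split(counts, counts$gene_id)
  usable <- vapply(by_gene, function(d) sum(d$n_T >= 1L) >= min_reads, logical(1))
  if (any(!usable)) {
    message(sum(!usable), " gene(s) skipped: fewer than ", min_reads,
            " informative reads")
  }
  by_gene <- by_gene[usable]
  rows <- lapply(names(by_gene), function(g) {
    fit <- fit_binomial_mixture(by_gene[[g]], fix_p_old = fix_p_old,
                                min_reads = min_reads)
    data.frame(gene_id = g, n_reads = fit$n_reads, theta = fit$theta,
               p_new = fit$p_new, p_old = fit$p_old,
               k_deg = suppressMessages(kdeg_from_theta(fit$theta, t_label)),
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene_id = character(0), n_reads = integer(0),
                      theta = numeric(0), p_new = numeric(0),
                      p_old = numeric(0), k_deg = numeric(0),
                      expression_level = numeric(0), k_syn = numeric(0),
                      converged = logical(0)))
  }
  if (!is.null(expression)) {
    m <- match(out$gene_id, expression$gene_id)
    out$expression_level <- expression$level[m]
    out$k_syn <- ifelse(is.na(out$expression_level), NA_real_,
                        ksyn_from_kdeg(out$k_deg, out$expression_level))
  } else {
    out$expression_level <- NA_real_
    out$k_syn <- NA_real_
  }
  rownames(out) <- NULL
  out
}

safe_pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  c(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cross-condition comparison of turnover kinetics
#'
#' Computes per-gene log2 fold changes of `k_deg` (and `k_syn`, and median
#' tail length when supplied) between two conditions, Pearson correlations
#' among them, and `k_deg` summaries per median-tail-length bin. Genes with
#' zero or undefined rates are excluded (count reported via message).
#'
#' @param kin_a,kin_b Per-gene kinetics tables from [estimate_kinetics()].
#' @param tails Optional data.frame `gene_id`, `median_a`, `median_b` of
#'   per-gene median tail lengths in the two conditions.
#' @param bin_width Median-tail bin width in nt for the binned `k_deg`
#'   summary (default 50).
#'
#' @return List: `fold_changes` (per gene: `lfc_kdeg`, `lfc_ksyn`,
#'   `lfc_tail`), `correlations` (rows `kdeg_vs_ksyn`, `tail_vs_kdeg`:
#'   Pearson `r`, `p`, `n`), `kdeg_by_bin` (condition, tail bin,
#'   `n_genes`, `median_kdeg`).
#' @export
compare_kinetics <- function(kin_a, kin_b, tails = NULL, bin_width = 50) {
  shared <- intersect(kin_a$gene_id, kin_b$gene_id)
  a <- kin_a[match(shared, kin_a$gene_id), ]
  b <- kin_b[match(shared, kin_b$gene_id), ]
  ok <- is.finite(a$k_deg) & is.finite(b$k_deg) & a$k_deg > 0 & b$k_deg > 0
  if (any(!ok)) message(sum(!ok), " gene(s) excluded: zero or undefined k_deg")
  a <- a[ok, ]; b <- b[ok, ]
  fc <- data.frame(
    gene_id = a$gene_id,
    lfc_kdeg = log2(a$k_deg / b$k_deg),
    lfc_ksyn = ifelse(is.finite(a$k_syn) & is.finite(b$k_syn) &
                        a$k_syn > 0 & b$k_syn > 0,
                      log2(a$k_syn / b$k_syn), NA_real_),
    stringsAsFactors = FALSE
  )
  if (!is.null(tails)) {
    m <- match(fc$gene_id, tails$gene_id)
    fc$lfc_tail <- ifelse(!is.na(m) & tails$median_a[m] > 0 & tails$median_b[m] > 0,
                          log2(tails$median_a[m] / tails$median_b[m]), NA_real_)
  } else {
    fc$lfc_tail <- NA_real_
  }
  cors <- rbind(
    kdeg_vs_ksyn = safe_pearson(fc$lfc_kdeg, fc$lfc_ksyn),
    tail_vs_kdeg = safe_pearson(fc$lfc_tail, fc$lfc_kdeg)
  )
  cors <- data.frame(comparison = rownames(cors), cors, row.names = NULL)
  kdeg_by_bin <- NULL
  if (!is.null(tails)) {
    bin_one <- function(kin, med, cond) {
      m <- match(kin$gene_id, tails$gene_id)
      med_v <- med[m]
      keep <- !is.na(med_v) & is.finite(kin$k_deg)
      if (!any(keep)) return(NULL)
      brk <- seq(0, max(med_v[keep]) + bin_width, by = bin_width)
      bin <- cut(med_v[keep], breaks = brk, right = FALSE)
      agg <- tapply(kin$k_deg[keep], bin, stats::median)
      cnt <- tapply(kin$k_deg[keep], bin, length)
      data.frame(condition = cond, bin = names(agg),
                 n_genes = as.integer(ifelse(is.na(cnt), 0L, cnt)),
                 median_kdeg = as.numeric(agg), stringsAsFactors = FALSE)
    }
    kdeg_by_bin <- rbind(bin_one(a, tails$median_a, "A"),
                         bin_one(b, tails$median_b, "B"))
    kdeg_by_bin <- kdeg_by_bin[!is.na(kdeg_by_bin$median_kdeg), ]
  }
  list(fold_changes = fc, correlations = cors, kdeg_by_bin = kdeg_by_bin)
}
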