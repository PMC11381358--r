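# Independent oracles used to cross-check package implementations. These
# deliberately avoid the code paths they verify.

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_exact_mw <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(na))
  us <- apply(utils::combn(length(pooled), na), 2, u_of)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# Literal Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Brute-force summary statistics (type-7 quantiles written out by hand).
oracle_summary <- function(x) {
  n <- length(x)
  s <- sort(x)
  q7 <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    s[lo + 1] + (h - lo) * (s[pmin(lo + 2, n)] - s[lo + 1])
  }
  med <- q7(0.5)
  sdv <- sqrt(sum((x - mean(x))^2) / (n - 1))
  list(n = n, mean = sum(x) / n, median = med, q25 = q7(0.25),
       q75 = q7(0.75),
       skew = if (n < 2 || sdv == 0) NA_real_ else 3 * (sum(x) / n - med) / sdv)
}

# O(reads x genes) maximal-overlap assignment with strand matching;
# ties and non-overlaps give NA.
oracle_assign <- function(reads, genes) {
  vapply(seq_len(nrow(reads)), function(i) {
    ov <- pmax(0, pmin(reads$ref_end[i], genes$end) -
                  pmax(reads$ref_start[i], genes$start))
    ov[genes$strand != reads$strand[i] | genes$chrom != reads$reference_name[i]] <- 0
    if (max(ov) == 0) return(NA_character_)
    best <- which(ov == max(ov))
    if (length(best) > 1L) NA_character_ else genes$gene_id[best]
  }, character(1))
}

# Independent re-scan of a SAM text file: count records whose transcript-3'
# soft clip passes the A-content rule. Parses the raw text, not via the
# package reader.
oracle_sam_tail_count <- function(path, min_frac = 0.85, min_len = 5) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  n_pass <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    cigar <- f[6]
    seq <- f[10]
    rev <- bitwAnd(flag, 16L) > 0L
    clip <- if (!rev) {
      m <- regmatches(cigar, regexec("([0-9]+)S$", cigar))[[1]]
      if (length(m) == 0) "" else substr(seq, nchar(seq) - as.integer(m[2]) + 1,
                                         nchar(seq))
    } else {
      m <- regmatches(cigar, regexec("^([0-9]+)S", cigar))[[1]]
      if (length(m) == 0) "" else {
        s <- substr(seq, 1, as.integer(m[2]))
        # reverse complement by lookup
        paste(rev(chartr("ACGTN", "TGCAN",
                         strsplit(s, "")[[1]])), collapse = "")
      }
    }
    len <- nchar(clip)
    if (len >= min_len &&
        lengths(regmatches(clip, gregexpr("A", clip))) / len >= min_frac) {
      n_pass <- n_pass + 1L
    }
  }
  n_pass
}

# Per-base re-alignment oracle for mutation counting: walks the CIGAR
# against an explicit reference chromosome string and applies the filters
# literally.
oracle_mutations <- function(seq, qual, cigar, ref_start, chrom_seq,
                             mask_pos = integer(0), min_qual = 40,
                             end_trim = 5, strand = "+") {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  q <- 1L; r <- ref_start + 1L
  n_T <- 0L; n_TC <- 0L
  qlen <- nchar(seq)
  for (tk in toks) {
    len <- as.integer(sub(".$", "", tk))
    op <- substr(tk, nchar(tk), nchar(tk))
    if (op %in% c("M", "=", "X")) {
      for (j in 0:(len - 1L)) {
        qp <- q + j; rp <- r + j
        rb <- substr(chrom_seq, rp, rp)
        bq <- utf8ToInt(substr(qual, qp, qp)) - 33L
        eligible <- bq >= min_qual && qp > end_trim && qp <= qlen - end_trim &&
          !(rp %in% mask_pos)
        tbase <- if (strand == "+") "T" else "A"
        mbase <- if (strand == "+") "C" else "G"
        if (eligible && rb == tbase) {
          n_T <- n_T + 1L
          if (substr(seq, qp, qp) == mbase) n_TC <- n_TC + 1L
        }
      }
      q <- q + len; r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      r <- r + len
    }
  }
  list(n_T = n_T, n_TC = n_TC)
}

# Small shared fixture: reference + truth used by several test files.
make_tiny_ref <- function(n_genes = 6, seed = 11) {
  generate_reference(n_genes, gene_length_range = c(800L, 1200L), seed = seed)
}
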