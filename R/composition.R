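#' Positional nucleotide composition of called tails
#'
#' Aligns tails at either the cleavage site (position 0 = first tail base
#' after the cleavage site, counting toward 3') or at the tail 3' end
#' (position 0 = terminal base, counting toward 5') and counts each
#' nucleotide at every position. T in the input is reported as U. Bases
#' outside A/C/G/T (e.g. N) are excluded from both counts and coverage.
#'
#' @param tails data.frame from [tail_table()] (only `is_tail = TRUE` rows
#'   are used) or a character vector of tail sequences.
#' @param anchor `"cleavage_site"` or `"three_prime_end"`.
#' @param max_pos Number of positions to profile. Defaults to 400 for the
#'   cleavage-site anchor and 50 for the 3'-end anchor.
#' @param condition Optional condition label stored in the output.
#'
#' @return Long-format data.frame: `condition`, `anchor`, `position`
#'   (0-based), `base` (A/C/G/U), `count`, `coverage`, `fraction`.
#' @export
build_profile <- function(tails,
                          anchor = c("cleavage_site", "three_prime_end"),
                          max_pos = NULL, condition = NA_character_) {
  anchor <- match.arg(anchor)
  if (is.null(max_pos)) max_pos <- if (anchor == "cleavage_site") 400L else 50L
  seqs <- if (is.data.frame(tails)) tails$tail_seq[tails$is_tail] else tails
  len <- nchar(seqs)
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", max_pos)
  for (p in seq_len(max_pos)) {           # p is 1-based; position = p - 1
    covered <- len >= p
    if (!any(covered)) {
      counts <- stats::setNames(rep(0L, 4L), bases)
    } else {
      ch <- if (anchor == "cleavage_site") {
        substring(seqs[covered], p, p)
      } else {
        substring(seqs[covered], len[covered] - p + 1L, len[covered] - p + 1L)
      }
      counts <- table(factor(ch, levels = bases))
    }
    cov <- sum(counts)
    rows[[p]] <- data.frame(
      condition = condition,
      anchor = anchor,
      position = p - 1L,
      base = c("A", "C", "G", "U"),
      count = as.integer(counts),
      coverage = as.integer(cov),
      fraction = if (cov > 0) as.numeric(counts) / cov else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Welch two-sample t-test on per-read binary indicators, from counts.
# Returns c(stat, df, p); NA p when either group has < 2 covered reads or
# both groups are constant but unequal (no finite statistic exists).
welch_binary_t <- function(k1, n1, k2, n2) {
  if (n1 < 2L || n2 < 2L) return(c(NA_real_, NA_real_, NA_real_))
  p1 <- k1 / n1
  p2 <- k2 / n2
  v1 <- p1 * (1 - p1) * n1 / (n1 - 1)
  v2 <- p2 * (1 - p2) * n2 / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (p1 == p2) return(c(0, n1 + n2 - 2, 1))
    return(c(NA_real_, NA_real_, NA_real_))
  }
  stat <- (p1 - p2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  c(stat, df, 2 * stats::pt(-abs(stat), df))
}

#' Position-wise comparison of non-A usage between two conditions
#'
#' At each tail position (under the chosen anchor) compares the per-read
#' binary non-A indicator between conditions with a Welch (unequal
#' variance) two-sample t-test. Positions covered by fewer than two reads
#' in either condition get an undefined p-value. No correction is applied
#' across positions.
#'
#' @param tails_a,tails_b Tail tables or sequence vectors, as in
#'   [build_profile()].
#' @param anchor,max_pos See [build_profile()].
#'
#' @return data.frame: `anchor`, `position`, `nonA_frac_a`, `nonA_frac_b`,
#'   `coverage_a`, `coverage_b`, `t_stat`, `df`, `p_value`.
#' @export
positionwise_test <- function(tails_a, tails_b,
                              anchor = c("cleavage_site", "three_prime_end"),
                              max_pos = NULL) {
  anchor <- match.arg(anchor)
  if (is.null(max_pos)) max_pos <- if (anchor == "cleavage_site") 400L else 50L
  pa <- build_profile(tails_a, anchor, max_pos)
  pb <- build_profile(tails_b, anchor, max_pos)
  nonA <- function(prof) {
    byp <- split(prof, prof$position)
    do.call(rbind, lapply(byp, function(d) {
      data.frame(position = d$position[1],
                 coverage = d$coverage[1],
                 k_nonA = sum(d$count[d$base != "A"]))
    }))
  }
  a <- nonA(pa)
  b <- nonA(pb)
  stats_m <- t(vapply(seq_len(nrow(a)), function(i) {
    welch_binary_t(a$k_nonA[i], a$coverage[i], b$k_nonA[i], b$coverage[i])
  }, numeric(3)))
  out <- data.frame(
    anchor = anchor,
    position = a$position,
    nonA_frac_a = ifelse(a$coverage > 0, a$k_nonA / a$coverage, NA_real_),
    nonA_frac_b = ifelse(b$coverage > 0, b$k_nonA / b$coverage, NA_real_),
    coverage_a = a$coverage,
    coverage_b = b$coverage,
    t_stat = stats_m[, 1],
    df = stats_m[, 2],
    p_value = stats_m[, 3],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$position), ]
}
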