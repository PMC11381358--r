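#' Mann-Whitney U test for two tail-length samples
#'
#' Reports the U statistic for sample `a` (computed from the rank sum) and
#' a two-sided p-value from the tie-corrected normal approximation with
#' continuity correction, as in [stats::wilcox.test()]. When every value in
#' both samples is identical the test is degenerate and `U = n_a * n_b / 2`,
#' `p = 1` is returned.
#'
#' @param a,b Numeric vectors, each nonempty.
#' @return List with `u_stat` and `p_value`. `U_a + U_b = n_a * n_b` always
#'   holds.
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  na <- length(a)
  nb <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (length(unique(c(a, b))) == 1L) {
    return(list(u_stat = na * nb / 2, p_value = 1))
  }
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  )
  if (is.na(p)) p <- 1
  list(u_stat = u_a, p_value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted values with enforced monotonicity, capped at 1, in the
#' input order (delegates to [stats::p.adjust()] after validating the
#' input).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length/order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differential tail length between two conditions
#'
#' Tests each group (gene or isoform) represented by at least `min_reads`
#' called tails in both conditions with the Mann-Whitney U test, adjusts
#' with Benjamini-Hochberg, and labels significant groups (`q < fdr`) with
#' the direction of the median difference.
#'
#' @param tails_a,tails_b Assigned tail tables ([assign_to_genes()]) for the
#'   two conditions; replicates are assumed pooled within each.
#' @param group_col Grouping column, default `"gene_id"` (use
#'   `"isoform_id"` for isoform tables).
#' @param min_reads Minimum called reads per condition per group.
#' @param fdr FDR threshold for the `significant` flag.
#'
#' @return data.frame sorted by `q_value`: `group_id`, `n_a`, `n_b`,
#'   `median_a`, `median_b`, `u_stat`, `p_value`, `q_value`, `direction`
#'   (`longer_in_A` / `longer_in_B` / `none`), `significant`.
#' @export
compare_conditions <- function(tails_a, tails_b, group_col = "gene_id",
                               min_reads = 100L, fdr = 0.05) {
  pick <- function(tt) {
    tt <- tt[tt$is_tail & !is.na(tt[[group_col]]), , drop = FALSE]
    split(tt$clip_length, tt[[group_col]])
  }
  ga <- pick(tails_a)
  gb <- pick(tails_b)
  shared <- intersect(names(ga), names(gb))
  shared <- shared[vapply(shared, function(g) {
    length(ga[[g]]) >= min_reads && length(gb[[g]]) >= min_reads
  }, logical(1))]
  if (length(shared) == 0L) {
    warning("no groups pass the read-count filter in both conditions")
    return(data.frame(group_id = character(0), n_a = integer(0),
                      n_b = integer(0), median_a = numeric(0),
                      median_b = numeric(0), u_stat = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      direction = character(0), significant = logical(0)))
  }
  rows <- lapply(shared, function(g) {
    a <- ga[[g]]
    b <- gb[[g]]
    mw <- mann_whitney_u(a, b)
    data.frame(group_id = g, n_a = length(a), n_b = length(b),
               median_a = stats::median(a), median_b = stats::median(b),
               u_stat = mw$u_stat, p_value = mw$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < fdr
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$median_a > out$median_b,
                                 "longer_in_A", "longer_in_B"))
  out <- out[order(out$q_value, out$p_value),
             c("group_id", "n_a", "n_b", "median_a", "median_b", "u_stat",
               "p_value", "q_value", "direction", "significant")]
  rownames(out) <- NULL
  out
}
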