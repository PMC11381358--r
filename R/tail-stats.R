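#' Read a gene annotation as GRanges
#'
#' Thin wrapper over [rtracklayer::import()] accepting BED/BED12 or GTF/GFF;
#' ensures a `gene_id` metadata column is present (taken from `name` for
#' BED, `gene_id` for GTF).
#'
#' @param path Annotation file (.bed or .gtf/.gff).
#' @return [GenomicRanges::GRanges] with a `gene_id` column.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  anno <- tryCatch(rtracklayer::import(path),
                   error = function(e) stop("malformed annotation file ", path,
                                            ": ", conditionMessage(e), call. = FALSE))
  mc <- S4Vectors::mcols(anno)
  if (!"gene_id" %in% names(mc)) {
    if ("name" %in% names(mc)) {
      anno$gene_id <- anno$name
    } else {
      stop("annotation has neither gene_id nor name fields", call. = FALSE)
    }
  }
  if (inherits(anno, "GRanges") && "type" %in% names(S4Vectors::mcols(anno))) {
    keep <- anno$type %in% c("gene", "exon", "transcript")
    if (any(keep)) anno <- anno[keep]
    anno <- anno[!duplicated(anno$gene_id)]
  }
  anno
}

#' Assign tail calls to genes by maximal same-strand overlap
#'
#' Each read's full reference span is intersected with same-strand gene
#' intervals; the read is assigned to the gene with the largest overlap.
#' Reads overlapping no gene, and exact ties between genes, are left
#' unassigned (`gene_id = NA`) so per-gene distributions stay disjoint.
#'
#' @param tails data.frame from [tail_table()] (needs `reference_name`,
#'   `ref_start`, `ref_end`, `strand`).
#' @param annotation [GenomicRanges::GRanges] with `gene_id`, or a file path
#'   accepted by [read_annotation()].
#'
#' @return `tails` with a `gene_id` column appended.
#' @export
assign_to_genes <- function(tails, annotation) {
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  gene_id <- rep(NA_character_, nrow(tails))
  if (nrow(tails) > 0L) {
    reads <- GenomicRanges::GRanges(
      seqnames = tails$reference_name,
      ranges = IRanges::IRanges(start = tails$ref_start + 1L, end = tails$ref_end),
      strand = tails$strand
    )
    GenomeInfoDb::seqlevels(reads) <-
      union(GenomeInfoDb::seqlevels(reads), GenomeInfoDb::seqlevels(annotation))
    hits <- GenomicRanges::findOverlaps(reads, annotation, ignore.strand = FALSE)
    if (length(hits) > 0L) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      w <- GenomicRanges::width(IRanges::pintersect(reads[q], annotation[s],
                                                    ignore.strand = TRUE))
      ord <- order(q, -w)
      q <- q[ord]; s <- s[ord]; w <- w[ord]
      first <- !duplicated(q)
      best_q <- q[first]
      best_s <- s[first]
      best_w <- w[first]
      # a tie exists when the second-best overlap for the same read equals
      # the best
      second <- which(first) + 1L
      tied <- second <= length(q) & !first[pmin(second, length(q))] &
        w[pmin(second, length(q))] == best_w &
        q[pmin(second, length(q))] == best_q
      gene_id[best_q] <- ifelse(tied, NA_character_,
                                annotation$gene_id[best_s])
    }
  }
  tails$gene_id <- gene_id
  tails
}

#' Pearson's second skewness coefficient
#'
#' `3 * (mean - median) / s`, with `s` the sample standard deviation (n - 1
#' denominator). Undefined (`NA`) when fewer than two observations or when
#' `s = 0`.
#'
#' @param lengths Numeric vector.
#' @return Numeric scalar or `NA`.
#' @export
pearson_skew <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 2L) return(NA_real_)
  s <- stats::sd(lengths)
  if (!is.finite(s) || s == 0) return(NA_real_)
  3 * (mean(lengths) - stats::median(lengths)) / s
}

#' Summarize one group of tail lengths
#'
#' Mean, median, quartiles (linear interpolation between order statistics),
#' Pearson's second skewness coefficient, and the number of observations.
#'
#' @param lengths Nonempty numeric vector of tail lengths (nt).
#' @return One-row data.frame: `n_reads`, `mean`, `median`, `q25`, `q75`,
#'   `pearson_skew`.
#' @export
summarize_group <- function(lengths) {
  if (length(lengths) == 0L) stop("cannot summarize an empty group", call. = FALSE)
  lengths <- as.numeric(lengths)
  q <- stats::quantile(lengths, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(
    n_reads = length(lengths),
    mean = mean(lengths),
    median = q[2],
    q25 = q[1],
    q75 = q[3],
    pearson_skew = pearson_skew(lengths)
  )
}

summarize_groups_by <- function(lengths, keys) {
  idx <- split(seq_along(lengths), keys, drop = TRUE)
  out <- do.call(rbind, lapply(idx, function(i) summarize_group(lengths[i])))
  key_rows <- do.call(rbind, lapply(idx, function(i) keys[i[1], , drop = FALSE]))
  res <- cbind(key_rows, out)
  rownames(res) <- NULL
  res
}

#' Per-gene tail-length summaries
#'
#' One [summarize_group()] row per (gene, condition) among called tails with
#' a gene assignment.
#'
#' @param tails data.frame from [assign_to_genes()]; only `is_tail = TRUE`
#'   rows with non-NA `gene_id` are used.
#' @return data.frame keyed by `gene_id`, `sample`.
#' @export
summarize_by_gene <- function(tails) {
  use <- tails[tails$is_tail & !is.na(tails$gene_id), , drop = FALSE]
  if (nrow(use) == 0L) {
    warning("no called, assigned tails to summarize")
    return(data.frame(gene_id = character(0), sample = character(0),
                      n_reads = integer(0), mean = numeric(0),
                      median = numeric(0), q25 = numeric(0), q75 = numeric(0),
                      pearson_skew = numeric(0)))
  }
  summarize_groups_by(use$clip_length,
                      use[, c("gene_id", "sample"), drop = FALSE])
}

#' Per-isoform tail-length summaries
#'
#' Joins called tails to an upstream read-to-isoform assignment table and
#' summarizes per (isoform, condition), propagating the intron-retention
#' flag. Reads absent from the isoform table are skipped.
#'
#' @param tails data.frame from [assign_to_genes()] (or [tail_table()]).
#' @param isoform_assignments data.frame: `read_id`, `isoform_id`,
#'   `gene_id`, `intron_retained` (logical).
#' @return data.frame keyed by `isoform_id`, `sample`, with `gene_id` and
#'   `is_intron_retained`.
#' @export
summarize_by_isoform <- function(tails, isoform_assignments) {
  iso <- isoform_assignments
  dup <- unique(iso$read_id[duplicated(iso$read_id)])
  if (length(dup) > 0L) {
    conflict <- vapply(dup, function(r) {
      length(unique(iso$isoform_id[iso$read_id == r])) > 1L
    }, logical(1))
    if (any(conflict)) {
      stop("conflicting isoform assignments for read(s): ",
           paste(dup[conflict], collapse = ", "), call. = FALSE)
    }
    iso <- iso[!duplicated(iso$read_id), , drop = FALSE]
  }
  use <- tails[tails$is_tail, , drop = FALSE]
  m <- match(use$read_id, iso$read_id)
  keep <- !is.na(m)
  use <- use[keep, , drop = FALSE]
  m <- m[keep]
  if (nrow(use) == 0L) {
    warning("no called tails matched the isoform assignment table")
    return(data.frame(isoform_id = character(0), sample = character(0),
                      gene_id = character(0), is_intron_retained = logical(0),
                      n_reads = integer(0), mean = numeric(0),
                      median = numeric(0), q25 = numeric(0), q75 = numeric(0),
                      pearson_skew = numeric(0)))
  }
  keys <- data.frame(isoform_id = iso$isoform_id[m],
                     sample = use$sample,
                     gene_id = iso$gene_id[m],
                     is_intron_retained = iso$intron_retained[m],
                     stringsAsFactors = FALSE)
  summarize_groups_by(use$clip_length, keys)
}
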