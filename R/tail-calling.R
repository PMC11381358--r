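#' Read primary mapped alignments from SAM/BAM
#'
#' Loads primary, mapped records (secondary and supplementary alignments are
#' dropped, matching upstream mapping with secondary output disabled) into a
#' plain data.frame. SAM input is converted on the fly; file order is
#' preserved for whole-file reads. Region queries require a BAM with an
#' index.
#'
#' @param path SAM or BAM file.
#' @param region Optional [GenomicRanges::GRanges] of length 1 restricting
#'   the query (BAM with index only).
#' @param sample Optional condition label attached to every record.
#'
#' @return data.frame with one row per alignment: `read_id`, `flag`,
#'   `reference_name`, `ref_start`/`ref_end` (0-based half-open), `mapq`,
#'   `is_reverse`, `cigar`, `seq`, `qual` (ASCII string or NA), `md`
#'   (MD tag or NA), `sample`.
#' @export
read_alignments <- function(path, region = NULL, sample = NA_character_) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  if (is_sam) {
    if (!is.null(region)) {
      stop("region queries require an indexed BAM, not SAM", call. = FALSE)
    }
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, indexDestination = FALSE)
    on.exit(unlink(path))
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  which <- if (is.null(region)) IRanges::IRangesList() else region
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(
      flag = flag, tag = "MD",
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  } else {
    Rsamtools::ScanBamParam(
      flag = flag, tag = "MD", which = region,
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  }
  res <- Rsamtools::scanBam(path, param = param)
  parts <- lapply(res, function(x) {
    n <- length(x$qname)
    data.frame(
      read_id = x$qname,
      flag = x$flag,
      reference_name = as.character(x$rname),
      ref_start = x$pos - 1L,
      ref_end = x$pos - 1L + cigar_reference_width(x$cigar),
      mapq = x$mapq,
      is_reverse = bitwAnd(x$flag, 16L) > 0L,
      cigar = x$cigar,
      seq = as.character(x$seq),
      qual = if (n > 0) as.character(x$qual) else character(0),
      md = if (is.null(x$tag$MD)) rep(NA_character_, n) else as.character(x$tag$MD),
      sample = rep(sample, n),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Extract the candidate poly(A) tail from one alignment
#'
#' Returns the transcript-3' terminal soft clip in transcript (5'->3')
#' orientation: for forward reads the trailing soft clip as stored; for
#' reverse-flagged reads the leading soft clip, reverse-complemented. Hard
#' clips are ignored. Returns the empty string when no such clip exists.
#'
#' @param cigar CIGAR string.
#' @param seq Stored read sequence (SAM orientation).
#' @param is_reverse Logical, reverse-strand flag.
#' @return Character scalar, possibly "".
#' @export
extract_candidate_tail <- function(cigar, seq, is_reverse) {
  ops <- parse_cigar(cigar)
  ops <- ops[ops$op != "H", , drop = FALSE]
  if (nrow(ops) == 0L) return("")
  if (!is_reverse) {
    last <- nrow(ops)
    if (ops$op[last] != "S") return("")
    n <- ops$length[last]
    substring(seq, nchar(seq) - n + 1L, nchar(seq))
  } else {
    if (ops$op[1L] != "S") return("")
    n <- ops$length[1L]
    revcomp(substring(seq, 1L, n))
  }
}

#' Call a poly(A) tail from a candidate clip
#'
#' A clip is called a tail when it is at least `min_len` nucleotides long
#' and at least `min_frac_A` of its bases are adenosine (inclusive
#' boundary; the 85% adenine rule). The reported tail length is the full
#' clip length, non-A bases included.
#'
#' @param clip Candidate clip sequence(s), transcript orientation
#'   (vectorized).
#' @param min_frac_A Minimum A fraction, in (0, 1]. Default 0.85.
#' @param min_len Minimum clip length in nt (>= 1). Default 5.
#'
#' @return data.frame: `clip_length`, `frac_A` (NA for empty clips),
#'   `is_tail`, `tail_seq`.
#' @export
call_tail <- function(clip, min_frac_A = 0.85, min_len = 5L) {
  stopifnot(min_frac_A > 0, min_frac_A <= 1, min_len >= 1L)
  len <- nchar(clip)
  fa <- fraction_a(clip)
  data.frame(
    clip_length = len,
    frac_A = fa,
    is_tail = !is.na(fa) & len >= min_len & fa >= min_frac_A,
    tail_seq = clip,
    stringsAsFactors = FALSE
  )
}

#' Tabulate tail calls for a set of alignments
#'
#' Applies [extract_candidate_tail()] and [call_tail()] to every alignment.
#' Rows failing the tail rule are retained with `is_tail = FALSE` so the
#' denominator is auditable; downstream stages use only `is_tail = TRUE`
#' rows.
#'
#' @param alignments data.frame from [read_alignments()].
#' @param min_frac_A,min_len Tail-calling parameters, see [call_tail()].
#'
#' @return data.frame with one row per alignment: `read_id`, `sample`,
#'   `reference_name`, `ref_start`, `ref_end`, `strand`, `clip_length`,
#'   `frac_A`, `is_tail`, `tail_seq`.
#' @export
tail_table <- function(alignments, min_frac_A = 0.85, min_len = 5L) {
  clips <- vapply(seq_len(nrow(alignments)), function(i) {
    extract_candidate_tail(alignments$cigar[i], alignments$seq[i],
                           alignments$is_reverse[i])
  }, character(1))
  calls <- call_tail(clips, min_frac_A = min_frac_A, min_len = min_len)
  out <- data.frame(
    read_id = alignments$read_id,
    sample = alignments$sample,
    reference_name = alignments$reference_name,
    ref_start = alignments$ref_start,
    ref_end = alignments$ref_end,
    strand = ifelse(alignments$is_reverse, "-", "+"),
    stringsAsFactors = FALSE
  )
  cbind(out, calls)
}
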