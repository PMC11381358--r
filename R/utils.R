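# Internal helpers shared across modules.

#' @importFrom stats rnbinom rpois rbinom rnorm runif pnbinom uniroot
NULL

# Evaluate `code` under an explicit RNG seed, restoring the caller's RNG
# state afterwards. All stochastic entry points take a required `seed`
# argument and route through this, so no function touches global RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Parse a CIGAR string into a data.frame of (length, op), in order.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "") {
    return(data.frame(length = integer(0), op = character(0)))
  }
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (length(toks) == 0L || sum(attr(m, "match.length")) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar, call. = FALSE)
  }
  data.frame(
    length = as.integer(sub("[MIDNSHP=X]$", "", toks)),
    op = substring(toks, nchar(toks), nchar(toks)),
    stringsAsFactors = FALSE
  )
}

# Reference-space width of an alignment (M, D, N, =, X consume reference).
cigar_reference_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- parse_cigar(cg)
    sum(ops$length[ops$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# Reverse-complement plain character vectors (DNA alphabet).
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# Fraction of A in each string; NA-free, 0-length strings give NA.
fraction_a <- function(x) {
  n <- nchar(x)
  a <- nchar(gsub("[^A]", "", x))
  ifelse(n > 0L, a / n, NA_real_)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, comment.char = "", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
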