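# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a nucleotide string
#'
#' Operates on plain character vectors; `N` maps to `N`.
#'
#' @param x character vector of sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' GC fraction of a nucleotide string
#'
#' @param x character vector of sequences.
#' @return numeric vector in `[0,1]`; `NA` for empty strings. Ambiguous
#'   bases (`N`) count toward the denominator.
#' @export
gc_fraction <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s)
    if (n == 0L) return(NA_real_)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(ch == "G" | ch == "C") / n
  }, numeric(1), USE.NAMES = FALSE)
}

# strrep() of a motif truncated/extended to exactly `len` characters
tile_motif <- function(motif, len) {
  substr(strrep(motif, ceiling(len / nchar(motif))), 1L, len)
}

# first token of a FASTA/FASTQ header
header_token <- function(x) sub("\\s.*$", "", x)

# stable order by decreasing score then lexicographic key
order_score_desc <- function(score, key) order(-score, key, method = "radix")
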