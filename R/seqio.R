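# Sequence and table IO plus the whole-read filtering stage.
#
# File formats handled here: FASTA, FASTQ (Sanger +33 qualities), tab-separated
# pairwise homology hit tables in the standard 12-column "outfmt 6" layout
# (optionally extended with qlen/slen as columns 13-14 and further named
# columns such as a subject description), and two-column abundance tables.

OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                  "qstart", "qend", "sstart", "send", "evalue", "bitscore")
OUTFMT6_NUMERIC <- c("pident", "length", "mismatch", "gapopen",
                     "qstart", "qend", "sstart", "send", "evalue", "bitscore",
                     "qlen", "slen")

#' Read a FASTA file of transcripts
#'
#' Record ids are the header token before the first whitespace and must be
#' unique within the file. An empty file yields an empty set.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] named by transcript id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 1L && nzchar(first) && !startsWith(first, ">")) {
    stop("FASTA parse error at line 1 of ", path, ": sequence line before header")
  }
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- header_token(names(x))
  if (anyDuplicated(names(x))) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  x
}

#' Write transcripts to FASTA
#'
#' @param x a [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path path to an (uncompressed) FASTQ file with Sanger-encoded
#'   qualities.
#' @return data.frame with columns `id`, `seq`, `qual` (quality kept as the
#'   ASCII string; see [phred_scores()]).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = header_token(names(x)),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param reads data.frame with `id`, `seq`, `qual` columns as returned by
#'   [read_fastq()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read paired FASTQ files into a read-pair table
#'
#' @param path1,path2 mate-1 and mate-2 FASTQ paths; records are paired by
#'   position and mate counts must agree.
#' @return data.frame with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- read_fastq(path1)
  r2 <- read_fastq(path2)
  if (nrow(r1) != nrow(r2)) stop("mate files differ in read count")
  data.frame(id = sub("/[12]$", "", r1$id),
             seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Decode a quality string to Phred scores
#'
#' @param qual quality string (one read).
#' @param offset ASCII offset; 33 is the Sanger convention.
#' @return integer vector of per-base Phred scores.
#' @export
phred_scores <- function(qual, offset = 33L) {
  if (nchar(qual) == 0L) return(integer(0))
  utf8ToInt(qual) - as.integer(offset)
}

#' Filter whole read pairs on quality, adapter content and poly-A tails
#'
#' A pair is removed, not trimmed, if either mate (a) has strictly more than
#' `max_low` positions with quality below `qual_floor`, (b) contains any
#' supplied adapter as an exact substring, or (c) contains a homopolymer run
#' of `A` (and, when `check_polyt = TRUE`, of `T`) of at least `polya_min`
#' bases. A read removed for several reasons is counted once, under the
#' first matching rule in the order low-quality, adapter, poly-A.
#'
#' @param reads read-pair data.frame (see [read_fastq_pairs()]).
#' @param adapters character vector of adapter sequences (may be empty).
#' @param qual_floor Phred score below which a base counts as low quality.
#' @param max_low maximum tolerated number of low-quality positions per mate.
#' @param polya_min minimum homopolymer length that marks a poly-A tail.
#' @param check_polyt also treat poly-T runs (reverse-complement reads of a
#'   poly-A tail) as uninformative.
#' @param qual_offset ASCII offset of the quality encoding.
#' @return list with `kept` (the surviving read-pair data.frame) and
#'   `report`, a named integer vector of removal counts by reason
#'   (`low_quality`, `adapter`, `polya`). `nrow(kept) + sum(report)` always
#'   equals `nrow(reads)`.
#' @export
filter_reads <- function(reads, adapters = character(), qual_floor = 20L,
                         max_low = 20L, polya_min = 20L, check_polyt = TRUE,
                         qual_offset = 33L) {
  n <- nrow(reads)
  report <- c(low_quality = 0L, adapter = 0L, polya = 0L)
  if (n == 0L) return(list(kept = reads, report = report))

  n_low <- function(q) sum(phred_scores(q, qual_offset) < qual_floor)
  low <- vapply(seq_len(n), function(i) {
    n_low(reads$qual1[i]) > max_low || n_low(reads$qual2[i]) > max_low
  }, logical(1))

  has_adapter <- rep(FALSE, n)
  for (ad in adapters) {
    has_adapter <- has_adapter |
      grepl(ad, reads$seq1, fixed = TRUE) | grepl(ad, reads$seq2, fixed = TRUE)
  }

  runs <- strrep("A", polya_min)
  if (check_polyt) runs <- c(runs, strrep("T", polya_min))
  polya <- rep(FALSE, n)
  for (r in runs) {
    polya <- polya | grepl(r, reads$seq1, fixed = TRUE) | grepl(r, reads$seq2, fixed = TRUE)
  }

  reason <- rep(NA_character_, n)
  reason[polya] <- "polya"
  reason[has_adapter] <- "adapter"
  reason[low] <- "low_quality"        # precedence: low-quality > adapter > poly-A

  tab <- table(factor(reason, levels = names(report)))
  report[names(tab)] <- as.integer(tab)
  list(kept = reads[is.na(reason), , drop = FALSE], report = report)
}

#' Parse a tabular pairwise homology hit file
#'
#' Accepts the standard 12-column tab-separated layout, optionally extended
#' by `qlen` and `slen` as columns 13-14, and optionally further extended by
#' named columns given in `extra_cols` (e.g. `"stitle"` for a subject
#' description, `"staxclass"` for a precomputed taxon-class label). Lines
#' starting with `#` are skipped. Downstream operations that need `qlen` or
#' `slen` fail loudly when fed a 12-column table.
#'
#' @param path path to the tab-separated file.
#' @param extra_cols names of additional columns appended after the standard
#'   ones (after `slen` in the 14-column dialect, after `bitscore`
#'   otherwise).
#' @return data.frame of hit records; `qlen`/`slen` are `NA` in the
#'   12-column dialect.
#' @export
parse_hit_table <- function(path, extra_cols = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(
    utils::read.delim(path, header = FALSE, comment.char = "#",
                      colClasses = "character", stringsAsFactors = FALSE),
    error = function(e) NULL
  )
  if (is.null(raw)) return(empty_hit_table(extra_cols))
  nc <- ncol(raw)
  expected12 <- 12L + length(extra_cols)
  expected14 <- 14L + length(extra_cols)
  if (nc == expected14) {
    names(raw) <- c(OUTFMT6_COLS, "qlen", "slen", extra_cols)
  } else if (nc == expected12) {
    names(raw) <- c(OUTFMT6_COLS, extra_cols)
    raw$qlen <- NA_character_
    raw$slen <- NA_character_
  } else {
    stop("hit table ", path, " has ", nc, " columns; expected ",
         expected12, " or ", expected14)
  }
  as_hit_table(raw, path)
}

empty_hit_table <- function(extra_cols = character()) {
  df <- as.data.frame(stats::setNames(
    c(rep(list(character(0)), 2),
      rep(list(numeric(0)), length(OUTFMT6_NUMERIC)),
      rep(list(character(0)), length(extra_cols))),
    c("qseqid", "sseqid", OUTFMT6_NUMERIC, extra_cols)),
    stringsAsFactors = FALSE)
  df[, c(OUTFMT6_COLS, "qlen", "slen", extra_cols), drop = FALSE]
}

as_hit_table <- function(df, path = "<data>") {
  for (col in intersect(OUTFMT6_NUMERIC, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad)) {
      stop("hit table ", path, ": non-numeric value '", df[[col]][bad[1]],
           "' in column ", col)
    }
    df[[col]] <- v
  }
  df
}

#' Write a hit table in the tab-separated dialect it was read from
#'
#' @param hits hit-record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- hits
  if (all(is.na(out$qlen)) && all(is.na(out$slen))) {
    out$qlen <- NULL
    out$slen <- NULL
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-library abundance table
#'
#' @param path tab-separated file with columns `transcript_id` and
#'   `abundance` (header line required).
#' @return named numeric vector of abundances keyed by transcript id.
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "abundance") %in% names(df))) {
    stop("abundance table ", path, " must have columns transcript_id, abundance")
  }
  if (anyDuplicated(df$transcript_id)) stop("duplicate transcript ids in ", path)
  if (any(df$abundance < 0)) stop("negative abundance in ", path)
  stats::setNames(as.numeric(df$abundance), df$transcript_id)
}

#' Write a per-library abundance table
#'
#' @param abund named numeric vector of abundances.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(abund, path) {
  utils::write.table(
    data.frame(transcript_id = names(abund), abundance = as.numeric(abund)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scale abundances to parts-per-million within a library
#'
#' @param abund named non-negative numeric vector.
#' @return vector rescaled to sum to 1e6 (all-zero input is returned as is).
#' @export
normalize_per_million <- function(abund) {
  s <- sum(abund)
  if (s == 0) return(abund)
  abund / s * 1e6
}
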