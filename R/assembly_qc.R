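# Assembly size statistics, reference-gene representation, and the two
# Ortholog Hit Ratio (OHR) completeness metrics.
#
# OHR asks how much of a reference ortholog an assembled transcript
# recovers. OHR_HITS is alignment-based: the fraction of the reference
# protein covered by the union of local-alignment segments (HSPs) of one
# transcript. OHR_ORF is more inclusive: the transcript's longest
# stop-free codon run in the search-defined reading frame, in codons,
# relative to the reference protein length.

#' Assembly length statistics over a core transcript set
#'
#' Transcripts shorter than `core_min_len` are excluded from the core set
#' used for mean and N50 (short contigs rarely yield informative homology
#' matches). N50 is the length L at which the cumulative length of core
#' transcripts, taken longest first, first reaches half the total core
#' length.
#'
#' @param transcripts a [Biostrings::DNAStringSet], named character vector
#'   of sequences, or numeric vector of lengths.
#' @param core_min_len minimum length (bp) for the core set; the bound is
#'   inclusive.
#' @param bin_width width (bp) of the length histogram bins.
#' @return list with `n_total`, `n_core`, `mean_len`, `n50` (`NA` when the
#'   core set is empty) and `length_histogram` (named count vector; names
#'   are bin lower bounds).
#' @export
length_stats <- function(transcripts, core_min_len = 400L, bin_width = 500L) {
  lens <- if (is.numeric(transcripts)) as.numeric(transcripts)
          else if (is.character(transcripts)) nchar(transcripts)
          else Biostrings::width(transcripts)
  core <- lens[lens >= core_min_len]
  n50 <- NA_real_
  mean_len <- NA_real_
  if (length(core) >= 1L) {
    s <- sort(core, decreasing = TRUE)
    n50 <- s[which(cumsum(s) >= sum(s) / 2)[1]]
    mean_len <- mean(core)
  }
  hist <- integer(0)
  if (length(lens)) {
    lo <- floor(lens / bin_width) * bin_width
    tab <- table(lo)
    hist <- stats::setNames(as.integer(tab), names(tab))
  }
  list(n_total = length(lens), n_core = length(core),
       mean_len = mean_len, n50 = n50, length_histogram = hist)
}

#' Reference-gene representation of an assembly
#'
#' A reference gene counts as represented when at least one hit targets it
#' (as subject) with bit-score at or above `bit_min`.
#'
#' @param hits hit-record data.frame (transcripts as queries, reference
#'   genes as subjects).
#' @param ref_gene_ids character vector of reference gene ids (non-empty).
#' @param bit_min significance threshold on the bit-score (inclusive).
#' @return list with `n_hit`, `fraction` (`n_hit / length(ref_gene_ids)`)
#'   and `matched_ids`.
#' @export
gene_representation <- function(hits, ref_gene_ids, bit_min = 50) {
  if (length(ref_gene_ids) == 0L) stop("reference gene set is empty")
  keep <- hits$bitscore >= bit_min & hits$sseqid %in% ref_gene_ids
  matched <- sort(unique(hits$sseqid[keep]))
  list(n_hit = length(matched),
       fraction = length(matched) / length(unique(ref_gene_ids)),
       matched_ids = matched)
}

#' Alignment-coverage Ortholog Hit Ratio for one transcript/gene pair
#'
#' The fraction of the reference protein covered by the union of the
#' pair's HSP subject intervals (orientation-normalized).
#'
#' @param hits_for_pair hit records sharing one `qseqid` and one `sseqid`,
#'   with `slen` present.
#' @return coverage fraction in `[0,1]`.
#' @export
ohr_hits <- function(hits_for_pair) {
  h <- hits_for_pair
  if (nrow(h) == 0L) return(0)
  if (length(unique(h$qseqid)) > 1L || length(unique(h$sseqid)) > 1L) {
    stop("ohr_hits expects HSPs of a single (transcript, gene) pair")
  }
  if (anyNA(h$slen)) stop("missing slen: ohr_hits needs the 14-column hit dialect")
  slen <- h$slen[1]
  lo <- pmin(h$sstart, h$send)
  hi <- pmax(h$sstart, h$send)
  cov <- IRanges::reduce(IRanges::IRanges(start = lo, end = hi))
  sum(IRanges::width(cov)) / slen
}

# longest stop-free codon run (count of codons) of `seq` in reading frame
# `frame` in {+1,+2,+3,-1,-2,-3}; codons containing N are treated as
# non-stop (cannot be confirmed as stops).
longest_orf_codons <- function(seq, frame) {
  stopifnot(frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
  s <- if (frame < 0) revcomp(seq) else seq
  off <- abs(frame) - 1L
  n <- nchar(s) - off
  if (n < 3L) return(0L)
  n_codons <- n %/% 3L
  starts <- off + 1L + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(s, starts, starts + 2L)
  is_stop <- codons %in% c("TAA", "TAG", "TGA")
  if (!any(is_stop)) return(n_codons)
  r <- rle(!is_stop)
  m <- r$lengths[r$values]
  if (length(m) == 0L) 0L else max(m)
}

#' ORF-based Ortholog Hit Ratio for one transcript
#'
#' Longest stop-free codon run of the transcript in the search-defined
#' reading frame, divided by the reference protein length and clamped to 1
#' (an assembled ORF can exceed its ortholog). No start codon is required:
#' assemblies commonly truncate 5' ends and demanding ATG would bias the
#' ratio downward.
#'
#' @param transcript sequence (character scalar or `DNAString`).
#' @param frame reading frame in `{+1,+2,+3,-1,-2,-3}`; negative frames
#'   read the reverse complement (a hit with `qstart > qend` implies a
#'   negative frame).
#' @param ref_protein_len reference protein length in amino acids.
#' @return ratio in `[0,1]`.
#' @export
ohr_orf <- function(transcript, frame, ref_protein_len) {
  stopifnot(ref_protein_len > 0)
  seq <- as.character(transcript)
  min(1, longest_orf_codons(seq, as.integer(frame)) / ref_protein_len)
}

#' Reading frame implied by a hit's query coordinates
#'
#' @param qstart,qend 1-based query coordinates of the hit; `qstart > qend`
#'   indicates the reverse strand.
#' @param qlen query (transcript) length in bp.
#' @return frame in `{+1,+2,+3,-1,-2,-3}`.
#' @export
hit_frame <- function(qstart, qend, qlen) {
  if (qstart <= qend) {
    as.integer((qstart - 1L) %% 3L + 1L)
  } else {
    -as.integer((qlen - qstart) %% 3L + 1L)
  }
}

#' Per-gene maxima and summary of Ortholog Hit Ratios
#'
#' When several transcripts match one reference gene only the largest OHR
#' is kept (per metric). Genes without any match are absent from the
#' result, not scored zero; the median is therefore over matched genes.
#'
#' @param per_pair data.frame with columns `gene_id`, `transcript_id`,
#'   `ohr_hits`, `ohr_orf` (one row per transcript/gene pair).
#' @param complete_min threshold above which a gene counts as "reasonably
#'   complete".
#' @return list with `per_gene` (data.frame `gene_id`, `best_transcript`,
#'   `ohr_hits`, `ohr_orf`) and `summary` (medians, counts at or above
#'   `complete_min`, and `n_genes_matched`).
#' @export
ohr_summarize <- function(per_pair, complete_min = 0.75) {
  if (nrow(per_pair) == 0L) {
    per_gene <- data.frame(gene_id = character(0), best_transcript = character(0),
                           ohr_hits = numeric(0), ohr_orf = numeric(0))
    return(list(per_gene = per_gene,
                summary = list(n_genes_matched = 0L,
                               median_ohr_hits = NA_real_, median_ohr_orf = NA_real_,
                               n_ge_hits = 0L, n_ge_orf = 0L)))
  }
  split_rows <- split(per_pair, per_pair$gene_id)
  per_gene <- do.call(rbind, lapply(split_rows, function(g) {
    o <- order(-g$ohr_hits, -g$ohr_orf, g$transcript_id, method = "radix")
    data.frame(gene_id = g$gene_id[1],
               best_transcript = g$transcript_id[o[1]],
               ohr_hits = max(g$ohr_hits),
               ohr_orf = max(g$ohr_orf),
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  per_gene <- per_gene[order(per_gene$gene_id, method = "radix"), , drop = FALSE]
  list(per_gene = per_gene,
       summary = list(
         n_genes_matched = nrow(per_gene),
         median_ohr_hits = stats::median(per_gene$ohr_hits),
         median_ohr_orf = stats::median(per_gene$ohr_orf),
         n_ge_hits = sum(per_gene$ohr_hits >= complete_min),
         n_ge_orf = sum(per_gene$ohr_orf >= complete_min)))
}
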