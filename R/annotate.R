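# Gene-name transfer and reciprocal-search gene lookup.
#
# Names are transferred from the best protein-database match whose
# description is informative; placeholder descriptions such as
# "uncharacterized protein" fall through to the next-best informative hit
# rather than leaving the transcript unnamed.

#' Default blacklist of uninformative description substrings
#'
#' Matched case-insensitively as substrings of the hit description.
#' @return character vector of lowercase substrings.
#' @export
default_name_blacklist <- function() {
  c("uncharacterized", "unknown", "hypothetical", "predicted protein")
}

is_informative <- function(desc, blacklist) {
  d <- tolower(desc)
  for (term in blacklist) {
    if (grepl(term, d, fixed = TRUE)) return(FALSE)
  }
  TRUE
}

#' Transfer gene names from a protein-database hit table
#'
#' Per transcript, hits are scanned in decreasing bit-score (ties broken
#' lexicographically by accession for determinism); the first hit with
#' E-value at or below `e_max` and an informative description supplies the
#' name. Transcripts without such a hit stay unnamed.
#'
#' @param hits hit-record data.frame carrying a `stitle` description
#'   column (transcripts as queries, protein accessions as subjects).
#' @param e_max E-value ceiling (inclusive).
#' @param blacklist lowercase substrings marking a description as
#'   uninformative.
#' @return data.frame with one row per distinct query: `transcript_id`,
#'   `gene_name` (`NA` if unnamed), `accession` (`NA` if unnamed),
#'   `evalue` (`NA` if unnamed).
#' @export
assign_gene_names <- function(hits, e_max = 1e-4,
                              blacklist = default_name_blacklist()) {
  if (!"stitle" %in% names(hits)) {
    stop("assign_gene_names needs hit descriptions (a 'stitle' column)")
  }
  ids <- sort(unique(hits$qseqid))
  out <- data.frame(transcript_id = ids,
                    gene_name = rep(NA_character_, length(ids)),
                    accession = rep(NA_character_, length(ids)),
                    evalue = rep(NA_real_, length(ids)),
                    stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(out)
  h <- hits[order(hits$qseqid, -hits$bitscore, hits$sseqid, method = "radix"), ,
            drop = FALSE]
  for (i in seq_along(ids)) {
    rows <- h[h$qseqid == ids[i], , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      if (rows$evalue[j] <= e_max && is_informative(rows$stitle[j], blacklist)) {
        out$gene_name[i] <- rows$stitle[j]
        out$accession[i] <- rows$sseqid[j]
        out$evalue[i] <- rows$evalue[j]
        break
      }
    }
  }
  out
}

#' Reciprocal-search lookup of transcripts for a target gene
#'
#' Forward search: a representative protein of the target gene against the
#' assembly; matches at bit-score >= `bit_min` are candidates. Each
#' candidate is then searched back against the protein database, and is
#' accepted when the description of its best informative reverse hit
#' contains at least one target keyword (case-insensitive substring).
#'
#' @param forward hit table of the query protein against the assembly
#'   (transcripts as subjects).
#' @param reverse hit table of candidate transcripts against the protein
#'   database, with a `stitle` description column.
#' @param target_keywords keywords naming the gene and accepted synonyms.
#' @param bit_min forward bit-score threshold (inclusive).
#' @param blacklist uninformative-description substrings (reverse best hit
#'   is the best informative one).
#' @return list with `accepted` (character vector of transcript ids) and
#'   `log` (data.frame `transcript_id`, `status`, `reason`, `best_desc`).
#' @export
reciprocal_search <- function(forward, reverse, target_keywords, bit_min = 45,
                              blacklist = default_name_blacklist()) {
  stopifnot(length(target_keywords) >= 1L)
  cand <- sort(unique(forward$sseqid[forward$bitscore >= bit_min]))
  log <- data.frame(transcript_id = cand, status = "rejected",
                    reason = NA_character_, best_desc = NA_character_,
                    stringsAsFactors = FALSE)
  if (length(cand) == 0L) return(list(accepted = character(0), log = log))
  if (nrow(reverse) > 0L && !"stitle" %in% names(reverse)) {
    stop("reverse hit table needs a 'stitle' column")
  }
  rev_sorted <- reverse[order(reverse$qseqid, -reverse$bitscore, reverse$sseqid,
                              method = "radix"), , drop = FALSE]
  kw <- tolower(target_keywords)
  for (i in seq_along(cand)) {
    rows <- rev_sorted[rev_sorted$qseqid == cand[i], , drop = FALSE]
    inf_rows <- rows[vapply(rows$stitle, is_informative, logical(1), blacklist), ,
                     drop = FALSE]
    if (nrow(inf_rows) == 0L) {
      log$reason[i] <- "no_reverse_hit"
      next
    }
    desc <- inf_rows$stitle[1]
    log$best_desc[i] <- desc
    hit_kw <- any(vapply(kw, function(k) grepl(k, tolower(desc), fixed = TRUE),
                         logical(1)))
    if (hit_kw) {
      log$status[i] <- "accepted"
    } else {
      log$reason[i] <- "keyword_mismatch"
    }
  }
  list(accepted = log$transcript_id[log$status == "accepted"], log = log)
}
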