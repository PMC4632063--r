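# Taxonomic-origin classification of assembled transcripts.
#
# Mixed host/symbiont RNA yields assemblies containing host (metazoan)
# transcripts, dinoflagellate symbiont transcripts, organelle-derived
# sequences (rRNA, mtDNA) and microbial bystanders. A fixed decision tree
# over pre-thresholded homology evidence from five databases (host rRNA,
# a cnidarian mitochondrial genome, host gene models, symbiont gene
# models, and a comprehensive protein database carrying a
# metazoan/nonmetazoan label) assigns each transcript exactly one
# category.

#' Origin categories, in reporting order
#' @export
origin_categories <- c("rRNA", "mtDNA", "dinoflagellate", "metazoan",
                       "other_taxa", "no_match")

#' Classify transcripts from pre-thresholded evidence
#'
#' Rules are applied in order; the first match wins:
#' 1. any rRNA hit: `rRNA`;
#' 2. any mitochondrial hit: `mtDNA`;
#' 3. symbiont score above host score (absent scores count as -Inf) and the
#'    comprehensive-database class not metazoan (nonmetazoan or absent):
#'    `dinoflagellate`;
#' 4. host score above symbiont score and the class metazoan or absent:
#'    `metazoan`;
#' 5. host/symbiont evidence conflicting with the class label, or an exact
#'    host/symbiont tie with both present: `other_taxa`;
#' 6. neither host nor symbiont hit: the class label decides (metazoan:
#'    `metazoan`; nonmetazoan: `other_taxa`);
#' 7. no evidence at all: `no_match`.
#'
#' @param evidence data.frame with one row per transcript and columns
#'   `rrna`, `mito`, `host`, `symbiont` (best bit-scores, `NA` when absent)
#'   and `nr_class` (`"metazoan"`, `"nonmetazoan"`, or `NA` when absent).
#'   Scores are assumed pre-filtered at the caller's thresholds.
#' @return factor of categories (levels [origin_categories]), one per row.
#' @export
classify_origin <- function(evidence) {
  stopifnot(all(c("rrna", "mito", "host", "symbiont", "nr_class") %in% names(evidence)))
  host <- ifelse(is.na(evidence$host), -Inf, evidence$host)
  symb <- ifelse(is.na(evidence$symbiont), -Inf, evidence$symbiont)
  nr <- as.character(evidence$nr_class)
  bad_class <- !is.na(nr) & !nr %in% c("metazoan", "nonmetazoan")
  if (any(bad_class)) stop("unknown nr_class label: ", nr[which(bad_class)[1]])
  nr_met <- !is.na(nr) & nr == "metazoan"
  nr_nonmet <- !is.na(nr) & nr == "nonmetazoan"

  n <- nrow(evidence)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <-
      if (!is.na(evidence$rrna[i])) "rRNA"
      else if (!is.na(evidence$mito[i])) "mtDNA"
      else if (is.infinite(host[i]) && is.infinite(symb[i])) {
        if (nr_met[i]) "metazoan"
        else if (nr_nonmet[i]) "other_taxa"
        else "no_match"
      }
      else if (symb[i] > host[i]) {
        if (nr_met[i]) "other_taxa" else "dinoflagellate"
      }
      else if (host[i] > symb[i]) {
        if (nr_nonmet[i]) "other_taxa" else "metazoan"
      }
      else "other_taxa"   # host == symbiont, both present: ambiguous
  }
  factor(out, levels = origin_categories)
}

# best (maximum) bit-score per query in a hit table, after thresholding;
# returns a named numeric vector (absent queries are simply missing)
best_bitscore <- function(hits, bit_min) {
  if (is.null(hits) || nrow(hits) == 0L) return(stats::setNames(numeric(0), character(0)))
  h <- hits[hits$bitscore >= bit_min, , drop = FALSE]
  if (nrow(h) == 0L) return(stats::setNames(numeric(0), character(0)))
  tapply_max <- tapply(h$bitscore, h$qseqid, max)
  stats::setNames(as.numeric(tapply_max), names(tapply_max))
}

# class label of the best comprehensive-database hit per query
# (max bitscore; ties by min evalue then lexicographic subject id)
best_nr_class <- function(nr_hits, e_max) {
  empty <- list(class = stats::setNames(character(0), character(0)))
  if (is.null(nr_hits) || nrow(nr_hits) == 0L) return(empty$class)
  if (!"staxclass" %in% names(nr_hits)) {
    stop("comprehensive-database hit table needs a 'staxclass' column")
  }
  h <- nr_hits[nr_hits$evalue <= e_max, , drop = FALSE]
  if (nrow(h) == 0L) return(empty$class)
  o <- order(h$qseqid, -h$bitscore, h$evalue, h$sseqid, method = "radix")
  h <- h[o, , drop = FALSE]
  first <- !duplicated(h$qseqid)
  stats::setNames(h$staxclass[first], h$qseqid[first])
}

#' Classify every transcript of an assembly
#'
#' Builds the per-transcript evidence bundle (best bit-score per database
#' after thresholding; class label of the best comprehensive-database hit)
#' and applies [classify_origin()]. The tally partitions the assembly:
#' counts sum to the number of transcripts and percentages to 100.
#'
#' @param transcript_ids character vector of all transcript ids (must be
#'   unique); transcripts without any hit are classified `no_match`.
#' @param rrna_hits,mito_hits,host_hits,symbiont_hits hit tables (may be
#'   `NULL` or empty).
#' @param nr_hits comprehensive-database hit table with an extra
#'   `staxclass` column (`"metazoan"`/`"nonmetazoan"`), or `NULL`.
#' @param bit_min bit-score threshold for the four small databases.
#' @param nr_emax E-value ceiling for the comprehensive database.
#' @return list with `calls` (data.frame `transcript_id`, `category`, and
#'   the evidence columns) and `tally` (data.frame `category`, `n`, `pct`).
#' @export
classify_assembly <- function(transcript_ids, rrna_hits = NULL, mito_hits = NULL,
                              host_hits = NULL, symbiont_hits = NULL,
                              nr_hits = NULL, bit_min = 45, nr_emax = 1e-5) {
  if (anyDuplicated(transcript_ids)) {
    stop("duplicate transcript ids: ",
         paste(unique(transcript_ids[duplicated(transcript_ids)]), collapse = ", "))
  }
  pick <- function(v) as.numeric(v[transcript_ids])
  ev <- data.frame(
    transcript_id = transcript_ids,
    rrna = pick(best_bitscore(rrna_hits, bit_min)),
    mito = pick(best_bitscore(mito_hits, bit_min)),
    host = pick(best_bitscore(host_hits, bit_min)),
    symbiont = pick(best_bitscore(symbiont_hits, bit_min)),
    nr_class = as.character(best_nr_class(nr_hits, nr_emax)[transcript_ids]),
    stringsAsFactors = FALSE)
  ev$category <- classify_origin(ev)
  tab <- table(ev$category)
  tally <- data.frame(category = names(tab), n = as.integer(tab),
                      pct = if (length(transcript_ids)) as.numeric(tab) / length(transcript_ids) * 100 else 0,
                      stringsAsFactors = FALSE)
  list(calls = ev[, c("transcript_id", "category", "rrna", "mito", "host",
                      "symbiont", "nr_class")],
       tally = tally)
}
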