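# Ortholog-group filtering and phylogenomic supermatrix construction.
#
# Groups arrive pre-clustered (and, when alignments are attached,
# pre-aligned); this module implements the terminal steps: keep the
# longest sequence per taxon, drop short members, filter on taxon
# occupancy, and concatenate the surviving aligned groups into a single
# partitioned matrix with all-gap blocks for missing taxa.

#' Construct an ortholog group
#'
#' @param group_id group identifier (concatenation order follows the
#'   lexicographic order of these ids).
#' @param members data.frame with columns `taxon`, `seq_id`, `length`
#'   (unaligned protein length in amino acids).
#' @param alignment optional named character vector (by `seq_id`) of
#'   aligned protein strings of equal length (gap character `-`).
#' @return an object of class `ortho_group`.
#' @export
ortho_group <- function(group_id, members, alignment = NULL) {
  stopifnot(is.character(group_id), length(group_id) == 1L)
  stopifnot(all(c("taxon", "seq_id", "length") %in% names(members)))
  if (anyDuplicated(members$seq_id)) stop("duplicate seq_id in group ", group_id)
  if (!is.null(alignment)) {
    if (!all(members$seq_id %in% names(alignment))) {
      stop("alignment missing sequences for group ", group_id)
    }
    w <- unique(nchar(alignment[members$seq_id]))
    if (length(w) > 1L) stop("unequal aligned lengths in group ", group_id)
  }
  structure(list(group_id = group_id,
                 members = members[, c("taxon", "seq_id", "length")],
                 alignment = alignment),
            class = "ortho_group")
}

#' Keep the longest sequence per taxon in a group
#'
#' Ties on length are broken by lexicographic `seq_id`.
#'
#' @param group an [ortho_group()].
#' @return the pruned group (alignment subset accordingly).
#' @export
prune_longest_per_taxon <- function(group) {
  m <- group$members
  o <- order(m$taxon, -m$length, m$seq_id, method = "radix")
  m <- m[o, , drop = FALSE]
  m <- m[!duplicated(m$taxon), , drop = FALSE]
  m <- m[order(m$taxon, method = "radix"), , drop = FALSE]
  rownames(m) <- NULL
  aln <- group$alignment
  if (!is.null(aln)) aln <- aln[m$seq_id]
  ortho_group(group$group_id, m, aln)
}

#' Filter groups by member length and taxon occupancy
#'
#' Members shorter than `min_aa` are dropped first; a group is retained
#' when its surviving distinct-taxon count reaches `min_taxa`.
#'
#' @param groups list of [ortho_group()] (pruned to one sequence per
#'   taxon).
#' @param min_aa minimum unaligned protein length (inclusive).
#' @param min_taxa minimum taxon occupancy (inclusive).
#' @param total_taxa size of the sampled taxon pool (`min_taxa` may not
#'   exceed it).
#' @return list of retained groups with short members removed.
#' @export
filter_groups <- function(groups, min_aa = 100L, min_taxa, total_taxa) {
  if (min_taxa > total_taxa) {
    stop("min_taxa (", min_taxa, ") exceeds total_taxa (", total_taxa, ")")
  }
  out <- lapply(groups, function(g) {
    m <- g$members[g$members$length >= min_aa, , drop = FALSE]
    if (length(unique(m$taxon)) < min_taxa) return(NULL)
    aln <- g$alignment
    if (!is.null(aln)) aln <- aln[m$seq_id]
    ortho_group(g$group_id, m, aln)
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Concatenate aligned groups into a partitioned supermatrix
#'
#' Groups are concatenated in lexicographic `group_id` order; a taxon
#' absent from a group receives an all-gap block for that partition.
#' Partition coordinates are 1-based inclusive, the common phylogenetics
#' partition-file convention.
#'
#' @param groups list of [ortho_group()], each with an alignment and at
#'   most one sequence per taxon.
#' @param taxa taxon order for the matrix rows; default is the sorted
#'   union over groups.
#' @param model substitution-model label written into the partition table.
#' @return object of class `supermatrix`: list with `taxa`, `matrix`
#'   (named character vector of equal-length rows) and `partitions`
#'   (data.frame `group_id`, `start`, `end`, `model`).
#' @export
concatenate_groups <- function(groups, taxa = NULL, model = "WAG") {
  if (length(groups) == 0L) stop("no groups to concatenate")
  for (g in groups) {
    if (is.null(g$alignment)) stop("group ", g$group_id, " has no alignment")
    if (anyDuplicated(g$members$taxon)) {
      stop("group ", g$group_id, " has several sequences for one taxon; prune first")
    }
    if (length(unique(nchar(g$alignment[g$members$seq_id]))) > 1L) {
      stop("unequal aligned lengths in group ", g$group_id)
    }
  }
  groups <- groups[order(vapply(groups, `[[`, character(1), "group_id"),
                         method = "radix")]
  if (is.null(taxa)) {
    taxa <- sort(unique(unlist(lapply(groups, function(g) g$members$taxon))))
  }
  blocks <- lapply(groups, function(g) {
    w <- nchar(g$alignment[[1]])
    row_of <- stats::setNames(as.character(g$alignment[g$members$seq_id]),
                              g$members$taxon)
    vapply(taxa, function(t) {
      if (!is.na(row_of[t])) row_of[[t]] else strrep("-", w)
    }, character(1))
  })
  widths <- vapply(groups, function(g) nchar(g$alignment[[1]]), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  mat <- stats::setNames(
    vapply(seq_along(taxa), function(i) {
      paste(vapply(blocks, `[[`, character(1), i), collapse = "")
    }, character(1)),
    taxa)
  structure(list(
    taxa = taxa,
    matrix = mat,
    partitions = data.frame(
      group_id = vapply(groups, `[[`, character(1), "group_id"),
      start = starts, end = ends, model = model,
      stringsAsFactors = FALSE)),
    class = "supermatrix")
}

#' Write a supermatrix to FASTA or relaxed PHYLIP
#'
#' @param sm a `supermatrix`.
#' @param path output path.
#' @param format `"fasta"` or `"phylip"` (relaxed: names padded, one row
#'   per line).
#' @return `path`, invisibly.
#' @export
write_supermatrix <- function(sm, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    writeLines(as.vector(rbind(paste0(">", sm$taxa), sm$matrix[sm$taxa])), path)
  } else {
    wid <- nchar(sm$matrix[[1]])
    pad <- max(nchar(sm$taxa)) + 2L
    writeLines(c(paste(length(sm$taxa), wid),
                 paste0(formatC(sm$taxa, width = -pad), sm$matrix[sm$taxa])),
               path)
  }
  invisible(path)
}

#' Write the partition table of a supermatrix
#'
#' One line per partition in the form `MODEL, group_id = start-end`.
#'
#' @param sm a `supermatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(sm, path) {
  p <- sm$partitions
  writeLines(sprintf("%s, %s = %d-%d", p$model, p$group_id, p$start, p$end), path)
  invisible(path)
}

#' Count groups containing every taxon of each queried set
#'
#' @param groups list of [ortho_group()].
#' @param taxon_sets list of character vectors; the empty set matches all
#'   groups.
#' @param taxa known taxon universe (default: union over groups); querying
#'   a taxon outside it is an error.
#' @return integer vector of counts, one per queried set (named when
#'   `taxon_sets` is named).
#' @export
shared_ortholog_counts <- function(groups, taxon_sets, taxa = NULL) {
  membership <- lapply(groups, function(g) unique(g$members$taxon))
  if (is.null(taxa)) taxa <- sort(unique(unlist(membership)))
  vapply(taxon_sets, function(q) {
    unknown <- setdiff(q, taxa)
    if (length(unknown)) stop("unknown taxon in query: ", paste(unknown, collapse = ", "))
    sum(vapply(membership, function(m) all(q %in% m), logical(1)))
  }, integer(1))
}

#' Write group membership to TSV
#'
#' @param groups list of [ortho_group()].
#' @param path output path (columns `group_id`, `taxon`, `seq_id`,
#'   `length`).
#' @return `path`, invisibly.
#' @export
write_group_members <- function(groups, path) {
  rows <- do.call(rbind, lapply(groups, function(g) {
    cbind(group_id = g$group_id, g$members)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ortholog groups from a membership TSV and per-group alignments
#'
#' @param members_path TSV with columns `group_id`, `taxon`, `seq_id`,
#'   `length`.
#' @param alignment_paths optional named vector (by group id) of aligned
#'   FASTA paths.
#' @return list of [ortho_group()].
#' @export
read_ortho_groups <- function(members_path, alignment_paths = NULL) {
  df <- utils::read.delim(members_path, stringsAsFactors = FALSE)
  lapply(split(df, df$group_id), function(m) {
    gid <- m$group_id[1]
    aln <- NULL
    if (!is.null(alignment_paths) && gid %in% names(alignment_paths)) {
      x <- Biostrings::readAAStringSet(alignment_paths[[gid]])
      names(x) <- header_token(names(x))
      aln <- stats::setNames(as.character(x), names(x))
    }
    ortho_group(gid, m[, c("taxon", "seq_id", "length")], aln)
  })
}
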