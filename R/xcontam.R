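# Cross-library contamination screen.
#
# Libraries prepared and sequenced together can exchange material (e.g.
# index hopping, carry-over), leaving nearly identical sequences in
# several assemblies. Near-identity is defined by cross-library hits at
# bit-score >= edge_min; connected components of that graph are clusters
# of putative shared sequence. Each cluster is assigned to the library in
# which it is most abundant when that library exceeds every other by at
# least fold_min; otherwise all copies are flagged "unknown origin" and
# dropped.

node_key <- function(library, transcript_id) paste0(library, "\x1f", transcript_id)

#' Build the cross-library near-identity graph
#'
#' @param cross_hits data.frame of cross-library hits with columns `qlib`,
#'   `slib` (library labels of query and subject), `qseqid`, `sseqid`,
#'   `bitscore`. Hits within one library are an error: the screen is about
#'   sharing between co-prepared libraries.
#' @param edge_min minimum bit-score (inclusive) for an edge.
#' @return an undirected [igraph::graph] whose vertices carry `library`
#'   and `transcript_id` attributes; duplicate and reciprocal hits
#'   collapse to single edges. Only transcripts on a retained edge appear.
#' @export
build_cross_graph <- function(cross_hits, edge_min = 100) {
  req <- c("qlib", "slib", "qseqid", "sseqid", "bitscore")
  stopifnot(all(req %in% names(cross_hits)))
  if (any(cross_hits$qlib == cross_hits$slib)) {
    stop("cross-library hit table contains a within-library comparison")
  }
  keep <- cross_hits[cross_hits$bitscore >= edge_min, , drop = FALSE]
  if (nrow(keep) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  a <- node_key(keep$qlib, keep$qseqid)
  b <- node_key(keep$slib, keep$sseqid)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  edges <- unique(data.frame(lo = lo, hi = hi, stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  parts <- strsplit(igraph::V(g)$name, "\x1f", fixed = TRUE)
  igraph::V(g)$library <- vapply(parts, `[[`, character(1), 1L)
  igraph::V(g)$transcript_id <- vapply(parts, `[[`, character(1), 2L)
  g
}

#' Decide the origin of each near-identity cluster from abundances
#'
#' Per connected component, let m be the highest per-library value (the
#' maximum member abundance within each library) and s the second highest.
#' If s is zero and m positive, the cluster is assigned with infinite fold
#' ratio; if m/s reaches `fold_min` (inclusive; a tiny relative epsilon
#' absorbs float rounding on exactly realized ratios) the cluster is
#' assigned to the arg-max library; otherwise every member is flagged
#' `unknown_origin`. Components confined to one library (within-library
#' duplicates cannot arise from cross-contamination) yield `singleton`
#' verdicts.
#'
#' @param graph graph from [build_cross_graph()].
#' @param abundances named list (by library) of named numeric vectors of
#'   per-million abundances; members missing from their table count as 0.
#' @param fold_min minimum fold difference for assignment (inclusive).
#' @return data.frame with one row per cluster member: `cluster_id`,
#'   `library`, `transcript_id`, `status` (`assigned`, `unknown_origin`,
#'   `singleton`), `source_library` (`NA` unless assigned), `fold_ratio`.
#' @export
screen_cross_contamination <- function(graph, abundances, fold_min = 10) {
  if (igraph::vcount(graph) == 0L) {
    return(data.frame(cluster_id = character(0), library = character(0),
                      transcript_id = character(0), status = character(0),
                      source_library = character(0), fold_ratio = numeric(0),
                      stringsAsFactors = FALSE))
  }
  comp <- igraph::components(graph)
  lib <- igraph::V(graph)$library
  tid <- igraph::V(graph)$transcript_id
  abund_of <- function(l, t) {
    v <- abundances[[l]]
    if (is.null(v) || is.na(match(t, names(v)))) 0 else as.numeric(v[[t]])
  }
  rows <- lapply(seq_len(comp$no), function(ci) {
    idx <- which(comp$membership == ci)
    m_lib <- unname(lib[idx])
    m_tid <- unname(tid[idx])
    cluster_id <- sprintf("cluster_%04d", ci)
    libs <- sort(unique(m_lib))
    if (length(libs) == 1L) {
      return(data.frame(cluster_id = cluster_id, library = m_lib,
                        transcript_id = m_tid, status = "singleton",
                        source_library = NA_character_, fold_ratio = NA_real_,
                        stringsAsFactors = FALSE))
    }
    per_lib <- vapply(libs, function(l) {
      max(vapply(m_tid[m_lib == l], function(t) abund_of(l, t), numeric(1)))
    }, numeric(1))
    o <- order(-per_lib, libs, method = "radix")
    m <- unname(per_lib[o[1]])
    s <- unname(per_lib[o[2]])
    if (m > 0 && s == 0) {
      status <- "assigned"; ratio <- Inf; src <- libs[o[1]]
    } else if (m == 0) {
      status <- "unknown_origin"; ratio <- NA_real_; src <- NA_character_
    } else {
      ratio <- m / s
      # relative epsilon: a planted ratio realized by one float division
      # must not fall on the wrong side of the inclusive boundary
      if (ratio >= fold_min * (1 - 1e-12)) {
        status <- "assigned"; src <- libs[o[1]]
      } else {
        status <- "unknown_origin"; src <- NA_character_
      }
    }
    data.frame(cluster_id = cluster_id, library = m_lib, transcript_id = m_tid,
               status = status, source_library = src, fold_ratio = ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Remove cross-contaminant copies from assemblies
#'
#' Assigned clusters keep only the copies in their source library; clusters
#' of unknown origin are removed from every library; singletons and
#' transcripts without cross-library matches are retained untouched. Every
#' input transcript appears exactly once in the cleaned output or the
#' removal report.
#'
#' @param assemblies named list (by library) of [Biostrings::DNAStringSet].
#' @param verdicts data.frame from [screen_cross_contamination()].
#' @return list with `assemblies` (cleaned) and `report` (data.frame
#'   `library`, `transcript_id`, `cluster_id`, `status`, `source_library`,
#'   `fold_ratio`, one row per removed copy).
#' @export
apply_verdicts <- function(assemblies, verdicts) {
  remove <- verdicts[
    (verdicts$status == "assigned" & verdicts$library != verdicts$source_library) |
      verdicts$status == "unknown_origin", , drop = FALSE]
  cleaned <- assemblies
  for (l in names(assemblies)) {
    drop_ids <- remove$transcript_id[remove$library == l]
    if (length(drop_ids)) {
      cleaned[[l]] <- assemblies[[l]][setdiff(names(assemblies[[l]]), drop_ids)]
    }
  }
  report <- remove[, c("library", "transcript_id", "cluster_id", "status",
                       "source_library", "fold_ratio"), drop = FALSE]
  rownames(report) <- NULL
  list(assemblies = cleaned, report = report)
}
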