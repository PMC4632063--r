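# Imperfect simple-sequence-repeat (microsatellite) discovery.
#
# A locus is a maximal region whose normalized edit distance to the
# best-phase perfect tandem array of a 2-5 bp motif ("deviation") stays
# within a tolerance, subject to minimum length and flanking-sequence
# requirements. Motifs are reported canonically: the lexicographic minimum
# over the motif's cyclic rotations and the rotations of its reverse
# complement, so (AC)n, (CA)n and (GT)n are one repeat type.

rotations <- function(motif) {
  k <- nchar(motif)
  vapply(seq_len(k), function(i) {
    paste0(substr(motif, i, k), substr(motif, 1, i - 1))
  }, character(1))
}

#' Canonical form of a repeat motif
#'
#' @param motif nucleotide motif (2-5 bp typically).
#' @return lexicographically smallest string among the motif's cyclic
#'   rotations and the rotations of its reverse complement.
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) min(c(rotations(m), rotations(revcomp(m)))),
         character(1), USE.NAMES = FALSE)
}

# minimal period of a motif (k => no internal repetition)
minimal_period <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0L && tile_motif(substr(motif, 1, d), k) == motif) return(d)
  }
  k
}

#' Deviation of a region from a perfect tandem array
#'
#' Edit (Levenshtein) distance between the region and the closest-phase
#' perfect array of the motif, normalized by region length. The minimum is
#' taken over all cyclic rotations of the motif and of its reverse
#' complement (each tiled to the region length), so the value is invariant
#' under canonicalization and strand flips.
#'
#' @param region nucleotide string.
#' @param motif repeat motif.
#' @return deviation in `[0,1]` (0 = perfect repeat).
#' @export
ssr_deviation <- function(region, motif) {
  n <- nchar(region)
  if (n == 0L) return(0)
  phases <- unique(c(rotations(motif), rotations(revcomp(motif))))
  tiles <- vapply(phases, tile_motif, character(1), len = n)
  min(utils::adist(region, tiles)) / n
}

# candidate period-k segments: maximal positively scoring runs of the
# "base equals base k later" profile (match +1, mismatch -1.5), i.e.
# regions dense in period-k structure even when no long exact run exists
period_candidates <- function(chars, k) {
  n <- length(chars)
  if (n < 2L * k + 2L) return(list())
  eq <- chars[seq_len(n - k)] == chars[(k + 1L):n]
  # penalty calibrated so an array at the 15% deviation ceiling (false
  # density up to ~0.4 in its worst half) still yields one spanning
  # segment, while random background (false density ~0.75) drifts
  # firmly negative
  score <- ifelse(eq, 1, -1.25)
  # Kadane-style sweep collecting all maximal positive-sum segments
  out <- list()
  best <- 0; cur <- 0; start <- 1L; seg_best <- 0; seg_end <- 0L
  i <- 1L
  while (i <= length(score)) {
    if (cur <= 0) { start <- i; cur <- 0; seg_best <- 0 }
    cur <- cur + score[i]
    if (cur > seg_best) { seg_best <- cur; seg_end <- i }
    nxt_neg <- (cur <= 0)
    if (nxt_neg || i == length(score)) {
      # the recorded end is the score argmax, which for imperfect arrays
      # can fall well before the array end; keep even short seeds (the
      # growth pass extends them) as long as the match surplus is real
      if (seg_best >= 3 && (seg_end - start + 1L + k) >= max(2L * k + 2L, 8L)) {
        out[[length(out) + 1L]] <- c(start, seg_end)
      }
      if (nxt_neg) { cur <- 0 }
    }
    i <- i + 1L
  }
  out
}

# pick the motif for a candidate region: among the most frequent k-mers
# (preferring those opening an exact adjacent copy), the one whose
# perfect array is closest to the region in edit distance; frequency
# alone misleads when edits shorten the clean stretches
extract_motif <- function(chars, s, e, k) {
  region <- chars[s:e]
  n <- length(region)
  if (n < k) return(NULL)
  starts <- seq_len(n - k + 1L)
  kmers <- vapply(starts, function(i) paste(region[i:(i + k - 1L)], collapse = ""),
                  character(1))
  dup <- starts[starts + 2L * k - 1L <= n]
  exact <- dup[vapply(dup, function(i) kmers[i] == kmers[i + k], logical(1))]
  top <- function(x, m) { t <- sort(table(x), decreasing = TRUE)
                          names(t)[seq_len(min(m, length(t)))] }
  cand <- unique(c(if (length(exact)) top(kmers[exact], 4L), top(kmers, 6L)))
  region_str <- paste(region, collapse = "")
  dev <- vapply(cand, function(m) ssr_deviation(region_str, m), numeric(1))
  cand[order(dev, cand)][seq_len(min(3L, length(cand)))]
}

# Refine a candidate window [s, e] (1-based inclusive) in four
# deterministic passes:
#   1. growth: extend outward with jump lookahead while the whole-window
#      deviation stays within max_dev (crosses interior edit clusters;
#      may absorb some flanking junk within the deviation budget);
#   2. junk trim: remove edge stretches that are mostly mismatch (at
#      least one edit per two bases) -- this strips absorbed flank, so a
#      short array padded to min_len by junk falls back below it;
#   3. shrink: drop the costlier edge base while the deviation still
#      exceeds max_dev (safety net, rarely triggered);
#   4. deviation polish: trim any edge stretch whose removal strictly
#      lowers the deviation, but never below min_len -- a perfect array
#      is thereby reported exactly, with deviation 0.
refine_window <- function(chars, s, e, motif, max_dev, max_jump, min_len) {
  n <- length(chars)
  k <- nchar(motif)
  cost_of <- function(a, b) {
    r <- paste(chars[a:b], collapse = "")
    ssr_deviation(r, motif) * (b - a + 1L)
  }
  cur <- cost_of(s, e)
  repeat {                                   # pass 1: growth (mostly-repeat rule)
    grown <- FALSE
    for (j in seq(max_jump, 1L)) {
      if (e + j > n) next
      cand <- cost_of(s, e + j)
      if (cand - cur < j / 2 && cand / (e + j - s + 1L) <= max_dev) {
        e <- e + j; cur <- cand; grown <- TRUE; break
      }
    }
    for (j in seq(max_jump, 1L)) {
      if (s - j < 1L) next
      cand <- cost_of(s - j, e)
      if (cand - cur < j / 2 && cand / (e - s + j + 1L) <= max_dev) {
        s <- s - j; cur <- cand; grown <- TRUE; break
      }
    }
    if (!grown) break
  }
  repeat {                                   # pass 2: junk trim
    if (e - s + 1L <= k) break
    trimmed <- FALSE
    for (j in seq_len(min(max_jump, e - s - k))) {
      cand <- cost_of(s + j, e)
      if (cur - cand >= j / 2) { s <- s + j; cur <- cand; trimmed <- TRUE; break }
    }
    for (j in seq_len(min(max_jump, e - s - k))) {
      cand <- cost_of(s, e - j)
      if (cur - cand >= j / 2) { e <- e - j; cur <- cand; trimmed <- TRUE; break }
    }
    if (!trimmed) break
  }
  while (e - s + 1L > k && cur / (e - s + 1L) > max_dev) {   # pass 3: shrink
    # lookahead on both sides: take the trim that lowers the deviation
    # most (single-base steps can stall when both edge bases match phase
    # while the excess edits sit a few bases in)
    len <- e - s + 1L
    best <- NULL
    best_dev <- Inf
    for (j in seq_len(min(max_jump, len - k))) {
      dl <- cost_of(s + j, e) / (len - j)
      if (dl < best_dev) { best_dev <- dl; best <- c(j, 0L) }
      dr <- cost_of(s, e - j) / (len - j)
      if (dr < best_dev) { best_dev <- dr; best <- c(0L, j) }
    }
    if (is.null(best)) break
    s <- s + best[1]
    e <- e - best[2]
    cur <- cost_of(s, e)
  }
  if (cur / (e - s + 1L) > max_dev) return(NULL)
  repeat {                                   # pass 4: deviation polish
    len <- e - s + 1L
    if (len <= max(k, min_len)) break
    dev <- cur / len
    improved <- FALSE
    for (j in seq_len(min(max_jump, len - min_len))) {
      cand <- cost_of(s + j, e)
      if (cand / (len - j) < dev - 1e-12) {
        s <- s + j; cur <- cand; improved <- TRUE; break
      }
    }
    len <- e - s + 1L
    dev <- cur / len
    for (j in seq_len(min(max_jump, len - min_len))) {
      cand <- cost_of(s, e - j)
      if (cand / (len - j) < dev - 1e-12) {
        e <- e - j; cur <- cand; improved <- TRUE; break
      }
    }
    if (!improved) break
  }
  repeat {                                   # pass 5: pure-junk edges
    # the deviation polish stops at the min_len floor, which can leave an
    # all-mismatch pad (every base an edit) on a window inflated to the
    # minimum length; remove such pads even below min_len (the caller
    # then rejects the too-short window). A lone edge mismatch is left
    # alone: it is indistinguishable from a real substitution at the
    # boundary of an imperfect array.
    if (e - s + 1L <= k) break
    trimmed <- FALSE
    for (j in 2:min(max_jump, e - s - k)) {
      if (j > e - s - k) break
      cand <- cost_of(s + j, e)
      if (cur - cand >= j) { s <- s + j; cur <- cand; trimmed <- TRUE; break }
    }
    for (j in 2:min(max_jump, e - s - k)) {
      if (j > e - s - k) break
      cand <- cost_of(s, e - j)
      if (cur - cand >= j) { e <- e - j; cur <- cand; trimmed <- TRUE; break }
    }
    if (!trimmed) break
  }
  c(s, e)
}

# Fallback when greedy refinement lands below min_len: exhaustively score
# candidate windows around the seed and keep the minimum-deviation one of
# admissible length, provided it qualifies and carries no all-mismatch
# edge pad (a pad of two or more pure junk bases is trimmed; if that
# drops the window below min_len there was no genuine locus here).
complete_window <- function(chars, s0, e0, motif, max_dev, min_len, pad) {
  n <- length(chars)
  dev_of <- function(a, b) ssr_deviation(paste(chars[a:b], collapse = ""), motif)
  lo <- max(1L, s0 - pad)
  hi <- min(n, e0 + pad)
  best <- NULL
  best_key <- c(Inf, -Inf)
  for (a in lo:s0) {
    for (b in e0:hi) {
      len <- b - a + 1L
      if (len < min_len) next
      d <- dev_of(a, b)
      if (d > max_dev) next
      if (d < best_key[1] - 1e-12 ||
          (abs(d - best_key[1]) <= 1e-12 && len > best_key[2])) {
        best <- c(a, b)
        best_key <- c(d, len)
      }
    }
  }
  if (is.null(best)) return(NULL)
  s <- best[1]; e <- best[2]
  k <- nchar(motif)
  cost_of <- function(a, b) dev_of(a, b) * (b - a + 1L)
  cur <- cost_of(s, e)
  repeat {
    if (e - s + 1L <= k + 2L) break
    trimmed <- FALSE
    for (j in 2:min(pad, e - s - k)) {
      if (cur - cost_of(s + j, e) >= j) { s <- s + j; cur <- cost_of(s, e); trimmed <- TRUE; break }
    }
    for (j in 2:min(pad, e - s - k)) {
      if (cur - cost_of(s, e - j) >= j) { e <- e - j; cur <- cost_of(s, e); trimmed <- TRUE; break }
    }
    if (!trimmed) break
  }
  if (e - s + 1L < min_len) return(NULL)
  c(s, e)
}

#' Detect imperfect simple sequence repeats in one sequence
#'
#' Candidate regions are seeded where the period-k self-match profile is
#' dense, a motif is extracted from the cleanest copy, and the window is
#' extended (with lookahead, so isolated edits inside a longer array are
#' crossed) and trimmed so the reported locus satisfies the deviation
#' bound. Loci must reach `min_len`, keep `min_flank` bases of flanking
#' sequence on both sides, and homopolymer motifs (including homopolymer
#' multiples such as `AA`) are excluded. Overlapping calls of the same
#' canonical repeat type collapse to the longest window.
#'
#' @param seq nucleotide sequence (character scalar or `DNAString`).
#' @param motif_lens motif lengths to scan.
#' @param min_len minimum locus length in bp (inclusive).
#' @param max_dev maximum deviation from a perfect repeat (inclusive).
#' @param min_flank minimum flanking sequence on each side in bp.
#' @param transcript_id id recorded in the output.
#' @return data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open), `motif` (canonical), `n_units`, `deviation`,
#'   `left_flank_len`, `right_flank_len`.
#' @export
find_ssrs <- function(seq, motif_lens = 2:5, min_len = 30L, max_dev = 0.15,
                      min_flank = 30L, transcript_id = "seq") {
  s_chr <- as.character(seq)
  chars <- strsplit(s_chr, "", fixed = TRUE)[[1]]
  n <- length(chars)
  empty <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      n_units = numeric(0), deviation = numeric(0),
                      left_flank_len = integer(0), right_flank_len = integer(0),
                      stringsAsFactors = FALSE)
  if (n < min_len + 2L * min_flank) return(empty)
  calls <- list()
  for (k in motif_lens) {
    for (seg in period_candidates(chars, k)) {
      s0 <- seg[1]
      e0 <- seg[2] + k          # eq index i covers seq positions i .. i+k
      for (motif in extract_motif(chars, s0, e0, k)) {
      if (is.null(motif) || grepl("N", motif, fixed = TRUE)) next
      if (minimal_period(motif) < k || length(unique(strsplit(motif, "")[[1]])) == 1L) next
      w <- refine_window(chars, s0, e0, motif, max_dev,
                         max_jump = 3L * k + 10L, min_len = min_len)
      if (is.null(w)) next
      if (w[2] - w[1] + 1L < min_len) {
        # only near misses are worth the exhaustive fallback; short
        # spurious seeds from random background never come close
        if (w[2] - w[1] + 1L < min_len - 12L) next
        w <- complete_window(chars, w[1], w[2], motif,
                             max_dev, min_len, pad = min_len)
        if (is.null(w)) next
      }
      # flank bases that coincidentally continue the repeat can pull the
      # window edge slightly too close to a sequence end; retract small
      # overhangs (at most k+2 per side) to restore the flank requirement
      deficit_l <- min_flank - (w[1] - 1L)
      if (deficit_l > 0L && deficit_l <= k + 2L) w[1] <- w[1] + deficit_l
      deficit_r <- min_flank - (n - w[2])
      if (deficit_r > 0L && deficit_r <= k + 2L) w[2] <- w[2] - deficit_r
      len <- w[2] - w[1] + 1L
      left <- w[1] - 1L
      right <- n - w[2]
      if (len < min_len || left < min_flank || right < min_flank) next
      if (ssr_deviation(paste(chars[w[1]:w[2]], collapse = ""), motif) > max_dev) next
      calls[[length(calls) + 1L]] <- data.frame(
        transcript_id = transcript_id,
        start = w[1] - 1L, end = w[2],            # 0-based half-open
        motif = canonical_motif(motif),
        n_units = len / k,
        deviation = ssr_deviation(paste(chars[w[1]:w[2]], collapse = ""), motif),
        left_flank_len = left, right_flank_len = right,
        stringsAsFactors = FALSE)
      }
    }
  }
  if (length(calls) == 0L) return(empty)
  out <- unique(do.call(rbind, calls))
  merge_same_type(out)
}

# collapse overlapping calls of the same canonical motif to the longest
# window (ties: leftmost, then smallest deviation)
merge_same_type <- function(calls) {
  pieces <- lapply(split(calls, calls$motif), function(g) {
    g <- g[order(-(g$end - g$start), g$start, g$deviation), , drop = FALSE]
    kept <- g[0, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      overlaps <- nrow(kept) > 0L &&
        any(g$start[i] < kept$end & g$end[i] > kept$start)
      if (!overlaps) kept <- rbind(kept, g[i, , drop = FALSE])
    }
    kept
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$transcript_id, out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect SSRs across a set of transcripts
#'
#' @param transcripts named [Biostrings::DNAStringSet] or named character
#'   vector.
#' @inheritParams find_ssrs
#' @return row-bound [find_ssrs()] results for every transcript.
#' @export
find_ssrs_all <- function(transcripts, motif_lens = 2:5, min_len = 30L,
                          max_dev = 0.15, min_flank = 30L) {
  seqs <- as.character(transcripts)
  ids <- names(transcripts)
  out <- lapply(seq_along(seqs), function(i) {
    find_ssrs(seqs[[i]], motif_lens, min_len, max_dev, min_flank,
              transcript_id = ids[i] %||% as.character(i))
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- find_ssrs("", transcript_id = "x")[0, ]
  rownames(res) <- NULL
  res
}

#' Collapse redundant SSR loci within each repeat type
#'
#' Within each canonical motif ("repeat type"), transcripts connected by
#' near-identity hits collapse to one representative: the longest
#' transcript (ties broken by id). Loci of the same motif on unrelated
#' transcripts are all kept, and identical transcripts carrying different
#' motifs contribute one representative per repeat type.
#'
#' @param loci data.frame of loci from [find_ssrs_all()].
#' @param cross_hits hit table among locus-bearing transcripts (queries
#'   and subjects are transcript ids); may be empty.
#' @param transcript_lengths named numeric vector of transcript lengths.
#' @param id_min minimum fractional identity (`pident/100`) for two
#'   transcripts to count as redundant.
#' @return subset of `loci` on the representative transcripts.
#' @export
dereplicate_ssrs <- function(loci, cross_hits, transcript_lengths, id_min = 0.95) {
  if (nrow(loci) == 0L) return(loci)
  keep <- lapply(split(loci, loci$motif), function(g) {
    tids <- unique(g$transcript_id)
    h <- cross_hits[cross_hits$pident >= id_min * 100 &
                      cross_hits$qseqid %in% tids &
                      cross_hits$sseqid %in% tids &
                      cross_hits$qseqid != cross_hits$sseqid, , drop = FALSE]
    if (nrow(h) == 0L) return(g)
    gr <- igraph::graph_from_data_frame(
      h[, c("qseqid", "sseqid")], directed = FALSE,
      vertices = data.frame(name = tids))
    comp <- igraph::components(gr)$membership
    reps <- vapply(split(names(comp), comp), function(members) {
      lens <- transcript_lengths[members]
      members[order(-lens, members)][1]
    }, character(1))
    g[g$transcript_id %in% reps, , drop = FALSE]
  })
  out <- do.call(rbind, keep)
  out <- out[order(out$transcript_id, out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select a primer-design target region around an SSR locus
#'
#' Starting from the locus plus the minimum flank on each side, the window
#' grows symmetrically (one-sided once a transcript end is reached) until
#' its length falls in `len_range` and its GC fraction in `gc_range`; the
#' first qualifying window is returned. `NULL` when no window within the
#' transcript can satisfy both constraints.
#'
#' @param locus one row of a [find_ssrs()] result.
#' @param transcript the sequence the locus lies on.
#' @param len_range allowed target length range (bp, inclusive).
#' @param gc_range allowed GC fraction range (inclusive).
#' @param min_flank flank kept around the locus inside the target.
#' @return list with `region_start`, `region_end` (0-based half-open),
#'   `gc_fraction` and `primer3` (a Boulder-IO record ready for a primer
#'   design run), or `NULL`.
#' @export
select_primer_target <- function(locus, transcript, len_range = c(150L, 500L),
                                 gc_range = c(0.45, 0.65), min_flank = 30L) {
  seq <- as.character(transcript)
  n <- nchar(seq)
  if (n < len_range[1]) return(NULL)
  s <- max(1L, locus$start + 1L - min_flank)   # to 1-based inclusive
  e <- min(n, locus$end + min_flank)
  repeat {
    len <- e - s + 1L
    if (len >= len_range[1]) {
      gc <- gc_fraction(substr(seq, s, e))
      if (gc >= gc_range[1] && gc <= gc_range[2]) break
    }
    if (len > len_range[2]) return(NULL)
    grew <- FALSE
    if (s > 1L) { s <- s - 1L; grew <- TRUE }
    if (e < n) { e <- e + 1L; grew <- TRUE }
    if (!grew) {
      if (len >= len_range[1] && len <= len_range[2]) {
        gc <- gc_fraction(substr(seq, s, e))
        if (gc >= gc_range[1] && gc <= gc_range[2]) break
      }
      return(NULL)
    }
  }
  len <- e - s + 1L
  if (len > len_range[2]) return(NULL)
  gc <- gc_fraction(substr(seq, s, e))
  target_start_in_region <- locus$start + 1L - s + 1L   # 1-based within region
  rec <- paste0(
    "SEQUENCE_ID=", locus$transcript_id, "_", locus$motif, "_", locus$start, "\n",
    "SEQUENCE_TEMPLATE=", substr(seq, s, e), "\n",
    "SEQUENCE_TARGET=", target_start_in_region, ",", locus$end - locus$start, "\n",
    "PRIMER_PRODUCT_SIZE_RANGE=", len_range[1], "-", len_range[2], "\n",
    "=\n")
  list(region_start = s - 1L, region_end = e, gc_fraction = gc, primer3 = rec)
}

#' Select primer targets for a table of loci
#'
#' @param loci data.frame from [find_ssrs_all()] / [dereplicate_ssrs()].
#' @param transcripts named sequence set the loci refer to.
#' @inheritParams select_primer_target
#' @return data.frame of qualifying targets (`transcript_id`, `motif`,
#'   `locus_start`, `locus_end`, `region_start`, `region_end`,
#'   `gc_fraction`, `primer3`); loci without a qualifying window are
#'   dropped.
#' @export
select_primer_targets <- function(loci, transcripts, len_range = c(150L, 500L),
                                  gc_range = c(0.45, 0.65), min_flank = 30L) {
  seqs <- as.character(transcripts)
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    locus <- loci[i, , drop = FALSE]
    tgt <- select_primer_target(locus, seqs[[locus$transcript_id]],
                                len_range, gc_range, min_flank)
    if (is.null(tgt)) return(NULL)
    data.frame(transcript_id = locus$transcript_id, motif = locus$motif,
               locus_start = locus$start, locus_end = locus$end,
               region_start = tgt$region_start, region_end = tgt$region_end,
               gc_fraction = tgt$gc_fraction, primer3 = tgt$primer3,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(0), motif = character(0),
                      locus_start = integer(0), locus_end = integer(0),
                      region_start = integer(0), region_end = integer(0),
                      gc_fraction = numeric(0), primer3 = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
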