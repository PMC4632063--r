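# Synthetic holobiont data with planted truth.
#
# Every pipeline stage is testable without external databases: the
# generator emits multi-library transcript sets of known origin
# (host/symbiont/rRNA/mitochondrial/bacterial), spikes cross-library
# contaminant copies at controlled abundance ratios, fabricates the hit
# tables a homology search would have produced (consistent with the
# planted truth; optionally with sub-threshold decoys), plants imperfect
# SSR loci with controlled edit counts, and records everything in a truth
# table. Bit-scores are planted relative to the decision thresholds, not
# drawn from an alignment-score model.

#' Simulation configuration
#'
#' Defaults echo the study conditions this package targets: four
#' co-prepared libraries, two aposymbiotic (small dinoflagellate
#' fraction) and two symbiotic (large one), transcript lengths around
#' 1.4 kb, host and symbiont differing in GC content, and 50 spiked
#' contaminant clusters spanning fold ratios on both sides of the 10-fold
#' decision boundary.
#'
#' @param seed integer RNG seed.
#' @param libraries library labels.
#' @param n_host,n_symbiont,n_rrna,n_mito,n_bacterial,n_nomatch
#'   per-library transcript counts (recycled over libraries).
#' @param n_contaminants number of spiked cross-library contaminant
#'   clusters.
#' @param fold_ratio_set planted abundance fold ratios, cycled over
#'   clusters.
#' @param len_mean,len_sd,len_min transcript length distribution (bp).
#' @param gc_host,gc_symbiont GC fractions of host and symbiont
#'   background sequence.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       libraries = paste0("lib", 1:4),
                       n_host = 500L,
                       n_symbiont = c(25L, 25L, 300L, 300L),
                       n_rrna = 10L,
                       n_mito = 5L,
                       n_bacterial = 25L,
                       n_nomatch = 50L,
                       n_contaminants = 50L,
                       fold_ratio_set = c(2, 5, 10, 20, 100),
                       len_mean = 1400, len_sd = 600, len_min = 200L,
                       gc_host = 0.39, gc_symbiont = 0.51) {
  nl <- length(libraries)
  cfg <- list(seed = as.integer(seed), libraries = libraries,
              n_host = rep_len(n_host, nl),
              n_symbiont = rep_len(n_symbiont, nl),
              n_rrna = rep_len(n_rrna, nl),
              n_mito = rep_len(n_mito, nl),
              n_bacterial = rep_len(n_bacterial, nl),
              n_nomatch = rep_len(n_nomatch, nl),
              n_contaminants = as.integer(n_contaminants),
              fold_ratio_set = fold_ratio_set,
              len_mean = len_mean, len_sd = len_sd, len_min = as.integer(len_min),
              gc_host = gc_host, gc_symbiont = gc_symbiont)
  counts <- unlist(cfg[c("n_host", "n_symbiont", "n_rrna", "n_mito",
                         "n_bacterial", "n_nomatch", "n_contaminants")])
  stopifnot(all(counts >= 0), all(cfg$fold_ratio_set > 0), len_sd >= 0)
  class(cfg) <- "sim_config"
  cfg
}

random_seq <- function(len, gc = 0.4) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p), collapse = "")
}

NONSTOP_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

# host-like transcript: 5' UTR + long stop-free ORF + 3' UTR, so the
# ORF-based completeness metric is exercised meaningfully
random_host_seq <- function(len, gc) {
  orf_codons <- max(10L, floor(len * 0.6 / 3))
  orf <- paste(sample(NONSTOP_CODONS, orf_codons, replace = TRUE), collapse = "")
  rest <- len - nchar(orf)
  utr5 <- max(0L, floor(rest / 2))
  utr3 <- max(0L, rest - utr5)
  paste0(random_seq(utr5, gc), orf, random_seq(utr3, gc))
}

draw_lengths <- function(n, cfg) {
  pmax(cfg$len_min, as.integer(round(stats::rnorm(n, cfg$len_mean, cfg$len_sd))))
}

#' Simulate multi-library assemblies with planted origins and contaminants
#'
#' Deterministic for a fixed `cfg$seed`. Contaminant clusters copy a host
#' transcript from a source library verbatim into a recipient library;
#' both copies share a `cluster_id` in the truth table, and the planted
#' fold ratio cycles through `cfg$fold_ratio_set`.
#'
#' @param cfg a [sim_config()].
#' @return list with `assemblies` (named list of
#'   [Biostrings::DNAStringSet]) and `truth` (data.frame
#'   `transcript_id`, `library`, `true_origin`, `cluster_id`,
#'   `source_library`, `fold_ratio`).
#' @export
simulate_assemblies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  libs <- cfg$libraries
  assemblies <- list()
  truth_rows <- list()
  for (li in seq_along(libs)) {
    lib <- libs[li]
    classes <- c(rep("metazoan", cfg$n_host[li]),
                 rep("dinoflagellate", cfg$n_symbiont[li]),
                 rep("rRNA", cfg$n_rrna[li]),
                 rep("mtDNA", cfg$n_mito[li]),
                 rep("other_taxa", cfg$n_bacterial[li]),
                 rep("no_match", cfg$n_nomatch[li]))
    n <- length(classes)
    lens <- draw_lengths(n, cfg)
    seqs <- character(n)
    for (i in seq_len(n)) {
      seqs[i] <- switch(classes[i],
        metazoan = random_host_seq(lens[i], cfg$gc_host),
        dinoflagellate = random_seq(lens[i], cfg$gc_symbiont),
        random_seq(lens[i], cfg$gc_host))
    }
    ids <- sprintf("%s_t%05d", lib, seq_len(n))
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    assemblies[[lib]] <- x
    truth_rows[[lib]] <- data.frame(
      transcript_id = ids, library = lib, true_origin = classes,
      cluster_id = NA_character_, source_library = NA_character_,
      fold_ratio = NA_real_, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL

  # spike contaminant clusters: host transcripts copied verbatim across
  # libraries, each cluster carrying one planted fold ratio
  n_spike <- cfg$n_contaminants
  if (n_spike > 0L) {
    if (length(libs) < 2L) stop("contaminant spiking needs >= 2 libraries")
    ratios <- rep_len(cfg$fold_ratio_set, n_spike)
    spare <- lapply(libs, function(l) {
      ids <- truth$transcript_id[truth$library == l & truth$true_origin == "metazoan"]
      sample(ids, length(ids))
    })
    names(spare) <- libs
    used <- stats::setNames(rep(0L, length(libs)), libs)
    extra_truth <- list()
    for (ci in seq_len(n_spike)) {
      src <- libs[(ci - 1L) %% length(libs) + 1L]
      recip <- libs[ci %% length(libs) + 1L]
      used[src] <- used[src] + 1L
      if (used[src] > length(spare[[src]])) stop("not enough host transcripts to spike")
      src_tid <- spare[[src]][used[src]]
      cl <- sprintf("spike_%03d", ci)
      new_id <- sprintf("%s_x%04d", recip, ci)
      seq <- assemblies[[src]][[src_tid]]
      assemblies[[recip]] <- c(assemblies[[recip]],
                               stats::setNames(Biostrings::DNAStringSet(seq), new_id))
      truth$cluster_id[truth$transcript_id == src_tid] <- cl
      truth$source_library[truth$transcript_id == src_tid] <- src
      truth$fold_ratio[truth$transcript_id == src_tid] <- ratios[ci]
      extra_truth[[ci]] <- data.frame(
        transcript_id = new_id, library = recip, true_origin = "metazoan",
        cluster_id = cl, source_library = src, fold_ratio = ratios[ci],
        stringsAsFactors = FALSE)
    }
    truth <- rbind(truth, do.call(rbind, extra_truth))
    rownames(truth) <- NULL
  }
  list(assemblies = assemblies, truth = truth)
}

make_hits <- function(qid, sid, bitscore, qlen, slen, evalue = NULL,
                      sstart = NULL, send = NULL) {
  n <- length(qid)
  if (n == 0L) return(empty_hit_table())
  alen <- pmax(30L, as.integer(pmin(qlen, slen * 3) * 0.5))
  if (is.null(sstart)) sstart <- rep(1L, n)
  if (is.null(send)) send <- pmin(slen, sstart + pmax(10L, alen %/% 3))
  if (is.null(evalue)) evalue <- 10^-stats::runif(n, 10, 60)
  data.frame(qseqid = qid, sseqid = sid, pident = round(stats::runif(n, 75, 99), 2),
             length = alen, mismatch = as.integer(alen * 0.1), gapopen = 0L,
             qstart = 1L, qend = pmin(qlen, alen), sstart = sstart, send = send,
             evalue = evalue, bitscore = bitscore, qlen = qlen, slen = slen,
             stringsAsFactors = FALSE)
}

#' Fabricate per-database and cross-library hit tables from planted truth
#'
#' In noiseless mode each transcript receives hits only in the databases
#' consistent with its true origin, with scores planted above the
#' decision thresholds; adversarial mode adds sub-threshold decoy hits
#' (bit-score just under 45, E-values above the comprehensive-database
#' ceiling) that must not change any classification. Cross-library tables
#' contain exactly the planted contaminant pairs, at bit-scores well
#' above the near-identity cutoff.
#'
#' @param sim result of [simulate_assemblies()].
#' @param adversarial add decoy hits.
#' @return list with `db` (per-library list of `rrna`, `mito`, `host`,
#'   `symbiont`, `nr` hit tables; the `nr` table carries a `staxclass`
#'   column) and `cross` (data.frame with `qlib`, `slib` plus hit
#'   columns).
#' @export
simulate_hit_tables <- function(sim, adversarial = FALSE) {
  truth <- sim$truth
  lens <- unlist(lapply(sim$assemblies, function(x) {
    stats::setNames(Biostrings::width(x), names(x))
  }), use.names = TRUE)
  names(lens) <- sub("^[^.]*\\.", "", names(lens))
  db <- list()
  for (lib in names(sim$assemblies)) {
    tr <- truth[truth$library == lib, , drop = FALSE]
    ql <- as.integer(lens[tr$transcript_id])
    pick <- function(cls) tr$true_origin == cls
    n <- nrow(tr)
    rrna <- pick("rRNA")
    mito <- pick("mtDNA")
    met <- pick("metazoan")
    dino <- pick("dinoflagellate")
    bact <- pick("other_taxa")

    # metazoan: host score strictly above any symbiont score; the
    # comprehensive database says metazoan or stays silent
    host_bit <- stats::runif(n, 60, 300)
    symb_lower <- pmax(46, host_bit * stats::runif(n, 0.5, 0.8))
    met_secondary <- met & stats::runif(n) < 0.5
    met_nr <- met & stats::runif(n) < 0.8
    # dinoflagellate: mirror image
    symb_bit <- stats::runif(n, 60, 300)
    host_lower <- pmax(46, symb_bit * stats::runif(n, 0.5, 0.8))
    dino_secondary <- dino & stats::runif(n) < 0.5
    dino_nr <- dino & stats::runif(n) < 0.7

    host_tab <- rbind(
      make_hits(tr$transcript_id[met], "host_gene_model", host_bit[met],
                ql[met], 450L),
      make_hits(tr$transcript_id[dino_secondary], "host_gene_model",
                host_lower[dino_secondary], ql[dino_secondary], 450L))
    symb_tab <- rbind(
      make_hits(tr$transcript_id[dino], "symbiont_gene_model", symb_bit[dino],
                ql[dino], 450L),
      make_hits(tr$transcript_id[met_secondary], "symbiont_gene_model",
                symb_lower[met_secondary], ql[met_secondary], 450L))
    nr_met_ids <- tr$transcript_id[met_nr]
    nr_nonmet_ids <- tr$transcript_id[(dino_nr) | bact]
    nr_tab <- rbind(
      cbind(make_hits(nr_met_ids, "nr_metazoan_acc",
                      stats::runif(length(nr_met_ids), 60, 300),
                      ql[match(nr_met_ids, tr$transcript_id)], 450L),
            staxclass = rep("metazoan", length(nr_met_ids))),
      cbind(make_hits(nr_nonmet_ids, "nr_other_acc",
                      stats::runif(length(nr_nonmet_ids), 60, 300),
                      ql[match(nr_nonmet_ids, tr$transcript_id)], 450L),
            staxclass = rep("nonmetazoan", length(nr_nonmet_ids))))
    rrna_tab <- make_hits(tr$transcript_id[rrna], "ref_rRNA",
                          stats::runif(sum(rrna), 100, 400), ql[rrna], 1800L)
    mito_tab <- make_hits(tr$transcript_id[mito], "ref_mtgenome",
                          stats::runif(sum(mito), 100, 400), ql[mito], 18000L)

    if (adversarial) {
      decoy <- bact | pick("no_match")
      decoy_tab <- make_hits(tr$transcript_id[decoy], "host_gene_model",
                             stats::runif(sum(decoy), 30, 44.9), ql[decoy], 450L)
      host_tab <- rbind(host_tab, decoy_tab)
      nomatch <- pick("no_match")
      weak_nr <- cbind(make_hits(tr$transcript_id[nomatch], "nr_weak_acc",
                                 stats::runif(sum(nomatch), 46, 60),
                                 ql[nomatch], 450L,
                                 evalue = 10^-stats::runif(sum(nomatch), 1, 4.9)),
                       staxclass = rep("nonmetazoan", sum(nomatch)))
      nr_tab <- rbind(nr_tab, weak_nr)
    }
    db[[lib]] <- list(rrna = rrna_tab, mito = mito_tab, host = host_tab,
                      symbiont = symb_tab, nr = nr_tab)
  }

  spikes <- truth[!is.na(truth$cluster_id) &
                    truth$library != truth$source_library, , drop = FALSE]
  cross_rows <- lapply(seq_len(nrow(spikes)), function(i) {
    r <- spikes[i, ]
    src_tid <- truth$transcript_id[which(truth$cluster_id == r$cluster_id &
                                           truth$library == r$source_library)][1]
    ql <- as.integer(lens[src_tid])
    cbind(qlib = r$source_library, slib = r$library,
          make_hits(src_tid, r$transcript_id,
                    stats::runif(1, 200, 2000), ql, as.integer(lens[r$transcript_id]),
                    sstart = 1L, send = as.integer(lens[r$transcript_id])))
  })
  cross <- if (length(cross_rows)) do.call(rbind, cross_rows)
           else cbind(qlib = character(0), slib = character(0), empty_hit_table())
  rownames(cross) <- NULL
  list(db = db, cross = cross)
}

#' Simulate per-library abundance tables realizing the planted ratios
#'
#' Baseline abundances are log-normal and scaled to parts per million;
#' contaminant copies are then overwritten so that, in noiseless mode,
#' source / recipient equals the planted fold ratio exactly (one float
#' division). Noisy mode multiplies recipient copies by log-normal noise.
#'
#' @param sim result of [simulate_assemblies()].
#' @param noisy apply log-normal noise to contaminant copies.
#' @param noise_sd standard deviation of the noise on the log scale.
#' @return named list (by library) of named numeric abundance vectors.
#' @export
simulate_abundances <- function(sim, noisy = FALSE, noise_sd = 0.3) {
  truth <- sim$truth
  abund <- lapply(sim$assemblies, function(x) {
    v <- stats::rlnorm(length(x), meanlog = 3, sdlog = 1.2)
    normalize_per_million(stats::setNames(v, names(x)))
  })
  spikes <- truth[!is.na(truth$cluster_id) &
                    truth$library != truth$source_library, , drop = FALSE]
  for (i in seq_len(nrow(spikes))) {
    r <- spikes[i, ]
    src_tid <- truth$transcript_id[which(truth$cluster_id == r$cluster_id &
                                           truth$library == r$source_library)][1]
    val <- abund[[r$source_library]][[src_tid]] / r$fold_ratio
    if (noisy) val <- val * exp(stats::rnorm(1, 0, noise_sd))
    abund[[r$library]][[r$transcript_id]] <- val
  }
  abund
}

#' Plant imperfect SSR loci into transcripts
#'
#' Each specification row becomes one locus on its own transcript: a
#' perfect tandem array mutated by exactly `floor(deviation * length)`
#' substitutions. Edits model scattered point mutations: positions are
#' drawn with pairwise distance greater than the motif length (so no
#' motif copy takes two edits and adjacent copies are never rewritten
#' into a coherent different repeat type, which would make the planted
#' motif an incorrect description of the locus), and each replacement is
#' a uniform draw from the three other bases. The realized edit distance
#' to the perfect array is therefore at most, and typically equal to,
#' the planted edit count. Loci are never placed within `min_flank`
#' bases of either end; transcripts too short for the locus plus flanks
#' are skipped and logged.
#'
#' @param transcripts named [Biostrings::DNAStringSet] or named character
#'   vector (host transcripts).
#' @param ssr_spec data.frame with columns `motif`, `n_units`,
#'   `deviation`.
#' @param min_flank minimum distance from transcript ends (bp).
#' @return list with `transcripts` (modified set), `loci` (truth
#'   data.frame: `transcript_id`, `start`, `end` 0-based half-open,
#'   `motif` canonical, `motif_planted`, `n_units`, `deviation`,
#'   `k_edits`) and `skipped` (spec row indices that found no transcript).
#' @export
plant_ssrs <- function(transcripts, ssr_spec, min_flank = 30L) {
  ids <- names(transcripts)
  seqs <- stats::setNames(as.character(transcripts), ids)
  stopifnot(!is.null(ids), nrow(ssr_spec) <= length(ids))
  loci <- list()
  skipped <- integer(0)
  ti <- 0L
  for (i in seq_len(nrow(ssr_spec))) {
    motif <- as.character(ssr_spec$motif[i])
    k <- nchar(motif)
    arr_len <- as.integer(round(ssr_spec$n_units[i] * k))
    placed <- FALSE
    while (ti < length(ids)) {
      ti <- ti + 1L
      L <- nchar(seqs[[ti]])
      if (L < arr_len + 2L * min_flank + 2L) next
      arr <- tile_motif(motif, arr_len)
      k_edits <- floor(ssr_spec$deviation[i] * arr_len)
      if (k_edits > 0L) {
        gap <- k + 1L                        # min pairwise edit distance
        slack <- arr_len - (k_edits - 1L) * gap
        if (slack < 1L) stop("deviation too high to spread edits for motif ", motif)
        pos <- sort(sample(slack, k_edits)) + (seq_len(k_edits) - 1L) * gap
        ch <- strsplit(arr, "")[[1]]
        for (p in pos) {
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        }
        arr <- paste(ch, collapse = "")
      }
      start <- sample(seq(min_flank + 1L, L - min_flank - arr_len + 1L), 1)
      substr(seqs[[ti]], start, start + arr_len - 1L) <- arr
      loci[[length(loci) + 1L]] <- data.frame(
        transcript_id = ids[ti], start = start - 1L, end = start + arr_len - 1L,
        motif = canonical_motif(motif), motif_planted = motif,
        n_units = arr_len / k, deviation = ssr_spec$deviation[i],
        k_edits = k_edits, stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) skipped <- c(skipped, i)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  loci_df <- if (length(loci)) do.call(rbind, loci) else
    data.frame(transcript_id = character(0), start = integer(0), end = integer(0),
               motif = character(0), motif_planted = character(0),
               n_units = numeric(0), deviation = numeric(0), k_edits = integer(0),
               stringsAsFactors = FALSE)
  list(transcripts = out, loci = loci_df, skipped = skipped)
}

#' Simulate reference-gene hit tables for representation and completeness
#'
#' A synthetic reference gene set with known protein lengths; per library
#' a fraction of genes receives significant hits from host transcripts
#' (with subject intervals for coverage-based completeness), a small
#' fraction only sub-threshold hits, and the rest none.
#'
#' @param sim result of [simulate_assemblies()].
#' @param n_ref reference gene count.
#' @param p_rep probability a gene is represented in a library.
#' @param p_weak probability an unrepresented gene still gets a
#'   sub-threshold hit.
#' @return list with `ref_gene_ids`, `ref_protein_len` (named vector) and
#'   `hits` (per-library 14-column tables, reference genes as subjects).
#' @export
simulate_reference_hits <- function(sim, n_ref = 200L, p_rep = 0.6, p_weak = 0.15) {
  ref_ids <- sprintf("refg%04d", seq_len(n_ref))
  ref_len <- stats::setNames(
    pmax(100L, as.integer(round(stats::rnorm(n_ref, 450, 150)))), ref_ids)
  hits <- list()
  for (lib in names(sim$assemblies)) {
    x <- sim$assemblies[[lib]]
    host_ids <- sim$truth$transcript_id[sim$truth$library == lib &
                                          sim$truth$true_origin == "metazoan"]
    if (length(host_ids) == 0L) { hits[[lib]] <- empty_hit_table(); next }
    rows <- list()
    for (g in ref_ids) {
      u <- stats::runif(1)
      slen <- ref_len[[g]]
      if (u < p_rep) {
        tid <- sample(host_ids, 1)
        qlen <- Biostrings::width(x[tid])
        n_hsp <- sample(1:3, 1)
        s0 <- sort(sample(seq_len(max(1L, slen - 40L)), n_hsp))
        s1 <- pmin(slen, s0 + as.integer(stats::runif(n_hsp, 30, slen * 0.6)))
        rows[[length(rows) + 1L]] <- make_hits(
          rep(tid, n_hsp), rep(g, n_hsp), stats::runif(n_hsp, 55, 300),
          rep(qlen, n_hsp), rep(slen, n_hsp), sstart = s0, send = s1)
      } else if (u < p_rep + p_weak) {
        tid <- sample(host_ids, 1)
        qlen <- Biostrings::width(x[tid])
        rows[[length(rows) + 1L]] <- make_hits(
          tid, g, stats::runif(1, 20, 49.9), qlen, slen)
      }
    }
    hits[[lib]] <- if (length(rows)) do.call(rbind, rows) else empty_hit_table()
    rownames(hits[[lib]]) <- NULL
  }
  list(ref_gene_ids = ref_ids, ref_protein_len = ref_len, hits = hits)
}

#' Simulate random aligned ortholog groups
#'
#' @param n_groups number of groups.
#' @param taxa taxon pool.
#' @param width_range aligned width range (columns).
#' @param paralog_prob probability a group carries a second (shorter or
#'   longer) sequence for one of its taxa.
#' @param gap_prob per-position gap probability within a row.
#' @return list of [ortho_group()] with alignments.
#' @export
simulate_ortho_groups <- function(n_groups, taxa, width_range = c(60L, 400L),
                                  paralog_prob = 0.3, gap_prob = 0.1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lapply(seq_len(n_groups), function(i) {
    gid <- sprintf("g%04d", i)
    occ <- sample(seq(2L, length(taxa)), 1)
    gtaxa <- sort(sample(taxa, occ))
    w <- sample(seq(width_range[1], width_range[2]), 1)
    mk_row <- function() {
      ch <- sample(aa, w, replace = TRUE)
      ch[stats::runif(w) < gap_prob] <- "-"
      paste(ch, collapse = "")
    }
    members <- data.frame(taxon = gtaxa,
                          seq_id = paste0(gid, "_", gtaxa, "_1"),
                          stringsAsFactors = FALSE)
    aln <- stats::setNames(vapply(seq_len(occ), function(j) mk_row(), character(1)),
                           members$seq_id)
    if (stats::runif(1) < paralog_prob) {
      t2 <- sample(gtaxa, 1)
      sid2 <- paste0(gid, "_", t2, "_2")
      members <- rbind(members, data.frame(taxon = t2, seq_id = sid2,
                                           stringsAsFactors = FALSE))
      aln[sid2] <- mk_row()
    }
    members$length <- vapply(aln[members$seq_id],
                             function(s) sum(strsplit(s, "")[[1]] != "-"),
                             integer(1))
    ortho_group(gid, members, aln)
  })
}

#' Simulate paired reads with planted removal reasons
#'
#' @param n_clean,n_lowq,n_boundary,n_adapter,n_polya read-pair counts:
#'   clean; 21 positions below Q20 (removed); exactly 20 positions below
#'   Q20 (kept: the rule is "strictly more than"); adapter-bearing;
#'   poly-A-tailed.
#' @param read_len read length (bp).
#' @param adapter adapter sequence used for the adapter class.
#' @return list with `reads` (read-pair data.frame) and `truth`
#'   (data.frame `id`, `planted`, one of `clean`, `low_quality`,
#'   `boundary`, `adapter`, `polya`).
#' @export
simulate_read_pairs <- function(n_clean = 50L, n_lowq = 20L, n_boundary = 20L,
                                n_adapter = 10L, n_polya = 10L, read_len = 100L,
                                adapter = "AGATCGGAAGAGC") {
  good_q <- strrep(intToUtf8(33L + 30L), read_len)
  qual_with_low <- function(n_low) {
    q <- rep(intToUtf8(33L + 30L), read_len)
    q[sample(read_len, n_low)] <- intToUtf8(33L + 19L)
    paste(q, collapse = "")
  }
  mk <- function(n, planted, f_seq1, f_qual1) {
    if (n == 0L) return(NULL)
    data.frame(id = paste0(planted, "_", seq_len(n)),
               seq1 = vapply(seq_len(n), function(i) f_seq1(), character(1)),
               qual1 = vapply(seq_len(n), function(i) f_qual1(), character(1)),
               seq2 = vapply(seq_len(n), function(i) random_seq(read_len), character(1)),
               qual2 = good_q, planted = planted, stringsAsFactors = FALSE)
  }
  # clean reads must not contain the adapter or a long A/T run by chance
  clean_seq <- function() {
    repeat {
      s <- random_seq(read_len)
      if (!grepl(adapter, s, fixed = TRUE) &&
          !grepl(strrep("A", 20), s, fixed = TRUE) &&
          !grepl(strrep("T", 20), s, fixed = TRUE)) return(s)
    }
  }
  adapter_seq <- function() {
    s <- clean_seq()
    pos <- sample(read_len - nchar(adapter) + 1L, 1)
    substr(s, pos, pos + nchar(adapter) - 1L) <- adapter
    s
  }
  polya_seq <- function() {
    s <- clean_seq()
    pos <- sample(read_len - 20L + 1L, 1)
    substr(s, pos, pos + 19L) <- strrep("A", 20)
    s
  }
  all <- rbind(
    mk(n_clean, "clean", clean_seq, function() good_q),
    mk(n_lowq, "low_quality", clean_seq, function() qual_with_low(21L)),
    mk(n_boundary, "boundary", clean_seq, function() qual_with_low(20L)),
    mk(n_adapter, "adapter", adapter_seq, function() good_q),
    mk(n_polya, "polya", polya_seq, function() good_q))
  list(reads = all[, c("id", "seq1", "qual1", "seq2", "qual2")],
       truth = all[, c("id", "planted")])
}

#' One-call simulation of a full holobiont dataset
#'
#' Seeds the RNG from `cfg$seed` (via [simulate_assemblies()]) and draws
#' everything downstream from the same stream, so the whole bundle is
#' deterministic per seed.
#'
#' @param cfg a [sim_config()].
#' @param adversarial passed to [simulate_hit_tables()].
#' @param noisy_abund passed to [simulate_abundances()].
#' @return list with `cfg`, `assemblies`, `truth`, `hits`, `cross`,
#'   `abundances`, `ref`.
#' @export
simulate_holobiont <- function(cfg = sim_config(), adversarial = FALSE,
                               noisy_abund = FALSE) {
  sim <- simulate_assemblies(cfg)
  ht <- simulate_hit_tables(sim, adversarial = adversarial)
  ab <- simulate_abundances(sim, noisy = noisy_abund)
  ref <- simulate_reference_hits(sim)
  list(cfg = cfg, assemblies = sim$assemblies, truth = sim$truth,
       hits = ht$db, cross = ht$cross, abundances = ab, ref = ref)
}

#' Write a simulated dataset to disk in the pipeline's input layout
#'
#' @param sim result of [simulate_holobiont()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_simulation <- function(sim, dir) {
  for (d in file.path(dir, c("assemblies", "hits", "abund", "ref"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  for (lib in names(sim$assemblies)) {
    write_fasta(sim$assemblies[[lib]], file.path(dir, "assemblies", paste0(lib, ".fasta")))
    for (dbn in names(sim$hits[[lib]])) {
      tab <- sim$hits[[lib]][[dbn]]
      utils::write.table(tab, file.path(dir, "hits", paste0(lib, "_", dbn, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_abundance_table(sim$abundances[[lib]],
                          file.path(dir, "abund", paste0(lib, ".tsv")))
    utils::write.table(sim$ref$hits[[lib]],
                       file.path(dir, "ref", paste0("generep_", lib, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(sim$cross, file.path(dir, "hits", "cross.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = sim$ref$ref_gene_ids,
               protein_len = as.integer(sim$ref$ref_protein_len)),
    file.path(dir, "ref", "ref_genes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
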