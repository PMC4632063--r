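# Independent oracles used to cross-check the package's implementations.
# These are deliberately naive (per-position scans, textbook DP) and do
# not share code with the functions they verify.

# per-position subject coverage of a set of HSP intervals
oracle_coverage <- function(sstart, send, slen) {
  covered <- logical(slen)
  for (i in seq_along(sstart)) {
    lo <- min(sstart[i], send[i])
    hi <- max(sstart[i], send[i])
    covered[lo:hi] <- TRUE
  }
  sum(covered) / slen
}

# naive longest stop-free codon run: walk codon by codon, count runs
oracle_longest_orf <- function(seq, frame) {
  s <- if (frame < 0) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
  } else seq
  off <- abs(frame) - 1
  best <- 0L
  run <- 0L
  i <- off + 1
  while (i + 2 <= nchar(s)) {
    codon <- substr(s, i, i + 2)
    if (codon %in% c("TAA", "TAG", "TGA")) {
      run <- 0L
    } else {
      run <- run + 1L
      if (run > best) best <- run
    }
    i <- i + 3
  }
  best
}

# alternative N50: the largest observed length L such that contigs of
# length >= L hold at least half the total
oracle_n50 <- function(lengths, core_min = 1) {
  core <- lengths[lengths >= core_min]
  if (length(core) == 0) return(NA_real_)
  half <- sum(core) / 2
  cand <- sort(unique(core), decreasing = TRUE)
  for (L in cand) {
    if (sum(core[core >= L]) >= half) return(L)
  }
  min(core)
}

# textbook Levenshtein DP (full matrix)
oracle_edit_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
    }
  }
  d[n + 1, m + 1]
}

oracle_rotations <- function(m) {
  k <- nchar(m)
  vapply(seq_len(k), function(i) paste0(substr(m, i, k), substr(m, 1, i - 1)),
         character(1))
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# deviation oracle: min DP distance over all rotations of motif and its
# reverse complement, each tiled to the region length
oracle_deviation <- function(region, motif) {
  n <- nchar(region)
  phases <- unique(c(oracle_rotations(motif), oracle_rotations(oracle_revcomp(motif))))
  tiles <- vapply(phases, function(p) {
    substr(strrep(p, ceiling(n / nchar(p))), 1, n)
  }, character(1))
  min(vapply(tiles, oracle_edit_distance, numeric(1), a = region)) / n
}

# convenience constructor for hit-record rows
make_hit <- function(q = "t1", s = "g1", bit = 100, qstart = 1, qend = 50,
                     sstart = 1, send = 50, qlen = 1000, slen = 100,
                     evalue = 1e-20, pident = 95, stitle = NULL) {
  df <- data.frame(qseqid = q, sseqid = s, pident = pident,
                   length = abs(send - sstart) + 1, mismatch = 0, gapopen = 0,
                   qstart = qstart, qend = qend, sstart = sstart, send = send,
                   evalue = evalue, bitscore = bit, qlen = qlen, slen = slen,
                   stringsAsFactors = FALSE)
  if (!is.null(stitle)) df$stitle <- stitle
  df
}

# random nucleotide string
rand_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# evidence row from a truth-table fixture row
evidence_from_fixture <- function(row) {
  hs <- switch(row$hostsymb,
    lt = c(host = 60, symb = 80),
    gt = c(host = 80, symb = 60),
    tie = c(host = 70, symb = 70),
    host_only = c(host = 75, symb = NA),
    symb_only = c(host = NA, symb = 75),
    neither = c(host = NA, symb = NA))
  data.frame(
    rrna = if (row$rrna == "yes") 200 else NA_real_,
    mito = if (row$mito == "yes") 150 else NA_real_,
    host = unname(hs["host"]),
    symbiont = unname(hs["symb"]),
    nr_class = if (row$nr == "absent") NA_character_ else row$nr,
    stringsAsFactors = FALSE)
}
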