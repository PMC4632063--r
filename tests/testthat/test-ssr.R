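# substitute `k` positions of a perfect array with bases foreign to the
# motif alphabet; the edit distance to the array is then exactly `k`
mutate_array <- function(arr, motif, k, seed) {
  set.seed(seed)
  foreign <- setdiff(c("A", "C", "G", "T"), unique(strsplit(motif, "")[[1]]))
  stopifnot(length(foreign) > 0)
  ch <- strsplit(arr, "")[[1]]
  pos <- sample(length(ch), k)
  ch[pos] <- sample(foreign, k, replace = TRUE)
  paste(ch, collapse = "")
}

test_that("canonical motifs minimize over rotations and strand", {
  expect_equal(canonical_motif("TG"), "AC")
  expect_equal(canonical_motif("AT"), "AT")
  expect_equal(canonical_motif("GGC"), "CCG")
  expect_equal(canonical_motif(c("CA", "AC", "GT", "TG")),
               rep("AC", 4))
})

test_that("deviation equals the independent DP oracle", {
  set.seed(9)
  motifs <- c("AT", "ACG", "AAGG", "ACGTC")
  for (m in motifs) {
    for (i in 1:10) {
      region <- rand_seq(sample(20:60, 1))
      expect_equal(ssr_deviation(region, m), oracle_deviation(region, m),
                   tolerance = 1e-12)
    }
    arr <- strrep(m, 12)
    expect_equal(ssr_deviation(arr, m), 0)
  }
})

test_that("perfect repeats at the thresholds are called or rejected correctly", {
  flank <- function(n, seed) { set.seed(seed); rand_seq(n) }
  # (AT) x 20 with 50 bp flanks: one locus, zero deviation
  s <- paste0(flank(50, 1), strrep("AT", 20), flank(50, 2))
  calls <- find_ssrs(s, transcript_id = "t")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$motif, "AT")
  expect_equal(calls$deviation, 0)
  expect_lte(calls$start, 50)
  expect_gte(calls$end, 90)

  # 28 bp repeat: below the 30 bp minimum (flanks chosen so they cannot
  # accidentally continue the array)
  s28 <- paste0(flank(57, 3), "CCC", strrep("AT", 14), "CCC", flank(57, 4))
  expect_equal(nrow(find_ssrs(s28)), 0L)

  # 20 bp left flank: rejected
  sflank <- paste0(flank(20, 5), strrep("AT", 20), flank(60, 6))
  expect_equal(nrow(find_ssrs(sflank)), 0L)

  # homopolymer runs are not SSRs
  shomo <- paste0(flank(60, 7), strrep("A", 40), flank(60, 8))
  expect_equal(nrow(find_ssrs(shomo)), 0L)
})

test_that("the deviation bound separates callable from uncallable regions", {
  flankL <- rand_seq(60)
  flankR <- rand_seq(60)
  arr <- strrep("AT", 20)                    # 40 bp perfect array
  ok <- mutate_array(arr, "AT", 5, seed = 10)      # deviation 0.125
  bad <- mutate_array(arr, "AT", 7, seed = 11)     # deviation 0.175
  expect_equal(oracle_deviation(ok, "AT"), 5 / 40)
  expect_equal(oracle_deviation(bad, "AT"), 7 / 40)
  calls_ok <- find_ssrs(paste0(flankL, ok, flankR))
  expect_true(any(calls_ok$motif == "AT" &
                    calls_ok$start < 100 & calls_ok$end > 60))
  calls_bad <- find_ssrs(paste0(flankL, bad, flankR))
  # no call may cover the over-mutated array at full length; any call that
  # slips through must itself re-verify the deviation bound
  if (nrow(calls_bad)) {
    for (i in seq_len(nrow(calls_bad))) {
      region <- substr(paste0(flankL, bad, flankR),
                       calls_bad$start[i] + 1, calls_bad$end[i])
      expect_lte(oracle_deviation(region, calls_bad$motif[i]), 0.15)
      expect_lt(calls_bad$end[i] - calls_bad$start[i], 40)
    }
  }
})

test_that("planted loci are recovered and every call re-verifies its invariants", {
  set.seed(123)
  n_loci <- 24
  motifs <- c("AT", "AC", "ACG", "AGC", "AAGG", "ACGT", "AACCG")
  spec <- data.frame(
    motif = rep_len(motifs, n_loci),
    n_units = rep_len(c(20, 22, 13, 14, 10, 10, 8), n_loci),
    deviation = rep_len(c(0, 0.05, 0.1, 0.15), n_loci),
    stringsAsFactors = FALSE)
  tr <- stats::setNames(vapply(seq_len(n_loci), function(i) rand_seq(600),
                               character(1)), paste0("t", seq_len(n_loci)))
  planted <- plant_ssrs(tr, spec)
  expect_equal(nrow(planted$loci), n_loci)
  calls <- find_ssrs_all(planted$transcripts)
  seqs <- as.character(planted$transcripts)
  for (i in seq_len(n_loci)) {
    p <- planted$loci[i, ]
    hit <- calls[calls$transcript_id == p$transcript_id &
                   calls$motif == p$motif &
                   calls$start < p$end & calls$end > p$start, ]
    expect_gte(nrow(hit), 1L)
  }
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    region <- substr(seqs[[cl$transcript_id]], cl$start + 1, cl$end)
    expect_gte(nchar(region), 30L)
    expect_lte(oracle_deviation(region, cl$motif), 0.15)
    expect_gte(cl$left_flank_len, 30L)
    expect_gte(cl$right_flank_len, 30L)
  }
})

test_that("detection is reverse-complement invariant", {
  set.seed(321)
  spec <- data.frame(motif = c("AC", "AGG", "AAGG"), n_units = c(18, 12, 9),
                     deviation = c(0, 0.1, 0.1), stringsAsFactors = FALSE)
  tr <- stats::setNames(vapply(1:3, function(i) rand_seq(500), character(1)),
                        paste0("t", 1:3))
  planted <- plant_ssrs(tr, spec)
  fwd <- find_ssrs_all(planted$transcripts)
  rc <- stats::setNames(revcomp(as.character(planted$transcripts)),
                        names(planted$transcripts))
  bwd <- find_ssrs_all(rc)
  n <- nchar(as.character(planted$transcripts))
  names(n) <- names(planted$transcripts)
  mirrored <- data.frame(transcript_id = bwd$transcript_id,
                         start = n[bwd$transcript_id] - bwd$end,
                         end = n[bwd$transcript_id] - bwd$start,
                         motif = bwd$motif, stringsAsFactors = FALSE)
  key <- function(df) {
    k <- paste(df$transcript_id, df$start, df$end, df$motif)
    sort(k)
  }
  expect_equal(key(fwd), key(mirrored))
})

test_that("redundant loci collapse within repeat types only", {
  loci <- data.frame(
    transcript_id = c("a", "b", "c", "a2"),
    start = c(50, 50, 50, 50), end = c(90, 90, 90, 90),
    motif = c("AC", "AC", "AC", "AAG"),
    n_units = 20, deviation = 0, left_flank_len = 50, right_flank_len = 50,
    stringsAsFactors = FALSE)
  lens <- c(a = 500, b = 600, c = 400, a2 = 500)
  # a and b are near-identical; c unrelated; a2 identical to a but a
  # different repeat type
  hits <- rbind(make_hit(q = "a", s = "b", bit = 500, pident = 99),
                make_hit(q = "a", s = "a2", bit = 500, pident = 100))
  derep <- dereplicate_ssrs(loci, hits, lens)
  expect_setequal(derep$transcript_id[derep$motif == "AC"], c("b", "c"))
  expect_true("a2" %in% derep$transcript_id)   # grouping is per repeat type
  # below the identity cutoff: both kept
  weak <- make_hit(q = "a", s = "b", bit = 500, pident = 90)
  expect_equal(sort(dereplicate_ssrs(loci, weak, lens)$transcript_id),
               sort(loci$transcript_id))
})

test_that("primer-target selection honors length and GC constraints", {
  set.seed(77)
  # 600 bp transcript near 50% GC with a centered perfect repeat
  s <- paste0(rand_seq(280, gc = 0.5), strrep("AT", 20), rand_seq(280, gc = 0.58))
  loci <- find_ssrs(s, transcript_id = "t1")
  expect_gte(nrow(loci), 1L)
  tgt <- select_primer_target(loci[1, ], s)
  expect_false(is.null(tgt))
  len <- tgt$region_end - tgt$region_start
  expect_gte(len, 150)
  expect_lte(len, 500)
  expect_gte(tgt$gc_fraction, 0.45)
  expect_lte(tgt$gc_fraction, 0.65)
  expect_lte(tgt$region_start, loci$start[1])
  expect_gte(tgt$region_end, loci$end[1])
  expect_match(tgt$primer3, "SEQUENCE_TEMPLATE=")

  # transcript too short for the minimum product size
  short <- loci[1, ]; short$start <- 40; short$end <- 80
  expect_null(select_primer_target(short, substr(s, 1, 120)))

  # GC far out of range everywhere
  gc_rich <- paste0(strrep("G", 200), strrep("AT", 20), strrep("C", 200))
  l2 <- data.frame(transcript_id = "t2", start = 200, end = 240, motif = "AT",
                   n_units = 20, deviation = 0, left_flank_len = 200,
                   right_flank_len = 200, stringsAsFactors = FALSE)
  expect_null(select_primer_target(l2, gc_rich))
})
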