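mk_group <- function(gid, taxa, lens, widths = NULL, seq_ids = NULL) {
  if (is.null(seq_ids)) seq_ids <- paste0(gid, "_", taxa, "_", seq_along(taxa))
  members <- data.frame(taxon = taxa, seq_id = seq_ids, length = lens,
                        stringsAsFactors = FALSE)
  aln <- NULL
  if (!is.null(widths)) {
    aln <- stats::setNames(
      vapply(seq_along(taxa), function(i) strrep("K", widths), character(1)),
      seq_ids)
  }
  ortho_group(gid, members, aln)
}

test_that("pruning keeps the longest sequence per taxon with documented ties", {
  g <- ortho_group("g1", data.frame(
    taxon = c("A", "A", "B"), seq_id = c("a1", "a2", "b1"),
    length = c(120, 300, 80), stringsAsFactors = FALSE))
  p <- prune_longest_per_taxon(g)
  expect_equal(p$members$seq_id, c("a2", "b1"))

  # already one per taxon: unchanged membership
  p2 <- prune_longest_per_taxon(p)
  expect_equal(p2$members, p$members)

  # length tie: lexicographically first id
  gt <- ortho_group("g2", data.frame(
    taxon = c("A", "A"), seq_id = c("zz", "aa"), length = c(150, 150),
    stringsAsFactors = FALSE))
  expect_equal(prune_longest_per_taxon(gt)$members$seq_id, "aa")
})

test_that("occupancy filtering applies length and taxon thresholds", {
  taxa15 <- paste0("T", 1:15)
  g13 <- mk_group("g1", taxa15[1:13], rep(200, 13))
  expect_length(filter_groups(list(g13), min_taxa = 14, total_taxa = 15), 0L)
  expect_length(filter_groups(list(g13), min_taxa = 10, total_taxa = 15), 1L)

  # a 99 aa member is removed before occupancy counting
  g_short <- mk_group("g2", c("A", "B", "C"), c(99, 200, 200))
  kept <- filter_groups(list(g_short), min_taxa = 3, total_taxa = 15)
  expect_length(kept, 0L)
  kept2 <- filter_groups(list(g_short), min_taxa = 2, total_taxa = 15)
  expect_equal(nrow(kept2[[1]]$members), 2L)
  # 100 aa survives (inclusive boundary)
  g_edge <- mk_group("g3", c("A", "B"), c(100, 150))
  expect_length(filter_groups(list(g_edge), min_taxa = 2, total_taxa = 15), 1L)

  expect_error(filter_groups(list(g13), min_taxa = 16, total_taxa = 15),
               "exceeds")
})

test_that("occupancy filter equals brute force and is monotone in min_taxa", {
  set.seed(71)
  taxa <- paste0("T", 1:15)
  groups <- simulate_ortho_groups(50, taxa)
  groups <- lapply(groups, prune_longest_per_taxon)
  brute <- function(min_taxa) {
    keep <- vapply(groups, function(g) {
      m <- g$members[g$members$length >= 100, , drop = FALSE]
      length(unique(m$taxon)) >= min_taxa
    }, logical(1))
    vapply(groups[keep], `[[`, character(1), "group_id")
  }
  ids <- function(gs) vapply(gs, `[[`, character(1), "group_id")
  for (mt in c(10, 14)) {
    expect_equal(ids(filter_groups(groups, min_taxa = mt, total_taxa = 15)),
                 brute(mt))
  }
  # monotone: relaxing the threshold never loses groups
  for (t1 in c(2, 5, 10)) {
    for (t2 in c(11, 14)) {
      expect_true(all(ids(filter_groups(groups, min_taxa = t2, total_taxa = 15)) %in%
                        ids(filter_groups(groups, min_taxa = t1, total_taxa = 15))))
    }
  }
})

test_that("concatenation builds a gap-filled partitioned matrix", {
  g1 <- mk_group("g1", c("A", "B", "C"), c(10, 10, 10), widths = 10)
  g2 <- mk_group("g2", c("A", "C"), c(20, 20), widths = 20)
  sm <- concatenate_groups(list(g2, g1))     # order by group_id, not input
  expect_equal(sm$taxa, c("A", "B", "C"))
  expect_equal(unname(nchar(sm$matrix)), rep(30L, 3))
  expect_equal(sm$partitions$start, c(1L, 11L))
  expect_equal(sm$partitions$end, c(10L, 30L))
  # taxon B missing from g2: all-gap block over columns 11-30
  expect_equal(substr(sm$matrix[["B"]], 11, 30), strrep("-", 20))
  expect_equal(substr(sm$matrix[["B"]], 1, 10), strrep("K", 10))

  # unequal aligned widths within a group are rejected
  bad <- mk_group("g3", c("A", "B"), c(5, 5), widths = 10)
  bad$alignment[[1]] <- "KKK"
  expect_error(concatenate_groups(list(bad)), "unequal")
})

test_that("random supermatrices conserve widths and row lengths", {
  set.seed(72)
  taxa <- paste0("T", 1:8)
  groups <- lapply(simulate_ortho_groups(40, taxa), prune_longest_per_taxon)
  sm <- concatenate_groups(groups)
  widths <- vapply(groups, function(g) nchar(g$alignment[[1]]), integer(1))
  expect_equal(length(unique(nchar(sm$matrix))), 1L)
  expect_equal(unname(nchar(sm$matrix[[1]])), sum(widths))
  expect_equal(sum(sm$partitions$end - sm$partitions$start + 1L), sum(widths))
  # content is independent of input group order
  sm2 <- concatenate_groups(rev(groups))
  expect_equal(sm$matrix, sm2$matrix)
  expect_equal(sm$partitions, sm2$partitions)
})

test_that("supermatrix and partition files round trip through FASTA", {
  g1 <- mk_group("g1", c("A", "B"), c(10, 10), widths = 10)
  g2 <- mk_group("g2", "A", 8, widths = 8)
  sm <- concatenate_groups(list(g1, g2), model = "WAG")
  fa <- withr::local_tempfile(fileext = ".fasta")
  pt <- withr::local_tempfile(fileext = ".txt")
  write_supermatrix(sm, fa)
  write_partitions(sm, pt)
  back <- Biostrings::readAAStringSet(fa)
  expect_equal(as.character(back), sm$matrix)
  expect_equal(readLines(pt), c("WAG, g1 = 1-10", "WAG, g2 = 11-18"))
})

test_that("shared ortholog counts enumerate taxon supersets", {
  gs <- list(mk_group("g1", c("A", "B"), c(100, 100)),
             mk_group("g2", c("A", "B", "C"), c(100, 100, 100)),
             mk_group("g3", "A", 100))
  expect_equal(unname(shared_ortholog_counts(gs, list(c("A", "B")))), 2L)
  expect_equal(unname(shared_ortholog_counts(gs, list(character(0)))), 3L)
  expect_equal(unname(shared_ortholog_counts(gs, list("C"), taxa = c("A", "B", "C", "D"))),
               1L)
  expect_equal(unname(shared_ortholog_counts(gs, list("D"), taxa = c("A", "B", "C", "D"))),
               0L)
  expect_error(shared_ortholog_counts(gs, list("Z")), "unknown taxon")
})

test_that("group membership and alignments round trip through files", {
  g1 <- mk_group("g1", c("A", "B"), c(10, 12), widths = 10)
  d <- withr::local_tempdir()
  members <- file.path(d, "members.tsv")
  aln_fa <- file.path(d, "g1.fasta")
  write_group_members(list(g1), members)
  writeLines(as.vector(rbind(paste0(">", names(g1$alignment)), g1$alignment)), aln_fa)
  back <- read_ortho_groups(members, c(g1 = aln_fa))
  expect_equal(back[[1]]$members, g1$members)
  expect_equal(back[[1]]$alignment, g1$alignment)
})
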