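cross_row <- function(qlib, slib, q, s, bit) {
  cbind(qlib = qlib, slib = slib, make_hit(q = q, s = s, bit = bit))
}

abund_tabs <- function(...) {
  lapply(list(...), function(x) x)
}

test_that("near-identity graph applies the inclusive bit-score cutoff", {
  g <- build_cross_graph(cross_row("A", "B", "t1", "t9", 250))
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::vcount(g), 2L)

  g0 <- build_cross_graph(cross_row("A", "B", "t1", "t9", 99.9))
  expect_equal(igraph::ecount(g0), 0L)

  # reciprocal hits collapse to one undirected edge
  g2 <- build_cross_graph(rbind(cross_row("A", "B", "t1", "t9", 250),
                                cross_row("B", "A", "t9", "t1", 260)))
  expect_equal(igraph::ecount(g2), 1L)

  expect_error(build_cross_graph(cross_row("A", "A", "t1", "t2", 500)),
               "within-library")
})

test_that("cluster verdicts follow the 10-fold rule with inclusive boundary", {
  g <- build_cross_graph(cross_row("A", "B", "t1", "t9", 250))
  decide <- function(a, b, fold_min = 10) {
    screen_cross_contamination(g, list(A = c(t1 = a), B = c(t9 = b)), fold_min)
  }
  v <- decide(100, 5)
  expect_true(all(v$status == "assigned"))
  expect_equal(unique(v$source_library), "A")
  expect_equal(unique(v$fold_ratio), 20)

  expect_true(all(decide(30, 6)$status == "unknown_origin"))   # ratio 5
  expect_true(all(decide(50, 5)$status == "assigned"))         # exactly 10
  # ratio realized through a float division still counts as 10-fold
  src <- 37.91
  expect_true(all(decide(src, src / 10)$status == "assigned"))

  inf <- decide(50, 0)
  expect_true(all(inf$status == "assigned"))
  expect_equal(unique(inf$fold_ratio), Inf)
  # both zero: undecidable
  expect_true(all(decide(0, 0)$status == "unknown_origin"))
  # missing abundance entries count as zero
  v0 <- screen_cross_contamination(g, list(A = c(t1 = 50)), 10)
  expect_true(all(v0$status == "assigned"))
})

test_that("within-library components become logged singletons", {
  g <- igraph::make_graph(c("A\x1ft1", "A\x1ft2"), directed = FALSE)
  igraph::V(g)$library <- c("A", "A")
  igraph::V(g)$transcript_id <- c("t1", "t2")
  v <- screen_cross_contamination(g, list(A = c(t1 = 5, t2 = 9)))
  expect_true(all(v$status == "singleton"))
})

test_that("verdict application conserves transcripts and removes the right copies", {
  mk_asm <- function(ids) {
    x <- Biostrings::DNAStringSet(stats::setNames(rep("ACGTACGT", length(ids)), ids))
    x
  }
  assemblies <- list(A = mk_asm(c("t1", "t2")), B = mk_asm(c("t9", "t8")))
  g <- build_cross_graph(cross_row("A", "B", "t1", "t9", 250))
  v <- screen_cross_contamination(g, list(A = c(t1 = 100), B = c(t9 = 5)))
  res <- apply_verdicts(assemblies, v)
  expect_equal(names(res$assemblies$A), c("t1", "t2"))
  expect_equal(names(res$assemblies$B), "t8")     # recipient copy removed
  expect_equal(nrow(res$report), 1L)
  n_in <- sum(lengths(assemblies))
  n_out <- sum(lengths(res$assemblies))
  expect_equal(n_out + nrow(res$report), n_in)

  # unknown-origin clusters are removed everywhere
  v2 <- screen_cross_contamination(g, list(A = c(t1 = 30), B = c(t9 = 6)))
  res2 <- apply_verdicts(assemblies, v2)
  expect_equal(names(res2$assemblies$A), "t2")
  expect_equal(names(res2$assemblies$B), "t8")
  expect_equal(nrow(res2$report), 2L)

  # no cross matches: identity
  res3 <- apply_verdicts(assemblies, v[0, ])
  expect_equal(res3$assemblies, assemblies)
})

test_that("planted contaminant clusters are recovered across the ratio range", {
  cfg <- sim_config(seed = 33, libraries = paste0("L", 1:4),
                    n_host = 100, n_symbiont = 10, n_rrna = 2, n_mito = 1,
                    n_bacterial = 5, n_nomatch = 5, n_contaminants = 25)
  sim <- simulate_holobiont(cfg)
  g <- build_cross_graph(sim$cross)
  v <- screen_cross_contamination(g, sim$abundances)
  spikes <- sim$truth[!is.na(sim$truth$cluster_id), ]
  for (cl in split(spikes, spikes$cluster_id)) {
    vv <- v[v$transcript_id %in% cl$transcript_id, ]
    expect_equal(nrow(vv), nrow(cl))
    if (cl$fold_ratio[1] >= 10) {
      expect_true(all(vv$status == "assigned"))
      expect_equal(unique(vv$source_library), cl$source_library[1])
    } else {
      expect_true(all(vv$status == "unknown_origin"))
    }
  }
})

test_that("verdicts are invariant under library relabeling and row order", {
  set.seed(88)
  hits <- rbind(cross_row("A", "B", "t1", "u1", 300),
                cross_row("B", "C", "u1", "v1", 200),
                cross_row("A", "C", "t2", "v2", 150))
  ab <- list(A = c(t1 = 100, t2 = 3), B = c(u1 = 4), C = c(v1 = 2, v2 = 50))
  v1 <- screen_cross_contamination(build_cross_graph(hits), ab)
  v1s <- v1[order(v1$library, v1$transcript_id), c("library", "transcript_id",
                                                   "status", "source_library")]
  hits2 <- hits[sample(nrow(hits)), ]
  relabel <- c(A = "Z", B = "Y", C = "X")
  hits2$qlib <- unname(relabel[hits2$qlib])
  hits2$slib <- unname(relabel[hits2$slib])
  ab2 <- stats::setNames(ab, unname(relabel[names(ab)]))
  v2 <- screen_cross_contamination(build_cross_graph(hits2), ab2)
  v2$library <- names(relabel)[match(v2$library, relabel)]
  v2$source_library <- names(relabel)[match(v2$source_library, relabel)]
  v2s <- v2[order(v2$library, v2$transcript_id), c("library", "transcript_id",
                                                   "status", "source_library")]
  rownames(v1s) <- rownames(v2s) <- NULL
  expect_equal(v1s, v2s)
})
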