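small_cfg <- function(seed = 5) {
  sim_config(seed = seed, libraries = paste0("lib", 1:3),
             n_host = 60, n_symbiont = c(5, 5, 30), n_rrna = 3, n_mito = 2,
             n_bacterial = 5, n_nomatch = 5, n_contaminants = 12)
}

test_that("simulation is byte-identical for a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  save_simulation(simulate_holobiont(small_cfg()), d1)
  save_simulation(simulate_holobiont(small_cfg()), d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  save_simulation(simulate_holobiont(small_cfg(seed = 6)), d3)
  expect_false(identical(readLines(file.path(d1, "assemblies", "lib1.fasta")),
                         readLines(file.path(d3, "assemblies", "lib1.fasta"))))
})

test_that("truth-table bookkeeping matches the configuration", {
  cfg <- small_cfg()
  sim <- simulate_assemblies(cfg)
  per_lib <- cfg$n_host + cfg$n_symbiont + cfg$n_rrna + cfg$n_mito +
    cfg$n_bacterial + cfg$n_nomatch
  expect_equal(nrow(sim$truth), sum(per_lib) + cfg$n_contaminants)
  expect_equal(sum(lengths(sim$assemblies)), nrow(sim$truth))
  # exactly one truth row per generated transcript
  expect_false(anyDuplicated(sim$truth$transcript_id) > 0)
  spikes <- sim$truth[!is.na(sim$truth$cluster_id), ]
  expect_equal(length(unique(spikes$cluster_id)), cfg$n_contaminants)
  # every cluster has a source row and a recipient row
  for (cl in split(spikes, spikes$cluster_id)) {
    expect_equal(nrow(cl), 2L)
    expect_equal(sum(cl$library == cl$source_library[1]), 1L)
  }
})

test_that("transcript lengths follow the configured distribution", {
  cfg <- sim_config(seed = 9, libraries = "L", n_host = 10000, n_symbiont = 0,
                    n_rrna = 0, n_mito = 0, n_bacterial = 0, n_nomatch = 0,
                    n_contaminants = 0, len_mean = 1400, len_sd = 600)
  sim <- simulate_assemblies(cfg)
  lens <- Biostrings::width(sim$assemblies$L)
  # truncation at len_min shifts the mean up slightly; 3 SE around the
  # truncated-normal mean computed by simple numeric integration
  se <- stats::sd(lens) / sqrt(length(lens))
  mu_trunc <- {
    f <- function(x) x * stats::dnorm(x, 1400, 600)
    lower <- cfg$len_min
    (stats::integrate(f, lower, Inf)$value +
       lower * stats::pnorm(lower, 1400, 600)) /
      1
  }
  expect_lt(abs(mean(lens) - mu_trunc), 3 * se + 1)  # +1 bp for rounding
})

test_that("hit tables are consistent with planted origins", {
  sim <- simulate_assemblies(small_cfg())
  ht <- simulate_hit_tables(sim)
  for (lib in names(sim$assemblies)) {
    tr <- sim$truth[sim$truth$library == lib, ]
    rrna_ids <- tr$transcript_id[tr$true_origin == "rRNA"]
    expect_setequal(unique(ht$db[[lib]]$rrna$qseqid), rrna_ids)
    expect_true(all(ht$db[[lib]]$rrna$bitscore >= 45))
    nomatch <- tr$transcript_id[tr$true_origin == "no_match"]
    for (tab in ht$db[[lib]]) expect_false(any(nomatch %in% tab$qseqid))
  }
  # cross-library table contains exactly the planted contaminant pairs
  spikes <- sim$truth[!is.na(sim$truth$cluster_id) &
                        sim$truth$library != sim$truth$source_library, ]
  expect_setequal(ht$cross$sseqid, spikes$transcript_id)
  expect_true(all(ht$cross$bitscore >= 100))
})

test_that("adversarial decoys change no classification", {
  sim <- simulate_assemblies(small_cfg())
  clean <- simulate_hit_tables(sim)
  adv <- simulate_hit_tables(sim, adversarial = TRUE)
  for (lib in names(sim$assemblies)) {
    classify_with <- function(db) {
      classify_assembly(names(sim$assemblies[[lib]]), db$rrna, db$mito,
                        db$host, db$symbiont, db$nr)$calls$category
    }
    expect_equal(classify_with(adv$db[[lib]]), classify_with(clean$db[[lib]]))
  }
})

test_that("abundances realize planted fold ratios after normalization", {
  sim <- simulate_assemblies(small_cfg())
  ab <- simulate_abundances(sim)
  for (lib in names(ab)) {
    expect_true(all(ab[[lib]] >= 0))
    # overwriting spiked copies after scaling moves sums a little off 1e6
    expect_equal(sum(ab[[lib]]), 1e6, tolerance = 0.1)
  }
  spikes <- sim$truth[!is.na(sim$truth$cluster_id) &
                        sim$truth$library != sim$truth$source_library, ]
  for (i in seq_len(nrow(spikes))) {
    r <- spikes[i, ]
    src_tid <- sim$truth$transcript_id[which(sim$truth$cluster_id == r$cluster_id &
                                               sim$truth$library == r$source_library)]
    ratio <- ab[[r$source_library]][[src_tid]] / ab[[r$library]][[r$transcript_id]]
    expect_equal(ratio, r$fold_ratio)
  }
})

test_that("noisy abundances still separate well-spaced ratios", {
  set.seed(14)
  cfg <- sim_config(seed = 14, libraries = paste0("lib", 1:4),
                    n_host = 150, n_symbiont = 5, n_rrna = 0, n_mito = 0,
                    n_bacterial = 0, n_nomatch = 0, n_contaminants = 40,
                    fold_ratio_set = 100)
  sim <- simulate_assemblies(cfg)
  ht <- simulate_hit_tables(sim)
  ab <- simulate_abundances(sim, noisy = TRUE, noise_sd = 0.3)
  v <- screen_cross_contamination(build_cross_graph(ht$cross), ab)
  assigned <- v$status[v$status != "singleton"]
  expect_gte(mean(assigned == "assigned"), 0.99)
})

test_that("planted SSR loci verify against the deviation oracle", {
  set.seed(15)
  spec <- data.frame(motif = c("AT", "ACG", "AAGG", "AACCG"),
                     n_units = c(20, 12, 10, 7),
                     deviation = c(0.1, 0.1, 0.15, 0.12),
                     stringsAsFactors = FALSE)
  tr <- stats::setNames(vapply(1:4, function(i) rand_seq(500), character(1)),
                        paste0("t", 1:4))
  pl <- plant_ssrs(tr, spec)
  seqs <- as.character(pl$transcripts)
  for (i in seq_len(nrow(pl$loci))) {
    p <- pl$loci[i, ]
    region <- substr(seqs[[p$transcript_id]], p$start + 1, p$end)
    expect_lte(oracle_deviation(region, p$motif_planted), p$deviation)
    expect_gte(p$start, 30)     # never within the flank margin of an end
    expect_gte(nchar(seqs[[p$transcript_id]]) - p$end, 30)
  }
  # transcript too short for locus plus flanks is skipped and logged
  tiny <- c(short = rand_seq(50))
  pl2 <- plant_ssrs(tiny, spec[1, , drop = FALSE])
  expect_equal(pl2$skipped, 1L)
  expect_equal(nrow(pl2$loci), 0L)
})
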