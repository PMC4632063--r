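#!/usr/bin/env Rscript
# Microsatellite marker discovery. Plants imperfect SSR loci with known
# motifs and deviations into host transcripts, detects loci, scores
# recovery, collapses redundancy within repeat types, and emits primer
# design targets (150-500 bp, 45-65% GC).

library(holoscreen)

set.seed(20260921)
n_loci <- 60
spec <- data.frame(
  motif = rep_len(c("AT", "AC", "AG", "ACG", "AGG", "ACT",
                    "AAGG", "ACCT", "AACCG", "AAGCC"), n_loci),
  n_units = rep_len(c(20, 21, 22, 13, 14, 15, 10, 11, 8, 9), n_loci),
  deviation = rep_len(c(0, 0.05, 0.08, 0.1, 0.12, 0.15), n_loci),
  stringsAsFactors = FALSE)
tr <- setNames(
  vapply(seq_len(n_loci), function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(400:900, 1), replace = TRUE),
          collapse = "")
  }, character(1)),
  sprintf("t%03d", seq_len(n_loci)))
planted <- plant_ssrs(tr, spec)

loci <- find_ssrs_all(planted$transcripts)
recovered <- vapply(seq_len(nrow(planted$loci)), function(i) {
  p <- planted$loci[i, ]
  any(loci$transcript_id == p$transcript_id & loci$motif == p$motif &
        loci$start < p$end & loci$end > p$start)
}, logical(1))

# dereplication: no near-identical transcripts were simulated here, so
# the cross-hit table is empty and all representatives are kept
lens <- setNames(nchar(as.character(planted$transcripts)),
                 names(planted$transcripts))
uniq <- dereplicate_ssrs(loci, holoscreen:::empty_hit_table(), lens)
targets <- select_primer_targets(uniq, planted$transcripts)

dir.create("results", showWarnings = FALSE)
write.table(loci, "results/ssr_loci.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(targets[, setdiff(names(targets), "primer3")],
            "results/ssr_primer_targets.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(targets$primer3, "results/ssr_primer3_input.txt")

cat(sprintf("Planted loci: %d; detected calls: %d; recovery: %.1f%%\n",
            n_loci, nrow(loci), 100 * mean(recovered)))
cat("Calls by canonical repeat type:\n")
print(table(loci$motif))
cat(sprintf("Primer-design targets satisfying length/GC constraints: %d of %d loci\n",
            nrow(targets), nrow(uniq)))
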