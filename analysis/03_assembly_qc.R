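#!/usr/bin/env Rscript
# Assembly size statistics and completeness. Computes per-library length
# statistics over the 400 bp core set, reference-gene representation at
# bit-score >= 50 against the synthetic reference gene set, and both
# Ortholog Hit Ratio variants (alignment coverage and longest in-frame
# ORF) summarized per reference gene.

library(holoscreen)

dir <- "results/simdata"
libs <- sub("\\.fasta$", "", list.files(file.path(dir, "assemblies")))
ref_genes <- read.delim(file.path(dir, "ref", "ref_genes.tsv"))
ref_len <- setNames(ref_genes$protein_len, ref_genes$gene_id)

stats_rows <- list()
rep_rows <- list()
ohr_rows <- list()
for (lib in libs) {
  asm <- read_fasta(file.path(dir, "assemblies", paste0(lib, ".fasta")))
  st <- length_stats(asm, core_min_len = 400)
  stats_rows[[lib]] <- data.frame(library = lib, n_total = st$n_total,
                                  n_core = st$n_core,
                                  mean_len = round(st$mean_len, 1),
                                  n50 = st$n50)
  hits <- holoscreen:::as_hit_table(
    read.delim(file.path(dir, "ref", paste0("generep_", lib, ".tsv"))))
  rep_ <- gene_representation(hits, ref_genes$gene_id, bit_min = 50)
  rep_rows[[lib]] <- data.frame(library = lib, n_ref = nrow(ref_genes),
                                n_hit = rep_$n_hit,
                                pct = round(100 * rep_$fraction, 1))

  # per (transcript, gene) pair: coverage OHR from the HSPs, ORF OHR from
  # the transcript in the hit-defined frame
  sig <- hits[hits$bitscore >= 50, , drop = FALSE]
  pairs <- unique(sig[, c("qseqid", "sseqid")])
  per_pair <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    h <- sig[sig$qseqid == pairs$qseqid[i] & sig$sseqid == pairs$sseqid[i], ,
             drop = FALSE]
    fr <- hit_frame(h$qstart[1], h$qend[1], h$qlen[1])
    data.frame(gene_id = pairs$sseqid[i], transcript_id = pairs$qseqid[i],
               ohr_hits = ohr_hits(h),
               ohr_orf = ohr_orf(as.character(asm[[pairs$qseqid[i]]]), fr,
                                 ref_len[[pairs$sseqid[i]]]))
  }))
  if (is.null(per_pair)) next
  summ <- ohr_summarize(per_pair)
  ohr_rows[[lib]] <- data.frame(
    library = lib, n_genes_matched = summ$summary$n_genes_matched,
    median_ohr_hits = round(summ$summary$median_ohr_hits, 3),
    median_ohr_orf = round(summ$summary$median_ohr_orf, 3),
    n_ge_075_hits = summ$summary$n_ge_hits,
    n_ge_075_orf = summ$summary$n_ge_orf)
}

stats_tab <- do.call(rbind, stats_rows)
rep_tab <- do.call(rbind, rep_rows)
ohr_tab <- do.call(rbind, ohr_rows)
write.table(stats_tab, "results/assembly_stats.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rep_tab, "results/gene_representation.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ohr_tab, "results/ohr_summary.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

cat("Assembly size statistics (core set >= 400 bp):\n"); print(stats_tab, row.names = FALSE)
cat("\nReference-gene representation (bit >= 50):\n"); print(rep_tab, row.names = FALSE)
cat("\nOrtholog Hit Ratio summary (per-gene maxima):\n"); print(ohr_tab, row.names = FALSE)
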