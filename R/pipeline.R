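# Stage orchestration over an on-disk dataset in the layout written by
# save_simulation(): assemblies/<lib>.fasta, hits/<lib>_<db>.tsv,
# hits/cross.tsv, abund/<lib>.tsv, ref/generep_<lib>.tsv,
# ref/ref_genes.tsv.

#' Default analysis thresholds
#'
#' The defaults are the decision values the screening procedure is built
#' around: bit-score 45 for the small taxon databases, 50 for
#' reference-gene representation, 100 for the near-identity
#' cross-library screen, a 10-fold abundance ratio, E-value ceilings of
#' 1e-5 (taxon classification) and 1e-4 (name transfer), a 400 bp
#' core-set cutoff and 0.75 as the "reasonably complete" ortholog hit
#' ratio.
#'
#' @return named list of thresholds; see [run_pipeline()].
#' @export
default_run_config <- function() {
  list(bit_min_small_db = 45, bit_min_generep = 50, edge_min = 100,
       fold_min = 10, e_max_nr = 1e-5, e_max_name = 1e-4,
       core_min_len = 400, ohr_complete = 0.75,
       ssr_min_len = 30, ssr_max_dev = 0.15, ssr_min_flank = 30,
       matrix_min_aa = 100, matrix_min_taxa = 10)
}

validate_run_config <- function(config) {
  defaults <- default_run_config()
  missing <- setdiff(names(defaults), names(config))
  if (length(missing)) stop("config missing: ", paste(missing, collapse = ", "))
  for (nm in names(defaults)) {
    v <- config[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("config value ", nm, " must be a finite positive number")
    }
  }
  if (config$ssr_max_dev > 1 || config$ohr_complete > 1) {
    stop("fractional thresholds must not exceed 1")
  }
  invisible(config)
}

#' Run screening stages over an on-disk dataset
#'
#' Stages execute in dependency order (`stats`, `classify`, `xcontam`,
#' `ssr`); each writes its tables under `out_dir` and contributes to a
#' single `summary.json`. Outputs are deterministic: re-running with the
#' same inputs and config reproduces them byte for byte. Missing input
#' files for a requested stage raise a named error before any stage
#' runs.
#'
#' @param input_dir dataset directory (layout of [save_simulation()]).
#' @param out_dir output directory (created if needed).
#' @param config threshold list, see [default_run_config()].
#' @param stages subset of `c("stats", "classify", "xcontam", "ssr")`.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         config = default_run_config(),
                         stages = c("stats", "classify", "xcontam")) {
  validate_run_config(config)
  stages <- match.arg(stages, c("stats", "classify", "xcontam", "ssr"),
                      several.ok = TRUE)
  fasta_paths <- sort(list.files(file.path(input_dir, "assemblies"),
                                 pattern = "\\.fasta$", full.names = TRUE))
  if (length(fasta_paths) == 0L) stop("no assemblies found under ", input_dir)
  libs <- sub("\\.fasta$", "", basename(fasta_paths))

  needed <- character(0)
  if ("classify" %in% stages) {
    needed <- c(needed, file.path(input_dir, "hits",
                                  paste0(rep(libs, each = 5), "_",
                                         c("rrna", "mito", "host", "symbiont", "nr"),
                                         ".tsv")))
  }
  if ("xcontam" %in% stages) {
    needed <- c(needed, file.path(input_dir, "hits", "cross.tsv"),
                file.path(input_dir, "abund", paste0(libs, ".tsv")))
  }
  absent <- needed[!file.exists(needed)]
  if (length(absent)) {
    stop("missing input for requested stages: ", paste(absent, collapse = ", "))
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assemblies <- stats::setNames(lapply(fasta_paths, read_fasta), libs)
  summary <- list(libraries = libs)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if ("stats" %in% stages) {
    st <- lapply(assemblies, length_stats, core_min_len = config$core_min_len)
    tsv(data.frame(library = libs,
                   n_total = vapply(st, `[[`, numeric(1), "n_total"),
                   n_core = vapply(st, `[[`, numeric(1), "n_core"),
                   mean_len = round(vapply(st, `[[`, numeric(1), "mean_len"), 1),
                   n50 = vapply(st, `[[`, numeric(1), "n50")),
        "assembly_stats.tsv")
    summary$stats <- lapply(st, function(s) s[c("n_total", "n_core", "mean_len", "n50")])
  }

  if ("classify" %in% stages) {
    tallies <- list()
    for (lib in libs) {
      ht <- function(db, extra = character()) {
        p <- file.path(input_dir, "hits", paste0(lib, "_", db, ".tsv"))
        df <- utils::read.delim(p, stringsAsFactors = FALSE)
        as_hit_table(df, p)
      }
      res <- classify_assembly(
        names(assemblies[[lib]]),
        rrna_hits = ht("rrna"), mito_hits = ht("mito"),
        host_hits = ht("host"), symbiont_hits = ht("symbiont"),
        nr_hits = ht("nr"),
        bit_min = config$bit_min_small_db, nr_emax = config$e_max_nr)
      tsv(res$calls, paste0("origin_calls_", lib, ".tsv"))
      tallies[[lib]] <- stats::setNames(as.list(res$tally$n), res$tally$category)
    }
    summary$origin_tally <- tallies
  }

  if ("xcontam" %in% stages) {
    cross <- as_hit_table(utils::read.delim(file.path(input_dir, "hits", "cross.tsv"),
                                            stringsAsFactors = FALSE))
    abund <- stats::setNames(lapply(libs, function(l) {
      read_abundance_table(file.path(input_dir, "abund", paste0(l, ".tsv")))
    }), libs)
    g <- build_cross_graph(cross, edge_min = config$edge_min)
    verdicts <- screen_cross_contamination(g, abund, fold_min = config$fold_min)
    cleaned <- apply_verdicts(assemblies, verdicts)
    tsv(verdicts, "xcontam_verdicts.tsv")
    tsv(cleaned$report, "xcontam_removals.tsv")
    dir.create(file.path(out_dir, "cleaned"), showWarnings = FALSE)
    for (lib in libs) {
      write_fasta(cleaned$assemblies[[lib]],
                  file.path(out_dir, "cleaned", paste0(lib, ".fasta")))
    }
    summary$xcontam <- list(
      n_clusters = length(unique(verdicts$cluster_id)),
      n_assigned = length(unique(verdicts$cluster_id[verdicts$status == "assigned"])),
      n_unknown_origin = length(unique(verdicts$cluster_id[verdicts$status == "unknown_origin"])),
      n_removed = nrow(cleaned$report))
  }

  if ("ssr" %in% stages) {
    loci <- do.call(rbind, lapply(libs, function(lib) {
      l <- find_ssrs_all(assemblies[[lib]],
                         min_len = config$ssr_min_len,
                         max_dev = config$ssr_max_dev,
                         min_flank = config$ssr_min_flank)
      if (nrow(l)) cbind(library = lib, l) else NULL
    }))
    if (is.null(loci)) {
      loci <- cbind(library = character(0),
                    find_ssrs("", transcript_id = "x")[0, ])
    }
    tsv(loci, "ssr_loci.tsv")
    summary$ssr <- list(n_loci = nrow(loci))
  }

  summary$config <- config
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
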