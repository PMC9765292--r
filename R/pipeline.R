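# One-call synthetic end-to-end run: genome -> library design -> screen
# counts -> normalization -> contrasts -> residual calls -> reporter screen
# -> COG profile, with per-stage files and a machine-readable manifest.

#' Run the full synthetic screen pipeline
#'
#' Generates a synthetic annotated genome, designs the CRISPRi library on
#' it, simulates pooled-screen counts under planted per-gene selection
#' (with classes neutral / essential / competence-costly), pools and
#' normalizes, scores the Ci-vs-mock, Ci+C-vs-mock and direct Ci+C-vs-Ci
#' contrasts, calls regression-residual outliers and confirms them against
#' the direct contrast, scores a simulated reporter screen, and profiles
#' hits by COG category. Every stage writes a TSV under `out_dir`; a
#' key=value `manifest.tsv` captures the configuration (with a hash), the
#' seed, and headline result counts. Re-running with the same seed and
#' configuration reproduces the manifest byte-identically.
#'
#' @param out_dir output directory (created).
#' @param seed master seed; stage seeds are derived from it.
#' @param n_genes genes in the synthetic genome (default 150).
#' @param frac_costly,frac_essential planted class fractions (defaults 0.05
#'   and 0.15).
#' @param s_delta competence-specific penalty (default -0.25).
#' @param reads_per_replicate,replicates sequencing depth (defaults 1.25e6
#'   and 4).
#' @param cutoff residual cutoff (default 2.5).
#' @param fdr_cutoff direct-confirmation FDR cutoff (default 0.05).
#' @param count_cutoff,fc_cutoff reporter cutoffs (defaults 0.02, 0.5).
#' @param alpha,n_permutations,pseudocount RRA/contrast settings (defaults
#'   0.25, 2000, 1).
#' @param generations growth generations (default 12).
#' @param write_fastq also emit FASTQ for the mock replicates and re-count
#'   them through the read-extraction path (default `FALSE`; slower).
#' @return invisibly, a list with the main result tables (`library_stats`,
#'   `scores_ci`, `scores_cic`, `scores_direct`, `residuals`, `reporter`,
#'   `cog_profile`, `truth`, `recovery`).
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_genes = 150L,
                         frac_costly = 0.05, frac_essential = 0.15,
                         s_delta = -0.25, reads_per_replicate = 1.25e6,
                         replicates = 4L, cutoff = 2.5, fdr_cutoff = 0.05,
                         count_cutoff = 0.02, fc_cutoff = 0.5, alpha = 0.25,
                         n_permutations = 2000L, pseudocount = 1,
                         generations = 12, write_fastq = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  stage_seed <- function(k) (seed * 101L + k) %% .Machine$integer.max

  # stage 1: genome
  genome <- simulate_genome(n_genes = n_genes, seed = stage_seed(1L))
  write_genome(genome, file.path(out_dir, "genome.fasta"),
               file.path(out_dir, "genome.gff3"))

  # stage 2: library design
  lib <- design_guides(genome)
  write_library(lib, file.path(out_dir, "library.tsv"),
                file.path(out_dir, "library.bed"))
  st <- library_stats(lib, genome)

  # stage 3: truth + counts
  genes <- genome$features$locus_tag[genome$features$kind == "CDS"]
  truth <- simulate_truth(genes,
                          n_costly = max(1L, round(frac_costly * length(genes))),
                          n_essential = round(frac_essential * length(genes)),
                          s_delta = s_delta, seed = stage_seed(2L))
  cfg <- sim_config(n_genes = length(genes), generations = generations,
                    reads_per_replicate = reads_per_replicate,
                    replicates = replicates, seed = stage_seed(3L))
  cm <- simulate_screen_counts(lib, truth, cfg)
  write_tsv_file(truth, file.path(out_dir, "truth.tsv"),
                 header_lines = .tsv_header(seed))
  write_counts(cm, file.path(out_dir, "counts_raw.tsv"),
               header_lines = .tsv_header(seed))
  if (write_fastq) {
    schema <- amplicon_schema("ACGTTGGATCCA", "TTCAGACGTGTA")
    mock <- count_matrix(cm$counts[, cm$samples$condition == "mock", drop = FALSE],
                         cm$samples[cm$samples$condition == "mock", ])
    sheet <- simulate_fastq(mock, schema, file.path(out_dir, "fastq"),
                            seed = stage_seed(4L))
    recount <- count_reads(sheet, lib, schema)
    write_counts(recount, file.path(out_dir, "counts_from_fastq.tsv"),
                 header_lines = .tsv_header(seed))
  }

  # stage 4: normalize + contrasts
  norm <- median_ratio_normalize(pool_replicates(cm))
  mk_cfg <- function(treat, ctrl, k) {
    contrast_config(treat, ctrl, pseudocount = pseudocount, alpha = alpha,
                    n_permutations = n_permutations, seed = stage_seed(k))
  }
  scores_ci <- gene_scores(norm, lib, mk_cfg("Ci", "mock", 5L))
  scores_cic <- gene_scores(norm, lib, mk_cfg("CiC", "mock", 6L))
  scores_direct <- gene_scores(norm, lib, mk_cfg("CiC", "Ci", 7L))
  write_gene_scores(scores_ci, file.path(out_dir, "scores_Ci_vs_mock.tsv"))
  write_gene_scores(scores_cic, file.path(out_dir, "scores_CiC_vs_mock.tsv"))
  write_gene_scores(scores_direct, file.path(out_dir, "scores_CiC_vs_Ci.tsv"))

  # stage 5: residual calls
  calls <- competence_residuals(scores_ci, scores_cic, cutoff = cutoff)
  calls <- confirm_direct(calls, scores_direct, fdr_cutoff = fdr_cutoff)
  fit <- attr(calls, "fit")
  write_tsv_file(calls, file.path(out_dir, "residual_calls.tsv"),
                 header_lines = .tsv_header(seed, extra = sprintf(
                   "regression slope=%.6g intercept=%.6g r_squared=%.6g cutoff=%.2f",
                   fit$slope, fit$intercept, fit$r_squared, cutoff)))

  # stage 6: reporter screen on planted clones (3 guides per costly gene,
  # plus neutral decoys)
  idx <- library_gene_index(lib)
  idx <- idx[!idx$multi_target, , drop = FALSE]
  pick_clones <- .with_seed(stage_seed(8L), {
    costly <- truth$gene[truth$class == "competence_costly"]
    neutral <- truth$gene[truth$class == "neutral"]
    sel <- lapply(costly, function(g) {
      sp <- idx$spacer[idx$gene == g]
      utils::head(sp, 3L)
    })
    decoys <- idx$spacer[idx$gene %in% sample(neutral, min(5L, length(neutral)))]
    decoys <- utils::head(decoys, 5L)
    data.frame(spacer = c(unlist(sel), decoys), stringsAsFactors = FALSE)
  })
  pick_clones$clone_id <- sprintf("clone_%03d", seq_len(nrow(pick_clones)))
  gene_of <- idx$gene[match(pick_clones$spacer, idx$spacer)]
  pick_clones$reporter_factor <- truth$reporter_factor[match(gene_of, truth$gene)]
  rep_cfg <- sim_config(seed = stage_seed(9L))
  sim_rep <- simulate_reporter(pick_clones[c("clone_id", "spacer", "reporter_factor")],
                               rep_cfg)
  fc <- reporter_fold_changes(sim_rep$timeseries,
                              sim_rep$clones[sim_rep$clones$clone_id != "reference",
                                             c("clone_id", "spacer")])
  reporter <- summarize_reporter_genes(fc, lib, count_cutoff, fc_cutoff)
  write_tsv_file(reporter, file.path(out_dir, "reporter_summary.tsv"),
                 header_lines = .tsv_header(seed))

  # stage 7: COG profile of the hit lists
  cog <- simulate_cog_table(genes, seed = stage_seed(10L))
  hits <- list(
    transformation = .with_seed(stage_seed(11L), {
      costly <- truth$gene[truth$class == "competence_costly"]
      sample(costly, min(5L, length(costly)))
    }),
    depletion = calls$gene[calls$class == "depleted"],
    reporter = reporter$gene[reporter$class == "antagonist"])
  profile <- profile_hits(hits, cog)
  write_cog_table(cog, file.path(out_dir, "cog_assignments.tsv"))
  write_tsv_file(profile, file.path(out_dir, "cog_profile.tsv"),
                 header_lines = .tsv_header(seed))

  # recovery summary against the planted truth
  is_costly <- calls$gene %in% truth$gene[truth$class == "competence_costly"]
  recovery <- data.frame(
    n_genes = length(genes),
    n_costly = sum(truth$class == "competence_costly"),
    sensitivity = mean(calls$class[is_costly] == "depleted"),
    false_positive_rate = mean(calls$class[!is_costly] != "neutral"),
    r_squared = fit$r_squared)
  write_tsv_file(recovery, file.path(out_dir, "recovery.tsv"),
                 header_lines = .tsv_header(seed))

  # manifest
  config <- list(version = .pkg_version(), seed = seed, n_genes = n_genes,
                 frac_costly = frac_costly, frac_essential = frac_essential,
                 s_delta = s_delta, reads_per_replicate = reads_per_replicate,
                 replicates = replicates, cutoff = cutoff,
                 fdr_cutoff = fdr_cutoff, count_cutoff = count_cutoff,
                 fc_cutoff = fc_cutoff, alpha = alpha,
                 n_permutations = n_permutations, pseudocount = pseudocount,
                 generations = generations, write_fastq = write_fastq)
  cfg_str <- paste(names(config), unlist(config), sep = "=", collapse = ";")
  manifest <- c(
    sprintf("config_hash=%s", .string_md5(cfg_str)),
    paste(names(config), unlist(config), sep = "="),
    sprintf("n_guides=%d", st$n_guides),
    sprintf("median_guides_per_cds=%s", st$median_guides_per_cds),
    sprintf("mean_spacing_bp=%s", st$mean_spacing_bp),
    sprintf("n_depleted=%d", sum(calls$class == "depleted")),
    sprintf("n_enriched=%d", sum(calls$class == "enriched")),
    sprintf("n_antagonist=%d", sum(reporter$class == "antagonist")),
    sprintf("r_squared=%.6f", fit$r_squared),
    sprintf("sensitivity=%.6f", recovery$sensitivity),
    sprintf("false_positive_rate=%.6f", recovery$false_positive_rate))
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(library_stats = st, scores_ci = scores_ci,
                 scores_cic = scores_cic, scores_direct = scores_direct,
                 residuals = calls, reporter = reporter,
                 cog_profile = profile, truth = truth, recovery = recovery))
}

#' @keywords internal
#' @noRd
.string_md5 <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}
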