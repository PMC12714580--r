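#' Simulation configuration for the synthetic genotoxicity study
#'
#' Builds the fully-seeded configuration object that drives every synthetic
#' generator in the package. The defaults emulate the study design the
#' analysis assumes: two lentiviral vectors (`pHR`, a self-inactivating SIN-LTR
#' configuration, and `pHV`, a native-LTR configuration) applied to iPSC
#' sampled early (day 3) and late (day 30) and to quiescent hepatocyte-like
#' cells (HLC) sampled early only, with three biological replicates per
#' condition and uninfected controls for the expression and methylation
#' layers.
#'
#' @param seed Integer root seed. All generators derive stage seeds from it;
#'   identical configs produce byte-identical outputs.
#' @param n_chrom Number of chromosomes in the synthetic genome.
#' @param genome_len Length (bp) of each chromosome.
#' @param n_genes Number of genes placed on the genome.
#' @param frac_oncogene,frac_tsg Fractions of genes flagged proto-oncogene /
#'   tumour-suppressor; `floor(frac * n_genes)` genes get each flag and the
#'   two fractions must sum to at most 1.
#' @param is_per_sample Integration sites emitted per sample.
#' @param p_genic Probability an integration site lands inside a transcription
#'   unit (lentiviral integration is strongly genic; default 0.75).
#' @param n_clonal_genes Number of genes carrying a planted clonal expansion.
#' @param clonal_fold Multiplier (>= 1) applied to late-timepoint sequence
#'   counts of sites in clonal genes; 1 disables the expansion.
#' @param n_de_genes Number of genes with a planted expression effect.
#' @param de_log2fc Planted log2 fold-change in infected groups.
#' @param nb_dispersion Negative-binomial dispersion of the count simulator
#'   (variance = mu + dispersion * mu^2).
#' @param n_modules,module_size,module_cor Planted co-expression structure:
#'   number of modules, genes per module, and target pairwise correlation.
#' @param n_probes Methylation probes simulated.
#' @param n_dmr_probes Probes carrying a planted methylation shift.
#' @param dmr_delta Planted beta-value shift in treated samples (in (-1, 1)).
#' @param beta_noise_sd Standard deviation of the logit-normal noise on beta.
#' @param replicates Biological replicates per condition.
#' @param fusion_fraction Fraction of genic integration sites that emit a
#'   vector-host fusion transcript record.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50, is_per_sample = 100)
#' cfg$n_genes
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 4L,
                       genome_len = 1.5e7,
                       n_genes = 2000L,
                       frac_oncogene = 0.02,
                       frac_tsg = 0.02,
                       is_per_sample = 2000L,
                       p_genic = 0.75,
                       n_clonal_genes = 50L,
                       clonal_fold = 4,
                       n_de_genes = 100L,
                       de_log2fc = 3,
                       nb_dispersion = 0.1,
                       n_modules = 2L,
                       module_size = 50L,
                       module_cor = 0.8,
                       n_probes = 5000L,
                       n_dmr_probes = 200L,
                       dmr_delta = 0.3,
                       beta_noise_sd = 0.05,
                       replicates = 3L,
                       fusion_fraction = 0.05) {
  check_count(seed, "seed")
  check_count(n_chrom, "n_chrom", min = 1)
  check_count(n_genes, "n_genes", min = 1)
  check_count(is_per_sample, "is_per_sample", min = 1)
  check_count(n_clonal_genes, "n_clonal_genes")
  check_count(n_de_genes, "n_de_genes")
  check_count(n_modules, "n_modules")
  check_count(module_size, "module_size")
  check_count(n_probes, "n_probes", min = 1)
  check_count(n_dmr_probes, "n_dmr_probes")
  check_count(replicates, "replicates", min = 1)
  check_fraction(frac_oncogene, "frac_oncogene")
  check_fraction(frac_tsg, "frac_tsg")
  check_fraction(p_genic, "p_genic")
  check_fraction(fusion_fraction, "fusion_fraction")
  check_fraction(module_cor, "module_cor", lo = 1e-6, hi = 1 - 1e-6)
  check_fraction(dmr_delta, "dmr_delta", lo = -1 + 1e-9, hi = 1 - 1e-9)
  if (frac_oncogene + frac_tsg > 1) {
    abort("`frac_oncogene` + `frac_tsg` must not exceed 1.")
  }
  if (clonal_fold < 1) abort("`clonal_fold` must be >= 1.")
  if (nb_dispersion <= 0) abort("`nb_dispersion` must be > 0.")
  if (genome_len <= 0) abort("`genome_len` must be > 0.")
  if (n_modules * module_size > n_genes) {
    abort("`n_modules` * `module_size` must not exceed `n_genes`.")
  }
  if (n_clonal_genes > is_per_sample) {
    abort("`n_clonal_genes` must not exceed `is_per_sample`.")
  }
  if (beta_noise_sd <= 0) abort("`beta_noise_sd` must be > 0.")

  structure(
    list(
      seed = as.integer(seed), n_chrom = as.integer(n_chrom),
      genome_len = genome_len, n_genes = as.integer(n_genes),
      frac_oncogene = frac_oncogene, frac_tsg = frac_tsg,
      is_per_sample = as.integer(is_per_sample), p_genic = p_genic,
      n_clonal_genes = as.integer(n_clonal_genes), clonal_fold = clonal_fold,
      n_de_genes = as.integer(n_de_genes), de_log2fc = de_log2fc,
      nb_dispersion = nb_dispersion, n_modules = as.integer(n_modules),
      module_size = as.integer(module_size), module_cor = module_cor,
      n_probes = as.integer(n_probes),
      n_dmr_probes = as.integer(n_dmr_probes), dmr_delta = dmr_delta,
      beta_noise_sd = beta_noise_sd,
      replicates = as.integer(replicates), fusion_fraction = fusion_fraction
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chrom x %s bp, %d genes (%.1f%% onco, %.1f%% TSG)\n",
              x$n_chrom, format(x$genome_len, big.mark = ","), x$n_genes,
              100 * x$frac_oncogene, 100 * x$frac_tsg))
  cat(sprintf("  IS: %d per sample, p_genic = %.2f, %d clonal genes x %g-fold\n",
              x$is_per_sample, x$p_genic, x$n_clonal_genes, x$clonal_fold))
  cat(sprintf("  expression: %d DE genes at log2FC %g, dispersion %g, %d modules of %d at r = %g\n",
              x$n_de_genes, x$de_log2fc, x$nb_dispersion, x$n_modules,
              x$module_size, x$module_cor))
  cat(sprintf("  methylation: %d probes, %d shifted by %+.2f\n",
              x$n_probes, x$n_dmr_probes, x$dmr_delta))
  cat(sprintf("  layout: pHR/pHV x {iPSC early, iPSC late, HLC early} x %d replicates, seed %d\n",
              x$replicates, x$seed))
  invisible(x)
}

#' Study design table for a simulation configuration
#'
#' Enumerates the infected samples of the emulated study: every combination
#' of vector (pHR, pHV), cell/timepoint condition (iPSC early, iPSC late,
#' HLC early) and replicate.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `sample`, `vector`, `cell`, `timepoint`,
#'   `replicate`.
#' @export
study_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  conditions <- tibble(
    cell = c("iPSC", "iPSC", "HLC"),
    timepoint = c("early", "late", "early")
  )
  tidyr::crossing(
    vector = c("pHR", "pHV"),
    conditions,
    replicate = seq_len(config$replicates)
  ) |>
    mutate(sample = sample_id(.data$vector, .data$cell, .data$timepoint,
                              .data$replicate)) |>
    select("sample", "vector", "cell", "timepoint", "replicate") |>
    arrange(.data$vector, .data$cell, dplyr::desc(.data$timepoint == "early"),
            .data$replicate)
}
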