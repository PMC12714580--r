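#' Sample sheet for the expression and methylation layers
#'
#' The transcriptome/methylome arm of the emulated study: all infected
#' samples of [study_design()] plus `replicates` uninfected control samples
#' per cell type (vector label `CTRL`). `group` concatenates vector, cell
#' and timepoint and is the unit of differential contrasts.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `sample`, `vector`, `cell`, `timepoint`,
#'   `replicate`, `group`, `infected`.
#' @export
expression_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  infected <- study_design(config) |> mutate(infected = TRUE)
  controls <- tidyr::crossing(cell = c("iPSC", "HLC"),
                              replicate = seq_len(config$replicates)) |>
    mutate(vector = "CTRL", timepoint = "early", infected = FALSE,
           sample = sample_id("CTRL", .data$cell, "early", .data$replicate))
  bind_rows(infected, controls) |>
    mutate(group = paste(.data$vector, .data$cell, .data$timepoint,
                         sep = "_")) |>
    select("sample", "vector", "cell", "timepoint", "replicate", "group",
           "infected")
}

#' Simulate a gene-by-sample expression count matrix
#'
#' Negative-binomial counts with log-normal gene baselines, per-sample
#' library-size factors, a planted differential-expression set and planted
#' co-expression modules:
#'
#' * `n_de_genes` genes are shifted by `de_log2fc` in infected samples
#'   (half up, half down), emulating the transcriptional response to
#'   vector infection.
#' * `n_modules` disjoint blocks of `module_size` genes share a per-sample
#'   latent factor so that their latent pairwise correlation is
#'   `module_cor`; the latent amplitude (2.4 on the log2 scale) and an
#'   elevated baseline keep the correlation visible above the
#'   negative-binomial noise floor.
#'
#' Counts are `rnbinom` with `size = 1/nb_dispersion` so that
#' `Var = mu + nb_dispersion * mu^2`.
#'
#' @param annotation A [make_genome()] annotation (supplies gene ids).
#' @param design A sample sheet as from [expression_design()]; any tibble
#'   with `sample`, `group` and logical `infected` columns works.
#' @param config A [sim_config()] object.
#' @return A list of class `expr_simulation`: `counts` (genes x samples
#'   integer matrix), `design`, `de_genes` (tibble of planted gene ids and
#'   signed log2 fold-changes) and `module_genes` (tibble gene_id/module).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 200, n_de_genes = 20,
#'                   module_size = 10, n_probes = 10)
#' sim <- simulate_expression(make_genome(cfg), expression_design(cfg), cfg)
#' dim(sim$counts)
#' @export
simulate_expression <- function(annotation, design, config) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "sim_config"))
  if (!all(c("sample", "group", "infected") %in% names(design))) {
    abort("`design` needs columns sample, group, infected.")
  }
  if (anyDuplicated(design$sample)) abort("duplicate sample ids in design.")
  if (config$nb_dispersion <= 0) abort("`nb_dispersion` must be > 0.")
  set.seed(derive_seed(config$seed, "expression"))

  genes <- annotation$genes$gene_id
  ng <- length(genes)
  ns <- nrow(design)

  # planted structure: modules first, then DE genes from the remainder
  module_genes <- tibble(gene_id = character(0), module = integer(0))
  if (config$n_modules > 0L && config$module_size > 0L) {
    picked <- sample(genes, config$n_modules * config$module_size)
    module_genes <- tibble(
      gene_id = picked,
      module = rep(seq_len(config$n_modules), each = config$module_size)
    )
  }
  base_log2 <- log2(rlnorm(ng, meanlog = log(100), sdlog = 1))
  names(base_log2) <- genes

  # Planted effects respect the compositional nature of sequencing:
  # up-regulated genes come from moderate baselines (a large fold-change
  # on a high-baseline gene would inflate the library itself and bias all
  # CPM fold-changes) and down-regulated genes from high baselines (so the
  # shifted counts stay above the Poisson noise floor). The removed and
  # added read mass roughly cancel.
  de_genes <- tibble(gene_id = character(0), log2fc = numeric(0))
  if (config$n_de_genes > 0L) {
    n_up <- ceiling(config$n_de_genes / 2)
    n_down <- config$n_de_genes - n_up
    base <- 2^base_log2
    up_pool <- setdiff(genes[base >= 20 & base <= 200],
                       module_genes$gene_id)
    down_pool <- setdiff(genes[base >= 400 & base <= 2000],
                         c(module_genes$gene_id, up_pool))
    up <- sample(up_pool, min(n_up, length(up_pool)))
    down <- sample(down_pool, min(n_down, length(down_pool)))
    de_genes <- tibble(
      gene_id = c(up, down),
      log2fc = c(rep(config$de_log2fc, length(up)),
                 rep(-config$de_log2fc, length(down)))
    )
  }
  # module genes get a comfortably expressed baseline so counting noise
  # does not drown the latent factor
  base_log2[module_genes$gene_id] <- log2(rlnorm(nrow(module_genes),
                                                 meanlog = log(500),
                                                 sdlog = 0.3))

  mu_log2 <- matrix(base_log2, nrow = ng, ncol = ns,
                    dimnames = list(genes, design$sample))

  infected <- design$infected
  if (nrow(de_genes)) {
    mu_log2[de_genes$gene_id, infected] <-
      mu_log2[de_genes$gene_id, infected] + de_genes$log2fc
  }
  if (nrow(module_genes)) {
    amp <- 2.4     # latent factor amplitude, log2 units
    rho <- config$module_cor
    for (m in seq_len(config$n_modules)) {
      ids <- module_genes$gene_id[module_genes$module == m]
      # standardized to unit sample variance: the planted amplitude is
      # exact in every realisation, not just in expectation
      f <- as.numeric(scale(rnorm(ns)))
      eps <- matrix(rnorm(length(ids) * ns), length(ids), ns)
      # half the genes load positively, half negatively (modules contain
      # both up- and down-regulated members); |cor| is unchanged and the
      # module's contribution to the library size stays balanced
      loading <- rep(c(1, -1), length.out = length(ids))
      mu_log2[ids, ] <- mu_log2[ids, ] +
        loading * amp * (sqrt(rho) * matrix(f, length(ids), ns, byrow = TRUE) +
                           sqrt(1 - rho) * eps)
    }
  }

  libfac <- rlnorm(ns, meanlog = 0, sdlog = 0.2)
  mu <- sweep(2^mu_log2, 2, libfac, `*`)
  counts <- matrix(
    rnbinom(ng * ns, size = 1 / config$nb_dispersion, mu = as.vector(mu)),
    nrow = ng, dimnames = dimnames(mu)
  )

  structure(list(counts = counts, design = design, de_genes = de_genes,
                 module_genes = module_genes),
            class = "expr_simulation")
}

#' Simulate a synthetic tumor/normal expression pair
#'
#' A bundled synthetic stand-in for tumor-versus-normal reference cohorts
#' used to derive cancer gene signatures. A planted tumor program
#' (`program_size` genes, shifted up by `program_lfc` in tumor samples,
#' low dispersion) sits on the same gene universe as the study annotation,
#' so derived signatures can score the study's samples.
#'
#' @param annotation A [make_genome()] annotation.
#' @param config A [sim_config()] object (supplies the seed).
#' @param n_per_group Samples per arm.
#' @param program_size Number of planted program genes.
#' @param program_lfc Planted log2 fold-change of the program.
#' @param dispersion Negative-binomial dispersion of this cohort.
#' @return A list of class `tumor_normal_simulation` with `counts` (genes x
#'   samples), `design` (`sample`, `group` in tumor/normal) and
#'   `program_genes`.
#' @export
simulate_tumor_normal <- function(annotation, config, n_per_group = 5L,
                                  program_size = 300L, program_lfc = 4,
                                  dispersion = 0.05) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "tumor_normal"))
  genes <- annotation$genes$gene_id
  ng <- length(genes)
  design <- tibble(
    sample = c(sprintf("TUM_%d", seq_len(n_per_group)),
               sprintf("NORM_%d", seq_len(n_per_group))),
    group = rep(c("tumor", "normal"), each = n_per_group)
  )
  base_log2 <- log2(rlnorm(ng, meanlog = log(100), sdlog = 1))
  # the program is a minority of genes, drawn from low baselines: a 2^4
  # shift on many high-baseline genes would dominate the library and be
  # absorbed by CPM normalisation (counts are compositional)
  k <- min(program_size, floor(ng / 4))
  pool <- order(abs(base_log2 - log2(30)))[seq_len(max(k * 2, k))]
  program <- sort(genes[sample(pool, k)])
  mu_log2 <- matrix(base_log2, ng, nrow(design),
                    dimnames = list(genes, design$sample))
  mu_log2[program, design$group == "tumor"] <-
    mu_log2[program, design$group == "tumor"] + program_lfc
  counts <- matrix(
    rnbinom(length(mu_log2), size = 1 / dispersion, mu = as.vector(2^mu_log2)),
    nrow = ng, dimnames = dimnames(mu_log2)
  )
  structure(list(counts = counts, design = design, program_genes = program),
            class = "tumor_normal_simulation")
}
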