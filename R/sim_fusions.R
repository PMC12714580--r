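#' Simulate vector-host fusion transcripts
#'
#' A configured fraction of genic integration sites emit one fusion-gene
#' record (splicing or readthrough from the provirus into the host gene),
#' so by construction every fusion gene carries an integration site in the
#' same sample.
#'
#' @param is_table Integration-site tibble as produced by
#'   [simulate_insertion_sites()].
#' @param annotation A [make_genome()] annotation.
#' @param config A [sim_config()] object (`fusion_fraction` and seed).
#' @return A tibble with columns `gene_id`, `sample`, `chrom`, `breakpoint`,
#'   `vector_side` (`LTR` or `internal`).
#' @export
simulate_fusions <- function(is_table, annotation, config) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "sim_config"))
  if (nrow(is_table) == 0L) abort("`is_table` is empty.")
  set.seed(derive_seed(config$seed, "fusions"))

  ann <- annotate_sites(is_table, annotation)
  genic <- ann |> filter(!is.na(.data$gene_id))
  emit <- runif(nrow(genic)) < config$fusion_fraction
  genic[emit, ] |>
    transmute(
      gene_id = .data$gene_id, sample = .data$sample, chrom = .data$chrom,
      breakpoint = .data$pos,
      vector_side = sample(c("LTR", "internal"), sum(emit), replace = TRUE,
                           prob = c(0.7, 0.3))
    )
}
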