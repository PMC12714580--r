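#' Simulate a gene-set collection
#'
#' Random functional gene sets over the annotation's gene universe, for
#' over-representation and ranked enrichment analysis. Optionally one set
#' is seeded from a supplied gene list (e.g. planted differential genes) so
#' enrichment has a true positive to find.
#'
#' @param annotation A [make_genome()] annotation.
#' @param config A [sim_config()] object (seed).
#' @param n_sets Number of random sets.
#' @param size_range Integer range of set sizes.
#' @param planted Optional character vector of gene ids; when given, a set
#'   named `PLANTED_PROGRAM` containing them is appended.
#' @return A named list of character vectors of gene ids.
#' @export
simulate_gene_sets <- function(annotation, config, n_sets = 25L,
                               size_range = c(20L, 150L), planted = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "gene_sets"))
  genes <- annotation$genes$gene_id
  sizes <- sample(seq(size_range[1], min(size_range[2], length(genes))),
                  n_sets, replace = TRUE)
  sets <- lapply(sizes, function(k) sort(sample(genes, k)))
  names(sets) <- sprintf("SET_%02d", seq_len(n_sets))
  if (!is.null(planted) && length(planted)) {
    sets$PLANTED_PROGRAM <- sort(intersect(planted, genes))
  }
  sets
}
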