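#' Intersect gene sets across omics layers
#'
#' Exact set algebra over the per-layer gene sets (integration-site
#' targets, differentially expressed genes, differentially methylated
#' genes, fusion genes, ...): every single-layer count, every pairwise and
#' every triple intersection, with member lists.
#'
#' @param layer_gene_sets Named list of character vectors (one per layer).
#' @return A tibble of class `omics_intersection` with `layers`
#'   (`+`-joined layer names), `order` (1, 2 or 3), `n`, `genes`
#'   (list-column).
#' @export
intersect_omics <- function(layer_gene_sets) {
  if (is.null(names(layer_gene_sets)) || any(names(layer_gene_sets) == "")) {
    abort("`layer_gene_sets` must be a fully named list.")
  }
  sets <- lapply(layer_gene_sets, function(x) sort(unique(x)))
  nms <- names(sets)
  combos <- unlist(lapply(1:min(3, length(sets)), function(k) {
    utils::combn(nms, k, simplify = FALSE)
  }), recursive = FALSE)
  out <- purrr::map_dfr(combos, function(cb) {
    g <- Reduce(intersect, sets[cb])
    tibble(layers = paste(cb, collapse = "+"), order = length(cb),
           n = length(g), genes = list(g))
  })
  class(out) <- c("omics_intersection", class(out))
  out
}

#' Triple-positive genes
#'
#' Genes simultaneously carrying a vector-host fusion transcript, an
#' integration site and a differential-expression call — the strongest
#' multi-layer genotoxicity signal.
#'
#' @param fusion_genes,is_genes,deg_genes Character vectors of gene ids.
#' @return A list with `genes` (the triple intersection, sorted) and
#'   `fraction` — the fraction of fusion genes that are triple positive
#'   (NA when there are no fusion genes).
#' @export
triple_positives <- function(fusion_genes, is_genes, deg_genes) {
  fusion_genes <- unique(fusion_genes)
  g <- sort(Reduce(intersect, list(fusion_genes, unique(is_genes),
                                   unique(deg_genes))))
  list(
    genes = g,
    fraction = if (length(fusion_genes)) length(g) / length(fusion_genes)
               else NA_real_
  )
}

#' Chi-square homogeneity test on an oncogene/TSG table
#'
#' Pearson chi-square with Yates continuity correction (df = 1) on a 2x2
#' table of oncogene and tumour-suppressor counts, e.g. between two
#' vectors' DEG sets. The continuity correction is on by default: it is
#' the convention under which the printed statistic of the reference
#' comparison (37/51 vs 81/82 giving 1.0523) is reproduced.
#'
#' @param table2x2 2x2 matrix of non-negative integer counts with all
#'   margins positive.
#' @param correct Apply Yates continuity correction (default TRUE).
#' @return A list with `chi2`, `p`, `df`, `table`.
#' @examples
#' onco_tsg_chisq(matrix(c(37, 81, 51, 82), nrow = 2))
#' @export
onco_tsg_chisq <- function(table2x2, correct = TRUE) {
  m <- as.matrix(table2x2)
  if (!all(dim(m) == c(2L, 2L))) abort("`table2x2` must be 2x2.")
  if (any(m < 0) || any(m != floor(m))) {
    abort("counts must be non-negative integers.")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("all margins of the 2x2 table must be positive.")
  }
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value),
       df = unname(ct$parameter), table = m)
}

#' Assemble the integrated genotoxicity report
#'
#' Pure aggregation (no recomputation) of the per-stage outputs into one
#' schema-checked report object, serialisable to JSON. Optional stages may
#' be `NULL` and are marked `absent`.
#'
#' @param stages Named list of stage outputs; recognised names:
#'   `region_profile`, `cis`, `clonal`, `deg`, `enrichment`, `modules`,
#'   `methylation`, `signature_scores`, `intersections`, `chisq`,
#'   `fusions`.
#' @param config The [sim_config()] (or other run configuration) used.
#' @param seed Root seed of the run.
#' @return A list of class `genotox_report` with `stages`, `present`
#'   (named logical), `meta`.
#' @export
build_report <- function(stages, config = NULL, seed = NULL) {
  known <- c("region_profile", "cis", "clonal", "deg", "enrichment",
             "modules", "methylation", "signature_scores", "intersections",
             "chisq", "fusions")
  unknown <- setdiff(names(stages), known)
  if (length(unknown)) {
    abort(sprintf("unknown stage(s): %s", paste(unknown, collapse = ", ")))
  }
  present <- vapply(known, function(k) !is.null(stages[[k]]), logical(1))
  structure(list(
    stages = stages[names(stages)[!vapply(stages, is.null, logical(1))]],
    present = present,
    meta = list(
      package_version = as.character(utils::packageVersion("lentitox")),
      seed = seed,
      config = if (!is.null(config)) unclass(config) else NULL
    )
  ), class = "genotox_report")
}

#' Serialise a genotoxicity report to JSON
#'
#' Deterministic JSON (no timestamps), so two runs under the same seed
#' produce byte-identical files.
#'
#' @param report A [build_report()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "genotox_report"))
  simplify <- function(x) {
    if (inherits(x, "data.frame")) {
      as.list(dplyr::select(x, dplyr::where(~ !is.list(.x))))
    } else if (is.list(x)) lapply(x, simplify) else x
  }
  jsonlite::write_json(simplify(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.genotox_report <- function(x, ...) {
  cat("<genotox_report>\n")
  cat("  stages present:",
      paste(names(x$present)[x$present], collapse = ", "), "\n")
  absent <- names(x$present)[!x$present]
  if (length(absent)) cat("  absent:", paste(absent, collapse = ", "), "\n")
  if (!is.null(x$meta$seed)) cat("  seed:", x$meta$seed, "\n")
  invisible(x)
}
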