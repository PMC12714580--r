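#' Run the full synthetic genotoxicity study end to end
#'
#' Generates the synthetic multi-omic study defined by `config` and runs
#' every analysis stage in dependency order: integration-site annotation
#' and region profiles, cancer-TSS proximity, common-integration-site
#' detection, clonal tracking (iPSC early vs late per vector),
#' moderated differential expression per vector/cell against uninfected
#' controls with oncogene/TSG accounting and the between-vector
#' chi-square, over-representation and ranked enrichment, cancer-signature
#' derivation and scoring, co-expression modules with trait correlation,
#' delta-beta methylation calls with region summaries, vector-host
#' fusions, and the multi-omics intersections. Entirely deterministic
#' under `config$seed`.
#'
#' @param config A [sim_config()]; its seed drives all randomness.
#' @param thresholds A [pipeline_config()] of analysis thresholds.
#' @param outdir Optional directory; when given, intermediate TSVs and
#'   `report.json` are written there (must not exist unless
#'   `force = TRUE`).
#' @param force Overwrite an existing `outdir`.
#' @param wgcna_top Number of most-variable genes entering the
#'   co-expression analysis (default 1000).
#' @return A [build_report()] object (class `genotox_report`).
#' @export
run_genotox_pipeline <- function(config = sim_config(),
                                 thresholds = pipeline_config(seed = config$seed),
                                 outdir = NULL, force = FALSE,
                                 wgcna_top = 1000L) {
  stopifnot(inherits(config, "sim_config"),
            inherits(thresholds, "pipeline_config"))
  if (!is.null(outdir)) {
    if (dir.exists(outdir) && !force) {
      abort(sprintf("output directory exists: %s (use force = TRUE)", outdir))
    }
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  }

  inform("stage: synthetic genome")
  annotation <- make_genome(config)

  inform("stage: integration sites")
  is_sim <- simulate_insertion_sites(annotation, config)
  sites <- relative_counts(is_sim$sites)
  ann_sites <- annotate_sites(sites, annotation,
                              cancer_window_bp = thresholds$cancer_window_bp)
  region <- region_summaries(ann_sites)
  proximity <- cancer_proximity(ann_sites)
  cis <- sites |>
    group_by(.data$vector, .data$cell, .data$timepoint) |>
    group_modify(~ detect_cis(.x, linkage_bp = thresholds$cis_linkage_bp) |>
                   select(-"members")) |>
    ungroup()

  inform("stage: clonal tracking")
  clonal <- purrr::map_dfr(c("pHR", "pHV"), function(v) {
    e <- filter(sites, .data$vector == v, .data$cell == "iPSC",
                .data$timepoint == "early")
    l <- filter(sites, .data$vector == v, .data$cell == "iPSC",
                .data$timepoint == "late")
    track_clones(e, l, annotation, fold_threshold = thresholds$scc_fold,
                 alpha = thresholds$scc_alpha) |>
      mutate(vector = v, .before = 1)
  })

  inform("stage: differential expression")
  design <- expression_design(config)
  expr_sim <- simulate_expression(annotation, design, config)
  flags <- select(annotation$genes, "gene_id", "is_oncogene", "is_tsg")
  contrasts <- tidyr::crossing(vector = c("pHR", "pHV"),
                               cell = c("iPSC", "HLC"))
  deg <- purrr::pmap(contrasts, function(vector, cell) {
    keep <- design$cell == cell & design$vector %in% c(vector, "CTRL")
    sub <- design[keep, ]
    grp <- factor(ifelse(sub$infected, "infected", "control"),
                  levels = c("control", "infected"))
    de <- run_de(expr_sim$counts[, sub$sample, drop = FALSE], grp)
    call_degs(de, lfc = thresholds$deg_lfc, alpha = thresholds$deg_alpha,
              cancer_flags = flags)
  })
  names(deg) <- paste(contrasts$vector, contrasts$cell, sep = "_")
  deg_counts <- purrr::imap(deg, function(d, nm) {
    mutate(d$counts, contrast = nm, .before = 1)
  }) |> bind_rows()

  hlc_tab <- rbind(
    pHR = unlist(deg$pHR_HLC$counts[, c("n_oncogene", "n_tsg")]),
    pHV = unlist(deg$pHV_HLC$counts[, c("n_oncogene", "n_tsg")])
  )
  chisq <- tryCatch(onco_tsg_chisq(hlc_tab),
                    error = function(e) {
                      warn(paste("onco/TSG chi-square skipped:",
                                 conditionMessage(e)))
                      NULL
                    })

  inform("stage: enrichment")
  de_main <- deg$pHV_iPSC$table
  gene_sets <- simulate_gene_sets(annotation, config,
                                  planted = expr_sim$de_genes$gene_id)
  deg_all <- unique(unlist(lapply(deg, function(d) c(d$up, d$down))))
  enrich <- if (length(deg_all)) {
    ora(intersect(deg_all, de_main$gene_id), de_main$gene_id, gene_sets,
        alpha = thresholds$ora_alpha)
  } else NULL
  ranked <- rank_genes(de_main, by = "t_mod")
  gsea_res <- gsea(ranked, gene_sets$PLANTED_PROGRAM, n_perm = 500,
                   seed = derive_seed(config$seed, "gsea"))

  inform("stage: cancer signatures")
  tn <- simulate_tumor_normal(annotation, config)
  sig <- derive_signature(
    tn$counts[, tn$design$group == "tumor"],
    tn$counts[, tn$design$group == "normal"],
    lfc = thresholds$sig_lfc, alpha = thresholds$sig_alpha
  )
  expr_log <- normalize_log2(expr_sim$counts)
  scores <- score_samples(expr_log, sig, signature_name = "synthetic_cancer")
  score_means <- average_scores(
    scores, grouping = select(design, sample_id = "sample", "group"))

  inform("stage: co-expression network")
  vars <- apply(expr_log, 1, var)
  top <- names(sort(vars, decreasing = TRUE))[seq_len(min(wgcna_top,
                                                          nrow(expr_log)))]
  sub <- expr_log[top, ]
  sp <- pick_soft_power(sub)
  adj <- adjacency(sub, sp$power)
  tom <- tom_similarity(adj)
  modules <- detect_modules(tom)
  conn <- intramodular_connectivity(adj, modules)
  has_modules <- any(modules$module != "grey")
  me <- if (has_modules) module_eigengene(sub, modules) else NULL
  traits <- tibble(infected = as.integer(design$infected),
                   pHV = as.integer(design$vector == "pHV"),
                   iPSC = as.integer(design$cell == "iPSC"))
  mtc <- if (has_modules) module_trait_correlation(me, traits) else NULL
  is_genes <- unique(stats::na.omit(ann_sites$gene_id))
  mod_overlap <- if (has_modules) {
    module_overlap(modules, list(is_targets = is_genes))
  } else NULL

  inform("stage: methylation")
  meth_sim <- simulate_methylation(annotation, design, config)
  infected_s <- design$sample[design$infected]
  control_s <- design$sample[!design$infected]
  deltas <- delta_beta(meth_sim$beta[, infected_s, drop = FALSE],
                       meth_sim$beta[, control_s, drop = FALSE])
  dmps <- call_dmps(deltas, annotation$probes,
                    threshold = thresholds$delta_beta)
  region_tab <- summarize_by_region(dmps)
  hyper_genes <- promoter_hyper_genes(dmps)

  inform("stage: fusions and multi-omics integration")
  fusions <- simulate_fusions(is_sim$sites, annotation, config)
  dmr_genes <- dmps |>
    filter(.data$state != "none") |>
    pull("gene_id") |> unique() |> sort()
  layers <- list(is_genes = is_genes, deg_genes = deg_all,
                 dmr_genes = dmr_genes,
                 fusion_genes = unique(fusions$gene_id))
  intersections <- intersect_omics(layers)
  triples <- triple_positives(fusions$gene_id, is_genes, deg_all)

  report <- build_report(list(
    region_profile = list(region_pct = region$region_pct,
                          proximity = proximity),
    cis = count(cis, .data$vector, .data$cell, .data$timepoint,
                multi = .data$n_sites >= 2, name = "n_clusters"),
    clonal = list(flagged = filter(clonal, .data$flagged),
                  n_tested = nrow(clonal)),
    deg = list(counts = deg_counts),
    enrichment = list(ora = if (!is.null(enrich)) select(enrich, -"leading")
                      else NULL,
                      gsea = gsea_res),
    modules = list(sizes = count(modules, .data$module),
                   soft_power = sp$power,
                   trait_cor = mtc,
                   overlap = mod_overlap,
                   n_hubs = sum(conn$is_hub)),
    methylation = list(region_counts = region_tab,
                       n_promoter_hyper_genes = length(hyper_genes)),
    signature_scores = score_means,
    intersections = select(intersections, -"genes"),
    chisq = if (!is.null(chisq)) {
      list(chi2 = chisq$chi2, p = chisq$p)
    } else NULL,
    fusions = list(n_fusions = nrow(fusions),
                   triple_positive_n = length(triples$genes),
                   triple_positive_fraction = triples$fraction)
  ), config = config, seed = config$seed)

  if (!is.null(outdir)) {
    readr::write_tsv(ann_sites |> select(-dplyr::where(is.list)),
                     file.path(outdir, "annotated_sites.tsv"))
    readr::write_tsv(clonal, file.path(outdir, "clonal_tracking.tsv"))
    readr::write_tsv(deg_counts, file.path(outdir, "deg_counts.tsv"))
    readr::write_tsv(dmps, file.path(outdir, "methylation_calls.tsv"))
    readr::write_tsv(scores, file.path(outdir, "signature_scores.tsv"))
    readr::write_tsv(modules, file.path(outdir, "module_assignment.tsv"))
    write_report_json(report, file.path(outdir, "report.json"))
  }
  report
}
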