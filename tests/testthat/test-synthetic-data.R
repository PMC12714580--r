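test_that("sim_config validates its fields and names the offender", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(frac_oncogene = 0.7, frac_tsg = 0.6), "frac")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(clonal_fold = 0.5), "clonal_fold")
  expect_error(sim_config(dmr_delta = 1), "dmr_delta")
  expect_error(sim_config(n_genes = 50, n_modules = 3, module_size = 20),
               "module_size")
  expect_error(sim_config(is_per_sample = 10, n_clonal_genes = 20),
               "n_clonal_genes")
})

test_that("study layout covers vectors, conditions and replicates", {
  d <- study_design(sim_config(replicates = 3))
  expect_equal(nrow(d), 2 * 3 * 3)
  expect_setequal(unique(d$vector), c("pHR", "pHV"))
  expect_equal(nrow(dplyr::distinct(d, cell, timepoint)), 3)
  e <- expression_design(sim_config(replicates = 3))
  expect_equal(sum(!e$infected), 6)
  expect_false(anyDuplicated(e$sample) > 0)
})

test_that("make_genome is deterministic and honours the flag floor rule", {
  cfg <- small_config(seed = 1, frac_oncogene = 0.1, frac_tsg = 0.05,
                      n_genes = 100)
  a1 <- make_genome(cfg)
  a2 <- make_genome(cfg)
  expect_identical(a1, a2)
  expect_equal(sum(a1$genes$is_oncogene), 10)
  expect_equal(sum(a1$genes$is_tsg), 5)
  expect_false(any(a1$genes$is_oncogene & a1$genes$is_tsg))
})

test_that("gene models satisfy the structural invariants", {
  ann <- make_genome(small_config(seed = 7))
  g <- ann$genes
  minus <- g[g$strand == "-", ]
  expect_equal(minus$tss, minus$tx_end - 1)
  plus <- g[g$strand == "+", ]
  expect_equal(plus$tss, plus$tx_start)
  expect_true(all(g$cds_start >= g$tx_start & g$cds_end <= g$tx_end))
  # exons disjoint and inside the transcript, first/last flush with bounds
  by_gene <- split(ann$exons, ann$exons$gene_id)
  for (gid in names(by_gene)) {
    e <- by_gene[[gid]][order(by_gene[[gid]]$start), ]
    gg <- g[g$gene_id == gid, ]
    expect_true(all(e$start >= gg$tx_start & e$end <= gg$tx_end))
    if (nrow(e) > 1) expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
    expect_equal(e$start[1], gg$tx_start)
    expect_equal(e$end[nrow(e)], gg$tx_end)
  }
  # each probe carries exactly one class pair
  expect_true(all(ann$probes$position_class %in%
                    c("TSS1500", "TSS200", "5UTR", "Body", "3UTR")))
  expect_true(all(ann$probes$cpg_class %in%
                    c("island", "shore", "shelf", "opensea")))
})

test_that("integration-site generator conserves counts and identities", {
  cfg <- small_config(seed = 2)
  ann <- make_genome(cfg)
  sim <- simulate_insertion_sites(ann, cfg)
  per_sample <- dplyr::count(sim$sites, sample)
  expect_true(all(per_sample$n == cfg$is_per_sample))
  expect_equal(length(sim$clonal_genes), cfg$n_clonal_genes)
  # site identity persists across timepoints within a replicate
  e <- sim$sites[sim$sites$cell == "iPSC" & sim$sites$vector == "pHR" &
                   sim$sites$replicate == 1 & sim$sites$timepoint == "early", ]
  l <- sim$sites[sim$sites$cell == "iPSC" & sim$sites$vector == "pHR" &
                   sim$sites$replicate == 1 & sim$sites$timepoint == "late", ]
  expect_equal(e[, c("chrom", "pos")], l[, c("chrom", "pos")])
  expect_identical(simulate_insertion_sites(ann, cfg), sim)
})

test_that("clonal_fold = 1 leaves clone counts identical across timepoints", {
  cfg <- small_config(seed = 4, clonal_fold = 1)
  ann <- make_genome(cfg)
  sim <- simulate_insertion_sites(ann, cfg)
  agg <- annotate_sites(sim$sites, ann) |>
    dplyr::filter(.data$gene_id %in% sim$clonal_genes,
                  .data$cell == "iPSC") |>
    dplyr::group_by(.data$gene_id, .data$vector, .data$replicate,
                    .data$timepoint) |>
    dplyr::summarise(n = sum(.data$seq_count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "n")
  # depth factors differ per sample; the underlying draws are shared, so
  # early and late counts are proportional within a replicate
  ratio <- agg$late / agg$early
  by_rep <- split(ratio, paste(agg$vector, agg$replicate))
  for (r in by_rep) expect_lt(diff(range(r)) / mean(r), 0.2)
})

test_that("p_genic = 1 places every background site in a transcription unit", {
  cfg <- small_config(seed = 5, p_genic = 1)
  ann <- make_genome(cfg)
  sim <- simulate_insertion_sites(ann, cfg)
  annotated <- annotate_sites(sim$sites, ann)
  expect_true(all(!is.na(annotated$gene_id)))
})

test_that("expression generator plants detectable structure deterministically", {
  cfg <- small_config(seed = 6)
  ann <- make_genome(cfg)
  des <- expression_design(cfg)
  s1 <- simulate_expression(ann, des, cfg)
  expect_identical(simulate_expression(ann, des, cfg), s1)
  s2 <- simulate_expression(ann, des, small_config(seed = 16))
  expect_false(identical(s1$counts, s2$counts))
  expect_equal(dim(s1$counts), c(cfg$n_genes, nrow(des)))
  expect_equal(nrow(s1$de_genes), cfg$n_de_genes)
  expect_error(simulate_expression(ann, des[, c("sample", "group")], cfg),
               "infected")
})

test_that("planted modules reach the designed pairwise correlation", {
  cfg <- sim_config(seed = 11, n_genes = 600, n_de_genes = 0,
                    n_probes = 10, is_per_sample = 100, n_clonal_genes = 10)
  ann <- make_genome(cfg)
  sim <- simulate_expression(ann, expression_design(cfg), cfg)
  y <- log2(sim$counts + 0.5)
  r <- sapply(seq_len(cfg$n_modules), function(m) {
    ids <- sim$module_genes$gene_id[sim$module_genes$module == m]
    cm <- cor(t(y[ids, ]))
    mean(abs(cm[upper.tri(cm)]))
  })
  expect_gte(mean(r), 0.9 * cfg$module_cor)
})

test_that("methylation generator stays in [0,1] and is null-calibrated", {
  cfg <- small_config(seed = 8)
  ann <- make_genome(cfg)
  des <- expression_design(cfg)
  sim <- simulate_methylation(ann, des, cfg)
  expect_true(all(sim$beta >= 0 & sim$beta <= 1))
  expect_equal(length(sim$dmr_probes), cfg$n_dmr_probes)
  expect_identical(simulate_methylation(ann, des, cfg), sim)

  # dmr_delta = 0: no probe should cross the hyper threshold
  cfg0 <- small_config(seed = 9, dmr_delta = 0)
  sim0 <- simulate_methylation(ann, des, cfg0)
  d <- delta_beta(sim0$beta[, des$sample[des$infected]],
                  sim0$beta[, des$sample[!des$infected]])
  calls <- call_dmps(d, ann$probes)
  expect_lte(mean(calls$state == "hyper"), 0.01)
})

test_that("fusion generator is conservative by construction", {
  cfg <- small_config(seed = 10, fusion_fraction = 1)
  ann <- make_genome(cfg)
  sim <- simulate_insertion_sites(ann, cfg)
  fus <- simulate_fusions(sim$sites, ann, cfg)
  annotated <- annotate_sites(sim$sites, ann)
  genic_n <- sum(!is.na(annotated$gene_id))
  expect_equal(nrow(fus), genic_n)
  # every fusion gene has an IS in the same sample
  is_pairs <- annotated |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::distinct(.data$gene_id, .data$sample)
  expect_equal(nrow(dplyr::anti_join(
    dplyr::distinct(fus, .data$gene_id, .data$sample),
    is_pairs, by = c("gene_id", "sample"))), 0)

  cfg0 <- small_config(seed = 10, fusion_fraction = 0)
  expect_equal(nrow(simulate_fusions(sim$sites, ann, cfg0)), 0)
})
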