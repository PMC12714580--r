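test_that("relative counts normalise within each sample", {
  x <- tibble::tibble(sample = "s1", seq_count = c(5, 5, 10))
  expect_equal(relative_counts(x)$rel_count, c(0.25, 0.25, 0.5))
  expect_equal(relative_counts(
    tibble::tibble(sample = "s", seq_count = 7))$rel_count, 1)
  expect_error(relative_counts(tibble::tibble(sample = "s", seq_count = 0)),
               ">= 1")

  cfg <- small_config(seed = 3)
  sim <- simulate_insertion_sites(make_genome(cfg), cfg)
  sums <- relative_counts(sim$sites) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(s = sum(.data$rel_count))
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("annotation resolves the worked single-gene fixture", {
  ann <- worked_gene("+")
  sites <- tibble::tibble(chrom = "chr1", pos = c(1050, 1500, 1150, 1850, 500),
                          strand = "+", seq_count = 1, sample = "s")
  a <- annotate_sites(sites, ann)
  # 1050: in exon1 before the ATG -> 5'UTR; 1150/1850 inside the CDS ->
  # exon (CDS precedence); 1500 between exons -> intron
  expect_equal(a$region, c("5UTR", "intron", "exon", "exon", "intergenic"))
  expect_equal(a$norm_pos[1], 0.05)
  expect_equal(a$dist_atg[1], 50)      # bp upstream of the CDS start
  expect_equal(a$norm_pos[2], 0.5)
  expect_equal(a$dist_tss[1], 50)
  expect_true(is.na(a$gene_id[5]))
  expect_equal(a$near_gene_id[5], "gA")
})

test_that("annotation mirrors coordinates on the minus strand", {
  ann <- worked_gene("-")
  sites <- tibble::tibble(chrom = "chr1", pos = c(1950, 1500, 1050),
                          strand = "+", seq_count = 1, sample = "s")
  a <- annotate_sites(sites, ann)
  # on '-': 5' side is the high-coordinate side; CDS is still 1100-1900
  expect_equal(a$region, c("5UTR", "intron", "3UTR"))
  expect_equal(a$norm_pos[1], (2000 - 1 - 1950) / 1000)
  expect_equal(a$dist_tss[1], 1999 - 1950)
  expect_equal(a$dist_atg[1], 1950 - 1899)
  expect_equal(a$dist_stop[3], 1100 - 1050)
})

test_that("overlapping genes resolve to the nearer TSS, ties lexicographic", {
  ann <- toy_annotation(
    genes = tibble::tibble(
      gene_id = c("gB", "gA"), chrom = "chr1", strand = "+",
      tx_start = c(0, 0), tx_end = c(1000, 1000),
      cds_start = c(100, 100), cds_end = c(900, 900)),
    exons = tibble::tibble(gene_id = c("gB", "gA"), start = 0, end = 1000,
                           rank = 1L)
  )
  a <- annotate_sites(tibble::tibble(chrom = "chr1", pos = 500, strand = "+",
                                     seq_count = 1, sample = "s"), ann)
  expect_equal(a$gene_id, "gA")   # equidistant -> lexicographically smaller
  expect_error(annotate_sites(
    tibble::tibble(chrom = "chrX", pos = 1, strand = "+", seq_count = 1,
                   sample = "s"), ann), "unknown chromosome")
})

test_that("annotation matches exhaustive per-base classification", {
  cfg <- sim_config(seed = 12, n_chrom = 1, genome_len = 1e5, n_genes = 12,
                    is_per_sample = 20, n_clonal_genes = 2, n_probes = 10,
                    n_modules = 1L, module_size = 5L)
  ann <- make_genome(cfg)
  oracle <- perbase_oracle(ann, 1e5)
  set.seed(31)
  pos <- sample(0:(1e5 - 1), 500)
  a <- annotate_sites(tibble::tibble(chrom = "chr1", pos = pos, strand = "+",
                                     seq_count = 1, sample = "s"), ann)
  expect_equal(a$region, oracle$region[pos + 1])
  expect_equal(a$gene_id, oracle$gene[pos + 1])
})

test_that("region percentages sum to 100 and degenerate profiles are exact", {
  ann <- worked_gene("+")
  allex <- tibble::tibble(chrom = "chr1", pos = rep(1850, 4), strand = "+",
                          seq_count = 1, sample = "s")
  rs <- region_summaries(annotate_sites(allex, ann))
  pct <- rs$region_pct
  expect_equal(pct$pct[pct$region == "exon"], 100)
  expect_equal(sum(pct$pct), 100)

  cfg <- small_config(seed = 13)
  sim <- simulate_insertion_sites(make_genome(cfg), cfg)
  rs2 <- region_summaries(annotate_sites(sim$sites, make_genome(cfg)))
  tot <- rs2$region_pct |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(s = sum(.data$pct))
  expect_true(all(abs(tot$s - 100) < 1e-6))
})

test_that("uniform sites recover a gene's intron share by length", {
  # one gene, 50% intron by construction: exons 0-2500 and 7500-10000
  ann <- toy_annotation(
    genes = tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                           tx_start = 0, tx_end = 10000,
                           cds_start = 10, cds_end = 9990),
    exons = tibble::tibble(gene_id = "g1", start = c(0, 7500),
                           end = c(2500, 10000), rank = 1:2))
  set.seed(1)
  sites <- tibble::tibble(chrom = "chr1", pos = sample(0:9999, 10000, TRUE),
                          strand = "+", seq_count = 1, sample = "s")
  pct <- region_summaries(annotate_sites(sites, ann))$region_pct
  expect_lt(abs(pct$pct[pct$region == "intron"] - 50), 3)
})

test_that("cancer proximity frequency spans its extremes", {
  genes <- tibble::tibble(
    gene_id = c("gC", "gN"), chrom = "chr1", strand = "+",
    tx_start = c(0, 5e5), tx_end = c(1000, 5e5 + 1000),
    cds_start = c(10, 5e5 + 10), cds_end = c(990, 5e5 + 990),
    is_oncogene = c(TRUE, FALSE), is_tsg = FALSE)
  exons <- tibble::tibble(gene_id = c("gC", "gN"),
                          start = c(0, 5e5), end = c(1000, 5e5 + 1000),
                          rank = 1L)
  ann <- toy_annotation(genes, exons)
  at_tss <- annotate_sites(tibble::tibble(
    chrom = "chr1", pos = c(0, 10, 50), strand = "+", seq_count = 1,
    sample = "s"), ann)
  expect_equal(cancer_proximity(at_tss)$frequency, 1)
  far <- annotate_sites(tibble::tibble(
    chrom = "chr1", pos = c(5e5, 5e5 + 10), strand = "+", seq_count = 1,
    sample = "s"), ann)
  expect_equal(cancer_proximity(far)$frequency, 0)

  # no cancer genes flagged at all
  ann0 <- ann
  ann0$genes$is_oncogene <- FALSE
  z <- annotate_sites(tibble::tibble(chrom = "chr1", pos = 5, strand = "+",
                                     seq_count = 1, sample = "s"), ann0)
  expect_equal(cancer_proximity(z)$frequency, 0)
})

test_that("planted proximity fractions are recovered", {
  # place a known fraction of sites within the window of the cancer TSS
  genes <- tibble::tibble(
    gene_id = "gC", chrom = "chr1", strand = "+",
    tx_start = 4e5, tx_end = 4e5 + 1000, cds_start = 4e5 + 10,
    cds_end = 4e5 + 990, is_oncogene = TRUE, is_tsg = FALSE)
  exons <- tibble::tibble(gene_id = "gC", start = 4e5, end = 4e5 + 1000,
                          rank = 1L)
  ann <- toy_annotation(genes, exons)
  set.seed(41)
  n <- 5000
  near <- runif(n) < 0.3
  pos <- ifelse(near, round(runif(n, 3e5, 5e5 - 1)),
                round(runif(n, 6e5, 2e6)))
  f <- cancer_proximity(annotate_sites(tibble::tibble(
    chrom = "chr1", pos = pos, strand = "+", seq_count = 1, sample = "s"),
    ann))$frequency
  expect_lt(abs(f - 0.3), 0.02)
})
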