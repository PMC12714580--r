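beta_fixture <- function() {
  case <- matrix(c(0.9, 0.9, 0.9,
                   0.5, 0.6, 0.7,
                   0.1, 0.1, 0.1,
                   0.4, 0.4, 0.4), 4, 3, byrow = TRUE,
                 dimnames = list(paste0("cg", 1:4), paste0("c", 1:3)))
  ctrl <- matrix(c(0.5, 0.5, 0.5,
                   0.6, 0.6, 0.6,
                   0.4, 0.4, 0.4,
                   0.4, 0.4, 0.4), 4, 3, byrow = TRUE,
                 dimnames = list(paste0("cg", 1:4), paste0("n", 1:3)))
  list(case = case, ctrl = ctrl)
}

test_that("delta-beta is the difference of arm means", {
  f <- beta_fixture()
  d <- delta_beta(f$case, f$ctrl)
  expect_equal(d$delta_beta, c(0.4, 0.0, -0.3, 0.0), tolerance = 1e-12)
  expect_equal(delta_beta(f$case, f$case)$delta_beta, rep(0, 4))
  expect_error(delta_beta(f$case[, 1, drop = FALSE], f$ctrl), "2 samples")
  noshare <- f$ctrl
  rownames(noshare) <- paste0("x", 1:4)
  expect_error(delta_beta(f$case, noshare), "shared")
  # probes with too many missing values are dropped with a warning
  miss <- f$case
  miss[1, 2:3] <- NA
  expect_warning(d2 <- delta_beta(miss, f$ctrl), "fewer than 2")
  expect_equal(nrow(d2), 3)
})

test_that("DMP calls are strict at the threshold", {
  d <- tibble::tibble(probe_id = paste0("cg", 1:5),
                      delta_beta = c(0.2, 0.201, -0.2, -0.25, 0))
  calls <- call_dmps(d)
  expect_equal(calls$state, c("none", "hyper", "none", "hypo", "none"))
  expect_error(call_dmps(d, threshold = 0), "0, 1")
  zero <- call_dmps(tibble::tibble(probe_id = "cg1", delta_beta = 0))
  expect_equal(zero$state, "none")
  # unannotated probes fall back to the unknown class
  pa <- tibble::tibble(probe_id = "cg1", gene_id = "g1",
                       position_class = "Body", cpg_class = "island")
  expect_message(c2 <- call_dmps(d, pa), "unknown")
  expect_equal(c2$position_class, c("Body", rep("unknown", 4)))
})

test_that("region cross-tab is complete and conserves totals", {
  recs <- tibble::tibble(
    probe_id = "cg1", delta_beta = 0.5, state = "hyper",
    position_class = "TSS200", cpg_class = "island", gene_id = "g1")
  tab <- summarize_by_region(recs)
  expect_equal(sum(tab$n), 1)
  expect_equal(tab$n[tab$position_class == "TSS200" &
                       tab$cpg_class == "island" & tab$state == "hyper"], 1)
  expect_equal(nrow(tab), 5 * 4 * 2)
  expect_equal(tab$log2_n, log2(tab$n + 1))

  # independent tally on a random 50-record fixture
  set.seed(36)
  recs2 <- tibble::tibble(
    probe_id = paste0("cg", 1:50),
    delta_beta = runif(50, -0.5, 0.5),
    state = sample(c("hyper", "hypo", "none"), 50, replace = TRUE),
    position_class = sample(c("TSS1500", "TSS200", "Body"), 50, TRUE),
    cpg_class = sample(c("island", "opensea"), 50, TRUE),
    gene_id = "g")
  tab2 <- summarize_by_region(recs2)
  expect_equal(sum(tab2$n), sum(recs2$state != "none"))
  for (i in sample(nrow(tab2), 10)) {
    want <- sum(recs2$state == tab2$state[i] &
                  recs2$position_class == tab2$position_class[i] &
                  recs2$cpg_class == tab2$cpg_class[i])
    expect_equal(tab2$n[i], want)
  }
  # marginals invariant under record permutation
  tab3 <- summarize_by_region(recs2[sample(50), ])
  expect_equal(dplyr::arrange(tab2, position_class, cpg_class, state),
               dplyr::arrange(tab3, position_class, cpg_class, state))
})

test_that("promoter hypermethylation gene list is exact on construction", {
  recs <- tibble::tibble(
    probe_id = paste0("cg", 1:5),
    delta_beta = c(0.5, 0.5, 0.5, -0.5, 0.5),
    state = c("hyper", "hyper", "hyper", "hypo", "hyper"),
    position_class = c("TSS200", "Body", "TSS1500", "TSS200", "TSS200"),
    cpg_class = c("island", "island", "island", "island", "opensea"),
    gene_id = c("gA", "gB", "gA", "gC", "gD"))
  # gB: body only; gC: hypo; gD: not island; gA twice -> once
  expect_equal(promoter_hyper_genes(recs), "gA")
})

test_that("planted methylation shifts are recovered at the 0.2 rule", {
  cfg <- sim_config(seed = 37)
  ann <- make_genome(cfg)
  des <- expression_design(cfg)
  sim <- simulate_methylation(ann, des, cfg)
  # 3 vs 3: one vector's late iPSC arm against the iPSC controls
  case <- sim$beta[, des$sample[des$vector == "pHV" & des$cell == "iPSC" &
                                  des$timepoint == "late"]]
  ctrl <- sim$beta[, des$sample[des$vector == "CTRL" & des$cell == "iPSC"]]
  calls <- call_dmps(delta_beta(case, ctrl), ann$probes)
  hit <- calls$probe_id[calls$state != "none"]
  expect_gte(mean(sim$dmr_probes %in% hit), 0.9)
  nulls <- setdiff(calls$probe_id, sim$dmr_probes)
  expect_lte(mean(nulls %in% hit), 0.01)
})
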