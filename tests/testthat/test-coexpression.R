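test_that("adjacency is the powered absolute correlation", {
  set.seed(31)
  m <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(sprintf("g%02d", 1:10), NULL))
  a1 <- adjacency(m, 1)
  expect_equal(unname(a1 - diag(nrow(a1))),
               unname(abs(cor(t(m))) - diag(nrow(a1))))
  # duplicated profiles are maximally adjacent
  m2 <- rbind(m, dup = m[1, ])
  a <- adjacency(m2, 6)
  expect_equal(unname(a["dup", "g01"]), 1)
  a6 <- adjacency(m, 6)
  expect_true(isSymmetric(unname(a6)))
  expect_true(all(a6 >= 0 & a6 <= 1))
  expect_error(adjacency(m, 0.5), ">= 1")
  expect_warning(adjacency(rbind(m, flat = rep(1, 12)), 2), "zero-variance")
})

test_that("topological overlap matches its formula limits and the naive oracle", {
  # fully-shared binary neighbourhood with a_ij = 1: TOM = 1 for the pair
  a <- matrix(0, 4, 4)
  a[1, ] <- a[, 1] <- c(1, 1, 1, 0)
  a[2, ] <- a[, 2] <- c(1, 1, 1, 0)
  a[3, 4] <- a[4, 3] <- 0.4
  diag(a) <- 1
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], 1)

  # zero adjacency: off-diagonal TOM = 0
  z <- diag(5)
  tz <- tom_similarity(z)
  expect_equal(unname(tz - diag(5)), matrix(0, 5, 5))

  set.seed(32)
  for (i in 1:5) {
    r <- matrix(runif(30 * 30), 30)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    tom <- tom_similarity(a)
    expect_equal(unname(tom), tom_oracle(a), tolerance = 1e-12)
    expect_true(isSymmetric(unname(tom)))
    expect_true(all(tom >= 0 & tom <= 1))
  }
  expect_error(tom_similarity(matrix(runif(9), 3)), "symmetric")
})

test_that("soft power selection returns an audit table and handles extremes", {
  set.seed(33)
  # heavy-tailed latent structure so low powers have a negative slope
  f <- rnorm(16)
  m <- matrix(rnorm(60 * 16, sd = 0.4), 60, 16) +
    outer(c(rep(1, 15), rep(0, 45)), f)
  rownames(m) <- sprintf("g%02d", 1:60)
  sp <- suppressWarnings(pick_soft_power(m))
  expect_s3_class(sp$fit, "tbl_df")
  expect_equal(nrow(sp$fit), 10)
  expect_true(all(c("power", "r2", "mean_k") %in% names(sp$fit)))
  expect_true(sp$power %in% 1:10)
  # degenerate target: the first power with non-negative fit wins
  sp0 <- suppressWarnings(pick_soft_power(m, r2_target = 0))
  expect_lte(sp0$power, sp$power)
  expect_error(pick_soft_power(m[, 1:4]), "8 samples")
})

test_that("planted blocks are recovered and pure noise stays grey", {
  cfg <- sim_config(seed = 3, n_de_genes = 0)
  ann <- make_genome(cfg)
  sim <- simulate_expression(ann, expression_design(cfg), cfg)
  y <- normalize_log2(sim$counts)
  set.seed(3)
  genes <- c(sim$module_genes$gene_id,
             sample(setdiff(rownames(y), sim$module_genes$gene_id), 400))
  sub <- y[genes, ]
  sp <- suppressWarnings(pick_soft_power(sub))
  mods <- detect_modules(tom_similarity(adjacency(sub, sp$power)))
  expect_equal(length(setdiff(unique(mods$module), "grey")), 2)
  truth <- dplyr::case_when(
    genes %in% sim$module_genes$gene_id[sim$module_genes$module == 1] ~ 1,
    genes %in% sim$module_genes$gene_id[sim$module_genes$module == 2] ~ 2,
    TRUE ~ 0)
  expect_gte(ari_oracle(truth, mods$module), 0.9)

  # min_size larger than everything -> all grey
  allgrey <- detect_modules(tom_similarity(adjacency(sub[1:40, ], 6)),
                            min_size = 100)
  expect_true(all(allgrey$module == "grey"))
})

test_that("eigengenes are PCA summaries with the documented invariances", {
  set.seed(34)
  f <- rnorm(12)
  m <- matrix(rnorm(20 * 12, sd = 0.3), 20, 12) + outer(rep(1, 20), f)
  rownames(m) <- sprintf("g%02d", 1:20)
  colnames(m) <- paste0("s", 1:12)
  asg <- tibble::tibble(gene_id = rownames(m), module = "turquoise")
  me <- module_eigengene(m, asg)
  expect_equal(dim(me), c(12, 1))
  expect_gt(cor(me[, 1], f), 0.95)
  # duplicating every gene leaves the eigengene unchanged
  m2 <- rbind(m, m)
  rownames(m2) <- sprintf("g%02d", 1:40)
  asg2 <- tibble::tibble(gene_id = rownames(m2), module = "turquoise")
  me2 <- module_eigengene(m2, asg2)
  expect_equal(abs(cor(me[, 1], me2[, 1])), 1, tolerance = 1e-10)
  # single-gene module: the standardized profile itself
  asg1 <- tibble::tibble(gene_id = "g01", module = "blue")
  me1 <- module_eigengene(m, asg1)
  expect_equal(unname(me1[, 1]), as.numeric(scale(m[1, ])),
               tolerance = 1e-10)
})

test_that("module-trait correlation matches the covariance formula", {
  me <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1,
               dimnames = list(paste0("s", 1:6), "turquoise"))
  traits <- data.frame(grp = c(0, 0, 0, 1, 1, 1))
  mtc <- module_trait_correlation(me, traits)
  x <- me[, 1]; yv <- traits$grp
  r_hand <- sum((x - mean(x)) * (yv - mean(yv))) /
    sqrt(sum((x - mean(x))^2) * sum((yv - mean(yv))^2))
  expect_equal(mtc$r, r_hand)
  # eigengene equal to the indicator
  me2 <- matrix(c(0, 0, 0, 1, 1, 1), 6, 1,
                dimnames = list(paste0("s", 1:6), "blue"))
  expect_equal(module_trait_correlation(me2, traits)$r, 1)
  expect_error(module_trait_correlation(me, data.frame(c0 = rep(1, 6))),
               "constant")
})

test_that("intramodular connectivity bounds and hub flags hold", {
  set.seed(35)
  m <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  a <- adjacency(m, 4)
  asg <- tibble::tibble(gene_id = rownames(m),
                        module = rep(c("turquoise", "blue"), each = 15))
  conn <- intramodular_connectivity(a, asg)
  expect_true(all(conn$kWithin <= conn$kTotal + 1e-12))
  expect_equal(sum(conn$is_hub), 4)  # top decile of 15 -> 2 per module
})

test_that("module overlap spans its extremes", {
  asg <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                        module = rep(c("turquoise", "grey"), each = 20))
  full <- module_overlap(asg, list(S = sprintf("g%02d", 1:20)))
  expect_equal(full$overlap_pct, 100)
  disjoint <- module_overlap(asg, list(S = sprintf("g%02d", 21:40)))
  expect_equal(disjoint$overlap_pct, 0)
  expect_equal(disjoint$p, 1)
})
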