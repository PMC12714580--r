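test_that("log2-CPM normalisation follows the definition", {
  m <- matrix(c(0, 10, 999990), 3, 1,
              dimnames = list(c("a", "b", "c"), "s1"))
  y <- normalize_log2(m)
  expect_equal(y["a", 1], log2(0.5 / 1e6 * 1e6))
  # doubling all counts of a sample leaves log2-CPM almost unchanged
  # (exact up to the prior count)
  m2 <- matrix(rpois(40, 50) + 1, 10, 4,
               dimnames = list(letters[1:10], paste0("s", 1:4)))
  y1 <- normalize_log2(m2, prior = 0)
  y2 <- normalize_log2(m2 * 2, prior = 0)
  expect_equal(y1, y2)
  # monotone in count for a fixed sample
  ord <- order(m2[, 1])
  expect_true(all(diff(normalize_log2(m2)[ord, 1]) >= 0))
  expect_error(normalize_log2(matrix(0, 2, 1)), "library size")
  expect_error(normalize_log2(matrix(-1, 1, 1)), "non-negative")
})

test_that("per-gene OLS equals group-mean differences and normal equations", {
  set.seed(5)
  n <- 6
  x <- matrix(rnorm(20 * n), 20, n, dimnames = list(sprintf("g%02d", 1:20),
                                                    paste0("s", 1:n)))
  grp <- factor(rep(c("a", "b"), each = 3))
  design <- model.matrix(~ grp)
  fit <- fit_linear_model(x, design)
  expect_equal(unname(fit$log2fc),
               unname(rowMeans(x[, 4:6]) - rowMeans(x[, 1:3])))
  # constant gene
  xc <- rbind(x, const = rep(5, n))
  fitc <- fit_linear_model(xc, design)
  expect_equal(unname(fitc$sigma2["const"]), 0)
  # brute-force normal equations per gene
  xtx_inv <- solve(t(design) %*% design)
  for (g in 1:20) {
    beta <- xtx_inv %*% t(design) %*% x[g, ]
    expect_equal(unname(fit$coefficients[g, ]), as.vector(beta))
  }
  expect_error(fit_linear_model(x, cbind(design, design[, 2])), "rank")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(6)
  for (i in 1:20) {
    p <- runif(200)
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("moderated t reduces to ordinary t at d0 = 0 and pools at Inf", {
  set.seed(7)
  x <- matrix(rnorm(50 * 6, sd = rep(sqrt(rchisq(50, 4) / 4), 6)), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6)))
  design <- model.matrix(~ rep(c(0, 1), each = 3))
  fit <- fit_linear_model(x, design)
  r0 <- ebayes_moderate(fit, d0 = 0, s02 = 1)
  t_ord <- fit$log2fc / (sqrt(fit$sigma2) * fit$stdev_unscaled)
  expect_lt(max(abs(r0$t_mod - unname(t_ord))), 1e-10)

  rInf <- ebayes_moderate(fit, d0 = Inf, s02 = 2)
  expect_true(all(rInf$s2_post == 2))

  # shrinkage: posterior variance lies between s2_g and s02
  r <- ebayes_moderate(fit)
  s02 <- attr(r, "s02")
  between <- (r$s2_post >= pmin(r$sigma^2, s02) - 1e-12) &
    (r$s2_post <= pmax(r$sigma^2, s02) + 1e-12)
  expect_true(all(between))
})

test_that("scaled-F simulation recovers the prior parameters", {
  set.seed(8)
  d0_true <- 8
  s02_true <- 4
  df <- 4
  n <- 5000
  s2 <- s02_true * (d0_true / rchisq(n, d0_true)) * (rchisq(n, df) / df)
  fit <- structure(list(
    sigma2 = s2, df_resid = df, log2fc = rnorm(n),
    stdev_unscaled = sqrt(2 / 3), avg_expr = rep(0, n),
    coefficients = matrix(0, n, 2)), class = "de_fit")
  r <- ebayes_moderate(fit)
  expect_lt(abs(attr(r, "s02") - s02_true) / s02_true, 0.10)
  expect_lt(abs(attr(r, "d0") - d0_true) / d0_true, 0.25)
})

test_that("moderated statistics agree with an independent implementation", {
  skip_if_not_installed("limma")
  set.seed(9)
  counts <- matrix(rnbinom(300 * 8, mu = 150, size = 10), 300, 8,
                   dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:8)))
  grp <- factor(rep(c("a", "b"), each = 4))
  y <- normalize_log2(counts)
  design <- model.matrix(~ grp)
  mine <- ebayes_moderate(fit_linear_model(y, design))
  lf <- limma::eBayes(limma::lmFit(y, design))
  expect_equal(mine$log2fc, unname(lf$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(attr(mine, "d0"), lf$df.prior, tolerance = 0.05)
  expect_equal(attr(mine, "s02"), lf$s2.prior, tolerance = 0.02)
  expect_equal(mine$t_mod, unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(mine$p, unname(lf$p.value[, 2]), tolerance = 1e-6)
})

test_that("DEG calls apply strict thresholds and count cancer flags", {
  res <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    log2fc = c(1.0, 1.5, -2, 0.5),
    p_adj = c(0.001, 0.001, 0.001, 0.5))
  flags <- tibble::tibble(gene_id = c("b", "c"),
                          is_oncogene = c(TRUE, FALSE),
                          is_tsg = c(FALSE, TRUE))
  calls <- call_degs(res, cancer_flags = flags)
  expect_equal(calls$up, "b")      # exactly 1.0 is not > 1
  expect_equal(calls$down, "c")
  expect_equal(calls$counts$n_oncogene, 1)
  expect_equal(calls$counts$n_tsg, 1)
  none <- call_degs(dplyr::mutate(res, p_adj = 1))
  expect_equal(none$counts$n_deg, 0)
})

test_that("planted differential expression is called with controlled FDR", {
  cfg <- sim_config(seed = 19, n_modules = 0)
  ann <- make_genome(cfg)
  des <- expression_design(cfg)
  sim <- simulate_expression(ann, des, cfg)
  keep <- des$cell == "iPSC" & des$vector %in% c("pHV", "CTRL") &
    des$timepoint == "early"
  sub <- des[keep, ]
  grp <- factor(ifelse(sub$infected, "inf", "ctl"), levels = c("ctl", "inf"))
  de <- run_de(sim$counts[, sub$sample], grp)
  calls <- call_degs(de)
  deg <- c(calls$up, calls$down)
  sens <- mean(sim$de_genes$gene_id %in% deg)
  fdr <- if (length(deg)) mean(!deg %in% sim$de_genes$gene_id) else 0
  expect_gte(sens, 0.8)
  expect_lte(fdr, 0.08)
})

test_that("tidiers summarise fitted objects", {
  set.seed(10)
  x <- matrix(rnorm(60), 10, 6, dimnames = list(letters[1:10],
                                                paste0("s", 1:6)))
  fit <- fit_linear_model(x, model.matrix(~ rep(0:1, each = 3)))
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 10)
  expect_named(td, c("gene_id", "log2fc", "sigma", "df_resid"))
  gl <- generics::glance(fit)
  expect_equal(gl$n_genes, 10)
  r <- ebayes_moderate(fit)
  expect_true(all(c("d0", "s02") %in% names(generics::glance(r))))
})
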