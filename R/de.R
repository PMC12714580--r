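#' Log2 counts-per-million normalisation
#'
#' `log2((count + prior) / library_size * 1e6)` per cell, where
#' `library_size` is the column sum of raw counts. Total-count CPM is the
#' minimal defensible normalisation given gene-level counts; it is
#' recorded in the run log of the full pipeline.
#'
#' @param counts Non-negative gene x sample count matrix.
#' @param prior Prior count added before the log (default 0.5).
#' @return Matrix of log2-CPM values, same dimensions and dimnames.
#' @examples
#' normalize_log2(matrix(c(0, 10), 2, 1, dimnames = list(c("a", "b"), "s1")))
#' @export
normalize_log2 <- function(counts, prior = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative.")
  lib <- colSums(counts)
  if (any(lib == 0)) abort("zero library size in at least one sample.")
  log2(sweep(counts + prior, 2, lib, `/`) * 1e6)
}

#' Fit per-gene linear models
#'
#' Ordinary least squares of every gene's (log) expression on a design
#' matrix, sharing one QR decomposition across genes. The contrast of
#' interest is a single coefficient (by default the second column, i.e.
#' treated minus control in a two-group `~ group` design).
#'
#' @param x Gene x sample numeric matrix (typically [normalize_log2()]
#'   output).
#' @param design Design matrix (samples x coefficients), full rank, with
#'   at least one residual degree of freedom.
#' @param coef Index or name of the coefficient of interest.
#' @return A list of class `de_fit`: `coefficients` (genes x coefficients),
#'   `log2fc` (coefficient of interest), `sigma2`, `df_resid`,
#'   `stdev_unscaled` (unscaled SE of the contrast), `avg_expr`, `coef`.
#' @export
fit_linear_model <- function(x, design, coef = 2L) {
  x <- as.matrix(x)
  design <- as.matrix(design)
  if (nrow(design) != ncol(x)) {
    abort("nrow(design) must equal ncol(x).")
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) abort("design matrix is rank deficient.")
  df_resid <- nrow(design) - ncol(design)
  if (df_resid < 1L) abort("at least one residual degree of freedom needed.")

  beta <- t(qr.coef(qr_d, t(x)))
  fitted <- beta %*% t(design)
  resid <- x - fitted
  sigma2 <- rowSums(resid^2) / df_resid

  xtx_inv <- chol2inv(qr.R(qr_d))
  dimnames(xtx_inv) <- list(colnames(design), colnames(design))
  if (is.character(coef)) coef <- match(coef, colnames(design))
  stdev_unscaled <- sqrt(xtx_inv[coef, coef])

  structure(list(
    coefficients = beta,
    log2fc = beta[, coef],
    sigma2 = sigma2,
    df_resid = df_resid,
    stdev_unscaled = stdev_unscaled,
    avg_expr = rowMeans(x),
    coef = coef
  ), class = "de_fit")
}

# Invert the trigamma function by Newton iteration (monotone decreasing).
trigamma_inverse <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v) || v <= 0) return(Inf)
    if (v > 1e7) return(1 / sqrt(v))
    y <- 0.5 + 1 / v
    for (i in 1:60) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / v) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) / y < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks per-gene residual variances toward a common prior and computes
#' moderated t-statistics. Under the hierarchical model
#' `s_g^2 ~ s0^2 * chisq(d) / d` scaled-F assumptions, the prior degrees
#' of freedom `d0` and prior variance `s0^2` are estimated by the method
#' of moments on `log(s_g^2)` using digamma/trigamma identities; the
#' posterior variance is `s_tilde^2 = (d0 * s0^2 + df * s_g^2) /
#' (d0 + df)` and the moderated t has `df + d0` degrees of freedom. When
#' the observed log-variances are no more dispersed than sampling alone
#' explains, `d0` is infinite and all genes share `s0^2`; if the
#' trigamma inversion fails to converge the same fallback applies with a
#' warning.
#'
#' @param fit A [fit_linear_model()] object.
#' @param d0,s02 Optional fixed prior df / prior variance overriding the
#'   estimate (`d0 = 0` reduces to the ordinary t-statistic, `d0 = Inf`
#'   pools all genes).
#' @return A tibble of class `de_table` with `gene_id`, `log2fc`,
#'   `avg_expr`, `sigma`, `df_resid`, `s2_post`, `t_mod`, `p`, `p_adj`,
#'   plus attributes `d0` and `s02`.
#' @export
ebayes_moderate <- function(fit, d0 = NULL, s02 = NULL) {
  stopifnot(inherits(fit, "de_fit"))
  s2 <- fit$sigma2
  df <- fit$df_resid
  ok <- s2 > 0 & is.finite(s2)
  if (is.null(d0) || is.null(s02)) {
    if (sum(ok) < 10L) {
      abort("need at least 10 genes with positive residual variance.")
    }
    z <- log(s2[ok])
    e <- z - digamma(df / 2) + log(df / 2)
    ebar <- mean(e)
    evar <- var(e)
    rhs <- evar - trigamma(df / 2)
    if (!is.finite(rhs)) {
      warn("trigamma inversion failed; falling back to d0 = Inf.")
      rhs <- 0
    }
    if (rhs > 0) {
      est_d0 <- 2 * trigamma_inverse(rhs)
      est_s02 <- exp(ebar + digamma(est_d0 / 2) - log(est_d0 / 2))
    } else {
      est_d0 <- Inf
      est_s02 <- exp(ebar)
    }
    d0 <- d0 %||% est_d0
    s02 <- s02 %||% est_s02
  }

  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + df * s2) / (d0 + df)
  }
  t_mod <- fit$log2fc / (sqrt(s2_post) * fit$stdev_unscaled)
  df_total <- df + d0
  p <- 2 * pt(-abs(t_mod), df = df_total)

  out <- tibble(
    gene_id = names(fit$sigma2) %||% rownames(fit$coefficients),
    log2fc = unname(fit$log2fc),
    avg_expr = unname(fit$avg_expr),
    sigma = sqrt(unname(s2)),
    df_resid = df,
    s2_post = unname(s2_post),
    t_mod = unname(t_mod),
    p = unname(p),
    p_adj = bh_adjust(unname(p))
  )
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  class(out) <- c("de_table", class(out))
  out
}

#' Call differentially expressed genes
#'
#' Applies the strict thresholds `log2fc > lfc` (up) / `log2fc < -lfc`
#' (down) with BH-adjusted `p_adj < alpha`; everything else is `ns`.
#' When cancer flags are supplied, the up/down sets are cross-tabulated
#' into oncogene / tumour-suppressor counts for the downstream chi-square
#' comparison between vectors.
#'
#' @param results A [ebayes_moderate()] table.
#' @param lfc Absolute log2 fold-change threshold (strict; default 1).
#' @param alpha Adjusted-p threshold (strict; default 0.01).
#' @param cancer_flags Optional tibble `gene_id`, `is_oncogene`, `is_tsg`.
#' @return A list of class `deg_calls`: `table` (the input plus `direction`
#'   and flags), `up`, `down` (gene-id vectors), and `counts` — a one-row
#'   tibble `n_deg`, `n_up`, `n_down`, `n_oncogene`, `n_tsg`.
#' @export
call_degs <- function(results, lfc = 1, alpha = 0.01, cancer_flags = NULL) {
  stopifnot(is.data.frame(results),
            all(c("gene_id", "log2fc", "p_adj") %in% names(results)))
  tab <- results |>
    mutate(direction = dplyr::case_when(
      .data$log2fc > lfc & .data$p_adj < alpha ~ "up",
      .data$log2fc < -lfc & .data$p_adj < alpha ~ "down",
      TRUE ~ "ns"
    ))
  if (!is.null(cancer_flags)) {
    tab <- tab |>
      left_join(select(cancer_flags, "gene_id", "is_oncogene", "is_tsg"),
                by = "gene_id") |>
      mutate(is_oncogene = dplyr::coalesce(.data$is_oncogene, FALSE),
             is_tsg = dplyr::coalesce(.data$is_tsg, FALSE))
  } else {
    tab <- tab |> mutate(is_oncogene = FALSE, is_tsg = FALSE)
  }
  deg <- filter(tab, .data$direction != "ns")
  counts <- tibble(
    n_deg = nrow(deg),
    n_up = sum(deg$direction == "up"),
    n_down = sum(deg$direction == "down"),
    n_oncogene = sum(deg$is_oncogene),
    n_tsg = sum(deg$is_tsg)
  )
  structure(list(
    table = tab,
    up = deg$gene_id[deg$direction == "up"],
    down = deg$gene_id[deg$direction == "down"],
    counts = counts
  ), class = "deg_calls")
}

#' Two-group differential expression, end to end
#'
#' Convenience wrapper chaining [normalize_log2()], expression filtering
#' (genes with log2-CPM above `filter_cpm` in at least `filter_n`
#' samples), [fit_linear_model()] on `~ group` and [ebayes_moderate()].
#'
#' @param counts Gene x sample count matrix.
#' @param group Factor-like vector, one entry per column; the first level
#'   is the reference (control).
#' @param filter_cpm,filter_n Expression filter (default: log2-CPM > 0 in
#'   at least 2 samples); set `filter_n = 0` to disable.
#' @return A [ebayes_moderate()] result table.
#' @export
run_de <- function(counts, group, filter_cpm = 0, filter_n = 2L) {
  group <- factor(group)
  if (nlevels(group) != 2L) abort("`group` must have exactly two levels.")
  y <- normalize_log2(counts)
  keep <- rowSums(y > filter_cpm) >= filter_n
  y <- y[keep, , drop = FALSE]
  design <- stats::model.matrix(~ group)
  fit <- fit_linear_model(y, design, coef = 2L)
  ebayes_moderate(fit)
}

#' @export
tidy.de_fit <- function(x, ...) {
  tibble(gene_id = rownames(x$coefficients) %||%
           as.character(seq_along(x$sigma2)),
         log2fc = unname(x$log2fc),
         sigma = sqrt(unname(x$sigma2)),
         df_resid = x$df_resid)
}

#' @export
glance.de_fit <- function(x, ...) {
  tibble(n_genes = length(x$sigma2), df_resid = x$df_resid,
         median_sigma = sqrt(median(x$sigma2)))
}

#' @export
glance.de_table <- function(x, ...) {
  tibble(n_genes = nrow(x), d0 = attr(x, "d0"), s02 = attr(x, "s02"),
         n_p_adj_lt_0.01 = sum(x$p_adj < 0.01))
}
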