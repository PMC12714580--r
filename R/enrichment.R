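#' Over-representation analysis (hypergeometric test)
#'
#' For each gene set, tests whether the selected genes overlap the set
#' more than expected under hypergeometric sampling from the universe:
#' `p = P[X >= k]` with `X ~ Hypergeom(N, K, n)` where `N` is the universe
#' size, `K` the set size within the universe, `n` the selection size and
#' `k` the overlap. Sets are intersected with the universe before testing;
#' p-values are BH-adjusted across sets. `gene_ratio = k / n` is the
#' dot-plot statistic.
#'
#' @param selected Character vector of selected genes (must be a subset of
#'   `universe`).
#' @param universe Character vector, the gene universe (all genes tested
#'   upstream).
#' @param gene_sets Named list of character vectors.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return A tibble with `set_name`, `k`, `K`, `n`, `N`, `gene_ratio`,
#'   `p`, `p_adj`, `significant`, `leading` (list-column of overlap genes),
#'   ordered by p.
#' @examples
#' ora(c("a", "b"), letters[1:4], list(S = c("a", "b")))
#' @export
ora <- function(selected, universe, gene_sets, alpha = 0.05) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (!length(universe)) abort("`universe` is empty.")
  if (!length(selected)) abort("`selected` is empty.")
  if (!all(selected %in% universe)) {
    abort("`selected` must be a subset of `universe`.")
  }
  if (!length(gene_sets)) abort("`gene_sets` is empty.")
  N <- length(universe)
  n <- length(selected)
  res <- purrr::imap(gene_sets, function(members, nm) {
    set_u <- intersect(unique(members), universe)
    K <- length(set_u)
    hits <- intersect(selected, set_u)
    k <- length(hits)
    p <- if (K == 0L) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set_name = nm, k = k, K = K, n = n, N = N,
           gene_ratio = k / n, p = p, leading = list(sort(hits)))
  }) |>
    bind_rows()
  res |>
    mutate(p_adj = bh_adjust(.data$p),
           significant = .data$p_adj < alpha) |>
    arrange(.data$p, .data$set_name) |>
    select("set_name", "k", "K", "n", "N", "gene_ratio", "p", "p_adj",
           "significant", "leading")
}

#' Rank genes for enrichment analysis
#'
#' Orders genes from highest to lowest score (moderated t or log2
#' fold-change) with a deterministic lexicographic tie-break on gene id.
#'
#' @param de_results Tibble with `gene_id` and the score column.
#' @param by Score column: `"t_mod"` or `"log2fc"`.
#' @return Named numeric vector of scores, names are gene ids, in
#'   descending order.
#' @export
rank_genes <- function(de_results, by = c("t_mod", "log2fc")) {
  by <- match.arg(by)
  if (!all(c("gene_id", by) %in% names(de_results))) {
    abort(sprintf("`de_results` needs columns gene_id and %s.", by))
  }
  s <- de_results[[by]]
  if (any(!is.finite(s))) abort("scores must be finite.")
  ord <- order(-s, de_results$gene_id)
  setNames(s[ord], de_results$gene_id[ord])
}

#' Ranked gene-set enrichment (weighted Kolmogorov-Smirnov)
#'
#' Computes the weighted KS running-sum enrichment score of a gene set in
#' a ranked list: hits advance the sum by `|score|^weight` (normalised),
#' misses retreat by `1 / (N - Nh)`; the ES is the extremum of the running
#' sum. The null distribution is generated by gene-label permutation
#' (`n_perm` draws, seeded); `NES = ES / mean(|null ES| of the same sign)`
#' and the permutation p-value uses +1 smoothing so it is never exactly 0.
#'
#' @param ranked Named numeric vector from [rank_genes()] (descending).
#' @param gene_set Character vector of member genes; must intersect the
#'   ranking and not cover it entirely.
#' @param weight Exponent on the scores (default 1; 0 gives the classic
#'   unweighted KS statistic).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutation null.
#' @return A tibble with `es`, `nes`, `p_perm`, `n_hits`, `n_perm`.
#' @export
gsea <- function(ranked, gene_set, weight = 1, n_perm = 1000, seed = 1L) {
  genes <- names(ranked)
  hits <- genes %in% gene_set
  nh <- sum(hits)
  if (nh == 0L) abort("gene set is disjoint from the ranking.")
  if (nh == length(genes)) abort("gene set covers the whole ranking.")

  w <- abs(ranked)^weight
  n <- length(genes)
  es_stat <- function(hit_idx) {
    step <- rep(-1 / (n - nh), n)
    step[hit_idx] <- w[hit_idx] / sum(w[hit_idx])
    rs <- cumsum(step)
    rs[which.max(abs(rs))]
  }

  es <- es_stat(which(hits))
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    es_stat(sample.int(n, nh))
  }, numeric(1))
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p_perm <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  tibble(es = es, nes = nes, p_perm = p_perm, n_hits = nh, n_perm = n_perm)
}
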