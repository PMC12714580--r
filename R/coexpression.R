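#' Pick the soft-threshold power for a co-expression network
#'
#' For each candidate power the unsigned adjacency `|cor|^beta` is formed,
#' connectivities `k_i` are binned (>= 10 bins) and the scale-free fit
#' index is computed as the sign-corrected `r^2` of regressing
#' `log10 p(k)` on `log10 k`. The chosen power is the smallest one
#' reaching `r2_target` while keeping the mean connectivity below
#' `sqrt(n_genes) / 2`; if no power reaches the target, the smallest
#' power satisfying the connectivity cap is used, with a warning.
#'
#' @param expr Gene x sample numeric matrix (log scale), >= 8 samples.
#' @param powers Candidate integer powers. The default stops at 10: with
#'   the small sample sizes typical of these designs, very high powers
#'   can satisfy the fit index while collapsing all topological overlap,
#'   so the unsigned-network convention of a moderate power cap is used.
#' @param r2_target Scale-free fit target (default 0.8).
#' @param n_bins Connectivity bins (default 10).
#' @return A list of class `soft_power`: `power` and `fit` — a tibble of
#'   `power`, `r2` (sign-corrected), `mean_k` for audit.
#' @export
pick_soft_power <- function(expr, powers = 1:10, r2_target = 0.8,
                            n_bins = 10L) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 8L) abort("at least 8 samples are required.")
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d zero-variance gene(s)", sum(sds == 0)))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  ac <- abs(cor(t(expr)))
  diag(ac) <- 0
  fit <- purrr::map_dfr(powers, function(b) {
    k <- rowSums(ac^b)
    # equal-width connectivity bins; empty bins dropped
    brk <- seq(min(k), max(k), length.out = n_bins + 1)
    if (brk[1] == brk[n_bins + 1]) {
      return(tibble(power = b, r2 = NA_real_, mean_k = mean(k)))
    }
    bin <- cut(k, brk, include.lowest = TRUE)
    dk <- as.numeric(tapply(k, bin, mean))
    pk <- as.numeric(table(bin)) / length(k)
    keep <- !is.na(dk) & dk > 0 & pk > 0
    if (sum(keep) < 3) {
      return(tibble(power = b, r2 = NA_real_, mean_k = mean(k)))
    }
    m <- lm(log10(pk[keep]) ~ log10(dk[keep]))
    r2 <- summary(m)$r.squared
    tibble(power = b, r2 = -sign(coef(m)[2]) * r2, mean_k = mean(k))
  })
  # scale-free fit subject to a mean-connectivity cap: very low powers can
  # satisfy the fit index while leaving the network too densely connected
  # for topological overlap to discriminate
  k_cap <- sqrt(nrow(expr)) / 2
  ok <- fit$power[!is.na(fit$r2) & fit$r2 >= r2_target &
                    fit$mean_k <= k_cap]
  if (length(ok)) {
    power <- min(ok)
  } else {
    low <- fit$power[fit$mean_k <= k_cap]
    power <- if (length(low)) min(low) else fit$power[which.max(fit$r2)]
    warn(sprintf(
      "no power reached the scale-free target %.2f at mean connectivity <= %.1f; using power %d",
      r2_target, k_cap, power))
  }
  structure(list(power = power, fit = fit), class = "soft_power")
}

#' Unsigned co-expression adjacency
#'
#' `A = |Pearson cor|^beta` between gene expression profiles. The
#' returned matrix carries a unit diagonal (the convention expected by
#' [tom_similarity()]); connectivity is computed as the off-diagonal row
#' sum, `k_i = rowSums(A) - 1`.
#'
#' @param expr Gene x sample numeric matrix.
#' @param power Soft-threshold power beta >= 1.
#' @return Symmetric gene x gene matrix with entries in \[0, 1\] and unit
#'   diagonal.
#' @export
adjacency <- function(expr, power) {
  if (power < 1) abort("`power` must be >= 1.")
  expr <- as.matrix(expr)
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d zero-variance gene(s)", sum(sds == 0)))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  a <- abs(cor(t(expr)))^power
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_{u != i} a_iu`, the sum running over `u != i, j`;
#' `TOM_ii = 1`. Computed by matrix multiplication.
#'
#' @param a Symmetric adjacency in \[0, 1\] with unit diagonal (see
#'   [adjacency()]).
#' @return TOM matrix, symmetric, entries in \[0, 1\], unit diagonal.
#' @export
tom_similarity <- function(a) {
  a <- as.matrix(a)
  if (!isSymmetric(unname(a), tol = 1e-8)) abort("`a` must be symmetric.")
  if (any(a < 0 | a > 1)) abort("adjacency entries must lie in [0, 1].")
  diag(a) <- 1
  k <- rowSums(a) - 1
  # (A %*% A)_ij counts u = i and u = j terms: subtract a_ii*a_ij + a_ij*a_jj
  shared <- a %*% a - 2 * a
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  tom
}

# Standard module color sequence (size-ordered labels).
module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue"
)

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - TOM`, cut statically at `cut_height`. The default cut is the
#' lower quartile of the merge heights: in sparse-module data the small
#' fraction of within-module merges occupies the bottom of the height
#' distribution while the bulk of merges is the near-unit-dissimilarity
#' background, so the lower quartile falls between module completion and
#' the background plateau. Clusters smaller than `min_size` are assigned
#' to `grey` (unassigned); the remaining clusters are labelled by
#' decreasing size from the standard color list.
#'
#' @param tom A [tom_similarity()] matrix with gene row/col names.
#' @param min_size Minimum module size (default 10).
#' @param cut_height Static cut height on the dendrogram; `NULL` for the
#'   default lower-quartile rule.
#' @return A tibble of class `module_assignment` with `gene_id`, `module`;
#'   attribute `tree` holds the hclust object.
#' @export
detect_modules <- function(tom, min_size = 10L, cut_height = NULL) {
  tom <- as.matrix(tom)
  genes <- rownames(tom) %||% sprintf("g%d", seq_len(nrow(tom)))
  tree <- hclust(as.dist(1 - tom), method = "average")
  cut_height <- cut_height %||% unname(quantile(tree$height, 0.25))
  cl <- cutree(tree, h = cut_height)
  sizes <- sort(table(cl), decreasing = TRUE)
  keep <- names(sizes)[sizes >= min_size]
  label <- setNames(rep("grey", length(sizes)), names(sizes))
  if (length(keep)) {
    label[keep] <- module_colors[seq_along(keep)]
  }
  out <- tibble(gene_id = genes, module = unname(label[as.character(cl)]))
  attr(out, "tree") <- tree
  attr(out, "cut_height") <- cut_height
  class(out) <- c("module_assignment", class(out))
  out
}

#' Module eigengenes
#'
#' First principal component of each module's standardized expression
#' submatrix, sign-aligned so that its correlation with the module's
#' average standardized expression is positive.
#'
#' @param expr Gene x sample matrix.
#' @param assignment A [detect_modules()] tibble; `grey` is skipped.
#' @return A samples x modules numeric matrix (column names are module
#'   labels).
#' @export
module_eigengene <- function(expr, assignment) {
  expr <- as.matrix(expr)
  mods <- setdiff(unique(assignment$module), "grey")
  if (!length(mods)) abort("no non-grey modules in the assignment.")
  me <- vapply(mods, function(m) {
    ids <- intersect(assignment$gene_id[assignment$module == m],
                     rownames(expr))
    sub <- expr[ids, , drop = FALSE]
    sds <- apply(sub, 1, sd)
    sub <- sub[sds > 0, , drop = FALSE]
    z <- (sub - rowMeans(sub)) / apply(sub, 1, sd)
    if (nrow(z) == 1L) return(as.numeric(z))
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (cor(e, colMeans(z)) < 0) e <- -e
    e
  }, numeric(ncol(expr)))
  rownames(me) <- colnames(expr)
  me
}

#' Module-trait correlation
#'
#' Pearson correlation (with two-sided p) between each module eigengene
#' and each binary sample-group indicator.
#'
#' @param eigengenes Samples x modules matrix from [module_eigengene()].
#' @param traits Samples x traits data frame / matrix of 0-1 indicators,
#'   same row order as `eigengenes`.
#' @return A tibble with `module`, `trait`, `r`, `p`.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  traits <- as.data.frame(traits)
  if (nrow(traits) != nrow(eigengenes)) {
    abort("`traits` must have one row per sample.")
  }
  for (tr in names(traits)) {
    v <- traits[[tr]]
    if (length(unique(v)) < 2) abort(sprintf("trait `%s` is constant.", tr))
  }
  tidyr::crossing(module = colnames(eigengenes), trait = names(traits)) |>
    mutate(purrr::map2_dfr(.data$module, .data$trait, function(m, tr) {
      ct <- cor.test(eigengenes[, m], as.numeric(traits[[tr]]))
      tibble(r = unname(ct$estimate), p = ct$p.value)
    }))
}

#' Intramodular connectivity
#'
#' For every gene, the total network connectivity `kTotal` (sum of
#' adjacency to all other genes) and the intramodular connectivity
#' `kWithin` (sum restricted to the gene's module). Hub genes are the
#' top decile of `kWithin` within their module.
#'
#' @param a An [adjacency()] matrix.
#' @param assignment A [detect_modules()] tibble.
#' @return The assignment plus `kTotal`, `kWithin`, `is_hub`.
#' @export
intramodular_connectivity <- function(a, assignment) {
  a <- as.matrix(a)
  diag(a) <- 0
  genes <- assignment$gene_id
  ktot <- rowSums(a)[genes]
  kwithin <- vapply(seq_along(genes), function(i) {
    ids <- assignment$gene_id[assignment$module == assignment$module[i]]
    sum(a[genes[i], setdiff(ids, genes[i])])
  }, numeric(1))
  assignment |>
    mutate(kTotal = unname(ktot), kWithin = kwithin) |>
    group_by(.data$module) |>
    mutate(is_hub = .data$module != "grey" &
             .data$kWithin >= quantile(.data$kWithin, 0.9)) |>
    ungroup()
}

#' Module overlap with external gene sets
#'
#' Overlap fraction `|module intersect set| / |module|` and hypergeometric
#' enrichment p (via [ora()], universe = all genes in the assignment)
#' for every module x set pair.
#'
#' @param assignment A [detect_modules()] tibble.
#' @param gene_sets Named list of gene-id vectors.
#' @return A tibble with `module`, `set_name`, `overlap_n`, `overlap_pct`,
#'   `p`, `p_adj` (BH across all pairs).
#' @export
module_overlap <- function(assignment, gene_sets) {
  if (!length(gene_sets)) abort("`gene_sets` is empty.")
  universe <- assignment$gene_id
  mods <- setdiff(unique(assignment$module), "grey")
  res <- purrr::map_dfr(mods, function(m) {
    members <- assignment$gene_id[assignment$module == m]
    o <- ora(members, universe, gene_sets, alpha = 1)
    tibble(module = m, set_name = o$set_name, overlap_n = o$k,
           overlap_pct = 100 * o$k / length(members), p = o$p)
  })
  res |> mutate(p_adj = bh_adjust(.data$p))
}
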