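#' Derive a cancer gene signature from a tumor/normal contrast
#'
#' Runs the moderated differential-expression stack on tumor versus normal
#' count matrices and returns the up-regulated genes passing the strict
#' thresholds `log2fc > lfc` and `p_adj < alpha`. With
#' `direction = "both"`, down-regulated genes (`log2fc < -lfc`) are also
#' returned and contribute negated z-scores when scoring.
#'
#' @param tumor_counts,normal_counts Gene x sample count matrices sharing
#'   row names; at least 2 samples per arm.
#' @param lfc Log2 fold-change threshold (strict; default 2).
#' @param alpha BH-adjusted p threshold (strict; default 0.01).
#' @param direction `"up"` (default) or `"both"`.
#' @return A list of class `gene_signature` with `up`, `down` (gene ids)
#'   and `de` (the full moderated table).
#' @export
derive_signature <- function(tumor_counts, normal_counts, lfc = 2,
                             alpha = 0.01, direction = c("up", "both")) {
  direction <- match.arg(direction)
  tumor_counts <- as.matrix(tumor_counts)
  normal_counts <- as.matrix(normal_counts)
  if (ncol(tumor_counts) < 2L || ncol(normal_counts) < 2L) {
    abort("at least 2 samples per group are required.")
  }
  common <- intersect(rownames(tumor_counts), rownames(normal_counts))
  if (!length(common)) abort("no shared genes between matrices.")
  counts <- cbind(tumor_counts[common, , drop = FALSE],
                  normal_counts[common, , drop = FALSE])
  group <- factor(rep(c("tumor", "normal"),
                      c(ncol(tumor_counts), ncol(normal_counts))),
                  levels = c("normal", "tumor"))
  de <- run_de(counts, group)
  up <- de$gene_id[de$log2fc > lfc & de$p_adj < alpha]
  down <- if (direction == "both") {
    de$gene_id[de$log2fc < -lfc & de$p_adj < alpha]
  } else character(0)
  if (!length(up) && !length(down)) {
    abort(paste("signature is empty at these thresholds;",
                "consider relaxing `lfc` or `alpha`."))
  }
  structure(list(up = sort(up), down = sort(down), de = de),
            class = "gene_signature")
}

#' Score samples by scaled mean signature expression
#'
#' For each signature gene, expression is z-scored across the scored
#' cohort (infected and control samples together, so controls sit near
#' baseline); a sample's score is the mean z over the signature genes.
#' Zero-variance genes are dropped with a warning; down-signature genes
#' contribute negated z-scores.
#'
#' @param expr_log Gene x sample matrix of (log-scale) expression.
#' @param signature A [derive_signature()] object or a character vector of
#'   up-genes.
#' @param signature_name Label carried into the output.
#' @return A tibble with `sample_id`, `signature_name`, `score`,
#'   `n_genes_used`. The score vector has mean 0 across the scored
#'   samples.
#' @export
score_samples <- function(expr_log, signature, signature_name = "signature") {
  expr_log <- as.matrix(expr_log)
  if (ncol(expr_log) < 2L) abort("at least 2 samples are required.")
  if (is.character(signature)) {
    signature <- structure(list(up = signature, down = character(0)),
                           class = "gene_signature")
  }
  up <- intersect(signature$up, rownames(expr_log))
  down <- intersect(signature$down, rownames(expr_log))
  if (!length(up) && !length(down)) {
    abort("signature does not intersect the expression matrix.")
  }
  zmat <- function(genes, sign) {
    if (!length(genes)) return(NULL)
    m <- expr_log[genes, , drop = FALSE]
    sds <- apply(m, 1, sd)
    if (any(sds == 0)) {
      warn(sprintf("dropping %d zero-variance signature gene(s)",
                   sum(sds == 0)))
      m <- m[sds > 0, , drop = FALSE]
      sds <- sds[sds > 0]
    }
    if (!nrow(m)) return(NULL)
    sign * (m - rowMeans(m)) / sds
  }
  z <- rbind(zmat(up, 1), zmat(down, -1))
  if (is.null(z) || !nrow(z)) {
    abort("no usable signature genes after dropping zero-variance genes.")
  }
  tibble(
    sample_id = colnames(expr_log),
    signature_name = signature_name,
    score = unname(colMeans(z)),
    n_genes_used = nrow(z)
  )
}

#' Average signature scores per group
#'
#' Mean and SEM of signature scores within sample groups (across
#' replicates and signatures). SEM = sd / sqrt(n); for a single
#' observation the SEM is undefined and reported as `NA`.
#'
#' @param scores A [score_samples()] tibble (possibly several signatures
#'   bound together).
#' @param grouping Tibble mapping `sample_id` to grouping columns, or a
#'   character vector of column names already present in `scores`.
#' @return A tibble with the grouping columns, `mean_score`, `sem`, `n`.
#' @export
average_scores <- function(scores, grouping) {
  if (is.data.frame(grouping)) {
    scores <- left_join(scores, grouping, by = "sample_id")
    by <- setdiff(names(grouping), "sample_id")
  } else {
    by <- grouping
  }
  missing <- setdiff(by, names(scores))
  if (length(missing)) {
    abort(sprintf("grouping column(s) not found: %s",
                  paste(missing, collapse = ", ")))
  }
  scores |>
    group_by(dplyr::across(dplyr::all_of(by))) |>
    summarise(
      mean_score = mean(.data$score),
      sem = if (dplyr::n() > 1) sd(.data$score) / sqrt(dplyr::n())
            else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}
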