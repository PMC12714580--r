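#' Per-probe delta-beta between two arms
#'
#' `delta_beta = rowMeans(case) - rowMeans(control)` over the probes
#' shared by both matrices. Missing values are excluded per probe; probes
#' with fewer than 2 usable values in either arm are dropped with a
#' warning.
#'
#' @param case_beta,control_beta Probe x sample beta matrices in \[0, 1\]
#'   with probe row names; >= 2 samples per arm.
#' @return A tibble with `probe_id`, `mean_case`, `mean_control`,
#'   `delta_beta`.
#' @export
delta_beta <- function(case_beta, control_beta) {
  case_beta <- as.matrix(case_beta)
  control_beta <- as.matrix(control_beta)
  if (ncol(case_beta) < 2L || ncol(control_beta) < 2L) {
    abort("at least 2 samples per arm are required.")
  }
  shared <- intersect(rownames(case_beta), rownames(control_beta))
  if (!length(shared)) abort("no shared probes between the matrices.")
  ca <- case_beta[shared, , drop = FALSE]
  co <- control_beta[shared, , drop = FALSE]
  usable <- rowSums(!is.na(ca)) >= 2 & rowSums(!is.na(co)) >= 2
  if (any(!usable)) {
    warn(sprintf("dropping %d probe(s) with fewer than 2 usable values",
                 sum(!usable)))
  }
  ca <- ca[usable, , drop = FALSE]
  co <- co[usable, , drop = FALSE]
  tibble(
    probe_id = rownames(ca),
    mean_case = unname(rowMeans(ca, na.rm = TRUE)),
    mean_control = unname(rowMeans(co, na.rm = TRUE))
  ) |>
    mutate(delta_beta = .data$mean_case - .data$mean_control)
}

#' Call differentially methylated positions
#'
#' Strict-threshold classification of per-probe delta-beta values:
#' `hyper` when `delta_beta > threshold`, `hypo` when
#' `delta_beta < -threshold`, otherwise `none` (a delta of exactly the
#' threshold is not called). Probe annotation (gene, position class, CpG
#' class) is joined; unannotated probes are kept with class `unknown`.
#'
#' @param deltas A [delta_beta()] tibble.
#' @param probe_annotation Tibble with `probe_id`, `gene_id`,
#'   `position_class`, `cpg_class` (e.g. `annotation$probes`).
#' @param threshold Delta-beta threshold in (0, 1); default 0.2.
#' @return A tibble with the delta columns plus `state`, `gene_id`,
#'   `position_class`, `cpg_class`.
#' @export
call_dmps <- function(deltas, probe_annotation = NULL, threshold = 0.2) {
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  out <- deltas |>
    mutate(state = dplyr::case_when(
      .data$delta_beta > threshold ~ "hyper",
      .data$delta_beta < -threshold ~ "hypo",
      TRUE ~ "none"
    ))
  if (!is.null(probe_annotation)) {
    out <- out |>
      left_join(select(probe_annotation, "probe_id", "gene_id",
                       "position_class", "cpg_class"),
                by = "probe_id")
    n_unk <- sum(is.na(out$position_class))
    if (n_unk) {
      inform(sprintf("%d probe(s) without annotation classified as unknown",
                     n_unk))
    }
    out <- out |>
      mutate(position_class = dplyr::coalesce(.data$position_class, "unknown"),
             cpg_class = dplyr::coalesce(.data$cpg_class, "unknown"))
  }
  out
}

#' Cross-tabulate methylation calls by region
#'
#' Complete position-class x CpG-class x state cross-tab of hyper/hypo
#' calls with zero cells filled, plus a `log2(count + 1)` companion
#' column (the scale used to display regional methylation burden).
#'
#' @param dm_records A [call_dmps()] tibble with annotation columns.
#' @return A tibble `position_class`, `cpg_class`, `state`, `n`,
#'   `log2_n` covering all combinations.
#' @export
summarize_by_region <- function(dm_records) {
  need <- c("position_class", "cpg_class", "state")
  if (!all(need %in% names(dm_records))) {
    abort("`dm_records` must carry position_class, cpg_class and state.")
  }
  pos_levels <- c("TSS1500", "TSS200", "5UTR", "Body", "3UTR")
  cpg_levels <- c("island", "shore", "shelf", "opensea")
  dm_records |>
    filter(.data$state %in% c("hyper", "hypo")) |>
    count(.data$position_class, .data$cpg_class, .data$state) |>
    tidyr::complete(
      position_class = union(pos_levels, unique(dm_records$position_class)),
      cpg_class = union(cpg_levels, unique(dm_records$cpg_class)),
      state = c("hyper", "hypo"),
      fill = list(n = 0L)
    ) |>
    mutate(log2_n = log2(.data$n + 1))
}

#' Genes with hypermethylated CpG-island promoters
#'
#' Unique genes carrying at least one `hyper` probe with
#' `cpg_class = "island"` in a promoter position class (TSS1500 or
#' TSS200) — the promoter-hypermethylation read-out.
#'
#' @param dm_records A [call_dmps()] tibble with annotation columns.
#' @return Sorted character vector of gene ids.
#' @export
promoter_hyper_genes <- function(dm_records) {
  need <- c("position_class", "cpg_class", "state", "gene_id")
  if (!all(need %in% names(dm_records))) {
    abort("`dm_records` must carry gene and region annotation.")
  }
  dm_records |>
    filter(.data$state == "hyper", .data$cpg_class == "island",
           .data$position_class %in% c("TSS1500", "TSS200")) |>
    pull("gene_id") |>
    unique() |>
    sort()
}
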