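#' Relative sequence counts per sample
#'
#' Converts absolute sheared-fragment sequence counts to the relative
#' sequence count of each integration site compared to all sequences of the
#' same sample: `rel_count = seq_count / sum(seq_count)` within `sample`.
#' Sequencing depth differs between samples, so all downstream clonality
#' comparisons operate on these fractions.
#'
#' @param sites Tibble with at least `sample` and `seq_count` columns.
#' @return The input with a `rel_count` column; per sample the column sums
#'   to 1.
#' @examples
#' relative_counts(tibble::tibble(sample = "s1", seq_count = c(5, 5, 10)))
#' @export
relative_counts <- function(sites) {
  if (!all(c("sample", "seq_count") %in% names(sites))) {
    abort("`sites` needs columns sample and seq_count.")
  }
  if (nrow(sites) && any(sites$seq_count < 1)) {
    abort("all seq_count values must be >= 1.")
  }
  sites |>
    group_by(.data$sample) |>
    mutate(rel_count = .data$seq_count / sum(.data$seq_count)) |>
    ungroup()
}

# 0-based half-open intervals -> GRanges (1-based closed)
granges0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
}

#' Annotate integration sites against gene models
#'
#' Assigns each integration site the genomic region it falls in, with the
#' precedence: a position inside the CDS is `exon`; inside an exon but
#' outside the CDS it is `5UTR` or `3UTR` depending on which side of the
#' CDS it lies in gene orientation; inside the transcription unit but not
#' in an exon it is `intron`; outside every transcription unit it is
#' `intergenic`. A site overlapping several genes is assigned to the gene
#' whose TSS is nearest (ties broken by lexicographically smaller gene id).
#'
#' Genic sites also get `norm_pos`, the position within the gene normalised
#' against gene length and oriented 5' to 3' (0 at the TSS), the signed
#' `dist_tss` (negative = upstream in gene orientation), `dist_atg` (bp
#' upstream of the CDS start, 5'UTR hits) and `dist_stop` (bp downstream
#' of the stop, 3'UTR hits). Intergenic sites keep `gene_id = NA`; the
#' nearest gene whose TSS lies within 100 kb is reported separately as
#' `near_gene_id` for proximity summaries. `near_cancer_tss` flags sites
#' within the half-open window `[TSS - w, TSS + w)` of any cancer-gene TSS.
#'
#' @param sites Tibble with `chrom`, `pos` (0-based bp) and any metadata.
#' @param annotation A [make_genome()] / [read_gene_models_gtf()] annotation.
#' @param cancer_window_bp Window around cancer-gene TSSs (default 100 kb).
#' @return The input plus annotation columns `gene_id`, `region`,
#'   `norm_pos`, `dist_tss`, `dist_atg`, `dist_stop`, `is_cancer`,
#'   `is_oncogene`, `is_tsg`, `near_gene_id`, `near_cancer_tss`.
#' @export
annotate_sites <- function(sites, annotation, cancer_window_bp = 100000) {
  stopifnot(inherits(annotation, "genome_annotation"))
  genes <- annotation$genes
  if (nrow(genes) == 0L) abort("annotation has no genes.")
  bad <- setdiff(unique(sites$chrom), unique(genes$chrom))
  if (length(bad)) {
    abort(sprintf("sites on unknown chromosome(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (nrow(sites) == 0L) {
    return(mutate(sites, gene_id = character(0), region = character(0),
                  norm_pos = numeric(0), dist_tss = numeric(0),
                  dist_atg = numeric(0), dist_stop = numeric(0),
                  is_cancer = logical(0), is_oncogene = logical(0),
                  is_tsg = logical(0), near_gene_id = character(0),
                  near_cancer_tss = logical(0)))
  }

  site_gr <- granges0(sites$chrom, sites$pos, sites$pos + 1)
  tx_gr <- granges0(genes$chrom, genes$tx_start, genes$tx_end)

  ov <- GenomicRanges::findOverlaps(site_gr, tx_gr)
  pairs <- tibble(
    site = S4Vectors::queryHits(ov),
    gi = S4Vectors::subjectHits(ov)
  ) |>
    mutate(
      gene_id = genes$gene_id[.data$gi],
      tss_dist = abs(sites$pos[.data$site] - genes$tss[.data$gi])
    ) |>
    arrange(.data$site, .data$tss_dist, .data$gene_id) |>
    distinct(.data$site, .keep_all = TRUE)

  # exon membership of the (site, assigned gene) pair
  exons <- annotation$exons
  ex_gr <- granges0(genes$chrom[match(exons$gene_id, genes$gene_id)],
                    exons$start, exons$end)
  exov <- GenomicRanges::findOverlaps(site_gr, ex_gr)
  ex_pairs <- tibble(site = S4Vectors::queryHits(exov),
                     gene_id = exons$gene_id[S4Vectors::subjectHits(exov)]) |>
    distinct()
  pairs <- pairs |>
    left_join(mutate(ex_pairs, in_exon = TRUE), by = c("site", "gene_id")) |>
    mutate(in_exon = !is.na(.data$in_exon))

  g <- genes[pairs$gi, ]
  pos <- sites$pos[pairs$site]
  plus <- g$strand == "+"
  in_cds <- pos >= g$cds_start & pos < g$cds_end
  five_side <- ifelse(plus, pos < g$cds_start, pos >= g$cds_end)
  region <- dplyr::case_when(
    pairs$in_exon & in_cds ~ "exon",
    pairs$in_exon & five_side ~ "5UTR",
    pairs$in_exon ~ "3UTR",
    TRUE ~ "intron"
  )
  len <- g$tx_end - g$tx_start
  genic <- tibble(
    site = pairs$site,
    gene_id = pairs$gene_id,
    region = region,
    norm_pos = ifelse(plus, (pos - g$tx_start) / len,
                      (g$tx_end - 1 - pos) / len),
    dist_tss = ifelse(plus, pos - g$tss, g$tss - pos),
    dist_atg = dplyr::if_else(region == "5UTR",
                              ifelse(plus, g$cds_start - pos,
                                     pos - (g$cds_end - 1)),
                              NA_real_),
    dist_stop = dplyr::if_else(region == "3UTR",
                               ifelse(plus, pos - (g$cds_end - 1),
                                      g$cds_start - pos),
                               NA_real_),
    is_oncogene = g$is_oncogene,
    is_tsg = g$is_tsg
  )

  out <- sites |>
    mutate(site = dplyr::row_number()) |>
    left_join(genic, by = "site") |>
    mutate(
      region = dplyr::coalesce(.data$region, "intergenic"),
      is_oncogene = dplyr::coalesce(.data$is_oncogene, FALSE),
      is_tsg = dplyr::coalesce(.data$is_tsg, FALSE),
      is_cancer = .data$is_oncogene | .data$is_tsg
    )

  # nearest gene (TSS within the window) for intergenic sites
  tss_gr <- granges0(genes$chrom, pmax(genes$tss - cancer_window_bp, 0),
                     genes$tss + cancer_window_bp)
  nv <- GenomicRanges::findOverlaps(site_gr, tss_gr)
  near <- tibble(site = S4Vectors::queryHits(nv),
                 gi = S4Vectors::subjectHits(nv)) |>
    mutate(dist = abs(sites$pos[.data$site] - genes$tss[.data$gi]),
           ng = genes$gene_id[.data$gi],
           cancer = genes$is_oncogene[.data$gi] | genes$is_tsg[.data$gi])
  nearest <- near |>
    arrange(.data$site, .data$dist, .data$ng) |>
    distinct(.data$site, .keep_all = TRUE) |>
    select("site", near_gene_id = "ng")
  near_cancer <- near |>
    group_by(.data$site) |>
    summarise(near_cancer_tss = any(.data$cancer), .groups = "drop")

  out |>
    left_join(nearest, by = "site") |>
    left_join(near_cancer, by = "site") |>
    mutate(
      near_gene_id = dplyr::if_else(.data$region == "intergenic",
                                    .data$near_gene_id, NA_character_),
      near_cancer_tss = dplyr::coalesce(.data$near_cancer_tss, FALSE)
    ) |>
    select(-"site")
}

#' Per-sample region profile of integration sites
#'
#' Summarises annotated integration sites per sample: the percentage of
#' sites in each region (normalised to the total number of sites of the
#' sample, so the five regions sum to 100), the mean and median normalised
#' gene position of exonic and intronic hits, the mean log10 bp distance of
#' UTR hits from ATG/stop, each split by cancer versus non-cancer genes.
#'
#' @param annotations Output of [annotate_sites()].
#' @return A list of class `region_summary` with tibbles `region_pct`
#'   (`sample`, `region`, `n`, `pct`), `position_stats` (`sample`,
#'   `is_cancer`, `region`, `mean_norm_pos`, `median_norm_pos`,
#'   `mean_log10_dist`) and `exon_median_norm_pos` (per sample).
#' @export
region_summaries <- function(annotations) {
  if (!"region" %in% names(annotations)) {
    abort("`annotations` must come from annotate_sites().")
  }
  regions <- c("exon", "intron", "5UTR", "3UTR", "intergenic")
  empty <- annotations |> count(.data$sample) |> filter(.data$n == 0)
  if (nrow(empty)) {
    warn(sprintf("excluding %d empty sample(s)", nrow(empty)))
  }
  region_pct <- annotations |>
    count(.data$sample, region = factor(.data$region, regions),
          .drop = FALSE) |>
    group_by(.data$sample) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(region = as.character(.data$region))

  position_stats <- annotations |>
    filter(.data$region != "intergenic") |>
    group_by(.data$sample, .data$is_cancer, .data$region) |>
    summarise(
      n = dplyr::n(),
      mean_norm_pos = mean(.data$norm_pos),
      median_norm_pos = median(.data$norm_pos),
      mean_log10_dist = mean(log10(pmax(
        dplyr::coalesce(.data$dist_atg, .data$dist_stop), 1)), na.rm = TRUE),
      .groups = "drop"
    )

  exon_median <- annotations |>
    filter(.data$region == "exon") |>
    group_by(.data$sample) |>
    summarise(median_norm_pos = median(.data$norm_pos), .groups = "drop")

  structure(list(region_pct = region_pct, position_stats = position_stats,
                 exon_median_norm_pos = exon_median),
            class = "region_summary")
}

#' Integration-site frequency near cancer-gene TSSs
#'
#' Relative frequency of integration sites detected within a `window` of
#' the TSS of any cancer-related (oncogene or tumour-suppressor) gene,
#' reported per grouping of the site metadata (default sample, vector,
#' cell, timepoint). The window is half-open on both sides of the TSS:
#' `[TSS - window, TSS + window)`.
#'
#' @param annotations Output of [annotate_sites()] (uses `near_cancer_tss`).
#' @param by Character vector of grouping columns.
#' @return Tibble with grouping columns, `n_sites`, `n_near_cancer`,
#'   `frequency` in \[0, 1\].
#' @export
cancer_proximity <- function(annotations,
                             by = c("sample", "vector", "cell", "timepoint")) {
  if (!"near_cancer_tss" %in% names(annotations)) {
    abort("`annotations` must come from annotate_sites().")
  }
  by <- intersect(by, names(annotations))
  annotations |>
    group_by(dplyr::across(dplyr::all_of(by))) |>
    summarise(n_sites = dplyr::n(),
              n_near_cancer = sum(.data$near_cancer_tss),
              frequency = .data$n_near_cancer / .data$n_sites,
              .groups = "drop")
}

#' Detect common integration sites by linkage clustering
#'
#' Graph-based common-integration-site (CIS) detection: every site is a
#' node, two nodes on the same chromosome are connected when their distance
#' is strictly below `linkage_bp`, and the connected components are the
#' CIS. Implemented as a single sorted sweep per chromosome, which by
#' transitivity is exactly the connected components of the pairwise graph.
#' Distance is `|pos1 - pos2|`, strand-ignored; ties at exactly
#' `linkage_bp` are not connected.
#'
#' @param sites Tibble with `chrom` and `pos` columns.
#' @param linkage_bp Linkage distance in bp (default 50 kb).
#' @param keep_singletons Keep single-site components (default TRUE;
#'   set FALSE to report only clusters of two or more sites).
#' @return A tibble with one row per cluster: `cis_id`, `chrom`, `start`,
#'   `end` (span of member positions), `n_sites`, `n_samples` (if a
#'   `sample` column is present) and `members` (list-column of row indices
#'   into `sites`).
#' @examples
#' detect_cis(tibble::tibble(chrom = "chr1", pos = c(100, 40000, 120000)))
#' @export
detect_cis <- function(sites, linkage_bp = 50000, keep_singletons = TRUE) {
  if (!all(c("chrom", "pos") %in% names(sites))) {
    abort("`sites` needs columns chrom and pos.")
  }
  if (nrow(sites) == 0L) {
    return(tibble(cis_id = character(0), chrom = character(0),
                  start = numeric(0), end = numeric(0), n_sites = integer(0),
                  n_samples = integer(0), members = list()))
  }
  ord <- order(sites$chrom, sites$pos)
  chrom <- sites$chrom[ord]
  pos <- sites$pos[ord]
  new_cluster <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                     (pos[-1] - pos[-length(pos)]) >= linkage_bp)
  comp <- cumsum(new_cluster)

  res <- tibble(chrom = chrom, pos = pos, row = ord, comp = comp) |>
    group_by(.data$comp) |>
    summarise(chrom = dplyr::first(.data$chrom),
              start = min(.data$pos), end = max(.data$pos),
              n_sites = dplyr::n(),
              members = list(.data$row), .groups = "drop")
  if ("sample" %in% names(sites)) {
    res$n_samples <- vapply(res$members, function(m)
      dplyr::n_distinct(sites$sample[m]), integer(1))
  } else {
    res$n_samples <- res$n_sites
  }
  if (!keep_singletons) res <- filter(res, .data$n_sites >= 2L)
  res |>
    mutate(cis_id = sprintf("CIS_%04d", dplyr::row_number())) |>
    select("cis_id", "chrom", "start", "end", "n_sites", "n_samples",
           "members")
}

#' Track clonal expansion by sequence-count change
#'
#' Gene-level clonal tracking between an early and a late harvest: per
#' gene, the relative sequence counts of all its integration sites are
#' aggregated within each replicate (replicates missing the gene
#' contribute 0), a pseudo-fraction `eps` is added, and a two-sample
#' Student's t-test on `log2(rel + eps)` across replicates compares late
#' versus early. The fold-change is `log2((mean_late + eps) /
#' (mean_early + eps))`; p-values are BH-adjusted over all genes with at
#' least one site at either timepoint, and a gene is flagged when its
#' absolute sequence-count change is at least `fold_threshold` and the
#' adjusted p-value is below `alpha`.
#'
#' @param sites_early,sites_late Site tibbles with `rel_count` (see
#'   [relative_counts()]) and `replicate` columns.
#' @param annotation Gene models used to assign sites to genes.
#' @param fold_threshold Linear fold-change threshold (default 2).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param eps Pseudo-fraction (default 1e-6).
#' @return A tibble with `gene_id`, `mean_rel_early`, `mean_rel_late`,
#'   `log2fc`, `p`, `p_adj`, `flagged`, `is_oncogene`, `is_tsg`.
#' @export
track_clones <- function(sites_early, sites_late, annotation,
                         fold_threshold = 2, alpha = 0.05, eps = 1e-6) {
  for (tb in list(sites_early, sites_late)) {
    if (!all(c("rel_count", "replicate") %in% names(tb))) {
      abort("site tables need rel_count (run relative_counts()) and replicate.")
    }
  }
  reps_e <- sort(unique(sites_early$replicate))
  reps_l <- sort(unique(sites_late$replicate))
  if (length(reps_e) < 2L || length(reps_l) < 2L) {
    abort("at least 2 replicates per timepoint are required.")
  }

  agg <- function(tb, reps) {
    annotate_sites(tb, annotation) |>
      filter(!is.na(.data$gene_id)) |>
      group_by(.data$gene_id, .data$replicate) |>
      summarise(rel = sum(.data$rel_count), .groups = "drop")
  }
  a_e <- agg(sites_early, reps_e)
  a_l <- agg(sites_late, reps_l)
  genes <- union(a_e$gene_id, a_l$gene_id)
  if (!length(genes)) abort("no genic sites at either timepoint.")

  fill <- function(a, reps) {
    tidyr::crossing(gene_id = genes, replicate = reps) |>
      left_join(a, by = c("gene_id", "replicate")) |>
      mutate(rel = dplyr::coalesce(.data$rel, 0)) |>
      arrange(.data$gene_id, .data$replicate)
  }
  to_mat <- function(m, reps) {
    matrix(m$rel, nrow = length(genes), ncol = length(reps), byrow = TRUE,
           dimnames = list(sort(genes), reps))
  }
  genes <- sort(genes)
  m_e <- to_mat(fill(a_e, reps_e), reps_e)
  m_l <- to_mat(fill(a_l, reps_l), reps_l)

  # vectorised pooled-variance two-sample Student's t on log2(rel + eps)
  le <- log2(m_e + eps)
  ll <- log2(m_l + eps)
  n1 <- ncol(ll)
  n2 <- ncol(le)
  d <- rowMeans(ll) - rowMeans(le)
  sp2 <- ((n1 - 1) * apply(ll, 1, var) + (n2 - 1) * apply(le, 1, var)) /
    (n1 + n2 - 2)
  tt <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tt), df = n1 + n2 - 2)
  p[sp2 == 0 & d == 0] <- 1       # all values identical
  p[sp2 == 0 & d != 0] <- 0       # exact separation with zero spread

  res <- tibble(
    gene_id = genes,
    mean_rel_early = rowMeans(m_e),
    mean_rel_late = rowMeans(m_l),
    log2fc = log2((rowMeans(m_l) + eps) / (rowMeans(m_e) + eps)),
    p = p
  )

  flags <- annotation$genes |>
    select("gene_id", "is_oncogene", "is_tsg")
  res |>
    mutate(p_adj = bh_adjust(.data$p),
           flagged = abs(.data$log2fc) >= log2(fold_threshold) &
             .data$p_adj < alpha) |>
    left_join(flags, by = "gene_id") |>
    arrange(.data$p_adj, .data$gene_id)
}
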