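# Readers/writers for the external formats the pipeline touches.
# All coordinates on disk are 0-based half-open (BED convention).

is_cols <- c("chrom", "start", "end", "name", "score", "strand",
             "seq_count", "sample", "vector", "cell", "timepoint",
             "replicate")

#' Write / read integration-site tables (BED6+)
#'
#' Sites are stored as BED6 plus extension columns `seq_count`, `sample`,
#' `vector`, `cell`, `timepoint`, `replicate`; `start = pos`,
#' `end = pos + 1`, `score = seq_count`.
#'
#' @param sites Site tibble (as from [simulate_insertion_sites()]).
#' @param path File path.
#' @return `write_is_table()` returns `path` invisibly; `read_is_table()`
#'   returns a validated site tibble.
#' @export
write_is_table <- function(sites, path) {
  need <- c("chrom", "pos", "strand", "seq_count", "sample", "vector",
            "cell", "timepoint", "replicate")
  if (!all(need %in% names(sites))) {
    abort(sprintf("`sites` needs columns: %s", paste(need, collapse = ", ")))
  }
  bed <- sites |>
    transmute(chrom = .data$chrom, start = .data$pos, end = .data$pos + 1,
              name = sprintf("IS_%06d", dplyr::row_number()),
              score = .data$seq_count, strand = .data$strand,
              seq_count = .data$seq_count, sample = .data$sample,
              vector = .data$vector, cell = .data$cell,
              timepoint = .data$timepoint, replicate = .data$replicate)
  readr::write_tsv(bed, path, col_names = TRUE)
  invisible(path)
}

#' @rdname write_is_table
#' @export
read_is_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), name = readr::col_character(),
    score = readr::col_double(), strand = readr::col_character(),
    seq_count = readr::col_double(), sample = readr::col_character(),
    vector = readr::col_character(), cell = readr::col_character(),
    timepoint = readr::col_character(), replicate = readr::col_integer()
  ), progress = FALSE)
  if (nrow(raw) == 0L) {
    warn(sprintf("empty integration-site file: %s", path))
  }
  missing <- setdiff(is_cols, names(raw))
  if (length(missing)) {
    abort(sprintf("malformed IS table, missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad <- which(is.na(raw$start) | raw$start < 0 | is.na(raw$seq_count) |
                 raw$seq_count < 1)
  if (length(bad)) {
    abort(sprintf("invalid IS row at line %d (position < 0 or count < 1)",
                  bad[1] + 1L))
  }
  raw |>
    transmute(chrom = .data$chrom, pos = .data$start, strand = .data$strand,
              seq_count = .data$seq_count, sample = .data$sample,
              vector = .data$vector, cell = .data$cell,
              timepoint = .data$timepoint, replicate = .data$replicate)
}

#' Write / read gene models
#'
#' Gene models travel as either GTF-lite (`gene`, `transcript`, `exon`,
#' `CDS` features, one transcript per gene, 1-based closed coordinates as
#' in GTF) or BED12 (0-based half-open; `thickStart`/`thickEnd` carry the
#' CDS, block structure carries the exons). Both encodings parse to the
#' same internal `genome_annotation` (probes empty). Validation enforces
#' the gene-model invariants: exons disjoint and within the transcript,
#' CDS inside the transcript.
#'
#' @param annotation A `genome_annotation` object.
#' @param path File path.
#' @param cancer_flags Reattach oncogene/TSG flags on read (optional
#'   tibble `gene_id`, `is_oncogene`, `is_tsg`).
#' @return Readers return a `genome_annotation`; writers return `path`
#'   invisibly.
#' @export
write_gene_models_gtf <- function(annotation, path) {
  g <- annotation$genes
  ex <- annotation$exons |>
    left_join(select(g, "gene_id", "chrom", "strand"), by = "gene_id")
  lines <- c(
    sprintf("%s\tlentitox\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            g$chrom, g$tx_start + 1, g$tx_end, g$strand, g$gene_id),
    sprintf("%s\tlentitox\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            ex$chrom, ex$start + 1, ex$end, ex$strand, ex$gene_id),
    sprintf("%s\tlentitox\tCDS\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            g$chrom, g$cds_start + 1, g$cds_end, g$strand, g$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gene_models_gtf
#' @export
write_gene_models_bed12 <- function(annotation, path) {
  g <- annotation$genes
  ex <- annotation$exons |> arrange(.data$gene_id, .data$start)
  blocks <- ex |>
    group_by(.data$gene_id) |>
    summarise(
      block_count = dplyr::n(),
      block_sizes = paste0(paste(.data$end - .data$start, collapse = ","), ","),
      block_starts = paste0(paste(.data$start - min(.data$start),
                                  collapse = ","), ","),
      .groups = "drop"
    )
  b <- g |> left_join(blocks, by = "gene_id")
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                   b$chrom, b$tx_start, b$tx_end, b$gene_id, b$strand,
                   b$cds_start, b$cds_end, b$block_count, b$block_sizes,
                   b$block_starts)
  writeLines(lines, path)
  invisible(path)
}

validate_gene_models <- function(genes, exons) {
  by_gene <- split(exons, exons$gene_id)
  for (gid in names(by_gene)) {
    e <- by_gene[[gid]][order(by_gene[[gid]]$start), ]
    g <- genes[genes$gene_id == gid, ]
    if (any(e$start < g$tx_start) || any(e$end > g$tx_end)) {
      abort(sprintf("gene %s: exon outside transcript bounds.", gid))
    }
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      abort(sprintf("gene %s: overlapping exons.", gid))
    }
    if (g$cds_start < g$tx_start || g$cds_end > g$tx_end ||
        g$cds_start >= g$cds_end) {
      abort(sprintf("gene %s: CDS outside transcript.", gid))
    }
  }
  invisible(TRUE)
}

finish_annotation <- function(genes, exons, cancer_flags = NULL) {
  genes <- genes |>
    mutate(tss = ifelse(.data$strand == "+", .data$tx_start,
                        .data$tx_end - 1),
           is_oncogene = FALSE, is_tsg = FALSE)
  if (!is.null(cancer_flags)) {
    genes <- genes |>
      select(-"is_oncogene", -"is_tsg") |>
      left_join(select(cancer_flags, "gene_id", "is_oncogene", "is_tsg"),
                by = "gene_id") |>
      mutate(is_oncogene = dplyr::coalesce(.data$is_oncogene, FALSE),
             is_tsg = dplyr::coalesce(.data$is_tsg, FALSE))
  }
  validate_gene_models(genes, exons)
  structure(list(
    genes = genes |>
      select("gene_id", "chrom", "strand", "tx_start", "tx_end",
             "cds_start", "cds_end", "tss", "is_oncogene", "is_tsg") |>
      arrange(.data$gene_id),
    exons = exons |> arrange(.data$gene_id, .data$start) |>
      group_by(.data$gene_id) |>
      mutate(rank = dplyr::row_number()) |>
      ungroup(),
    probes = tibble(probe_id = character(0), chrom = character(0),
                    pos = numeric(0), gene_id = character(0),
                    position_class = character(0), cpg_class = character(0))
  ), class = "genome_annotation")
}

#' @rdname write_gene_models_gtf
#' @export
read_gene_models_gtf <- function(path, cancer_flags = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "source", "feature", "start", "end", "score",
                  "strand", "frame", "attributes"),
    col_types = "cccddcccc", comment = "#", progress = FALSE
  )
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", raw$attributes)
  raw$gene_id <- gid
  genes <- raw |>
    filter(.data$feature == "gene") |>
    transmute(gene_id = .data$gene_id, chrom = .data$chrom,
              strand = .data$strand, tx_start = .data$start - 1,
              tx_end = .data$end)
  cds <- raw |>
    filter(.data$feature == "CDS") |>
    group_by(.data$gene_id) |>
    summarise(cds_start = min(.data$start) - 1, cds_end = max(.data$end),
              .groups = "drop")
  exons <- raw |>
    filter(.data$feature == "exon") |>
    transmute(gene_id = .data$gene_id, start = .data$start - 1,
              end = .data$end)
  if (!nrow(genes)) abort("no gene features in GTF.")
  finish_annotation(left_join(genes, cds, by = "gene_id"), exons,
                    cancer_flags)
}

#' @rdname write_gene_models_gtf
#' @export
read_gene_models_bed12 <- function(path, cancer_flags = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand",
                  "thick_start", "thick_end", "rgb", "block_count",
                  "block_sizes", "block_starts"),
    col_types = "cddcdcddcdcc", progress = FALSE
  )
  if (!nrow(raw)) abort("empty BED12 file.")
  genes <- raw |>
    transmute(gene_id = .data$name, chrom = .data$chrom,
              strand = .data$strand, tx_start = .data$start,
              tx_end = .data$end, cds_start = .data$thick_start,
              cds_end = .data$thick_end)
  exons <- purrr::map_dfr(seq_len(nrow(raw)), function(i) {
    sizes <- as.numeric(strsplit(raw$block_sizes[i], ",")[[1]])
    starts <- as.numeric(strsplit(raw$block_starts[i], ",")[[1]])
    if (length(sizes) != raw$block_count[i] ||
        length(starts) != raw$block_count[i]) {
      abort(sprintf("line %d: block counts do not match.", i))
    }
    tibble(gene_id = raw$name[i], start = raw$start[i] + starts,
           end = raw$start[i] + starts + sizes)
  })
  finish_annotation(genes, exons, cancer_flags)
}

#' Write / read GMT gene-set collections
#'
#' Tab-separated GMT: set name, description, then members. Duplicate
#' members within a set are stored once; duplicate set names and empty
#' sets are rejected.
#'
#' @param gene_sets Named list of character vectors.
#' @param path File path.
#' @param descriptions Optional character vector of set descriptions.
#' @return `read_gmt()` returns a named list; `write_gmt()` returns
#'   `path` invisibly.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(names(gene_sets))) abort("`gene_sets` must be named.")
  descriptions <- descriptions %||% rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      abort(sprintf("line %d: GMT rows need at least 3 columns.", i))
    }
    nm <- parts[1]
    if (nm %in% names(sets)) {
      abort(sprintf("duplicate gene set `%s` at line %d.", nm, i))
    }
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) abort(sprintf("empty gene set `%s`.", nm))
    sets[[nm]] <- members
  }
  sets
}

#' Write / read feature-by-sample matrices as TSV
#'
#' First column `feature_id`, remaining columns one per sample. Feature
#' and sample ids must be unique; all cells numeric. Beta matrices are
#' additionally validated to lie in \[0, 1\].
#'
#' @param m Numeric matrix with row and column names.
#' @param path File path.
#' @param beta Validate values in \[0, 1\] on read (default FALSE).
#' @return `read_matrix()` returns a numeric matrix; `write_matrix()`
#'   returns `path` invisibly.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("matrix must have row and column names.")
  }
  df <- bind_cols(tibble(feature_id = rownames(m)), as_tibble(m))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, beta = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(),
    .default = readr::col_character()
  ), progress = FALSE)
  if (!"feature_id" %in% names(df)) {
    abort("first column must be `feature_id`.")
  }
  if (anyDuplicated(df$feature_id)) {
    abort(sprintf("duplicate feature id: %s",
                  df$feature_id[duplicated(df$feature_id)][1]))
  }
  if (anyDuplicated(names(df))) {
    abort("duplicate sample id in header.")
  }
  vals <- as.matrix(df[-1])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals),
                                 dimnames = NULL))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("non-numeric cell at row %d, column %d.",
                  bad[1, 1], bad[1, 2] + 1L))
  }
  dimnames(num) <- list(df$feature_id, colnames(vals))
  if (beta && any(num < 0 | num > 1, na.rm = TRUE)) {
    abort("beta values must lie in [0, 1].")
  }
  num
}

#' Pipeline thresholds and configuration
#'
#' The analysis thresholds, all defaulting to the reference values used
#' throughout the package: CIS linkage 50 kb, cancer-TSS window 100 kb,
#' DEG |log2FC| > 1 at BH p < 0.01, clonal sequence-count change >= 2-fold
#' at BH p < 0.05, signature log2FC > 2 at BH p < 0.01, enrichment BH
#' p < 0.05, delta-beta 0.2.
#'
#' @param cis_linkage_bp,cancer_window_bp,deg_lfc,deg_alpha,scc_fold,scc_alpha,sig_lfc,sig_alpha,ora_alpha,delta_beta Thresholds.
#' @param seed Root seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cis_linkage_bp = 50000, cancer_window_bp = 100000,
                            deg_lfc = 1.0, deg_alpha = 0.01, scc_fold = 2.0,
                            scc_alpha = 0.05, sig_lfc = 2.0, sig_alpha = 0.01,
                            ora_alpha = 0.05, delta_beta = 0.2, seed = 1L) {
  cfg <- list(cis_linkage_bp = cis_linkage_bp,
              cancer_window_bp = cancer_window_bp,
              deg_lfc = deg_lfc, deg_alpha = deg_alpha, scc_fold = scc_fold,
              scc_alpha = scc_alpha, sig_lfc = sig_lfc, sig_alpha = sig_alpha,
              ora_alpha = ora_alpha, delta_beta = delta_beta,
              seed = as.integer(seed))
  errs <- validate_pipeline_config(cfg)
  if (length(errs)) abort(paste(errs, collapse = "\n"))
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  errs <- character(0)
  thresholds <- c("cis_linkage_bp", "cancer_window_bp", "deg_lfc", "scc_fold",
                  "sig_lfc")
  alphas <- c("deg_alpha", "scc_alpha", "sig_alpha", "ora_alpha")
  known <- c(thresholds, alphas, "delta_beta", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    errs <- c(errs, sprintf("unknown key(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  for (k in intersect(thresholds, names(cfg))) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      errs <- c(errs, sprintf("`%s` must be > 0.", k))
    }
  }
  for (k in intersect(alphas, names(cfg))) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0 || cfg[[k]] >= 1) {
      errs <- c(errs, sprintf("`%s` must lie in (0, 1).", k))
    }
  }
  if (!is.null(cfg$delta_beta) &&
      (!is.numeric(cfg$delta_beta) || cfg$delta_beta <= 0 ||
         cfg$delta_beta >= 1)) {
    errs <- c(errs, "`delta_beta` must lie in (0, 1).")
  }
  errs
}

#' Read and validate a pipeline configuration from YAML
#'
#' Unknown keys are rejected; thresholds outside their documented ranges
#' produce an error naming the key.
#'
#' @param path YAML file with any subset of the [pipeline_config()] keys.
#' @return A `pipeline_config` (defaults filled for absent keys).
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- unclass(pipeline_config())
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, user)
  errs <- validate_pipeline_config(cfg)
  if (length(errs)) abort(paste(errs, collapse = "\n"))
  structure(cfg, class = "pipeline_config")
}
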