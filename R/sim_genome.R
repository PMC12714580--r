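#' Generate a synthetic annotated genome
#'
#' Builds the gene models and methylation-probe map that every other
#' generator and the annotation machinery consume. Genes are placed in
#' non-overlapping slots along each chromosome with log-normal lengths,
#' multi-exon structure (first exon starts at `tx_start`, last ends at
#' `tx_end`), and a CDS whose ATG lies in the first exon and stop codon in
#' the last, so every transcript derives 5'/3' UTR intervals. A
#' `floor(frac * n_genes)` subset of genes is flagged proto-oncogene and a
#' disjoint subset tumour suppressor, mirroring a Cancer Gene Census-style
#' list. Methylation probes are assigned to genes with a position class
#' (TSS1500, TSS200, 5UTR, Body, 3UTR) and a CpG class (island, shore,
#' shelf, opensea); promoter-proximal probes are island-enriched.
#'
#' Coordinates are 0-based half-open throughout (BED convention). The TSS is
#' `tx_start` on the `+` strand and `tx_end - 1` on the `-` strand.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `genome_annotation` with tibbles `genes`
#'   (`gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`, `cds_start`,
#'   `cds_end`, `tss`, `is_oncogene`, `is_tsg`), `exons` (`gene_id`,
#'   `start`, `end`, `rank`) and `probes` (`probe_id`, `chrom`, `pos`,
#'   `gene_id`, `position_class`, `cpg_class`).
#' @examples
#' ann <- make_genome(sim_config(seed = 1, n_genes = 20, n_probes = 100))
#' ann$genes
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))

  n <- config$n_genes
  per_chrom <- ceiling(n / config$n_chrom)
  slot_len <- floor(config$genome_len / per_chrom)
  if (slot_len < 3000) {
    abort("genome_len too small for n_genes: gene slots below 3 kb.")
  }

  gene_id <- sprintf("G%04d", seq_len(n))
  chrom <- paste0("chr", ((seq_len(n) - 1L) %/% per_chrom) + 1L)
  slot_idx <- (seq_len(n) - 1L) %% per_chrom
  slot_start <- slot_idx * slot_len

  # log-normal gene lengths, truncated to fit with a margin inside the slot
  len <- round(rlnorm(n, meanlog = log(8000), sdlog = 0.6))
  len <- pmax(2000, pmin(len, floor(slot_len * 0.8)))
  offset <- floor(runif(n, 0, slot_len - len))
  tx_start <- slot_start + offset
  tx_end <- tx_start + len
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", tx_start, tx_end - 1)

  n_onco <- floor(config$frac_oncogene * n)
  n_tsg <- floor(config$frac_tsg * n)
  flagged <- sample(n, n_onco + n_tsg)
  is_oncogene <- seq_len(n) %in% flagged[seq_len(n_onco)]
  is_tsg <- seq_len(n) %in% flagged[n_onco + seq_len(n_tsg)]

  genes <- tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    tx_start = as.numeric(tx_start), tx_end = as.numeric(tx_end),
    tss = as.numeric(tss),
    is_oncogene = is_oncogene, is_tsg = is_tsg
  )

  exons <- purrr::map_dfr(seq_len(n), function(i) {
    L <- len[i]
    k <- 1L + rbinom(1L, 7L, 0.4)   # 1..8 exons
    if (k == 1L) {
      return(tibble(gene_id = gene_id[i], start = tx_start[i],
                    end = tx_end[i], rank = 1L))
    }
    # partition the span into k exons and k-1 introns (gamma proportions;
    # introns drawn longer on average, as in real genes)
    w <- c(stats::rgamma(k, shape = 1.5), stats::rgamma(k - 1L, shape = 6))
    piece <- floor(L * w / sum(w))
    piece[piece < 50] <- 50
    piece[1L] <- piece[1L] + (L - sum(piece))  # absorb rounding in exon 1
    if (piece[1L] < 50) { # pathological rounding; fall back to even split
      piece <- rep(floor(L / (2 * k - 1L)), 2L * k - 1L)
      piece[1L] <- piece[1L] + (L - sum(piece))
    }
    ord <- c(rbind(seq_len(k), c(k + seq_len(k - 1L), NA)))
    ord <- ord[!is.na(ord)]          # exon1, intron1, exon2, ...
    bounds <- tx_start[i] + cumsum(c(0, piece[ord]))
    starts <- bounds[seq(1, 2 * k - 1, by = 2)]
    ends <- bounds[seq(2, 2 * k, by = 2)]
    tibble(gene_id = gene_id[i], start = as.numeric(starts),
           end = as.numeric(ends), rank = seq_len(k))
  })

  # CDS: ATG inside the first exon, stop inside the last (genomic order)
  cds <- exons |>
    group_by(.data$gene_id) |>
    summarise(
      first_s = dplyr::first(.data$start), first_e = dplyr::first(.data$end),
      last_s = dplyr::last(.data$start), last_e = dplyr::last(.data$end),
      .groups = "drop"
    )
  cds_start <- floor(cds$first_s + runif(n, 0.2, 0.8) * (cds$first_e - cds$first_s))
  cds_end <- ceiling(cds$last_s + runif(n, 0.2, 0.8) * (cds$last_e - cds$last_s))
  single <- cds$first_s == cds$last_s
  if (any(single)) { # one-exon genes: two interior points, ordered
    a <- floor(cds$first_s + runif(n, 0.1, 0.4) * (cds$first_e - cds$first_s))
    b <- ceiling(cds$first_s + runif(n, 0.6, 0.9) * (cds$first_e - cds$first_s))
    cds_start[single] <- a[single]
    cds_end[single] <- b[single]
  }
  genes <- genes |>
    left_join(tibble(gene_id = cds$gene_id, cds_start = as.numeric(cds_start),
                     cds_end = as.numeric(cds_end)), by = "gene_id") |>
    select("gene_id", "chrom", "strand", "tx_start", "tx_end",
           "cds_start", "cds_end", "tss", "is_oncogene", "is_tsg")

  probes <- simulate_probe_map(genes, config)

  structure(list(genes = genes, exons = exons, probes = probes),
            class = "genome_annotation")
}

# Probe map: each probe maps to exactly one (position_class, cpg_class).
simulate_probe_map <- function(genes, config) {
  np <- config$n_probes
  gi <- sample(nrow(genes), np, replace = TRUE)
  g <- genes[gi, ]
  position_class <- sample(
    c("TSS1500", "TSS200", "5UTR", "Body", "3UTR"), np, replace = TRUE,
    prob = c(0.15, 0.10, 0.10, 0.50, 0.15)
  )
  up <- ifelse(g$strand == "+", -1, 1)   # genomic direction of "upstream"
  pos <- dplyr::case_when(
    position_class == "TSS200" ~ g$tss + up * floor(runif(np, 1, 200)),
    position_class == "TSS1500" ~ g$tss + up * floor(runif(np, 201, 1500)),
    position_class == "5UTR" ~ ifelse(
      g$strand == "+",
      g$tx_start + floor(runif(np) * pmax(1, g$cds_start - g$tx_start)),
      g$cds_end + floor(runif(np) * pmax(1, g$tx_end - g$cds_end))),
    position_class == "3UTR" ~ ifelse(
      g$strand == "+",
      g$cds_end + floor(runif(np) * pmax(1, g$tx_end - g$cds_end)),
      g$tx_start + floor(runif(np) * pmax(1, g$cds_start - g$tx_start))),
    TRUE ~ g$tx_start + floor(runif(np) * (g$tx_end - g$tx_start))
  )
  promoter <- position_class %in% c("TSS1500", "TSS200")
  cpg_class <- ifelse(
    runif(np) < ifelse(promoter, 0.7, 0.15), "island",
    sample(c("shore", "shelf", "opensea"), np, replace = TRUE,
           prob = c(0.25, 0.15, 0.60))
  )
  tibble(
    probe_id = sprintf("cg%06d", seq_len(np)),
    chrom = g$chrom, pos = pmax(0, pos), gene_id = g$gene_id,
    position_class = position_class, cpg_class = cpg_class
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "<genome_annotation> %d genes on %d chromosomes, %d exons, %d probes\n",
    nrow(x$genes), dplyr::n_distinct(x$genes$chrom), nrow(x$exons),
    nrow(x$probes)))
  cat(sprintf("  oncogenes: %d, tumour suppressors: %d\n",
              sum(x$genes$is_oncogene), sum(x$genes$is_tsg)))
  invisible(x)
}
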