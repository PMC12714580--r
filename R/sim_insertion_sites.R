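#' Simulate mapped vector integration sites
#'
#' Emits an integration-site (IS) table for every sample of the study layout
#' (vector x cell x timepoint x replicate). Each replicate carries
#' `is_per_sample` sites drawn once per (vector, cell, replicate), so site
#' identity persists across the early and late timepoints of a replicate:
#'
#' * **Background sites** (`is_per_sample - n_clonal_genes` of them) land
#'   inside a random gene's transcription unit with probability `p_genic`,
#'   otherwise uniformly on a random chromosome. Their sheared-fragment
#'   sequence counts are log-normal (meanlog 2, sdlog 1), rounded to at
#'   least 1 — the heavy-tailed clone-size spectrum — and are redrawn at
#'   each timepoint (sampling turnover).
#' * **Planted clone founders**: one site per clonal gene per replicate,
#'   placed uniformly in that gene, with a tight founder abundance
#'   (log-normal meanlog 4.2, sdlog 0.1, i.e. dominant clones of
#'   near-equal initial size). Their late-timepoint counts are the early
#'   counts multiplied by `clonal_fold` (persistent multiplicative
#'   expansion); at `clonal_fold = 1` early and late clone counts are
#'   identical.
#'
#' Every sample's counts are scaled by a log-normal depth factor, so total
#' depth varies between samples and downstream comparisons must use
#' relative sequence counts.
#'
#' @param annotation A [make_genome()] annotation.
#' @param config A [sim_config()] object.
#' @return A list of class `is_simulation` with `sites` — a tibble with
#'   columns `chrom`, `pos`, `strand`, `seq_count`, `sample`, `vector`,
#'   `cell`, `timepoint`, `replicate` — and `clonal_genes`, the planted
#'   gene ids.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50, is_per_sample = 60,
#'                   n_clonal_genes = 5, n_probes = 10)
#' sim <- simulate_insertion_sites(make_genome(cfg), cfg)
#' dplyr::count(sim$sites, sample)
#' @export
simulate_insertion_sites <- function(annotation, config) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "sim_config"))
  if (nrow(annotation$genes) == 0L) abort("annotation has no genes.")
  if (config$n_clonal_genes > config$is_per_sample) {
    abort("`n_clonal_genes` must not exceed `is_per_sample`.")
  }
  set.seed(derive_seed(config$seed, "insertion_sites"))

  genes <- annotation$genes
  clonal_genes <- if (config$n_clonal_genes > 0L) {
    sort(sample(genes$gene_id, min(config$n_clonal_genes, nrow(genes))))
  } else character(0)
  cl <- genes[match(clonal_genes, genes$gene_id), ]
  n_bg <- config$is_per_sample - length(clonal_genes)
  # background genic placement avoids the clonal genes: their occupancy is
  # exactly the planted clone, keeping the planted truth identifiable
  bg_genes <- genes[!genes$gene_id %in% clonal_genes, ]

  design <- study_design(config)
  base <- design |> distinct(.data$vector, .data$cell, .data$replicate)

  in_clonal_span <- function(chrom, pos) {
    if (!nrow(cl)) return(rep(FALSE, length(pos)))
    hit <- rep(FALSE, length(pos))
    for (j in seq_len(nrow(cl))) {
      hit <- hit | (chrom == cl$chrom[j] & pos >= cl$tx_start[j] &
                      pos < cl$tx_end[j])
    }
    hit
  }

  draw_background <- function(n) {
    genic <- runif(n) < config$p_genic
    gi <- sample(nrow(bg_genes), n, replace = TRUE)
    gpos <- floor(bg_genes$tx_start[gi] +
                    runif(n) * (bg_genes$tx_end[gi] - bg_genes$tx_start[gi]))
    ichrom <- sample(unique(genes$chrom), n, replace = TRUE)
    ipos <- floor(runif(n, 0, config$genome_len))
    out <- tibble(
      chrom = ifelse(genic, bg_genes$chrom[gi], ichrom),
      pos = ifelse(genic, gpos, ipos),
      clonal = FALSE
    )
    # intergenic draws are rejection-sampled out of clonal gene spans so
    # the planted clone stays the only occupant of its gene
    for (it in 1:25) {
      bad <- which(in_clonal_span(out$chrom, out$pos))
      if (!length(bad)) break
      out$chrom[bad] <- sample(unique(genes$chrom), length(bad),
                               replace = TRUE)
      out$pos[bad] <- floor(runif(length(bad), 0, config$genome_len))
    }
    out
  }

  sites <- purrr::map_dfr(seq_len(nrow(base)), function(i) {
    b <- base[i, ]
    pos <- bind_rows(
      draw_background(n_bg),
      tibble(chrom = cl$chrom,
             pos = floor(cl$tx_start + runif(nrow(cl)) *
                           (cl$tx_end - cl$tx_start)),
             clonal = TRUE)
    ) |>
      mutate(strand = sample(c("+", "-"), dplyr::n(), replace = TRUE))
    founder <- rlnorm(nrow(cl), meanlog = 4.2, sdlog = 0.1)
    tps <- design |>
      filter(.data$vector == b$vector, .data$cell == b$cell,
             .data$replicate == b$replicate) |>
      pull("timepoint")
    purrr::map_dfr(tps, function(tp) {
      cnt <- pmax(1, round(rlnorm(n_bg, meanlog = 2, sdlog = 1)))
      clk <- if (tp == "late") founder * config$clonal_fold else founder
      depth <- rlnorm(1, meanlog = 0, sdlog = 0.4)
      pos |>
        mutate(
          seq_count = pmax(1, round(c(cnt, clk) * depth)),
          sample = sample_id(b$vector, b$cell, tp, b$replicate),
          vector = b$vector, cell = b$cell, timepoint = tp,
          replicate = b$replicate
        ) |>
        select(-"clonal")
    })
  })

  structure(list(sites = sites, clonal_genes = clonal_genes),
            class = "is_simulation")
}
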