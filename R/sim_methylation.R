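#' Simulate a probe-by-sample methylation beta matrix
#'
#' Baseline beta values follow the bimodal pattern of array methylation
#' data: promoter-island probes are lowly methylated (Beta(2, 10)),
#' everything else highly methylated (Beta(10, 2)). Per-sample values add
#' logit-normal noise whose beta-scale standard deviation is approximately
#' `beta_noise_sd`. `n_dmr_probes` planted probes are shifted by
#' `dmr_delta` on the beta scale in infected samples, then clipped to
#' \[0, 1\]; planted probes are chosen among probes with headroom for the
#' shift (hypermethylation is planted at lowly methylated probes and vice
#' versa), mirroring promoter hypermethylation in carcinogenesis.
#'
#' @param annotation A [make_genome()] annotation (supplies the probe map).
#' @param design A sample sheet as from [expression_design()] (`sample` and
#'   logical `infected` columns used).
#' @param config A [sim_config()] object.
#' @return A list of class `meth_simulation`: `beta` (probes x samples
#'   matrix in \[0, 1\]), `design`, `dmr_probes` (planted probe ids).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50, n_probes = 300, n_dmr_probes = 20)
#' sim <- simulate_methylation(make_genome(cfg), expression_design(cfg), cfg)
#' range(sim$beta)
#' @export
simulate_methylation <- function(annotation, design, config) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "sim_config"))
  if (abs(config$dmr_delta) >= 1) abort("`dmr_delta` must lie in (-1, 1).")
  if (!all(c("sample", "infected") %in% names(design))) {
    abort("`design` needs columns sample, infected.")
  }
  set.seed(derive_seed(config$seed, "methylation"))

  probes <- annotation$probes
  np <- nrow(probes)
  ns <- nrow(design)
  promoter_island <- probes$cpg_class == "island" &
    probes$position_class %in% c("TSS1500", "TSS200")
  base <- ifelse(promoter_island,
                 stats::rbeta(np, 2, 10),
                 stats::rbeta(np, 10, 2))

  # planted probes need headroom so the shift survives clipping
  eligible <- which(base + config$dmr_delta > 0.02 &
                      base + config$dmr_delta < 0.98)
  dmr_idx <- if (config$n_dmr_probes > 0L && length(eligible)) {
    sort(sample(eligible, min(config$n_dmr_probes, length(eligible))))
  } else integer(0)

  shift <- matrix(0, np, ns)
  shift[dmr_idx, design$infected] <- config$dmr_delta

  b <- pmin(pmax(base, 0.01), 0.99)
  # logit-scale noise scaled so the beta-scale sd is ~beta_noise_sd on
  # mid-range probes; the denominator is floored so probes near 0 or 1 get
  # proportionally smaller absolute noise (array noise is heteroscedastic)
  # instead of heavy logit-tails
  sd_logit <- config$beta_noise_sd / pmax(b * (1 - b), 0.1)
  noise <- matrix(rnorm(np * ns), np, ns) * sd_logit
  beta <- stats::plogis(stats::qlogis(b) + noise) + shift
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(probes$probe_id, design$sample)

  structure(list(beta = beta, design = design,
                 dmr_probes = probes$probe_id[dmr_idx]),
            class = "meth_simulation")
}
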