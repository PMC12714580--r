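# Shared fixtures and independent brute-force oracles.

# A small configuration for fast unit tests.
small_config <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed, n_chrom = 2L, genome_len = 2e6, n_genes = 120L,
    is_per_sample = 150L, n_clonal_genes = 10L, n_de_genes = 20L,
    n_modules = 2L, module_size = 10L, n_probes = 400L,
    n_dmr_probes = 40L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Hand-built genome_annotation from plain tibbles (computes TSS).
toy_annotation <- function(genes, exons, probes = NULL) {
  genes$tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1)
  if (!"is_oncogene" %in% names(genes)) genes$is_oncogene <- FALSE
  if (!"is_tsg" %in% names(genes)) genes$is_tsg <- FALSE
  if (is.null(probes)) {
    probes <- tibble::tibble(
      probe_id = character(0), chrom = character(0), pos = numeric(0),
      gene_id = character(0), position_class = character(0),
      cpg_class = character(0))
  }
  structure(list(genes = genes, exons = exons, probes = probes),
            class = "genome_annotation")
}

# The worked single-gene fixture used across annotation tests:
# '+' gene, tx 1000-2000, exon1 1000-1200, CDS 1100-1900, exon2 1800-2000.
worked_gene <- function(strand = "+") {
  toy_annotation(
    genes = tibble::tibble(
      gene_id = "gA", chrom = "chr1", strand = strand,
      tx_start = 1000, tx_end = 2000, cds_start = 1100, cds_end = 1900,
      is_oncogene = FALSE, is_tsg = FALSE),
    exons = tibble::tibble(
      gene_id = "gA", start = c(1000, 1800), end = c(1200, 2000),
      rank = 1:2)
  )
}

# --- independent oracles -------------------------------------------------

# BH step-up from the definition: p_adj(i) = min_{j: p_(j) >= p_(i)} n p_(j)/j
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    r_i <- which(o == i)          # rank of p[i]
    cands <- vapply(r_i:n, function(j) n * p[o[j]] / j, numeric(1))
    adj[i] <- min(1, min(cands))
  }
  adj
}

# Hypergeometric upper tail by explicit pmf summation.
hyper_oracle <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# CIS oracle: build the full pairwise adjacency matrix explicitly and take
# connected components by breadth-first search over it.
cis_oracle <- function(chrom, pos, linkage) {
  n <- length(pos)
  adj <- outer(pos, pos, function(a, b) abs(a - b) < linkage) &
    outer(chrom, chrom, `==`)
  diag(adj) <- FALSE
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nb <- which(matrixStats_colAny(adj[frontier, , drop = FALSE]) &
                    comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

matrixStats_colAny <- function(m) colSums(m) > 0

# Exhaustive per-base region classification for a toy annotation.
# Returns a function pos -> list(gene_id, region) for one chromosome.
perbase_oracle <- function(annotation, chrom_len, chrom = "chr1") {
  genes <- annotation$genes[annotation$genes$chrom == chrom, ]
  lookup_gene <- rep(NA_character_, chrom_len)
  lookup_region <- rep("intergenic", chrom_len)
  for (b in seq_len(chrom_len)) {
    pos <- b - 1
    cover <- genes[genes$tx_start <= pos & pos < genes$tx_end, ]
    if (!nrow(cover)) next
    d <- abs(pos - cover$tss)
    cover <- cover[order(d, cover$gene_id), ]
    g <- cover[1, ]
    ex <- annotation$exons[annotation$exons$gene_id == g$gene_id, ]
    in_exon <- any(ex$start <= pos & pos < ex$end)
    in_cds <- g$cds_start <= pos & pos < g$cds_end
    region <- if (in_exon && in_cds) "exon"
      else if (in_exon) {
        five <- if (g$strand == "+") pos < g$cds_start else pos >= g$cds_end
        if (five) "5UTR" else "3UTR"
      } else "intron"
    lookup_gene[b] <- g$gene_id
    lookup_region[b] <- region
  }
  list(gene = lookup_gene, region = lookup_region)
}

# Naive O(n^3) TOM oracle.
tom_oracle <- function(a) {
  n <- nrow(a)
  diag(a) <- 1
  k <- rowSums(a) - 1
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Yates-corrected chi-square from the definition; the correction is
# clamped so it never overshoots past zero deviation.
chisq_yates_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum(pmax(0, abs(m - e) - 0.5)^2 / e)
}

# Adjusted Rand index (direct contingency-table formula).
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  sij <- s(as.vector(tab)); si <- s(rowSums(tab)); sj <- s(colSums(tab))
  expected <- si * sj / choose(sum(tab), 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
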