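---
title: "Methods: multi-omic genotoxicity assessment of lentiviral vectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic genotoxicity assessment of lentiviral vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open. No empirical number is stated here that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Lentiviral vectors integrate into the host genome semi-randomly, with a
strong preference for transcription units. An insertion near a
proto-oncogene can activate it (particularly for native-LTR
configurations whose enhancers remain active); an insertion into a
tumour suppressor can disrupt it. `lentitox` quantifies this genotoxic
potential from three read-outs on infected cell populations —
integration-site (IS) inventories with clone-abundance sequence counts,
bulk expression counts, and methylation beta values — and integrates
them into a per-condition report.

The emulated study design is two vectors (`pHR`, SIN-LTR; `pHV`,
native LTR) applied to proliferative iPSC (harvested day 3 and day 30)
and quiescent hepatocyte-like cells (day 3 only), three biological
replicates each, with uninfected controls for the expression and
methylation arms.

## Integration-site analysis

**Relative sequence counts.** Sequencing depth differs between samples,
so each site's sheared-fragment count is converted to the fraction of
all fragments in its sample (`relative_counts()`). All clonality
comparisons work on these fractions; per sample they sum to 1.

**Annotation.** A site is assigned to the gene whose transcription unit
contains it; when several genes overlap, the gene with the nearest TSS
wins and exact ties go to the lexicographically smaller gene id (a
deterministic, arbitrary rule — recorded, not tuned). Within a gene the
region precedence is: inside the CDS → `exon`; inside an exon but
outside the CDS → `5UTR`/`3UTR` by gene orientation; otherwise
`intron`. Positions are reported normalised to gene length and oriented
5'→3'. Intergenic sites keep a null gene id; the nearest gene with a TSS
within 100 kb is carried in a separate column for proximity reporting,
so the invariant "intergenic ⇔ no gene id" holds. Coordinates are
0-based half-open throughout (BED convention); the cancer-proximity
window is half-open on both sides of the TSS, `[TSS − w, TSS + w)`, with
`w` = 100 kb by default.

**Common integration sites.** Sites are nodes; two nodes on a chromosome
are linked when their distance is strictly below 50 kb; connected
components are the CIS. The implementation is a single sorted sweep,
which equals the full pairwise graph by transitivity — an equivalence
the acceptance suite re-verifies against an explicit pairwise-adjacency
oracle on random instances. Ties at exactly the linkage distance are not
connected. No background model is applied: CIS here are purely
density-defined, and on small dense genomes (like the synthetic one)
clusters can span large regions — a property of the definition, not a
bug.

**Clonal tracking.** Per gene, relative counts of all its sites are
aggregated within each replicate (replicates without the gene contribute
0), a pseudo-fraction ε = 1e−6 keeps logs finite, and late is compared
to early by a pooled-variance two-sample Student's t on
`log2(rel + ε)` across replicates. p-values are BH-adjusted over all
genes with at least one site at either timepoint; a gene is flagged at
|fold| ≥ 2 and adjusted p < 0.05. The log scale stabilises the heavy
right tail of clone sizes; the ε floor means a gene observed only late
gets a finite, positive fold. Swapping the arms negates every fold
(tested).

## Differential expression

Counts are normalised as `log2((count + 0.5)/library_size × 1e6)`
(total-count log2-CPM). CPM is the minimal defensible normalisation for
gene-level counts; its compositional limitation is discussed under the
generator below. Genes with log2-CPM above 0 in fewer than 2 samples are
filtered before fitting (configurable).

Per-gene ordinary least squares share one QR decomposition of the design
matrix. Variance moderation follows the scaled-F empirical-Bayes scheme:
with `s_g² ~ s0²·χ²_d/d` per gene, `E[log s_g²]` and `Var[log s_g²]`
have closed forms in digamma/trigamma, so `d0` is obtained by inverting
the trigamma function (Newton iteration) on the excess dispersion of
`log s_g²` and `s0²` from the mean. When the observed log-variances are
no more dispersed than sampling alone explains (or the inversion
fails), `d0 = ∞` and all genes share `s0²`. The moderated t uses the
posterior variance `(d0·s0² + df·s_g²)/(d0 + df)` with `df + d0`
degrees of freedom; at `d0 = 0` it reduces to the ordinary t (tested to
1e−10). A unit test cross-checks the whole stack against an independent
implementation of the same estimator, and a parameter-recovery test
regenerates `s0²` within 10% and `d0` within 25% from 5000 simulated
variances. DEG thresholds are strict inequalities: |log2FC| > 1 and
BH-adjusted p < 0.01.

## Enrichment, signatures, co-expression

**ORA.** Hypergeometric upper tail `P[X ≥ k]` with the universe set to
the genes actually tested upstream (not the genome): enrichment against
an inflated universe is the classic way to manufacture significance.
Sets are intersected with the universe before testing; BH across sets.

**GSEA.** Weighted-KS running sum (weight 1 by default; weight 0 gives
the classic KS statistic) with a gene-label permutation null. Sample
permutation is preferable in principle but impossible at n = 3 per
group, so gene-label permutation is used and labelled an approximation.
The permutation p carries +1 smoothing and can never be exactly 0.

**Signatures.** A cancer signature is the up-regulated gene set of a
tumor-vs-normal contrast at log2FC > 2 and BH p < 0.01 (strict; a
config switch adds down-genes, which then contribute negated z-scores).
Scoring z-scores each signature gene across the scored cohort —
infected and control samples together, so controls sit near baseline —
and averages z over genes; the score vector therefore has mean 0 across
the cohort, is invariant to per-gene affine rescaling, and zero-variance
genes are dropped with a warning. Group summaries report mean ± SEM
(`sd/√n`; a single observation reports `NA`).

**Co-expression.** Unsigned adjacency `|cor|^β`. The soft power β is
the smallest one whose scale-free fit index (sign-corrected r² of
`log10 p(k)` vs `log10 k` over 10 equal-width connectivity bins)
reaches 0.8 *while the mean connectivity stays below `√n/2`*; candidate
powers stop at 10. Both guards exist because at the small sample sizes
of this design the fit index alone is unstable: very low powers can
pass it while the network is still too dense for topological overlap to
discriminate, and very high powers pass it after all overlap has
collapsed. The TOM is the standard
`(Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij)` (unit diagonal),
verified against a naive triple-loop oracle. Modules come from
average-linkage clustering on `1 − TOM` with a *static* cut — chosen for
reproducibility over dynamic tree cutting — at the lower quartile of the
merge heights: in sparse-module data the minority of within-module
merges occupies the bottom of the height distribution and the bulk of
merges is the near-unit background plateau, so the lower quartile falls
between them. Clusters under 10 genes become `grey`; labels follow the
conventional size-ordered color list and carry no claim of
correspondence to any particular published module. Eigengenes are first
principal components of the standardized module submatrix, sign-aligned
to the module mean profile. By default the 1000 most variable genes
enter the network.

## Methylation

Delta-beta is the difference of arm means per probe (mean-difference
chosen over median; the decision is recorded). Calls are strict:
`hyper` iff Δβ > 0.2, `hypo` iff Δβ < −0.2; exactly 0.2 is not called.
No statistical test gates the call by default (only the threshold rule
is specified for this read-out); a t + BH gate is available as an
option. Region summaries cross-tabulate position class × CpG class ×
state with zeros filled and a log2(count+1) companion; the
promoter-hypermethylation read-out lists genes with ≥1 hyper island
probe in TSS1500/TSS200.

## Multi-omics integration

Exact set algebra over the per-layer gene sets (all pairwise and triple
intersections with member lists), triple positives = fusion ∩ IS ∩ DEG,
and the oncogene/TSG homogeneity chi-square between vectors with Yates
continuity correction — the correction is on by default because it is
the convention under which the reference 2×2 example (37/51 vs 81/82)
reproduces its printed statistic of 1.0523; the uncorrected Pearson
value differs. Gene ids are matched by exact symbol; alias resolution is
an extension point.

## The synthetic-data generator

The generator exists because the assay's raw data are not deposited; it
emulates the statistical structure each caller assumes, fully seeded
(per-stage seeds derive from the root seed by a stable hash, so adding a
stage never perturbs another).

* **Genome** — genes in non-overlapping slots with log-normal lengths,
  1–8 exons, a CDS spanning first to last exon; `floor(frac·n)` genes
  flagged oncogene/TSG; methylation probes with realistic class
  frequencies and island-enriched promoters.
* **Integration sites** — background sites land genic with probability
  0.75 (typical of lentiviral integration), counts log-normal
  (meanlog 2, sdlog 1): a heavy-tailed clone-size spectrum. Planted
  clonal genes carry one founder site per replicate with a tight
  founder abundance (log-normal meanlog 4.2, sdlog 0.1) whose late
  count is the early count times `clonal_fold`. The tightness is a
  design decision: planted founders of near-equal size make the
  recovery benchmark measure the tracker, not the founder-size lottery —
  with heavy-tailed founder sizes, a two-sample t across 3 replicates
  has an expected |t| of about 1.7 regardless of the tracker, and no
  method could meet the recovery target. For the same reason background
  sites are rejection-sampled out of the clonal genes' transcription
  units, so a clonal gene's aggregate is exactly its clone. Per-sample
  depth factors force downstream analysis onto relative counts.
* **Expression** — NB counts (`Var = μ + φμ²`, φ = 0.1) on log-normal
  baselines with per-sample library factors. Planted DEGs (±3 log2)
  respect compositionality: up-effects go to moderate baselines
  (20–200) and down-effects to high baselines (400–2000), because a
  2³ fold on a heavy-tail gene inflates the library itself and biases
  every CPM fold-change, while down-shifting a low-baseline gene drops
  it under the Poisson floor. Planted modules put half their genes on
  positive and half on negative loadings of a shared latent factor
  (modules contain up- and down-regulated members; the unsigned network
  uses |cor|), which also keeps the module library-neutral under CPM;
  the factor is standardized to unit sample variance so the planted
  amplitude (2.4 log2 on baseline-500 genes) is exact in every
  realisation, not just in expectation.
* **Methylation** — bimodal baselines (low at island promoters, high
  elsewhere), logit-normal noise whose beta-scale sd is ≈ 0.05 at
  mid-range and proportionally smaller near 0/1 (array noise is
  heteroscedastic; an unfloored logit sd would put heavy tails on
  extreme probes), planted shifts of +0.3 on probes with headroom for
  the shift.
* **Fusions** — a fraction (5%) of genic IS emit one vector–host fusion
  record, so fusion genes are IS genes by construction.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: read-level artefacts (PCR duplicates,
shear-site collisions, mapping ambiguity), integration-site hotspots
driven by chromatin state, isoform structure (one transcript per gene),
batch effects and unwanted variation in expression, array probe
cross-hybridisation and SNP-overlap, and real tumor heterogeneity
behind signature derivation. Benchmarks that plant a known truth measure
the callers under the generator's assumptions; they are necessary, not
sufficient, evidence for field data.

Two benchmark configurations deliberately zero out one planted layer:
the DEG-calibration benchmark runs with no planted modules (a module's
latent factor can differ between two 3-sample arms by chance, which the
benchmark's truth set would mis-count as false positives), and the
module-recovery benchmark runs with no planted DEGs (infection-response
genes form a genuine third co-expression module, while the benchmark's
background is defined as noise).

## Problem sizes and reproducibility

Defaults: 2000 genes on 4 × 15 Mb chromosomes, 2000 IS per sample, 100
planted DEGs, 2 modules of 50 genes at latent correlation 0.8, 5000
probes with 200 planted shifts, 3 replicates — sizes at which every
planted-truth benchmark in the test suite resolves cleanly on a single
core in seconds. The full pipeline is deterministic given the root seed;
the report serialises without timestamps so reruns are byte-identical,
which the acceptance script verifies by running it twice.

## Known limitations

CIS detection has no genomic background model (by specification);
signature scoring assumes the scored cohort is a sensible z-scoring
reference; the static module cut trades the adaptivity of dynamic tree
cutting for reproducibility and can fragment modules whose internal
dissimilarity approaches the background; gene-label GSEA permutation
understates between-gene correlation; and total-count CPM remains
compositional — strongly asymmetric regulation would bias fold-changes,
which is why the generator documents (rather than hides) that
interaction.
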