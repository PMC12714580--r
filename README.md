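# lentitox

Multi-omic genotoxicity assessment of lentiviral gene-therapy vectors.

Lentiviral vectors integrate semi-randomly into the host genome, and an
insertion near a proto-oncogene or tumour suppressor can deregulate it —
the central safety concern for gene-therapy products. `lentitox`
implements an integrated desk-side analysis of this risk from three omic
read-outs on infected cells (e.g. iPSC and hepatocyte-like cells infected
with a SIN-LTR versus a native-LTR vector):

* **Integration sites (IS)** — per-site sheared-fragment sequence counts
  are converted to relative sequence counts, sites are annotated against
  gene models (exon / intron / 5'UTR / 3'UTR / intergenic, position
  normalised to gene length, distance to TSS/ATG/stop), common
  integration sites are detected as connected components of the graph
  linking sites closer than 50 kb, proximity to cancer-gene TSSs is
  scored in a ±100 kb window, and clonal expansion is tracked per gene as
  the change in relative sequence count between an early and a late
  harvest (two-sample Student's t on log2 fractions, Benjamini–Hochberg
  adjusted, flagged at ≥2-fold and adjusted p < 0.05).
* **Transcriptome** — log2-CPM normalisation, per-gene linear models and
  empirical-Bayes variance moderation: the prior degrees of freedom `d0`
  and prior variance `s0²` of the scaled-F hierarchical model
  `s_g² ~ s0²·χ²_d/d` are estimated by the method of moments on
  `log s_g²` (digamma/trigamma identities), the posterior variance is
  `(d0·s0² + df·s_g²)/(d0 + df)` and the moderated t has `df + d0`
  degrees of freedom. DEGs pass |log2FC| > 1 and BH p < 0.01; oncogene /
  tumour-suppressor DEG counts are compared between vectors by
  Yates-corrected chi-square. Enrichment via the hypergeometric
  upper-tail test and a weighted-KS ranked GSEA; cancer signature scores
  as the scaled (z-scored) mean expression of tumor-derived gene sets;
  WGCNA-style co-expression modules from the topological overlap matrix
  `TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij)` with soft
  threshold chosen by scale-free fit, module eigengenes, module–trait
  correlation and intramodular connectivity.
* **Methylome** — per-probe delta-beta between arms, hyper/hypo calls at
  the strict |Δβ| > 0.2 rule, cross-tabulated by promoter position class
  (TSS1500/TSS200/5'UTR/Body/3'UTR) and CpG context
  (island/shore/shelf/open-sea), and promoter-island hypermethylated
  gene lists.

The layers are intersected (IS ∩ DEG ∩ DMR ∩ fusion genes, with
"triple positives" among vector–host fusion transcripts) and assembled
into a per-condition genotoxicity report.

Because the assay's raw sequencing data are not publicly deposited, the
package ships a fully seeded synthetic-data generator
(`sim_config()`, `make_genome()`, `simulate_insertion_sites()`,
`simulate_expression()`, `simulate_methylation()`, `simulate_fusions()`)
that emulates the study design — 2 vectors × {iPSC day 3, iPSC day 30,
HLC day 3} × 3 replicates plus uninfected controls — with planted clonal
expansions, differential genes, co-expression modules and methylation
shifts, so every caller can be validated against a known truth.

## Worked example

```r
library(lentitox)

cfg <- sim_config(seed = 42)          # the default synthetic study
report <- run_genotox_pipeline(cfg)   # ~15 s on one core
report
#> <genotox_report>
#>   stages present: region_profile, cis, clonal, deg, enrichment, modules,
#>     methylation, signature_scores, intersections, fusions
#>   seed: 42

nrow(report$stages$clonal$flagged)    # genes with significant clonal
#> [1] 91                              # sequence-count change (of 100 planted)

report$stages$modules$sizes
#> # A tibble: 4 x 2
#>   module        n
#>   <chr>     <int>
#> 1 blue         50
#> 2 brown        50
#> 3 grey        798
#> 4 turquoise   102
```

`blue` and `brown` are the two planted 50-gene co-expression modules;
`turquoise` is the infection-response module formed by the planted
differential genes. The oncogene/TSG homogeneity test between two DEG
sets (here the published 37/51 vs 81/82 example):

```r
onco_tsg_chisq(matrix(c(37, 81, 51, 82), nrow = 2))
#> $chi2  1.052338
#> $p     0.3049692
#> $df    1
```

Every fitted object has broom-style accessors (`tidy()`, `glance()`) and
each result type has a ggplot display (`autoplot()`, `plot_volcano()`,
`plot_enrichment()`, `plot_signature_scores()`, `plot_module_trait()`,
`plot_methylation_regions()`).

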