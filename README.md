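# tromics

Integrative trans-omics network analysis for two-group phenotype
contrasts.

## The problem

Small case–control omics studies — the motivating design contrasts
peripheral blood monocytes from five high- versus five low-hip-BMD
(bone mineral density) subjects — rarely yield genome-wide-significant
hits in any single omics layer. `tromics` implements a pipeline that
pools the weak per-layer evidence instead:

1. **Meta-integration.** For gene *g* and layer *k* (expression, promoter
   methylation), the association score `S_gk` is a pooled two-sample
   t statistic, standardized by its permutation standard deviation
   (`Z_gk = S_gk / sd_perm`). The combined score is the half-normal sum

   ```
   S_g_meta = sum_k |Z_gk|
   ```

   with integrated p-value `P(sum_k |Z_k| > s)` under the null (for two
   layers this equals the closed form `1 - [2*Phi(s/sqrt(2)) - 1]^2`),
   followed by Benjamini–Hochberg FDR.

2. **Pathway impact.** Per pathway, hypergeometric over-representation of
   the seed genes (`P_NDE`) and a bootstrap p-value for the
   topology-propagated net perturbation (`P_PERT`, with perturbation
   factors solving `PF = dE + B PF`, `B_ij = beta_ij / N_ds(j)`) are
   combined into `P_G = c - c*ln(c)`, `c = P_NDE * P_PERT`.

3. **Module discovery.** On a reliability-weighted interactome with node
   prizes `b_i = -ln p_i` and edge costs `c_e = 1 - prod_j R_j`, the
   disease module minimizes the prize-collecting Steiner tree objective

   ```
   sum_{e in E'} c_e  -  lambda * sum_{i in V'} b_i
   ```

   over connected subgraphs. `lambda` is calibrated so that simulated
   networks matched to the prize graph's statistics recover at least 70%
   of their planted essential nodes.

4. **miRNA regulation.** Candidate miRNAs (selected at `p <= 0.05`, in
   EM/E classes by data availability) are attached to module genes at
   Pearson `r <= -0.55`, screened against a miRNA-target map, and each
   module gene is classified into one of four regulation patterns:
   promoter methylation, miRNA, neighbor/transcription factor, or
   methylation+miRNA co-regulation.

A fully synthetic, ground-truth-annotated generator
(`generate_dataset()`) emulates the assumed data structure — planted
differential genes, expression–methylation anti-correlation, a planted
connected interactome module, miRNA–target anti-correlation — so every
stage is testable offline. See the methods vignette
(`vignettes/tromics-methods.Rmd`) for models, assumptions and design
choices.

## Worked example

```r
library(tromics)

ds <- generate_dataset(synthetic_config(seed = 42))   # 2000 genes, 200 miRNAs, 5+5
write_dataset(ds, "demo_data")

cfg <- pipeline_config(
  expression        = "demo_data/expression.tsv",
  methylation       = "demo_data/methylation.tsv",
  groups            = "demo_data/groups.tsv",
  mirna_expression  = "demo_data/mirna_expression.tsv",
  mirna_methylation = "demo_data/mirna_methylation.tsv",
  interactome       = "demo_data/interactome.tsv",
  pathways_gmt      = "demo_data/pathways.gmt",
  pathway_topology  = "demo_data/pathway_topology.tsv",
  target_map        = "demo_data/target_map.tsv",
  lambda = "calibrate", seed = 42
)
res <- run_pipeline(cfg)
res
#> <tromics_results>
#>   genes integrated: 2000 (q <= 0.05: 18)
#>   miRNAs integrated (EM): 100; pathways tested: 20
#>   candidates: 20; module: 10 nodes (lambda = 0.07)
#>   screened miRNA pairs: 67 (4 target-supported)
```

Eighteen genes pass FDR 0.05; the seeded disease pathway dominates the
pathway table (17 of its genes are seeds, `P_NDE = 9.1e-20`); the
calibration settles on `lambda* = 0.07` and the solver returns a 10-gene
module tree:

```r
head(tidy(res$integration_genes)[, c("feature", "s_meta", "p_inte", "q_inte")], 3)
#>   feature s_meta   p_inte   q_inte
#> 1 g0356    13.2  2.30e-20 4.61e-17
#> 2 g0634    10.7  7.87e-14 7.87e-11
#> 3 g1863    10.4  3.65e-13 2.43e-10

res$module
#> <tromics_module> 10 nodes, 9 edges; objective -8.6201 (lambda = 0.07, heuristic)
#>   nodes: g0024, g0165, g0321, g0356, g0410, g0561, g0622, g0634, g1152, g1170

tidy(res)[1:5, c("gene", "pattern", "methyl_p", "methyl_corr", "mirna_partner")]
#>   gene  pattern      methyl_p methyl_corr mirna_partner
#> 1 g0024 METHYLATION  4.40e- 6      -0.800 <NA>
#> 2 g0165 NEIGHBOR_TF  3.61e- 1       0.412 <NA>
#> 3 g0321 CO_REGULATED 8.90e- 4      -0.862 mir002
#> 4 g0356 METHYLATION  2.18e-10      -0.947 <NA>
#> 5 g0410 MIRNA        1.10e- 1      -0.660 mir003
```

The pattern table reads directly as biology: `g0024` is
methylation-driven (methylation p = 4.4e-6, correlation −0.80), `g0410`
is repressed by its anti-correlated target-mapped miRNA (`mir003`,
r = −0.89), `g0321` shows both lines of evidence, and `g0165` is
explained by a strongly co-expressed module neighbor. Against the
generator's ground truth this module overlaps the planted 12-gene module
at Jaccard 0.83. `autoplot()` methods display the integration volcano,
the pathway evidence plane, the module tree and the calibration sweep;
`glance()`/`tidy()` give broom-style summaries at each stage.

A thin command-line wrapper with `simulate`, `integrate`, `run-all` and
`calibrate-lambda` subcommands is installed at `inst/cli/tromics.R`.

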