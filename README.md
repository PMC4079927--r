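# microdelta

Paired-intervention analysis linking changes in gut microbiota composition to
changes in host metabolic parameters.

## The problem and who this is for

In small human diet-intervention cohorts, stable inter-individual differences
dominate faecal community profiles, so cross-sectional comparisons are nearly
powerless. The paired alternative analyses *per-subject change*: every
microbiota parameter `M` (rank-aggregated relative abundances, the
Firmicutes/Bacteroidetes and Prevotella/Bacteroides ratios, alpha-diversity
indices) and every host parameter `P` (anthropometry, substrate oxidation,
plasma markers, ...) is reduced to

```
ΔM = M_t29 − M_t0            (arithmetic difference)
ΔP = (P_t29 − P_t0) / P_t0   (baseline-relative difference)
```

All (ΔM, ΔP) pairs are correlated with Kendall's tie-corrected tau-b,

```
tau_b = (C − D) / sqrt((n0 − n1)(n0 − n2)),   n0 = n(n−1)/2,
```

pairs with `|tau| ≥ 0.65` (inclusive, configurable) become edges of a
bipartite microbiota–host network, and connected components group parameters
that respond together. A multivariate layer confirms the picture: the RV
matrix correlation between whole delta blocks, and NIPALS PLS1 models with
leave-one-out cross-validation (`Q² = 1 − PRESS/TSS`) and Tukey-jackknife
variable selection. A univariate paired host test (subject-blocked
two-timepoint model with a log-transform heuristic and a `3·√MSE` outlier
rule) completes the stack.

The package is for microbiome and systems-biology researchers who want this
workflow as composable, tested R functions: every user-facing function takes
a data frame and returns a tibble, results have `tidy()`/`glance()` methods
and `autoplot()` visualizations, and a synthetic paired-cohort generator
with *planted, known-truth* associations makes the whole pipeline's
sensitivity and false-edge behaviour measurable.

## Worked example

```r
library(microdelta)

cfg <- cohort_config(n_subjects = 10, n_genera = 40, n_phyla = 5,
                     n_links = 4, link_strength = 0.9,
                     host_params_total = 30, seed = 2024)
res <- run_pipeline(run_config(simulate = cfg, depth = 1000,
                               cutoff = 0.65, seed = 2024))
res$network
#> Bipartite microbiota-host correlation network
#>   nodes: 20 (10 microbial, 10 host)
#>   edges: 10 (6 positive, 4 negative)

head(dplyr::arrange(tidy(res$network), dplyr::desc(abs(tau))), 5)
#> # A tibble: 5 × 6
#>   microbial_param host_param    tau n_pairs excluded_reason  sign
#>   <chr>           <chr>       <dbl>   <int> <chr>           <int>
#> 1 g__Genus010     host_06    -0.911      10 <NA>               -1
#> 2 div__simpson    host_05     0.822      10 <NA>                1
#> 3 g__Genus003     host_01    -0.750      10 <NA>               -1
#> 4 g__Genus011     host_15    -0.711      10 <NA>               -1
#> 5 div__richness   host_26     0.707      10 <NA>                1

exact_tau_null(10, 0.65, n_mc = 1e5, seed = 1)$probability
#> [1] 0.00468
```

Reading this: at n = 10 subjects the network's 10 edges include recovered
planted associations (e.g. the strength-0.9 link behind the −0.911 edge) next
to chance threshold-crossings — `exact_tau_null()` shows a raw |tau| ≥ 0.65
cutoff passes ~0.47% of null pairs at this cohort size, so with thousands of
candidate pairs a raw-threshold network necessarily carries null edges. The
same pipeline at n = 50 recovers ≥ 90% of planted links with essentially no
false edges (see the acceptance benchmark below). `res` also carries the
diversity table, Bray–Curtis/UPGMA clustering, the full correlation table,
per-component reports, the RV coefficient, PLS fits and the univariate host
tests, plus a provenance report sufficient to re-run the analysis.

## Layout

| Path | Contents |
|---|---|
| `R/synthetic_cohort.R` | taxonomy/count/host generators, planted links, ground truth |
| `R/community_metrics.R` | rarefaction, rank aggregation, diversity, ratios, Bray–Curtis, UPGMA |
| `R/kendall.R`, `R/delta_network.R` | tau-b, exact small-n null, deltas, pairwise correlations, network, components |
| `R/multivariate.R`, `R/pls.R`, `R/host_test.R` | autoscaling, RV, NIPALS PLS + LOO-CV + jackknife, paired host test |
| `R/pipeline.R`, `R/io.R` | end-to-end runner, TSV/JSON/GraphML/SIF/Newick I/O |
| `vignettes/microbiota-host-networks.Rmd` | the methods vignette |
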