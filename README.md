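# netpharm

Network-pharmacology screening and bioassay analytics for herbal compound
libraries, in R.

Multi-herb traditional formulas act through many compounds hitting many
targets. A common computational screen for such libraries works in two
stages, followed by bench validation of the best hit:

1. **ADMET screening.** Upstream classifiers emit *signed probabilities*
   for absorption endpoints (human intestinal absorption, Caco-2
   permeability) and for inhibition of the five major CYP450 isoforms
   (1A2, 2C9, 2D6, 2C19, 3A4): the sign encodes the predicted class, the
   magnitude the classifier's confidence. Compounds with non-positive
   absorption predictions are discarded, and the metabolism predictions are
   collapsed into a composite score weighted by each classifier's overall
   predictive accuracy *Q*:

   score = Σₖ resultₖ · Qₖ,  k over the five CYP isoforms,

   with default Q = (0.8147, 0.8018, 0.8551, 0.8054, 0.6450) applied
   positionally to the report column order 1A2, 2C9, 2D6, 2C19, 3A4.
   Compounds whose composite score is not positive are discarded too.

2. **Network construction.** Retained compounds and their predicted protein
   targets form a bipartite compound–target network; targets with degree
   ≥ 10 are extracted as hubs, intersected with disease-associated target
   sets, and linked into a target–disease–group network (MeSH-style
   category codes). SIF and GraphML writers keep everything
   Cytoscape-compatible.

3. **Bioassay analytics.** The statistics used to validate a hit at the
   bench: MTT inhibition rate `100·(A_ctrl − A_treat)/A_ctrl`,
   four-parameter log-logistic IC50 fitting, relative gene expression by
   2^−ΔΔCt, Annexin V/PI quadrant gating, JC-1 depolarized-fraction
   estimation, and a permutation dose-trend test.

Every input has a seeded synthetic generator with planted ground truth
(`simulate_*`), so the full pipeline is testable without any external data.

## Worked example

```r
library(netpharm)

tbl <- read_admet_table(system.file("extdata", "admet_candidates.csv",
                                    package = "netpharm"))
res <- screen_library(tbl)
res
#> <screen_result> 32 compounds: 32 retained, 0 discarded (0 absorption, 0 score)
#> score floor > 0; weights: cyp_1a2=0.8147, cyp_2c9=0.8018, cyp_2d6=0.8551, cyp_2c19=0.8054, cyp_3a4=0.6450

head(rank_compounds(res)[, c("compound_id", "score")], 3)
#> # A tibble: 3 × 2
#>   compound_id score
#>   <chr>       <dbl>
#> 1 Majudin      3.48
#> 2 Bergapten    3.47
#> 3 Sesamin      3.46
```

The bundled table holds 32 candidate compounds that already passed both
filters; all 32 are retained, ranked by composite CYP score (Majudin tops
the list at 3.48407919; the stilbene alpha-Viniferin scores 1.13587144
because two of its CYP predictions are of the non-inhibitor class and
subtract from the sum).

Downstream, with synthetic data:

```r
net <- with(simulate_bipartite_edges(seed = 1),
            build_bipartite_network(compounds, targets, edges))
length(hub_nodes(net, "target", min_degree = 10))
#> [1] 5

fit <- fit_dose_response(simulate_dose_response(noise_sd = 0, seed = 1)$plate)
glance(fit)$ic50
#> [1] 13.61
```

`run_pipeline()` chains all stages from a single YAML (or list) config and
writes per-stage tables, a timestamped log, and a deterministic
`report.json`.

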