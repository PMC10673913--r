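# ccnet

Co-consumption network analysis of dietary intake.

## The problem

Classical dietary-pattern analysis (factor scores, diet indices) summarizes
*what* and *how much* people eat, but discards the third component of a
dietary pattern: *which foods are eaten together*. `ccnet` represents a
cohort's diet as a **co-consumption network (CCN)**: food groups are nodes,
sized by how many participants consume them, and an edge connects two groups
whose gram-per-day intakes are positively rank-correlated across
participants — robustly so, not just in one sample. The network view exposes
dietary structure that single-food analyses miss — hub foods, cliques of
jointly consumed groups, and healthy/unhealthy modules — and links it to a
clinical outcome, here hepatic steatosis measured by the FibroScan
controlled attenuation parameter (CAP, dB/m).

It is aimed at nutritional epidemiologists working with food frequency
questionnaire (FFQ) data converted to g/day, plus basic covariates (age,
sex, BMI, energy intake) and a CAP score.

## The method

Given an intake matrix *X* (participants × food groups, g/day):

1. **Edge validation.** Participants are randomly split in half 100 times.
   A pair of groups *(g, h)* is connected iff its Spearman correlation is
   significant (α = 0.05) and positive in *both* halves of *every* repeat,
   and the mean test-half correlation r̄ exceeds the soft threshold 0.2.
   The edge weight is r̄.
2. **Node weights.** Each group's consumption score is the number of
   participants whose intake exceeds the group's first quartile (strictly);
   for zero-inflated groups with Q1 = 0 this counts the non-zero consumers.
3. **Modules.** The graph is clustered by label propagation; because single
   runs are stochastic, 50 restarts are run and the most frequent
   (canonicalized) partition is kept, scored by modularity
   Q = Σ_c (e_cc − a_c²).
4. **Participant membership.** For each participant, consumed module-labeled
   groups are tested for over-representation in each module with an
   upper-tail hypergeometric probability; p < 0.1 in exactly one module
   assigns the participant to it, otherwise they are "other". The module
   whose members have the higher mean CAP is named *unhealthy*.
5. **Contrasts.** Member covariates are compared by t and chi-square tests;
   sex- and disease-stratified (CAP < 238 vs ≥ 293 dB/m) networks yield
   differential CCNs (tagged symmetric differences); age strata (< 30,
   30–50, > 50 years) yield a trend network of pairs whose correlation
   rises with age; maximal cliques of size ≥ 4 inside one module are tested
   for differential consumption between member groups with chi-square and
   Benjamini–Hochberg FDR.

Because cohort FFQ data are rarely shareable, the package ships a synthetic
cohort generator (`simulate_cohort`) with two planted correlated blocks,
zero-inflated log-normal intakes, and a CAP outcome driven by the latent
adherences — so every stage can be tested against known ground truth.

## Worked example

```r
library(ccnet)

coh <- simulate_cohort(default_cohort_spec(), seed = 42)
fit <- ccn(coh$intake, seed = 42)
print(fit)
#> Co-consumption network: 40 food groups, 176 validated edges, 10 isolated
#>   participants: 1500  threshold: mean rho > 0.2 over 100 split-half repeats
#>   modules: M1 (16 nodes), M2 (14 nodes)  modularity: 0.474

res <- ccn_analysis(coh$intake, coh$covariates, seed = 42)
print(res)
#> Co-consumption analysis (seed 42 )
#>   network: 40 nodes, 176 edges, 10 isolated; hub: Cereals.Refined (degree 15)
#>   modules: unhealthy=16, healthy=14 ; modularity 0.474
#>   density (edges/node): unhealthy=6.75, healthy=4.86
#>   members: unhealthy=257, healthy=255, other=988
#>   member mean CAP: unhealthy=260.9, healthy=205.4 dB/m
#>   differential edges: sex 36 , disease 125 ; trend edges: 58 ; related cliques: 8
```

Reading the output: the 40 food groups form a network with two clear
modules (modularity 0.474 — well above 0, so the diet has modular
structure). The 10 isolated nodes are groups whose consumption tracks no
other group — mostly the heavily zero-inflated ones. Of 1500 participants,
257 are significantly enriched in unhealthy-module foods and 255 in
healthy-module foods; the unhealthy members' mean CAP is ~55 dB/m higher,
i.e. markedly fattier livers:

```r
cmp <- res$comparison
cmp[cmp$variable == "CAP score (dB/m)", ]
#>           variable mean_unhealthy sd_unhealthy mean_healthy sd_healthy        p
#> 4 CAP score (dB/m)          260.9        44.53        205.4      42.49 7.3e-40
```

`res$cliques` lists the module-related cliques with consumer percentages in
both member groups and FDR-adjusted p-values; `write_cohort()`,
`write_ccn()` and `ccn_analysis(..., out_dir = )` export everything as
CSV/GraphML/JSON.

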