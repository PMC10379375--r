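# timask

Time-intensity (TI) sensory curve analysis and flavor-masking
classification, in tidyverse-style R.

Sensory panels for flavor development record, at 1 Hz, how the perceived
intensity of a flavor rises, peaks and fades after a sample enters the
mouth. For product work on plant-protein foods, the practical question is
which flavoring materials best *mask* an off-flavor — here, the beany
note of soymilk — and which features of a material's temporal profile
predict that masking ability. `timask` is for sensory and flavor
scientists who have (or want to simulate) panel TI data and need the
complete, reproducible chain from raw replicate curves to a statistical
answer.

## What it computes

* **TI parameters.** Each material's averaged curve is segmented into
  increasing, plateau and decreasing phases and summarised by the 14
  standard descriptors: Tstart, Tend, Imax, TsPl, TePl, DurPl, DurInc,
  DurDec, SIMInc, SIMDec and the trapezoidal phase areas AreaInc,
  AreaPl, AreaDec, AreaTse (with AreaInc + AreaPl + AreaDec = AreaTse).
* **Masking scores.** From visual-analog-scale (VAS) ratings of residual
  beany intensity b on the 10-point scale, each material scores
  `masking = 10 − median(b)`; a material whose residual median is 4.0
  scores 6.0.
* **Group tests.** The retained TI parameters are compared between the
  top-k and bottom-k masking materials with the two-tailed Mann–Whitney
  U test (U in min(U₁, U₂) form; exact p for n + m ≤ 24 without ties,
  normal approximation with tie and continuity correction otherwise).
* **Pruning and classification.** Near-duplicate parameters
  (|r| ≥ 0.98) are dropped in favor of conventional representatives;
  the remainder is standardized ((x − x̄)/σₙ), decomposed by PCA, and
  clustered with seeded k-means++ (k = 3 by default) in the PCA1–PCA2
  plane, with clusters relabeled so the highest-masking cluster is
  always the last label.
* **Synthetic studies.** A seeded generator draws ramp-plus-exponential
  release archetypes per material type (oil / essence / flavor), renders
  noisy panelist curves, and links VAS ratings to the closed-form
  decreasing-phase area, so the whole pipeline runs and is testable with
  no external data.

## A worked example

One config and one seed drive everything:

```r
library(timask)

cfg <- default_run_config(seed = 11)
cfg$synthetic$n_essence    <- 6L   # scaled-down demo study
cfg$synthetic$n_oil        <- 6L
cfg$synthetic$n_flavor     <- 6L
cfg$synthetic$n_panelists  <- 4L
cfg$synthetic$n_replicates <- 4L
cfg$stats$top_bottom_k     <- 4L

report <- run_ti_pipeline(cfg)
report
```

```
timask run report (version 0.1.0, seed 11)
input: synthetic study
...
top vs bottom masking groups (Mann-Whitney U, two-tailed):
 parameter   U p_two_tailed method  median_top median_bottom significant
    Tstart 2.5       0.1370 normal    5.500000      4.000000       FALSE
      Imax 4.0       0.3430  exact   45.437112     41.994414       FALSE
    DurDec 0.0       0.0286  exact  196.500000     42.000000        TRUE
   AreaInc 0.0       0.0286  exact  395.092379    150.896459        TRUE
   AreaDec 0.0       0.0286  exact 2187.779016    534.688925        TRUE
...
clusters (k = 3, inertia = 50.484, PC1 65.6% / PC2 19.2% of variance):
 cluster n mean_masking_score                         members
       0 8                4.4 e02 e03 e05 e06 f02 f03 f04 f05
       1 4                5.1                 e01 e04 f01 f06
       2 6                8.7         o01 o02 o03 o04 o05 o06
highest-masking cluster 2 vs rest: U = 0, p = 0.0001077
```

Reading this: materials whose flavor *persists* in the decreasing phase
(high DurDec/AreaDec — here the oil-type materials) mask the beany note
best; the top-vs-bottom comparison flags exactly those persistence
parameters, and the k-means clusters recover the oil group as the
high-masking cluster (mean score 8.7 vs 4.4–5.1, exact Mann–Whitney
p ≈ 1e−4). Individual stages are available as plain functions —
`masking_scores()`, `extract_ti_parameters()`, `prune_correlated()`,
`compare_top_bottom()`, `classify_materials()` — all taking and
returning tibbles, with `tidy()`/`glance()` on the fitted model and
`autoplot()` for the PCA scatter. A thin command-line wrapper lives at
`inst/cli/timask.R`.

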