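# nephroclust

Unsupervised subtyping of the clinical course of primary nephrotic syndrome.

Primary nephrotic syndrome (minimal change disease, membranous nephropathy,
focal segmental glomerulosclerosis and related glomerulonephritides) is
diagnosed by kidney biopsy, but its course is monitored with a handful of
objective laboratory items. `nephroclust` implements a pipeline that
classifies two-year clinical courses without using the histopathological
diagnosis:

1. **Inputs.** Five items — serum creatinine (mg/dL), serum albumin (g/dL),
   dipstick hematuria and proteinuria grades (ordinal 0–5), and the urine
   protein-to-creatinine ratio (UPCR, g/gCr) — observed at months
   1, 3, 6, 12 and 24 after biopsy. Complete cases only; per-item pooled
   z-scoring.
2. **Embedding.** An LSTM encoder–decoder (encoder 5 → 24 → 12 → 2; decoder
   mirrored) is trained to reconstruct the standardized 5 × 5 trajectory
   block under mean-squared-error loss (mini-batch Adam, 5 sets × 4 epochs ×
   1,000 updates, batch size 10, early stop when the epoch loss no longer
   drops significantly). The final-step output of the 2-unit LSTM is the
   case's point in a 2-D feature space.
3. **Clustering.** A full-covariance Gaussian mixture is fitted to the
   embedding by EM (seeded multi-restart). Each case joins the component
   with the highest weighted log-likelihood
   `argmax_k [log w_k + log N(z; mu_k, Sigma_k)]`; BIC
   (`-2 loglik + p log n`) is available for selecting the component count.
4. **Characterization.** Cluster sizes, disease-by-cluster crosstab,
   at-biopsy mean (SD) tables, per-cluster item time courses, a canonical
   severity ordering (ascending month-24 creatinine), and latent-plane
   log-likelihood contour grids.

Because the underlying registry cohort is not publicly deposited, the
package ships a **synthetic cohort generator**: four trajectory archetypes
(C1–C4) calibrated to the published cluster weights (85:52:32:36),
per-cluster at-biopsy means/SDs, and per-cluster disease mixes, with course
shapes that reproduce the described phenotypes (C1 mild/fast remission, C2
intermediate/slow remission, C3 initially severe with a good course, C4
persistent proteinuria with a late creatinine rise). Planted labels make
every downstream stage testable.

## Worked example

```r
library(nephroclust)

cfg <- pipeline_config(n = 205, visit_sd_scale = 0.5, K = 4, seed = 1)
res <- run_pipeline(cfg)
#> [simulate] generated 205 patients (seed 49281)
#> [filter] complete cases: 205 of 205
#> [train] 11 epochs, first/final loss 0.3975 / 0.1002
#> [cluster] fitted K = 4 mixture (loglik 155.58)
#> [done] analyzed 205 patients into 4 clusters in 10.7s

res$profile$sizes
#> cluster
#> C1 C2 C3 C4
#> 64 55 73 13

res$profile$severity
#> C1 C2 C3 C4
#>  3  4  2  1
```

The mixture's component indices are arbitrary; `res$profile$severity` is
the canonical ordering (1 = mildest course by month-24 creatinine). Here
fitted component C2 carries the most severe courses and C4 the mildest.

```r
head(res$profile$crosstab)
#>         cluster
#> disease  C1 C2 C3 C4 Total
#>   MCD    11  3 62 11    87
#>   MN     37 37  6  1    81
#>   FSGS    1  9  4  1    15
#>   MPGN    4  3  1  0     8
#>   IgAN    8  3  0  0    11
#>   MesPGN  3  0  0  0     3
```

Minimal change disease concentrates in the mild fast-remitting component
(here C3) while membranous nephropathy spreads across components — the
qualitative pattern the classification is meant to expose. With
`out_dir` set, `run_pipeline()` writes every artifact (cohort CSV,
embedding, mixture JSON, assignments with responsibilities, profile tables,
contour grid, manifest) for reuse; individual stages are exported
(`generate_cohort()`, `filter_complete()`, `fit_scaler()`,
`train_autoencoder()`, `encode_cohort()`, `fit_mixture()`,
`assign_clusters()`, `select_k_bic()`, `cluster_profile()`, ...).

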