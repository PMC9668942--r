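---
title: "Methods: trajectory embedding and mixture clustering in nephroclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory embedding and mixture clustering in nephroclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`nephroclust` classifies two-year clinical courses of primary nephrotic
syndrome from five routinely monitored items — serum creatinine (mg/dL),
serum albumin (g/dL), dipstick hematuria and proteinuria grades (ordinal
0–5), and the urine protein-to-creatinine ratio (UPCR, g/gCr) — observed at
months 1, 3, 6, 12 and 24 after kidney biopsy. The method is a two-stage
unsupervised pipeline:

1. a sequence autoencoder compresses each standardized 5-visit × 5-item
   trajectory into a point in a 2-D feature space, and
2. a full-covariance Gaussian mixture model (GMM) over that plane defines
   the clusters; each case is assigned to the component with the highest
   weighted log-likelihood,
   $\arg\max_k\,[\log w_k + \log \mathcal N(z_i;\mu_k,\Sigma_k)]$,
   which equals the maximum-responsibility (MAP) component.

The premise is that course *shape* — how fast proteinuria remits, whether
kidney function deteriorates late — carries prognostic structure that
single-visit values do not. The autoencoder is trained only to reconstruct
its input, so the latent organization emerges without outcome labels or
histological diagnoses.

### Encoder–decoder architecture

The encoder applies an LSTM with 24 units across the five timesteps, a
per-step dense sigmoid layer down to 12 units, and a second LSTM with 2
units; the case's latent point is the **final-step hidden output** of that
2-unit LSTM (the standard seq2seq bottleneck; cell state and per-step
averages are the natural alternatives, and the final hidden state was chosen
because it is the quantity the recurrence itself propagates forward as "the
summary so far"). The decoder mirrors the stack — the latent point is
repeated across five steps, passed through LSTM(2→12), dense sigmoid
(12→24), LSTM(24→5) — and a per-step linear readout maps the bounded
(−1, 1) LSTM outputs onto the unbounded z-score scale. Without that affine
readout the decoder could not represent standardized values beyond ±1 and
the loss would have an artificial floor.

Training minimizes the mean squared reconstruction error with mini-batch
Adam (learning rate 10⁻³, β₁ = 0.9, β₂ = 0.999): 5 sets × 4 epochs ×
1,000 updates per epoch on mini-batches of 10 cases drawn by
replacement-free reshuffling that wraps over the cohort. "1,000 learnings
per epoch" is read as 1,000 gradient updates — the only reading consistent
with the batch size being specified separately. A `reverse_target` switch
trains the decoder against the time-reversed sequence instead (the
alternative reading of "restores the inputs in the reverse order"); the
default reconstructs chronological order, reading that phrase as describing
the mirrored layer stack.

**Early stopping.** Training halts once the relative epoch-to-epoch loss
reduction falls below `early_stop_rel_tol`. The default is 0.02: a 2 %
per-epoch improvement threshold makes the rule actually bind within the
20-epoch budget on cohort-sized data (typically stopping after 7–18
epochs). With a much smaller tolerance the rule never fires — the loss
keeps creeping down by ~1 % per epoch while the 205-case model overfits,
and planted-cluster recovery in the latent plane measurably degrades.

All weights initialize uniformly in ±1/√fan-in with zero biases except a
forget-gate bias of 1; initialization and shuffling are driven by a single
seed, and the compiled core (RcppArmadillo) is deterministic given its
inputs, so equal (data, configuration, seed) reproduce the loss history and
embedding exactly. Gradients are backpropagation-through-time derived by
hand and verified in the test suite against central finite differences; the
forward pass is cross-checked against an independent plain-R
implementation.

### Preprocessing

* **Complete cases only.** A case is retained when all five items are
  present at baseline and at every scheduled visit. No imputation.
* **Dipstick coding.** (−) → 0, (±) → 1, (1+) → 2 … (4+) → 5. A six-level
  scale is required because reported proteinuria grade means exceed 4.0,
  impossible on a 0–4 coding.
* **Standardization.** Per-item z-scoring pooled over all five visits of
  the fitted cohort (SD floored at 10⁻⁸). The items span two orders of
  magnitude (UPCR ≈ 8 g/gCr vs grades ≤ 5 vs creatinine ≈ 1); an MSE loss
  on raw units would be dominated by UPCR.
* **Baseline values** (at biopsy) are not model inputs; they feed only the
  at-biopsy summary table. Visit month is not an input feature either — the
  sequence is five ordered steps.

### Mixture clustering

EM with full (anisotropic) 2 × 2 covariances, a ridge of 10⁻⁶ on each
covariance diagonal at every M-step, and `n_init = 10` seeded restarts. The
first restart starts from a Ward-linkage agglomerative partition; the rest
alternate k-means partitions and random soft responsibilities. Because the
unconstrained mixture likelihood is unbounded, restarts whose smallest
component retains fewer than d + 1 expected members are screened out when
any alternative exists; among the rest the best final log-likelihood wins.
Assignment ties break toward the lowest component index, for determinism.
`select_k_bic()` scores K = k\_min…k\_max with
$\mathrm{BIC} = -2\ell + p\log n$, $p = (K-1) + Kd + Kd(d+1)/2$, and keeps
the minimizer. K = 4 is the package default, matching the reference
analysis; the BIC search is provided because the original component-count
choice procedure is not documented.

### Characterization

`cluster_profile()` reproduces the reporting surfaces: cluster sizes, the
disease-by-cluster crosstab with margins, at-biopsy mean (SD) per cluster
("x.xx (y.yy)"), per-cluster per-item visit-time mean/SD curves, and a
canonical severity ordering. Severity is operationalized as ascending mean
serum creatinine at month 24, ties broken by month-24 UPCR, then original
index — a reproducible proxy for the informal "initial values and course"
ordering. `likelihood_contours()` evaluates the max-component weighted
log-density on a rectangular grid; the numeric grid is the tested surface
(rendering is cosmetic).

## The synthetic cohort generator

The registry cohort behind the reference analysis is not deposited, so the
package generates labeled stand-in cohorts whose *statistical structure*
matches what the analysis assumes.

Each of four archetypes C1–C4 carries: a mixing weight (85:52:32:36 /205);
at-biopsy means and SDs of the five items equal to the published
per-cluster summaries; a disease distribution equal to the published
disease-by-cluster counts (MCD, MN, FSGS, MPGN, IgAN, MesPGN); a 5 × 5
course-multiplier matrix; and a 5 × 5 visit-level SD matrix.

**Course shapes.** The published per-cluster curves exist only as plots, so
the multipliers are package-chosen constants realizing the described
phenotypes:

* **C1** — mild disease, fast remission (proteinuria multiplier falls to
  0.04 by month 24, albumin doubles, creatinine stable);
* **C2** — intermediate severity, slow gradual remission;
* **C3** — initially severe hematuria and proteinuria (near C4's starting
  level) followed by brisk remission and full albumin recovery;
* **C4** — persistently high proteinuria, non-declining UPCR
  (multiplier 0.96 → 1.12), and a late creatinine rise (1.00 → 1.55 across
  months 1 → 24).

C3's "high start, good course" is deliberately a *crossing* trajectory:
during design, monotone drafts in which C1 < C2 < C3 < C4 along a single
severity axis made C3 a latent-space interpolation of C2 and C4 that no
clustering could recover. The final shapes give the four archetypes
course directions, not just course magnitudes. The default month-24
creatinine cluster means come out strictly ordered (0.93, 1.14, 1.18, 2.08
mg/dL), so the canonical severity ordering reproduces C1→C4.

**Value model.** Baselines are drawn as censored normals: continuous items
floored just above zero, grades clamped to [0, 5] and rounded to the
integer grid. Censoring means large-cohort sample means sit slightly above
the nominal mixture of published means (for UPCR about +0.075 g/gCr,
analytically); the tests therefore check calibration against the *exact*
generative means, computed by an independent normal-CDF oracle, as well as
against the published totals at their coarser tolerances.

**Within-patient correlation** comes solely from a shared damped intercept:
with $b_j$ the patient's censored baseline draw,

$$x_{jt} = \big[\mu_j + \rho\,(b_j - \mu_j)\big]\, m_{jt} +
\varepsilon_{jt},\qquad \varepsilon_{jt}\sim\mathcal N(0, s_{jt}),$$

censored like the baseline. The persistence fraction ρ
(`intercept_strength`, default 0.35) encodes that treated disease remits
toward the cluster course largely regardless of where a patient started —
at-biopsy deviations propagate only partially into the follow-up visits.
The choice matters: with ρ = 1 the intercept variance of the high-SD items
(UPCR SD ≈ 4–6.5 g/gCr) dominates the between-cluster course differences
along exactly the directions a reconstruction-driven 2-D code preserves,
and planted clusters — though nearly perfectly separable in the full
25-cell space — become unrecoverable by *any* two-dimensional code followed
by a GMM. No visit-level dispersions or serial correlations are published,
so both ρ and the visit SDs,
$s_{jt} = 0.4\,\mathrm{SD}^{\mathrm{base}}_j \max(m_{jt}, 0.25)$
(dispersion shrinking as an item remits, never below a tenth of the
baseline SD), are the package's own calibration, fixed as part of the
reference study conditions. `scale_archetype_noise()` exposes both SDs as
explicit knobs; shrinking the visit-level SD tightens trajectories around
their cluster course and is the canonical way to generate easier or harder
recovery problems.

A fixed 19/205 fraction of patients is flagged untreated, independent of
cluster (no cluster linkage is published), supporting the treated-only
sensitivity filter (205 → 186 cases).

**What the generator does not emulate:** enrollment and dropout of the
full registry, visit-time jitter, autoregressive within-patient noise,
detection limits and reporting quirks of real laboratory data, or any
association between treatment status and course. Passing tests demonstrate
that the pipeline recovers planted structure of this calibrated form — not
that the real cohort's clusters are correct.

## Numerical choices and degenerate inputs

* Scaler SDs floored at 10⁻⁸: constant items standardize to 0 rather than
  NaN; a cohort of identical trajectories embeds to a single point.
* Covariance ridge 10⁻⁶ keeps EM finite on (near-)degenerate embeddings.
* EM convergence: relative log-likelihood change < 10⁻⁸, max 500
  iterations; non-convergence returns the best iterate with a warning.
* Assignment ties (measure-zero in practice) go to the lowest component
  index.
* All stage seeds derive deterministically from one global seed
  (`run_pipeline()`), so stages can be rerun in isolation from saved
  artifacts; checkpoints and mixtures serialize as plain JSON.
* Tests run the generator at n = 205 (pipeline properties), n = 2,000
  (trajectory-mean recovery) and n = 20,000 (baseline calibration);
  property tests that retrain the autoencoder use a shortened schedule
  (2 × 2 epochs × 300–500 updates), sizes chosen to exercise the asymptotic
  claims at desk scale.

## Known limitations

* **Two dimensions are a hard bottleneck.** The latent code keeps the
  variance directions that aid reconstruction; cluster contrasts that are
  orthogonal to them can merge. Across training seeds the recovery of
  planted clusters is bimodal — most runs separate all four archetypes,
  a minority merge the two intermediate ones. Restart selection by
  reconstruction loss does not cure this (loss barely correlates with
  latent cluster quality), so the package keeps the faithful single-model
  pipeline.
* **BIC component-count selection on autoencoder latents is unstable.**
  The latent blobs are not Gaussian, and adjacent K differ by only a few
  nats; an independent reference implementation (mclust) selects the same
  wrong counts on the same embeddings. The acceptance suite reports this
  honestly rather than tuning around it; K = 4 as a fixed default is the
  reliable mode of use.
* The severity ordering is a proxy; with close month-24 creatinine means
  (default C2 vs C3 differ by 0.04 mg/dL) sampled cohorts can swap those
  ranks.
* The generator's censored-normal value model reproduces means and SDs,
  not the full shape of real laboratory distributions (UPCR is
  right-skewed in practice).
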