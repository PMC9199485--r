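---
title: "Methods: network integration, transfer, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network integration, transfer, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpc)
```

## The model and its assumptions

`netpc` analyses two-arm (intervention vs active control, 2:1 allocation),
two-visit designs in which each subject contributes a symmetric functional
connectivity (FC) matrix per visit and longitudinal scores in a trained
domain, a transfer domain, and a null (no-expected-effect) domain.

The core quantity is the weighted participation coefficient. Given an
a-priori partition of nodes into $M$ networks, node $i$'s strength is
$k_i = \sum_j w_{ij}$ over nonnegative edge weights, its per-network
strength is $k_{i,m}$, and

$$\mathrm{PC}_i \;=\; 1 - \sum_{m=1}^{M}\left(\frac{k_{i,m}}{k_i}\right)^2 .$$

Assumptions worth stating explicitly:

* **Rectification.** Negative FC has no agreed interpretation, so negative
  edges are set to zero before any metric; `participation_coefficient()`
  refuses signed input rather than silently absorbing it.
* **Weighted, not binarised.** PC is computed on edge weights directly;
  no proportional thresholding is applied, so results do not depend on an
  arbitrary sparsity target.
* **Fixed partition.** Networks are an input (default: the canonical
  seven cortical networks), never re-derived by community detection. This
  makes PC comparable across subjects and visits but ties its meaning to
  the chosen parcellation.
* **Isolated nodes** ($k_i = 0$) get PC 0 with a flag instead of NaN. This
  keeps network means defined; the flagged count surfaces in messages so a
  pathological matrix cannot pass silently.
* **Inference on change scores.** The interaction model
  $\Delta y = \beta_0 + \beta_1 G + \beta_2 \Delta\mathrm{PC} +
  \beta_3\, \Delta\mathrm{PC}\times G + \varepsilon$ (control = 0) is a
  Gaussian identity-link least-squares fit; each coefficient is tested with
  a 1-df Wald $\chi^2 = (B/SE)^2$. The published form of this model labels
  the interaction coefficient $\beta_4$ with no $\beta_3$ term; we treat
  that as a typographical gap — the model has exactly the four terms above
  plus optional covariates.
* **FDR family.** BH adjustment is applied across the seven network-level
  tests per cognitive domain; the global-PC test is reported unadjusted,
  outside the family.
* **GEE.** The visit-by-group model on PC uses a Gaussian identity-link GEE
  with AR(1) working correlation and robust sandwich errors. With two
  visits AR(1) and exchangeable coincide (one free parameter) — a tested
  invariant. The outcome distribution family is not identified by the
  marginal model; Gaussian is assumed. `geepack` is not a dependency: the
  estimator (iterated GLS with moment estimation of the working
  correlation) is implemented in-package and validated against OLS on the
  balanced case, where the point estimates must agree exactly.
* **Mediation.** Paths are standardized regression coefficients from three
  OLS fits; the indirect effect $a\cdot b$ gets a case-resampling
  percentile bootstrap CI (BCa by flag). Mediation is assessed regardless
  of total-effect significance: a near-zero total effect can mask opposing
  indirect paths (the "inconsistent mediation" configuration, which the
  test suite reproduces with $a b = 0.25$, $c' = -0.25$).

## Tunable parameters that matter

| parameter | default | units / scale | why |
|---|---|---|---|
| `within_mean`, `between_mean` | 0.17, 0.01 | correlation | calibrated so baseline positive-edge density lands in the 63–80% (within) and 42–62% (between) bands typical of dense cortical FC |
| `edge_sd` | 0.30 | correlation | same calibration; 0 gives exact block means |
| `integration_shift_mean`, `_sd` | 0.01, 0.01 | correlation | subject-specific post-visit increase in between-network coupling for intervention subjects; the SD creates between-subject ΔPC variance, without which no interaction is estimable |
| `trained_gain` | 0.5 | baseline-SD units | matches a medium training effect (g ≈ 0.5) |
| `transfer_coupling` | 20 | score units per unit ΔPC | order of magnitude of published change-score interaction coefficients; ΔPC is ~0.01–0.05 so the implied behavioural effect is a fraction of an SD |
| `behavior_noise_sd`, `null_domain_sd` | 0.5 | baseline-SD units | post-visit residual noise |
| `sem_mode` | `"mean"` | — | "1 SEM of baseline data" is ambiguous; SD/√n is the default, the psychometric SD·√(1−reliability) is available when a reliability coefficient exists; the mode is recorded in every result |
| `fraction` (high-PC) | 0.20 | — | diverse-club convention; `floor(fraction · N)` nodes, ties broken by node id |
| `n_boot` | 5000 | replicates | bootstrap CI resolution; tests use 1000 for runtime |

## What the generator emulates — and what it does not

`generate_connectomes()` draws, per subject-visit, a block-model matrix:
within-network blocks centred at `within_mean`, between-network blocks at
`between_mean` (+ the subject's integration shift at the intervention post
visit), i.i.d. Gaussian edge noise per undirected pair, mirrored, clamped to
$[-1, 1]$, zero diagonal. `generate_behavior()` computes each subject's
realised global ΔPC from those matrices and plants: a trained-domain gain in
the intervention group, a transfer-domain gain of
`transfer_coupling · ΔPC` in the intervention group only, and pure noise in
the null domain. An optional factor-model time-series mode
(`generate_timeseries()`) produces nodal series whose correlation structure
matches the same blocks, to exercise the FC-construction path.

The generator deliberately does **not** model BOLD physiology, motion
artifacts, spatial autocorrelation, hemispheric structure, heterogeneous
network sizes within a scan, or floor/ceiling effects in test scores. A
green recovery test therefore establishes that the estimators recover
planted parameters under the stated statistical structure — not that the
pipeline is robust to acquisition artifacts it never sees.

Two consequences of the calibration are worth knowing. First, at
`edge_sd = 0` all edges are positive, so densities are exactly 100%; the
density bands are only meaningful at the calibrated noise level. Second,
between-network density cannot fall below 50% while `between_mean > 0`,
which the analytic PC oracle requires; the calibrated defaults give a
global density of ~54% rather than the ~49% seen empirically, while both
block-level bands are met. We accepted this mismatch rather than allow
negative expected between-network coupling.

## Numerical choices

* Symmetry is enforced by $(A + A^\top)/2$ on load, warning above a
  $10^{-10}$ tolerance; the diagonal is always zeroed.
* Edges count as present iff weight $> 0$: exact zeros (the product of
  rectification) are absent edges, which makes density invariant to
  rectification — a tested identity.
* Confound regression uses pivoted QR; rank deficiency aborts with the
  names of the aliased columns rather than silently dropping them.
* BH adjustment is the literal step-up rule
  $\min_{j \ge i} \, m\, p_{(j)} / j$ capped at 1, checked against an
  independent brute-force oracle and against `p.adjust`.
* The reliable-change boundary is strict: a gain of exactly one SEM does
  not count as improvement.
* Hedge's $J$ uses the reciprocal form
  $[1 - 3/(4(N-1)-1)]^{-1}$ as published for this analysis; the standard
  small-sample correction $1 - 3/(4\,df - 1)$ is available by flag. The two
  differ by <2% at these sample sizes but in opposite directions from 1.
* Bootstrap replicates reuse the analysis sample's standardization rather
  than restandardising per replicate, keeping paths comparable; the
  decomposition $c = c' + ab$ then holds exactly in every replicate.
* The pipeline derives all stage seeds deterministically from one root
  seed, so e.g. changing `n_boot` cannot perturb cohort generation, and an
  identical config yields a byte-identical JSON report.

## Design choices where the design was open

* **SEM definition.** Implemented as a mode switch (see table) because the
  source material is ambiguous and the classic trial it cites used the
  psychometric standard error of measurement. The pooled two-group baseline
  SD is used; per-group SDs are not, as no grouping is stated.
* **Hedge's denominator.** "Intra-subject standard deviation" is read as
  the pooled SD of change scores (the quantity whose group difference g
  standardises).
* **Top-20% rule.** `floor(0.2 N)` with node-id tie-break, over the whole
  node set (not per hemisphere); no rule is stated in the source material.
* **Mediation sample.** Intervention group only by default (the scenario
  in which transfer operates); a full-sample mode is available.
* **Partial correlation.** FC is the correlation of confound-residualised
  series; no additional partialisation between node pairs is applied.
* **Integration shift variance.** The between-subject SD of the planted
  shift (0.01) is a calibration choice, not an empirical value: no study
  reports the variance of ΔPC across subjects.

## Known limitations

* The GEE implementation targets the balanced two-visit Gaussian case it is
  used for; it accepts unbalanced clusters but has not been exercised
  against long irregular panels.
* Mediation covers the single-mediator model only.
* The pipeline holds all matrices in memory; at thousands of nodes and
  hundreds of subjects, memory — not time — becomes the binding constraint.
* Acceptance-style checks of the published headline coefficients (e.g. the
  ventral-attention interaction B = 30.88) are impossible without the
  original imaging data, which were never deposited; the test suite instead
  anchors on self-contained printed statistics and on property/recovery
  simulations with known ground truth. Every empirical number quoted in
  this vignette is recomputed by the test suite or the acceptance script.
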