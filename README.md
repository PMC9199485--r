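# netpc

Participation-coefficient analysis of functional connectomes for two-arm,
two-visit cognitive-training studies.

## The scientific problem

Cognitive training is most useful when gains *transfer* beyond the trained
task — for example, when speed-of-processing training in older adults with
amnestic mild cognitive impairment (aMCI) also improves working memory. One
candidate neural substrate of transfer is the brain's capacity for
*integration*: the degree to which cortical regions connect across, rather
than only within, the large-scale functional networks. `netpc` implements
the full analysis chain used to test this idea on resting-state functional
connectivity (FC):

1. **Connectome construction** — nodal time series are residualised on
   nuisance regressors (motion, tissue and global signals), pairwise Pearson
   correlations form a symmetric FC matrix, and negative edges are set to
   zero (rectification) before any graph metric is computed.
2. **Graph metrics** — for node *i* with strength *k<sub>i</sub>* and
   per-network strengths *k<sub>i,m</sub>* over the *M* declared networks
   (default: the seven canonical cortical networks — visual, somatomotor,
   dorsal attention, ventral attention, limbic, frontoparietal, default
   mode),

   PC<sub>i</sub> = 1 − Σ<sub>m=1..M</sub> (k<sub>i,m</sub> / k<sub>i</sub>)²

   A node whose edges stay inside its own network has PC 0; even spread over
   all networks approaches the maximum 1 − 1/M. Network and global PC are
   node means; the top 20% of nodes by PC form the "diverse club".
3. **Behavioural outcomes** — reliable improvement (follow-up exceeding
   baseline by more than one SEM of baseline data), uncorrected Pearson
   chi-square group comparisons, pooled-variance t tests, and bias-corrected
   Hedge's g.
4. **Inference** — change-score interaction GLMs
   (ΔCognition ~ Group + ΔPC + ΔPC×Group) with Benjamini–Hochberg adjustment
   across the seven network-level tests, visit×group Gaussian GEE with AR(1)
   working correlation and robust sandwich errors, and case-resampling
   bootstrap mediation of transfer through ΔPC (percentile CIs, tested
   regardless of the total effect's significance).
5. **Synthetic cohorts** — a seeded block-model generator plants a
   group-by-visit shift in between-network coupling and couples behavioural
   change to the realised change in PC, providing ground truth for recovery,
   type-I-error and coverage studies. Defaults are calibrated so baseline
   positive-edge densities land in the empirical bands for dense cortical FC
   (63–80% within-network, 42–62% between-network).

## Worked example

```r
library(netpc)

## nodal PC on a toy two-network graph
ids <- c("a1","a2","a3","b1","b2","b3")
m <- matrix(0, 6, 6, dimnames = list(ids, ids))
m["a1","a2"] <- 1; m["a1","a3"] <- 1; m["a2","b1"] <- 2; m["a2","a3"] <- 1
m["b1","b2"] <- 0.5; m["b2","b3"] <- 0.5
m <- m + t(m)
part <- network_partition(ids, rep(c("A","B"), each = 3))
participation_coefficient(connectivity_matrix(m), part)
#>   node_id network strength   pc isolated
#> 1      a1       A      2.0 0.00    FALSE
#> 2      a2       A      4.0 0.50    FALSE
#> 3      a3       A      2.0 0.00    FALSE
#> 4      b1       B      2.5 0.32    FALSE
#> 5      b2       B      1.0 0.00    FALSE
#> 6      b3       B      0.5 0.00    FALSE
```

`a1` touches only its own network, so its PC is 0; `a2` splits its strength
evenly between networks, giving 1 − (0.5² + 0.5²) = 0.5.

```r
## an end-to-end simulated study (56 + 28 subjects, 7 x 10 nodes)
cfg <- run_config(mode = "simulate", seed = 42,
                  synthetic = list(n_intervention = 56L, n_control = 28L,
                                   nodes_per_network = rep(10L, 7)),
                  analysis = list(n_boot = 1000))
report <- run_pipeline(cfg)
report
#> netpc pipeline report
#>   baseline density (global): 0.540
#>   scales: visual, somatomotor, dorsal_attention, ventral_attention,
#>           limbic, frontoparietal, default_mode, global
#>   episodic_memory: strongest interaction at limbic (B = -24.176, raw p = 0.0700)
#>   ufov: strongest interaction at dorsal_attention (B = 27.240, raw p = 0.0540)
#>   working_memory: strongest interaction at default_mode (B = 20.872, raw p = 0.1415)
#>   mediation indirect effect -0.0040, 95% CI [-0.0963, 0.0910]
```

The interaction estimates are on the scale "change in cognitive score per
unit change in PC, intervention beyond control"; at the study-sized n of 84
the planted coupling of 20 is inside every scale's confidence interval but
rarely significant — which is exactly why the test suite checks recovery at
n = 300 over 100 replicates rather than at desk scale. The per-stage CSV/JSON
artifacts, a combined `report.json` and a log are written when
`out_dir` is set.

A command-line wrapper with the same stages as subcommands lives at
`inst/cli/netpc.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","netpc.R",package="netpc"))')" \
    run --config cfg.yaml --seed 42 --out out/
```

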