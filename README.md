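# mcorrnet

Group-level differential **metabolic correlation network** analysis for
targeted metabolomics panels, including the **network growth rate** — the
least-squares slope of significant-edge count against subsample size under
ramped random resampling.

Classical metabolomics compares per-metabolite abundances between a case and
a control group. This package addresses the complementary question: how does
the *coordination* of the metabolome — the network of pairwise metabolite
correlations — differ between groups, and how fast does that network grow as
samples accumulate? It is aimed at researchers analysing cohort
mass-spectrometry panels (hundreds of metabolites annotated to a few dozen
biochemical pathways, tens of samples per group).

## The statistics at the core

- **Z-scores**: per metabolite, `z = (log2 AUC − mean_ctrl) / sd_ctrl`
  with control-group reference statistics (optionally sex-matched).
- **Networks**: for all `M(M−1)/2` pairs, Pearson `r` with two-sided
  p-values from `t = r√((n−2)/(1−r²))`, Benjamini–Hochberg FDR and Storey
  q-values; an edge is a pair with `q < q*` (default 0.05), signed by `r`,
  and scoped *in*- or *out-of-pathway*.
- **Hubs**: all edges touching a chosen pathway, split into in-pathway core
  and cross-pathway spokes; the **+r/−r ratio** (positive / negative hub
  edges) with a sample-level bootstrap SE; partner-pathway tallies;
  **hypercorrelator** ranking of metabolites by between-group out-of-pathway
  degree difference.
- **Growth rate**: subset sizes ramp 4, 6, … to `n−1`, 50 random subsamples
  per size, q-values recomputed within each subsample, significant edges
  counted; the OLS slope of `count ~ size` (edges per added sample) is the
  growth rate, compared between groups by a group × size interaction test.
- **Synthetic cohorts**: a latent pathway-factor generator with closed-form
  ground-truth correlations, used for the calibration and recovery tests.

## Worked example

```r
library(mcorrnet)

cfg <- synthetic_config(
  n_case = 24, n_control = 24,
  pathways = setNames(rep(6L, 8), sprintf("pw%d", 1:8)),
  rho_within = c(control = 0.6, case = 0.3),
  hub_links = data.frame(metabolite = "pw1_m01", target_pathway = "pw2",
                         sign = "-", strength = 0.35),
  seed = 42)
cohort <- generate_cohort(cfg)
z  <- zscore_transform(cohort$table)
zc <- subset_samples(z, group = "control")

net <- build_network(adjust_pvalues(pairwise_correlations(zc)),
                     cohort$pmap, q_threshold = 0.05, group = "control")
net
#> <metab_network> [control] 84 edges among 45/48 metabolites (q < 0.05)
#>
#>     in out
#>   -  0   2
#>   + 79   3

curve <- resample_edge_counts(zc, cohort$pmap, replicates = 20,
                              scope = "both", seed = 7)
fit_vnet(curve)
#> <vnet_fit> growth rate = 4.437 +/- 0.13 edges/sample (intercept -32.76, r^2 = 0.838, fit on raw_points, 220 points)
```

The control cohort was simulated with within-pathway correlation 0.6 plus
one negative cross-pathway hub link, so nearly all recovered edges are
positive and in-pathway, and the network gains about 4.4 edges for every
sample added — the growth rate. The pathway hub and its
stimulatory/inhibitory balance:

```r
hub <- extract_hub(net, "pw1")
hub
#> <hub_result> 'pw1' [control]: 16 hub edges (15 in-pathway, 1 spokes), +15 / -1
plus_minus_ratio(hub, zc, n_boot = 200, seed = 1)
#> <ratio_estimate> 'pw1': +r/-r = 15 +/- 2.6 (bootstrap, 200 reps)  [+15 / -1]
```

An end-to-end run (z-scoring, per-group networks, hubs, hypercorrelators,
growth curves and both group tests, written as a TSV/JSON bundle) is one
call: `run_pipeline("config.yaml")`; see `?read_run_config` for the format.

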