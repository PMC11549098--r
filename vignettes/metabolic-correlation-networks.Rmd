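---
title: "Metabolic correlation networks and the network growth rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic correlation networks and the network growth rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(mcorrnet)
```

## The model

Targeted mass-spectrometry metabolomics yields, for each sample, a vector of
peak areas (AUCs) over a panel of several hundred metabolites, each annotated
to one of a few dozen biochemical pathways. Beyond per-metabolite abundance
differences, case and control groups can differ in how *coordinated* their
metabolomes are: the structure of the pairwise correlation network. mcorrnet
implements a group-level differential correlation analysis built from four
pieces.

**Z-scoring.** AUCs are log2-transformed and standardized per metabolite
against the control group: $z_{ij} = (\log_2 a_{ij} - \mu_j^{ctrl}) /
\sigma_j^{ctrl}$, with the sample SD ($n-1$ denominator) over controls.
Controls then have mean 0 and SD 1 per metabolite; cases are expressed in
control-SD units. Pearson correlations are invariant to this per-column
affine map, so the network itself would be identical on raw log2 values —
the z-scale matters for effect-size reporting and cross-cohort comparability,
and the invariance is asserted in the test suite. Z-scoring requires strictly
positive, complete AUC matrices; missing or non-positive cells are a hard
error (no imputation is attempted), and a metabolite constant across controls
is rejected because its reference SD is zero. When male- or female-only
networks are analysed, `zscore_transform(by_sex = TRUE)` uses sex-matched
control references.

**Signed, q-thresholded networks.** For all $M(M-1)/2$ metabolite pairs,
the Pearson coefficient and its two-sided p-value from $t = r\sqrt{(n-2) /
(1-r^2)}$ on $n-2$ df are computed; multiple testing is handled both by
Benjamini–Hochberg FDR and by Storey q-values, and an edge enters the
network when $q$ falls below the chosen threshold (0.05 by default; chord
figures in this literature also use $10^{-5}$ and 0.01, so the threshold is
an argument everywhere, never a constant). Edges carry the sign of $r$ and a
pathway scope: *in* when both endpoints share a pathway, *out* otherwise.

**Hubs, ratios, hypercorrelators.** The hub of a pathway is every network
edge touching at least one of its metabolites; edges internal to the pathway
are the core, the rest are spokes tallied by partner pathway. The +r/−r
ratio — positive over negative hub edge count — summarizes the net
stimulatory-vs-inhibitory correlation balance of the pathway, and
`plus_minus_ratio()` attaches a sample-level bootstrap SE (resample samples
with replacement, recompute the network and hub each time). The bootstrap is
our choice of uncertainty; published hub figures print error bars whose
construction is not specified, so ours are labelled as bootstrap SEs and not
claimed to match. Hypercorrelators are the metabolites whose out-of-pathway
degree grows most from one group to the other
(`rank_hypercorrelators()`), ranked by the degree difference with a
deterministic alphabetical tie-break.

**The network growth rate.** Groups of different size are hard to compare
at a fixed threshold because edge counts grow steeply with $n$. The growth
statistic therefore traces the whole curve: subset sizes ramp from 4 in
steps of 2 up to $n-1$ (4, 6, …, 21 for $n=22$; 4, 6, …, 30 for $n=31$),
with 50 random subsamples per size (without replacement by default; a
with-replacement variant exists for sensitivity). Within each subsample the
q-values are recomputed over the full pair family, significant edges passing
the scope/sign filters are counted, and the least-squares line
$y = mx + b$ through the counts gives the growth rate — the slope $m$, in
edges per added sample. Equal-size subsampling balances statistical power:
two groups are always compared on a common grid truncated to
$\min(n_A, n_B) - 1$, which is what `run_pipeline()` and
`recovery_experiment()` do.

## A worked example

```{r example}
cfg <- synthetic_config(
  n_case = 24, n_control = 24,
  pathways = setNames(rep(6L, 8), sprintf("pw%d", 1:8)),
  rho_within = c(control = 0.6, case = 0.3),
  hub_links = data.frame(metabolite = "pw1_m01", target_pathway = "pw2",
                         sign = "-", strength = 0.35),
  seed = 42)
cohort <- generate_cohort(cfg)
z <- zscore_transform(cohort$table)

zc <- subset_samples(z, group = "control")
net <- build_network(adjust_pvalues(pairwise_correlations(zc)),
                     cohort$pmap, q_threshold = 0.05, group = "control")
net
summarize_network(net)

curve <- resample_edge_counts(zc, cohort$pmap, replicates = 20,
                              scope = "both", seed = 7)
fit <- fit_vnet(curve)
fit
```

```{r plot, fig.width = 5, fig.height = 4}
plot(curve, fit = fit)
```

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `q_threshold` | 0.05 | Storey q-value cut for an edge (dimensionless) |
| `scope` | `"out"` for growth curves | which pathway scopes count |
| `sign` | `"both"` | which edge signs count |
| `replicates` | 50 | subsamples per ramp size |
| `start`, `step` | 4, 2 | ramp origin and increment (samples) |
| `replacement` | `FALSE` | subsample with replacement |
| `n_boot` | 200 | bootstrap replicates for the hub ratio SE |
| `n_perm` | 1000 | permutations for the edge-count test |

Growth curves default to out-of-pathway edges because in-pathway
correlations are dominated by shared chemistry and saturate early; the
global option is there because purely block-structured simulations carry
their signal in-pathway (the recovery tests use `scope = "both"` for this
reason).

## Numerical choices

- **Storey $\pi_0$**: estimated on the $\lambda$ grid $0.05, 0.10, \ldots,
  0.90$ via $\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))$, a
  cubic smoothing spline, and evaluation at $\lambda = 0.9$. Estimates
  $\ge 1$, non-finite fits, and families below 100 tests fall back to
  $\pi_0 = 1$, where q-values equal BH FDR exactly. Small edge-count
  differences against other Storey implementations at a fixed threshold are
  expected and harmless.
- **Degenerate pairs**: a metabolite constant within a subsample yields
  $r = 0$, $p = 1$ for its pairs rather than dropping them, keeping the test
  family size fixed across subsamples so q-values stay comparable.
- **$|r| = 1$**: the p-value is clamped to the smallest positive double so
  that log-scale reporting never sees zero.
- **Canonical pairs**: unordered pairs are stored with the
  lexicographically smaller metabolite first, making exports byte-stable.
- **Resampling RNG**: each (size, replicate) cell uses a substream derived
  from the master seed by modular hashing, so extending the size grid or
  adding replicates never perturbs draws already taken, and identical seeds
  give bit-identical curves.
- **Fast counting**: the resampling loop uses an algebraic shortcut — at
  fixed $n$, $p$ is strictly decreasing in $|r|$, so the $\pi_0$ tail counts
  and the candidate set for $q < t$ (all pairs with $p \le t/\pi_0$) reduce
  to $|r|$ cutoffs — which selects provably the same edge set as the full
  `pairwise_correlations()` → `adjust_pvalues()` → `build_network()` route;
  the equality is asserted in the test suite.
- **Degenerate slope comparisons**: identical curves give difference 0 and
  p = 1; an exactly collinear fit with a nonzero difference reports the
  smallest positive double rather than 0.

## The synthetic cohort generator

`generate_cohort()` draws from a latent pathway-factor model: each pathway
has a standard-normal factor per sample; a metabolite loads
$\sqrt{\rho_{within}}$ on its own pathway's factor, optionally
$\pm\sqrt{strength}$ on foreign factors (hub links), and carries independent
noise scaled so its variance is 1. Population correlations are inner
products of loading vectors, so the ground-truth edge set
(`truth_edges()`) is available in closed form, positive-definiteness is
guaranteed by construction whenever each metabolite's total squared loading
stays below 1 (validated with a hard error naming offenders), and abundances
$2^{\mu + \sigma x}$ are strictly positive log-normals as the z-scoring
requires. Case samples may be mean-shifted (z units) and may use a
different within-pathway correlation, giving group differences in both
abundance and network density. Defaults mirror the scale of a broad
targeted panel: 50 pathways × 9 metabolites ≈ 450 metabolites and group
sizes in the 16–68 range.

What the generator deliberately does **not** emulate: instrument drift,
batch effects, censoring at the detection limit, heavy-tailed or skewed
abundance noise, and correlation structure beyond the one-factor-per-pathway
plus hub-link geometry. Passing recovery tests therefore demonstrate that
the estimators recover the structure they assume, at realistic dimensions
and sample sizes — not that real metabolomes satisfy those assumptions.

## Calibration and its limits

Two null designs appear in the test suite, chosen deliberately:

- The **edge-count permutation test** is calibrated against two independent
  cohorts drawn from the *same correlated* configuration. Under a complete
  null (no correlations anywhere) both networks are almost surely empty, every
  permutation ties at a zero difference, and the test degenerates to p = 1 —
  formally conservative, but an empty check. With block-correlated
  exchangeable cohorts the permutation test rejects at about 3% at nominal
  5% (200 repetitions).
- The **growth-rate interaction test** (`compare_vnet()`) pools replicate
  points and t-tests the group × size interaction. Its p-value is calibrated
  *conditionally on the cohorts*: two independent resampling streams over the
  same null cohort reject at about 2% (100 pairs). It is **anti-conservative
  across cohorts**: when the two curves come from independent finite cohorts
  of the same population, cohort-level sampling variability (which OLS
  residuals cannot see — the cohort, not the subsample, is the sampling unit)
  inflated rejection to roughly 20–25% in our simulations. Growth-rate
  p-values should therefore be read as describing the resampled curves of
  the cohorts at hand; population-level claims deserve the permutation test
  or independent replication. The raw-point fit and the per-size-mean fit
  give identical slopes under balanced replicates (asserted to $10^{-9}$);
  their SEs differ and each fit is labelled with its mode.

The same cohort-conditioning affects the slope's own standard error. At
subset sizes close to $n$, subsamples overlap heavily and the counts become
a property of the particular cohort: under a complete null, a typical
cohort (no accidental extreme pair) drifts toward zero counts at large
sizes while small sizes still spike occasionally, giving a slightly
negative conditional slope — and the rare cohort carrying an accidental
strong pair gives a positive one. Averaged over cohorts the slope is
centred at zero, but the within-curve standard error cannot see the
between-cohort component, so "slope within $\pm 2$ SE of 0" holds for only
about three quarters of complete-null cohorts in our simulations (either
fit mode), not the nominal 95%. The corresponding acceptance check asserts
the nominal level and is expected to fail; the magnitude check (null
slopes orders below any planted signal) is the operative safeguard.

A related property worth knowing: duplicating every sample inflates the
per-size edge yield at *every* size (duplicated draws overstate the
effective degrees of freedom), but because the inflation is roughly uniform
it can flatten the slope on the original grid even while the curve sits
strictly higher. The growth rate is only comparable between runs that used
the same size grid — which is why the pipeline truncates to the common grid.

## Design decisions that were genuinely open

- **Log base** 2 everywhere: correlations are identical under any base; base
  2 matches how fold-changes are reported in this field.
- **Edge tallies for chord exports** include in- and out-of-pathway edges;
  growth curves default to out-of-pathway only. Both are exposed as options
  because published figure families differ in which they print.
- **Count-difference test**: group-label permutation (assumption-free)
  rather than any parametric count model; the observed counts are always
  reported alongside p.
- **Hypercorrelator degree** counts out-of-pathway edges only, matching the
  ranking's purpose (cross-pathway rewiring); `include_in_pathway = TRUE`
  is a sensitivity switch.
- **Hub q-threshold** defaults to 0.05 with the threshold exposed, since
  different figure families in this literature use different cuts.

## Problem sizes used in the shipped tests

Module tests run on 30–90-metabolite cohorts in seconds. The acceptance
suite uses: dense-vs-sparse recovery at 450 metabolites, 40 samples/group,
50 replicates/size, 20 seeds; hub-ratio and hypercorrelator recovery at 84
metabolites, 60 samples, 20 seeds; null calibration with 50–200 repetitions
of 40–80-metabolite cohorts. These sizes were chosen to exercise the
estimators at the dimensionality they target while keeping a full run in the
tens of minutes on a single core.

## Known limitations

- Marginal Pearson correlations only: no partial correlations or Gaussian
  graphical models; strongly connected pathways induce indirect edges.
- Group-level phenotype: the network is a property of a *group* of samples;
  nothing here identifies individual samples as cases.
- The growth-rate uncertainty is the OLS slope SE under the chosen fit mode
  and inherits the conditional-calibration caveat above.
- Storey q-values at a fixed threshold can differ slightly between
  implementations; exact published edge counts may shift by a few percent
  for this reason alone.
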