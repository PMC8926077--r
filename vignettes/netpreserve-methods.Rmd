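---
title: "Differential module preservation: models, parameters, and design choices"
author: "netpreserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential module preservation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, why the
defaults are what they are, and what the test suite does and does not
demonstrate about real data.

# The pipeline and its model

`netpreserve` compares how gene coexpression modules detected in one
*reference* condition are preserved in two *test* conditions, and scores the
difference. All stages operate on log2-scale expression matrices (genes ×
samples) wrapped in an `ExpressionDataset` (a `SummarizedExperiment`
subclass carrying `condition`, `batch`, `age`, `sex` per sample).

## Signed networks

Per condition, the network is the signed adjacency
$a_{ij} = ((1 + r_{ij})/2)^\beta$ on Pearson correlations $r_{ij}$.
"Signed" matters: raising raw correlations to an even power would identify
$r = -1$ with $r = 1$; the signed transform maps perfect anticorrelation to
adjacency 0. $\beta$ (a positive integer, default grid 1..20) is the soft
threshold: larger powers suppress weak correlations and push the
connectivity distribution toward scale-free topology.

The scale-free fit of a network is computed from the connectivities
$k_i = \sum_{j \ne i} a_{ij}$: 10 equal-width bins over the range of $k$,
empty bins dropped, and an ordinary regression of $\log_{10}$ bin frequency
on $\log_{10}$ mean bin connectivity. The reported index is $R^2$ signed by
$-\mathrm{sign}(\text{slope})$, so only a *decreasing* frequency–connectivity
relationship counts as a fit. `selectSoftThreshold()` picks the smallest
power in the grid whose fit reaches the target (default 0.90); if none
reaches it, the power with maximal fit is returned and the scan is flagged.
The bin count (10) and equal-width binning are conventions; the data do not
dictate them, and moderate changes move the fit by a few percent.

## Module detection

Clustering runs on the topological-overlap dissimilarity $1 - TOM$ with
$$TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}},$$
under average-linkage hierarchical clustering (direct $1 - a$ is available
behind an option). Modules come from a *static-height* variant of dynamic
tree cut: the dendrogram is cut at a quantile of its merge heights, and
every branch with at least `minModuleSize` (default 30) leaves becomes a
module; everything else is `grey` (unassigned). Modules are named by
descending size along the conventional colour sequence (turquoise, blue,
brown, ...).

**Cut quantile.** The default is 0.6. The cut must fall above the dense
within-module merge regime (so modules are fully formed) but below the
chaining regime where unassigned background genes attach one by one; in
average-linkage trees of module-structured data those regimes occupy
roughly the lower and upper parts of the merge-height distribution. We
calibrated the default once against three structural contracts of the
generator: noiseless planted blocks must be recovered exactly (this holds at
any quantile — their internal merges sit at height ~0), pure-noise data must
come out ≥95% grey (holds for quantiles up to ~0.9), and weak planted
modules (loading 0.6, noise 0.8, 100 samples) must be recovered with
adjusted Rand index above 0.8 (holds in a band around 0.6; median ARI 0.98
over seeds at 0.6). Very high quantiles (0.95+) fail all of these: the top
merges are background attachments, so cutting there produces one giant
cluster. A single static height remains a compromise — with a tight small
block in a sea of noise, background genes can chain onto the block before
the default cut; the hybrid branch-analysis variant of dynamic tree cut
avoids this but is deliberately out of scope (it is not oracle-testable in
the same way). The quantile is exposed in `cutTreeDynamic()` and
`pipelineConfig()`.

Eigengenes are unit-norm first right singular vectors of the
row-standardized module submatrix, oriented so their correlation with the
module's mean profile is non-negative; `propVarExplained` is the share of
the first squared singular value. kME is the gene–eigengene correlation
with a t-distribution p-value ($n-2$ df); kIM is the within-module
adjacency sum; hubs are the top 10 members by kIM among those with
own-module kME p < 0.05. `datasetModuleCorrelation()` is the QC guard
against batch-driven modules (eigengene vs one-vs-rest dataset indicator,
Benjamini–Hochberg across the table).

## Preservation statistics

For a reference module evaluated in a test network, three density
statistics (mean off-diagonal test adjacency; variance explained by the
module's test eigengene; mean sign-aware kME,
$\overline{\mathrm{sign}(kME^{ref})\,kME^{test}}$) and three connectivity
statistics (correlation of reference vs test kIM over module genes;
correlation of reference vs test kME over *all* genes; correlation of the
vectorized within-module correlation matrices) are each standardized
against a permutation null: every permutation draws a uniform random gene
set of the module's size from the shared universe and recomputes the
statistic with that set playing the module's role in both networks
(500 permutations by default; the add-one estimator
$(1 + \#\{perm \ge obs\})/(n_{perm}+1)$ keeps permutation p-values
positive). $Z_{density}$ and $Z_{connectivity}$ are the class medians,
$Z_{summary}$ their mean, and $Z_{summary} > 10$ is read as
well-preserved. A statistic whose permutation SD is zero is dropped from
its class median with a warning rather than yielding an infinite Z. The
statistic set is a deliberately minimal 3+3 selection with the standard
aggregation; rank-based summaries (e.g. medianRank) are out of scope, and
preservation is directional — swapping reference and test changes the
answer.

$Z_{summary}$ is a *significance* measure, not an effect size: its null is
formed inside each test network, so its magnitude depends on the universe
the permutations draw from. If a module occupies a large fraction of the
universe, the random sets are contaminated by the module itself; in the
extreme (a 100-gene module in a 300-gene universe) the null for the
connectivity statistics is itself strongly positive and a perfectly
preserved module can score $Z_{summary} < 10$, and ordering across
preserved/weakened/destroyed regimes can invert between networks of
different overall density. The calibration studies in the test suite
therefore plant target modules as a small fraction (~6%) of an 800–1000
gene universe with constant context modules — the regime real studies
operate in (tens of modules in ~20k genes).

Cross-tabulation against the test network's own partition reports gene
overlaps with upper-tail hypergeometric (Fisher exact) p-values evaluated
in log space (`phyper(..., log.p = TRUE)`), so overlaps whose p-value
underflows double precision (magnitudes like $10^{-310}$) still report a
finite $-\log_{10}p$.

## Differential preservation

$\Delta Z_{summary} = Z_{summary}(A) - Z_{summary}(B)$ per module, computed
on the same reference partition; positive is GOP (gain of preservation in A
relative to B), negative LOP, exactly zero "neutral" (a measure-zero event
left explicit rather than folded into either call). The table is
antisymmetric under swapping A and B by construction.

# Preprocessing choices

* **Normalization** is log2 plus per-sample median alignment (each sample
  shifted so its median equals the median of sample medians). Variance
  stabilizing transforms add machinery irrelevant to the correlation-based
  statistics under test here, and the synthetic generator produces
  log-scale data directly; with real intensity data a dedicated VSN step
  would be a reasonable upstream replacement.
* **Batch correction** is the parametric empirical-Bayes location/scale
  model: per-gene standardization against pooled moments, per-batch per-gene
  moment estimates of location $\gamma$ and scale $\delta^2$, shrinkage
  toward batch-level priors (normal on $\gamma$, inverse-gamma on $\delta^2$
  fitted by method of moments) with the standard iterative posterior solve.
  It matches `sva::ComBat` (no covariate design) to ~1e-6 on test data; the
  test suite uses ComBat as an independent cross-check, never as the
  implementation. No condition labels are protected during correction:
  batches must not span conditions, and the pipeline driver refuses
  configurations where they do. Because of shrinkage the correction is not
  exactly idempotent — a second application moves values by well under a
  fifth of the first — and per-gene residual batch differences of order
  $\sigma\sqrt{2/n}$ are irreducible sampling noise, so recovery is
  assessed in aggregate across genes.
* **Covariate adjustment** is plain per-gene least squares on age and sex
  with the gene's grand mean retained; constant covariates are dropped with
  a warning, collinear designs are an error. No shrinkage across genes is
  applied (an intentionally simple, fully reproducible choice).
* **Outlier removal** standardizes each sample's mean correlation with all
  other samples and removes those below −2.5; an average-linkage sample
  dendrogram is returned for inspection. The rule is deterministic, but on
  *homogeneous* data the minimum standardized score dips below −2.5 for a
  substantial fraction of random datasets at modest sample sizes (the
  mean-correlation distribution is left-skewed), so expect an occasional
  false positive; the flagged sample is always the most extreme one, and
  removing a borderline-typical sample is harmless for the downstream
  correlation statistics.
* **Low-abundance filter**: genes with mean value strictly below the 5th
  percentile of gene means (linear interpolation between order statistics)
  are removed; ties with the threshold survive, so a constant matrix loses
  nothing and `percentile = 0` is the identity.
* The driver fixes the stage order: summarize → filter → normalize →
  batch-correct → covariate-adjust → outlier-removal, then intersects the
  per-condition gene universes before any network is built.

# The synthetic generator

Each planted module is a single-latent-factor block: member gene $g$ in
condition $c$ is $\lambda_c w_g f + \varepsilon$, with $f$ standard normal
per sample, $\varepsilon \sim N(0, \sigma^2)$, loading $\lambda_c \in
(0,1]$ and an optional per-gene multiplier profile $w_g$ (default uniform
1). The uniform default keeps the closed form for the expected
within-module correlation, $\lambda^2/(\lambda^2+\sigma^2)$, which the test
suite verifies by simulation. Regimes per test condition: *preserved*
(same loading), *weakened* (reduced loading), *split* (two independent
factors on the module's halves — emulating a module that falls apart into
separate modules), *destroyed* (loading 0). Gene-level baselines
($N(8,1)$, shared across conditions), batch effects (location shift plus
scale factor applied to the stochastic part around the baseline — exactly
the model the batch correction assumes), uniform ages, Bernoulli(0.5) sex,
and all noise derive from one master seed; identical seeds give
bitwise-identical studies.

Defaults $\lambda = 0.8$, $\sigma = 0.6$ give a within-module correlation
of 0.64 — a deliberately strong module, the regime in which the
preservation statistics are easiest to reason about. These are calibration
choices, not estimates of any particular dataset.

**What the generator does not emulate.** Probe-level artefacts,
heavy-tailed noise, correlated background genes, and — under the uniform
default — within-module hub structure: with $w_g \equiv 1$ every member
gene has the same expected connectivity, so (a) intramodular-connectivity
rankings are pure noise and the connectivity-preservation statistics carry
no within-module signal (density statistics then dominate $Z_{summary}$),
and (b) the connectivity distribution of a synthetic study is bimodal
(background hump + module hump) rather than scale-free — the automatic
soft-threshold scan on uniform synthetic data typically peaks near signed
$R^2 \approx 0.45$–$0.6$ and does not reach the 0.90 target that real
expression data reach. A non-uniform `loadingProfile` (e.g. a step or
gradient) plants genuine hubs and moves the spectrum toward scale-free;
the hub-recovery test uses exactly that. Passing tests on this generator
therefore demonstrates correctness of the statistics and their
calibration, not that synthetic data reproduce every topological property
of real coexpression networks.

# Numerical details

* Eigengene sign: oriented against the module's mean standardized profile;
  tie at exactly zero correlation is left as returned by the SVD.
* The static cut adds a $10^{-9}$ relative tolerance to the cut height so
  merges exactly at the quantile (noiseless blocks produce ties) stay below
  the cut.
* kME p-values clamp $1 - r^2$ at machine epsilon before the t transform;
  $|r| = 1$ maps to p = 0.
* Fisher/hypergeometric p-values are computed and stored as
  $-\log_{10} p$; they are never exponentiated internally.
* Zero-variance genes are a named error everywhere a correlation is taken
  (they cannot be standardized), and a batch with a single sample is an
  error (its scale effect is undefined).
* Sub-seeds for pipeline stages derive deterministically from the master
  seed (multiplicative hash mod $2^{31} - 19$), so per-stage randomness is
  reproducible yet decorrelated.

# Problem sizes used by the test suite

Simulation-backed checks run at deliberately modest sizes chosen for
stable statistics: universes of 300–1000 genes, 40–100 samples per
condition, 100–200 permutations for preservation (500 remains the analysis
default), 25 replicates for regime-monotonicity, 50 for hub recovery, and
pooled Z scores across three independent structureless studies (36 modules)
for null calibration. At these sizes the full suite completes in a few
minutes on one core.

# Known limitations

* The static-height tree cut is a simplification of the adaptive dynamic
  tree cut family; module boundaries on real, noisy dendrograms will
  differ from the hybrid variant, especially for small tight modules
  embedded in large backgrounds.
* $Z_{summary}$ magnitudes are not comparable across universes of very
  different size or density (see above); only within-analysis comparisons —
  which is all $\Delta Z_{summary}$ needs — are meaningful.
* Covariate adjustment is unshrunken least squares; with very few samples
  per condition, shrinkage-based adjustment would be more stable.
* The preservation statistic set is the minimal 3+3 core; separability
  statistics and rank-based aggregates are intentionally absent.
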