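---
title: "Seeded brain-region co-expression networks: models and design decisions"
author: "SeedCoNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seeded brain-region co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SeedCoNet)
```

# Scope

SeedCoNet quantifies how tightly an established disease-gene ("seed") set
clusters in region-restricted gene co-expression networks, and prioritizes
novel candidates by combining seeded-network evidence with gene-level GWAS
evidence and model-organism knockout phenotypes. This vignette is the
package's own account of the models it fits, the parameters that matter,
the decisions taken where the design was genuinely open, and what the
synthetic validation does and does not establish.

# From samples to region-level expression

The expected input is a probe-or-gene × sample matrix from a small number
of donor brains, each sample annotated at three nested levels of
granularity (high-level structure: cerebrum / cerebellum / brain stem;
mid-level structure; finest region label). Ingest is strict: every sample
must be annotated, the hierarchy must nest uniquely, and missing values
are rejected rather than imputed — with a handful of donors there is no
safe imputation model, and silent imputation would leak into every
downstream correlation.

`collapseProbes()` averages all probes mapping to a gene, per sample,
before any modeling. `pcaQC()` gives centered (unscaled) principal
components of the samples for batch/structure inspection; centering-only
is deliberate, since genes are already on a common log scale and scaling
would up-weight near-constant genes.

## The mixed model

Samples repeatedly measure both donors and regions, so a plain region
mean confounds donor effects with region effects. Per gene we fit

$$y_s = \mu + \beta_{\mathrm{region}(s)} + u_{\mathrm{brain}(s)} +
\varepsilon_s,\qquad u \sim N(0, \sigma_u^2),\ \varepsilon \sim N(0, \sigma^2)$$

by REML (lme4), and take the estimated region cell means
$\mu + \beta_r$ — the donor intercept marginalized out — as the gene ×
region matrix (`fitRegionExpression()`). The model is intentionally
minimal: a region fixed effect at the chosen granularity and a donor
random intercept, no region × donor interaction and no sample-level
covariates. With typically ≤ 6 donors, an interaction is barely
identifiable and would absorb exactly the signal the region profile is
meant to carry.

Two practical notes:

* **Balanced designs have a closed form.** If every donor contributes the
  same number of samples to every region, the GLS estimator of the region
  cell means equals the plain per-region mean for *any* values of
  $(\sigma_u^2, \sigma^2)$: the random-effect design is then orthogonal to
  the region design ($V x_r = \sigma^2 x_r + \sigma_u^2 k\,\mathbf{1}$,
  which stays in the span of the region indicators). The implementation
  detects this and uses the closed form; the equality against the
  per-gene lme4 fit is verified numerically in the test suite.
* **Degenerate fits fall back.** A gene whose mixed-model fit fails (for
  example, a region observed in a single sample in a pathological subset)
  falls back to per-region means, and the count of such genes is logged.

`perBrainRegionMeans()` provides the companion single-donor view (plain
group means; no mixed model is possible within one donor), which feeds the
per-donor consistency analysis.

# Networks, correlation ranks, and the MRC

`buildNetwork()` computes edge weights $w_{ij} = |r_{ij}|$, the absolute
Pearson correlation of two genes' region-level profiles across a stated
region subset (a whole structure, or the early-/late-stage cerebral
subsets). Absolute values are used because a strong negative
co-regulation is as informative as a positive one for
guilt-by-association; Pearson (not Spearman) is the declared choice
throughout. Genes with zero variance over a subset would propagate NaN;
their edges are set to 0 instead (with a warning) so that every ranking
remains total. A subset must contain at least 3 regions for a correlation
to be minimally defined.

Each non-seed gene is scored by its **summed absolute correlation** to
the seeds, and scores are rank-normalized: rank 1 is the largest sum and
`percentile = rank / (N + 1)`, which is exactly uniform on
$\{1..N\}/(N+1)$ over distinct scores. Ties receive average ranks, which
preserves the mean of the uniform scale. Two orientations of the same
percentile are kept explicitly, because the downstream consumers need
opposite conventions: `percentileTop` (small = strongly seed-correlated)
feeds the upper-tail normal quantile that defines the network Z-score,
while `cr = 1 − percentileTop` (large = strongly seed-correlated) is the
orientation used in the reference CR tables.

## Leave-one-out CRs for the seeds themselves

A seed gene cannot be ranked against a seed set containing itself. For
seed $g$, `seedCrLoo()` removes it, recomputes the summed correlation to
$S \setminus \{g\}$ for $g$ *and for every non-seed gene*, and ranks $g$
in that pooled list. The design decision here — ranking each seed against
the full non-seed reference pool, with sums recomputed against the
reduced seed set for everyone — is the simplest construction that makes a
seed's CR directly comparable with the non-seed CR distribution, and
makes CRs uniform under exchangeability (verified by simulation in the
test suite: mean CR ≈ 0.5, and pooled CRs pass a KS test against
uniformity when no module is planted). Alternative pool compositions
(e.g. seeds ranked only among themselves) would make the metric depend
strongly on the seed-set size and were rejected.

The **MRC** is the median of the seed CRs — a single robust number in
(0, 1) per network, 0.5 under the null, approaching 1 when the seed set
is tightly co-expressed. Being a median of ranks, it is invariant to any
monotone transformation of the underlying correlation scale, which is
what makes MRCs comparable between networks with different correlation
distributions (different region counts, different structures).

# Cross-network consistency

With few donors, rankings could be driven by one brain.
`perBrainSeedRanks()` rebuilds the network per donor (single-donor region
means, same region subset) and re-ranks all non-seed genes;
`kendallMatrix()` reports pairwise Kendall tau between donors. The tau-b
(tie-corrected) variant is used because summed-correlation ties, though
rare, are possible; with no ties tau-b equals plain tau.

`pairedCrTest()` compares the seed CR vectors of two networks (one CR per
seed per network) with a Wilcoxon signed-rank test, two-sided by default,
reporting both medians. The exact distribution is used for n ≤ 25 when no
zero differences or tied absolute differences occur; otherwise the normal
approximation with continuity correction. A one-sided `alternative` is
available, as for `wilcox.test`; which test and sidedness a given
analysis should report is a substantive choice, and the default is the
conservative two-sided paired test. On the packaged early/late reference
CR table this gives medians 0.615 / 0.733 with a two-sided signed-rank
p ≈ 0.19 (the one-sided rank-sum p on the same vectors is ≈ 0.052);
`scripts/acceptance.R` computes both medians and the signed-rank p.

# GWAS evidence and the combined score

Gene-level association starts from the best (minimum) SNP p-value in the
gene and the SNP count N (`bestSnpReduce()` if SNP-level input is given;
the SNP→gene assignment itself is taken from the input and never
re-derived). The correction

$$p_{\mathrm{gene}} = 1 - (1 - p_{\mathrm{best}})^{(N+1)/2}$$

treats $(N+1)/2$ as the effective number of independent tests. For SNPs
correlated through LD and recombination-hotspot structure this count is
deliberately generous, making the corrected p conservative; for fully
independent SNPs it would under-count (the exact Šidák exponent would be
N), so the null-calibration simulations (`simulateNullSnps`) draw SNP
z-scores with exchangeable within-gene correlation ρ = 0.8 — the regime
the formula is designed for — and verify type-I error at or below nominal.
The correction is the identity at N = 1 and monotone in both arguments,
so $p_{\mathrm{gene}} \ge p_{\mathrm{best}}$ always. It is implemented
with `expm1`/`log1p` so that genome-wide-significant p-values (1e-300) do
not underflow.

One-tailed Z-scores are used throughout ($z = \Phi^{-1}(1-p)$): the
pipeline combines strength of evidence, not direction of effect. The two
channels are merged by the equal-weight Stouffer sum
$z_c = (0.5 z_{\mathrm{gwas}} + 0.5 z_{\mathrm{net}})/\sqrt{0.5^2+0.5^2}
= (z_{\mathrm{gwas}} + z_{\mathrm{net}})/\sqrt 2$, which maps two
standard-normal inputs to a standard-normal output (KS-checked by
simulation). Equal weights are a declared choice, not an optimized one.

Candidates are then filtered to genes whose knockout phenotype set
intersects {DM, DA, OS, PA}, and BH-FDR is computed **within the filtered
set**: `bhFdr(p, m)` generalizes `p.adjust(..., "BH")` with an explicit
universe size so that a reported top slice of a larger screen can be
adjusted against the full screen size (the reference candidate table uses
m = 654, the size of its phenotype-filtered universe — back-calculation
from its printed q-values pins this down exactly: 1.34e-5 × 654 =
8.77e-3). Output rows are ordered by combined Z descending with
alphabetical tie-breaks, for reproducible tables. Seed genes are never
ranked as candidates.

# The synthetic generator

`simulateStudy()` emulates the statistical structure the analysis
assumes, not brain biology:

$$y_{gs} = \mu_g + \beta_{g,\mathrm{region}(s)}
 + \lambda_{g,\mathrm{struct}} F_{\mathrm{region}(s)}
 + u_{g,\mathrm{brain}(s)} + \varepsilon_{gs}$$

with per-gene region effects $\beta$ (SD `sigmaRegion` = 1), a single
standard-normal latent factor value per region shared by all loaded
genes, donor intercepts $u$ (SD `sigmaBrain` = 0.5) and residual noise
(SD `sigmaNoise` = 0.1, i.e. a tenth of the region-effect scale). Seed
and planted signal genes carry loading $\lambda$ equal to the configured
per-structure-subset value; all other genes load 0. One latent factor per
structure subset is the simplest mechanism that produces
structure-graded seed co-expression; it does not attempt realistic
region-region correlation structure, probe-level noise, or anatomy.

Default dimensions mirror a six-donor whole-brain atlas: 79 early-stage
and 37 late-stage cerebral regions (the Braak-stage split used for the
stage networks), 15 cerebellar and 25 brain-stem regions, 2 samples per
region per donor (≈ 3700 samples), 52 seed genes. Default loadings grade
the module by structure (late cerebral 0.60 > early 0.45 > brain stem
0.35 > cerebellum 0.25), matching the qualitative ordering the seeded
analysis is designed to detect. GWAS records are emitted gene-level
(upper-tail p of the simulated Z, `n_snps = 1`) so the hotspot correction
is the identity on synthetic data and planted effects pass through
undistorted. A configurable fraction (default 0.654) of non-seed genes
carries at least one AD-related phenotype code, always including the
signal genes. All randomness flows from the single `rngSeed`; the global
RNG state is saved and restored.

**What passing synthetic tests shows — and does not.** Parameter-recovery
results (a planted late-stage loading of 0.8 versus 0 in the cerebellum
produces an MRC gap > 0.2 in ≥ 95% of replicates; 10 planted signal genes
among 2000 are recovered with median precision@10 ≥ 0.6 at GWAS effect
3.0 and loading 0.6) demonstrate that the estimators read out their own
generative model at realistic dimensions. They do not certify performance
on real atlas data, where co-expression is not low-rank, noise is not
homoscedastic, and the seed set's module structure is not a single shared
factor.

# Numerical choices and test problem sizes

* Ties in any ranking: average ranks. Zero-variance genes: edges 0, never
  NaN. Percentiles for Z-conversion are strictly inside (0, 1) by
  construction of rank/(N+1).
* `pToZ` clamps p = 0 or 1 to machine-representable bounds with a
  warning rather than returning ±Inf.
* Write/read round trips preserve 12 significant digits (values are
  written with 15).
* The test suite and acceptance script keep simulations modest by
  configuration — e.g. 60–500 genes for property checks, 100 replicates
  at the default 500-gene/156-region scale for the MRC-gap check, 50
  replicates at 2000 genes for precision@10 — sizes chosen so the whole
  suite runs in a few minutes on one CPU while keeping Monte-Carlo error
  well below the asserted margins.
* Monte-Carlo assertions on error rates allow 3 binomial standard errors
  above the nominal level (at N = 1 the corrected p is exactly uniform,
  so a strict ≤ would fail half the time by noise).

# Known limitations

* The mixed model omits region × donor interactions and covariates; with
  few donors these are not identifiable, but real data may violate the
  additive structure.
* The hotspot correction's calibration depends on the LD regime; for
  genes with many truly independent SNPs it is anti-conservative by
  construction.
* GWAS and network evidence are combined as if independent; on real data
  both can reflect shared confounders (e.g. cell-type composition).
* Per-donor networks use plain region means, so donor-specific noise is
  not shrunk; Kendall concordance between donors should be read as a
  lower bound on ranking stability.
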