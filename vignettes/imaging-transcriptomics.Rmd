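---
title: "Linking meta-analytic brain maps to cortical gene expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking meta-analytic brain maps to cortical gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imagetx)
```

`imagetx` implements a complete imaging-transcriptomics chain: a
coordinate-based effect-size meta-analysis of resting-state functional
alterations, atlas-style preprocessing of multi-donor cortical expression,
sphere-sampled gene-wise spatial correlation with false-discovery-rate
control, a spatial-autocorrelation-preserving permutation test, and
downstream characterization of the associated genes. This vignette explains
the models, the parameters that matter, the synthetic-data design, and the
numerical and design choices that were genuinely open.

## 1. Coordinate-based meta-analysis

Published studies rarely share statistic images; they publish peak
coordinates with t (or convertible z/p) values and group sizes. The package
reconstructs a per-study effect-size map from those peaks and combines the
maps with a standard random-effects model. This is a transparent
Hedges-g/DerSimonian–Laird substitute for the seed-based d mapping software
used in practice; that software's multiple imputation of subject images is
deliberately **not** reproduced, so exact published z values are not
expected to be reproduced either — what is checkable, and what the tests
check, is the printed z↔p pairing, the threshold rules, the heterogeneity
bands, and the diagnostic logic.

**Effect conversion.** A two-sample t with group sizes $n_1, n_2$ gives
$d = t\sqrt{1/n_1 + 1/n_2}$, the small-sample correction
$J = 1 - 3/(4(n_1+n_2-2)-1)$, $g = Jd$, and sampling variance
$\mathrm{var}(g) = (n_1+n_2)/(n_1 n_2) + g^2/(2(n_1+n_2-2))$.

**Map reconstruction.** Each peak is spread with an isotropic Gaussian
kernel, FWHM 20 mm ($\sigma = \mathrm{FWHM}/2.3548$), the convention for
this style of analysis. At voxel $v$,
$g(v) = \sum_k w_k g_k / \max(\sum_k w_k, 1)$ — a weighted mean where
kernels overlap strongly, a taper to zero in unsupported tissue. Weights
below $e^{-9/2}$ (3σ) are truncated: bounded kernel support keeps the
variance interpolation stable. Voxels with no kernel support contribute
$g = 0$ with a large default variance (10× the median peak variance; 10×
the no-effect variance $(n_1+n_2)/(n_1n_2)$ for a peakless, null-result
study). Partially supported voxels blend the interpolated variance toward
that default in proportion to the missing kernel mass, so the taper region
cannot acquire spuriously tiny variances (a weighted variance
$\sum w_k \mathrm{var}_k / \max(\sum w_k, 1)$ alone would shrink toward
zero at the support edge and let near-zero effects dominate the pooled
estimate). Null-result studies enter as zero maps by default — the
alternative (dropping them) is a configuration choice, since source
meta-analyses do not state how they handled them.

**Combination.** Per voxel, with $w_i = 1/\mathrm{var}_i$:
$Q = \sum w_i (g_i - \bar g_w)^2$,
$\tau^2 = \max\!\big(0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w)\big)$,
random-effects weights $w_i^* = 1/(\mathrm{var}_i + \tau^2)$,
$\hat g = \sum w^* g / \sum w^*$, $z = \hat g \sqrt{\sum w^*}$, and
$I^2 = \max(0, 100 (Q - (k-1))/Q)$, clamped to $[0, 100]$. The p map is the
**one-sided** tail $1 - \Phi(|z|)$: published cluster tables pair z = 4.13
with 1.81×10⁻⁵ and z = 3.17 with 7.63×10⁻⁴, which match the one-sided
convention (to within the rounding of z to two decimals) and not the
two-sided one.

**Thresholding and diagnostics.** Suprathreshold voxels (one-sided
p < 0.005, positive and negative z treated separately) are grouped by
26-connectivity; clusters under 20 voxels are dropped. Per-cluster $I^2$
is labelled by the conventional 25/50/75 anchors, boundary values taking
the higher category (a mean $I^2$ of exactly 50 is "medium"); a 10⁻⁹ guard
absorbs the floating error of $100(Q-\mathrm{df})/Q$. The Egger test
regresses $g_i/SE_i$ on $1/SE_i$ at each cluster peak and t-tests the
intercept; it is reported unavailable (`NA`, not an error) with fewer than
3 studies or constant precisions. Excess significance compares the observed
number of individually significant studies with the sum of
normal-approximation powers to detect the pooled effect, via a one-sided
binomial test. Jackknife consistency is the fraction of leave-one-out
reruns in which a same-sign suprathreshold cluster overlaps each
full-analysis cluster by at least one voxel.

## 2. Expression preprocessing

The pipeline order is fixed and logged: intensity filter → RNA-seq-guided
probe selection → sample filter → normalization → differential-stability
filter.

- **Intensity filter** (`min_frac = 0.5`): a probe is kept when above
  background in at least half of all samples, pooled across donors. The
  boundary is inclusive ("at least 50 %"), and pooling (rather than
  requiring the criterion per donor) is the default reading of an ambiguous
  rule; both are tested behaviours.
- **Probe selection** (`min_r = 0.2`): per gene present in the RNA-seq
  reference, each probe is correlated with the reference across matched
  samples; probes with r < 0.2 are dropped and the highest-correlating
  survivor represents the gene. Spearman correlation is the default — the
  two platforms differ in scale, and rank correlation is the robust choice;
  Pearson is a switch. Fewer than 3 matched samples leaves correlations
  undefined: the probes are dropped with a warning rather than an error.
- **Sample filter**: left-hemisphere cortical samples whose MNI coordinate
  falls in an in-mask voxel. Expression atlases have dense left-hemisphere
  coverage only, and cortical/subcortical expression differs enough that
  mixing them would dominate any spatial correlation.
- **Scaled robust sigmoid**: for a vector $x$,
  $s(x_i) = 1/(1+\exp(-(x_i - \mathrm{median}(x))/(\mathrm{IQR}(x)/1.35)))$,
  min–max rescaled to $[0,1]$; applied across genes within each sample,
  then across samples within each gene, **separately per donor** (the step
  exists to remove donor-specific offset and scale effects; a global mode
  is available). Quartiles use linear interpolation (type 7) — median-
  unbiased variants differ at n ≤ 4 — and 1.35 converts the IQR to a
  normal-σ estimate. A zero-IQR vector maps to 0.5 with a warning. The
  transform is monotone and affine-invariant, so ranks survive and one
  extreme outlier cannot compress the rest of the scale.
- **Differential stability** (`top_frac_ds = 0.5`): per gene, expression is
  averaged per region label within each donor, and DS is the mean over
  donor pairs of the Spearman correlation between regional profiles over
  shared regions (pairs sharing < 3 regions are skipped). Region labels,
  not raw samples, are the cross-donor matching unit — donors do not share
  sample locations. Genes are ranked by DS descending with ties broken by
  gene identifier, and the top `ceiling(0.5·G)` kept; 0.4/0.5/0.6 give
  nested subsets by construction.

## 3. Spatial association

The meta-analytic z map is averaged over in-mask voxels whose centres lie
within 3 mm (inclusive — with 2–3 mm voxels a centre exactly at the radius
is a common case, and excluding it would make results depend on floating
noise) of each tissue sample's coordinate. A sample whose sphere contains
no in-mask voxel is dropped by default (samples were already restricted to
the mask, so empties indicate a sample that does not belong); snapping to
the nearest in-mask voxel is available by flag. Gene-wise Pearson
correlations across samples get two-sided p values from the t transform
with $n-2$ degrees of freedom; constant genes are reported with `NA` and
excluded from testing. Benjamini–Hochberg q values are computed over tested
genes and significance is declared at **q ≤ 0.05**: the step-up rule's own
threshold is $p_{(k)} \le k\alpha/m$, so the strict inequality sometimes
printed ("q < 0.05") would contradict the procedure it names.

## 4. The spatially constrained permutation test

Smooth maps correlate with smooth maps. Under spatial autocorrelation the
number of BH-significant genes is inflated far beyond the nominal level,
and a naive permutation (shuffling sample labels) destroys the
autocorrelation and understates the null — the test suite demonstrates the
upper tail of the surrogate null dominating the shuffle null on
autocorrelated synthetic data. The package therefore builds
variogram-matched surrogates:

1. randomly permute the observed values;
2. smooth the permutation over each point's k nearest neighbours with an
   exponentially decaying kernel $\exp(-d_{ij}/d_k(i))$ (self included),
   for each k in a candidate grid (default 5 %, 10 %, 20 % of n, floor 5);
3. regress the source variogram on the smoothed map's variogram over
   distance bins, $\hat\gamma_{src} \approx \alpha + \beta\,\gamma_{sm}$
   (ordinary least squares; the empirical variogram is
   $\gamma(h) = \tfrac12\,\mathrm{mean}\,(v_i - v_j)^2$ over pairs binned
   uniformly up to 25 % of the maximum pairwise distance, 25 bins);
4. form $\sqrt{\max(\beta,0)}\,\cdot\mathrm{smoothed} +
   \sqrt{\max(\alpha,0)}\,\cdot\varepsilon$ with standard normal
   $\varepsilon$ — the variogram of a sum of independent components is the
   weighted sum of variograms, with the white-noise term contributing the
   nugget $\alpha$; negative fitted coefficients are floored at zero before
   the square roots and the fit diagnostics are kept;
5. keep the k with the smallest fit SSE;
6. optionally replace the surrogate's values by the source values at
   matching ranks, preserving the value multiset exactly (the default).

The permutation test recomputes the BH-significant gene count with the
randomized side replaced by surrogates. Two modes exist: per-gene
surrogates (the default, mirroring the description of surrogating every
gene's expression map) and a single surrogate of the statistic map per
permutation — orders of magnitude cheaper and exchangeable in this design,
since only one side of each correlation needs randomizing. Both are tested;
the pipeline demonstration uses the map mode. The p value uses the add-one
estimator $(b+1)/(n_{perm}+1)$, under which the reported "none out of 5000
permutations" yields $1/5001 < 0.0002$ — reproducing the printed bound is a
direct consequence of the estimator choice, which is also the one that
never returns 0.

## 5. Characterization of the gene list

Fisher's exact test on the 2×2 overlap table per gene set, BH across sets.
The background universe defaults to the **tested** (DS-filtered) gene
universe, not the whole genome: the selection procedure operated on that
universe, so the null should too; an override exists. The reported odds
ratio is the sample ratio $ad/bc$ ($\infty$-flagged when $bc=0$ with
$ad>0$), not the conditional MLE, with the exact p from the hypergeometric
distribution. Interaction edges are kept at confidence **strictly** above
0.9 and restricted to the significant genes; hubs are the top
`ceiling(0.10 · n_connected)` nodes by degree (ties broken by identifier) —
the ceiling reproduces 689 → 69. Behavioral relevance reuses the sphere
extraction on term activation maps and summarizes each term as the mean
absolute per-gene correlation, |r|_mean: both signs indicate a gene
contributes, and the absolute value avoids offset cancellation. Terms with
|r|_mean > 0.2 are flagged; constant extractions are skipped with a
warning.

## 6. The synthetic-data module

The generators produce every pipeline input with known ground truth.

- **Brain grid**: a cubic or ellipsoidal mask on an isotropic grid centred
  on the MNI origin. The demonstration geometry is a 30³ grid at 3 mm
  (a ~90 mm domain): roughly six autocorrelation lengths across, like real
  left-cortex extent relative to the 15 mm expression autocorrelation. On a
  much smaller toy domain a single smooth mode dominates every field and
  spurious gene–map correlations of |r| ≈ 0.3–0.5 are routine — a regime in
  which no planted signal can cleanly beat the spatial null, and not one
  that resembles cortex.
- **Study peaks**: each study reports one peak per planted cluster with
  effect `pooled_effect + N(0, noise_sd)` on the g scale, stored as the t
  value that converts back exactly; group sizes default to the eight
  included studies' published counts (500 patients, 469 controls) when 8
  studies are requested.
- **Expression**: sample coordinates are drawn at in-mask voxel centres and
  split across donors. Background genes are Gaussian random fields with
  exponential covariance $\exp(-d/\lambda)$, $\lambda$ = 15 mm by default
  ("nearby regions have more similar expression"). A planted gene mixes the
  standardized sphere-sampled target map $t$ with an independent field $e$
  as $r\,\mathrm{std}(t) + \sqrt{1-r^2}\,\mathrm{std}(e)$, after
  residualizing $e$ against $t$: two smooth fields on a finite domain share
  chance correlation, and without the residualization the realized
  correlation scatters far beyond the Fisher-z band around the target.
  Each gene carries a **donor-stability weight** s — 1 for planted genes,
  uniform on (0.2, 1) for background genes — and a donor measures
  $\sqrt{s}\cdot\mathrm{shared} + \sqrt{1-s}\cdot\mathrm{donor~field}$.
  This is what gives differential stability something real to measure:
  genes whose expression tracks a disease map are donor-conserved by
  premise (that is the stated rationale for DS filtering), while background
  genes vary in conservation. Donor offset and scale jitter (removed by the
  per-donor normalization), per-probe noise, one below-background probe per
  planted gene, a gene-level RNA-seq reference with platform noise, region
  labels from a fixed spatial block partition shared across donors, and a
  configurable fraction of right-hemisphere/subcortical decoy samples
  complete the dataset.
- **Annotation assets**: gene sets drawn from the universe with one set
  enriched in a designated target list at a configured odds ratio (via
  membership odds), a simple random interaction graph with uniform
  confidence scores, and smooth term maps (separably Gaussian-smoothed
  white noise, 12 mm FWHM).

What the generator does **not** emulate: realistic cortical geometry and
folding, donor ontology structure, microarray batch artifacts, gene–gene
co-expression modules beyond what shared smoothness induces, and spatially
varying autocorrelation. Passing tests therefore show the chain's logic and
calibration under idealized spatial statistics, not performance on real
atlas data.

In the permutation-test demonstrations one third of genes is planted — the
share of genes the original analysis itself found significant — so the
synthetic observed count sits clearly above the spatial null, as the real
one did.

## 7. Numerical choices and degenerate inputs

- Coordinates are MNI mm throughout; voxel indices are 0-based; conversion
  only through the NIfTI affine. Inputs in Talairach space are out of
  scope and must be converted upstream.
- The empirical variogram accepts any n ≥ 2 (a two-point map has one pair);
  fitting surrogates requires n ≥ 10. Candidate neighbourhood sizes above
  n−1 are skipped with a warning; if none remain, an error.
- `fisher.test` p values are capped at 1 (the exact-sum occasionally
  overshoots by floating error); BH q values are capped at 1 by
  construction.
- Zero-IQR normalization vectors → 0.5 with a warning; constant genes →
  `NA` r, excluded from testing; constant term maps → skipped with a
  warning; empty cluster tables and empty edge lists are valid outputs.
- Determinism: every generator and the permutation machinery are pure
  functions of their seed; the pipeline derives stage seeds from
  `config$seed` by fixed offsets, and two runs with identical config hash
  identically (the timestamped log is excluded from the manifest).

## 8. Problem sizes in the tests

The suite exercises the chain at deliberately small scale: grids of 14³–30³
voxels, 100–300 tissue samples, 30–300 genes, 19–199 permutations in the
test suite, 50-surrogate ensembles for the variogram-match property, and
50-replicate calibration loops for the BH false-discovery property. These
sizes were chosen as the smallest at which the statistical properties under
test are stable; the functions themselves scale to atlas-sized inputs
(hundreds of samples, thousands of genes) with the map-surrogate mode
recommended for large permutation counts.

## 9. Known limitations

- The meta-analysis is a standard Hedges-g/DL pipeline, not a
  reimplementation of seed-based d mapping with permutation of subject
  images; published SDM z values will differ.
- Per-gene surrogate mode at full scale (thousands of genes × 5000
  permutations) is computationally heavy in pure R; the map-surrogate mode
  is the practical default at scale.
- Probe re-annotation, specificity-index computation, FWE/TFCE correction,
  meta-regression on moderators, and live queries to annotation services
  are out of scope; gene sets, edge lists and term maps enter as local
  files.
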