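---
title: "Methods: balance selection, dysbiosis stratification, and seed-based structural covariance inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: balance selection, dysbiosis stratification, and seed-based structural covariance inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutbraincov)
```

`gutbraincov` implements a two-arm analysis that links a compositional
gut-microbiome signature to grey-matter structural covariance networks:

1. **Microbiome arm.** A phylum-level abundance table is filtered
   (taxa with more than 20% zeros are discarded), zeros are imputed, and a
   forward search finds the *balance* — the log-ratio of geometric means of
   two disjoint taxon groups A and B — most predictive of body-mass index.
   The obese subgroup is then split at the median of this balance into
   gut-dysbiosis and no-dysbiosis strata, and cognitive/mood scores are
   compared between strata.
2. **Imaging arm.** Per-subject modulated grey-matter volumes (MNI space,
   2-mm grid) yield hypothalamic seed values (medial, MH, and lateral, LH,
   2-mm-radius spheres). A voxel-wise GLM with sequentially orthogonalized
   covariates tests the seed-by-group interaction — differences between
   strata in the covariance of seed grey matter with grey matter everywhere
   else — with TFCE enhancement and max-statistic permutation FWE control.

Because no per-sample study data are distributed, both arms ship with
synthetic generators that reproduce the statistical structure the analysis
assumes; every stage of the pipeline is exercised end to end on generated
cohorts.

## The balance statistic

For a strictly positive abundance row $x$ and disjoint taxon groups $A$,
$B$:

$$
B(x) = c \cdot \log \frac{\operatorname{gmean}(x_A)}{\operatorname{gmean}(x_B)},
\qquad c = \begin{cases}
\sqrt{\lvert A\rvert \lvert B\rvert / (\lvert A\rvert + \lvert B\rvert)} & \text{ilr convention}\\
1 & \text{default}
\end{cases}
$$

Positive values mean the A taxa are jointly more abundant. The statistic
involves only within-sample ratios, so counts, proportions, or arbitrarily
rescaled rows give identical values (closure invariance); the tests verify
this to 1e-12. The default is the natural log with $c = 1$, which matches
the plain log-ratio scale on which group means are usually reported; the
ilr coefficient is available by flag. Zeros are imputed with an additive
pseudocount of 0.5 counts (scaled by read depth for proportion tables) —
simple and deterministic, a documented divergence from Bayesian
multiplicative imputation.

## Forward balance selection

`select_first_pair()` scores every ordered taxon pair by the $R^2$ of an
OLS fit of the response on the pair's balance (plus optional covariates)
and orients the winner so the balance rises with the response.
`forward_select()` then repeatedly evaluates every remaining taxon on
either side and accepts the single best addition while it improves $R^2$
by at least `min_improvement` (default 1e-4 — unstated in the original
algorithm description; it prevents noise-driven drift) up to `max_size`
(default 8) taxa. All ties break lexicographically by taxon id, numerator
side first, so selection is fully deterministic.

`cross_validate_signature()` wraps the search in repeated k-fold
cross-validation (5 folds x 10 repeats by default — the published default
of the selbal algorithm, adopted because the study reports using
cross-validation without stating its design). Held-out MSE is recorded for
every signature size along each training-fold path; the reported size is
the smallest whose mean held-out MSE is within one standard error of the
minimum (the conservative 1-SE convention, chosen because the size rule
itself is unstated). The robustness table reports how often each taxon and
each complete balance was selected across the fold fits, mirroring the
selection-percentage displays used for this algorithm.

Two distinct recovery notions matter when validating on synthetic data:
membership of the planted taxa in the *full-data forward path* (recall of
the search itself) and membership in the *CV-truncated* final signature.
The 1-SE rule is deliberately conservative and often truncates below the
planted size under noise, so the recovery tests target the forward path;
the CV rule is tested separately for calibration-free properties
(determinism, frequency ranking).

## Stratification and group comparisons

`stratify_by_median()` computes the median balance over obese subjects
only; obese subjects strictly above it form the dysbiosis stratum. Values
exactly at the median go to the no-dysbiosis side (`ties = "lower"`), a
documented, configurable reading of a higher-versus-lower split. With
an even number of obese subjects this forces strata of equal size (28/29
at n = 57). `compare_groups()` is a pooled-variance t-test by default
(the variables compared were screened for variance homogeneity);
covariate adjustment (e.g. the age-controlled comparison) switches to an
ANCOVA whose group-coefficient t is reported.

## Synthetic microbiome cohorts

Baseline taxon intensities are independent log-normals, closed to
proportions — simple, and heavy-tailed like real phylum distributions.
Defaults (31 taxa, 104 subjects, 5000 multinomial reads per sample,
matching the study's scale) plant a 2-versus-3 balance whose numerator
phyla are dominant and denominator phyla rare. Two constraints shaped the
default parameters, fixed before the acceptance suite was frozen:

* the planted denominator phyla must survive the 20%-zeros prevalence
  filter at 5000 reads (as the study's signature phyla survived its own
  filter), which bounds how rare they can be; and
* each planted taxon should carry a comparable share of the balance
  variance (log-sd of denominator taxa 1.5 times that of numerator taxa
  for a 2-vs-3 split), so recovery is a property of the search rather than
  of one dominant taxon.

This yields a planted balance near 5.3 (natural-log units) with standard
deviation about 0.65. BMI is linear in the planted balance plus Gaussian
noise; the default slope is calibrated analytically (and
`balance_effect_for_r2()` empirically) so the balance-BMI correlation is
0.57, and the intercept places the cohort at 55% obesity prevalence
(BMI >= 30). Stroop-interference and PHQ-9 scores are linear in the
planted balance with realistic noise, so the dysbiosis strata differ by
moderate effect sizes. BMI is not truncated to a physiologic range; at
the default parameters implausible values are rare and harmless to the
linear analyses.

## Synthetic volume stacks

Each subject volume on the default 32 x 38 x 32 grid (2-mm voxels, mm
origin on a voxel center near mid-grid so the stated seed coordinates are
voxel centers) is

$$
v_i = T + \textstyle\sum_s z_{is} S_s + \sum_w \beta_{g_i w} z_{i,\mathrm{seed}(w)} M_w
  + \alpha_a \tilde a_i F_a + \alpha_s \tilde s_i F_s + \gamma u_i T + \varepsilon_i,
$$

with $T$ a smooth ellipsoidal GM template, $S_s$ the seed-sphere
indicators, $M_w$ spherical network masks with per-stratum covariance
slopes $\beta_{gw}$, $F$ fixed smooth confound fields, $u_i$ a latent
global-volume factor, and $\varepsilon_i$ Gaussian voxel noise smoothed by
a separable Gaussian kernel (sd = FWHM/2.3548 in voxel units, renormalized
at the edges; default 8 mm). Planted effects are added *after* smoothing:
the support of each planted network is then exactly its mask, which is
what makes "no signal outside the planted masks" a well-defined ground
truth for the localization tests. Only the noise field carries the
smoothing kernel, whose spatial correlation is what the cluster-level
inference must cope with.

Network couplings default to moderate values (slope differences 0.4-0.45
against a 0.1 baseline, 7-mm radii, per-voxel interaction t around 7).
Much larger couplings were found to make the planted regions a
non-negligible share of global grey-matter volume; the global-GMV
covariate then itself carries a group-dependent seed component, the
orthogonalized seed regressor inherits a group-dependent distortion, and
genuine interaction signal appears *outside* the declared masks — i.e.
the generator would no longer generate what it claims. The default
amplitudes keep that leakage far below detection (verified by null
calibration at full scale).

The generator does not emulate several features of real modulated GM
data: values are not bounded to [0, 1], tissue boundaries and
subject-specific anatomy are absent, noise is stationary, and confound
fields are smooth random fields rather than anatomically structured
patterns. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to real
anatomical variation.

## Structural covariance GLM

The design enters in the fixed order age, sex (0 = female), global GMV
(sum of modulated voxel values, reported in ml), the other hypothalamic
seed, and the seed of interest; `orthogonalize_design()` centers each
column and residualizes it on all previously entered columns (classical
Gram-Schmidt with a reorthogonalization pass; rank deficiency at any step
names the offending column). The GLM at each masked voxel regresses GM on
an intercept, the orthogonalized covariates, group indicators (reference:
non-obese), the seed, and seed-by-group terms. The interaction t maps are
the slope-difference contrasts (one signed map for two groups, pairwise
maps for three); per-group seed-slope maps are exposed as the within-group
covariance maps from the same fit. Seeds are bilateral by default (the
two hemisphere spheres averaged into one regressor — per-hemisphere mode
is available), sphere membership is voxel-center distance with inclusive
boundary (a 2-mm sphere on the 2-mm grid is the 7-voxel face
neighbourhood), and coordinates are snapped to the nearest voxel center
with a message when the snap exceeds half a voxel.

## TFCE and permutation inference

TFCE with the canonical VBM defaults E = 0.5, H = 2, 26-connectivity.
The integration step is `max(|t|)/100`. One numerical choice deserves
emphasis: within a permutation analysis the *observed* map's step is used
for **all** permuted maps. Per-map steps make the discretization bias of
the threshold sum depend on each map's maximum; when strong planted signal
inflates the observed maximum, observed null-region voxels would be
integrated on a coarser grid than the permuted maps and acquire a relative
bias. A single shared grid makes observed and permuted statistics exactly
comparable. The transform itself is implemented incrementally (voxels
sorted by height, union-find component tracking), is exact for the stated
threshold grid, and is verified against a naive per-threshold relabelling
oracle to 1e-6.

Inference uses the permutation distribution of the maximum TFCE statistic
(positive and negative tails separately, each at p < 0.05, matching
directional reporting conventions), with
$p_{\mathrm{FWE}}(v) = (1 + \#\{\max_b \ge \mathrm{TFCE}_{obs}(v)\})/(B+1)$.
The default scheme is Freedman-Lane: residuals under the reduced model
(all seed-by-group columns removed) are permuted and the full model refit;
simple group-label exchange is available as a fallback. For samples so
small that fewer distinct permutations exist than requested, all
permutations are enumerated with a warning. Small-volume correction
restricts the null maximum to an a-priori sphere (3-mm radius subcortical,
5-mm cortical by default) while reusing the exact permutation sequence,
so a sphere covering the whole mask reproduces whole-brain inference
identically. The desk-scale default is 500 permutations; 5000 (the
full-study convention) is a flag away.

**What "localization" means here.** TFCE integrates cluster extent over
all thresholds, so the support of a significant cluster legitimately
extends beyond the voxels carrying the underlying effect — immediately
adjacent voxels share the cluster's extent term, and at low thresholds a
noise blob can bridge into a planted cluster. The end-to-end tests
therefore require that every significant cluster *intersects* the planted
network it is attributed to (equivalently, that cluster peaks localize to
planted regions, which is how cluster tables are reported in practice),
rather than that no single significant voxel falls outside the mask — the
latter is not a property TFCE-based inference can be expected to have.

## Problem sizes in the test-suite

The packaged tests run the oracle comparisons at small grids (10-14
voxels per axis), the null calibration at 200 datasets of a 16^3 grid
with n = 40 and 500 permutations, and the end-to-end pipeline at the full
default scale (n = 104, 32 x 38 x 32, 500 permutations, both seed models)
across 10 generator seeds. These sizes were chosen as the smallest at
which each property is a meaningful test of the corresponding claim.

## Known limitations

* The binary-response (AUC) variant of balance selection is out of scope;
  the association criterion is OLS $R^2$ only.
* The permutation engine assumes a shared design across voxels (no
  voxel-wise missingness); a singular design raises an error rather than
  per-voxel exclusion.
* Freedman-Lane exchangeability is approximate under group-dependent
  residual variance; the planted generators are homoscedastic, and the
  null calibration verifies the attained level under that model only.
* NIfTI I/O assumes one shared affine across subjects and does not
  resample mismatched grids.
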