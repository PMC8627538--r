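---
title: "Quantifying intra-patient lesion heterogeneity in PET radiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra-patient lesion heterogeneity in PET radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiohet)
```

## The problem

In recurrent metastatic prostate cancer, patients routinely carry several
choline-PET-avid lesions at once — regional lymph nodes, distant nodes, and
bone deposits. Clinical practice classifies such patients as
*oligometastatic* (limited burden, candidates for focal therapy) or
*plurimetastatic* using a simple lesion count, with 3 and 5 the two
thresholds in common use. The count says nothing about whether a patient's
lesions are biologically alike. `radiohet` asks that question
quantitatively: it describes every lesion by a radiomic feature vector and
then measures, per patient, how tightly the patient's lesions cluster
relative to everybody else's lesions.

## The statistic

Each lesion VOI is summarized by 42 features (shape, first-order intensity
statistics, and the GLCM, GLRLM, NGLDM and GLZLM texture families, following
the LIFEx family structure). Features are z-scored over all lesions —
optionally followed by PCA — and lesion cohesion is measured with the
silhouette index using patients as groups: for lesion $i$ of patient $P$
with $|P|\ge 2$,

$$ s(i) = \frac{b(i) - a(i)}{\max\{a(i), b(i)\}}, $$

where $a(i)$ is the mean Euclidean distance from $i$ to the other lesions of
$P$ and $b(i)$ is the smallest mean distance from $i$ to the lesions of any
other patient. $s$ lies in $[-1, 1]$; values near 1 mean a patient's lesions
look alike, negative values mean lesions sit closer to other patients'
lesions than to their siblings — high intra-patient heterogeneity. Patients
with a single lesion are assigned the value 0 and *excluded* from every
cohort average and every group test (the single-lesion convention; they
carry no within-patient information).

The analysis is repeated under three slicings, each independently
re-embedded because each restriction is its own analysis:

* **patient-based** — all lesions, patients as groups;
* **anatomy-based** — restricted to one site class (regional node, distant
  node, bone);
* **metabolism-based** — restricted to one SUVmax tertile; boundaries are
  the inclusive empirical 1/3 and 2/3 quantiles of lesion SUVmax over the
  whole cohort, with boundary ties going to the lower tertile (deterministic
  and order-independent; an all-equal cohort falls wholly in tertile 1).

Restricted slicings are compared to the patient-based result with a paired
t-test on per-patient means (pairing key: patient id, non-excluded in both).
Degenerate cases follow fixed conventions: all-zero paired differences give
$t = 0, p = 1$; constant non-zero differences are flagged and reported as
`NaN` rather than an infinite statistic.

Burden is classified under both oligometastatic definitions. Because the
literature is genuinely ambiguous between "up to three" and "< 3", both an
inclusive (`n <= 3`, the default) and an exclusive (`n < 3`) boundary mode
are implemented rather than resolving the discrepancy silently.

Marginal feature screening uses the two-tailed Mann–Whitney test per
feature, at the screening conventions $\alpha = 0.01$ for the Gleason split
and $\alpha = 0.001$ for all other categories; PSA is analysed apart at
$\alpha = 0.05$, also by rank tests since PSA is heavily right-skewed. No
multiple-testing correction is applied by default (a Benjamini–Hochberg
column is available behind a flag). Per-patient silhouettes are compared
across clinical splits with the tie-corrected Kruskal–Wallis test.
Unsupervised k-means clustering (Ward linkage behind a flag) with the
number of clusters chosen by maximal mean silhouette closes the pipeline;
"best interpretable choice" is operationalized as that argmax, which is an
interpretation, not a claim about how any particular study chose its
cluster count.

## What the synthetic generator emulates

Real multi-lesion PET cohorts with segmented VOIs are rarely shareable, so
the generator is a first-class module, not a test fixture. Each patient
draws a latent *phenotype archetype* (a point in feature space, dispersion
`sigma_between` per axis); each lesion is the archetype mean plus an
additive site-class shift (`site_effect_scale`) plus spherical Gaussian
within-patient noise (`sigma_within`). The single ratio
`sigma_within / sigma_between` therefore controls intra-patient cohesion
monotonically, which is exactly the quantity the silhouette analysis
estimates — the simplest model for which the analysis is well-posed.

Design choices worth knowing:

* **Defaults emulate a realistic cohort shape**: 92 patients, site
  probabilities 68/81/221 over regional node / distant node / bone, a
  lesion-count law mixing ~37% single-lesion patients with a plurimetastatic
  tail (~4 lesions/patient on average), per-site lognormal SUVmax laws with
  bone slightly hotter than nodes, lognormal PSA rising with burden, and
  ~36% of patients on ADT. These defaults are for realism; none of them is
  used as a test oracle.
* **Archetype sharing**: with `n_archetypes >= n_patients` every patient
  gets its own phenotype (well-separated world); with fewer archetypes
  patients share phenotypes, which is what produces the negative cohort
  silhouettes seen in real cohorts ("overlap of lesions belonging to
  different patients"). The parameter-recovery checks use the distinct
  regime for the monotonicity grid (a shared-archetype cohort cannot exceed
  $s \approx 0$ even at tiny within-patient noise, because co-archetype
  patients coincide) and the shared regime for the negative-index
  condition.
* **Burden-dependent dispersion** (`within_count_slope`) grows
  within-patient dispersion with lesion count but *saturates above four
  lesions* (`1 + slope * min(n - 1, 3)`). The saturation is deliberate: it
  concentrates the burden contrast at low counts, so a 3-lesion threshold
  separates heterogeneity groups sharply while a 5-lesion threshold mixes
  plateau patients into the low-burden group and attenuates the contrast —
  the qualitative pattern the burden comparison is designed to detect.
* **Metabolic coupling** (`suv_coupling`) ties SUVmax to a patient-level
  latent metabolic trait, so a patient's lesions land in the same SUVmax
  tertile together. Under this coupling, tertile-restricted analyses face
  fewer, metabolically comparable competitor patients and intra-patient
  similarity rises — the mechanism behind "metabolically homogeneous
  slicings look less heterogeneous". Coupling SUV to a feature-space
  coordinate instead would keep each patient's nearest confusable
  neighbours inside the same tertile and produce the opposite direction;
  this is why the trait is patient-level and feature-independent.
* **Volumes**: when image-level testing is wanted, lesions are rendered as
  ellipsoidal VOIs filled with a correlated Gaussian random field (white
  noise smoothed at a controllable correlation length, rescaled, clipped at
  zero) — two knobs (variance, correlation length) that move every texture
  family. The generator does not attempt whole-body scans, scanner physics,
  attenuation, or PSA kinetics; SUVmax from the feature-mode law and from
  rendered volumes agree in distributional shape only.

Passing tests on these cohorts show the *statistical machinery* is correct
and directionally faithful; they cannot show that any particular clinical
cohort has high or low heterogeneity, and none of the printed clinical
values from any study is used as an expected value anywhere in the suite.

## Numerical choices

* **Discretization**: relative min–max binning with 64 grey levels
  (`level = 1 + floor(n_bins (x - min)/(max - min))`, clamped at the top;
  constant VOIs map to level 1). Relative mode never produces empty bins on
  synthetic data; absolute SUV bounds are available where a fixed
  calibration is preferred.
* **Resampling**: 2 mm isotropic, trilinear for intensities,
  nearest-neighbour for masks (typical PET radiomics practice; the
  interpolator is validated against the closed-form trilinear value on ramp
  volumes).
* **Texture aggregation**: co-occurrences and runs are accumulated over all
  13 unique 3-D directions into a single matrix (not 13 per-direction
  feature sets averaged); the GLCM is symmetrized and normalized to sum 1.
  Kurtosis is non-excess. Zero-denominator conventions: GLCM correlation
  is 0 when a marginal variance vanishes, NGLDM busyness is 0 and
  coarseness is capped at 1e6 on constant VOIs, and `0 log 0 := 0`
  throughout.
* **Surface area for sphericity**: marching tetrahedra on the binary mask
  with per-configuration area weights calibrated against exact
  plane-cell intersection areas over randomly oriented digitized planes.
  This removes the staircase over-estimation that raw isosurface meshes
  suffer on binary data: flat faces are near-exact (a digitized cube's
  sphericity lands within ~2% of the closed form) and digitized balls land
  within ~1% of the true sphere area. Values may marginally exceed 1 on
  coarse grids; single-voxel masks fall back to the exposed voxel-face
  area.
* **Silhouette**: plain Euclidean distance in the z-scored (optionally
  PCA-projected) space — the standard choice absent other guidance; the
  implementation is checked to 1e-12 against a brute-force O(n²) oracle
  and against an independent library implementation.
* **k-means determinism**: 20 seeded restarts per candidate k; ties in the
  selection score resolve to the smaller k.

## Problem sizes used by the test suite

The suite runs entirely on synthetic data at deliberately modest sizes —
cohorts of 8–60 patients, VOIs of at most a few thousand voxels, 100-seed
repetition loops, and a 2000-replicate null simulation at 5 features for
the type-I-error check. These sizes were chosen so that every stochastic
check has comfortable statistical margin while the whole suite stays fast;
all of them are stated in the tests themselves.

## Known limitations

* The 42-feature roster follows the LIFEx family structure (2 shape + 9
  first-order + 6 GLCM + 11 GLRLM + 3 NGLDM + 11 GLZLM); any study's exact
  roster and preprocessing may differ, so the roster and discretization are
  configurable rather than hard-coded.
* Whether a cohort mean silhouette should average per lesion or per patient
  is a genuine convention choice; the package averages per patient (the
  per-lesion table is always available for the other convention).
* The univariate screen compares lesion rows labelled by their patient's
  group by default; patient-level median aggregation is available via
  `level = "patient"`.
* Synthetic feature vectors are Gaussian in feature space; real radiomic
  features are correlated, skewed and partly redundant. The generator's
  dispersion-ratio knob is faithful for rank-based and distance-based
  statistics, but absolute silhouette magnitudes on real cohorts will
  differ.

## A worked run

```{r}
cohort <- simulate_cohort(cohort_config(n_patients = 30, seed = 42))
fit <- lesion_similarity(cohort$feature_table)
fit
```

```{r}
burden <- classify_burden(cohort$cohort_table)
table(burden$class3way)
sp <- clinical_split(cohort$cohort_table, "BURDEN3")
silhouette_group_test(fit, sp)$p
```

```{r, fig.width = 6, fig.height = 4}
plot(fit)
```
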