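---
title: "Mapping pulvino-cortical functional topography with slab-seeded connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping pulvino-cortical functional topography with slab-seeded connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulvtopo)
```

## The scientific question

The pulvinar, the largest thalamic nucleus, is reciprocally connected with
most of the cortex, and its connections are believed to be topographically
organized: neighbouring parts of the nucleus talk to neighbouring parts of
the cortex. `pulvtopo` implements a resting-state fMRI analysis that makes
this topography measurable. The nucleus is subdivided into fixed-thickness
slabs along an anatomical axis (latero-medial, antero-posterior, or
ventro-dorsal); each slab's mean time series seeds a whole-cortex
correlation analysis; each cortical voxel is then assigned to the slab it
correlates with most (winner-take-all, WTA); and within individual sulci
the winning slab's position is regressed on the voxel's position along the
sulcus, yielding a gradient whose *polarity* is either direct (anterior
sulcus with anterior nucleus) or reversed (anterior sulcus with posterior
nucleus, as in the anterior cingulate).

Because real multi-subject macaque recordings are not redistributable, the
package ships a synthetic-cohort generator that plants a known topography,
so that every stage of the pipeline can be validated against ground truth.

## The model, stage by stage

**Slabs.** A seed-nucleus mask is cut into half-open bins of
`slab_thickness_mm` (default 2 mm) along the chosen axis, anchored at the
mask's own minimum world coordinate. All geometry is computed in world
millimetres through the NIfTI affine (RAS+), never in array-index space,
because the axes of interest are anatomical. The latero-medial axis is
hemisphere-aware: labels always run lateral to medial, so left- and
right-hemisphere maps are directly comparable. Boundary voxels are decided
by the half-open rule on the voxel-centre coordinate; this is a
convention, and an arbitrary one, but it is deterministic and
partition-preserving. Bins left empty by non-convex masks are compacted
out; slab centres keep their original world coordinates, so normalized
slab positions reflect true anatomical spacing.

**Preprocessing.** Each run is smoothed with a separable spatial Gaussian
(default FWHM 2 mm, `sd = fwhm / 2.355`, renormalized truncation at the
volume edges) and then each voxel's series is replaced by the residual of
an OLS regression on an intercept, a linear trend, and the six motion
regressors. Smoothing before nuisance removal mirrors the usual
acquisition-to-analysis order; because the nuisance projection is linear
and per-voxel, the order affects results only marginally. Rank-deficient
designs (e.g. motionless synthetic runs) drop the offending columns with
a warning rather than failing.

**Connectivity statistics.** For every slab and run, the slab's mean
series is correlated with every cortical voxel (seed voxels are excluded
from the target set to avoid self-correlation). Correlations are
variance-stabilized with Fisher's z and the per-run z values enter a
one-sample two-sided t-test across runs (df = runs − 1). A voxel-slab
pair is significant at `alpha` (default 0.001, uncorrected, matching
standard practice for this analysis). Two degenerate cases have explicit
conventions: identical nonzero z across runs is significant with p
recorded as 0, and identical zeros give t = 0, p = 1.

**Winner-take-all.** The default comparison statistic for the argmax is
the mean Fisher-z — the strength of connectivity itself — with the t-test
acting purely as the significance gate, and the gate applied to the
*winning* slab: the voxel is assigned to its globally best-correlated
slab if that slab is significant there, and left unassigned otherwise
(`winner_take_all(stat = "mean_z", gate = "winner")`). The alternative
semantics — argmax of the t statistic restricted to the slabs that are
individually significant — is available as `stat = "t"`,
`gate = "candidates"`. The distinction matters at small run counts: with
two runs the t statistic has one degree of freedom, so which slab
clears p < 0.001 is nearly uninformative (each *null* slab passes at
exactly rate alpha, while a strongly connected slab passes only when its
two z values happen to agree closely), and ranking by t lets
lucky-but-wrong slabs capture roughly a quarter of assigned voxels. Gating
the correlation argmax instead leaves assignment sparse but essentially
error-free, which is the behaviour a topography analysis needs. With many
runs the two semantics agree almost everywhere. Exact ties break toward
the smaller slab label, a measure-zero event on real data that the tests
exercise deliberately.

**Group consensus.** Per voxel, the normalized winning-slab positions are
averaged over the subjects in which the voxel is assigned, and the voxel
is retained only when at least half the subjects support it
(`support >= ceiling(n/2)`). Averaging positions rather than raw labels
keeps subjects with different slab counts commensurable.

**Consistency.** Between-subject agreement is the Spearman correlation of
winning-slab positions over voxels assigned in *both* maps (at least 10
jointly assigned voxels are required; fewer is reported as undefined, not
as a number). Axis-level comparison uses a Friedman test over blocks
(subject pair × hemisphere, df = 2 for three axes) with post-hoc paired
two-sided Wilcoxon signed-rank tests, Bonferroni-adjusted. Fully tied
blocks are the no-evidence case and return chi-squared 0, p = 1 by
convention (the textbook statistic is 0/0 there).

**Local gradients.** Each sulcus mask is parameterized to [0, 1] along
its declared anatomical axis. Assigned voxels inside the sulcus are
pooled across subjects as (sulcus position, winning-slab position)
points — pooling, rather than averaging per-subject slopes, because the
per-subject point counts are unbalanced and the pooled fit weighs
subjects by the evidence they contribute. The OLS slope's two-sided p
(equivalently the correlation t-test with n − 2 df) decides polarity at
0.05: direct for positive, reversed for negative slopes. An axis
explains a sulcus only if it is significant in *both* hemispheres with
agreeing slope signs; among qualifying axes the one with the larger
`min(|r_L|, |r_R|)` is selected. Non-monotone (dual-gradient) profiles,
as seen in the superior temporal sulcus, are flagged but not modelled:
each fit reports `nonmonotone = TRUE` when a two-segment piecewise line
improves the BIC over the single line (segments of at least 8 points,
split searched over the 30th-70th position percentiles); the linear fit
itself is still what polarity and axis selection use.

## What the synthetic cohort emulates

`cohort_config()` describes a two-hemisphere world on a 24³ grid at 1 mm:
an ellipsoidal nucleus per hemisphere (centre ±(6, −2, 0) mm, radii
(2.5, 5, 5) mm, hence five 2-mm slabs along the antero-posterior axis)
and two cortical bands per hemisphere — an IPS-like dorsal strip with a
*direct* antero-posterior mapping and an ACC-like ventral strip with a
*reversed* one — plus a neutral strip carrying no planted signal, which
keeps false-positive assignment observable. Nucleus voxels of slab *k*
and the cortical band segment assigned to slab *k* share a latent
unit-variance Gaussian AR(1) series scaled by `signal_sd`; every voxel
adds independent AR(1) noise (`noise_sd`, `ar1_phi`, default 0.3) and a
global leak of the first motion regressor (`motion_leak`), with motion
itself a smooth random walk. Band-segment boundaries are jittered per
subject (`subject_jitter_sd`, mm) to emulate inter-individual
variability. Everything is deterministic given `(rng_seed,
subject_index)`.

The default conditions — 4 subjects, 2 runs × 200 volumes at TR 2 s,
`signal_sd = noise_sd = 1` — are the desk-scale regime used throughout
the tests; consistency and calibration experiments use 6 runs × 100
volumes so the across-run test has honest degrees of freedom. These sizes
were chosen once, as the smallest regime in which every stage has
non-trivial behaviour.

What the generator does *not* model, and what passing tests therefore do
not show: haemodynamic response shapes, physiological noise, contrast-agent
(MION) polarity (correlation topology is sign-agnostic, so generic
positive latents suffice), realistic cortical folding, distance-dependent
spatial autocorrelation of noise, and registration error. Recovery rates
on this cohort demonstrate the *pipeline's* correctness, not the
detectability of gradients in any particular real acquisition.

## Numerical choices and degenerate inputs

- Correlations are clipped to ±(1 − 1e−12) before Fisher's z inside the
  pipeline, so noiseless synthetic data cannot produce infinities;
  `fisher_z()` itself refuses |r| ≥ 1.
- Zero-variance target voxels yield missing correlations and are never
  significant; a zero-variance *seed* series is an error.
- Slab binning adds 1e−9 mm before flooring so coordinates that are exact
  bin multiples up to float error land in the intended bin.
- A mask thinner than one slab yields a single slab whose normalized
  position is defined as 0.5.
- Grid agreement between any two volumes means equal dimensions and
  affines within 1e−4 mm per element; every cross-volume operation checks
  it.

## A worked example

```{r example, eval = FALSE}
cfg <- cohort_config(rng_seed = 500)
subjects <- lapply(1:4, function(i) generate_subject(cfg, i))
res <- analyze_cohort(subjects)
res
#> cohort_analysis: 4 subjects, axes LM/AP/VD
#>   planted-slab recovery: 100.0% of 166 assigned voxels
#>   IPS: axis AP, polarity direct
#>   ACC: axis AP, polarity reversed
res$gradients$ACC[res$gradients$ACC$pulvinar_axis == "AP", ]
#>   sulcus hemisphere pulvinar_axis     slope intercept          r            p
#> 2    ACC          L            AP -1.092624  1.045552 -0.9806880 2.973183e-29
#> 5    ACC          R            AP -1.174882  1.085452 -0.9773671 1.331128e-28
#>   n_points polarity
#> 2       41 reversed
#> 5       42 reversed
```

`generate_cohort()` writes the same cohort to disk (NIfTI runs, motion
tables, masks, ground-truth CSVs, YAML manifest) and `run_pipeline()`
consumes that layout end to end, writing WTA and consensus volumes,
consistency and gradient tables, and a machine-readable `results.json`.

## Known limitations

- Seeds are slabs, not single voxels; a per-voxel seed mode would
  reproduce the literal voxelwise procedure at a much higher cost and
  converges to the same WTA labels as noise vanishes.
- The consistency analysis requires enough jointly assigned voxels; under
  few-run, strict-alpha regimes the assignment is sparse by design and
  pairwise consistency may be undefined rather than estimated.
- Sulcus parameterization is linear along one world axis; strongly curved
  sulci would need a geodesic coordinate, which is out of scope.
- The Friedman comparison treats subject-pair × hemisphere blocks as
  exchangeable; pairs sharing a subject are not independent, which is a
  known property of this design and one reason the post-hoc tests are
  reported with conservative Bonferroni adjustment.
- The chi-squared approximation behind the Friedman test is mildly
  anti-conservative for three conditions (empirical type-I error near
  0.057 at nominal 0.05 for 12-30 blocks), an inherent property of the
  approximation rather than of this implementation.
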