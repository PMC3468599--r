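---
title: "Methods: gray-matter/memory correlation and lateralization-index curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gray-matter/memory correlation and lateralization-index curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbmli)
```

# The analysis model

`vbmli` analyzes spatially aligned, modulated gray-matter (GM) volumes:
maps in which each voxel's GM density has been scaled by the Jacobian of
its spatial normalization so that regional volume is preserved. The
pipeline deliberately begins *after* segmentation and registration — those
stages belong to dedicated neuroimaging tools — and treats the per-subject
volumes, a covariate table and a behavioral score table as its inputs.

## Voxelwise GLM

At every voxel inside the analysis mask we fit, by ordinary least squares,

$$ y_v = X\beta_v + \varepsilon_v $$

where the design $X$ holds an intercept, the behavioral score of interest,
and nuisance regressors (group indicator, age, intracranial volume, sex
indicator). The contrast of interest is the score coefficient, tested with

$$ t_v = \frac{c'\hat\beta_v}{\sqrt{\hat\sigma_v^2\, c'(X'X)^{-1}c}},
\qquad \mathrm{df} = N - \mathrm{rank}(X). $$

The default test is **one-sided** in the positive direction: the working
hypothesis of a volume–behavior correlation analysis is that poorer memory
goes with *less* gray matter, so only positive score slopes are of
interest. A two-sided option (`sided = 2`) exists. Assumptions are the
usual ones — independent subjects, voxelwise Gaussian residuals,
exchangeable error variance across subjects — and the smoothing step makes
the Gaussian approximation more defensible at the cost of resolution.

Voxels with exactly zero residual variance (possible in noise-free
simulations) get $t = \pm\infty$, are flagged, and are excluded from the
FDR ranking so undefined p-values cannot distort the step-up order; they
survive every threshold, which is the right degenerate limit.

## Thresholding and clusters

Voxel-level control is `uncorrected` ($p < \alpha$, default
$\alpha = 0.005$), `fdr` (Benjamini–Hochberg step-up over in-mask one-sided
p values), or `bonferroni` ($p < \alpha/m$). Bonferroni serves as the
family-wise-error control; it is conservative but assumption-free, and
cluster-level inference in this pipeline rests on the extent filter rather
than on random-field theory. Cluster extraction then takes connected
components of the surviving voxels — **18-connectivity** (faces + edges) by
default, the dominant neuroimaging convention, with 6 and 26 selectable —
and drops components below `k` voxels (default 50). Extent is counted on
the connected component *before* intersecting with atlas regions; region
breakdowns are reported afterwards. Peaks are the highest-t voxel, ties
broken by smallest linear index, so output is invariant to discovery
order.

Peak and extent coordinates can be converted from MNI to Talairach space
with the standard two-piece pose/scale correction (different z-scaling
above and below the axial origin); for simulated data, which lives in no
standard space, a passthrough mode reports native world mm.

## Lateralization-index curves

For a statistic map thresholded at $t$, with $T_\mathrm{left}(t)$ the mean
of the statistic over the left-ROI voxels strictly exceeding $t$ (defined
as 0 when no voxel survives),

$$ LI_{L-R}(t) = \frac{T_\mathrm{left}(t) - T_\mathrm{right}(t)}
                     {T_\mathrm{left}(t) + T_\mathrm{right}(t)} \in [-1, 1], $$

and the same construction compares the anterior vs posterior part of each
hippocampus ($LI_{A-P}$), split at a coronal plane (default world
$y = -20$ mm, the classical equal-volume hippocampal split). Because LI
depends strongly on $t$, it is evaluated on a ladder of twenty thresholds
and summarized by median, MAD, min and max.

Three details here were genuinely open design choices:

* **Ladder anchoring.** Thresholds are $t_i = (i/n)\,M$, $i = 0 \dots
  n-1$, with $M$ the maximum statistic over the ROI union. The top rung is
  excluded so the peak voxel always survives the last threshold and the
  curve has at least one defined value. Anchoring at the data maximum also
  makes every LI value invariant to positive rescaling of the map, a
  property the tests enforce.
* **Mean over survivors, not over all ROI voxels.** With zeros averaged
  in, $T$ would never be exactly 0 and the ±1 "one-sided detection"
  endpoints would be unreachable; the survivors-only mean reproduces the
  endpoint semantics exactly. Both this and the ladder are config-exposed.
* **MAD is unscaled** — median of absolute deviations from the median,
  with no 1.4826 normal-consistency factor. It is reported as a raw
  dispersion summary of the 20 curve values, not as a robust SD estimate.

Negative statistic values never contribute: the ladder starts at 0 and
only the hypothesized (positive) direction is thresholded.

## Behavioral statistics

The memory instrument is a cue-word test: 6 cues × 5 life periods (0–9 y,
10–29 y, 30–59 y, after 60 y, previous year), each elicited memory scored
0–5 for episodic specificity; period scores are sums over cues (0–30) and
the total is 0–150.

* **Group ANCOVA.** `ancova_group` fits `total ~ group + age` and tests
  the group term by model comparison (equivalent to a Type-III test, which
  matters because the groups are unbalanced). Error df = N − groups − 1;
  with 26 subjects in two groups this is 23.
* **Group × period.** `rm_anova_group_by_period` is a univariate
  split-plot ANOVA (period within subject, group between, no sphericity
  correction). The age covariate is **crossed with the within-subject
  factor**: the within-error df is then
  $(\text{periods}-1)(N - \text{groups} - 1) = 4 \times 23 = 92$ for 26
  subjects. This is the df structure classical repeated-measures ANCOVA
  software produces, and it is the reason the covariate cannot enter as a
  between-subject term only (that would leave 96 error df).
* **Fisher's LSD** post-hocs are plain pairwise t tests on the omnibus
  error mean square with no multiplicity adjustment — that is what LSD
  means. The pipeline computes inter-group comparisons per period from the
  pooled model's within-error term; per-group contrasts can be had by
  subsetting and re-running, but pooled is the default.

# The synthetic cohort generator

No public dataset accompanies this design, so the simulator is a
first-class module: every downstream stage is validated on cohorts with
*known planted structure*.

Each subject's volume is

$$ V_i = B + \sum_r s_r\,(x_i - \bar x)\,\mathbb{1}_r
       + a_r\,\mathbb{1}_r\,\mathbb{1}[\text{patient}] + \epsilon_i,
       \quad \epsilon_i \sim N(0, \sigma^2)\ \text{i.i.d., clipped at } 0 $$

where $B$ is a smooth radially symmetric "head" template (a superposition
of Gaussians — all geometry controlled, nothing downloaded), $s_r$ is the
planted slope of region $r$ in GM units per score point, $x_i$ the coupled
score (total or one period), and $a_r$ a group-level atrophy offset.
The ROI "atlas" is a pair of ellipsoidal hippocampi, mirror-symmetric
about the sagittal midline (centers ±14, −20, −6 mm; semi-axes 6, 10,
6 mm), each split into anterior/posterior halves at $y = -20$.

Default conditions mirror the study design the pipeline targets: 15
patients and 11 controls on a 32³ grid of 2 mm voxels; voxel noise SD 0.05
GM units; a left-hippocampal slope of 0.002 GM/point; atrophy −0.06 GM
units bilaterally in patients. Ages are drawn near 73 ± 6 (patients) and
69 ± 5 (controls), ICV near 1.4–1.5 L with a sex offset.

Behavioral scores are drawn per cue × period from a discretized normal
(rounded, clamped to 0–5) around per-group period means, plus a
subject-level shift that generates realistic between-subject spread of
totals. The default profile gives controls a flat-high curve with a
childhood dip and patients a graded profile (10–29 bump, then declining
into the most recent periods), with group totals centering near 120 and
70–85 — the qualitative pattern of elderly controls vs amnestic patients.
Because the subject shift correlates the five period scores within
subject, a slope planted on one period also leaks (attenuated) into the
others, exactly as collinear behavioral covariates would in real data.

What the generator does **not** emulate: cortical anatomy and
gyrification, partial-volume effects, registration error, spatially
correlated (rather than i.i.d.) noise, and site/scanner effects. Passing
tests on these cohorts therefore demonstrate correctness of the
statistical machinery and recoverability of planted effects under clean
assumptions — not robustness to real-data artifacts.

## Smoothing scale on the synthetic head

Smoothing uses a separable Gaussian kernel specified as FWHM in mm
(σ = FWHM/2√(2 ln 2) per axis, converted to voxels via the affine), with
zero-padded borders — borders sit outside the analysis mask in practice,
so no edge renormalization is applied. The real-data default is 12 mm,
the conventional VBM choice. The synthetic head, however, spans only
~64 mm: a 12 mm kernel there is proportionally twice as smooth as on a
real brain, which inflates null cluster extents. Analyses of the
simulated cohorts therefore use a 6 mm kernel, preserving the real
study's smoothness-to-field-of-view ratio; this is a property of the
phantom's scale, not a tuning knob.

# Numerical choices and degenerate inputs

* The analysis mask is `mean GM > 0.1` across subjects (strict), the
  usual absolute-masking rule for modulated GM; a threshold of 0 selects
  strictly positive voxels, and an empty mask is an explicit error.
* Design matrices are checked for full column rank; collinear columns are
  named in the error message.
* FWHM below half a voxel leaves that axis untouched (exact identity
  limit) rather than building a sub-voxel kernel.
* `li_curve` raises an explicit "no detection" error when the ROI-union
  maximum is not positive; in the pipeline this is caught and recorded as
  an absent curve — under a null simulation it is a data outcome, not a
  failure.
* An empty side of the anterior/posterior split is a warning (the LI then
  degenerates to ±1 by the detection semantics), not an error.
* Cluster and curve outputs are deterministic: sorted, with stated
  tie-breaks, independent of component discovery order.

# Problem sizes used by the test suite

The suite validates kernels on 5³–20³ grids against per-voxel regression
and graph-component oracles; calibration uses 200 null replicates × 2000
voxels (voxel level) and 1000 replicates of the 26-subject ANCOVA
(behavioral level); planted-effect recovery uses 100 seeded end-to-end
runs on 32³ cohorts of 26 subjects, plus a 100-subject cohort for slope
recovery. These sizes make the whole suite run in a few minutes on one
core while keeping Monte-Carlo error well inside the asserted tolerances.

# Known limitations

* Random-field-theory FWE and permutation inference are not implemented;
  Bonferroni is the only FWE control.
* The MNI→Talairach conversion is the standard piecewise-affine
  approximation; it is not exact for any individual brain.
* Brodmann-area labeling and real-atlas region naming are out of scope;
  the atlas interface accepts any set of NIfTI masks on the analysis grid.
* The repeated-measures model assumes sphericity (uncorrected df, by
  design, matching classical reporting); Greenhouse–Geisser correction is
  not offered.
* LI bootstrap confidence bands are not implemented.
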