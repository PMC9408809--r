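---
title: "Regional cardiac DTI biomarkers of chronic infarction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional cardiac DTI biomarkers of chronic infarction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cardti)
```

`cardti` analyses in vivo cardiac diffusion tensor imaging (cDTI) of
chronically infarcted left ventricles. The scientific question it serves
is which diffusion quantities best separate infarcted and border-zone
myocardium from remote (healthy) myocardium without contrast agents.
The package implements the full chain from raw inputs to regional
statistics, a seeded phantom generator that provides ground truth for
every stage, and a Monte-Carlo random-walk simulator that relates the
extracellular volume fraction (ECV) to the diffusion tensor quantities.

This vignette documents the models, the tunable parameters, the
numerical choices, and the limits of what the synthetic tests
demonstrate.

## Biomarkers

Per voxel, the diffusion tensor `D` (mm^2/s) is summarised by its sorted
eigenvalues `e1 >= e2 >= e3` and

* mean diffusivity `MD = (e1 + e2 + e3) / 3`,
* radial diffusivity `RD = (e2 + e3) / 2` — the average of the secondary
  and tertiary eigenvalues, i.e. diffusivity transverse to the myocyte
  long axis,
* fractional anisotropy
  `FA = sqrt(3/2) * ||(e1, e2, e3) - MD|| / ||(e1, e2, e3)||`
  (the standard Basser definition; defined as 0 for a zero tensor).

In chronic infarction the extracellular space expands mostly transverse
to the surviving myocyte direction, so `e2`, `e3`, and hence RD are
expected to rise more than `e1`; FA falls. The pipeline's end-to-end
test checks exactly this ordering.

## LGE segmentation (`estimate_region_stats`, `classify_voxels`)

Following the established signal-threshold scheme for late gadolinium
enhancement, remote-zone statistics (`mu_remote`, `sigma_remote`) and an
infarct-ROI mean (`mu_infarct`) are pooled across all slices of a
subject, defining

* `t_low  = mu_remote + 2 * sigma_remote`
* `t_high = (mu_remote + mu_infarct) / 2`

and the classification (within a supplied myocardium mask):
`SI <= t_low` remote, `t_low < SI < t_high` border, `SI >= t_high`
infarct. Where prose and displayed inequalities could disagree, the
displayed inequalities (`<=` for remote, `>=` for infarct, strict for
border) are authoritative here; they make the three classes a partition
of the myocardium. `sigma` uses the population formula (divisor `n`) by
default, configurable via `ddof`; the infarct SD is computed and stored
although the rule does not use it. Thresholds with `t_low >= t_high` are
flagged degenerate and refused by the classifier rather than silently
producing an empty border class.

ROIs are ordinary mask inputs; on the phantom they are drawn
automatically from the truth labels eroded by one voxel
(`phantom_rois`), emulating conservative manual ROIs.

## Registration of diastolic label maps onto systolic cDTI (`register_labels`)

LGE is acquired in diastole, motion-compensated cDTI in systole, at
different resolutions. The chain is:

1. **Rigid alignment** from the orientation quaternions stored in the
   two image headers (`q_fixed * q_moving^-1`) plus the translation
   aligning the world centroids of the foreground masks. Reading
   "quaternions computed from the images" as header metadata (not an
   intensity optimisation) is a design choice; the centroid translation
   is the mask-moment part.
2. **Longitudinal rescale**: slice z positions are mapped affinely so
   the most basal/apical label slices hit the corresponding cDTI
   slices; interior spacing scales uniformly. This encodes systolic
   longitudinal shortening.
3. **Myocardial contours** on each cDTI b = 0 slice by Canny edge
   detection (Gaussian sigma 1.4 voxels; hysteresis thresholds tied to
   the Otsu level of the gradient magnitude, low = 0.5x, high = 1.0x,
   all configurable). Edge pixels are grouped by 8-connectivity; the two
   largest groups are the endo- and epicardial contours. Contour points
   are refined to sub-pixel position by a parabolic fit of the gradient
   magnitude along the ray from the contour centroid — without this the
   half-voxel quantisation of edge pixels dominates the final label
   accuracy. Masks at intermediate z are distance-weighted averages of
   the neighbouring slice masks, thresholded at 0.5 (ties at exactly
   0.5 are included).
4. **Non-rigid registration**, slice-wise, of the label support onto the
   averaged cDTI mask by a symmetric demons scheme on the smoothed
   binary masks (default 200 iterations, update capped at 1 voxel/iter,
   field smoothing sigma 1.5 voxels). Masks rather than intensities
   drive the match because the task is shape transfer. The recovered
   field warps labels with nearest-neighbour sampling so the alphabet
   {0,1,2,3} is preserved; the warped-support Dice against the fixed
   mask is logged and warned about below a configurable floor (0.8).
5. **3D interpolation** onto the original cDTI slice positions:
   one-hot label indicators are interpolated linearly in z and the
   arg-max label taken, ties resolved toward the more severe label
   (infarct > border > remote > background). Positions outside the span
   use the nearest slice.

Finally labels are restricted to the detected cDTI myocardium and any
unlabeled myocardial pixels are filled from the modal neighbour label
(ties again severe). In-plane resampling of the diastolic labels onto
the cDTI grid uses the same one-hot/arg-max device, which keeps
sub-voxel boundary placement without inventing new label values.

The rigid reading assumes in-plane slice orientations (short-axis
stacks); oblique re-slicing is out of scope.

## Tensor reconstruction (`fit_tensor_loglinear`) and rejection filter

Plain ordinary least squares on the log signal:
`ln S(b, g) = ln S0 - b g' D g`, solved per voxel for `ln S0` and the six
tensor components. No weighting and no positivity constraint: negative
eigenvalues are reported as-is (a `clip_negative` flag exists). Voxels
with any nonpositive signal are marked invalid. Repeated b = 0 volumes
enter the fit as repeated rows, which is equivalent to magnitude
averaging for the noise-free case and close to it otherwise.

Voxels with `MD` above the free diffusivity of water
(3e-3 mm^2/s) are removed before statistics; the rejected fraction is
reported. "Above" is read strictly, with a 1e-9 relative guard so a
trace that sums to exactly three times the threshold is kept despite
floating-point round-off.

## ECV mapping (`compute_ecv`)

`ECV = (1 - Hct) * dR1_myo / dR1_blood`, `dR1 = 1/T1_post - 1/T1_pre`.
Blood T1 enters as a scalar pair (blood-pool ROI means). Voxels with
nonpositive myocardial `dR1` are set to 0 and flagged; ECV > 1 is
flagged but retained, never clipped — downstream statistics can exclude
flagged voxels explicitly.

## Regional statistics (`pool_by_region`, `kruskal_wallis_pairwise`, ...)

All myocardial voxels are pooled by registered region; each voxel
contributes to exactly one region, and MD-rejected or invalid voxels are
excluded. Normality is screened with the case-3 Anderson-Darling test
(mean and variance estimated, small-sample correction). Group
differences use the two-group tie-corrected Kruskal-Wallis H with a
chi-square(1) p-value per region pair, Bonferroni-multiplied by the
number of pairs (3) and capped at 1; significance is declared at
p < 0.01. Summaries report mean, median, and quartiles with the
linear-interpolation quantile convention (R type 7) — worth stating
because quartile conventions differ enough to move printed values.
Percent changes are computed between medians with sign preserved, so FA
changes come out negative.

## The phantom generator (`make_lv_phantom`)

The phantom provides ground truth for every stage: a 5-slice annular LV
(8 mm slices) with basal endo/epi radii 15/27 mm tapering 25% toward the
apex; an infarct sector (90 deg at mid-ventricle) with a 30 deg border
rim on each side, its angular extent shrinking sinusoidally to 55%
toward base and apex as territorial infarcts do — this axial structure
is also what makes the longitudinal-rescale ablation measurable; LGE on
a 1.33 x 1.33 mm grid with remote N(100, 10), infarct N(300, 20), and
border intensities drawn uniformly on the open interval between the two
classification thresholds (so ground truth is consistent with the
classifier by construction — the real border zone is a biological
mixture with no published distribution, and these intensity parameters
are placeholders, not estimates of any acquired data); systole modelled
as 10% wall thickening at fixed epicardium plus uniform longitudinal
scaling 0.75, applied analytically so registration error is computable
exactly; DWI on a 2 x 2 mm systolic grid at b = 0 and 350 s/mm^2 with
12 icosahedral directions, synthesized from per-region ground-truth
tensors whose eigenvalues default to the reported in vivo medians
(remote 1.94/1.38/1.06, border 2.14/1.65/1.24, infarct
2.28/1.83/1.42 x 1e-3 mm^2/s) with a circumferential primary
eigenvector swept by a +/-60 deg transmural helix; Rician noise at
S0 SNR 16. T1 maps are emulated directly on the systolic grid, with
post-contrast values solved so that the noise-free regional ECV equals
the reported medians (0.31/0.38/0.47) at Hct 0.30 — the in vivo ECV
registration reuses the same label-registration operations, so a second
registration pass is not separately modelled.

What the phantom does **not** emulate: papillary muscles, perfusion and
motion/eddy artifacts, B0/B1 inhomogeneity, partial-volume blood
signal, intensity inhomogeneity of LGE, or realistic border-zone
histology. Passing phantom tests therefore demonstrates correctness of
the operations and their composition under known geometry and noise —
not performance on acquired data.

## The random-walk simulator (`diffsim`)

Synthetic myocytes are impermeable cylinders (diameters uniform in
9–20 um, 100 um axial segments) chained into trees along z on a
jittered hexagonal cross-sectional lattice inside a periodic
0.5 mm cube. Each segment's axis is tilted by |N(0, 10 deg)| at a random
azimuth — cardiomyocytes show orientation dispersion of this order, and
the resulting axial tortuosity is what gives `e1` its ECV dependence.
Branches connect adjacent trees with probability 0.3 per pair per
100 um level (about 1.5 branches per adjacent pair across the cube),
reflecting that real cardiomyocytes are branched, multiply connected
cells; the published geometry description leaves branching unspecified,
so this density is a documented choice, and the sweep trends are
required (and tested) to hold rather than depend on its exact value.
The lattice spacing is solved iteratively until the Monte-Carlo-measured
ECV (2e5 point samples) is within +/-0.02 of target (+/-0.05 is the
acceptance band); cylinder overlap is permitted at high packing, where
overlapping cells simply merge.

Walkers (default 20000) start uniformly in the extracellular space and
take per-axis Gaussian steps of variance `2 D0 dt`
(`D0 = 3e-3 mm^2/s` extracellular, `2.2e-3` intracellular,
`dt = 10 us`, duration 51 ms = the in vivo diffusion-encoding time).
Steps that would cross a membrane are rejected and redrawn (up to 50
attempts, then the walker rests that step); a single-scatter specular
reflection is available as the `membrane = "reflect"` alternative, and a
fixed-length-step model as `step_model = "fixed"` — both satisfy the
same invariants. The cube is periodic; positions accumulate unwrapped
and membership tests wrap, with cylinders replicated across faces.
Intracellular walkers can be simulated but are always excluded from the
readout, matching the extracellular sensitivity of the low-b in vivo
acquisition.

Readout: net displacements are projected on the 12 icosahedral
directions; each gives an apparent diffusivity
`D_g = <(dx . g)^2> / (2 t)` (narrow-pulse Gaussian readout), and the
tensor is solved from `D_g = g' D g` by least squares. A b-value
signal-attenuation readout was considered and deliberately not made the
default: at b = 350 s/mm^2 the two agree closely for Gaussian-like
displacement distributions, and the variance readout has lower Monte
Carlo noise.

`run_ecv_sweep` builds several structures per target ECV and repeats
each simulation, reporting per-run biomarkers and per-target
(ECV +/- 0.05 by construction) cluster medians. The full published
design is 9 targets x 5 structures x 5 repeats at 20000 walkers; the
package's tests use a scaled grid (3 targets x 2 x 2 at 2000 walkers)
chosen so that each trend check has clear Monte-Carlo margin at desk
scale, and the free-diffusion checks use 4000–5000 walkers. These sizes
are the package's own test design; all functions default to the full
published parameters.

## Numerical choices collected

* Quaternions are scalar-first, normalised at construction; volumes
  refuse zero-norm orientations.
* NIfTI I/O writes integers (labels) as int32 and floats as doubles, so
  round-trips are exact; non-uniform slice spacing (which arises only
  mid-registration) is an in-memory state and cannot be written.
* Gradient schemes demand at least one b = 0 entry; with 6+ nonzero
  directions the direction rank (3) and quadratic design rank (6) are
  verified at construction, and the tensor fit refuses anything less.
* Otsu thresholds use 256 histogram bins.
* Mask binarisation after weighted averaging is at 0.5 with ties
  included; label ties anywhere resolve to the more severe class.
* The demons update is capped at 1 voxel per iteration; its denominator
  is regularised by `|grad|^2 + diff^2 + 1e-9`.
* Seeds: every stochastic entry point (`make_lv_phantom`,
  `build_cell_structure`, `simulate_walkers`, `add_rician_noise`,
  `measure_ecv`) takes or carries an explicit seed; sweep runs derive
  per-run seeds deterministically from the config seed.

## Known limitations

* The registration chain assumes short-axis stacks with approximately
  in-plane rotations; through-plane deformation is not modelled.
* The demons scheme registers supports, not intensities; structures
  that move without changing their support are invisible to it.
* The simulator's geometry is a simplified cylinder forest: no
  sheetlets, no wall curvature, no permeability, no relaxation
  weighting.
* Statistics pool voxels (as the tables they mirror do); subject-level
  mixed-effects modelling is out of scope.
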