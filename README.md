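# cardti

Regional diffusion-tensor biomarkers of chronic myocardial infarction
from in vivo cardiac DTI (cDTI), for imaging scientists who want the
whole chain — segmentation, registration, tensor reconstruction, ECV,
statistics — as tested, scriptable R functions rather than a GUI.

After a myocardial infarction the extracellular space of the scarred
and border-zone myocardium expands, mostly transverse to the surviving
myocyte direction. The package quantifies this with the diffusion
tensor eigenvalues `e1 >= e2 >= e3` and the derived invariants

* mean diffusivity `MD = (e1 + e2 + e3)/3`,
* radial diffusivity `RD = (e2 + e3)/2` (diffusivity transverse to the
  myocyte long axis),
* fractional anisotropy
  `FA = sqrt(3/2) ||(e1,e2,e3) - MD|| / ||(e1,e2,e3)||`,

compared across remote, border, and infarct myocardium together with
extracellular volume fraction
`ECV = (1 - Hct) * dR1_myo / dR1_blood`, `dR1 = 1/T1_post - 1/T1_pre`,
and native T1. The expected disease signature is
infarct > border > remote for MD, the eigenvalues and RD (with RD, e2,
e3 rising the most), the reverse for FA.

What the package provides:

* **core I/O** — NIfTI volumes with slice geometry and orientation
  quaternions, FSL-dialect bval/bvec gradient tables, label maps.
* **segmentation** — LGE signal-intensity thresholding
  (`mu_remote + 2 sigma_remote` and the remote/infarct midpoint) into
  remote / border / infarct label maps.
* **registration** — the five-step chain mapping diastolic LGE-based
  labels onto systolic cDTI slices: metadata-quaternion rigid
  alignment, uniform longitudinal rescaling, Canny endo/epicardial
  contour detection with distance-weighted mask averaging, slice-wise
  demons registration of the label support, and one-hot 3D label
  interpolation.
* **dti** — log-linear least-squares tensor reconstruction, invariant
  maps, and the rejection filter for voxels with MD above free water
  (3e-3 mm^2/s).
* **ecv** — pre/post-contrast T1 + hematocrit ECV maps with
  out-of-range flagging.
* **regional statistics** — voxel pooling by region, Anderson-Darling
  normality screening, pairwise tie-corrected Kruskal-Wallis tests with
  Bonferroni adjustment (significance p < 0.01), median/quartile
  summary tables and percent changes of medians.
* **synthetic data** — a seeded infarcted-LV phantom (diastolic LGE
  grid vs. systolic cDTI grid, Rician noise at SNR 16) giving every
  stage known ground truth.
* **diffsim** — a Monte-Carlo random-walk simulator of water diffusion
  among impermeable cylindrical myocytes (9–20 um diameter, 100 um
  segments, branched trees in a periodic 0.5 mm voxel; dt = 10 us,
  51 ms, 20000 walkers) relating ECV to the same tensor biomarkers.

## Worked example

```r
library(cardti)

study <- make_lv_phantom(phantom_config(seed = 1))
res <- run_pipeline(study, out_dir = "out")

subset(res$summary, quantity %in% c("MD", "RD", "FA", "ECV"))
```

```
 quantity  region  median      q1      q3   n
      ECV  remote 0.30965 0.30220 0.31812 847
      ECV  border 0.38026 0.36996 0.38950 219
      ECV infarct 0.46840 0.46007 0.47772 232
       FA  remote 0.35828 0.28909 0.43060 847
       FA  border 0.34229 0.28638 0.40570 219
       FA infarct 0.30667 0.24814 0.36712 232
       MD  remote 0.00148 0.00136 0.00163 847
       MD  border 0.00165 0.00153 0.00180 219
       MD infarct 0.00186 0.00169 0.00198 232
       RD  remote 0.00120 0.00105 0.00135 847
       RD  border 0.00135 0.00123 0.00152 219
       RD infarct 0.00155 0.00139 0.00171 232
```

Medians (MD and RD in mm^2/s) order infarct > border > remote, ECV
rises from 0.31 to 0.47, and FA falls — the expected infarct signature.
The pairwise percent changes with Bonferroni-adjusted p-values:

```r
subset(res$changes, quantity %in% c("MD", "RD", "FA") & pair != "infarct-border")
```

```
 quantity           pair percent_change    p_adj
       MD  border-remote          11.51 2.52e-25
       MD infarct-remote          25.31 1.40e-71
       FA  border-remote          -4.46 1.11e-01
       FA infarct-remote         -14.40 6.25e-12
       RD  border-remote          12.58 1.08e-20
       RD infarct-remote          28.87 6.23e-65
```

RD changes more than MD in both comparisons, and FA decreases. (A
single phantom subject leaves FA border-remote non-significant at
p < 0.01; pooling a five-subject cohort, as the in vivo analysis does,
makes every pair significant — that is exactly what the end-to-end test
in `tests/testthat/test-acceptance.R` checks.) `run_pipeline` also
writes the summary/percent-change/per-subject CSV tables, the biomarker
maps and registered labels as NIfTI, a JSON manifest, and a structured
JSON-lines log under `out/`.

The simulator side:

```r
sweep <- run_ecv_sweep(sim_config(n_walkers = 2000, seed = 5),
                       target_ecvs = c(0.3, 0.6, 1.0),
                       structures_per_ecv = 2, repeats = 2)
sweep$clusters
```

```
  target_ecv measured_ecv       MD      FA       e1       e2       e3       RD
1        0.3       0.3093 0.001852 0.37293 0.002682 0.001489 0.001405 0.001446
2        0.6       0.5891 0.002392 0.17465 0.002846 0.002214 0.002106 0.002153
3        1.0       1.0000 0.003037 0.04414 0.003158 0.003023 0.002909 0.002968
```

Cluster-median MD, e1, and RD increase with ECV while FA decreases, and
the low-to-high percent increase of RD (~105%) far exceeds e1's (~18%).

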