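---
title: "Methods: multi-observer structure comparison and dosimetric evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-observer structure comparison and dosimetric evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When several clinics (or auto-segmentation models) delineate the same
radiotherapy targets on one patient, the contours differ. Those
differences matter twice: geometrically (how far apart are the
delineated borders?) and dosimetrically (if a plan is optimized for one
observer's target, does it still cover everyone else's, and what do the
heart and lungs receive?). `rtcompare` implements that whole comparison
chain for adjuvant breast radiotherapy — breast CTV, grouped axillary
nodal CTV (levels I–IV plus interpectoral nodes), internal-mammary CTV,
and the thoracic organs at risk — as a deterministic, testable pipeline
on voxel grids.

Everything operates on a shared `voxel_grid` (dims, spacing in mm,
world origin; x runs patient-right→left, y anterior→posterior, z
caudal→cranial). Structures are binary occupancy masks; dose is absolute
Gy per voxel with an attached prescription (40.05 Gy in 15 fractions by
default, the moderately hypofractionated schedule common in this
setting). Observers' masks must be resampled (nearest neighbour) to one
reference grid before any comparison.

# Consensus: the mean structure

The gold-standard contour is the *mean structure*: per voxel, the mean
of the observers' binary masks is the agreement fraction, and the
consensus contains every voxel with agreement **≥ 0.5**. The tie is
deliberately inclusive — with an even number of observers, a voxel
claimed by exactly half of them belongs to the consensus — so the
consensus always contains the intersection of the inputs, is contained
in their union, and is invariant to observer order. No sub-voxel
anti-aliasing or interpolation is applied before averaging: agreement is
computed on the common grid exactly as the masks stand. Probabilistic
label fusion (STAPLE-style weighting) is intentionally out of scope.

# Surface dice at a tolerance

Geometric concordance is scored with the surface dice similarity
coefficient (sDSC). Each mask's surface is the set of voxel faces
separating occupied from unoccupied voxels (the grid boundary counts as
unoccupied), each face weighted by its physical area — for a digitized
axis-aligned box this reproduces the exact box surface area. With
$S_A$, $S_B$ the two surfaces and $B_\tau$ ($A_\tau$) the set of points
within tolerance $\tau$ of the other surface,

$$\mathrm{sDSC}_\tau(A,B) \;=\;
\frac{|S_A \cap B_\tau| + |S_B \cap A_\tau|}{|S_A| + |S_B|}.$$

1 means every surface element of each structure lies within $\tau$ of
the other's surface; 0 means none does. Defaults are $\tau = 3$ and
$5$ mm, the conventional values for delineation audits.

Numerically, face centres live on a half-spacing lattice
(`2*dims + 1` points per axis), so marking one surface on that lattice
and running a Euclidean distance transform yields the **exact** nearest
face-centre distance for every element of the other surface — there is
no quantization band between the production path and a brute-force
all-pairs computation, and the test suite asserts equality to 1e-12
against exactly that oracle. The distance transform is an anisotropic
3D Felzenszwalb–Huttenlocher lower-envelope transform implemented in
C++; no installed R package provides one in 3D. The tolerance
comparison is inclusive (distance ≤ τ counts). Comparing an empty mask
is an error, never a silent 0, because zeros would poison cohort means.

# Margins and border measurements

`expand_mask()` grows a CTV to a PTV by an exact Euclidean criterion: a
voxel is included iff its centre lies within the margin of some
occupied input voxel centre (anisotropic spacing respected, via the
same distance transform). The default margin is 5 mm. The expansion
itself is purely geometric — it is **not** cropped at the skin. The
pipeline, however, intersects PTVs with the body before planning and
coverage evaluation: dose cannot exist outside the patient, and an
uncropped PTV protruding through the skin would receive 0 Gy in those
voxels and report a meaningless D98% of zero. This mirrors routine
clinical practice; the uncropped mask remains available by calling
`expand_mask()` directly.

Border extents (cranial/caudal/medial/lateral) are extreme world
coordinates of occupied voxel centres, with the medial/lateral
assignment resolved by laterality. Reported border differences are the
maximum absolute pairwise difference across observers, in cm. Measuring
on voxel centres (rather than contour polygons) is resolution-dependent
but unambiguous and directly testable; both the polygon entry path
(`rasterize_polygons()`, even-odd voxel-centre rule) and the mask path
are exposed so either convention can be reproduced.

# Dose metrics

All DVH metrics use whole-voxel counting over the structure's occupied
voxels — no partial-volume weighting — so every reported number is
exactly reproducible by sorting or counting voxel doses, and the test
suite does exactly that. Conventions:

* `VxGy` / `Vx%` thresholds are inclusive (≥); the "irradiated volume
  outside the PTV" uses a strict > 90% of prescription, following the
  usual definition of that spill metric (a flag flips it to ≥).
* `D98%` is computed by exact sorting (the dose exceeded by 98% of the
  structure volume), never read off a binned DVH, and is reported as a
  percentage of the prescription. The binned `compute_dvh()` curve
  (default bin 0.01 Gy) exists for plotting and export only.
* ICRU-50 treated/irradiated volumes are the body volumes at ≥ 90% /
  ≥ 50% of prescription.
* Coverage verdicts (Swedish national guideline defaults: combined
  breast + nodal CTV D98% ≥ 95%, internal-mammary CTV D98% ≥ 90%,
  combined PTVs D98% ≥ 93%) pass at equality, per the "≥" wording of
  the guideline. Missing structures yield a non-evaluable verdict, not
  an error.
* Dose is always resampled (trilinearly) to the structure grid, never
  the reverse: structures define the analysis frame.

# The synthetic cohort

No patient data ships with the package; the generator produces
everything the analysis needs.

**Phantom.** An elliptic-cylinder thorax (≈ 300 × 200 mm cross-section)
with breast bulges carries a hemi-ellipsoidal left-breast CTV
(≈ 854 cc), a five-component axillary/supraclavicular nodal cluster
(grouped `CTVN`, ≈ 94 cc), a thin parasternal internal-mammary tube
(≈ 7 cc), and ellipsoid/tube organs at risk (heart, both lungs,
contralateral breast, esophagus, thyroid, humeral head). Sizes were
chosen once so target volumes sit in the range typical of adjuvant
breast radiotherapy (breast targets of order 800–900 cc, nodal targets
of order 100 cc, internal-mammary targets of order 5 cc); they are not
fitted to any particular patient. The default grid is 2.5 mm isotropic,
132 × 96 × 112 voxels — fine enough that surface metrics are meaningful,
small enough that a full cohort analysis runs in minutes on one core.

**Observer noise.** A simulated observer re-thresholds each structure's
signed distance field against a smooth zero-mean Gaussian random field:
voxel occupied iff signed distance ≤ field value. The field has
marginal standard deviation `sigma_mm` (the boundary displacement
scale) and correlation length `correlation_mm` (default 10 mm), is
generated on a kernel-padded grid and cropped so it is exactly
stationary, and is rescaled by the closed-form stationary sd of the
smoothed process. One field is drawn per observer and applied to all
structures, so an observer who reads a boundary generously does so
coherently. `sigma_mm = 0` returns the reference exactly, and
everything is reproducible under the seed. Level-set perturbation
guarantees closed, clinician-plausible contours; independent voxel
noise would produce speckle no human draws.

A calibration note: the realized mean absolute boundary displacement
equals `sigma_mm * sqrt(2/pi)` (≈ 0.8 σ) only up to grid quantization —
on a coarse grid, displacements below half a voxel do not move the
digitized boundary at all. The displacement-calibration test therefore
runs on a 1 mm-spacing spherical fixture, where the measured mean
displacement for σ = 3 mm is within 30% of σ; on the default 2.5 mm
phantom grid the same measurement reads systematically lower. The
calibration property belongs to the generator, not to any particular
grid.

**Dose model.** The simplified plan model is geometric, not a beam
transport calculation: the PTV is expanded by twice the penumbra scale
(the field aperture), extended along the beam axis for flash (up to
four penumbra lengths; tangential fields run along the in-plane
diagonal, AP-PA along y), smoothed with an isotropic Gaussian of the
penumbra scale (default 5 mm), scaled to the prescription, and a
uniform scatter bath (default 2% of prescription) is added inside the
body; dose is identically zero outside the body and bounded by
prescription × (1 + bath). Because aperture margin and flash both scale
with the penumbra, the penumbra → 0 limit is exactly the prescription
indicator on the PTV, which pins the model's degenerate behaviour in
tests. The model reproduces the qualitative couplings that make
delineation differences dosimetrically relevant — in particular, a
breast CTV reaching closer to the heart drags the tangential dose cloud
onto the heart, which the test suite asserts as a strict increase in
heart Dmean under a 10 mm posterior-medial shift of the breast target.
Absolute organ-at-risk values from this model are indicative only and
are not calibrated against any treatment planning system.

# The pipeline

`run_analysis()` takes an `analysis_config` (R constructor or YAML) and
produces four report families: per-observer volumes with ranges, border
difference tables, the sDSC table against the consensus (or a named
observer), organ-at-risk dose metrics per plan, and the
cross-application coverage matrix in which each plan — by default built
on the consensus and on the largest- and smallest-breast-volume
observers — is evaluated against every observer's targets and the
consensus (D98% criteria plus the high-dose volume outside the PTV).
Observers missing a structure are excluded from that structure's
consensus and rows with a logged warning. Reports are written as CSV
(2 decimals, the precision such tables are conventionally printed at)
with a full-precision JSON mirror; a rerun with the same config and
seed reproduces the CSV bodies byte for byte.

Problem sizes in the shipped tests: oracle-equivalence checks run on
hundreds of random masks up to ~14³ voxels where the O(n²) brute-force
oracle is cheap; cohort-level properties (noise-free recovery, sDSC
monotonicity across σ ∈ {1, 2, 4, 8} mm with 20 observers) run on the
full default phantom; pipeline integration tests use a 4 mm-spacing
phantom with identical anatomy. The whole suite completes in a few
minutes on one core.

# Known limitations

* Binary DICOM parsing is not implemented; structure input is NIfTI
  masks or plain-text (JSON/YAML) slice-wise contour polygons.
* Whole-voxel counting can differ from planning systems that weight
  partial voxels; agreement with any specific TPS's printed DVH values
  is not claimed.
* The dose model has no tissue heterogeneity, divergence, or scatter
  physics; it exists to make the dosimetric machinery testable and to
  propagate geometry into dose plausibly, not to predict clinical dose.
* Surfaces are voxel-face sets, not marching-cubes meshes; sDSC values
  on very coarse grids depend on the discretization, though the
  identity/disjoint boundary values (1 and 0) hold at any resolution.
* The synthetic cohort perturbs a common reference, so it cannot
  reproduce systematic protocol differences between clinics (e.g. two
  schools of thought about a border); passing cohort tests demonstrates
  the machinery, not the full variability structure of real
  multi-centre data.
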