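---
title: "Local atrial conduction velocity and LGE-MRI wall intensity: models and methods"
author: "AtrialCV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local atrial conduction velocity and LGE-MRI wall intensity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Atrial fibrosis slows and disorganizes electrical conduction, and both are
implicated in the maintenance of atrial fibrillation. Fibrotic remodelling
can be imaged non-invasively as late gadolinium enhancement (LGE) on cardiac
MRI, while conduction velocity (CV) must be measured invasively with a
multielectrode mapping catheter. If wall enhancement predicts local CV at
clinically relevant scales — the footprint of a mapping electrode or an
ablation lesion, a few millimetres — then LGE imaging could stand in for
part of the invasive workup. `AtrialCV` implements the full measurement and
modelling chain for that question, driven entirely by a synthetic-data
generator so that every stage is testable without patient data.

# Local CV by triad triangulation

A 20-pole double-loop catheter held against the atrial wall records 20
unipolar electrograms per placement ("kernel"). The local activation time
(LAT) of each electrogram is the time of the maximum negative voltage
gradient (`annotateLAT()`: centred differences, parabolic sub-sample
refinement, and an earliest-plateau-midpoint rule for ties, which makes the
degenerate pure-ramp case reproducible).

Within a kernel, every 3-subset of electrodes (a *triad*) triangulates a
local plane-wave velocity. `triadCV()` rotates the triad into its own plane
and solves the linear system `t_i − t_1 = s · (p_i − p_1)` for the in-plane
slowness vector `s`; speed is `1/|s|` (mm/ms = m/s). Solving in the triangle
plane avoids the rank deficiency of the equivalent 3D system; the surviving
numerical hazards are handled explicitly:

* triads whose smallest internal angle is below 5° are rejected — the
  conditioning of the slowness solve degrades as 1/sin(angle);
* slowness magnitudes below 1e-6 ms/mm (LATs effectively equal) are
  flagged as infinite speed and discarded rather than reported as huge
  velocities.

`enumerateTriads()` applies the two physical constraints: the minimum
interelectrode distance in a triad must exceed the registration error of the
dataset (so LAT differences are not swamped by position uncertainty), and
the enclosed area must stay below a cut — 80 mm² by default — because the
association of interest is local. Bins are half-open `[lo, hi)` throughout.

# Regional wavefront fit and kernel quality

Triad triangulation assumes locally planar propagation. `fitCircularWavefront()`
tests that assumption per kernel by fitting an ideal circularly propagating
wavefront, `t_i = t0 + |p_i − c| / v`, to all 20 electrodes. Only the origin
is iterated (Levenberg–Marquardt with restarts placed on both sides of the
kernel along the initial planar direction, at distances from 15 mm to 2 m to
cover the planar limit); for each candidate origin the optimal `(t0, 1/v)`
solve is linear. The residual index

```
eta = RMS temporal residual (s) / mean electrode distance to origin (mm)
```

carries s/mm units; large values mean the activation pattern is not a smooth
wavefront (collision, block, fractionation) and the kernel is unusable for
plane-wave analysis. The exact functional form behind the published index is
not reproduced in the source literature, so this definition is documented
here and configurable. Note one genuine ambiguity: the source text prints
"kernels with eta < 5 s/mm were rejected" yet also states that *high* eta
indicates a violated assumption, and the reported kernel counts cannot
disambiguate the inequality. `rejectKernels()` therefore defaults to
rejecting `eta > threshold` (treating the printed direction as a sign slip)
and exposes `direction = "below"` for the literal reading. A kernel exactly
at the threshold is accepted.

# Wall intensity, NI and IIR

The imaging side samples the LGE volume at every vertex of the epicardial
surface: the maximum trilinearly interpolated intensity along a 3 mm
inward-facing normal (`sampleWallIntensity()`, 0.5 mm steps — at most half
the smallest reconstructed voxel pitch). Raw intensities are meaningless
across scans, so they are referenced to the blood pool, whose statistics
come from the voxels inside the surface shrunk inward along vertex normals
(`bloodPoolStats()`; SD uses the n−1 denominator):

* **NI** (normalized intensity) = (raw − μ_bp) / σ_bp, in blood-pool SD
  units — invariant under *any* positive affine rescaling of the image;
* **IIR** (image intensity ratio) = raw / μ_bp — invariant under pure gain
  only, not under offsets.

The two are linked vertex-wise by `iir = 1 + ni · σ_bp/μ_bp`, and an IIR of
exactly 1 corresponds to NI 0. This affine-invariance asymmetry is the
mechanical reason NI reproduces across scans with different dynamic ranges
while IIR does not, and the package's reproducibility comparison
(`reproducibilityCompare()`) demonstrates it directly: an intensity offset
applied to a second scan leaves every NI-based quantity bit-comparable and
shifts every IIR-based slope.

The published shrink is quoted as "5 voxels (3 mm)", which is inconsistent
on the stated reconstructed grid; the metric figure (3 mm) is taken as the
definition, configurable. One caveat specific to the synthetic phantom: its
wall occupies the full shell thickness (4.5 mm by default) with no
trabeculation, so the pipeline configuration shrinks by 6 mm to keep the
wall shell out of the blood-pool sample. With real anatomy the conventional
3 mm applies.

`triadMeanIntensity()` averages the chosen metric over the surface vertices
whose closest-point projection falls strictly inside the triad's triangle
(area-weighted by barycentric vertex areas, restricted to vertices within
3 mm of the triangle plane so the opposite wall cannot contribute), with a
documented fallback to the three electrode-adjacent vertices for
micro-triads below the mesh resolution. Surface vertices, not image voxels,
are the integration support — the pipeline's native representation is the
per-vertex map.

# Registration and fusion

The electroanatomic surface is co-registered to the imaging surface by
6-DOF rigid ICP (`rigidICP()`): closest-vertex correspondences and Kabsch
updates, iterated to convergence. Smooth, nearly ellipsoidal atrial
surfaces let single-start ICP slide into rotational local minima, so the
implementation restarts from a small bank of initial rotations and keeps the
lowest-RMS result. No scaling or deformable component is included: both
surfaces describe the same chamber in mm. Accuracy is summarized as target
registration error (`targetRegistrationError()`), the RMS distance between
transformed fiducial vertices and their true counterparts; the pipeline
reuses each dataset's TRE as the minimum triad edge-length constraint.
Electrodes are mapped to their exact closest point on the mesh (point-to-
triangle, not vertex snapping, to avoid mesh-resolution bias) and electrodes
more than 5 mm from the surface are disregarded.

# The multilevel association model

The central statistical object is

$$V_{ijk} = (\beta_0 + u_j + v_k) + (\beta_1 + \beta_{2j})\, I_{ijk} + \varepsilon_{ijk}$$

for triad `i`, patient `j`, pacing cycle length `k`: crossed random
intercepts `u_j` and `v_k` (cycle lengths are shared across patients, so
crossed rather than nested), a per-patient random slope deviation
`beta_2j` independent of the intercepts (the model has no intercept–slope
covariance term), and the overall slope `beta_1` as the parameter of
interest. `fitMultilevel()` fits by maximum likelihood — not REML — because
model comparison uses likelihood-ratio tests between fixed structures
(`likelihoodRatioTest()`). Degenerate regimes are explicit: data exactly on
a line would push the likelihood to infinity, so such fits return the exact
OLS line with an `exact_fit` flag; a collapsed variance component flags the
fit singular without failing; with all random terms disabled the fit
reproduces OLS exactly.

Confidence intervals on the fixed effects use the Wald SE with a t
reference at `J − 1` degrees of freedom (J = number of patients). The
replication unit for both fixed effects is the patient, so the asymptotic
normal reference is anti-conservative at realistic cohort sizes: in a
calibration of 200 simulated cohorts at study scale (8 patients), z-based
intervals covered the generative slope 88.5% of the time, the t(J−1) form
92.5%. Per-patient deviations are reported as empirical BLUPs with
conditional-variance standard errors and Wald tests (`perPatientEffects()`);
the LRT for a random slope tests a variance on its boundary, so the nominal
chi-squared reference is conservative there — the test suite checks size
from above, not equality.

# Measurement scale and the area-binned slope

Averaging intensity over regions larger than the spatial scale of fibrosis
dilutes a local association. `areaBinnedSlopes()` quantifies this by
refitting the model within 10 mm² half-open triad-area bins over 0–160 mm²
(bins with fewer than 50 triads or fewer than 2 patients are skipped with a
logged reason).

The synthetic generator reproduces the attenuation mechanism, and the
choice deserves documentation because the obvious construction fails. If
generative CV responds to the field at the triangle *centroid* and the
covariate is the field averaged over the enclosed area, the fitted slope is
`Cov(S_c, S̄_A)/Var(S̄_A)`, which *rises* with area for a stationary field
(the centroid is the best-connected point of the triangle; Monte-Carlo on a
Gaussian-covariance field gives 1.02 → 1.36 over 5 → 155 mm²). The
physically correct anchoring is at the electrodes: triad CV is computed
from LATs measured at the triangle's *vertices*, so the generator sets the
local speed from the mean of the three point intensities at the electrode
sites. Against an interior-quadrature area average, that ratio falls
monotonically (0.95 → 0.37 over the same range), which is what the binned
fits recover. In `generateCohort()`, `intensity_measure = "electrode"`
(default) records the same covariate that drives CV — the well-posed
setting for parameter recovery — while `intensity_measure = "area"` records
the area average and reproduces the attenuation.

# The synthetic cohort: what it emulates and what it does not

`generateCohort()` reproduces the study conditions: 8 patients, pacing
cycle lengths {250, 300, 350, 600} ms, 12 kernels per patient (~500 triads
per patient under the default constraints), generative fixed effects equal
to the published overall associations (NI: intercept 1.00 m/s, slope
−0.104 m/s per NI unit; IIR: 1.94 m/s and −0.942 m/s per IIR unit), and
random-effect SDs σ_u = 0.05, σ_v = 0.02, σ_slope = 0.02, σ_eps = 0.1 m/s.
The random-effect scales are simulation conventions chosen to keep recovery
feasible at cohort scale — the source study does not publish its variance
components — and are config values, not claims about the data. Enhancement
fields default to a mean of 1.5 and SD of 1.0 NI units (respectively 1.15
and 0.10 IIR units) with a 5 mm correlation length, matching the scale on
which atrial gadolinium uptake is described as patchy; with those defaults
the generative mean CV is ~0.84 m/s, in the physiological range reported
for paced atria.

Geometry: surfaces are subdivided icosahedra mapped to an ellipsoid of
~41 mm major axis (typical echocardiographic LA diameter) with a smooth
radial perturbation; the catheter is modelled as a two-turn spiral laid in
the local tangent plane with exactly 4 mm consecutive chord spacing (the
proprietary loop geometry is unpublished; radii 4.5–8 mm accommodate the 19
gaps). The wall is a single shell of configurable thickness, 4.5 mm by
default so that 3 mm-deep sampling with trilinear support never leaves the
shell. All randomness flows from one root seed through named substreams
(surface / field / placement / noise), so identical configurations are
bit-identical.

Deliberate simplifications: activation is kinematic (closed-form planar and
circular waves — no eikonal or reaction-diffusion propagation, so LAT
fields are exactly consistent with one wave per kernel); there is no MRI
artifact model (bias field, motion); wall thickness is uniform; the
interior test used for rasterization and blood-pool statistics is radial
and therefore assumes star-shaped surfaces, which all generated surfaces
are. Consequently, passing tests demonstrate correctness of the measurement
and inference chain under the generative model, not robustness to real
imaging artifacts or complex propagation.

# Numerical choices and fixture design

* Icosphere subdivision gives 12–10242 vertices; the smallest level
  with at least the requested count is used.
* The smooth enhancement field is a weighted sum of Gaussian bumps
  (bump SD = correlation length /√2, about 3 bumps per correlation area),
  affinely calibrated so the per-vertex mean and SD are exact; it is
  evaluable at arbitrary 3D points, which is what allows electrode-level
  versus area-averaged covariates to be generated from one object.
* The plateau field mode (piecewise-constant over farthest-point patches)
  exists for exact-recovery fixtures: with kernels seated at patch centres,
  per-kernel intensity is exactly constant. The end-to-end noise-free run
  uses 6 patches per patient, triad areas below 50 mm² and 0.8 mm isotropic
  voxels; a precision analysis of the remaining stochastic term (blood-pool
  μ̂, σ̂ estimated from ~10⁴ voxels — it cannot be removed because NI
  requires σ_bp > 0) bounds the fixed-effect error below the 1e-3 m/s
  tolerance asserted in the pipeline test.
* Simulation sizes in the test suite (100 replicate cohorts for parameter
  recovery, 60 null simulations for LRT size, 500 random triads for the
  plane-wave oracle) were chosen so the whole suite completes in minutes on
  a single core while keeping Monte-Carlo error well inside the asserted
  bands.

# Known limitations

* The eta rejection direction and the eta formula itself are
  reconstructions of an under-specified published criterion; both are
  configurable and documented rather than silently guessed.
* The per-dataset TRE of a real study (~3 mm average) is reproduced only
  qualitatively (via configurable jitter); which anatomical landmarks
  produced the published figure is unknown, so synthetic fiducial vertices
  stand in.
* `triadMeanIntensity()` integrates over surface vertices; whether the
  original analysis averaged image voxels or surface samples is not stated.
  The surface-sample choice matches the package's per-vertex map
  representation.
* Registration is rigid only. Deformable mismatch between imaging and
  mapping geometry is out of scope.
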