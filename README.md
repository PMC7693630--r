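# AtrialCV

Local atrial conduction velocity (CV) estimation, LGE-MRI wall-intensity
normalization, surface registration, and multilevel modelling of the
CV–enhancement association — with a synthetic-data generator that makes the
entire pipeline testable without clinical data.

## The problem

Atrial fibrosis both slows conduction and promotes the re-entry that
sustains atrial fibrillation. Fibrosis can be imaged non-invasively as late
gadolinium enhancement (LGE) on cardiac MRI; conduction velocity must be
measured invasively with a multielectrode catheter. The question this
package addresses is whether — and at what spatial scale — LGE intensity
predicts local CV, which would let imaging stand in for part of the
invasive electrical workup in patients with persistent AF.

The analysis chain, for people who work with electroanatomic maps and LGE
volumes:

* **Local CV** by triangulation over electrode *triads* within a 20-pole
  double-loop catheter placement (*kernel*): the triad is rotated into its
  plane and the LAT differences solved for the in-plane slowness **s**
  (`t_i − t_1 = s · (p_i − p_1)`), giving speed `1/|s|` in m/s. LATs are the
  time of the maximum negative unipolar electrogram gradient.
* **Kernel quality** by fitting an ideal circular wavefront
  `t_i = t0 + |p_i − c|/v` to all 20 electrodes; the RMS temporal residual
  per unit propagation distance (η, s/mm) rejects kernels whose activation
  is not a smooth wavefront.
* **Wall intensity** as the maximum trilinear sample along a 3 mm
  inward-facing surface normal, normalized against blood-pool statistics as
  **NI** = (raw − μ_bp)/σ_bp or **IIR** = raw/μ_bp, averaged over each
  triad's enclosed area.
* **Fusion** by rigid ICP co-registration with target registration error
  (TRE), and closest-point electrode projection with a 5 mm distance filter.
* **Association** by a crossed-random-effects multilevel model, fit by ML:

  V_ijk = (β0 + u_j + v_k) + (β1 + β2j) · I_ijk + ε_ijk

  with patient intercepts u_j, cycle-length intercepts v_k and per-patient
  random slopes β2j; β1 is the quantity of interest. Likelihood-ratio tests
  compare nested structures, and the model is refit within 10 mm² triad-area
  bins to show how measurement scale attenuates the association.

## Worked example

Simulate a cohort at study scale (8 patients, pacing cycle lengths 250–600
ms, ~500 triads per patient with area < 80 mm², generative NI association
β0 = 1.00 m/s, β1 = −0.104 m/s per NI unit) and fit the multilevel model:

```r
library(AtrialCV)

coh <- generateCohort(seed = 7)
fit <- fitMultilevel(observations(coh), metric = "ni")
fit
#> MixedModelFit (ni, ML): CV = 1.0283 -0.1148 * intensity
#>   SE(slope) = 0.00733, logLik = 3550.89, n = 4032

slopeCI(fit)        # t(J-1) Wald interval
#> -0.1321 to -0.0975   (generative slope -0.104)

head(perPatientEffects(fit)[, c("patient", "slope_dev", "slope_p")], 4)
#>   patient slope_dev  slope_p
#> 1     P01   0.02974 6.68e-05
#> 2     P02  -0.00797 2.01e-01
#> 3     P03  -0.00392 4.42e-01
#> 4     P04  -0.02855 8.32e-06

red <- fitMultilevel(observations(coh), metric = "ni", random_slopes = FALSE)
likelihoodRatioTest(fit, red)
#> stat = 43.9, df = 1, p = 3.4e-11   (random slopes are supported)
```

The fitted line says CV falls by about 0.11 m/s per blood-pool SD of
enhancement, from 1.03 m/s at NI 0; the interval covers the generative
value, and the per-patient rows show which patients deviate significantly
from the overall slope. The same cohort generator drives the geometric
pipeline end to end (`runPipeline(defaultConfig())`): surface → LGE-like
volume → perturbed EAM surface → ICP registration → electrode projection →
wavefront screening → triad CV → intensity mapping → model fit, with every
artifact written to disk on request (PLY/VTK meshes, NIfTI volumes, CSV
kernels and observations, JSON fits, YAML transforms and configs).

To see the measurement-scale effect, record the covariate as the
area-averaged intensity and refit per area bin:

```r
coh <- generateCohort(seed = 11, catheter_scale = c(1, 2), min_edge_mm = 0,
                      triads_per_kernel = 150, max_area_mm2 = Inf,
                      intensity_measure = "area")
bins <- areaBinnedSlopes(observations(coh))
bins[c(1, 16), c("bin_lo", "bin_hi", "beta1")]
#>   bin_lo bin_hi   beta1
#> 1      0     10 -0.0780
#> 16   150    160 -0.0092
```

|β1| shrinks by an order of magnitude from the smallest to the largest
bins: averaging enhancement over areas much larger than the ~5 mm fibrosis
patch scale dilutes the local association.

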