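Package: AtrialCV
Title: Local Atrial Conduction Velocity and LGE-MRI Wall-Intensity Fusion
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the electro-architectural relationship
    between left-atrial conduction velocity (CV) and wall enhancement on
    late-gadolinium-enhanced cardiac MRI. Implements local CV estimation
    by triangulation over electrode triads of a 20-pole double-loop
    mapping catheter, regional circular-wavefront fitting with a
    residual-based kernel quality criterion, blood-pool based intensity
    normalization (normalized intensity and image intensity ratio),
    rigid surface co-registration with target registration error,
    electrode-to-surface projection, and a crossed-random-effects
    multilevel model of CV against wall intensity, including the
    dependence of the fitted association on triad measurement area.
    A synthetic-data generator produces atrial-like surfaces, patchy
    enhancement fields, intensity volumes, catheter kernels and
    activation times with the statistical structure the analysis
    assumes, so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    lme4,
    minpack.lm,
    RNifti,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
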