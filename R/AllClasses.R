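#' @import methods
#' @importFrom stats rnorm runif median sd var optim pchisq pnorm qnorm qt
#'   quantile setNames logLik coef lm p.adjust cor.test dist uniroot
#' @importFrom utils combn read.csv write.csv
NULL

#' Triangulated surface mesh
#'
#' A triangle mesh in physical (mm) coordinates with outward-oriented
#' per-vertex unit normals. Surfaces produced by [generateAtrialSurface()]
#' are closed genus-0 manifolds; arbitrary meshes (e.g. open test patches)
#' are permitted by the class, and closedness can be checked with
#' [isClosedManifold()].
#'
#' @slot vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @slot faces integer matrix, m x 3, 1-based vertex indices per triangle,
#'   consistently oriented counter-clockwise seen from outside.
#' @slot normals numeric matrix, n x 3, per-vertex outward unit normals.
#'
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix", normals = "matrix"),
  validity = function(object) {
    v <- object@vertices; f <- object@faces; nrm <- object@normals
    if (ncol(v) != 3L) return("vertices must be an n x 3 matrix")
    if (ncol(f) != 3L) return("faces must be an m x 3 matrix")
    if (nrow(f) > 0 && (min(f) < 1L || max(f) > nrow(v)))
      return("face indices out of range")
    if (nrow(nrm) != nrow(v) || ncol(nrm) != 3L)
      return("normals must match vertices in shape")
    if (nrow(nrm) > 0) {
      len <- sqrt(rowSums(nrm^2))
      if (any(abs(len - 1) > 1e-6)) return("normals must be unit length")
    }
    TRUE
  })

#' 3D scalar intensity volume
#'
#' A regular scalar grid in arbitrary intensity units with voxel spacing
#' and origin in mm. `voxels[i, j, k]` is centred at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @slot voxels numeric 3D array, non-negative intensities.
#' @slot spacing numeric length-3, mm per voxel along each axis (> 0).
#' @slot origin numeric length-3, mm position of the centre of voxel (1,1,1).
#'
#' @export
setClass("IntensityVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L) return("voxels must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 strictly positive values")
    if (length(object@origin) != 3L) return("origin must have length 3")
    TRUE
  })

#' One catheter placement (kernel)
#'
#' The concurrently recorded electrode set of one placement of the 20-pole
#' double-loop mapping catheter: positions, local activation times and a
#' contact flag per electrode, together with patient/scan labels and the
#' pacing cycle length.
#'
#' @slot patient_id character scalar.
#' @slot scan_id character scalar.
#' @slot kernel_id character scalar.
#' @slot cycle_length_ms numeric scalar, pacing cycle length in ms.
#' @slot electrode_positions numeric matrix, up to 20 x 3, mm.
#' @slot lat_ms numeric vector, local activation time per electrode in ms
#'   (NA where no usable deflection was annotated).
#' @slot contact_ok logical vector, per-electrode contact/quality flag.
#'
#' @export
setClass("Kernel",
  representation(patient_id = "character", scan_id = "character",
                 kernel_id = "character", cycle_length_ms = "numeric",
                 electrode_positions = "matrix", lat_ms = "numeric",
                 contact_ok = "logical"),
  validity = function(object) {
    n <- nrow(object@electrode_positions)
    if (n > 20L) return("a kernel has at most 20 electrodes")
    if (ncol(object@electrode_positions) != 3L)
      return("electrode_positions must be n x 3")
    if (length(object@lat_ms) != n || length(object@contact_ok) != n)
      return("lat_ms and contact_ok must match electrode count")
    if (any(object@contact_ok & !is.finite(object@lat_ms)))
      return("contact-ok electrodes must have finite LATs")
    if (n >= 2) {
      d <- as.matrix(dist(object@electrode_positions))
      if (min(d[upper.tri(d)]) <= 0) return("electrode positions must be distinct")
    }
    TRUE
  })

#' Patchy wall-enhancement field on a surface
#'
#' A spatially correlated scalar field over (a neighbourhood of) a surface,
#' represented as a weighted sum of isotropic Gaussian bumps plus an affine
#' calibration, so it can be evaluated at arbitrary 3D points (electrode
#' positions, quadrature points inside a triad) as well as at mesh vertices.
#' The bump width is chosen so the field's spatial autocorrelation length
#' approximates `patch_scale_mm`.
#'
#' @slot centers numeric matrix, M x 3, bump centres (mm).
#' @slot weights numeric length-M bump weights.
#' @slot bump_sd numeric scalar, Gaussian bump SD (mm).
#' @slot gain,offset numeric scalars of the affine calibration
#'   `gain * raw + offset` applied to the bump sum.
#' @slot values numeric per-vertex field values on the generating mesh.
#' @slot mode character, `"smooth"` (Gaussian-bump random field) or
#'   `"plateau"` (piecewise-constant over nearest-centre patches; used for
#'   controlled fixtures where intensity must be exactly constant over a
#'   catheter footprint).
#'
#' @export
setClass("FibrosisField",
  representation(centers = "matrix", weights = "numeric", bump_sd = "numeric",
                 gain = "numeric", offset = "numeric", values = "numeric",
                 mode = "character"))

#' Rigid-body transform
#'
#' @slot rotation 3 x 3 rotation matrix (det = +1).
#' @slot translation numeric length-3, mm.
#'
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3 x 3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      return("rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-9) return("rotation must have determinant +1")
    if (length(object@translation) != 3L) return("translation must have length 3")
    TRUE
  })

#' Circular-wavefront fit for one kernel
#'
#' Parameters of an ideal circular (spherical in 3D) propagating wavefront
#' fitted to a kernel's electrode positions and LATs, with the fit residual
#' eta used for kernel quality rejection.
#'
#' @slot origin numeric length-3, wavefront origin (mm).
#' @slot onset_ms numeric, activation onset time t0 (ms).
#' @slot speed_m_per_s numeric, regional propagation speed (m/s).
#' @slot radius_mm numeric, wavefront radius at the median activation time.
#' @slot eta numeric, RMS temporal residual per unit propagation distance
#'   (s/mm); high values indicate a non-smooth wavefront.
#' @slot accepted logical, set by [rejectKernels()].
#' @slot converged logical.
#'
#' @export
setClass("WavefrontFit",
  representation(origin = "numeric", onset_ms = "numeric",
                 speed_m_per_s = "numeric", radius_mm = "numeric",
                 eta = "numeric", accepted = "logical", converged = "logical"),
  validity = function(object) {
    if (isTRUE(object@converged) && object@speed_m_per_s <= 0)
      return("speed must be positive on success")
    if (is.finite(object@eta) && object@eta < 0) return("eta must be >= 0")
    TRUE
  })

#' Blood-pool intensity statistics
#'
#' Mean and SD of the voxels inside the epicardial surface shrunk inward
#' along vertex normals; the reference for NI and IIR normalization.
#'
#' @slot mu_bp,sigma_bp numeric, mean and SD (n-1 denominator) of blood-pool
#'   voxel intensities (arbitrary units).
#' @slot n_voxels integer, number of voxels used.
#' @slot zero_variance logical, TRUE when sigma_bp is 0 (NI undefined).
#'
#' @export
setClass("BloodPoolStats",
  representation(mu_bp = "numeric", sigma_bp = "numeric",
                 n_voxels = "integer", zero_variance = "logical"),
  validity = function(object) {
    if (object@sigma_bp < 0) return("sigma_bp must be >= 0")
    if (object@n_voxels <= 0L) return("n_voxels must be positive")
    TRUE
  })

#' Per-vertex wall-intensity map
#'
#' Raw maximum wall intensity per surface vertex plus its NI and IIR
#' normalizations and the blood-pool statistics they refer to.
#'
#' @slot raw,ni,iir numeric per-vertex values (NA where the sampling ray
#'   left the volume).
#' @slot stats a [BloodPoolStats-class] object.
#'
#' @export
setClass("IntensitySurfaceMap",
  representation(raw = "numeric", ni = "numeric", iir = "numeric",
                 stats = "BloodPoolStats"),
  validity = function(object) {
    if (length(object@ni) != length(object@raw) ||
        length(object@iir) != length(object@raw))
      return("raw, ni, iir must have equal length")
    ok <- is.finite(object@raw)
    s <- object@stats
    if (s@sigma_bp > 0 &&
        max(abs(object@ni[ok] - (object@raw[ok] - s@mu_bp) / s@sigma_bp),
            0) > 1e-8)
      return("ni must equal (raw - mu_bp)/sigma_bp")
    if (s@mu_bp > 0 &&
        max(abs(object@iir[ok] - object@raw[ok] / s@mu_bp), 0) > 1e-8)
      return("iir must equal raw/mu_bp")
    TRUE
  })

#' Multilevel model fit of CV against wall intensity
#'
#' Result of fitting V_ijk = (b0 + u_j + v_k) + (b1 + b2_j) I_ijk + e_ijk
#' by maximum likelihood: crossed random intercepts for patient (u_j) and
#' pacing cycle length (v_k) and an independent per-patient random slope
#' deviation (b2_j) on intensity.
#'
#' @slot beta0,beta1 numeric fixed effects: overall intercept (m/s) and
#'   slope (m/s per intensity unit).
#' @slot se_beta0,se_beta1 numeric standard errors.
#' @slot u,v,beta2 named numeric vectors of predicted random effects.
#' @slot var_u,var_v,var_slope,var_eps numeric variance components.
#' @slot loglik numeric maximized log-likelihood (Inf for an exact fit).
#' @slot df integer, number of estimated parameters.
#' @slot n_obs integer.
#' @slot metric character, "ni" or "iir".
#' @slot singular,exact_fit logical flags.
#' @slot model the underlying lme4 fit (or NULL for exact/OLS fits).
#'
#' @export
setClass("MixedModelFit",
  representation(beta0 = "numeric", beta1 = "numeric",
                 se_beta0 = "numeric", se_beta1 = "numeric",
                 u = "numeric", v = "numeric", beta2 = "numeric",
                 var_u = "numeric", var_v = "numeric", var_slope = "numeric",
                 var_eps = "numeric", loglik = "numeric", df = "integer",
                 n_obs = "integer", metric = "character",
                 singular = "logical", exact_fit = "logical", model = "ANY"),
  validity = function(object) {
    vs <- c(object@var_u, object@var_v, object@var_slope, object@var_eps)
    if (any(vs < 0)) return("variance components must be >= 0")
    if (object@n_obs < 2L) return("n_obs too small")
    TRUE
  })

#' Synthetic study cohort
#'
#' Output of [generateCohort()]: the generative truth record, per-patient
#' geometry (mesh, enhancement field, kernels) and the triad observation
#' table consumed by [fitMultilevel()].
#'
#' @slot truth list with the generative fixed effects, random-effect draws
#'   and hyperparameters.
#' @slot patients list, one entry per patient with elements `mesh`, `field`
#'   and `kernels`.
#' @slot observations data.frame with columns cv, intensity, metric,
#'   patient, cycle_length, area_mm2, min_edge_mm, kernel_id, scan.
#' @slot config list of the generator parameters actually used.
#'
#' @export
setClass("SyntheticCohort",
  representation(truth = "list", patients = "list",
                 observations = "data.frame", config = "list"))

## ---- show methods ----------------------------------------------------------

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces%s\n",
              nrow(object@vertices), nrow(object@faces),
              if (isClosedManifold(object)) " (closed)" else ""))
})

setMethod("show", "IntensityVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("IntensityVolume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x ")))
})

setMethod("show", "Kernel", function(object) {
  cat(sprintf("Kernel %s (patient %s, scan %s): %d electrodes (%d in contact), CL %g ms\n",
              object@kernel_id, object@patient_id, object@scan_id,
              nrow(object@electrode_positions), sum(object@contact_ok),
              object@cycle_length_ms))
})

setMethod("show", "WavefrontFit", function(object) {
  cat(sprintf("WavefrontFit: v = %.3f m/s, radius = %.1f mm, eta = %.3g s/mm%s\n",
              object@speed_m_per_s, object@radius_mm, object@eta,
              if (length(object@accepted) && !is.na(object@accepted))
                sprintf(" [%s]", if (object@accepted) "accepted" else "rejected")
              else ""))
})

setMethod("show", "BloodPoolStats", function(object) {
  cat(sprintf("BloodPoolStats: mu = %.2f, sigma = %.2f (n = %d voxels)%s\n",
              object@mu_bp, object@sigma_bp, object@n_voxels,
              if (object@zero_variance) " [zero variance]" else ""))
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform:\n  rotation:\n")
  print(round(object@rotation, 6))
  cat("  translation:", paste(format(object@translation), collapse = " "), "mm\n")
})

setMethod("show", "MixedModelFit", function(object) {
  cat(sprintf("MixedModelFit (%s, ML): CV = %.4f %+.4f * intensity\n",
              object@metric, object@beta0, object@beta1))
  cat(sprintf("  SE(slope) = %.4g, logLik = %.2f, n = %d%s%s\n",
              object@se_beta1, object@loglik, object@n_obs,
              if (object@singular) " [singular]" else "",
              if (object@exact_fit) " [exact fit]" else ""))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d patients, %d observations (%s)\n",
              length(object@patients), nrow(object@observations),
              object@config$metric))
})

## ---- accessors -------------------------------------------------------------

#' Mesh accessors
#'
#' @param x a [SurfaceMesh-class].
#' @return `vertices` and `normals` return n x 3 matrices; `faces` returns
#'   the m x 3 index matrix.
#' @export
vertices <- function(x) x@vertices

#' @rdname vertices
#' @export
faces <- function(x) x@faces

#' @rdname vertices
#' @export
normals <- function(x) x@normals

#' Kernel accessors
#'
#' @param x a [Kernel-class].
#' @return `electrodePositions` returns the n x 3 position matrix; `lats`
#'   the per-electrode LAT vector (ms); `cycleLength` the pacing CL (ms).
#' @export
electrodePositions <- function(x) x@electrode_positions

#' @rdname electrodePositions
#' @export
lats <- function(x) x@lat_ms

#' @rdname electrodePositions
#' @export
cycleLength <- function(x) x@cycle_length_ms

#' Cohort accessors
#'
#' @param x a [SyntheticCohort-class].
#' @return `observations` returns the triad observation data.frame;
#'   `cohortTruth` the generative truth list.
#' @export
observations <- function(x) x@observations

#' @rdname observations
#' @export
cohortTruth <- function(x) x@truth

#' Fixed effects of a multilevel fit
#'
#' @param fit a [MixedModelFit-class].
#' @return named numeric vector with elements `beta0` and `beta1`.
#' @export
fixedEffects <- function(fit) c(beta0 = fit@beta0, beta1 = fit@beta1)

#' Confidence intervals for the overall slope and intercept
#'
#' Wald-type intervals using a t reference with `J - 1` degrees of freedom,
#' where `J` is the number of patients: the replication unit for both fixed
#' effects is the patient (the slope varies across patients through the
#' random slopes, the intercept through the random intercepts), so the
#' asymptotic normal reference is anti-conservative at typical cohort sizes
#' and the patient-level t correction is the standard small-sample choice.
#'
#' @param fit a [MixedModelFit-class].
#' @param level confidence level.
#' @return numeric length-2 vector (lower, upper).
#' @export
slopeCI <- function(fit, level = 0.95) {
  q <- qt(1 - (1 - level) / 2, df = max(length(fit@u) - 1, 1))
  fit@beta1 + c(-1, 1) * q * fit@se_beta1
}

#' @rdname slopeCI
#' @export
interceptCI <- function(fit, level = 0.95) {
  q <- qt(1 - (1 - level) / 2, df = max(length(fit@u) - 1, 1))
  fit@beta0 + c(-1, 1) * q * fit@se_beta0
}
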