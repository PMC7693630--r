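# Whole-cohort synthetic study generator.

# Strictly interior barycentric lattice (degree 6): the 10 points with all
# barycentric coordinates >= 1/6. Used to area-average a field over a triad's
# enclosed triangle without touching the electrode sites themselves.
.interiorBarycentric <- function() {
  g <- expand.grid(i = 1:4, j = 1:4)
  g <- g[g$i + g$j <= 5, ]
  cbind(g$i, g$j, 6 - g$i - g$j) / 6
}

#' Generate a full synthetic study cohort
#'
#' Produces a cohort with the statistical structure assumed by the
#' multilevel analysis: per-patient random intercepts `u_j ~ N(0, sd_u)`,
#' per-cycle-length random intercepts `v_k ~ N(0, sd_v)`, per-patient random
#' slope deviations `b2_j ~ N(0, sd_slope)`, and per-triad conduction
#' velocity
#' \deqn{V = (\beta_0 + u_j + v_k) + (\beta_1 + b_{2j}) I + \epsilon,}
#' where `I` is the wall-enhancement intensity sensed at the triad's three
#' electrode positions (mean of the three point values of the patchy field)
#' and `eps ~ N(0, sd_eps)`.
#'
#' Each patient gets a closed atrial-like surface, a patchy enhancement
#' field (correlation length `patch_scale_mm`) and `kernels_per_patient`
#' catheter placements at random sites, with cycle lengths assigned
#' round-robin. Triads are enumerated per kernel under the minimum-edge and
#' maximum-area constraints and subsampled to about `triads_per_kernel`.
#'
#' The recorded intensity covariate is controlled by `intensity_measure`:
#' `"electrode"` records the same electrode-level intensity that drives the
#' generative CV (the well-posed setting for parameter-recovery studies);
#' `"area"` records the field averaged over the triangle enclosed by the
#' triad (interior quadrature), which reproduces the attenuation of the
#' fitted slope with increasing measurement area seen when a patchy field is
#' averaged over regions larger than its correlation length.
#'
#' Kernels also carry simulated LATs from a planar wave propagating in the
#' local tangent plane at the kernel's generative mean speed, so the CV
#' estimation stages can run on the same cohort.
#'
#' @param n_patients number of patients (>= 2).
#' @param cycle_lengths pacing cycle lengths in ms (non-empty).
#' @param kernels_per_patient catheter placements per patient.
#' @param triads_per_kernel target number of triads sampled per kernel.
#' @param metric `"ni"` or `"iir"`; selects the intensity units and the
#'   default fixed effects.
#' @param beta0,beta1 generative fixed effects (m/s and m/s per intensity
#'   unit). Defaults: 1.00 and -0.104 for NI; 1.94 and -0.942 for IIR.
#' @param sd_u,sd_v,sd_slope,sd_eps random-effect and residual SDs (m/s).
#' @param intensity_mean,intensity_sd marginal mean/SD of the enhancement
#'   field in the metric's units. Defaults: 1.5 / 1.0 (NI); 1.15 / 0.10
#'   (IIR).
#' @param patch_scale_mm field correlation length (mm).
#' @param max_area_mm2,min_edge_mm triad constraints (area strictly below,
#'   minimum edge strictly above).
#' @param catheter_scale template scale factor; > 1 enlarges the loops to
#'   reach larger triad areas in measurement-scale experiments. A length-2
#'   vector is treated as a range spread deterministically across the
#'   kernels of each patient.
#' @param intensity_measure `"electrode"` or `"area"` (see Details).
#' @param lat_noise_sd_ms LAT annotation noise for the simulated kernels.
#' @param n_vertices,roughness surface generator parameters.
#' @param field_mode `"smooth"` or `"plateau"` (piecewise-constant field for
#'   exact-recovery fixtures; kernels are then placed at patch centres).
#' @param seed integer root seed; the full dataset is bit-identical per seed.
#' @return a [SyntheticCohort-class].
#' @export
generateCohort <- function(n_patients = 8,
                           cycle_lengths = c(250, 300, 350, 600),
                           kernels_per_patient = 12,
                           triads_per_kernel = 42,
                           metric = c("ni", "iir"),
                           beta0 = NULL, beta1 = NULL,
                           sd_u = 0.05, sd_v = 0.02, sd_slope = 0.02,
                           sd_eps = 0.1,
                           intensity_mean = NULL, intensity_sd = NULL,
                           patch_scale_mm = 5,
                           max_area_mm2 = 80, min_edge_mm = 3,
                           catheter_scale = 1,
                           intensity_measure = c("electrode", "area"),
                           lat_noise_sd_ms = 0,
                           n_vertices = 642, roughness = 0.05,
                           field_mode = c("smooth", "plateau"),
                           seed = 1) {
  metric <- match.arg(metric)
  intensity_measure <- match.arg(intensity_measure)
  field_mode <- match.arg(field_mode)
  if (n_patients < 2) stop("n_patients must be at least 2")
  if (length(cycle_lengths) == 0) stop("cycle_lengths must be non-empty")
  if (is.null(beta0)) beta0 <- if (metric == "ni") 1.00 else 1.94
  if (is.null(beta1)) beta1 <- if (metric == "ni") -0.104 else -0.942
  if (is.null(intensity_mean)) intensity_mean <- if (metric == "ni") 1.5 else 1.15
  if (is.null(intensity_sd)) intensity_sd <- if (metric == "ni") 1.0 else 0.10
  if (beta0 <= 0) stop("beta0 must be positive")
  if (sd_eps < 0) stop("sd_eps must be >= 0")

  set.seed(.substream(seed, "effects"))
  pat_ids <- sprintf("P%02d", seq_len(n_patients))
  cl_ids <- as.character(cycle_lengths)
  u <- setNames(rnorm(n_patients, 0, sd_u), pat_ids)
  v <- setNames(rnorm(length(cycle_lengths), 0, sd_v), cl_ids)
  beta2 <- setNames(rnorm(n_patients, 0, sd_slope), pat_ids)

  qbar <- .interiorBarycentric()
  patients <- vector("list", n_patients)
  names(patients) <- pat_ids
  obs <- vector("list", n_patients)

  for (j in seq_len(n_patients)) {
    pseed <- .substream(seed, paste0("patient", j))
    mesh <- generateAtrialSurface(n_vertices = n_vertices,
                                  roughness = roughness, seed = pseed)
    plateau_centers <- if (field_mode == "plateau")
      mesh@vertices[.farthestPointSample(mesh@vertices,
                                         max(kernels_per_patient, 4L)), ,
                    drop = FALSE] else NULL
    field <- generateFibrosisField(mesh, patch_scale_mm = patch_scale_mm,
                                   ni_mean = intensity_mean,
                                   ni_sd = intensity_sd, seed = pseed + 1L,
                                   mode = field_mode,
                                   plateau_centers = plateau_centers)
    rmodel <- .radialModel(mesh, n_theta = 48L, n_phi = 96L)
    set.seed(.substream(pseed, "sites"))
    sites <- if (field_mode == "plateau") {
      # seat kernels at patch centres so intensity is constant per kernel
      ctr <- field@centers
      idx <- rep(seq_len(nrow(ctr)), length.out = kernels_per_patient)
      vapply(idx, function(i) {
        which.min(colSums((t(mesh@vertices) - ctr[i, ])^2))
      }, integer(1))
    } else sample.int(nrow(mesh@vertices), kernels_per_patient, replace = TRUE)
    scales <- if (length(catheter_scale) == 2)
      seq(catheter_scale[1], catheter_scale[2],
          length.out = kernels_per_patient)
    else rep(catheter_scale[1], kernels_per_patient)
    kernels <- vector("list", kernels_per_patient)
    obs_k <- vector("list", kernels_per_patient)
    for (k in seq_len(kernels_per_patient)) {
      kseed <- .substream(pseed, paste0("kernel", k))
      cl <- cycle_lengths[((k - 1) %% length(cycle_lengths)) + 1]
      pos <- placeCatheterKernel(mesh, sites[k], seed = kseed,
                                 scale = scales[k],
                                 max_seat_mm = 5 + 5 * scales[k],
                                 seat_check = "radial", radial_model = rmodel)
      elec_i <- evalField(field, pos)
      speed_kernel <- (beta0 + u[j] + v[as.character(cl)]) +
        (beta1 + beta2[j]) * mean(elec_i)
      # planar wave in the local tangent plane
      pb <- .planeBasis(pos)
      set.seed(.substream(kseed, "wavedir"))
      ang <- runif(1, 0, 2 * pi)
      dirw <- cos(ang) * pb$e1 + sin(ang) * pb$e2
      lat <- simulateActivation(pos, list(type = "planar", direction = dirw,
                                          speed_m_per_s = max(speed_kernel, 0.05),
                                          t0_ms = 0),
                                noise_sd_ms = lat_noise_sd_ms, seed = kseed)
      kid <- sprintf("%s_K%03d", pat_ids[j], k)
      kern <- new("Kernel", patient_id = pat_ids[j], scan_id = "S1",
                  kernel_id = kid, cycle_length_ms = cl,
                  electrode_positions = pos, lat_ms = lat,
                  contact_ok = rep(TRUE, nrow(pos)))
      kernels[[k]] <- kern
      tri <- enumerateTriads(kern, min_edge_mm = min_edge_mm,
                             max_area_mm2 = max_area_mm2)
      if (nrow(tri) == 0) next
      set.seed(.substream(kseed, "triadsample"))
      if (nrow(tri) > triads_per_kernel)
        tri <- tri[sort(sample.int(nrow(tri), triads_per_kernel)), ,
                   drop = FALSE]
      i1 <- tri$idx1; i2 <- tri$idx2; i3 <- tri$idx3
      gen_int <- (elec_i[i1] + elec_i[i2] + elec_i[i3]) / 3
      obs_int <- if (intensity_measure == "electrode") gen_int else {
        # one batched field evaluation over all quadrature points
        nq <- nrow(qbar)
        qpts <- matrix(0, nrow(tri) * nq, 3)
        for (t_ in seq_len(nrow(tri))) {
          p <- rbind(pos[i1[t_], ], pos[i2[t_], ], pos[i3[t_], ])
          qpts[(t_ - 1) * nq + seq_len(nq), ] <- qbar %*% p
        }
        qv <- evalField(field, qpts)
        colMeans(matrix(qv, nrow = nq))
      }
      set.seed(.substream(kseed, "eps"))
      cv <- (beta0 + u[j] + v[as.character(cl)]) +
        (beta1 + beta2[j]) * gen_int + rnorm(nrow(tri), 0, sd_eps)
      obs_k[[k]] <- data.frame(
        cv = cv, intensity = obs_int, metric = metric,
        patient = pat_ids[j], cycle_length = cl,
        area_mm2 = tri$area_mm2, min_edge_mm = tri$min_edge_mm,
        kernel_id = kid, scan = "S1",
        stringsAsFactors = FALSE)
    }
    patients[[j]] <- list(mesh = mesh, field = field, kernels = kernels)
    obs[[j]] <- do.call(rbind, obs_k)
  }
  observations <- do.call(rbind, obs)
  rownames(observations) <- NULL
  truth <- list(beta0 = beta0, beta1 = beta1, u = u, v = v, beta2 = beta2,
                sd_u = sd_u, sd_v = sd_v, sd_slope = sd_slope,
                sd_eps = sd_eps, metric = metric)
  config <- list(n_patients = n_patients, cycle_lengths = cycle_lengths,
                 kernels_per_patient = kernels_per_patient,
                 triads_per_kernel = triads_per_kernel, metric = metric,
                 intensity_mean = intensity_mean, intensity_sd = intensity_sd,
                 patch_scale_mm = patch_scale_mm, max_area_mm2 = max_area_mm2,
                 min_edge_mm = min_edge_mm, catheter_scale = catheter_scale,
                 intensity_measure = intensity_measure,
                 lat_noise_sd_ms = lat_noise_sd_ms, n_vertices = n_vertices,
                 roughness = roughness, field_mode = field_mode, seed = seed)
  new("SyntheticCohort", truth = truth, patients = patients,
      observations = observations, config = config)
}
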