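# End-to-end synthetic study: simulate -> perturb/register -> estimate CV ->
# map intensity -> fuse -> fit.

#' Default pipeline configuration
#'
#' All stage parameters with their defaults: triad area cut 80 mm^2,
#' electrode-surface distance filter 5 mm, 3 mm wall-sampling depth, 3 mm
#' blood-pool shrink, eta threshold 5 s/mm, 10 mm^2 area bins over
#' 0-160 mm^2, pacing cycle lengths {250, 300, 350, 600} ms, 8 patients and
#' 12 kernels per patient. The generative fixed effects default to the NI
#' association (intercept 1.00 m/s, slope -0.104 m/s per NI unit).
#'
#' @param ... named overrides of any default.
#' @return named list.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    n_patients = 8,
    cycle_lengths = c(250, 300, 350, 600),
    kernels_per_patient = 12,
    triads_per_kernel = 42,
    metric = "ni",
    beta0 = 1.00, beta1 = -0.104,
    sd_u = 0.05, sd_v = 0.02, sd_slope = 0.02, sd_eps = 0.1,
    intensity_mean = 1.5, intensity_sd = 1.0,
    patch_scale_mm = 5,
    field_mode = "smooth",
    n_vertices = 642, roughness = 0.05,
    lat_noise_sd_ms = 0,
    # imaging stage
    blood_mu = 600, blood_sd = 50,
    wall_thickness_mm = 4.5,
    spacing = c(1.25, 1.25, 2.5),
    # the phantom wall occupies the full shell, so the blood-pool shrink must
    # clear wall_thickness (real-data convention is 3 mm; see bloodPoolStats)
    shrink_mm = 6, depth_mm = 3, step_mm = 0.5,
    # registration stage
    rotation_deg = 6, translation_mm = c(3, -2, 1), jitter_sd_mm = 0,
    n_landmarks = 25,
    max_electrode_distance_mm = 5,
    # CV stage
    eta_threshold = 5, eta_direction = "above",
    min_edge_mm = 3, min_edge_rule = "tre",
    max_area_mm2 = 80, min_area_mm2 = 0,
    catheter_scale = 1,
    # area scan
    bin_width_mm2 = 10, area_range_mm2 = c(0, 160), run_area_scan = FALSE,
    seed = 1)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' Configurations round-trip losslessly; unknown keys are rejected on read.
#'
#' @param config named list from [defaultConfig()].
#' @param path YAML file path.
#' @return `writePipelineConfig` returns `path` invisibly;
#'   `readPipelineConfig` the config list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path, precision = 17)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(defaultConfig, y)
}

#' Run the full synthetic study pipeline
#'
#' Executes the complete analysis in acquisition order: cohort simulation;
#' rasterization of an LGE-like volume per patient; rigid perturbation of
#' the surface into electroanatomic-map space; ICP co-registration back to
#' the imaging surface with target registration error (TRE) on fiducial
#' vertices; electrode projection with the 5 mm distance filter; regional
#' circular-wavefront fitting with eta-based kernel rejection; triad
#' enumeration (minimum edge above the per-dataset TRE when
#' `min_edge_rule = "tre"`) and local CV triangulation; wall-intensity
#' mapping, NI/IIR normalization and per-triad area averaging; and the
#' multilevel model fit. Rerunning with an identical config yields identical
#' results.
#'
#' @param config list from [defaultConfig()].
#' @param out_dir optional directory; when given, every intermediate
#'   artifact (meshes, volumes, kernels, observations, fit, transforms,
#'   manifest) is written there.
#' @param verbose print per-stage progress.
#' @return list with `fit` (a [MixedModelFit-class]), `observations`,
#'   `registration` (per-patient TRE and transforms), `kernel_accounting`
#'   (acquired / rejected / remaining), `area_scan` (when enabled),
#'   `cohort` and `manifest`.
#' @export
runPipeline <- function(config = defaultConfig(), out_dir = NULL,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  say("stage 1/6: simulating cohort (seed %d)", config$seed)
  cohort <- generateCohort(
    n_patients = config$n_patients, cycle_lengths = config$cycle_lengths,
    kernels_per_patient = config$kernels_per_patient,
    triads_per_kernel = config$triads_per_kernel, metric = config$metric,
    beta0 = config$beta0, beta1 = config$beta1, sd_u = config$sd_u,
    sd_v = config$sd_v, sd_slope = config$sd_slope, sd_eps = config$sd_eps,
    intensity_mean = config$intensity_mean,
    intensity_sd = config$intensity_sd,
    patch_scale_mm = config$patch_scale_mm,
    max_area_mm2 = config$max_area_mm2, min_edge_mm = config$min_edge_mm,
    catheter_scale = config$catheter_scale,
    lat_noise_sd_ms = config$lat_noise_sd_ms,
    n_vertices = config$n_vertices, roughness = config$roughness,
    field_mode = config$field_mode, seed = config$seed)

  obs_rows <- list()
  registration <- list()
  acquired <- rejected <- 0L
  for (j in seq_along(cohort@patients)) {
    pid <- names(cohort@patients)[j]
    pat <- cohort@patients[[j]]
    pseed <- .substream(config$seed, paste0("pipeline", j))
    say("stage 2/6 [%s]: rasterizing volume", pid)
    vol <- rasterizeVolume(pat$mesh, pat$field, blood_mu = config$blood_mu,
                           blood_sd = config$blood_sd,
                           wall_thickness_mm = config$wall_thickness_mm,
                           spacing = config$spacing, seed = pseed)
    say("stage 3/6 [%s]: perturbing and registering surfaces", pid)
    pert <- perturbSurface(pat$mesh, rotation_deg = config$rotation_deg,
                           translation_mm = config$translation_mm,
                           jitter_sd_mm = config$jitter_sd_mm, seed = pseed)
    reg <- rigidICP(pert$mesh, pat$mesh)
    set.seed(.substream(pseed, "landmarks"))
    lm_idx <- sample.int(nrow(pat$mesh@vertices), config$n_landmarks)
    tre <- targetRegistrationError(pert$mesh@vertices[lm_idx, , drop = FALSE],
                                   pat$mesh@vertices[lm_idx, , drop = FALSE],
                                   reg$transform)
    registration[[pid]] <- list(transform = reg$transform, tre_mm = tre,
                                rms_mm = reg$rms_mm,
                                true_transform = pert$transform)
    say("stage 4/6 [%s]: intensity mapping (TRE %.2f mm)", pid, tre)
    imap <- intensitySurfaceMap(vol, pat$mesh, depth_mm = config$depth_mm,
                                step_mm = config$step_mm,
                                shrink_mm = config$shrink_mm)
    min_edge <- if (identical(config$min_edge_rule, "tre"))
      max(config$min_edge_mm, tre) else config$min_edge_mm
    say("stage 5/6 [%s]: CV estimation and fusion", pid)
    for (k in seq_along(pat$kernels)) {
      kern <- pat$kernels[[k]]
      acquired <- acquired + 1L
      # kernels live in EAM space: apply the generative perturbation, then
      # map them back with the recovered registration
      eam_pos <- applyTransform(pert$transform, kern@electrode_positions)
      mri_pos <- applyTransform(reg$transform, eam_pos)
      wf <- tryCatch(fitCircularWavefront(
        new("Kernel", patient_id = kern@patient_id, scan_id = kern@scan_id,
            kernel_id = kern@kernel_id,
            cycle_length_ms = kern@cycle_length_ms,
            electrode_positions = mri_pos, lat_ms = kern@lat_ms,
            contact_ok = kern@contact_ok)),
        error = function(e) NULL)
      if (is.null(wf)) { rejected <- rejected + 1L; next }
      part <- rejectKernels(list(wf), eta_threshold = config$eta_threshold,
                            direction = config$eta_direction)
      if (!part$keep[1]) { rejected <- rejected + 1L; next }
      proj <- projectElectrodes(mri_pos, pat$mesh,
                                max_distance_mm = config$max_electrode_distance_mm)
      kern2 <- new("Kernel", patient_id = kern@patient_id,
                   scan_id = kern@scan_id, kernel_id = kern@kernel_id,
                   cycle_length_ms = kern@cycle_length_ms,
                   electrode_positions = mri_pos, lat_ms = kern@lat_ms,
                   contact_ok = kern@contact_ok & proj$keep)
      tri <- enumerateTriads(kern2, min_edge_mm = min_edge,
                             max_area_mm2 = config$max_area_mm2)
      if (config$min_area_mm2 > 0)
        tri <- tri[tri$area_mm2 >= config$min_area_mm2, , drop = FALSE]
      if (nrow(tri) == 0) next
      set.seed(.substream(pseed, paste0("triads", k)))
      if (nrow(tri) > config$triads_per_kernel)
        tri <- tri[sort(sample.int(nrow(tri), config$triads_per_kernel)), ,
                   drop = FALSE]
      tri <- triadCVTable(kern2, tri)
      tri <- tri[is.finite(tri$cv_m_per_s), , drop = FALSE]
      if (nrow(tri) == 0) next
      intens <- vapply(seq_len(nrow(tri)), function(t_) {
        tp <- proj$projected[c(tri$idx1[t_], tri$idx2[t_], tri$idx3[t_]), ,
                             drop = FALSE]
        triadMeanIntensity(tp, pat$mesh, imap, metric = config$metric)
      }, numeric(1))
      obs_rows[[length(obs_rows) + 1L]] <- data.frame(
        cv = tri$cv_m_per_s, intensity = intens, metric = config$metric,
        patient = pid, cycle_length = kern@cycle_length_ms,
        area_mm2 = tri$area_mm2, min_edge_mm = tri$min_edge_mm,
        kernel_id = kern@kernel_id, scan = "S1", stringsAsFactors = FALSE)
    }
    if (!is.null(out_dir)) {
      writeMeshPLY(pat$mesh, file.path(out_dir, paste0(pid, "_mri.ply")))
      writeMeshPLY(pert$mesh, file.path(out_dir, paste0(pid, "_eam.ply")))
      writeVolumeNIfTI(vol, file.path(out_dir, paste0(pid, "_lge.nii.gz")))
      writeTransformYAML(reg$transform,
                         file.path(out_dir, paste0(pid, "_transform.yaml")))
      writeKernelCSV(pat$kernels, file.path(out_dir, paste0(pid, "_kernels.csv")))
    }
  }
  observations <- do.call(rbind, obs_rows)
  say("stage 6/6: multilevel model fit (%d observations)", nrow(observations))
  fit <- fitMultilevel(observations, metric = config$metric)
  area_scan <- NULL
  if (isTRUE(config$run_area_scan))
    area_scan <- areaBinnedSlopes(observations,
                                  bin_width_mm2 = config$bin_width_mm2,
                                  range_mm2 = config$area_range_mm2,
                                  metric = config$metric)
  manifest <- list(
    package_version = as.character(utils::packageVersion("AtrialCV")),
    config = config,
    kernels = list(acquired = acquired, rejected = rejected,
                   remaining = acquired - rejected),
    n_observations = nrow(observations),
    tre_mm = vapply(registration, function(r) r$tre_mm, numeric(1)),
    fit = list(beta0 = fit@beta0, beta1 = fit@beta1, loglik = fit@loglik))
  if (!is.null(out_dir)) {
    writeObservationCSV(observations, file.path(out_dir, "observations.csv"))
    writeFitJSON(fit, file.path(out_dir, "fit.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(fit = fit, observations = observations, registration = registration,
       kernel_accounting = manifest$kernels, area_scan = area_scan,
       cohort = cohort, manifest = manifest)
}
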