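# Synthetic-data generator: surfaces, fields, volumes, catheters, activation.

test_that("zero-roughness surface is an exact closed ellipsoid", {
  sa <- c(20.5, 16.5, 14)
  m <- generateAtrialSurface(500, roughness = 0, seed = 1, semi_axes = sa)
  expect_true(isClosedManifold(m))
  resid <- abs(rowSums(sweep(vertices(m), 2, sa, `/`)^2) - 1)
  expect_lt(max(resid), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(normals(m)^2)) - 1)), 1e-6)
})

test_that("surface generation is deterministic and genus 0 under roughness", {
  m1 <- generateAtrialSurface(500, roughness = 0.1, seed = 2)
  m2 <- generateAtrialSurface(500, roughness = 0.1, seed = 2)
  expect_identical(vertices(m1), vertices(m2))
  expect_identical(faces(m1), faces(m2))
  expect_identical(eulerCharacteristic(m1), 2L)
  expect_true(isClosedManifold(m1))
  expect_error(generateAtrialSurface(50), "n_vertices")
})

test_that("fibrosis field matches requested moments and correlation scale", {
  m <- generateAtrialSurface(2500, roughness = 0.05, seed = 3)
  f0 <- generateFibrosisField(m, 5, ni_mean = 1.2, ni_sd = 0, seed = 3)
  expect_true(all(f0@values == 1.2))

  f <- generateFibrosisField(m, 5, ni_mean = 1.5, ni_sd = 1, seed = 3)
  expect_lt(abs(mean(f@values) - 1.5), 0.15)
  expect_lt(abs(sd(f@values) - 1), 0.1)
  # empirical spatial autocorrelation: 5 mm lag beats 20 mm lag
  v <- vertices(m)
  set.seed(1)
  idx <- sample(nrow(v), 1200)
  d <- as.matrix(dist(v[idx, ]))
  z <- f@values[idx] - mean(f@values[idx])
  corr_at <- function(lag, tol = 1) {
    sel <- which(abs(d - lag) < tol & upper.tri(d), arr.ind = TRUE)
    mean(z[sel[, 1]] * z[sel[, 2]]) / var(z)
  }
  expect_gt(corr_at(5), corr_at(20))

  # different seeds: different fields, matching calibrated moments
  g <- generateFibrosisField(m, 5, ni_mean = 1.5, ni_sd = 1, seed = 4)
  expect_false(isTRUE(all.equal(f@values, g@values)))
  expect_lt(abs(mean(g@values) - mean(f@values)), 1e-9)
  expect_lt(abs(sd(g@values) - sd(f@values)), 1e-9)
})

test_that("rasterized volume carries the NI-encoded wall and blood pool", {
  m <- generateAtrialSurface(642, roughness = 0, seed = 5)
  # field identically 0 and noiseless blood: wall raw values equal blood_mu
  vol <- rasterizeVolume(m, rep(0, nrow(vertices(m))), blood_mu = 500,
                         blood_sd = 0, wall_thickness_mm = 3,
                         spacing = c(1.5, 1.5, 1.5), seed = 1)
  vx <- as.numeric(vol@voxels)
  expect_true(all(vx %in% c(0, 500)))
  expect_gt(sum(vx == 500), 1000)
  expect_error(rasterizeVolume(m, rep(0, nrow(vertices(m))),
                               spacing = c(100, 100, 100)),
               "spacing")
})

test_that("rasterize / sample / normalize round-trip recovers the field", {
  m <- generateAtrialSurface(2500, roughness = 0.04, seed = 5)
  f <- generateFibrosisField(m, 5, 1.5, 1, seed = 6)
  vol <- rasterizeVolume(m, f, blood_mu = 600, blood_sd = 50,
                         wall_thickness_mm = 4.5, spacing = c(1, 1, 1),
                         seed = 7)
  bp <- bloodPoolStats(vol, m, shrink_mm = 6)
  raw <- sampleWallIntensity(vol, m, depth_mm = 3, step_mm = 0.5)
  ni <- normalizeNI(raw, bp)
  rmse <- sqrt(mean((ni - f@values)^2, na.rm = TRUE))
  expect_lt(rmse, 0.25)
})

test_that("catheter template is exact in the flat limit and seats on the atrium", {
  plane <- flatPatchMesh()
  pos <- placeCatheterKernel(plane, c(0, 0, 0), seed = 4, seat_check = "none")
  expect_identical(dim(pos), c(20L, 3L))
  expect_lt(max(abs(pos[, 3])), 1e-9)                   # coplanar
  gaps <- sqrt(rowSums(diff(pos)^2))
  expect_lt(max(abs(gaps - 4)), 1e-9)                   # 4 mm spacing
  d <- as.matrix(dist(pos))
  expect_gt(min(d[upper.tri(d)]), 0)                    # pairwise distinct

  m <- generateAtrialSurface(642, roughness = 0.05, seed = 6)
  pos2 <- placeCatheterKernel(m, 10, seed = 7, seat_check = "exact")
  pr <- projectElectrodes(pos2, m)
  expect_lt(max(pr$distance_mm), 5)
  # high curvature: a tiny surface cannot seat the loops
  tiny <- generateAtrialSurface(500, roughness = 0, seed = 1,
                                semi_axes = c(5, 4, 3.5))
  expect_error(placeCatheterKernel(tiny, 1, seat_check = "exact"), "seat")
})

test_that("kinematic activation has the closed-form times and symmetries", {
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 7, 0))
  lat <- simulateActivation(pos, list(type = "planar", direction = c(1, 0, 0),
                                      speed_m_per_s = 1, t0_ms = 0))
  expect_equal(lat, c(0, 10, 0), tolerance = 1e-12)
  # two electrodes equidistant from a circular origin share the LAT
  latc <- simulateActivation(rbind(c(5, 0, 0), c(-5, 0, 0), c(0, 5, 0)),
                             list(type = "circular", origin = c(0, 0, 0),
                                  speed_m_per_s = 0.5, t0_ms = 2))
  expect_equal(latc[1], latc[2])
  expect_equal(latc[1], latc[3])
  expect_error(simulateActivation(pos, list(type = "planar",
                                            direction = c(1, 0, 0),
                                            speed_m_per_s = 0)), "positive")
})

test_that("surface perturbation records its transform exactly", {
  m <- generateAtrialSurface(642, roughness = 0.1, seed = 8)
  p0 <- perturbSurface(m, rotation_deg = 0, translation_mm = c(0, 0, 0),
                       jitter_sd_mm = 0)
  expect_equal(vertices(p0$mesh), vertices(m), tolerance = 1e-12)
  p <- perturbSurface(m, rotation_deg = 10, translation_mm = c(3, 0, 0),
                      jitter_sd_mm = 0, seed = 8)
  back <- applyTransform(invertTransform(p$transform), vertices(p$mesh))
  expect_lt(max(abs(back - vertices(m))), 1e-9)
})

test_that("cohort generation is deterministic and honours the generative model", {
  c1 <- generateCohort(n_patients = 2, kernels_per_patient = 3,
                       triads_per_kernel = 10, seed = 4)
  c2 <- generateCohort(n_patients = 2, kernels_per_patient = 3,
                       triads_per_kernel = 10, seed = 4)
  expect_identical(observations(c1), observations(c2))
  expect_identical(vertices(c1@patients[[1]]$mesh),
                   vertices(c2@patients[[1]]$mesh))

  # all variance components zero: observations sit exactly on the line
  c0 <- generateCohort(n_patients = 2, kernels_per_patient = 3,
                       triads_per_kernel = 10, sd_u = 0, sd_v = 0,
                       sd_slope = 0, sd_eps = 0, seed = 5)
  obs <- observations(c0)
  expect_lt(max(abs(obs$cv - (1.0 - 0.104 * obs$intensity))), 1e-9)

  expect_error(generateCohort(cycle_lengths = numeric(0)), "cycle_lengths")
  expect_error(generateCohort(n_patients = 1), "n_patients")
})

test_that("per-patient intercept spread matches its hyperparameter", {
  # Monte-Carlo check of u_j ~ N(0, 0.05): with many patients the empirical
  # SD of realized per-patient intercept deviations approaches 0.05 m/s
  coh <- generateCohort(n_patients = 50, kernels_per_patient = 2,
                        triads_per_kernel = 12, cycle_lengths = c(300, 600),
                        sd_u = 0.05, seed = 6)
  expect_lt(abs(sd(cohortTruth(coh)$u) - 0.05) / 0.05, 0.5)
  obs <- observations(coh)
  tr <- cohortTruth(coh)
  # residual intercept per patient after removing the known slope/CL parts
  resid <- obs$cv - (tr$beta1 + tr$beta2[obs$patient]) * obs$intensity -
    tr$v[as.character(obs$cycle_length)] - tr$beta0
  per_pat <- tapply(resid, obs$patient, mean)
  expect_lt(abs(sd(per_pat) - 0.05) / 0.05, 0.5)
})
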