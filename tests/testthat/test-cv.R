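# LAT annotation, triad triangulation, triad enumeration, circular
# wavefront fitting and eta-based kernel rejection.

test_that("LAT annotation finds the steepest negative deflection", {
  fs <- 1000  # 1 kHz -> 1 ms sampling
  t <- seq(0, 80, by = 1)
  # biphasic wave whose maximum negative slope is analytically at t = 41 ms
  sig <- -tanh((t - 41) / 2)
  expect_lt(abs(annotateLAT(sig, fs) - 41), 0.5)

  # pure down-ramp: every interior slope ties; the midpoint rule documents it
  ramp <- -t
  lat <- annotateLAT(ramp, fs)
  expect_equal(lat, mean(t[c(2, length(t) - 1)]), tolerance = 1e-9)

  expect_error(annotateLAT(rep(1, 50), fs), "no negative deflection")
  expect_error(annotateLAT(seq(0, 5, length.out = 50), fs),
               "no negative deflection")
  expect_error(annotateLAT(c(1, 0), fs), "3 samples")
})

test_that("triad CV solves the plane-wave closed form", {
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  res <- triadCV(pos, c(0, 10, 0))
  expect_equal(res$speed_m_per_s, 1.0, tolerance = 1e-12)
  expect_equal(res$direction, c(1, 0, 0), tolerance = 1e-12)

  # frame invariance: rigid rotation leaves speed unchanged, rotates direction
  p <- perturbSurface(generateAtrialSurface(500, seed = 1),
                      rotation_deg = 33, translation_mm = c(5, -2, 7))
  res2 <- triadCV(applyTransform(p$transform, pos), c(0, 10, 0))
  expect_equal(res2$speed_m_per_s, 1.0, tolerance = 1e-9)
  expect_equal(res2$direction,
               as.numeric(p$transform@rotation %*% res$direction),
               tolerance = 1e-9)

  # scale covariance: k times the LAT differences divides the speed by k
  res3 <- triadCV(pos, c(0, 30, 0))
  expect_equal(res3$speed_m_per_s, res$speed_m_per_s / 3, tolerance = 1e-12)

  expect_error(triadCV(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)),
                       c(0, 1, 2)), "collinear")
  res4 <- triadCV(pos, c(1, 1, 1))
  expect_true(is.na(res4$speed_m_per_s))
  expect_identical(res4$rejected, "infinite-speed")
})

test_that("triad CV is exact on 500 random noise-free planar waves", {
  set.seed(42)
  worst <- 0
  for (i in 1:500) {
    tr <- randomPlanarTriad()
    res <- triadCV(tr$positions, tr$lats)
    worst <- max(worst, abs(res$speed_m_per_s - tr$speed))
  }
  expect_lt(worst, 1e-9)
})

test_that("triad enumeration matches combinatorics and a brute-force filter", {
  plane <- flatPatchMesh()
  pos <- placeCatheterKernel(plane, c(0, 0, 0), seed = 1, seat_check = "none")
  lat <- simulateActivation(pos, list(type = "planar", direction = c(1, 0, 0),
                                      speed_m_per_s = 1))
  k <- makeKernel(pos, lat)
  expect_identical(nrow(enumerateTriads(k)), 1140L)           # C(20, 3)
  expect_identical(nrow(enumerateTriads(k, min_edge_mm = 30)), 0L)

  tri <- enumerateTriads(k, min_edge_mm = 5, max_area_mm2 = 40)
  expect_lte(nrow(tri), choose(20, 3))
  # independent brute force over all combinations
  combos <- t(combn(20, 3))
  n_keep <- 0L
  for (r in seq_len(nrow(combos))) {
    p <- pos[combos[r, ], ]
    e <- c(sqrt(sum((p[2, ] - p[1, ])^2)), sqrt(sum((p[3, ] - p[1, ])^2)),
           sqrt(sum((p[3, ] - p[2, ])^2)))
    s <- (e[1] + e[2] + e[3]) / 2
    area <- sqrt(max(s * (s - e[1]) * (s - e[2]) * (s - e[3]), 0))  # Heron
    if (min(e) > 5 && area < 40) n_keep <- n_keep + 1L
  }
  expect_identical(nrow(tri), n_keep)
  # missing LATs shrink the eligible electrode set
  k2 <- makeKernel(pos, replace(lat, 1:4, NA),
                   contact = c(rep(FALSE, 4), rep(TRUE, 16)))
  expect_identical(nrow(enumerateTriads(k2)), as.integer(choose(16, 3)))
})

test_that("circular wavefront fit recovers noise-free parameters", {
  plane <- flatPatchMesh()
  pos <- placeCatheterKernel(plane, c(0, 0, 0), seed = 2, seat_check = "none")
  origin <- c(25, 10, 0)
  v <- 0.8
  lat <- simulateActivation(pos, list(type = "circular", origin = origin,
                                      speed_m_per_s = v, t0_ms = 3))
  wf <- fitCircularWavefront(makeKernel(pos, lat))
  expect_lt(abs(wf@speed_m_per_s - v), 1e-6)
  expect_lt(sqrt(sum((wf@origin - origin)^2)), 1e-3)
  expect_lt(abs(wf@onset_ms - 3), 1e-6)
  expect_lt(wf@eta, 1e-9)
  # radius = v * (median LAT - t0)
  expect_equal(wf@radius_mm, v * (median(lat) - wf@onset_ms), tolerance = 1e-6)

  # planar wave: the limiting fit has a huge radius and near-zero residual
  latp <- simulateActivation(pos, list(type = "planar", direction = c(0, 1, 0),
                                       speed_m_per_s = 1))
  wfp <- fitCircularWavefront(makeKernel(pos, latp))
  expect_gt(wfp@radius_mm, 200)
  expect_lt(wfp@eta, 1e-6)

  # permuting LATs across electrodes destroys wavefront smoothness
  set.seed(3)
  wfperm <- fitCircularWavefront(makeKernel(pos, sample(lat)))
  expect_gt(wfperm@eta, wf@eta)
  expect_error(fitCircularWavefront(makeKernel(pos[1:4, ], lat[1:4])),
               "5 electrodes")
})

test_that("local triad CVs cohere with the regional circular fit", {
  plane <- flatPatchMesh()
  pos <- placeCatheterKernel(plane, c(0, 0, 0), seed = 4, seat_check = "none")
  lat <- simulateActivation(pos, list(type = "circular", origin = c(30, -5, 0),
                                      speed_m_per_s = 0.9, t0_ms = 0))
  k <- makeKernel(pos, lat)
  wf <- fitCircularWavefront(k)
  tri <- triadCVTable(k, enumerateTriads(k, min_edge_mm = 4))
  local_mean <- mean(tri$cv_m_per_s, na.rm = TRUE)
  expect_lt(abs(local_mean - wf@speed_m_per_s) / wf@speed_m_per_s, 0.02)
})

test_that("kernel rejection partitions by eta with the documented boundary rule", {
  mk <- function(eta) new("WavefrontFit", origin = c(0, 0, 0), onset_ms = 0,
                          speed_m_per_s = 1, radius_mm = 10, eta = eta,
                          accepted = NA, converged = TRUE)
  fits <- lapply(c(0, 0, 0), mk)
  expect_true(all(rejectKernels(fits)$keep))
  # exactly at the threshold: accepted (rejection is strict)
  expect_true(rejectKernels(list(mk(5)), eta_threshold = 5)$keep)
  expect_false(rejectKernels(list(mk(5.0001)), eta_threshold = 5)$keep)
  # mixed set equals the element-wise filter; literal direction inverts it
  etas <- c(0.1, 7, 5, 2, 12)
  part <- rejectKernels(lapply(etas, mk), eta_threshold = 5)
  expect_identical(part$keep, etas <= 5)
  expect_identical(length(part$accepted) + length(part$rejected), 5L)
  part_lit <- rejectKernels(lapply(etas, mk), eta_threshold = 5,
                            direction = "below")
  expect_identical(part_lit$keep, etas >= 5)
})
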