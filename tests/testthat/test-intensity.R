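# Blood-pool statistics, wall sampling, NI/IIR normalization, triad-area
# intensity averaging.

test_that("blood-pool statistics summarize the chamber interior", {
  m <- generateAtrialSurface(642, roughness = 0, seed = 1)
  # constant interior: zero-variance flag raised
  volc <- constantVolume(m, 400)
  bp <- bloodPoolStats(volc, m, shrink_mm = 3)
  expect_equal(bp@mu_bp, 400)
  expect_identical(bp@sigma_bp, 0)
  expect_true(bp@zero_variance)

  # Monte-Carlo: Normal(600, 50) interior recovered within +/- 2
  voln <- constantVolume(m, 0)
  set.seed(2)
  voln@voxels[] <- rnorm(length(voln@voxels), 600, 50)
  bpn <- bloodPoolStats(voln, m, shrink_mm = 3)
  expect_gt(bpn@n_voxels, 1e4)
  expect_lt(abs(bpn@mu_bp - 600), 2)
  expect_lt(abs(bpn@sigma_bp - 50), 2)

  # shrink beyond the inradius: no interior left
  expect_error(bloodPoolStats(voln, m, shrink_mm = 14.5),
               "insufficient blood pool|inradius")
})

test_that("wall sampling takes the max along the inward normal", {
  m <- generateAtrialSurface(642, roughness = 0, seed = 3)
  vol <- constantVolume(m, 100, spacing = c(0.6, 0.6, 0.6))
  raw <- sampleWallIntensity(vol, m, depth_mm = 3, step_mm = 0.5)
  expect_true(all(abs(raw - 100) < 1e-9))

  # a bright blob 2 mm along one vertex's inward normal is picked up; the
  # same blob 4 mm deep at another vertex is out of the 3 mm reach
  to_idx <- function(p) round((p - vol@origin) / vol@spacing) + 1
  blob <- function(vox, center_idx, val) {
    rng <- lapply(center_idx, function(c) (c - 1):(c + 1))
    vox[rng[[1]], rng[[2]], rng[[3]]] <- val
    vox
  }
  v1 <- 5L; v2 <- 200L
  p1 <- vertices(m)[v1, ] - 2 * normals(m)[v1, ]
  p2 <- vertices(m)[v2, ] - 4 * normals(m)[v2, ]
  vol@voxels <- blob(vol@voxels, to_idx(p1), 900)
  vol@voxels <- blob(vol@voxels, to_idx(p2), 900)
  raw2 <- sampleWallIntensity(vol, m, depth_mm = 3, step_mm = 0.25)
  expect_gt(raw2[v1], 850)
  expect_lt(raw2[v2], 500)

  # monotone in depth: deeper sampling never decreases any vertex value
  raw3 <- sampleWallIntensity(vol, m, depth_mm = 4.5, step_mm = 0.25)
  expect_true(all(raw3 - raw2 >= -1e-12, na.rm = TRUE))
})

test_that("NI and IIR follow their definitions and invariances", {
  bp <- new("BloodPoolStats", mu_bp = 600, sigma_bp = 50, n_voxels = 1000L,
            zero_variance = FALSE)
  expect_identical(normalizeNI(600, bp), 0)
  expect_identical(normalizeNI(700, bp), 2)
  expect_identical(normalizeIIR(600, bp), 1)
  expect_identical(normalizeIIR(0, bp), 0)
  bp0 <- new("BloodPoolStats", mu_bp = 600, sigma_bp = 0, n_voxels = 1000L,
             zero_variance = TRUE)
  expect_error(normalizeNI(1, bp0), "zero intensity variance")
  bpneg <- new("BloodPoolStats", mu_bp = 0, sigma_bp = 10, n_voxels = 10L,
               zero_variance = FALSE)
  expect_error(normalizeIIR(1, bpneg), "not positive")

  # NI is invariant under positive affine volume transforms; IIR only
  # under pure gain (the dynamic-range argument for preferring NI)
  m <- generateAtrialSurface(642, roughness = 0.05, seed = 4)
  f <- generateFibrosisField(m, 5, 1.5, 1, seed = 5)
  vol <- rasterizeVolume(m, f, 600, 50, 4.5, c(1, 1, 1), seed = 6)
  map1 <- intensitySurfaceMap(vol, m, shrink_mm = 6)
  a <- 1.7; b <- 120
  vol2 <- vol; vol2@voxels <- a * vol@voxels + b
  map2 <- intensitySurfaceMap(vol2, m, shrink_mm = 6)
  expect_lt(max(abs(map2@ni - map1@ni), na.rm = TRUE), 1e-9)
  expect_gt(max(abs(map2@iir - map1@iir), na.rm = TRUE), 0.01)
  vol3 <- vol; vol3@voxels <- a * vol@voxels        # pure gain
  map3 <- intensitySurfaceMap(vol3, m, shrink_mm = 6)
  expect_lt(max(abs(map3@iir - map1@iir), na.rm = TRUE), 1e-9)

  # the two metrics are linked vertex-wise: iir = 1 + ni * sigma/mu
  s <- map1@stats
  expect_lt(max(abs(map1@iir - (1 + map1@ni * s@sigma_bp / s@mu_bp)),
                na.rm = TRUE), 1e-9)
})

test_that("triad-area averaging integrates the per-vertex map", {
  plane <- flatPatchMesh(half_mm = 25, n = 41)
  nv <- nrow(vertices(plane))
  bp <- new("BloodPoolStats", mu_bp = 100, sigma_bp = 10, n_voxels = 100L,
            zero_variance = FALSE)
  mkmap <- function(raw) new("IntensitySurfaceMap", raw = raw,
                             ni = (raw - 100) / 10, iir = raw / 100,
                             stats = bp)
  tripos <- rbind(c(-10, -8, 0), c(12, -6, 0), c(0, 12, 0))

  # constant field: any triad averages to the constant
  mapc <- mkmap(rep(130, nv))
  expect_equal(triadMeanIntensity(tripos, plane, mapc, "ni"), 3,
               tolerance = 1e-12)
  expect_equal(triadMeanIntensity(tripos, plane, mapc, "iir"), 1.3,
               tolerance = 1e-12)

  # linear ramp: the area mean equals the centroid value (analytic integral
  # of a linear field over a triangle), up to mesh discretization
  rawlin <- 100 + 2 * vertices(plane)[, 1] + 1 * vertices(plane)[, 2]
  maplin <- mkmap(rawlin)
  centroid <- colMeans(tripos)
  expected <- (2 * centroid[1] + 1 * centroid[2]) / 10
  got <- triadMeanIntensity(tripos, plane, maplin, "ni")
  expect_lt(abs(got - expected), 0.2)

  # micro-triad below the mesh resolution: documented 3-vertex fallback
  micro <- rbind(c(0.1, 0.1, 0), c(0.4, 0.1, 0), c(0.2, 0.35, 0))
  gotm <- triadMeanIntensity(micro, plane, maplin, "ni")
  near <- sapply(1:3, function(i)
    which.min(colSums((t(vertices(plane)) - micro[i, ])^2)))
  expect_equal(gotm, mean(maplin@ni[near]), tolerance = 1e-12)
})
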