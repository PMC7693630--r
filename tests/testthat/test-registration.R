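# Rigid ICP, target registration error, electrode projection.

test_that("ICP returns the identity for self-registration", {
  m <- generateAtrialSurface(642, roughness = 0.1, seed = 1)
  reg <- rigidICP(m, m)
  expect_lt(reg$rms_mm, 1e-9)
  expect_lt(max(abs(reg$transform@rotation - diag(3))), 1e-9)
  expect_lt(max(abs(reg$transform@translation)), 1e-9)
})

test_that("ICP inverts a known rigid perturbation to machine precision", {
  m <- generateAtrialSurface(642, roughness = 0.1, seed = 2)
  p <- perturbSurface(m, rotation_deg = 10, translation_mm = c(3, 0, 0),
                      jitter_sd_mm = 0, seed = 3)
  reg <- rigidICP(p$mesh, m)
  expect_lt(reg$rms_mm, 1e-6)
  # group property: recovered o generative = identity
  comp <- composeTransforms(reg$transform, p$transform)
  expect_lt(max(abs(comp@rotation - diag(3))), 1e-6)
  expect_lt(max(abs(comp@translation)), 1e-6)
  # RMS trace is monotone non-increasing
  expect_true(all(diff(reg$rms_trace) <= 1e-12))
})

test_that("residual RMS under vertex jitter scales with the jitter SD", {
  m <- generateAtrialSurface(642, roughness = 0.1, seed = 4)
  p <- perturbSurface(m, rotation_deg = 5, translation_mm = c(2, 1, 0),
                      jitter_sd_mm = 1, seed = 5)
  reg <- rigidICP(p$mesh, m)
  expect_gt(reg$rms_mm, 0.5)
  expect_lt(reg$rms_mm, 2)
  # TRE consistent with the jitter scale (about sd * sqrt(2) from two noisy
  # endpoints, inflated by the nearest-vertex bias absorbed during ICP)
  set.seed(6)
  idx <- sample(nrow(vertices(m)), 50)
  tre <- targetRegistrationError(vertices(p$mesh)[idx, ],
                                 vertices(m)[idx, ], reg$transform)
  expect_gt(tre, 0.5)
  expect_lt(tre, 3)
  expect_error(rigidICP(flatPatchMesh(), m), "degenerate")
})

test_that("TRE equals the RMS landmark mismatch", {
  id <- new("RigidTransform", rotation = diag(3), translation = c(0, 0, 0))
  pts <- matrix(rnorm(30), 10)
  expect_identical(targetRegistrationError(pts, pts, id), 0)
  # single pair offset by 3 mm
  expect_equal(targetRegistrationError(matrix(c(0, 0, 0), 1),
                                       matrix(c(3, 0, 0), 1), id), 3)
  # brute-force RMS oracle on random pairs under a random rigid transform
  set.seed(7)
  mv <- matrix(rnorm(45, 0, 10), 15)
  fx <- matrix(rnorm(45, 0, 10), 15)
  p <- perturbSurface(generateAtrialSurface(500, seed = 1),
                      rotation_deg = 25, translation_mm = c(1, -4, 2))
  tr <- p$transform
  moved <- t(tr@rotation %*% t(mv)) + matrix(tr@translation, 15, 3, byrow = TRUE)
  oracle <- sqrt(mean(rowSums((moved - fx)^2)))
  expect_equal(targetRegistrationError(mv, fx, tr), oracle, tolerance = 1e-12)
  expect_error(targetRegistrationError(mv[0, , drop = FALSE],
                                       fx[0, , drop = FALSE], tr), "landmark")
})

test_that("electrode projection matches an exhaustive face search and drops at 5 mm", {
  m <- generateAtrialSurface(500, roughness = 0.08, seed = 8)
  # an electrode exactly on a vertex projects to itself
  v7 <- vertices(m)[7, , drop = FALSE]
  pr <- projectElectrodes(v7, m)
  expect_lt(max(abs(pr$projected - v7)), 1e-12)
  expect_lt(pr$distance_mm, 1e-12)
  # 6 mm off-surface along the normal: dropped
  off6 <- v7 + 6 * normals(m)[7, , drop = FALSE]
  off4 <- v7 + 4 * normals(m)[7, , drop = FALSE]
  pr2 <- projectElectrodes(rbind(off6, off4), m)
  expect_identical(pr2$keep, c(FALSE, TRUE))
  # exhaustive oracle: dense barycentric sampling of every face (independent
  # of the analytic closest-point code; distance is 1-Lipschitz so the grid
  # bounds the error by its own spacing)
  set.seed(9)
  pts <- matrix(rnorm(15, 0, 12), 5)
  pr3 <- projectElectrodes(pts, m)
  v <- vertices(m); f <- faces(m)
  g <- expand.grid(a = seq(0, 1, by = 1 / 40), b = seq(0, 1, by = 1 / 40))
  g <- g[g$a + g$b <= 1, ]
  bary <- cbind(g$a, g$b, 1 - g$a - g$b)
  for (i in seq_len(nrow(pts))) {
    dmin <- Inf
    for (k in seq_len(nrow(f))) {
      tri <- v[f[k, ], , drop = FALSE]
      samp <- bary %*% tri
      dmin <- min(dmin, sqrt(min(colSums((t(samp) - pts[i, ])^2))))
    }
    expect_equal(pr3$distance_mm[i], dmin, tolerance = 0.02)
    expect_lte(pr3$distance_mm[i], dmin + 1e-9)
  }
  # projection idempotence
  pr4 <- projectElectrodes(pr3$projected, m)
  expect_lt(max(abs(pr4$projected - pr3$projected)), 1e-9)
})
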