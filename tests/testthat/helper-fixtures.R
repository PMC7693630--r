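# Fixtures built in code: meshes, kernels, volumes.

# A flat rectangular patch mesh in the z = 0 plane (open; used for the
# flat-limit catheter and projection tests).
flatPatchMesh <- function(half_mm = 25, n = 21) {
  ax <- seq(-half_mm, half_mm, length.out = n)
  g <- expand.grid(x = ax, y = ax)
  v <- cbind(g$x, g$y, 0)
  idx <- function(i, j) (j - 1L) * n + i
  f <- NULL
  for (j in seq_len(n - 1)) for (i in seq_len(n - 1)) {
    f <- rbind(f,
               c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
               c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  new("SurfaceMesh", vertices = v, faces = f,
      normals = matrix(rep(c(0, 0, 1), nrow(v)), ncol = 3, byrow = TRUE))
}

makeKernel <- function(positions, lats, contact = rep(TRUE, nrow(positions)),
                       cl = 300, id = "K1") {
  new("Kernel", patient_id = "P01", scan_id = "S1", kernel_id = id,
      cycle_length_ms = cl, electrode_positions = positions,
      lat_ms = lats, contact_ok = contact)
}

# Uniform-intensity volume covering a mesh with padding.
constantVolume <- function(mesh, value, spacing = c(1, 1, 1), pad = 6) {
  ext <- apply(mesh@vertices, 2, range)
  origin <- ext[1, ] - pad
  dims <- ceiling((diff(ext) + 2 * pad) / spacing) + 1L
  new("IntensityVolume", voxels = array(value, dim = dims),
      spacing = spacing, origin = origin)
}

# Random non-degenerate triad in a random 3D plane together with an in-plane
# planar wave; returns positions, lats and the generative speed.
randomPlanarTriad <- function() {
  repeat {
    b <- qr.Q(qr(matrix(rnorm(9), 3)))  # random orthonormal frame
    e1 <- b[, 1]; e2 <- b[, 2]
    cen <- rnorm(3, 0, 20)
    xy <- matrix(runif(6, -8, 8), 3)
    pos <- matrix(cen, 3, 3, byrow = TRUE) + xy[, 1] %o% e1 + xy[, 2] %o% e2
    ed <- rbind(pos[2, ] - pos[1, ], pos[3, ] - pos[2, ], pos[1, ] - pos[3, ])
    len <- sqrt(rowSums(ed^2))
    if (min(len) < 1) next
    ang <- acos(pmin(pmax(
      c(sum(-ed[3, ] * ed[1, ]), sum(-ed[1, ] * ed[2, ]),
        sum(-ed[2, ] * ed[3, ])) / c(len[3] * len[1], len[1] * len[2],
                                     len[2] * len[3]), -1), 1))
    if (min(ang) < 8 * pi / 180) next
    th <- runif(1, 0, 2 * pi)
    dirw <- cos(th) * e1 + sin(th) * e2
    v <- runif(1, 0.3, 1.5)
    lats <- simulateActivation(pos, list(type = "planar", direction = dirw,
                                         speed_m_per_s = v, t0_ms = runif(1, 0, 10)))
    return(list(positions = pos, lats = lats, speed = v, direction = dirw))
  }
}

# Observation rows for one patient by running the measurement chain against a
# supplied volume (used by the two-scan reproducibility tests).
measureObservations <- function(patient, pid, volume, metric,
                                shrink_mm = 6, max_area = 80, min_edge = 3,
                                n_triads = 20) {
  imap <- intensitySurfaceMap(volume, patient$mesh, shrink_mm = shrink_mm)
  rows <- list()
  for (k in patient$kernels) {
    proj <- projectElectrodes(electrodePositions(k), patient$mesh)
    k2 <- new("Kernel", patient_id = k@patient_id, scan_id = k@scan_id,
              kernel_id = k@kernel_id, cycle_length_ms = k@cycle_length_ms,
              electrode_positions = k@electrode_positions,
              lat_ms = k@lat_ms, contact_ok = k@contact_ok & proj$keep)
    tri <- enumerateTriads(k2, min_edge, max_area)
    if (nrow(tri) == 0) next
    tri <- tri[seq(1, nrow(tri), length.out = min(n_triads, nrow(tri))), ]
    tri <- triadCVTable(k2, tri)
    tri <- tri[is.finite(tri$cv_m_per_s), , drop = FALSE]
    if (nrow(tri) == 0) next
    ints <- vapply(seq_len(nrow(tri)), function(t_) {
      tp <- proj$projected[c(tri$idx1[t_], tri$idx2[t_], tri$idx3[t_]), ,
                           drop = FALSE]
      triadMeanIntensity(tp, patient$mesh, imap, metric = metric)
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      cv = tri$cv_m_per_s, intensity = ints, metric = metric, patient = pid,
      cycle_length = k@cycle_length_ms, area_mm2 = tri$area_mm2,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
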