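# Synthetic-data generator: atrial-like surfaces, patchy enhancement fields,
# LGE-like intensity volumes, catheter kernels, activation times and full
# study cohorts with the statistical structure the analysis assumes.

.atrialcv_cache <- new.env(parent = emptyenv())

#' Generate a closed atrial-like surface
#'
#' Builds a closed genus-0 triangle mesh by subdividing an icosahedron,
#' mapping it onto an ellipsoid of roughly 40 mm major axis (a typical
#' echocardiographic left-atrial dimension) and applying a smooth radial
#' perturbation. With `roughness = 0` the vertices lie exactly on the
#' ellipsoid.
#'
#' @param n_vertices minimum number of vertices (>= 100); the smallest
#'   icosphere subdivision with at least this many vertices is used.
#' @param roughness relative SD of the smooth radial perturbation
#'   (dimensionless; 0 gives the exact ellipsoid).
#' @param seed integer seed; meshes are bit-identical per seed.
#' @param semi_axes numeric length-3 ellipsoid semi-axes in mm.
#' @return a [SurfaceMesh-class] (closed, outward-oriented).
#' @export
generateAtrialSurface <- function(n_vertices = 642, roughness = 0.05, seed = 1,
                                  semi_axes = c(20.5, 16.5, 14)) {
  if (n_vertices < 100)
    stop("n_vertices must be at least 100 to triangulate the surface")
  if (any(semi_axes <= 0)) stop("semi_axes must be positive")
  lv <- .icosphereLevel(n_vertices)
  key <- paste0("ico", lv)
  ico <- .atrialcv_cache[[key]]
  if (is.null(ico)) {
    ico <- .icosphere(lv)
    .atrialcv_cache[[key]] <- ico
  }
  dirs <- ico$vertices
  scale <- rep(1, nrow(dirs))
  if (roughness > 0) {
    g <- .sphereBumps(dirs, n_bumps = 64L, width = 0.5,
                      seed = .substream(seed, "surface"))
    scale <- 1 + roughness * g
    if (any(scale <= 0.1)) stop("roughness too large; surface degenerates")
  }
  v <- dirs * scale
  v <- sweep(v, 2, semi_axes, `*`)
  new("SurfaceMesh", vertices = v, faces = ico$faces,
      normals = .vertexNormals(v, ico$faces))
}

#' Generate a patchy wall-enhancement field
#'
#' Builds a spatially correlated random field over the surface emulating the
#' patchy, non-uniform character of atrial gadolinium enhancement, which
#' varies on scales of about 5 mm. The smooth mode sums isotropic Gaussian
#' bumps scattered over the surface (field autocorrelation length is
#' approximately `patch_scale_mm`); the plateau mode assigns one constant
#' value per nearest-centre patch. The field is affinely calibrated so its
#' per-vertex values have exactly the requested mean and SD, and can be
#' evaluated at any 3D point near the surface with [evalField()].
#'
#' @param mesh a [SurfaceMesh-class].
#' @param patch_scale_mm spatial correlation length in mm (> 0).
#' @param ni_mean,ni_sd target per-vertex mean and SD (in the intensity
#'   metric's units: blood-pool SD units for NI, dimensionless for IIR).
#' @param seed integer seed.
#' @param mode `"smooth"` or `"plateau"`.
#' @param plateau_centers optional k x 3 matrix of patch centres for the
#'   plateau mode (defaults to a random vertex subset).
#' @return a [FibrosisField-class].
#' @export
generateFibrosisField <- function(mesh, patch_scale_mm = 5, ni_mean = 1.5,
                                  ni_sd = 1, seed = 1,
                                  mode = c("smooth", "plateau"),
                                  plateau_centers = NULL) {
  if (patch_scale_mm <= 0) stop("patch_scale_mm must be positive")
  if (ni_sd < 0) stop("ni_sd must be >= 0")
  mode <- match.arg(mode)
  v <- mesh@vertices
  set.seed(.substream(seed, "field"))
  if (mode == "smooth") {
    # bump density: several bumps per correlation area, scattered on vertices
    # with radial jitter so centres do not coincide with the vertex lattice
    area <- .meshArea(mesh)
    M <- max(50L, ceiling(3 * area / patch_scale_mm^2))
    centers <- v[sample.int(nrow(v), M, replace = TRUE), , drop = FALSE] +
      matrix(rnorm(M * 3, 0, patch_scale_mm / 4), ncol = 3)
    w <- rnorm(M)
    bump_sd <- patch_scale_mm / sqrt(2)  # field covariance ~ exp(-d^2/(2 L^2))
    raw <- .bumpEval(centers, w, bump_sd, v)
  } else {
    if (is.null(plateau_centers)) {
      k <- max(8L, ceiling(.meshArea(mesh) / (4 * patch_scale_mm^2)))
      plateau_centers <- v[.farthestPointSample(v, k), , drop = FALSE]
    }
    centers <- plateau_centers
    w <- rnorm(nrow(centers))
    bump_sd <- NA_real_
    raw <- .plateauEval(centers, w, v)
  }
  if (ni_sd == 0) {
    gain <- 0; offset <- ni_mean
  } else {
    s <- sd(raw)
    if (s == 0) stop("degenerate field; increase mesh resolution")
    gain <- ni_sd / s
    offset <- ni_mean - gain * mean(raw)
  }
  new("FibrosisField", centers = centers, weights = w, bump_sd = bump_sd,
      gain = gain, offset = offset, values = gain * raw + offset, mode = mode)
}

.bumpEval <- function(centers, w, bump_sd, pts) {
  out <- numeric(nrow(pts))
  chunk <- 2000L
  for (s in seq(1L, nrow(pts), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(pts))
    d2 <- outer(rowSums(pts[idx, , drop = FALSE]^2), rowSums(centers^2), `+`) -
      2 * pts[idx, , drop = FALSE] %*% t(centers)
    out[idx] <- exp(-pmax(d2, 0) / (2 * bump_sd^2)) %*% w
  }
  out
}

# Greedy farthest-point subset of the rows of v (well-separated patch
# centres; the first point is the vertex farthest from the centroid).
.farthestPointSample <- function(v, k) {
  cen <- colMeans(v)
  idx <- which.max(rowSums(sweep(v, 2, cen)^2))
  dmin <- rowSums(sweep(v, 2, v[idx, ])^2)
  for (i in seq_len(k - 1)) {
    nxt <- which.max(dmin)
    idx <- c(idx, nxt)
    dmin <- pmin(dmin, rowSums(sweep(v, 2, v[nxt, ])^2))
  }
  idx
}

.plateauEval <- function(centers, w, pts) {
  out <- numeric(nrow(pts))
  chunk <- 4000L
  for (s in seq(1L, nrow(pts), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(pts))
    d2 <- outer(rowSums(pts[idx, , drop = FALSE]^2), rowSums(centers^2), `+`) -
      2 * pts[idx, , drop = FALSE] %*% t(centers)
    out[idx] <- w[max.col(-d2, ties.method = "first")]
  }
  out
}

#' Evaluate a fibrosis field at arbitrary points
#'
#' @param field a [FibrosisField-class].
#' @param pts n x 3 matrix of mm coordinates.
#' @return numeric vector of field values in the field's calibrated units.
#' @export
evalField <- function(field, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  raw <- if (field@mode == "plateau")
    .plateauEval(field@centers, field@weights, pts)
  else
    .bumpEval(field@centers, field@weights, field@bump_sd, pts)
  field@gain * raw + field@offset
}

.meshArea <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  cr <- .cross3(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
                v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  sum(0.5 * sqrt(rowSums(cr^2)))
}

#' Rasterize an LGE-like intensity volume
#'
#' Builds a 3D intensity volume around a closed star-shaped surface: voxels
#' inside the surface shrunk by `wall_thickness_mm` are blood pool, drawn
#' from Normal(`blood_mu`, `blood_sd`) truncated at 0; voxels in the wall
#' shell carry `blood_mu + NI * blood_sd` with NI taken from the enhancement
#' field; exterior voxels are 0. Interior/wall classification uses a radial
#' model of the surface (exact for the star-shaped surfaces the generator
#' produces), with the shell thickness corrected for the local angle between
#' the surface normal and the radial direction so that the wall measures
#' `wall_thickness_mm` along the normal.
#'
#' @param mesh a closed [SurfaceMesh-class] (star-shaped about its centroid).
#' @param field a [FibrosisField-class] or a numeric per-vertex NI vector.
#' @param blood_mu,blood_sd blood-pool intensity mean and SD (arbitrary
#'   units; `blood_mu` > 0).
#' @param wall_thickness_mm wall-shell thickness along the normal (must be
#'   at least the largest voxel spacing).
#' @param spacing numeric length-3, voxel size in mm.
#' @param seed integer seed for the blood-pool noise.
#' @param pad_mm padding of empty space around the surface bounding box.
#' @return an [IntensityVolume-class].
#' @export
rasterizeVolume <- function(mesh, field, blood_mu = 600, blood_sd = 50,
                            wall_thickness_mm = 3,
                            spacing = c(1.25, 1.25, 2.5), seed = 1,
                            pad_mm = 6) {
  ext <- apply(mesh@vertices, 2, range)
  if (any(spacing > diff(ext)))
    stop("voxel spacing exceeds the mesh extent")
  if (wall_thickness_mm < max(spacing))
    stop("wall_thickness_mm must be >= the largest voxel spacing")
  vert_ni <- if (is(field, "FibrosisField")) field@values else
    as.numeric(field)
  if (length(vert_ni) != nrow(mesh@vertices))
    stop("field must supply one value per mesh vertex")
  origin <- ext[1, ] - pad_mm
  dims <- ceiling((diff(ext) + 2 * pad_mm) / spacing) + 1L
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 1) * spacing[k])
  pts <- cbind(rep(ax[[1]], times = dims[2] * dims[3]),
               rep(rep(ax[[2]], each = dims[1]), times = dims[3]),
               rep(ax[[3]], each = dims[1] * dims[2]))
  # radial model carrying surface radius, per-direction NI and the cosine of
  # the normal/radial angle
  cen <- colMeans(mesh@vertices)
  rel <- sweep(mesh@vertices, 2, cen)
  cosang <- pmax(rowSums(.unit(rel) * mesh@normals), 0.2)
  model <- .radialModel(mesh, values = vert_ni)
  model_cos <- .radialModel(mesh, values = cosang)
  lk <- .radialLookup(model, pts, "R")
  ni_s <- .radialLookup(model, pts, "V")$surface
  cos_s <- pmax(.radialLookup(model_cos, pts, "V")$surface, 0.2)
  shell <- wall_thickness_mm / cos_s   # radial thickness of the wall shell
  vox <- numeric(nrow(pts))
  inside_wall <- lk$radius <= lk$surface & lk$radius > lk$surface - shell
  inside_blood <- lk$radius <= lk$surface - shell
  set.seed(.substream(seed, "bloodnoise"))
  vox[inside_blood] <- pmax(rnorm(sum(inside_blood), blood_mu, blood_sd), 0)
  vox[inside_wall] <- pmax(blood_mu + ni_s[inside_wall] * blood_sd, 0)
  new("IntensityVolume", voxels = array(vox, dim = dims),
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

## ---- catheter placement ----------------------------------------------------

# 2D template of the 20-pole double-loop catheter: an Archimedean spiral of
# two turns with 20 electrodes at exactly 4 mm consecutive chord spacing.
# The true proprietary loop geometry is not published; radii (4.5 -> 8 mm)
# are chosen so two loops accommodate the 19 gaps.
.catheterTemplate <- function() {
  tpl <- .atrialcv_cache[["catheter"]]
  if (!is.null(tpl)) return(tpl)
  r_of <- function(th) 4.5 + (8 - 4.5) * th / (4 * pi)
  pt <- function(th) r_of(th) * c(cos(th), sin(th))
  theta <- numeric(20)
  for (i in 2:20) {
    f <- function(th) sqrt(sum((pt(th) - pt(theta[i - 1]))^2)) - 4
    theta[i] <- uniroot(f, c(theta[i - 1] + 1e-6, theta[i - 1] + 1.5),
                        tol = 1e-13)$root
  }
  tpl <- t(vapply(theta, pt, numeric(2)))
  .atrialcv_cache[["catheter"]] <- tpl
  tpl
}

#' Place a double-loop catheter kernel on a surface
#'
#' Seats the 20-electrode double-loop catheter tangentially at a surface
#' site: the spiral template (4 mm consecutive electrode spacing) is laid in
#' the local tangent plane with a seed-determined in-plane rotation. An
#' error is raised when local curvature is too high for the loops to seat
#' (any electrode further than `max_seat_mm` from the surface).
#'
#' @param mesh a [SurfaceMesh-class].
#' @param site a vertex index or a 3D point (snapped to the nearest vertex).
#' @param seed integer seed (in-plane rotation).
#' @param scale multiplies the template (radii and spacing); 1 reproduces
#'   the 4 mm catheter.
#' @param max_seat_mm maximum allowed electrode-surface distance (mm).
#' @param seat_check `"exact"` (point-to-triangle distance), `"radial"`
#'   (fast radial proxy) or `"none"`.
#' @param radial_model optional precomputed radial surface model (internal
#'   use by the cohort generator to avoid rebuilding it per kernel).
#' @return 20 x 3 matrix of electrode positions (mm).
#' @export
placeCatheterKernel <- function(mesh, site, seed = 1, scale = 1,
                                max_seat_mm = 5,
                                seat_check = c("exact", "radial", "none"),
                                radial_model = NULL) {
  seat_check <- match.arg(seat_check)
  if (length(site) == 1L) {
    vi <- as.integer(site)
    if (vi < 1L || vi > nrow(mesh@vertices)) stop("site vertex index out of range")
  } else {
    d2 <- colSums((t(mesh@vertices) - as.numeric(site))^2)
    vi <- which.min(d2)
  }
  p0 <- mesh@vertices[vi, ]
  n0 <- mesh@normals[vi, ]
  # tangent basis
  ref <- if (abs(n0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n0) * n0; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n0[2] * e1[3] - n0[3] * e1[2],
          n0[3] * e1[1] - n0[1] * e1[3],
          n0[1] * e1[2] - n0[2] * e1[1])
  set.seed(.substream(seed, "placement"))
  phi <- runif(1, 0, 2 * pi)
  tpl <- .catheterTemplate() * scale
  rot <- cbind(c(cos(phi), sin(phi)), c(-sin(phi), cos(phi)))
  xy <- tpl %*% rot
  pos <- matrix(p0, 20, 3, byrow = TRUE) + outer(xy[, 1], e1) + outer(xy[, 2], e2)
  if (seat_check == "exact") {
    d <- .closestPointOnMesh(mesh, pos)$distance
    if (max(d) > max_seat_mm)
      stop(sprintf("catheter cannot seat: electrode %.1f mm from surface",
                   max(d)))
  } else if (seat_check == "radial") {
    # radial proxy distance; adequate for the generator's smooth surfaces
    md <- if (is.null(radial_model))
      .radialModel(mesh, n_theta = 48L, n_phi = 96L) else radial_model
    lk <- .radialLookup(md, pos, "R")
    if (max(abs(lk$radius - lk$surface)) > max_seat_mm)
      stop("catheter cannot seat: local curvature too high")
  }
  pos
}

#' Simulate local activation times
#'
#' Kinematic activation: a planar wave gives t = t0 + (x . d) / v, a
#' circular wave t = t0 + |x - c| / v, with positions in mm, speeds in m/s
#' (1 m/s = 1 mm/ms) and times in ms. Gaussian annotation noise may be
#' added.
#'
#' @param positions n x 3 electrode positions (mm).
#' @param wave list with `type` (`"planar"` or `"circular"`),
#'   `speed_m_per_s` (> 0), `t0_ms` (default 0) and either `direction`
#'   (planar, any non-zero 3-vector) or `origin` (circular, mm).
#' @param noise_sd_ms SD of additive Gaussian LAT noise (ms).
#' @param seed integer seed for the noise.
#' @return numeric vector of LATs in ms.
#' @export
simulateActivation <- function(positions, wave, noise_sd_ms = 0, seed = 1) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  v <- wave$speed_m_per_s
  if (!is.numeric(v) || v <= 0) stop("wave speed must be positive")
  t0 <- if (is.null(wave$t0_ms)) 0 else wave$t0_ms
  if (wave$type == "planar") {
    d <- as.numeric(wave$direction)
    d <- d / sqrt(sum(d^2))
    t <- t0 + as.numeric(positions %*% d) / v
  } else if (wave$type == "circular") {
    cc <- as.numeric(wave$origin)
    t <- t0 + sqrt(colSums((t(positions) - cc)^2)) / v
  } else stop("wave$type must be 'planar' or 'circular'")
  if (noise_sd_ms > 0) {
    set.seed(.substream(seed, "latnoise"))
    t <- t + rnorm(length(t), 0, noise_sd_ms)
  }
  t
}

#' Apply a rigid perturbation plus vertex jitter to a mesh
#'
#' Used to create a misregistered electroanatomic-mapping surface from the
#' imaging surface. The rigid transform (rotation about `axis` through the
#' mesh centroid by `rotation_deg`, then translation) is returned so that
#' registration recovery and target-registration-error oracles can invert
#' it exactly.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param rotation_deg rotation angle in degrees.
#' @param translation_mm numeric length-3 translation (mm).
#' @param jitter_sd_mm SD of i.i.d. Gaussian vertex jitter applied after
#'   the rigid transform (mm).
#' @param axis rotation axis (default z).
#' @param seed integer seed for the jitter.
#' @return list with elements `mesh` (the perturbed [SurfaceMesh-class])
#'   and `transform` (the generative [RigidTransform-class]).
#' @export
perturbSurface <- function(mesh, rotation_deg = 0, translation_mm = c(0, 0, 0),
                           jitter_sd_mm = 0, axis = c(0, 0, 1), seed = 1) {
  axis <- axis / sqrt(sum(axis^2))
  th <- rotation_deg * pi / 180
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  cen <- colMeans(mesh@vertices)
  # rotate about the centroid, then translate
  t_vec <- as.numeric(cen - R %*% cen + translation_mm)
  v <- t(R %*% t(mesh@vertices)) + matrix(t_vec, nrow(mesh@vertices), 3,
                                          byrow = TRUE)
  if (jitter_sd_mm > 0) {
    set.seed(.substream(seed, "jitter"))
    v <- v + matrix(rnorm(length(v), 0, jitter_sd_mm), ncol = 3)
    nrm <- .vertexNormals(v, mesh@faces)
  } else {
    nrm <- t(R %*% t(mesh@normals))
  }
  list(mesh = new("SurfaceMesh", vertices = v, faces = mesh@faces,
                  normals = .unit(nrm)),
       transform = new("RigidTransform", rotation = R, translation = t_vec))
}
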