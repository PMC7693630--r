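# Low-level mesh / grid geometry shared across modules.

# Deterministic substream seed derived from a root seed and a stage tag, so
# independent stages (surface / field / placement / noise) draw from
# independent, reproducible streams. Kept below 2^31 - 1.
.substream <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629) + 1L
}

.unit <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  m / pmax(sqrt(rowSums(m^2)), .Machine$double.eps)
}

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Area-weighted outward vertex normals of an oriented triangle mesh.
.vertexNormals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  fn <- .cross3(b - a, c_ - a)  # length = 2 * face area, outward for CCW faces
  n <- matrix(0, nrow(vertices), 3)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- tapply(fn[, k], faces[, j], sum)
      idx <- as.integer(names(acc))
      n[idx, k] <- n[idx, k] + as.numeric(acc)
    }
  }
  .unit(n)
}

#' Test whether a mesh is a closed orientable manifold
#'
#' Checks that every undirected edge is shared by exactly two faces with
#' opposite orientation.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return logical scalar.
#' @export
isClosedManifold <- function(mesh) {
  f <- mesh@faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  if (any(tab != 2L)) return(FALSE)
  # opposite orientation: each directed edge appears exactly once
  dkey <- paste(e[, 1], e[, 2])
  !any(duplicated(dkey))
}

#' Euler characteristic of a mesh
#'
#' V - E + F; equals 2 for a closed genus-0 surface.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return integer.
#' @export
eulerCharacteristic <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(mesh@vertices) - length(key) + nrow(f)
}

# Icosphere: subdivided icosahedron on the unit sphere, consistently
# CCW-outward oriented. Levels 0..5 give 12, 42, 162, 642, 2562, 10242 verts.
.icosphere <- function(level) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- .unit(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lv in seq_len(level)) {
    nv <- nrow(v)
    edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    uek <- unique(ek)
    mid_idx <- match(ek, uek) + nv
    ue <- edges[!duplicated(ek), , drop = FALSE]
    mids <- .unit((v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2)
    v <- rbind(v, mids)
    m12 <- mid_idx[seq_len(nrow(f))]
    m23 <- mid_idx[nrow(f) + seq_len(nrow(f))]
    m31 <- mid_idx[2 * nrow(f) + seq_len(nrow(f))]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  storage.mode(f) <- "integer"
  dimnames(f) <- NULL
  list(vertices = v, faces = f)
}

# Smallest icosphere level with at least n vertices.
.icosphereLevel <- function(n) {
  sizes <- c(12L, 42L, 162L, 642L, 2562L, 10242L, 40962L)
  lv <- which(sizes >= n)[1]
  if (is.na(lv)) stop("requested vertex count too large")
  lv - 1L
}

# Smooth scalar function on the unit sphere: sum of Gaussian bumps at random
# directions, standardized to zero mean / unit SD over the supplied points.
.sphereBumps <- function(dirs, n_bumps, width, seed) {
  set.seed(seed)
  c_dir <- .unit(matrix(rnorm(n_bumps * 3), ncol = 3))
  w <- rnorm(n_bumps)
  sim <- dirs %*% t(c_dir)                 # cos(angle)
  g <- exp((sim - 1) / width^2) %*% w
  g <- as.numeric(g)
  s <- sd(g)
  if (s == 0) rep(0, length(g)) else (g - mean(g)) / s
}

## ---- radial (star-shaped) surface model ------------------------------------

# An angular lookup of surface radius (and optionally a per-vertex scalar)
# around the mesh centroid. Exact only for star-shaped surfaces, which all
# generator meshes are; used for O(1) inside/outside voxel classification.
.radialModel <- function(mesh, values = NULL, n_theta = 96L, n_phi = 192L) {
  cen <- colMeans(mesh@vertices)
  rel <- sweep(mesh@vertices, 2, cen)
  r <- sqrt(rowSums(rel^2))
  d <- rel / r
  theta <- seq(0, pi, length.out = n_theta)
  phi <- seq(-pi, pi, length.out = n_phi + 1L)[seq_len(n_phi)]
  grid_dir <- cbind(rep(sin(theta), times = n_phi) * cos(rep(phi, each = n_theta)),
                    rep(sin(theta), times = n_phi) * sin(rep(phi, each = n_theta)),
                    rep(cos(theta), times = n_phi))
  # kernel-weighted interpolation of vertex radii over direction space;
  # bandwidth tied to the mesh's angular resolution
  h <- max(4 / sqrt(nrow(mesh@vertices)), 0.05)
  R <- numeric(nrow(grid_dir))
  V <- if (!is.null(values)) numeric(nrow(grid_dir)) else NULL
  chunk <- 4000L
  for (s in seq(1L, nrow(grid_dir), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(grid_dir))
    sim <- grid_dir[idx, , drop = FALSE] %*% t(d)
    w <- exp((sim - 1) / h^2)
    ws <- rowSums(w)
    R[idx] <- (w %*% r) / ws
    if (!is.null(values)) V[idx] <- (w %*% values) / ws
  }
  list(center = cen,
       R = matrix(R, n_theta, n_phi),
       V = if (!is.null(values)) matrix(V, n_theta, n_phi) else NULL,
       n_theta = n_theta, n_phi = n_phi)
}

# Bilinear lookup on the (theta, phi) grid for arbitrary points (n x 3).
.radialLookup <- function(model, pts, what = "R") {
  rel <- sweep(pts, 2, model$center)
  r <- sqrt(rowSums(rel^2))
  theta <- acos(pmin(pmax(rel[, 3] / pmax(r, 1e-12), -1), 1))
  phi <- atan2(rel[, 2], rel[, 1])
  nt <- model$n_theta; np <- model$n_phi
  ti <- theta / pi * (nt - 1L) + 1
  pj <- (phi + pi) / (2 * pi) * np + 1
  i0 <- pmin(pmax(floor(ti), 1L), nt - 1L); fi <- ti - i0
  j0 <- floor(pj); fj <- pj - j0
  j0w <- ((j0 - 1L) %% np) + 1L
  j1w <- (j0 %% np) + 1L
  G <- model[[what]]
  val <- G[cbind(i0, j0w)] * (1 - fi) * (1 - fj) +
         G[cbind(i0 + 1L, j0w)] * fi * (1 - fj) +
         G[cbind(i0, j1w)] * (1 - fi) * fj +
         G[cbind(i0 + 1L, j1w)] * fi * fj
  list(radius = r, surface = val)
}

## ---- trilinear volume sampling ---------------------------------------------

# Trilinear interpolation of a volume at arbitrary mm points. Points whose
# 8-voxel support leaves the grid return NA.
.trilinear <- function(volume, pts) {
  sp <- volume@spacing; or <- volume@origin
  dm <- dim(volume@voxels)
  x <- (pts[, 1] - or[1]) / sp[1] + 1
  y <- (pts[, 2] - or[2]) / sp[2] + 1
  z <- (pts[, 3] - or[3]) / sp[3] + 1
  i0 <- floor(x); j0 <- floor(y); k0 <- floor(z)
  ok <- i0 >= 1 & i0 + 1 <= dm[1] & j0 >= 1 & j0 + 1 <= dm[2] &
        k0 >= 1 & k0 + 1 <= dm[3]
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  fx <- x[ok] - i0; fy <- y[ok] - j0; fz <- z[ok] - k0
  vox <- volume@voxels
  idx <- function(di, dj, dk) vox[cbind(i0 + di, j0 + dj, k0 + dk)]
  val <- idx(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
         idx(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
         idx(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
         idx(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
         idx(1, 1, 0) * fx * fy * (1 - fz) +
         idx(1, 0, 1) * fx * (1 - fy) * fz +
         idx(0, 1, 1) * (1 - fx) * fy * fz +
         idx(1, 1, 1) * fx * fy * fz
  out[ok] <- val
  out
}

## ---- point-to-triangle distance --------------------------------------------

# Closest point on triangle (a, b, c) to point p (all length-3 vectors).
# Standard region classification on barycentric coordinates.
.closestPointOnTriangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + (d1 / (d1 - d3)) * ab)
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + (d2 / (d2 - d6)) * ac)
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (c - b))
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}

# Closest point on a mesh to each query point (n x 3). Exact point-to-triangle
# search over all faces, with a vertex-distance prefilter per query point.
.closestPointOnMesh <- function(mesh, pts) {
  v <- mesh@vertices; f <- mesh@faces
  n <- nrow(pts)
  cp <- matrix(NA_real_, n, 3)
  dmin <- numeric(n)
  # face centroids & bounding radii for the prefilter
  fa <- v[f[, 1], , drop = FALSE]
  fb <- v[f[, 2], , drop = FALSE]
  fc <- v[f[, 3], , drop = FALSE]
  fcen <- (fa + fb + fc) / 3
  frad <- sqrt(pmax(rowSums((fa - fcen)^2),
                    rowSums((fb - fcen)^2),
                    rowSums((fc - fcen)^2)))
  for (i in seq_len(n)) {
    p <- pts[i, ]
    dcen <- sqrt(colSums((t(fcen) - p)^2))
    best_upper <- min(dcen + frad)
    cand <- which(dcen - frad <= best_upper + 1e-9)
    bd <- Inf; bp <- NULL
    for (k in cand) {
      q <- .closestPointOnTriangle(p, fa[k, ], fb[k, ], fc[k, ])
      d <- sum((p - q)^2)
      if (d < bd) { bd <- d; bp <- q }
    }
    cp[i, ] <- bp
    dmin[i] <- sqrt(bd)
  }
  list(points = cp, distance = dmin)
}

# Orthonormal in-plane basis for a point set (rows of x): returns e1, e2
# spanning the best-fit plane and the plane normal.
.planeBasis <- function(x) {
  cen <- colMeans(x)
  s <- svd(sweep(x, 2, cen))
  list(center = cen, e1 = s$v[, 1], e2 = s$v[, 2], normal = s$v[, 3])
}

# Triangle area (mm^2) and minimum edge length for a 3 x 3 position matrix.
.triangleAreaMinEdge <- function(p) {
  e1 <- p[2, ] - p[1, ]; e2 <- p[3, ] - p[1, ]; e3 <- p[3, ] - p[2, ]
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  list(area = 0.5 * sqrt(sum(cr^2)),
       min_edge = sqrt(min(sum(e1^2), sum(e2^2), sum(e3^2))))
}
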