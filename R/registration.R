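# Rigid surface co-registration, target registration error, electrode
# projection onto the imaging surface.

#' Apply a rigid transform to points
#'
#' @param transform a [RigidTransform-class].
#' @param pts n x 3 matrix (mm).
#' @return transformed n x 3 matrix.
#' @export
applyTransform <- function(transform, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  t(transform@rotation %*% t(pts)) +
    matrix(transform@translation, nrow(pts), 3, byrow = TRUE)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param second,first [RigidTransform-class] objects.
#' @return a [RigidTransform-class].
#' @export
composeTransforms <- function(second, first) {
  new("RigidTransform",
      rotation = second@rotation %*% first@rotation,
      translation = as.numeric(second@rotation %*% first@translation) +
        second@translation)
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return a [RigidTransform-class].
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  new("RigidTransform", rotation = Rt,
      translation = as.numeric(-Rt %*% transform@translation))
}

# Least-squares rigid alignment of paired point sets (Kabsch/Umeyama,
# rotation constrained to det +1).
.kabsch <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  H <- crossprod(sweep(moving, 2, cm), sweep(fixed, 2, cf))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  new("RigidTransform", rotation = R,
      translation = as.numeric(cf - R %*% cm))
}

#' Rigid iterative-closest-point surface registration
#'
#' Registers the moving surface to the fixed surface with 6-DOF rigid ICP:
#' closest-vertex correspondences followed by a Kabsch least-squares rigid
#' update, iterated until the RMS improvement drops below `tol` or
#' `max_iter` is reached. The RMS is monotone non-increasing across
#' iterations within each start. Because smooth, nearly ellipsoidal atrial
#' surfaces let plain ICP slide into rotational local minima, the search is
#' restarted from a small bank of initial rotations about the centroid (plus
#' a centroid-aligning translation) and the start with the lowest final RMS
#' wins.
#'
#' @param moving,fixed [SurfaceMesh-class] objects (non-empty).
#' @param max_iter maximum iterations per start.
#' @param tol convergence tolerance on the RMS change (mm).
#' @param restart_angles_deg rotation magnitudes (degrees) of the restart
#'   bank; each is applied about all three coordinate axes in both
#'   directions.
#' @return list with `transform` (a [RigidTransform-class]), `rms_mm`
#'   (final closest-point RMS), `rms_trace` (per-iteration RMS of the
#'   winning start) and `iterations`.
#' @export
rigidICP <- function(moving, fixed, max_iter = 200, tol = 1e-10,
                     restart_angles_deg = c(10, 25)) {
  mv <- moving@vertices; fx <- fixed@vertices
  if (nrow(mv) == 0 || nrow(fx) == 0) stop("registration failed: empty mesh")
  if (qr(sweep(mv, 2, colMeans(mv)))$rank < 3 ||
      qr(sweep(fx, 2, colMeans(fx)))$rank < 3)
    stop("registration failed: degenerate (coplanar or collinear) vertex set")

  axis_rot <- function(axis, deg) {
    th <- deg * pi / 180
    K <- rbind(c(0, -axis[3], axis[2]),
               c(axis[3], 0, -axis[1]),
               c(-axis[2], axis[1], 0))
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  # start bank: identity plus rotations about each axis, all about the
  # moving centroid, composed with a centroid-aligning translation
  cm <- colMeans(mv); cf <- colMeans(fx)
  starts <- list(diag(3))
  for (a in restart_angles_deg)
    for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
      starts <- c(starts, list(axis_rot(ax, a)), list(axis_rot(ax, -a)))

  run_icp <- function(init) {
    cur <- applyTransform(init, mv)
    transform <- init
    rms_trace <- numeric(0)
    prev_rms <- Inf
    for (it in seq_len(max_iter)) {
      nn <- .nearestVertex(fx, cur)
      target <- fx[nn, , drop = FALSE]
      rms <- sqrt(mean(rowSums((cur - target)^2)))
      rms_trace <- c(rms_trace, rms)
      if (prev_rms - rms < tol) break
      prev_rms <- rms
      upd <- .kabsch(cur, target)
      cur <- applyTransform(upd, cur)
      transform <- composeTransforms(upd, transform)
    }
    list(transform = transform, rms = rms_trace[length(rms_trace)],
         rms_trace = rms_trace)
  }
  best <- NULL
  for (R0 in starts) {
    init <- new("RigidTransform", rotation = R0,
                translation = as.numeric(cf - R0 %*% cm))
    res <- run_icp(init)
    if (is.null(best) || res$rms < best$rms) best <- res
    if (best$rms < tol * 10) break
  }
  list(transform = best$transform, rms_mm = best$rms,
       rms_trace = best$rms_trace, iterations = length(best$rms_trace))
}

# Index of the nearest row of `ref` for each row of `query` (chunked
# brute-force; meshes here have O(1e3) vertices).
.nearestVertex <- function(ref, query) {
  n <- nrow(query)
  out <- integer(n)
  r2 <- rowSums(ref^2)
  chunk <- 2000L
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    d2 <- outer(rowSums(query[idx, , drop = FALSE]^2), r2, `+`) -
      2 * query[idx, , drop = FALSE] %*% t(ref)
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Target registration error
#'
#' Root-mean-square Euclidean distance between transformed moving landmarks
#' and their fixed counterparts.
#'
#' @param moving_landmarks,fixed_landmarks n x 3 matrices of corresponding
#'   points (>= 1 pair).
#' @param transform a [RigidTransform-class] applied to the moving landmarks.
#' @return TRE in mm.
#' @export
targetRegistrationError <- function(moving_landmarks, fixed_landmarks,
                                    transform) {
  if (is.null(dim(moving_landmarks)))
    moving_landmarks <- matrix(moving_landmarks, ncol = 3)
  if (is.null(dim(fixed_landmarks)))
    fixed_landmarks <- matrix(fixed_landmarks, ncol = 3)
  if (nrow(moving_landmarks) < 1)
    stop("at least one landmark pair is required")
  if (nrow(moving_landmarks) != nrow(fixed_landmarks))
    stop("landmark sets must have equal size")
  m <- applyTransform(transform, moving_landmarks)
  sqrt(mean(rowSums((m - fixed_landmarks)^2)))
}

#' Project electrodes onto a surface
#'
#' Maps each electrode to its exact closest point on the mesh (point-to-
#' triangle distance over all faces, not vertex snapping) and flags
#' electrodes farther than `max_distance_mm` from the surface as dropped.
#'
#' @param positions n x 3 electrode positions (mm).
#' @param surface a [SurfaceMesh-class] (non-empty).
#' @param max_distance_mm drop threshold (default 5 mm; electrodes strictly
#'   beyond it are disregarded).
#' @return list with `projected` (n x 3 closest points), `distance_mm`
#'   (n distances) and `keep` (logical).
#' @export
projectElectrodes <- function(positions, surface, max_distance_mm = 5) {
  if (nrow(surface@faces) == 0) stop("surface has no faces")
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  res <- .closestPointOnMesh(surface, positions)
  list(projected = res$points, distance_mm = res$distance,
       keep = res$distance <= max_distance_mm)
}
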