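# Local and regional conduction-velocity estimation.

#' Annotate the local activation time of a unipolar electrogram
#'
#' The LAT is the time of the maximum negative gradient of the unipolar
#' signal, located by centred differences with parabolic sub-sample
#' refinement. When several samples tie for the steepest slope (a plateau,
#' e.g. a pure down-ramp), the midpoint of the earliest plateau is returned
#' and no refinement is applied.
#'
#' @param signal numeric sampled voltage series (>= 3 samples).
#' @param sample_rate_hz sampling rate in Hz.
#' @param t0_ms time of the first sample (ms).
#' @return LAT in ms.
#' @export
annotateLAT <- function(signal, sample_rate_hz, t0_ms = 0) {
  n <- length(signal)
  if (n < 3) stop("signal must have at least 3 samples")
  dt <- 1000 / sample_rate_hz  # ms per sample
  # centred first difference at interior samples 2..(n-1)
  g <- (signal[3:n] - signal[1:(n - 2)]) / (2 * dt)
  if (min(g) >= 0)
    stop("no negative deflection in signal; cannot annotate LAT")
  gmin <- min(g)
  tol <- max(abs(gmin), 1) * 1e-9
  at_min <- which(g <= gmin + tol)
  # earliest contiguous plateau of the minimum
  first <- at_min[1]
  run_end <- first
  while (run_end + 1 <= length(g) && any(at_min == run_end + 1))
    run_end <- run_end + 1
  if (run_end > first) {
    k <- (first + run_end) / 2  # midpoint of the plateau
    return(t0_ms + k * dt)      # interior index i of g maps to sample i+1
  }
  k <- first
  # parabolic refinement on the gradient samples
  if (k > 1 && k < length(g)) {
    a <- g[k - 1]; b <- g[k]; c_ <- g[k + 1]
    denom <- a - 2 * b + c_
    off <- if (abs(denom) > 1e-15) 0.5 * (a - c_) / denom else 0
    off <- max(min(off, 0.5), -0.5)
  } else off <- 0
  t0_ms + (k + off) * dt
}

#' Local conduction velocity of one electrode triad
#'
#' Triangulates the local plane-wave velocity from the LAT differences of
#' three electrodes: the triad is rotated into its own plane and the
#' two-equation linear system `t_i - t_1 = s . (p_i - p_1)` is solved for
#' the in-plane slowness vector `s`; speed is `1/|s|` (m/s with positions in
#' mm and times in ms) and the propagation direction is `s/|s|` expressed in
#' 3D.
#'
#' @param positions 3 x 3 matrix of electrode positions (mm).
#' @param lats_ms numeric length-3 LATs (ms).
#' @param min_angle_deg collinearity tolerance; triads whose smallest
#'   internal angle is below this are rejected as degenerate.
#' @param slowness_floor |s| below this (ms/mm) is treated as an infinite
#'   speed and rejected.
#' @return list with `speed_m_per_s`, `direction` (unit 3-vector) and
#'   `slowness_ms_per_mm`.
#' @export
triadCV <- function(positions, lats_ms, min_angle_deg = 5,
                    slowness_floor = 1e-6) {
  if (!all(dim(positions) == c(3L, 3L))) stop("positions must be 3 x 3")
  if (length(lats_ms) != 3L || any(!is.finite(lats_ms)))
    stop("lats_ms must be 3 finite times")
  e <- list(positions[2, ] - positions[1, ],
            positions[3, ] - positions[2, ],
            positions[1, ] - positions[3, ])
  len <- vapply(e, function(x) sqrt(sum(x^2)), numeric(1))
  if (min(len) <= 0) stop("degenerate triad: coincident electrodes")
  # smallest internal angle from the law of cosines
  ang <- sapply(1:3, function(i) {
    a <- len[i]; b <- len[(i %% 3) + 1]; c_ <- len[((i + 1) %% 3) + 1]
    acos(pmin(pmax((a^2 + b^2 - c_^2) / (2 * a * b), -1), 1))
  })
  if (min(ang) < min_angle_deg * pi / 180)
    stop("degenerate triad geometry: collinear electrodes")
  pb <- .planeBasis(positions)
  p2 <- cbind((positions %*% pb$e1), (positions %*% pb$e2))
  A <- rbind(p2[2, ] - p2[1, ], p2[3, ] - p2[1, ])
  b <- c(lats_ms[2] - lats_ms[1], lats_ms[3] - lats_ms[1])
  s2 <- solve(A, b)                       # in-plane slowness, ms/mm
  smag <- sqrt(sum(s2^2))
  if (smag < slowness_floor)
    return(list(speed_m_per_s = NA_real_, direction = rep(NA_real_, 3),
                slowness_ms_per_mm = smag, rejected = "infinite-speed"))
  dir3 <- (s2[1] * pb$e1 + s2[2] * pb$e2) / smag
  list(speed_m_per_s = 1 / smag, direction = as.numeric(dir3),
       slowness_ms_per_mm = smag, rejected = NA_character_)
}

#' Enumerate electrode triads of a kernel
#'
#' All 3-subsets of the kernel's contact-ok electrodes with finite LATs
#' whose minimum pairwise electrode distance strictly exceeds `min_edge_mm`
#' (the registration-error constraint) and whose triangle area (from the
#' cross-product formula) is strictly below `max_area_mm2`.
#'
#' @param kernel a [Kernel-class].
#' @param min_edge_mm minimum interelectrode distance constraint (mm);
#'   0 disables it.
#' @param max_area_mm2 maximum triangle area (mm^2); `Inf` disables it.
#' @return data.frame with columns kernel_id, idx1, idx2, idx3, area_mm2,
#'   min_edge_mm (one row per eligible triad; possibly 0 rows).
#' @export
enumerateTriads <- function(kernel, min_edge_mm = 0, max_area_mm2 = Inf) {
  ok <- kernel@contact_ok & is.finite(kernel@lat_ms)
  idx <- which(ok)
  empty <- data.frame(kernel_id = character(0), idx1 = integer(0),
                      idx2 = integer(0), idx3 = integer(0),
                      area_mm2 = numeric(0), min_edge_mm = numeric(0))
  if (length(idx) < 3) return(empty)
  pos <- kernel@electrode_positions
  combos <- combn(idx, 3)
  p1 <- pos[combos[1, ], , drop = FALSE]
  p2 <- pos[combos[2, ], , drop = FALSE]
  p3 <- pos[combos[3, ], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1; e3 <- p3 - p2
  cr <- .cross3(e1, e2)
  area <- 0.5 * sqrt(rowSums(cr^2))
  min_edge <- sqrt(pmin(rowSums(e1^2), rowSums(e2^2), rowSums(e3^2)))
  keep <- min_edge > min_edge_mm & area < max_area_mm2
  if (!any(keep)) return(empty)
  data.frame(kernel_id = kernel@kernel_id,
             idx1 = combos[1, keep], idx2 = combos[2, keep],
             idx3 = combos[3, keep],
             area_mm2 = area[keep], min_edge_mm = min_edge[keep],
             stringsAsFactors = FALSE)
}

#' Local CV for every triad in a table
#'
#' Applies [triadCV()] to each row of an [enumerateTriads()] table; triads
#' that are degenerate or have effectively infinite speed get NA.
#'
#' @param kernel a [Kernel-class].
#' @param triads data.frame from [enumerateTriads()].
#' @return the table with added columns cv_m_per_s, dir_x, dir_y, dir_z.
#' @export
triadCVTable <- function(kernel, triads) {
  pos <- kernel@electrode_positions
  lat <- kernel@lat_ms
  n <- nrow(triads)
  cv <- numeric(n); dir <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    res <- tryCatch(
      triadCV(pos[c(triads$idx1[i], triads$idx2[i], triads$idx3[i]), ],
              lat[c(triads$idx1[i], triads$idx2[i], triads$idx3[i])]),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$speed_m_per_s)) {
      cv[i] <- NA_real_
    } else {
      cv[i] <- res$speed_m_per_s
      dir[i, ] <- res$direction
    }
  }
  triads$cv_m_per_s <- cv
  triads$dir_x <- dir[, 1]; triads$dir_y <- dir[, 2]; triads$dir_z <- dir[, 3]
  triads
}

#' Fit an ideal circular wavefront to a kernel
#'
#' Nonlinear least squares of `t_i = t0 + |p_i - c| / v` over the wavefront
#' origin `c`, onset `t0` and regional speed `v`, by Levenberg-Marquardt
#' with multiple restarts placed behind the kernel along the planar-wave
#' direction. For each candidate origin the optimal `(t0, 1/v)` solve is
#' linear, so only the origin is iterated. The residual quality index
#' `eta` is the RMS temporal residual (converted to seconds) divided by the
#' mean electrode distance to the fitted origin (s/mm); the wavefront radius
#' is `v * (median(t_i) - t0)` in mm.
#'
#' @param kernel a [Kernel-class] with at least 5 usable electrodes.
#' @return a [WavefrontFit-class].
#' @export
fitCircularWavefront <- function(kernel) {
  ok <- kernel@contact_ok & is.finite(kernel@lat_ms)
  if (sum(ok) < 5)
    stop("need at least 5 electrodes with LATs to fit a circular wavefront")
  p <- kernel@electrode_positions[ok, , drop = FALSE]
  t <- kernel@lat_ms[ok]
  pb <- .planeBasis(p)

  # linear profile over (t0, slowness) given an origin; returns sse
  profile <- function(cc) {
    d <- sqrt(colSums((t(p) - cc)^2))
    X <- cbind(1, d)
    fit <- tryCatch(qr.solve(X, t), error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit[2]) || fit[2] <= 0)
      return(list(sse = Inf))
    r <- t - X %*% fit
    list(sse = sum(r^2), t0 = fit[1], slow = fit[2], d = d,
         resid = as.numeric(r))
  }
  residFun <- function(cc) {
    pr <- profile(cc)
    if (!is.finite(pr$sse)) return(rep(1e6, length(t)))
    pr$resid
  }
  # initial wave direction from an in-plane planar fit (the 3D regression is
  # rank-deficient for coplanar electrodes): t ~ (p.e1, p.e2) . s2
  p2 <- cbind(p %*% pb$e1, p %*% pb$e2)
  s2 <- tryCatch(qr.solve(cbind(1, p2), t)[-1], error = function(e) c(1, 0))
  ns2 <- sqrt(sum(s2^2))
  dirw <- if (ns2 > 0) (s2[1] * pb$e1 + s2[2] * pb$e2) / ns2 else pb$e1
  best <- NULL; best_sse <- Inf
  for (d0 in c(15, 40, 100, 400, 2000)) for (sgn in c(-1, 1)) {
    start <- pb$center + sgn * d0 * dirw
    if (!is.finite(profile(start)$sse)) next
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = residFun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (!is.finite(profile(fit$par)$sse)) next
    sse <- sum(residFun(fit$par)^2)
    if (sse < best_sse) { best_sse <- sse; best <- fit$par }
  }
  if (is.null(best) || !is.finite(best_sse))
    stop("circular wavefront fit failed to converge; kernel rejected")
  pr <- profile(best)
  v <- unname(1 / pr$slow)               # mm/ms = m/s
  rms_ms <- sqrt(mean(pr$resid^2))
  eta <- unname((rms_ms / 1000) / mean(pr$d))  # s/mm
  radius <- unname(v * (median(t) - pr$t0))
  new("WavefrontFit", origin = as.numeric(best), onset_ms = unname(pr$t0),
      speed_m_per_s = v, radius_mm = radius, eta = eta,
      accepted = NA, converged = TRUE)
}

#' Partition kernels by wavefront-fit quality
#'
#' A high residual index eta indicates the wavefront is not smooth enough
#' within the kernel for the plane-wave triad analysis, so by default
#' kernels with `eta` strictly greater than the threshold are rejected
#' (a kernel exactly at the threshold is accepted). The opposite, literal
#' reading of the rejection rule is available via `direction = "below"`.
#'
#' @param fits list of [WavefrontFit-class] objects.
#' @param eta_threshold threshold in s/mm (default 5).
#' @param direction `"above"` (default: reject eta > threshold) or
#'   `"below"` (reject eta < threshold).
#' @return list with `accepted` and `rejected` lists of fits (each fit's
#'   `accepted` slot filled in) and logical vector `keep`.
#' @export
rejectKernels <- function(fits, eta_threshold = 5,
                          direction = c("above", "below")) {
  direction <- match.arg(direction)
  eta <- vapply(fits, function(f) f@eta, numeric(1))
  keep <- if (direction == "above") eta <= eta_threshold else
    eta >= eta_threshold
  fits <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]; f@accepted <- keep[i]; f
  })
  list(accepted = fits[keep], rejected = fits[!keep], keep = keep)
}
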