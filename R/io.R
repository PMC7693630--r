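# Artifact I/O: ASCII PLY / legacy VTK meshes, NIfTI volumes, kernel and
# observation CSV, fit JSON, transform and config YAML. Coordinates are
# always mm, times ms, speeds m/s.

#' Write / read a surface mesh as ASCII PLY
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output file.
#' @return `writeMeshPLY` returns `path` invisibly; `readMeshPLY` returns a
#'   [SurfaceMesh-class].
#' @export
writeMeshPLY <- function(mesh, path) {
  v <- mesh@vertices; n <- mesh@normals; f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               "property double nx", "property double ny", "property double nz",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(format(cbind(v, n), digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' @rdname writeMeshPLY
#' @export
readMeshPLY <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("not an ASCII PLY file: ", path)
  hdr_end <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vdat <- do.call(rbind, lapply(strsplit(
    lines[(hdr_end + 1):(hdr_end + nv)], " +"), as.numeric))
  fdat <- do.call(rbind, lapply(strsplit(
    lines[(hdr_end + nv + 1):(hdr_end + nv + nf)], " +"), as.integer))
  if (any(fdat[, 1] != 3L)) stop("only triangle faces are supported")
  new("SurfaceMesh", vertices = vdat[, 1:3, drop = FALSE],
      faces = fdat[, 2:4, drop = FALSE] + 1L,
      normals = .unit(vdat[, 4:6, drop = FALSE]))
}

#' Write a mesh (with optional per-vertex scalars) as legacy ASCII VTK
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output file.
#' @param scalars optional named list of per-vertex numeric vectors written
#'   as POINT_DATA arrays (e.g. raw/NI/IIR maps for visualization).
#' @return `path`, invisibly.
#' @export
writeMeshVTK <- function(mesh, path, scalars = NULL) {
  v <- mesh@vertices; f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nrow(v))), con)
  writeLines(apply(format(v, digits = 17, trim = TRUE, scientific = FALSE),
                   1, paste, collapse = " "), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  if (!is.null(scalars)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(scalars)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(scalars[[nm]], digits = 17, trim = TRUE), con)
    }
  }
  invisible(path)
}

#' Write / read an intensity volume as NIfTI-1
#'
#' The affine carries the voxel spacing and origin.
#'
#' @param volume an [IntensityVolume-class].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `writeVolumeNIfTI` returns `path` invisibly; `readVolumeNIfTI`
#'   returns an [IntensityVolume-class].
#' @export
writeVolumeNIfTI <- function(volume, path) {
  img <- RNifti::asNifti(volume@voxels)
  RNifti::pixdim(img) <- volume@spacing
  affine <- diag(c(volume@spacing, 1))
  affine[1:3, 4] <- volume@origin
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolumeNIfTI
#' @export
readVolumeNIfTI <- function(path) {
  img <- RNifti::readNifti(path)
  affine <- RNifti::xform(img)
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("malformed NIfTI affine: not invertible")
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  new("IntensityVolume", voxels = array(as.numeric(img), dim = dim(img)),
      spacing = as.numeric(spacing), origin = as.numeric(affine[1:3, 4]))
}

.kernel_cols <- c("patient_id", "scan_id", "kernel_id", "cycle_length_ms",
                  "electrode_idx", "x_mm", "y_mm", "z_mm", "lat_ms",
                  "contact_ok")

#' Write / read kernels as CSV
#'
#' One row per electrode with columns patient_id, scan_id, kernel_id,
#' cycle_length_ms, electrode_idx, x_mm, y_mm, z_mm, lat_ms, contact_ok.
#' On read, a missing `lat_ms` marks the electrode as non-contact rather
#' than raising an error; unknown extra columns are ignored. Schema
#' violations report the offending column.
#'
#' @param kernels list of [Kernel-class] objects.
#' @param path CSV file path.
#' @return `writeKernelCSV` returns `path` invisibly; `readKernelCSV`
#'   returns a list of [Kernel-class] objects.
#' @export
writeKernelCSV <- function(kernels, path) {
  rows <- lapply(kernels, function(k) {
    n <- nrow(k@electrode_positions)
    data.frame(patient_id = k@patient_id, scan_id = k@scan_id,
               kernel_id = k@kernel_id, cycle_length_ms = k@cycle_length_ms,
               electrode_idx = seq_len(n),
               x_mm = k@electrode_positions[, 1],
               y_mm = k@electrode_positions[, 2],
               z_mm = k@electrode_positions[, 3],
               lat_ms = k@lat_ms, contact_ok = k@contact_ok,
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeKernelCSV
#' @export
readKernelCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.kernel_cols, names(df))
  if (length(miss))
    stop("kernel CSV lacks column(s): ", paste(miss, collapse = ", "))
  for (col in c("cycle_length_ms", "x_mm", "y_mm", "z_mm")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop(sprintf("kernel CSV: non-numeric '%s' at row %d", col, bad[1]))
  }
  df$contact_ok <- as.logical(df$contact_ok) & is.finite(df$lat_ms)
  lapply(split(df, df$kernel_id), function(g) {
    g <- g[order(g$electrode_idx), ]
    new("Kernel", patient_id = as.character(g$patient_id[1]),
        scan_id = as.character(g$scan_id[1]),
        kernel_id = as.character(g$kernel_id[1]),
        cycle_length_ms = g$cycle_length_ms[1],
        electrode_positions = as.matrix(g[, c("x_mm", "y_mm", "z_mm")]),
        lat_ms = g$lat_ms, contact_ok = g$contact_ok)
  })
}

#' Write / read the triad observation table as CSV
#'
#' @param obs observation data.frame (columns cv, intensity, metric,
#'   patient, cycle_length, area_mm2, scan, ...).
#' @param path CSV file path.
#' @return `writeObservationCSV` returns `path` invisibly;
#'   `readObservationCSV` the data.frame.
#' @export
writeObservationCSV <- function(obs, path) {
  write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeObservationCSV
#' @export
readObservationCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("cv", "intensity", "patient", "cycle_length")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("observation CSV lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Serialize a multilevel fit to JSON
#'
#' @param fit a [MixedModelFit-class].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
writeFitJSON <- function(fit, path) {
  out <- list(metric = fit@metric,
              beta0 = fit@beta0, beta1 = fit@beta1,
              se_beta0 = fit@se_beta0, se_beta1 = fit@se_beta1,
              u = as.list(fit@u), v = as.list(fit@v),
              beta2 = as.list(fit@beta2),
              var_u = fit@var_u, var_v = fit@var_v,
              var_slope = fit@var_slope, var_eps = fit@var_eps,
              loglik = fit@loglik, df = fit@df, n_obs = fit@n_obs,
              singular = fit@singular, exact_fit = fit@exact_fit)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a rigid transform as YAML (4x4 row-major matrix)
#'
#' @param transform a [RigidTransform-class].
#' @param path YAML file path.
#' @return `writeTransformYAML` returns `path` invisibly;
#'   `readTransformYAML` a [RigidTransform-class].
#' @export
writeTransformYAML <- function(transform, path) {
  m <- rbind(cbind(transform@rotation, transform@translation), c(0, 0, 0, 1))
  yaml::write_yaml(list(matrix = as.list(as.data.frame(t(m)))), path,
                   precision = 17)
  invisible(path)
}

#' @rdname writeTransformYAML
#' @export
readTransformYAML <- function(path) {
  y <- yaml::read_yaml(path)
  m <- t(vapply(y$matrix, as.numeric, numeric(4)))
  if (!all(dim(m) == c(4, 4))) m <- matrix(unlist(y$matrix), 4, 4, byrow = FALSE)
  dimnames(m) <- NULL
  new("RigidTransform", rotation = m[1:3, 1:3],
      translation = as.numeric(m[1:3, 4]))
}
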