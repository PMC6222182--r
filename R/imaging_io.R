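# CT volume I/O, coordinate transforms, and surface meshing.
#
# Conventions (fixed package-wide):
#   * voxel indices are 0-based; an integer index addresses a voxel center;
#   * the world frame is the DICOM patient frame (LPS, +x left, +y posterior,
#     +z superior), in mm; NIfTI input (RAS) is converted on load;
#   * `affine` maps homogeneous 0-based voxel indices to world mm.

#' CT volume container
#'
#' Bundles a 3D scalar grid in Hounsfield units with its voxel-to-world
#' affine. All package geometry is expressed in this object's world frame
#' (LPS patient coordinates, mm).
#'
#' @param voxels 3D numeric array of intensities (HU).
#' @param affine 4x4 matrix mapping homogeneous 0-based voxel indices
#'   `(i, j, k, 1)` to world mm.
#' @param orientation world-frame tag; only `"LPS"` is used internally.
#' @return An object of class `ct_volume` with fields `voxels`, `affine`,
#'   `spacing` (per-axis mm, derived from the affine columns) and
#'   `orientation`.
#' @export
ct_volume <- function(voxels, affine = diag(4), orientation = "LPS") {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  if (!all(is.finite(voxels))) stop("voxel intensities must be finite")
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0)) stop("spacing components must be positive")
  structure(list(voxels = voxels, affine = affine, spacing = spacing,
                 orientation = orientation),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm (%s)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$orientation))
  cat(sprintf("  HU range [%.0f, %.0f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Map voxel indices to world coordinates (and back)
#'
#' `world_from_voxel` applies the volume affine to continuous 0-based voxel
#' indices; `voxel_from_world` applies its inverse. The two are inverse maps
#' to better than 1e-6 mm.
#'
#' @param vol a [ct_volume()].
#' @param ijk numeric length-3 vector or n x 3 matrix of 0-based voxel
#'   indices (may be fractional).
#' @param xyz numeric length-3 vector or n x 3 matrix of world mm points.
#' @return Points in the other frame, matching the input shape.
#' @export
world_from_voxel <- function(vol, ijk) {
  single <- is.null(dim(ijk))
  m <- if (single) matrix(ijk, 1L) else as.matrix(ijk)
  out <- t(vol$affine[1:3, 1:3] %*% t(m)) +
    matrix(vol$affine[1:3, 4], nrow(m), 3L, byrow = TRUE)
  if (single) drop(out) else out
}

#' @rdname world_from_voxel
#' @export
voxel_from_world <- function(vol, xyz) {
  single <- is.null(dim(xyz))
  m <- if (single) matrix(xyz, 1L) else as.matrix(xyz)
  inv <- solve(vol$affine)
  out <- t(inv[1:3, 1:3] %*% t(m)) +
    matrix(inv[1:3, 4], nrow(m), 3L, byrow = TRUE)
  if (single) drop(out) else out
}

# world-mm bounding box of the voxel lattice (voxel centers)
volume_bounds <- function(vol) {
  d <- dim(vol$voxels) - 1L
  corners <- as.matrix(expand.grid(c(0, d[1]), c(0, d[2]), c(0, d[3])))
  w <- world_from_voxel(vol, corners)
  rbind(lo = apply(w, 2, min), hi = apply(w, 2, max))
}

#' Load a CT volume from NIfTI or a DICOM series
#'
#' NIfTI files are read with RNifti and converted from the NIfTI RAS world
#' frame to the package's LPS frame. DICOM directories are read slice-wise:
#' slices are sorted by their position projected on the slice normal (not by
#' InstanceNumber), stored values are rescaled to HU with RescaleSlope /
#' RescaleIntercept, and the affine is assembled from ImageOrientationPatient,
#' PixelSpacing and the slice origins.
#'
#' @param path a NIfTI file or a directory containing one DICOM series.
#' @param format one of `"auto"`, `"nifti"`, `"dicom_dir"`.
#' @return A [ct_volume()].
#' @export
load_volume <- function(path, format = c("auto", "nifti", "dicom_dir")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_dir" else "nifti"
  if (format == "nifti") load_nifti(path) else load_dicom_series(path)
}

load_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4L, 4L)
  # NIfTI world is RAS; LPS flips the first two world axes
  ras_to_lps <- diag(c(-1, -1, 1, 1))
  vox <- array(as.numeric(img), dim = dim(img))
  ct_volume(vox, ras_to_lps %*% aff)
}

#' Write a CT volume or mask to NIfTI-1
#'
#' The LPS affine is converted back to the NIfTI RAS convention.
#'
#' @param vol a [ct_volume()], or a 3D array together with `affine`.
#' @param path output filename (`.nii` or `.nii.gz`).
#' @param affine affine override when `vol` is a bare array.
#' @param datatype passed to RNifti (e.g. `"uint8"` for masks).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, affine = NULL, datatype = "auto") {
  if (inherits(vol, "ct_volume")) {
    arr <- vol$voxels
    aff <- vol$affine
  } else {
    arr <- vol
    aff <- affine %||% diag(4)
  }
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  ras <- diag(c(-1, -1, 1, 1)) %*% aff
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::sform(img) <- structure(ras, code = 2L)
  RNifti::qform(img) <- structure(ras, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Triangle mesh in world coordinates
#'
#' @param vertices n x 3 numeric matrix of world-mm points.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (nrow(faces) == 0L) stop("mesh has no faces")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
          faces[, 1] == faces[, 3]))
    stop("degenerate (repeated-vertex) triangles")
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Total surface area of a triangle mesh
#'
#' @param mesh a [tri_mesh()].
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  a <- v[mesh$faces[, 2], , drop = FALSE] - v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 3], , drop = FALSE] - v[mesh$faces[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Extract the boundary surface of a binary mask
#'
#' Runs marching tetrahedra at iso-level 0.5 on the 0/1 grid and maps the
#' vertices through the affine, yielding a closed triangulated surface of the
#' mask boundary in world mm. A light Gaussian pre-smoothing (default half a
#' voxel) de-aliases the binary staircase so surface areas approach their
#' analytic values; it falls back to the raw grid whenever smoothing would
#' lose the surface entirely (e.g. single-voxel masks), and `smooth_sigma_vox
#' = 0` disables it.
#'
#' @param mask 3D logical/numeric array.
#' @param affine 4x4 voxel-to-world affine (0-based indices).
#' @param smooth_sigma_vox pre-smoothing scale in voxels.
#' @return A [tri_mesh()].
#' @export
extract_surface <- function(mask, affine = diag(4), smooth_sigma_vox = 0.5) {
  arr <- array(as.numeric(mask), dim = dim(mask))
  if (sum(arr) == 0) stop("mask is empty")
  # pad so that boundary voxels produce closed surfaces
  d <- dim(arr)
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- arr
  if (smooth_sigma_vox > 0) {
    sm <- cpp_gaussian_smooth(padded, dim(padded), rep(smooth_sigma_vox, 3))
    if (any(sm > 0.5)) padded <- sm
  }
  res <- cpp_marching_tets(padded, dim(padded), 0.5)
  verts <- res$vertices - 1  # undo pad; still 0-based voxel coords
  w <- t(affine[1:3, 1:3] %*% t(verts)) +
    matrix(affine[1:3, 4], nrow(verts), 3L, byrow = TRUE)
  tri_mesh(w, res$faces)
}

#' Write / read a Wavefront OBJ mesh
#'
#' ASCII OBJ with `v x y z` vertex lines and 1-based `f i j k` face lines;
#' `read_obj` parses the same subset back, so write/read round-trips are the
#' identity on faces and on vertices to float precision.
#'
#' @param mesh a [tri_mesh()].
#' @param path output file.
#' @return `path` invisibly (`write_obj`); a [tri_mesh()] (`read_obj`).
#' @export
write_obj <- function(mesh, path) {
  if (!inherits(mesh, "tri_mesh")) stop("mesh must be a tri_mesh")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# airway surface mesh", con)
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
    as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  tri_mesh(verts, faces)
}
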