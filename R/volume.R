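#' Signed volume of the tetrahedron spanned by a triangle and the origin
#'
#' The volume of the tetrahedron formed by triangle (p1, p2, p3) and the
#' coordinate origin is (1/3) a h with a the triangle area and h its
#' height over the origin; in vector form this is the scalar triple
#' product (1/6) (p1 x p2) . p3. The sign follows the vertex winding:
#' positive when the triangle's normal points away from the origin,
#' negative when it points towards it. Antisymmetric under swapping any
#' two arguments; degenerate (collinear) triangles give 0.
#'
#' @param p1,p2,p3 numeric length-3 vertex positions (mm).
#' @return signed volume in mm^3.
#' @examples
#' tetra_signed_volume(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) # 1/6
#' @export
tetra_signed_volume <- function(p1, p2, p3) {
  stopifnot(length(p1) == 3L, length(p2) == 3L, length(p3) == 3L,
            all(is.finite(c(p1, p2, p3))))
  (p1[1L] * (p2[2L] * p3[3L] - p2[3L] * p3[2L]) +
   p1[2L] * (p2[3L] * p3[1L] - p2[1L] * p3[3L]) +
   p1[3L] * (p2[1L] * p3[2L] - p2[2L] * p3[1L])) / 6
}

#' Enclosed volume of a closed surface mesh by polygon summation
#'
#' Sums the signed tetrahedron volumes of every face against a reference
#' point. For a watertight, consistently oriented surface the sum is the
#' enclosed volume, signed by global orientation (positive for outward
#' winding). The reference point is mathematically irrelevant for closed
#' surfaces; internally the bounding-box centre is used to reduce
#' floating-point cancellation for meshes far from the origin, which is
#' provably volume-neutral. Accumulation uses R's extended-precision
#' summation.
#'
#' @param mesh a [triangle_mesh()].
#' @param strict if `TRUE` (default) refuse meshes that are not watertight
#'   or not consistently oriented, because the summation is only an
#'   enclosed volume for closed oriented surfaces. With `FALSE` the sum is
#'   computed anyway and the diagnostics flag the defect.
#' @return A `volume_result`: list with `volume_cm3`, `signed_volume_cm3`,
#'   `volume_mm3`, `signed_volume_mm3`, `method = "mesh_polygon_summation"`,
#'   `n_elements` (faces) and `diagnostics` ([mesh_diagnostics()]).
#' @examples
#' mesh_volume(cube_mesh(10))$volume_cm3  # exactly 1
#' @export
mesh_volume <- function(mesh, strict = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  diag <- mesh_diagnostics(mesh)
  if (strict && !(diag$is_watertight && diag$is_orientation_consistent))
    stop("mesh is not watertight/consistently oriented; ",
         "its polygon-summation volume is not an enclosed volume ",
         "(use strict = FALSE to compute it anyway)")
  v <- mesh$vertices
  ctr <- (apply(v, 2L, min) + apply(v, 2L, max)) / 2
  v <- sweep(v, 2L, ctr)
  p1 <- v[mesh$faces[, 1L], , drop = FALSE]
  p2 <- v[mesh$faces[, 2L], , drop = FALSE]
  p3 <- v[mesh$faces[, 3L], , drop = FALSE]
  signed_mm3 <- sum(rowSums(cross3(p1, p2) * p3)) / 6
  volume_result(signed_mm3, method = "mesh_polygon_summation",
                n_elements = nrow(mesh$faces), diagnostics = diag)
}

volume_result <- function(signed_mm3, method, n_elements, diagnostics = NULL) {
  structure(list(
    volume_cm3 = abs(signed_mm3) / 1000,
    signed_volume_cm3 = signed_mm3 / 1000,
    volume_mm3 = abs(signed_mm3),
    signed_volume_mm3 = signed_mm3,
    method = method,
    n_elements = as.integer(n_elements),
    diagnostics = diagnostics
  ), class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("Volume: %.4f cm^3 (signed %.4f cm^3)\n",
              x$volume_cm3, x$signed_volume_cm3))
  cat(sprintf("  method: %s over %d %s\n", x$method, x$n_elements,
              if (x$method == "slice_summation") "slices" else "faces"))
  if (inherits(x$diagnostics, "mesh_diagnostics") &&
      !(x$diagnostics$is_watertight && x$diagnostics$is_orientation_consistent))
    cat("  WARNING: surface not closed/oriented; volume is not well-defined\n")
  invisible(x)
}

#' Binary voxel mask with anisotropic spacing
#'
#' @param occupancy 3D array of 0/1 (logical accepted).
#' @param spacing voxel edge lengths (dx, dy, dz) in mm, all > 0.
#' @param origin position (mm) of the corner of voxel (1,1,1); voxel
#'   (i,j,k) occupies the half-open box
#'   `[origin + (i-1) * dx, origin + i * dx) x ...`.
#' @param slice_axis which grid axis (1, 2 or 3) is the slicing (long)
#'   axis for slice-summation volumetry. Default 3.
#' @return an object of class `voxel_mask`.
#' @export
voxel_mask <- function(occupancy, spacing, origin = c(0, 0, 0), slice_axis = 3L) {
  occupancy <- as.array(occupancy)
  if (is.logical(occupancy)) {
    o <- occupancy
    occupancy <- array(0L, dim(o)); occupancy[o] <- 1L
  }
  storage.mode(occupancy) <- "integer"
  if (length(dim(occupancy)) != 3L) stop("'occupancy' must be a 3D array")
  if (!all(occupancy %in% c(0L, 1L))) stop("'occupancy' must contain only 0/1")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive lengths (mm)")
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) stop("'slice_axis' must be 1, 2 or 3")
  structure(list(occupancy = occupancy, spacing = spacing,
                 origin = as.numeric(origin), slice_axis = slice_axis),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("Voxel mask %d x %d x %d, spacing (%g, %g, %g) mm, slice axis %d\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$slice_axis))
  cat(sprintf("  %d occupied voxels (%.4f cm^3)\n", sum(x$occupancy),
              sum(x$occupancy) * prod(x$spacing) / 1000))
  invisible(x)
}

#' Cross-sectional area of one mask slice
#'
#' The voxel area of a slice: number of occupied voxels times the in-plane
#' voxel area.
#'
#' @param mask_slice 2D binary matrix (one slice of a mask).
#' @param spacing in-plane voxel edge lengths (dx, dy) in mm.
#' @return area in mm^2.
#' @export
slice_area <- function(mask_slice, spacing) {
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 2L, all(spacing > 0))
  if (!all(mask_slice %in% c(0, 1))) stop("slice must be binary")
  sum(mask_slice) * spacing[1L] * spacing[2L]
}

#' Chamber volume by Simpson's-rule slice summation
#'
#' Clinical Simpson's rule: the mask is divided into equally spaced slices
#' perpendicular to the slicing axis, the voxel area of each slice is
#' measured and multiplied by the slice thickness, and the slice volumes
#' are summed. This is deliberately the flat disk-area-times-thickness
#' rule (the clinical platforms' behaviour), not a higher-order
#' quadrature; it equals occupied-voxel count times voxel volume and is
#' therefore invariant under the choice of slicing axis.
#'
#' @param mask a [voxel_mask()].
#' @param slice_axis override the mask's slicing axis.
#' @return A `volume_result` with `method = "slice_summation"`,
#'   `n_elements` the number of non-empty slices, and per-slice areas
#'   (mm^2) in `diagnostics$slice_areas_mm2`.
#' @export
slice_volume <- function(mask, slice_axis = NULL) {
  stopifnot(inherits(mask, "voxel_mask"))
  ax <- if (is.null(slice_axis)) mask$slice_axis else as.integer(slice_axis)
  if (!ax %in% 1:3) stop("'slice_axis' must be 1, 2 or 3")
  counts <- apply(mask$occupancy, ax, sum)
  inplane <- prod(mask$spacing[-ax])
  dz <- mask$spacing[ax]
  areas <- counts * inplane
  signed_mm3 <- sum(areas) * dz
  res <- volume_result(signed_mm3, method = "slice_summation",
                       n_elements = sum(counts > 0L),
                       diagnostics = list(slice_axis = ax,
                                          slice_thickness_mm = dz,
                                          slice_areas_mm2 = areas))
  res
}

#' Compare the two volume engines on one object
#'
#' Runs polygon summation on a surface mesh and slice summation on a voxel
#' mask assumed to represent the same object, and reports both volumes,
#' their difference and relative difference (relative to the mean of the
#' two).
#'
#' @param mesh a [triangle_mesh()].
#' @param mask a [voxel_mask()].
#' @param strict passed to [mesh_volume()].
#' @return list with `mesh` and `slice` `volume_result`s,
#'   `difference_cm3` (mesh minus slice) and `relative_difference`.
#' @export
compare_engines <- function(mesh, mask, strict = TRUE) {
  vm <- mesh_volume(mesh, strict = strict)
  vs <- slice_volume(mask)
  d <- vm$volume_cm3 - vs$volume_cm3
  m <- (vm$volume_cm3 + vs$volume_cm3) / 2
  structure(list(mesh = vm, slice = vs, difference_cm3 = d,
                 relative_difference = if (m > 0) d / m else 0),
            class = "engine_comparison")
}

#' @export
print.engine_comparison <- function(x, ...) {
  cat(sprintf("Polygon summation: %.4f cm^3 (%d faces)\n",
              x$mesh$volume_cm3, x$mesh$n_elements))
  cat(sprintf("Slice summation:   %.4f cm^3 (%d slices)\n",
              x$slice$volume_cm3, x$slice$n_elements))
  cat(sprintf("Difference: %+.4f cm^3 (%+.3f%%)\n",
              x$difference_cm3, 100 * x$relative_difference))
  invisible(x)
}

#' Read a binary segmentation mask from NIfTI
#'
#' Voxel spacing is taken from the image's pixel dimensions; images whose
#' affine is not axis-aligned (non-zero off-diagonal rotation part) are
#' rejected, because a sheared/rotated grid has no well-defined slice
#' stack in grid coordinates.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param slice_axis slicing axis for [slice_volume()].
#' @param threshold values strictly above this are occupied (handles
#'   masks stored as 0/255 or probabilities).
#' @return a [voxel_mask()].
#' @export
read_mask_nifti <- function(path, slice_axis = 3L, threshold = 0.5) {
  img <- RNifti::readNifti(path)
  xf <- unclass(RNifti::xform(img))
  rot <- xf[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)))))
    stop("NIfTI affine is not axis-aligned; rotated/sheared grids are not supported")
  spacing <- abs(RNifti::pixdim(img))[1:3]
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) arr <- array(arr, dim(arr)[1:3])
  voxel_mask(arr > threshold, spacing = spacing,
             origin = xf[1:3, 4L], slice_axis = slice_axis)
}

#' Write a voxel mask to NIfTI
#'
#' @param mask a [voxel_mask()].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  img <- RNifti::asNifti(mask$occupancy)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
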