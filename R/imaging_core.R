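#' Physical image grid
#'
#' Describes the geometry shared by a volume and its segmentation masks: the
#' voxel lattice dimensions, the physical voxel spacing in millimeters along
#' each axis, and the physical position (mm) of the center of voxel
#' \code{(1,1,1)} (indices are 1-based in R; physical coordinates refer to
#' voxel centers).
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (each > 0).
#' @param origin numeric vector of length 3, mm position of the first voxel
#'   center. Defaults to \code{c(0, 0, 0)}.
#' @return An object of class \code{image_grid}.
#' @examples
#' g <- image_grid(c(64, 64, 32), spacing = c(0.8, 0.8, 3))
#' voxel_volume_cm3(g)
#' @export
image_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L))
    stop("invalid grid: `shape` must be 3 integers, each >= 1", call. = FALSE)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("invalid grid: `spacing` must be 3 positive reals (mm)", call. = FALSE)
  if (length(origin) != 3L || anyNA(origin))
    stop("invalid grid: `origin` must be 3 finite reals (mm)", call. = FALSE)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %d x %d x %d voxels @ (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Test two grids for physical identity
#'
#' Grids are considered identical when shapes match exactly and spacing and
#' origin agree within \code{tol} millimeters. All cross-image operations
#' require identical grids; no registration is performed.
#'
#' @param a,b \code{image_grid} objects.
#' @param tol numeric tolerance in mm.
#' @return logical scalar.
#' @export
grids_identical <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "image_grid"), inherits(b, "image_grid"))
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

check_same_grid <- function(a, b, what = "objects") {
  if (!grids_identical(a, b))
    stop(sprintf("grid mismatch: %s must share an identical grid (shape, spacing, origin); register upstream", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Single-phase 3D scalar volume
#'
#' @param values 3D numeric array of voxel intensities; all values finite.
#' @param grid an \code{image_grid} whose shape equals \code{dim(values)}.
#' @param phase one of \code{"unenhanced_T1"}, \code{"arterial_T1"},
#'   \code{"subtracted"}.
#' @return An object of class \code{volume_image}.
#' @export
volume_image <- function(values, grid, phase = c("unenhanced_T1", "arterial_T1", "subtracted")) {
  phase <- match.arg(phase)
  stopifnot(inherits(grid, "image_grid"))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("`values` dimensions do not match grid shape", call. = FALSE)
  if (!all(is.finite(values)))
    stop("`values` must be finite everywhere", call. = FALSE)
  structure(list(values = values, grid = grid, phase = phase),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("volume_image [%s]: ", x$phase))
  print(x$grid)
  invisible(x)
}

#' Binary lesion segmentation mask
#'
#' @param voxels 3D logical array, TRUE inside the lesion. An empty mask is
#'   legal (it is the complete-devascularization output).
#' @param grid the \code{image_grid} the mask lives on.
#' @param lesion_id identifier string.
#' @return An object of class \code{segmentation_mask}.
#' @export
segmentation_mask <- function(voxels, grid, lesion_id = "lesion") {
  stopifnot(inherits(grid, "image_grid"))
  if (is.numeric(voxels)) voxels <- array(voxels != 0, dim = dim(voxels))
  if (!is.array(voxels) || length(dim(voxels)) != 3L || !is.logical(voxels))
    stop("`voxels` must be a 3D logical array", call. = FALSE)
  if (!identical(as.integer(dim(voxels)), grid$shape))
    stop("mask dimensions do not match grid shape", call. = FALSE)
  if (anyNA(voxels)) stop("mask voxels must not contain NA", call. = FALSE)
  structure(list(voxels = voxels, grid = grid, lesion_id = as.character(lesion_id)),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("segmentation_mask '%s': %d voxels (%.4g cm^3) on ",
              x$lesion_id, sum(x$voxels), mask_volume_cm3(x)))
  print(x$grid)
  invisible(x)
}

#' Volume of one voxel in cubic centimeters
#'
#' @param grid an \code{image_grid}.
#' @return positive numeric, \code{prod(spacing) / 1000} (mm^3 to cm^3).
#' @examples
#' voxel_volume_cm3(image_grid(c(10, 10, 10), c(2, 2, 2)))  # 0.008
#' @export
voxel_volume_cm3 <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  prod(grid$spacing) / 1000
}

#' Mask volume in cubic centimeters
#'
#' Voxel count times physical voxel volume. This is the whole-tumor volume
#' when applied to a lesion mask and the enhancing-tumor volume when applied
#' to the enhancing-voxel mask.
#'
#' @param mask a \code{segmentation_mask}.
#' @return non-negative numeric (cm^3); 0 for an empty mask.
#' @export
mask_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  sum(mask$voxels) * voxel_volume_cm3(mask$grid)
}

## Integer voxel offsets whose physical center distance is <= radius_mm.
## The structuring element is a ball in physical space, so anisotropic
## slice spacing shrinks the element along the coarse axis as it should.
ball_offsets <- function(spacing, radius_mm) {
  nmax <- floor(radius_mm / spacing)
  ox <- seq.int(-nmax[1], nmax[1])
  oy <- seq.int(-nmax[2], nmax[2])
  oz <- seq.int(-nmax[3], nmax[3])
  off <- expand.grid(i = ox, j = oy, k = oz)
  d2 <- (off$i * spacing[1])^2 + (off$j * spacing[2])^2 + (off$k * spacing[3])^2
  off[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

## Shift a 3D logical array by integer voxel offset, padding with FALSE.
shift_mask <- function(m, di, dj, dk) {
  d <- dim(m)
  out <- array(FALSE, dim = d)
  src_i <- seq_len(d[1]) - di; src_j <- seq_len(d[2]) - dj; src_k <- seq_len(d[3]) - dk
  ok_i <- src_i >= 1 & src_i <= d[1]
  ok_j <- src_j >= 1 & src_j <= d[2]
  ok_k <- src_k >= 1 & src_k <= d[3]
  if (!any(ok_i) || !any(ok_j) || !any(ok_k)) return(out)
  out[which(ok_i), which(ok_j), which(ok_k)] <-
    m[src_i[ok_i], src_j[ok_j], src_k[ok_k], drop = FALSE]
  out
}

#' Balloon-style mask refinement
#'
#' Grows (\code{delta_mm > 0}) or shrinks (\code{delta_mm < 0}) a segmentation
#' mask by morphological dilation or erosion with a ball of radius
#' \code{|delta_mm|} defined in physical millimeters, honoring anisotropic
#' voxel spacing. This is a physical-space surrogate for the interactive
#' balloon tool of semi-automatic segmentation software.
#'
#' Erosion treats the volume outside the grid as background, so a mask
#' touching the image boundary erodes inward from the boundary as well.
#'
#' @param mask a \code{segmentation_mask}.
#' @param delta_mm signed radius in mm; 0 returns the mask unchanged.
#' @param max_delta_mm guard on \code{|delta_mm|} (default 20 mm).
#' @return A \code{segmentation_mask}. If erosion empties a non-empty mask the
#'   empty mask is returned with attribute \code{emptied = TRUE} and a warning.
#' @export
balloon_refine <- function(mask, delta_mm, max_delta_mm = 20) {
  stopifnot(inherits(mask, "segmentation_mask"))
  if (!is.finite(delta_mm) || abs(delta_mm) > max_delta_mm)
    stop(sprintf("|delta_mm| must be finite and <= %g mm", max_delta_mm), call. = FALSE)
  if (delta_mm == 0) return(mask)
  off <- ball_offsets(mask$grid$spacing, abs(delta_mm))
  m <- mask$voxels
  if (delta_mm > 0) {
    acc <- array(FALSE, dim = dim(m))
    for (r in seq_len(nrow(off)))
      acc <- acc | shift_mask(m, off$i[r], off$j[r], off$k[r])
  } else {
    acc <- array(TRUE, dim = dim(m))
    for (r in seq_len(nrow(off)))
      acc <- acc & shift_mask(m, off$i[r], off$j[r], off$k[r])
  }
  out <- segmentation_mask(acc, mask$grid, mask$lesion_id)
  if (!any(acc) && any(m)) {
    warning(sprintf("erosion by %g mm emptied mask '%s'", abs(delta_mm), mask$lesion_id),
            call. = FALSE)
    attr(out, "emptied") <- TRUE
  }
  out
}

## ---- NIfTI-1 I/O ------------------------------------------------------

grid_from_nifti <- function(img, file = "<nifti>") {
  x <- RNifti::xform(img)
  lin <- x[1:3, 1:3]
  if (max(abs(lin - diag(diag(lin)))) > 1e-4 || any(diag(lin) <= 0))
    stop(sprintf("%s: affine has rotation/shear or axis flips; only positive diagonal scaling is supported — resample upstream", file),
         call. = FALSE)
  d <- dim(img)
  if (length(d) != 3L) stop(sprintf("%s: expected a 3D volume", file), call. = FALSE)
  image_grid(d, spacing = diag(lin), origin = x[1:3, 4])
}

as_nifti_with_grid <- function(values, grid) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- grid$spacing
  m <- diag(c(grid$spacing, 1))
  m[1:3, 4] <- grid$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  img
}

#' Read / write volumes and masks as NIfTI-1
#'
#' Voxel spacing is taken from the header \code{pixdim}; the affine must be a
#' positive diagonal scaling (plus translation) or the file is rejected.
#' Masks are stored as uint8 0/1.
#'
#' @param file path to a \code{.nii} or \code{.nii.gz} file.
#' @param phase phase label to attach on read (not stored in NIfTI).
#' @param image a \code{volume_image}.
#' @param mask a \code{segmentation_mask}.
#' @param lesion_id identifier to attach on read.
#' @return \code{read_volume}/\code{read_mask} return the corresponding object;
#'   the writers return \code{file} invisibly.
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
read_volume <- function(file, phase = c("unenhanced_T1", "arterial_T1", "subtracted")) {
  phase <- match.arg(phase)
  img <- RNifti::readNifti(file)
  grid <- grid_from_nifti(img, file)
  volume_image(array(as.numeric(img), dim = dim(img)), grid, phase)
}

#' @rdname nifti_io
#' @export
write_volume <- function(image, file) {
  stopifnot(inherits(image, "volume_image"))
  RNifti::writeNifti(as_nifti_with_grid(image$values, image$grid), file)
  invisible(file)
}

#' @rdname nifti_io
#' @export
read_mask <- function(file, lesion_id = "lesion") {
  img <- RNifti::readNifti(file)
  grid <- grid_from_nifti(img, file)
  segmentation_mask(array(as.numeric(img) != 0, dim = dim(img)), grid, lesion_id)
}

#' @rdname nifti_io
#' @export
write_mask <- function(mask, file) {
  stopifnot(inherits(mask, "segmentation_mask"))
  img <- as_nifti_with_grid(array(as.integer(mask$voxels), dim = dim(mask$voxels)),
                            mask$grid)
  img <- RNifti::asNifti(img, datatype = "uint8")
  RNifti::writeNifti(img, file)
  invisible(file)
}

## Physical coordinates (mm) of every voxel center along one axis.
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

## Squared physical distance field from `center` (mm), as a 3D array.
distance2_field <- function(grid, center) {
  dx2 <- (axis_coords(grid, 1) - center[1])^2
  dy2 <- (axis_coords(grid, 2) - center[2])^2
  dz2 <- (axis_coords(grid, 3) - center[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}
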