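#' 3-D voxel grid with physical spacing
#'
#' A `voxel_grid` is a rank-3 numeric array plus the voxel spacing in mm
#' along each axis. All geometric quantities downstream (volumes in mm^3,
#' surface areas in mm^2) are derived from this spacing; the orientation
#' part of any NIfTI affine is deliberately ignored because every score
#' computed here is rotation-invariant.
#'
#' @param values numeric 3-D array (SUV for PET, intensity/HU for CT).
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, mm; informational only.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 4)), spacing = c(2, 2, 3.75))
#' voxel_volume(g)
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("expected 3-D volume: `values` must be a rank-3 array")
  if (any(dim(values) < 1L))
    stop("every dimension must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive finite values (mm)")
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin)),
    class = "voxel_grid"
  )
}

#' Binary mask sharing a voxel grid's geometry
#'
#' @param values logical 3-D array.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param origin numeric length-3, informational.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("expected 3-D volume: mask `values` must be a rank-3 array")
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask may not contain NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive finite values (mm)")
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin)),
    class = "binary_mask"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  rng <- range(x$values)
  cat("  values in [", signif(rng[1], 5), ", ", signif(rng[2], 5), "]\n",
      sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, ", sum(x$values), " foreground voxels\n", sep = "")
  invisible(x)
}

# geometry compatibility check shared by several operations
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' Physical volume of one voxel
#'
#' @param grid a `voxel_grid` or `binary_mask`.
#' @return Voxel volume in mm^3 (product of the spacing components).
#' @export
voxel_volume <- function(grid) {
  prod(grid$spacing)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`). Spacing is
#' taken from the header zooms; the rotational part of the affine is not
#' used (shape scores are rotation-invariant).
#'
#' @param path path to a readable NIfTI-1 file.
#' @return A [voxel_grid()].
#' @seealso [read_pet()] which additionally clips negative values.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected 3-D volume, got ", length(d), "-D image")
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(sp[1:3] <= 0))
    stop("non-positive voxel spacing in header of ", path)
  hdr <- RNifti::niftiHeader(img)
  org <- as.numeric(c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z))
  if (length(org) != 3L || anyNA(org)) org <- c(0, 0, 0)
  voxel_grid(array(as.numeric(img), dim = d), spacing = sp[1:3], origin = org)
}

#' Read a PET volume, clipping negative values to zero
#'
#' Scatter-corrected PET reconstructions can contain small negative
#' values; because the VOI threshold is defined through the mean of
#' *strictly positive* voxels, negatives are clipped at load time so they
#' can neither enter the mean nor count as "non-zero".
#'
#' @inheritParams read_volume
#' @return A [voxel_grid()] with all values >= 0.
#' @export
read_pet <- function(path) {
  g <- read_volume(path)
  g$values[g$values < 0] <- 0
  g
}

#' Write a volume as NIfTI-1
#'
#' Values are stored as 32-bit float (lossless round-trip within float32
#' precision); spacing is stored exactly in the header zooms.
#'
#' @param grid a [voxel_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a binary mask from NIfTI-1
#'
#' Any strictly non-zero voxel is foreground.
#'
#' @inheritParams read_volume
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  g <- read_volume(path)
  binary_mask(array(g$values != 0, dim = dim(g$values)),
              spacing = g$spacing, origin = g$origin)
}

#' Write a binary mask as unsigned 8-bit NIfTI-1 with values {0, 1}
#'
#' @param mask a [binary_mask()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$values), dim = dim(mask$values)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
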