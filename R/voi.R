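#' SUV statistics and VOI threshold
#'
#' The amyloid VOI is segmented at a multiple `k` of the mean SUV, where
#' the mean is taken over *strictly positive* PET voxels only ("non-zero
#' mean"). The clinically validated operating point is `k = 6`.
#'
#' @param pet a [voxel_grid()] of SUV values.
#' @param k threshold multiple (> 0), default 6.
#' @return An object of class `suv_stats` with fields `suv_mean_nonzero`,
#'   `k`, `threshold` (= `k * suv_mean_nonzero`) and the source grid
#'   dimensions.
#' @examples
#' pet <- voxel_grid(array(c(0, 0, 2, 4, 0, 0, 0, 0), c(2, 2, 2)), c(1, 1, 1))
#' compute_suv_mean(pet, k = 2)
#' @export
compute_suv_mean <- function(pet, k = 6) {
  stopifnot(inherits(pet, "voxel_grid"))
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("`k` must be a single positive number")
  pos <- pet$values[pet$values > 0]
  if (length(pos) == 0L)
    stop("no positive voxels: cannot compute the non-zero SUV mean")
  m <- mean(pos)
  structure(
    list(suv_mean_nonzero = m, k = k, threshold = k * m,
         source_dim = dim(pet$values)),
    class = "suv_stats"
  )
}

#' @export
print.suv_stats <- function(x, ...) {
  cat("<suv_stats> non-zero SUV mean ", signif(x$suv_mean_nonzero, 5),
      ", k = ", x$k, ", threshold ", signif(x$threshold, 5), "\n", sep = "")
  invisible(x)
}

#' Segment the amyloid VOI at the SUV-mean threshold
#'
#' Voxels with value >= `stats$threshold` are selected (inclusive, so a
#' uniform grid at `k = 1` yields a full mask rather than an empty one).
#' The result may be empty; [quantify_case()] treats that as an error but
#' callers of this low-level operation decide for themselves.
#'
#' @param pet a [voxel_grid()] of SUV values.
#' @param stats an `suv_stats` object computed from the same grid.
#' @return A [binary_mask()].
#' @export
threshold_voi <- function(pet, stats) {
  stopifnot(inherits(pet, "voxel_grid"), inherits(stats, "suv_stats"))
  if (!identical(dim(pet$values), stats$source_dim))
    stop("shape mismatch: `stats` was computed from a grid of different dimensions")
  binary_mask(array(pet$values >= stats$threshold, dim = dim(pet$values)),
              spacing = pet$spacing, origin = pet$origin)
}

# 26-connectivity component labels of a mask, as an integer array
component_labels <- function(mask, connectivity = 26L) {
  lab <- .cc_label_cpp(as.logical(mask$values), dim(mask$values),
                       as.integer(connectivity))
  array(lab, dim = dim(mask$values))
}

#' Remove small connected components
#'
#' Components are defined by 26-connectivity (the VOI is treated as a
#' solid). `min_voxels = 0` is the identity: all supra-threshold voxels
#' are kept and multi-component surface areas and volumes simply sum.
#'
#' @param mask a [binary_mask()].
#' @param min_voxels components with fewer voxels than this are dropped.
#' @return A [binary_mask()].
#' @export
filter_components <- function(mask, min_voxels = 0L) {
  stopifnot(inherits(mask, "binary_mask"))
  min_voxels <- as.integer(min_voxels)
  if (min_voxels <= 0L || !any(mask$values)) return(mask)
  lab <- component_labels(mask)
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts >= min_voxels)
  binary_mask(array(lab %in% keep & lab > 0L, dim = dim(mask$values)),
              spacing = mask$spacing, origin = mask$origin)
}

# fill cavities: background (6-connected) components not touching the
# array border are interior holes
fill_holes <- function(mask) {
  bg <- binary_mask(!mask$values, mask$spacing)
  lab <- component_labels(bg, connectivity = 6L)
  d <- dim(lab)
  border <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]
  ))
  border <- border[border > 0L]
  fill <- !(lab %in% c(0L, border))
  binary_mask(array(mask$values | fill, dim = d), mask$spacing, mask$origin)
}

#' Derive a whole-brain mask from CT by intensity windowing
#'
#' A deliberately simple stand-in for a learned parenchyma segmentation:
#' voxels inside the intensity window `[low, high]` (soft tissue on the
#' Hounsfield scale; default 0..80 HU) are kept, reduced to the largest
#' 26-connected component, and interior cavities are filled in 3-D.
#' Users with a proper segmentation should supply their own mask file and
#' skip this function entirely: downstream scores only require *a* brain
#' parenchyma mask, not this particular one.
#'
#' @param ct a [voxel_grid()] of CT intensities.
#' @param low,high inclusive intensity window, default 0 and 80.
#' @return A [binary_mask()] of brain parenchyma.
#' @export
brain_mask_from_ct <- function(ct, low = 0, high = 80) {
  stopifnot(inherits(ct, "voxel_grid"))
  sel <- ct$values >= low & ct$values <= high
  if (!any(sel))
    stop("no brain-like tissue found in intensity window [", low, ", ", high, "]")
  m <- binary_mask(array(sel, dim = dim(ct$values)), ct$spacing, ct$origin)
  lab <- component_labels(m)
  counts <- tabulate(lab[lab > 0L])
  largest <- which.max(counts)
  m$values <- array(lab == largest, dim = dim(lab))
  fill_holes(m)
}
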