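#' Physical volume of a mask
#'
#' Volume is voxel counting times the physical voxel volume. Mesh-enclosed
#' volume is deliberately not used: the score definitions pair "volume"
#' with the segmented voxel set itself.
#'
#' @param mask a non-empty [binary_mask()].
#' @return Volume in mm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  n <- sum(mask$values)
  if (n == 0L) stop("empty mask: volume undefined")
  n * voxel_volume(mask)
}

#' Extract a closed triangle mesh of a mask surface
#'
#' The mask is zero-padded (so the surface closes), smoothed with a small
#' Gaussian (sub-voxel vertex placement; without it the midpoint-interpolated
#' surface of a binary field overestimates areas by several percent), and
#' the 0.5-level iso-surface is triangulated by marching tetrahedra on the
#' Kuhn 6-tetrahedra cell decomposition, which is translation-consistent
#' and therefore yields watertight meshes. Vertex coordinates are in mm.
#'
#' One-voxel-thick structures are washed below the 0.5 level by the
#' smoothing and yield no surface; this is reported as an error because
#' such structures have no meaningful iso-surface at this resolution (the
#' voxel-face method still applies to them).
#'
#' @param mask a non-empty [binary_mask()].
#' @param smoothing_sigma Gaussian sigma in voxel units (per axis),
#'   default 1.25.
#' @return A `triangle_mesh`: list with `vertices` (n x 3 matrix, mm),
#'   `triangles` (m x 3 integer matrix, 1-based) and `area` (mm^2).
#' @export
mask_mesh <- function(mask, smoothing_sigma = 1.25) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$values)) stop("empty mask: no surface to extract")
  pad <- max(2L, as.integer(ceiling(3.5 * smoothing_sigma)) + 1L)
  d <- dim(mask$values)
  dp <- d + 2L * pad
  field <- array(0, dim = dp)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask$values)
  if (smoothing_sigma > 0)
    field <- array(.gaussian_blur_cpp(field, dp, rep(smoothing_sigma, 3)),
                   dim = dp)
  res <- .march_tetra_cpp(as.numeric(field), dp, mask$spacing, 0.5)
  if (nrow(res$triangles) == 0L)
    stop("mask too thin for mesh extraction at this resolution; ",
         "use method = \"voxel_faces\" or coarser smoothing")
  # shift vertices back to the unpadded frame
  res$vertices <- sweep(res$vertices, 2, pad * mask$spacing - mask$origin)
  structure(list(vertices = res$vertices, triangles = res$triangles,
                 area = res$area),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("<triangle_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles, area ", signif(x$area, 6), " mm^2\n",
      sep = "")
  invisible(x)
}

#' Surface area of a mask
#'
#' Two estimators are provided. `mesh` (default) measures the triangulated
#' 0.5-level iso-surface (see [mask_mesh()]); its error vanishes as the
#' structure grows relative to the voxel size. `voxel_faces` counts voxel
#' faces that adjoin a background/outside voxel, each weighted by its
#' physical face area; it is exactly computable by hand (and *exact* for
#' axis-aligned boxes) but overestimates curved surfaces by a constant
#' staircase factor, so it serves as an independent oracle rather than the
#' primary estimator.
#'
#' @param mask a non-empty [binary_mask()].
#' @param method `"mesh"` or `"voxel_faces"`.
#' @param smoothing_sigma passed to [mask_mesh()] for `method = "mesh"`.
#' @return Surface area in mm^2.
#' @export
mask_surface_area <- function(mask, method = c("mesh", "voxel_faces"),
                              smoothing_sigma = 1.25) {
  method <- match.arg(method)
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$values)) stop("empty mask: surface area undefined")
  if (method == "voxel_faces") {
    .voxel_face_area_cpp(as.logical(mask$values), dim(mask$values),
                         mask$spacing)
  } else {
    mask_mesh(mask, smoothing_sigma = smoothing_sigma)$area
  }
}

#' Surface area of the sphere with a given volume
#'
#' The sphere minimizes surface area at fixed volume, so this is the
#' denominator/numerator that normalizes both sphericity scores:
#' `(36 * pi)^(1/3) * volume^(2/3)`.
#'
#' @param volume volume in mm^3, >= 0.
#' @return Surface area in mm^2.
#' @export
equivalent_sphere_surface <- function(volume) {
  if (!is.numeric(volume) || any(volume < 0))
    stop("`volume` must be non-negative")
  (36 * pi)^(1 / 3) * volume^(2 / 3)
}

#' Cerebral amyloid smoothing score (CASS)
#'
#' Ratio of the equivalent-sphere surface of the VOI's volume to the VOI's
#' actual surface area. By the isoperimetric inequality the dimensionless
#' score lies in (0, 1]: smoother, more compact uptake scores higher.
#' `scale_sigma` is a pure reporting scale (see Details).
#'
#' @details The originally published CASS and BAI magnitudes (thousands,
#' and ~1e-4) are impossible for dimensionless isoperimetric ratios, yet
#' their product matches the published shape feature, implying a hidden
#' unit factor that cancels in the product. This package computes the
#' dimensionless ratios and exposes `scale_sigma` (default 1) purely to
#' mimic legacy magnitudes; [shape_feature()] is provably unaffected.
#'
#' @param voi_surface_area VOI surface area in mm^2, > 0.
#' @param voi_volume VOI volume in mm^3, > 0.
#' @param scale_sigma reporting scale, > 0, default 1.
#' @return Dimensionless CASS (times `scale_sigma`).
#' @export
cass <- function(voi_surface_area, voi_volume, scale_sigma = 1) {
  if (voi_volume <= 0) stop("`voi_volume` must be positive")
  if (voi_surface_area <= 0) stop("`voi_surface_area` must be positive")
  if (scale_sigma <= 0) stop("`scale_sigma` must be positive")
  equivalent_sphere_surface(voi_volume) / voi_surface_area * scale_sigma
}

#' Brain atrophy index (BAI)
#'
#' Ratio of the brain mask's surface area to the equivalent-sphere surface
#' of its volume; the dimensionless score is >= 1, and deepening sulci
#' (atrophy) increase it. The reciprocal normalization of [cass()].
#'
#' @param brain_surface_area brain surface area in mm^2, > 0.
#' @param brain_volume brain volume in mm^3, > 0.
#' @param scale_sigma reporting scale, > 0, default 1 (divides BAI so that
#'   the product CASS x BAI is scale-free).
#' @return Dimensionless BAI (divided by `scale_sigma`).
#' @export
bai <- function(brain_surface_area, brain_volume, scale_sigma = 1) {
  if (brain_volume <= 0) stop("`brain_volume` must be positive")
  if (brain_surface_area <= 0) stop("`brain_surface_area` must be positive")
  if (scale_sigma <= 0) stop("`scale_sigma` must be positive")
  brain_surface_area / equivalent_sphere_surface(brain_volume) / scale_sigma
}

#' Shape feature: CASS x BAI
#'
#' The combined amyloid-deposition + brain-atrophy biomarker. Because
#' `scale_sigma` multiplies CASS and divides BAI, the product is exactly
#' independent of it.
#'
#' @param cass_value CASS, > 0.
#' @param bai_value BAI, > 0.
#' @return The product, dimensionless.
#' @examples
#' shape_feature(1, 1)
#' @export
shape_feature <- function(cass_value, bai_value) {
  if (any(cass_value <= 0) || any(bai_value <= 0))
    stop("CASS and BAI must be positive")
  cass_value * bai_value
}

#' Mask-based SUV ratio
#'
#' Mean PET value inside the target mask divided by the mean inside the
#' reference mask. This is a plain mask-based stand-in for atlas-based
#' regional SUVr; it is invariant under global rescaling of the PET image.
#'
#' @param pet a [voxel_grid()].
#' @param target,reference non-empty [binary_mask()]s matching the PET
#'   geometry.
#' @return SUVr, a positive real.
#' @export
suvr <- function(pet, target, reference) {
  stopifnot(inherits(pet, "voxel_grid"),
            inherits(target, "binary_mask"),
            inherits(reference, "binary_mask"))
  if (!same_geometry(pet, target) || !same_geometry(pet, reference))
    stop("mask geometry does not match the PET grid")
  if (!any(target$values)) stop("empty target mask")
  if (!any(reference$values)) stop("empty reference mask")
  ref_mean <- mean(pet$values[reference$values])
  if (ref_mean == 0) stop("reference region mean is zero")
  mean(pet$values[target$values]) / ref_mean
}

#' Quantify one PET/CT case
#'
#' Runs the full per-case pipeline: non-zero SUV mean, VOI segmentation at
#' `k` times that mean, optional small-component removal, surface areas
#' and volumes of VOI and brain mask, CASS, BAI, shape feature, and a
#' mask-based SUVr (target = VOI, reference = whole brain).
#'
#' @param pet a [voxel_grid()] of SUV values (positive voxels required).
#' @param brain_mask a non-empty [binary_mask()] of brain parenchyma with
#'   the same geometry.
#' @param k threshold multiple of the non-zero SUV mean, default 6.
#' @param scale_sigma reporting scale for CASS/BAI, default 1.25.
#' @param surface_method `"mesh"` (default) or `"voxel_faces"`.
#' @param min_component_voxels VOI components smaller than this are
#'   dropped before measurement; default 0 (keep all).
#' @param smoothing_sigma mesh pre-smoothing in voxels, default 1.25.
#' @param reference_mask optional [binary_mask()] used as the SUVr
#'   reference region; default `NULL` uses the whole brain mask
#'   (global normalization). Supply a dedicated nonspecific-uptake
#'   region (e.g. cerebellum) when one is available.
#' @param .brain_geom optional precomputed brain geometry, a list with
#'   `volume` and `area` as returned for the same mask, method and
#'   smoothing; used by [threshold_sweep()] to avoid re-meshing the
#'   (k-independent) brain surface at every threshold multiple.
#' @return An object of class `shape_scores`; see
#'   [as.data.frame.shape_scores()] for the flat record layout.
#' @export
quantify_case <- function(pet, brain_mask, k = 6, scale_sigma = 1,
                          surface_method = c("mesh", "voxel_faces"),
                          min_component_voxels = 0L, smoothing_sigma = 1.25,
                          reference_mask = NULL, .brain_geom = NULL) {
  surface_method <- match.arg(surface_method)
  stopifnot(inherits(pet, "voxel_grid"), inherits(brain_mask, "binary_mask"))
  if (!same_geometry(pet, brain_mask))
    stop("PET and brain mask geometry differ")
  if (!any(brain_mask$values)) stop("empty brain mask")

  stats <- compute_suv_mean(pet, k = k)
  voi <- threshold_voi(pet, stats)
  voi <- filter_components(voi, min_voxels = min_component_voxels)
  if (!any(voi$values))
    stop("no VOI above threshold ", signif(stats$threshold, 6),
         " (k = ", k, ")")

  voi_vol <- mask_volume(voi)
  voi_area <- mask_surface_area(voi, method = surface_method,
                                smoothing_sigma = smoothing_sigma)
  if (is.null(.brain_geom)) {
    brain_vol <- mask_volume(brain_mask)
    brain_area <- mask_surface_area(brain_mask, method = surface_method,
                                    smoothing_sigma = smoothing_sigma)
  } else {
    brain_vol <- .brain_geom$volume
    brain_area <- .brain_geom$area
  }

  cass_v <- cass(voi_area, voi_vol, scale_sigma)
  bai_v <- bai(brain_area, brain_vol, scale_sigma)

  structure(
    list(
      suv_mean_nonzero = stats$suv_mean_nonzero,
      k = k,
      threshold = stats$threshold,
      voi_voxels = sum(voi$values),
      voi_volume = voi_vol,
      voi_surface_area = voi_area,
      voi_equiv_sphere_surface = equivalent_sphere_surface(voi_vol),
      brain_volume = brain_vol,
      brain_surface_area = brain_area,
      brain_equiv_sphere_surface = equivalent_sphere_surface(brain_vol),
      cass = cass_v,
      bai = bai_v,
      shape_feature = shape_feature(cass_v, bai_v),
      suvr = suvr(pet, voi, reference_mask %||% brain_mask),
      surface_method = surface_method,
      scale_sigma = scale_sigma
    ),
    class = "shape_scores"
  )
}

#' @export
print.shape_scores <- function(x, ...) {
  cat("<shape_scores> k = ", x$k, ", surface method ", x$surface_method,
      "\n", sep = "")
  cat(sprintf("  SUV mean (non-zero) %.4g, threshold %.4g\n",
              x$suv_mean_nonzero, x$threshold))
  cat(sprintf("  VOI:   %.4g mm^3, %.4g mm^2  ->  CASS %.4g\n",
              x$voi_volume, x$voi_surface_area, x$cass))
  cat(sprintf("  brain: %.4g mm^3, %.4g mm^2  ->  BAI  %.4g\n",
              x$brain_volume, x$brain_surface_area, x$bai))
  cat(sprintf("  shape feature %.4g, SUVr %.4g\n", x$shape_feature, x$suvr))
  invisible(x)
}

#' Flatten shape scores to a one-row data frame
#'
#' Column layout matches the per-case CSV emitted by [run_quantify()]:
#' `case_id, k, suv_mean, voi_volume_mm3, voi_area_mm2, brain_volume_mm3,
#' brain_area_mm2, cass, bai, shape_feature, suvr, surface_method,
#' scale_sigma`.
#'
#' @param x a `shape_scores` object.
#' @param row.names,optional,... ignored (S3 signature).
#' @param case_id identifier stored in the first column, default `NA`.
#' @return A one-row `data.frame`.
#' @export
as.data.frame.shape_scores <- function(x, row.names = NULL, optional = FALSE,
                                       ..., case_id = NA_character_) {
  data.frame(
    case_id = case_id,
    k = x$k,
    suv_mean = x$suv_mean_nonzero,
    voi_volume_mm3 = x$voi_volume,
    voi_area_mm2 = x$voi_surface_area,
    brain_volume_mm3 = x$brain_volume,
    brain_area_mm2 = x$brain_surface_area,
    cass = x$cass,
    bai = x$bai,
    shape_feature = x$shape_feature,
    suvr = x$suvr,
    surface_method = x$surface_method,
    scale_sigma = x$scale_sigma,
    stringsAsFactors = FALSE
  )
}
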