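# Synthetic PET/CT phantoms with known geometric ground truth.
#
# Shapes are star-shaped surfaces r(u) = R * (1 + sum_i a_i * B_i(u)) with
# smooth Gaussian bump basis functions B_i centred on random directions,
# minus sulcus-like narrow indentations scaled by an atrophy depth in mm.
# Star shapes voxelate trivially (compare voxel radius with r(u)) and a
# densely sampled parametric reference surface provides ground-truth area
# and volume oracles independent of any voxel-based estimator.

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# deterministic per-case seed splitting rule (documented: all case-level
# randomness flows from the master seed through this affine map)
split_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + 104729 * as.numeric(index)) %%
               2147483647)
}

#' Specification of a synthetic PET/CT phantom
#'
#' Collects every generative parameter with a fixed seed; identical specs
#' produce bit-identical volumes.
#'
#' @param grid_shape integer length-3 voxel dimensions.
#' @param spacing mm per voxel, default `c(2, 2, 3.75)` (a typical PET
#'   in-plane resolution with the CT slice thickness used clinically).
#' @param base_radius object radius R in mm.
#' @param perturbation_amplitudes numeric vector; each entry is a bump
#'   amplitude as a fraction of R, applied along a random direction.
#' @param bump_width angular width (radians) of the shape bumps.
#' @param atrophy_depth sulcal indentation depth in mm, >= 0.
#' @param n_sulci number of sulcus-like indentations.
#' @param sulcus_width angular width (radians) of the indentations.
#' @param uptake_pattern `"filled_smooth"` (AD-like compact uptake) or
#'   `"cortical_ribbon"` (non-AD-like thin cortical pattern).
#' @param ribbon_thickness cortical ribbon thickness in mm.
#' @param erosion_mm inward margin of the filled uptake region, mm.
#' @param blur_fwhm PET point-spread emulation, Gaussian FWHM in mm.
#' @param noise_sd additive Gaussian noise SD (SUV units).
#' @param seed integer seed controlling all random draws.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(52, 52, 32),
                         spacing = c(2, 2, 3.75),
                         base_radius = 40,
                         perturbation_amplitudes = numeric(0),
                         bump_width = 0.5,
                         atrophy_depth = 0,
                         n_sulci = 24,
                         sulcus_width = 0.22,
                         uptake_pattern = c("filled_smooth", "cortical_ribbon"),
                         ribbon_thickness = 6,
                         erosion_mm = 3,
                         blur_fwhm = 6,
                         noise_sd = 0.05,
                         seed = 1) {
  uptake_pattern <- match.arg(uptake_pattern)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4),
            length(spacing) == 3L, all(spacing > 0),
            base_radius > 0, ribbon_thickness > 0,
            atrophy_depth >= 0, blur_fwhm >= 0, noise_sd >= 0,
            bump_width > 0, sulcus_width > 0, n_sulci >= 0)
  if (ribbon_thickness >= base_radius)
    stop("ribbon_thickness must be smaller than base_radius")
  structure(
    list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
         base_radius = base_radius,
         perturbation_amplitudes = as.numeric(perturbation_amplitudes),
         bump_width = bump_width, atrophy_depth = atrophy_depth,
         n_sulci = as.integer(n_sulci), sulcus_width = sulcus_width,
         uptake_pattern = uptake_pattern,
         ribbon_thickness = ribbon_thickness, erosion_mm = erosion_mm,
         blur_fwhm = blur_fwhm, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# uniform random unit vectors, n x 3
random_directions <- function(n) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# draw the random geometry (bump and sulcus directions) for a spec;
# the bump part of the radial function is rescaled so that the enclosed
# continuum volume stays at the base ball's 4/3*pi*R^3 — perturbations
# then change surface area at (near-)constant volume, as atrophy-free
# shape change should
star_params <- function(spec) {
  params <- with_seed(spec$seed, {
    bump_dirs <- random_directions(length(spec$perturbation_amplitudes))
    sulcus_dirs <- random_directions(spec$n_sulci)
    list(bump_dirs = bump_dirs, sulcus_dirs = sulcus_dirs)
  })
  params$volume_scale <- 1
  if (length(spec$perturbation_amplitudes) > 0) {
    n_th <- 96L; n_ph <- 192L
    thm <- (seq_len(n_th) - 0.5) * pi / n_th
    phm <- (seq_len(n_ph) - 0.5) * 2 * pi / n_ph
    U <- cbind(as.numeric(outer(sin(thm), cos(phm))),
               as.numeric(outer(sin(thm), sin(phm))),
               as.numeric(outer(cos(thm), rep(1, n_ph))))
    w <- as.numeric(outer(sin(thm), rep(1, n_ph))) *
      (pi / n_th) * (2 * pi / n_ph)
    r_raw <- radial_function(spec, params, U, include_atrophy = FALSE)
    vol_raw <- sum(r_raw^3 / 3 * w)
    params$volume_scale <- (4 / 3 * pi * spec$base_radius^3 / vol_raw)^(1 / 3)
  }
  params
}

# radial function r(u) in mm for unit directions U (n x 3);
# include_atrophy toggles the sulcal indentations
radial_function <- function(spec, params, U, include_atrophy = TRUE) {
  r <- rep(spec$base_radius, nrow(U))
  amps <- spec$perturbation_amplitudes
  clamp_cos <- function(m) {
    m[m > 1] <- 1
    m[m < -1] <- -1
    m
  }
  if (length(amps) > 0) {
    ang <- acos(clamp_cos(U %*% t(params$bump_dirs)))
    bumps <- exp(-0.5 * (ang / spec$bump_width)^2)
    r <- (r + spec$base_radius * as.numeric(bumps %*% amps)) *
      (params$volume_scale %||% 1)
  }
  if (include_atrophy && spec$atrophy_depth > 0 && spec$n_sulci > 0) {
    ang <- acos(clamp_cos(U %*% t(params$sulcus_dirs)))
    sulci <- exp(-0.5 * (ang / spec$sulcus_width)^2)
    # cap total indentation so overlapping sulci cannot exceed the depth
    r <- r - spec$atrophy_depth * pmin(1, rowSums(sulci))
  }
  if (any(r <= 0))
    stop("perturbations drive the radius non-positive; reduce amplitudes ",
         "or atrophy_depth")
  as.numeric(r)
}

# voxel-centre radii and unit directions of a phantom grid, centre of mass
# at the grid centre
grid_directions <- function(spec) {
  d <- spec$grid_shape
  sp <- spec$spacing
  ctr <- (d - 1) / 2 * sp
  x <- (seq_len(d[1]) - 1) * sp[1] - ctr[1]
  y <- (seq_len(d[2]) - 1) * sp[2] - ctr[2]
  z <- (seq_len(d[3]) - 1) * sp[3] - ctr[3]
  X <- array(rep(x, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(z, each = d[1] * d[2]), dim = d)
  r <- sqrt(X^2 + Y^2 + Z^2)
  U <- cbind(as.numeric(X), as.numeric(Y), as.numeric(Z)) /
    pmax(as.numeric(r), 1e-9)
  list(r = as.numeric(r), U = U)
}

# dense parametric reference surface: ground-truth area (triangulated
# lat-long grid) and volume (spherical integral of r^3/3), independent of
# any voxel representation
reference_surface <- function(spec, params, include_atrophy = TRUE,
                              n_theta = 240L, n_phi = 480L) {
  th <- seq(0, pi, length.out = n_theta + 1L)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  TH <- matrix(rep(th, times = n_phi), n_theta + 1L, n_phi)
  PH <- matrix(rep(ph, each = n_theta + 1L), n_theta + 1L, n_phi)
  U <- cbind(as.numeric(sin(TH) * cos(PH)),
             as.numeric(sin(TH) * sin(PH)),
             as.numeric(cos(TH)))
  R <- matrix(radial_function(spec, params, U, include_atrophy),
              n_theta + 1L, n_phi)
  P <- array(U * as.numeric(R), dim = c(n_theta + 1L, n_phi, 3L))

  nxt <- c(seq_len(n_phi)[-1], 1L)  # periodic phi neighbour
  a <- P[-(n_theta + 1L), , , drop = FALSE]
  b <- P[-1L, , , drop = FALSE]
  cpt <- P[-1L, nxt, , drop = FALSE]
  dpt <- P[-(n_theta + 1L), nxt, , drop = FALSE]
  tri_area <- function(p, q, s) {
    u1 <- q - p; v1 <- s - p
    cx <- u1[, , 2] * v1[, , 3] - u1[, , 3] * v1[, , 2]
    cy <- u1[, , 3] * v1[, , 1] - u1[, , 1] * v1[, , 3]
    cz <- u1[, , 1] * v1[, , 2] - u1[, , 2] * v1[, , 1]
    0.5 * sum(sqrt(cx^2 + cy^2 + cz^2))
  }
  area <- tri_area(a, b, cpt) + tri_area(a, cpt, dpt)

  # volume via midpoint quadrature of r^3/3 sin(theta)
  thm <- (th[-1] + th[-(n_theta + 1L)]) / 2
  phm <- ph + pi / n_phi
  THm <- matrix(rep(thm, times = n_phi), n_theta, n_phi)
  PHm <- matrix(rep(phm, each = n_theta), n_theta, n_phi)
  Um <- cbind(as.numeric(sin(THm) * cos(PHm)),
              as.numeric(sin(THm) * sin(PHm)),
              as.numeric(cos(THm)))
  Rm <- radial_function(spec, params, Um, include_atrophy)
  vol <- sum(Rm^3 / 3 * sin(as.numeric(THm))) * (pi / n_theta) *
    (2 * pi / n_phi)
  list(area = area, volume = vol)
}

#' Voxelize a star-shaped phantom with ground-truth geometry
#'
#' @param spec a [phantom_spec()].
#' @param include_atrophy apply the sulcal indentations (default TRUE).
#' @return A list: `mask` ([binary_mask()]), `voxel_count`,
#'   `reference_area` and `reference_volume` (mm^2 / mm^3 from a densely
#'   sampled parametric surface, independent of the voxelization).
#' @examples
#' ball <- make_star_shape(phantom_spec(grid_shape = c(24, 24, 24),
#'                                      spacing = c(2, 2, 2),
#'                                      base_radius = 16, seed = 7))
#' ball$voxel_count
#' @export
make_star_shape <- function(spec, include_atrophy = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  params <- star_params(spec)
  g <- grid_directions(spec)
  rad <- radial_function(spec, params, g$U, include_atrophy)
  mask <- binary_mask(array(g$r <= rad, dim = spec$grid_shape), spec$spacing)
  ref <- reference_surface(spec, params, include_atrophy)
  list(mask = mask, voxel_count = sum(mask$values),
       reference_area = ref$area, reference_volume = ref$volume)
}

#' Synthesize a CT volume with skull shell and ground-truth brain mask
#'
#' The brain parenchyma (intensity 40) is the spec's star shape with
#' atrophy-scaled sulcal indentations; a high-intensity shell (1000)
#' emulates the skull and follows the *unatrophied* outer surface, so
#' deepening sulci widen the subdural space as in real atrophy. All
#' remaining space, including sulci and the brain-skull gap, is air-like
#' (-1000): a synthetic simplification (real CSF sits near 15 HU) chosen
#' so that the documented soft-tissue window recovers the parenchyma mask
#' exactly.
#'
#' @param spec a [phantom_spec()].
#' @param skull_gap gap between brain surface and skull, mm.
#' @param skull_thickness skull shell thickness, mm.
#' @return A list: `ct` ([voxel_grid()]) and `brain_mask` (ground truth
#'   [binary_mask()]).
#' @export
make_brain_ct <- function(spec, skull_gap = 2, skull_thickness = 5) {
  stopifnot(inherits(spec, "phantom_spec"))
  params <- star_params(spec)
  g <- grid_directions(spec)
  rad_brain <- radial_function(spec, params, g$U, include_atrophy = TRUE)
  rad_outer <- radial_function(spec, params, g$U, include_atrophy = FALSE)
  brain <- g$r <= rad_brain
  skull <- g$r > rad_outer + skull_gap &
    g$r <= rad_outer + skull_gap + skull_thickness
  vals <- rep(-1000, length(g$r))
  vals[skull] <- 1000
  vals[brain] <- 40
  list(
    ct = voxel_grid(array(vals, dim = spec$grid_shape), spec$spacing),
    brain_mask = binary_mask(array(brain, dim = spec$grid_shape),
                             spec$spacing)
  )
}

#' Synthesize a PET uptake volume for a phantom brain
#'
#' Two uptake patterns emulate the visual-read archetypes: AD-like scans
#' show a compact filled uptake region (uniform 2.5 inside the brain
#' eroded by `erosion_mm`, background 1.0), non-AD-like scans a thin
#' cortical ribbon (2.0 on a `ribbon_thickness` shell under the brain
#' surface, background 1.0). The pattern is then blurred with a Gaussian
#' of `blur_fwhm` (PET point-spread emulation), Gaussian noise of sd
#' `noise_sd` is added, and values are clipped at 0.
#'
#' @param spec a [phantom_spec()].
#' @param brain_mask the phantom's brain mask (geometry is validated).
#' @return A [voxel_grid()] of SUV-like values.
#' @export
make_pet <- function(spec, brain_mask) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(brain_mask, "binary_mask"))
  if (!identical(dim(brain_mask$values), spec$grid_shape))
    stop("brain mask does not match the spec's grid")
  params <- star_params(spec)
  g <- grid_directions(spec)
  rad_brain <- radial_function(spec, params, g$U, include_atrophy = TRUE)
  vals <- rep(1.0, length(g$r))
  if (spec$uptake_pattern == "filled_smooth") {
    vals[g$r <= rad_brain - spec$erosion_mm] <- 2.5
  } else {
    vals[g$r <= rad_brain & g$r > rad_brain - spec$ribbon_thickness] <- 2.0
  }
  vol <- array(vals, dim = spec$grid_shape)
  if (spec$blur_fwhm > 0) {
    sigma_vox <- (spec$blur_fwhm / (2 * sqrt(2 * log(2)))) / spec$spacing
    vol <- array(.gaussian_blur_cpp(as.numeric(vol), spec$grid_shape,
                                    sigma_vox), dim = spec$grid_shape)
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(split_seed(spec$seed, 1L),
                       rnorm(length(vol), 0, spec$noise_sd))
    vol <- vol + array(noise, dim = spec$grid_shape)
  }
  vol[vol < 0] <- 0
  voxel_grid(vol, spec$spacing)
}

#' Simulate a two-group phantom cohort
#'
#' Generates `n_pos` AD-like cases (predominantly filled-smooth uptake
#' and deeper sulci) and `n_neg` non-AD-like cases (predominantly
#' cortical-ribbon uptake, shallower sulci), quantifies each with
#' [quantify_case()], and returns the per-case score table. `effect` in
#' `[0, 1]` scales the separation between the generating distributions;
#' `effect = 0` makes them identical (a null simulation, flagged as
#' such). All randomness derives from `seed` through a fixed per-case
#' splitting rule, so the same seed reproduces the cohort exactly and
#' individual cases can be regenerated in isolation.
#'
#' The phantom intensity scale is simplified (background 1.0, uptake
#' 2.0-2.5), so the threshold multiple playing the role of the clinical
#' operating point is `k = 1.5` here; see the package vignette.
#'
#' @param n_pos,n_neg group sizes, >= 1; defaults 23 and 27 match the
#'   cohort sizes at which the reference statistics are exercised.
#' @param effect group-separation parameter in `[0, 1]`, default 0.8.
#' @param seed master seed.
#' @param k threshold multiple used for quantification, default 1.5.
#' @param grid_shape,spacing,base_radius phantom geometry defaults.
#' @param noise_sd,blur_fwhm PET degradation defaults.
#' @param surface_method passed to [quantify_case()].
#' @param keep_cases if TRUE, the generated `pet`/`brain_mask` pairs are
#'   attached as attribute `"cases"` (needed by [threshold_sweep()]).
#' @param write_dir optional directory; if given, per-case NIfTI pairs
#'   (`<case_id>_pet.nii.gz`, `<case_id>_brain.nii.gz`) and the cohort CSV
#'   are written there.
#' @return A `data.frame` (the cohort table) with columns `case_id`,
#'   `group` (`"positive"`/`"negative"`), `suv_mean`, `cass`, `bai`,
#'   `shape_feature`, `suvr`, `mmse`.
#' @export
simulate_cohort <- function(n_pos = 23, n_neg = 27, effect = 0.8, seed = 1,
                            k = 1.5,
                            grid_shape = c(52, 52, 32),
                            spacing = c(2, 2, 3.75),
                            base_radius = 40,
                            noise_sd = 0.05, blur_fwhm = 6,
                            surface_method = "mesh",
                            keep_cases = FALSE, write_dir = NULL) {
  stopifnot(n_pos >= 1, n_neg >= 1, effect >= 0, effect <= 1)
  n <- n_pos + n_neg
  rows <- vector("list", n)
  cases <- if (keep_cases || !is.null(write_dir)) vector("list", n) else NULL

  for (i in seq_len(n)) {
    positive <- i <= n_pos
    case_seed <- split_seed(seed, i)
    draw <- with_seed(case_seed, {
      p_filled <- if (positive) 0.5 + 0.5 * effect else 0.5 - 0.5 * effect
      pattern <- if (runif(1) < p_filled) "filled_smooth" else "cortical_ribbon"
      depth <- runif(1, 0.5, 3.5) + (if (positive) 1.5 * effect else 0)
      mmse_mean <- if (positive) 25.5 - 4.5 * effect else 25.5
      list(pattern = pattern, depth = depth,
           radius = base_radius * runif(1, 0.95, 1.05),
           amps = runif(3, 0, 0.06),
           mmse = max(0, min(30, round(rnorm(1, mmse_mean, 2.5)))))
    })
    spec <- phantom_spec(grid_shape = grid_shape, spacing = spacing,
                         base_radius = draw$radius,
                         perturbation_amplitudes = draw$amps,
                         atrophy_depth = draw$depth,
                         uptake_pattern = draw$pattern,
                         noise_sd = noise_sd, blur_fwhm = blur_fwhm,
                         seed = case_seed)
    anat <- make_brain_ct(spec)
    pet <- make_pet(spec, anat$brain_mask)
    # SUVr reference: nonspecific background outside the head (the
    # phantom analogue of a cerebellar reference region)
    ref <- binary_mask(!anat$brain_mask$values, spacing)
    sc <- quantify_case(pet, anat$brain_mask, k = k,
                        surface_method = surface_method,
                        reference_mask = ref)
    case_id <- sprintf("case_%03d", i)
    rows[[i]] <- data.frame(
      case_id = case_id,
      group = if (positive) "positive" else "negative",
      suv_mean = sc$suv_mean_nonzero,
      cass = sc$cass, bai = sc$bai,
      shape_feature = sc$shape_feature, suvr = sc$suvr,
      mmse = draw$mmse, stringsAsFactors = FALSE
    )
    if (!is.null(cases))
      cases[[i]] <- list(case_id = case_id, pet = pet,
                         brain_mask = anat$brain_mask,
                         group = if (positive) "positive" else "negative")
  }

  cohort <- do.call(rbind, rows)
  if (effect == 0) {
    message("effect = 0: null simulation (groups share one generating ",
            "distribution)")
    attr(cohort, "null_simulation") <- TRUE
  }
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    for (cs in cases) {
      write_volume(cs$pet, file.path(write_dir,
                                     paste0(cs$case_id, "_pet.nii.gz")))
      write_mask(cs$brain_mask,
                 file.path(write_dir, paste0(cs$case_id, "_brain.nii.gz")))
    }
    write.csv(cohort, file.path(write_dir, "cohort.csv"), row.names = FALSE)
  }
  if (keep_cases) attr(cohort, "cases") <- cases
  cohort
}
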