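# Analytic fixture builders shared across test files.

# digitized ball of radius r (mm) with optional sub-voxel centre offset
ball_mask <- function(r, spacing = c(1, 1, 1), margin = 3, offset = c(0, 0, 0)) {
  d <- ceiling(2 * (r + margin) / spacing)
  ctr <- (d - 1) / 2 * spacing + offset
  x <- (seq_len(d[1]) - 1) * spacing[1] - ctr[1]
  y <- (seq_len(d[2]) - 1) * spacing[2] - ctr[2]
  z <- (seq_len(d[3]) - 1) * spacing[3] - ctr[3]
  X <- array(rep(x, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(z, each = d[1] * d[2]), dim = d)
  binary_mask(sqrt(X^2 + Y^2 + Z^2) <= r, spacing)
}

# solid axis-aligned box of a x b x c voxels inside a padded grid
box_mask <- function(a, b, c, spacing = c(1, 1, 1), pad = 2) {
  d <- c(a, b, c) + 2 * pad
  m <- array(FALSE, dim = d)
  m[pad + seq_len(a), pad + seq_len(b), pad + seq_len(c)] <- TRUE
  binary_mask(m, spacing)
}

# small deterministic phantom case (PET + brain mask), cheap to quantify;
# isotropic 2 mm spacing keeps the thin cortical-ribbon pattern at least
# three voxels thick along every axis
small_case <- function(seed, pattern = "filled_smooth", depth = 2,
                       grid_shape = c(36, 36, 30), base_radius = 26,
                       spacing = c(2, 2, 2)) {
  sp <- phantom_spec(grid_shape = grid_shape, spacing = spacing,
                     base_radius = base_radius,
                     perturbation_amplitudes = c(0.03, 0.03),
                     atrophy_depth = depth, uptake_pattern = pattern,
                     ribbon_thickness = 10, blur_fwhm = 4,
                     seed = seed)
  anat <- make_brain_ct(sp)
  list(pet = make_pet(sp, anat$brain_mask), brain_mask = anat$brain_mask,
       ct = anat$ct, spec = sp)
}

# every mesh edge must be shared by exactly two triangles (watertight)
expect_closed_mesh <- function(mesh) {
  tr <- mesh$triangles
  edges <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  edges <- t(apply(edges, 1, sort))
  key <- paste(edges[, 1], edges[, 2])
  expect_true(all(table(key) == 2))
}
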