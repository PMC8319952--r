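# Shared fixtures: small analytic phantoms built in code.

# Logical sphere mask on a lattice centred at `center` (mm).
sphere_mask <- function(shape, spacing, origin, center, radius) {
  cc <- suboar:::lattice_coords(shape, spacing, origin)
  (cc$x - center[1])^2 + (cc$y - center[2])^2 + (cc$z - center[3])^2 <=
    radius^2
}

# Centred cubic lattice of physical half-extent `half_mm` at voxel size `h`.
centred_lattice <- function(half_mm, h) {
  n <- 2L * ceiling(half_mm / h) + 1L
  list(shape = rep(n, 3L), spacing = rep(h, 3L),
       origin = rep(-(n - 1) * h / 2, 3L))
}

# Sphere target + concentric spherical-shell organ structure set.
shell_phantom <- function(h, r_target = 20, r_inner = 20, r_outer = 40,
                          half_mm = r_outer + 2) {
  lat <- centred_lattice(half_mm, h)
  cc <- suboar:::lattice_coords(lat$shape, lat$spacing, lat$origin)
  r2 <- cc$x^2 + cc$y^2 + cc$z^2
  structure_set(
    list(hrctv = r2 <= r_target^2,
         organ = r2 > r_inner^2 & r2 <= r_outer^2),
    spacing = lat$spacing, origin = lat$origin
  )
}

# A tiny structure set + uniform-dose grid for dosimetry unit tests:
# `levels` is a list of (volume voxels, dose) blocks laid out along x.
block_dose_phantom <- function(levels, voxel_cm3 = 0.001) {
  # voxel volume 0.001 cm3 -> 1 mm isotropic spacing
  n <- sum(vapply(levels, `[[`, numeric(1), "n"))
  shape <- c(n, 1L, 1L)
  dose <- array(unlist(lapply(levels, function(l) rep(l$dose, l$n))),
                dim = shape)
  mask <- array(TRUE, dim = shape)
  sp <- rep(10 * voxel_cm3^(1 / 3), 3L)
  list(dose = dose_grid(dose, sp), mask = mask, spacing = sp)
}

# Small cohort config used by pipeline tests (full default lattice, few plans).
tiny_pipeline_config <- function(out_dir, n_plans = 16L, seed = 11L) {
  pipeline_config(
    out_dir = out_dir,
    phantom = phantom_config(n_plans = n_plans, seed = seed),
    svr = svr_config(C_grid = c(1, 100), gamma_grid = c(0.01, 0.1),
                     cv_folds = 3L, seed = seed),
    n_train = n_plans - 4L, n_valid = 4L,
    seed = seed, log_level = "quiet"
  )
}
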