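# Ring-shell expansion geometry and sub-OAR volumes.

test_that("distance map is zero inside, axis-exact outside, and matches brute force", {
  m <- array(FALSE, dim = c(6, 5, 5))
  m[1, 1, 1] <- TRUE
  d <- distance_map(m, c(1, 1, 1))
  expect_identical(d[1, 1, 1], 0)
  expect_equal(d[4, 1, 1], 3.0)
  expect_equal(d[1, 3, 1], 2.0)

  set.seed(42)
  for (trial in 1:4) {
    sp <- runif(3, 0.5, 3)
    mm <- array(runif(7 * 6 * 8) < 0.12, dim = c(7, 6, 8))
    if (!any(mm)) mm[2, 2, 2] <- TRUE
    expect_equal(distance_map(mm, sp), brute_force_distance(mm, sp),
                 tolerance = 1e-12)
  }
})

test_that("distance to a digitized sphere approaches the analytic distance", {
  lat <- centred_lattice(27, 1)
  target <- sphere_mask(lat$shape, lat$spacing, lat$origin, c(0, 0, 0), 20)
  d <- distance_map(target, lat$spacing)
  # query voxel on the x axis, 25 mm from the center: analytic distance 5 mm
  ix <- (lat$shape[1] + 1) / 2 + 25
  mid <- (lat$shape[2] + 1) / 2
  expect_equal(d[ix, mid, mid], 5.0, tolerance = sqrt(3) / 5)
})

test_that("empty or malformed masks are rejected", {
  expect_error(distance_map(array(FALSE, c(3, 3, 3)), c(1, 1, 1)),
               "empty structure")
  expect_error(distance_map(array(TRUE, c(3, 3)), c(1, 1, 1)), "3-D")
  expect_error(distance_map(array(TRUE, c(3, 3, 3)), c(1, -1, 1)), "positive")
})

test_that("ring shells are half-open, capped, and partition the expansion", {
  lat <- centred_lattice(60, 2)
  ss <- structure_set(
    list(hrctv = sphere_mask(lat$shape, lat$spacing, lat$origin, c(0, 0, 0), 10)),
    spacing = lat$spacing, origin = lat$origin
  )
  rings <- derive_rings(ss)
  expect_s3_class(rings, "ring_set")
  expect_equal(rings$width_mm, 5.0)
  expect_equal(rings$n_max, 10L)

  d <- distance_map(ss$masks$hrctv, lat$spacing)
  # shell membership: (k-1)*w < d <= k*w
  expect_true(all(rings$ring_index[d > 0 & d <= 5] == 1L))
  expect_true(all(rings$ring_index[d > 5 & d <= 10] == 2L))
  expect_true(all(rings$ring_index[d > 50] == 0L))
  expect_true(all(rings$ring_index[ss$masks$hrctv] == 0L))
  # partition: every voxel with 0 < d <= n_max*w is in exactly one ring
  expect_equal(sum(rings$ring_index > 0L), sum(d > 0 & d <= 50))
  # the midsurface metric never exceeds, and tracks, the center metric
  ds <- distance_map(ss$masks$hrctv, lat$spacing, to = "surface")
  expect_true(all(ds <= d + 1e-12))
  expect_true(all(d - ds <= sqrt(3) * 2 + 1e-12))

  expect_error(derive_rings(ss, width_mm = 0), "positive")
  expect_error(derive_rings(ss, n_max = 0), "at least 1")
})

test_that("boundary voxels at an exact multiple of the width join the inner ring", {
  m <- array(FALSE, dim = c(13, 3, 3))
  m[1, , ] <- TRUE
  ss <- structure_set(list(hrctv = m), spacing = c(2.5, 2.5, 2.5))
  rings <- derive_rings(ss, width_mm = 5)
  # voxel 3 sits exactly 5.0 mm from the target centers: ring 1, not ring 2
  expect_equal(rings$ring_index[3, 2, 2], 1L)
  expect_equal(rings$ring_index[4, 2, 2], 2L)
  # under the midsurface metric the same voxel is 3.75 mm out: still ring 1
  rs <- derive_rings(ss, width_mm = 5, distance_to = "surface")
  expect_equal(rs$ring_index[3, 2, 2], 1L)
  expect_equal(rs$ring_index[4, 2, 2], 2L)
})

test_that("sub-OAR volumes conserve organ volume across rings", {
  ss <- shell_phantom(h = 2)
  rings <- derive_rings(ss)
  sub <- sub_oar_volumes(rings, ss, "organ")
  expect_true(all(sub$volumes_cm3 >= 0))
  expect_lte(sum(sub$volumes_cm3), sub$total_cm3 + 1e-12)
  # organ volume = in-ring volume + beyond-ring volume (target overlap is 0)
  d <- distance_map(ss$masks$hrctv, ss$spacing)
  beyond <- sum(ss$masks$organ & d > 50) * voxel_volume_cm3(ss$spacing)
  expect_equal(sum(sub$volumes_cm3) + beyond, sub$total_cm3, tolerance = 1e-12)
  expect_error(sub_oar_volumes(rings, ss, "femur"), "unknown structure")
})

test_that("an organ beyond the outermost ring has all-zero sub-volumes", {
  lat <- centred_lattice(80, 4)
  hr <- sphere_mask(lat$shape, lat$spacing, lat$origin, c(0, 0, 0), 10)
  far <- sphere_mask(lat$shape, lat$spacing, lat$origin, c(75, 0, 0), 8)
  ss <- structure_set(list(hrctv = hr, organ = far),
                      spacing = lat$spacing, origin = lat$origin)
  sub <- sub_oar_volumes(derive_rings(ss), ss, "organ")
  expect_true(all(sub$volumes_cm3 == 0))
  expect_gt(sub$total_cm3, 0)
})

test_that("feature vectors use V_HR-CTV except for the small intestine", {
  lat <- centred_lattice(50, 2.5)
  hr <- sphere_mask(lat$shape, lat$spacing, lat$origin, c(0, 0, 0), 15)
  bl <- sphere_mask(lat$shape, lat$spacing, lat$origin, c(0, -35, 0), 12)
  si <- sphere_mask(lat$shape, lat$spacing, lat$origin, c(0, 0, 38), 10)
  ss <- structure_set(list(hrctv = hr, bladder = bl, small_intestine = si,
                           rectum = sphere_mask(lat$shape, lat$spacing,
                                                lat$origin, c(0, 35, 0), 10)),
                      spacing = lat$spacing, origin = lat$origin)
  rings <- derive_rings(ss)

  fv_re <- build_feature_vector(sub_oar_volumes(rings, ss, "rectum"), ss, "rectum")
  expect_length(fv_re, 6L)
  expect_named(fv_re, c("V_hrctv", paste0("v", 1:5)))
  expect_equal(unname(fv_re[1]), structure_volume_cm3(ss, "hrctv"))

  fv_si <- build_feature_vector(sub_oar_volumes(rings, ss, "small_intestine"),
                                ss, "small_intestine")
  expect_named(fv_si, c("V_bladder", paste0("v", 1:5)))
  expect_equal(unname(fv_si[1]), structure_volume_cm3(ss, "bladder"))

  # missing bladder is an error for the small intestine only
  ss2 <- structure_set(list(hrctv = hr, small_intestine = si),
                       spacing = lat$spacing, origin = lat$origin)
  rings2 <- derive_rings(ss2)
  expect_error(
    build_feature_vector(sub_oar_volumes(rings2, ss2, "small_intestine"),
                         ss2, "small_intestine"),
    "bladder"
  )
})

test_that("structure sets reject overlap with the target and mixed lattices", {
  m <- array(FALSE, c(4, 4, 4)); m[1:2, 1:2, 1:2] <- TRUE
  o <- array(FALSE, c(4, 4, 4)); o[2:3, 2:3, 2:3] <- TRUE
  expect_error(structure_set(list(hrctv = m, organ = o), c(1, 1, 1)),
               "overlaps the HR-CTV")
  expect_error(structure_set(list(organ = o), c(1, 1, 1)), "hrctv")
  expect_error(structure_set(list(hrctv = array(FALSE, c(4, 4, 4))), c(1, 1, 1)),
               "empty")
  expect_error(structure_set(list(hrctv = m, organ = array(TRUE, c(3, 3, 3))),
                             c(1, 1, 1)),
               "share one grid shape")
})

test_that("structure sets survive a NIfTI round trip", {
  lat <- centred_lattice(30, 2.5)
  hr <- sphere_mask(lat$shape, lat$spacing, lat$origin, c(0, 0, 0), 12)
  bl <- sphere_mask(lat$shape, lat$spacing, lat$origin, c(0, -25, 0), 8)
  ss <- structure_set(list(hrctv = hr, bladder = bl),
                      spacing = lat$spacing, origin = lat$origin)
  path <- tempfile(fileext = ".nii.gz")
  write_structures(ss, path)
  ss2 <- read_structures(path)
  expect_identical(ss2$masks$hrctv, ss$masks$hrctv)
  expect_identical(ss2$masks$bladder, ss$masks$bladder)
  expect_equal(ss2$spacing, ss$spacing)
  expect_equal(ss2$origin, ss$origin)
})
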