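# DVH metrics: D2cm3, D90, EQD2, constraints.

test_that("cumulative DVH reproduces step curves for uniform and two-level doses", {
  ph <- block_dose_phantom(list(list(n = 10000, dose = 5)))  # 10 cm3 at 5 Gy
  dvh <- cumulative_dvh(ph$dose, ph$mask)
  expect_equal(dvh$total_cm3, 10)
  expect_equal(sum(dvh$doses_desc >= 5) * dvh$voxel_cm3, 10)
  expect_equal(sum(dvh$doses_desc >= 5.01) * dvh$voxel_cm3, 0)

  two <- block_dose_phantom(list(list(n = 3000, dose = 10),
                                 list(n = 7000, dose = 1)))
  curve <- as.data.frame(cumulative_dvh(two$dose, two$mask))
  expect_equal(nrow(curve), 2L)
  expect_equal(curve$volume_cm3[curve$dose_Gy == 10], 3)
  expect_equal(curve$volume_cm3[curve$dose_Gy == 1], 10)

  expect_error(cumulative_dvh(ph$dose, array(FALSE, dim(ph$dose$dose))),
               "empty structure")
  expect_error(cumulative_dvh(ph$dose, array(TRUE, c(2, 2, 2))),
               "different lattices")
})

test_that("D2cm3 handles uniform, single-level and two-level hot spots", {
  uni <- block_dose_phantom(list(list(n = 10000, dose = 5)))
  expect_equal(dose_at_volume(cumulative_dvh(uni$dose, uni$mask), 2), 5)

  hot <- block_dose_phantom(list(list(n = 3000, dose = 10),
                                 list(n = 7000, dose = 1)))
  expect_equal(dose_at_volume(cumulative_dvh(hot$dose, hot$mask), 2), 10)

  two <- block_dose_phantom(list(list(n = 1000, dose = 10),
                                 list(n = 1000, dose = 8),
                                 list(n = 8000, dose = 1)))
  expect_equal(dose_at_volume(cumulative_dvh(two$dose, two$mask), 2), 8)

  small <- block_dose_phantom(list(list(n = 1000, dose = 5)))  # 1 cm3 organ
  expect_error(dose_at_volume(cumulative_dvh(small$dose, small$mask), 2),
               "smaller than volume criterion")
})

test_that("D90 matches uniform, stepped and ramped dose distributions", {
  uni <- block_dose_phantom(list(list(n = 5000, dose = 7)))
  expect_equal(dose_to_fraction(cumulative_dvh(uni$dose, uni$mask), 0.9), 7)

  stepped <- block_dose_phantom(list(list(n = 9000, dose = 7),
                                     list(n = 1000, dose = 3)))
  expect_equal(dose_to_fraction(cumulative_dvh(stepped$dose, stepped$mask), 0.9), 7)

  # linear ramp 0..10 Gy uniformly over the organ: D90 ~ 10% quantile = 1 Gy
  n <- 2000L
  ramp <- dose_grid(array(seq(0, 10, length.out = n), dim = c(n, 1, 1)),
                    rep(1, 3))
  d90 <- dose_to_fraction(cumulative_dvh(ramp, array(TRUE, c(n, 1, 1))), 0.9)
  expect_equal(d90, 1, tolerance = 0.01)

  expect_error(dose_to_fraction(cumulative_dvh(uni$dose, uni$mask), 0),
               "in \\(0, 1]")
  expect_error(dose_to_fraction(cumulative_dvh(uni$dose, uni$mask), 1.1),
               "in \\(0, 1]")
})

test_that("DVH metrics agree with the sort-and-accumulate oracle on random grids", {
  set.seed(7)
  for (trial in 1:10) {
    shape <- c(sample(4:9, 1), sample(4:9, 1), sample(4:9, 1))
    sp <- runif(3, 1, 4)
    dose <- array(rexp(prod(shape), rate = 1 / 3), dim = shape)
    mask <- array(runif(prod(shape)) < 0.7, dim = shape)
    if (sum(mask) < 4) mask[1:4] <- TRUE
    dg <- dose_grid(dose, sp)
    dvh <- cumulative_dvh(dg, mask)
    vv <- voxel_volume_cm3(sp)
    v_organ <- sum(mask) * vv
    for (v in c(0.5 * v_organ, 0.9 * v_organ, min(2, 0.99 * v_organ))) {
      expect_equal(dose_at_volume(dvh, v),
                   oracle_dose_at_volume(dose[mask], vv, v),
                   tolerance = 1e-9)
    }
    expect_equal(dose_to_fraction(dvh, 0.9),
                 oracle_dose_at_volume(dose[mask], vv, 0.9 * v_organ),
                 tolerance = 1e-9)
  }
})

test_that("D2cm3 scales linearly under uniform dose scaling", {
  set.seed(11)
  dose <- array(runif(500, 0, 8), dim = c(500, 1, 1))
  mask <- array(TRUE, c(500, 1, 1))
  base <- dose_at_volume(cumulative_dvh(dose_grid(dose, c(2, 2, 2)), mask), 2)
  for (s in c(0.25, 2, 7.5)) {
    scaled <- dose_at_volume(
      cumulative_dvh(dose_grid(dose * s, c(2, 2, 2)), mask), 2)
    expect_equal(scaled, s * base, tolerance = 1e-12)
  }
})

test_that("EQD2 follows the linear-quadratic conversion", {
  # at 2 Gy per fraction the conversion factor is 1
  expect_equal(eqd2(10, 2, 10), 20)
  expect_equal(eqd2(4, 7, 10), 28 * 17 / 12)   # 39.667 Gy
  expect_equal(eqd2(4, 0, 3), 0)
  # additive over courses with equal dose per fraction
  expect_equal(eqd2(3, 5, 3) + eqd2(2, 5, 3), eqd2(5, 5, 3))
  expect_error(eqd2(4, 7, 0), "positive")
  expect_error(eqd2(4, 7, -3), "positive")
})

test_that("per-fraction constraints use strict organ-specific thresholds", {
  mk <- function(bl, re, sg, si) plan_dose_metrics(
    7, c(bladder = bl, rectum = re, sigmoid_colon = sg, small_intestine = si))
  expect_equal(unname(check_constraints(mk(5.19, 4.69, 4.0, 4.0))),
               rep("pass", 4))
  expect_equal(check_constraints(mk(5.2, 4.0, 4.0, 4.0))[["bladder"]], "fail")
  expect_equal(check_constraints(mk(5.0, 4.7, 4.0, 4.0))[["rectum"]], "fail")
  expect_equal(unname(check_constraints(mk(0, 0, 0, 0))), rep("pass", 4))

  m <- plan_dose_metrics(7, c(bladder = 3))
  v <- check_constraints(m)
  expect_equal(v[["bladder"]], "pass")
  expect_equal(v[["rectum"]], "missing")
})

test_that("plan metrics keep the exact ratio invariant", {
  m <- plan_dose_metrics(7, c(bladder = 3.5, rectum = 2.8), d_prescription = 7)
  expect_identical(m$ratio, m$d2cm3 / 7)
  expect_error(plan_dose_metrics(7, c(bladder = -1)), "non-negative")
  expect_error(plan_dose_metrics(7, c(bladder = 1), d_prescription = 0),
               "positive")
})

test_that("per-plan metrics are written as tidy CSV rows", {
  ml <- list(
    p1 = plan_dose_metrics(7, c(bladder = 3.5, rectum = 2.8)),
    p2 = plan_dose_metrics(7, c(bladder = 4.2, rectum = 3.1))
  )
  path <- tempfile(fileext = ".csv")
  write_metrics_csv(ml, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 4L)
  expect_named(tab, c("plan_id", "organ", "D2cm3_Gy", "ratio"))
  expect_equal(tab$ratio, tab$D2cm3_Gy / 7, tolerance = 1e-12)
})
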