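# Seeded synthetic pelvic-phantom cohort: parametric structure geometry plus
# a clipped inverse-square point-source dose engine, normalized so that the
# HR-CTV D90 equals the prescription dose.
#
# The generator emulates a tandem-and-ovoid cohort at desk scale: an
# ellipsoidal HR-CTV with the bladder anterior, rectum posterior, sigmoid
# colon posterior-superior and a small-intestine blob cluster superior, each
# placed with a randomized surface-to-surface gap to the target.  Because
# dose falls off with distance from the dwells inside the HR-CTV, plans in
# which an organ sits closer to the target (larger near-target sub-OAR
# volumes) receive systematically higher D2cm3 -- the volume-dose mechanism
# the regression model learns.

#' Phantom cohort configuration
#'
#' All linear dimensions in mm.  Axis convention: x = left-right,
#' y = anterior(-)/posterior(+), z = inferior(-)/superior(+); the HR-CTV is
#' centred at the physical origin.
#'
#' @param n_plans Number of plans in the cohort (default 200).
#' @param shape Grid shape (voxels), default `c(76, 96, 96)`.
#' @param spacing Voxel spacing in mm, default 2.5 mm isotropic.
#' @param hrctv_base_mm Range of the HR-CTV mean radius; the three ellipsoid
#'   semi-axes are the drawn base radius times independent `exp(U(-0.08, 0.08))`
#'   shape factors, so target volume varies several-fold while the shape
#'   stays near-spherical and the volume remains informative of every axis.
#' @param gap_mm Range of the organ-to-target surface gap; organs are placed
#'   so their nearest surface sits this far outside the HR-CTV.  The
#'   small-intestine gap is additionally coupled to the drawn bladder radius
#'   (fuller bladder, smaller bowel-to-target gap), reproducing a positive
#'   association between bladder volume and small-intestine dose.
#' @param bladder_radius_mm,rectum_radius_mm,sigmoid_radius_mm,intestine_radius_mm
#'   Organ size ranges (sphere radius for bladder/intestine blobs, tube
#'   radius for rectum/sigmoid).
#' @param weight_jitter_sd Standard deviation of the lognormal dwell-weight
#'   jitter (relative; default 0.05), modelling residual plan-to-plan
#'   optimizer variability around the common loading pattern.
#' @param r_min_mm Clip radius of the point-source kernel (default 1 mm).
#' @param d_prescription Prescription dose in Gy per fraction (default 7).
#' @param n_fractions Number of brachytherapy fractions (default 4).
#' @param seed Root seed for the whole cohort.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(n_plans = 200L,
                           shape = c(76L, 96L, 96L),
                           spacing = c(2.5, 2.5, 2.5),
                           hrctv_base_mm = c(16, 28),
                           gap_mm = c(2, 14),
                           bladder_radius_mm = c(20, 32),
                           rectum_radius_mm = c(9, 14),
                           sigmoid_radius_mm = c(9, 13),
                           intestine_radius_mm = c(12, 16),
                           weight_jitter_sd = 0.05,
                           r_min_mm = 1.0,
                           d_prescription = 7.0,
                           n_fractions = 4L,
                           seed = 20260101L) {
  stopifnot(n_plans >= 1L, length(shape) == 3L, all(shape > 0),
            length(spacing) == 3L, all(spacing > 0),
            all(hrctv_base_mm > 0), all(gap_mm > 0),
            weight_jitter_sd >= 0, r_min_mm > 0, d_prescription > 0)
  structure(
    list(n_plans = as.integer(n_plans), shape = as.integer(shape),
         spacing = as.numeric(spacing),
         origin = -(as.integer(shape) - 1) * as.numeric(spacing) / 2,
         hrctv_base_mm = hrctv_base_mm, gap_mm = gap_mm,
         bladder_radius_mm = bladder_radius_mm,
         rectum_radius_mm = rectum_radius_mm,
         sigmoid_radius_mm = sigmoid_radius_mm,
         intestine_radius_mm = intestine_radius_mm,
         weight_jitter_sd = weight_jitter_sd, r_min_mm = r_min_mm,
         d_prescription = d_prescription, n_fractions = as.integer(n_fractions),
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate one phantom structure set
#'
#' Deterministic for a fixed `(cfg, plan_seed)`.  Organs are placed with an
#' analytic clearance to the HR-CTV and re-drawn (bounded retries) in the
#' rare case voxelization still produces an overlap.
#'
#' @param cfg A [phantom_config].
#' @param plan_seed Integer seed for this plan.
#' @param coords Optional precomputed [lattice_coords()] for the lattice
#'   (a cohort-level cache; recomputed when `NULL`).
#' @return A [structure_set] with hrctv + the four OARs, plus attribute
#'   `"hrctv_radii"` used by the dwell layout.
#' @export
generate_structures <- function(cfg, plan_seed, coords = NULL) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (is.null(coords))
    coords <- lattice_coords(cfg$shape, cfg$spacing, cfg$origin)
  X <- coords$x; Y <- coords$y; Z <- coords$z

  with_seed(plan_seed, {
    base <- runif1(cfg$hrctv_base_mm)
    a <- base * exp(stats::runif(1, -0.08, 0.08))   # x semi-axis
    b <- base * exp(stats::runif(1, -0.08, 0.08))   # y semi-axis
    c_ <- base * exp(stats::runif(1, -0.08, 0.08))  # z semi-axis
    hr <- (X / a)^2 + (Y / b)^2 + (Z / c_)^2 <= 1

    draw_until_disjoint <- function(draw) {
      for (i in 1:20) {
        m <- draw()
        if (!any(m & hr)) return(m)
      }
      stop("infeasible organ placement after bounded retries")
    }

    rb <- runif1(cfg$bladder_radius_mm)
    bladder <- draw_until_disjoint(function() {
      g <- runif1(cfg$gap_mm)
      cx <- stats::runif(1, -6, 6); cz <- stats::runif(1, -6, 6)
      cy <- -(b + g + rb)
      (X - cx)^2 + (Y - cy)^2 + (Z - cz)^2 <= rb^2
    })

    rectum <- draw_until_disjoint(function() {
      rr <- runif1(cfg$rectum_radius_mm)
      g <- runif1(cfg$gap_mm)
      cx <- stats::runif(1, -5, 5)
      cy <- b + g + rr
      cz <- stats::runif(1, -10, 10)
      hl <- 40 + stats::runif(1, 0, 15)
      (X - cx)^2 + (Y - cy)^2 <= rr^2 & abs(Z - cz) <= hl
    })

    sigmoid <- draw_until_disjoint(function() {
      rs <- runif1(cfg$sigmoid_radius_mm)
      g <- runif1(cfg$gap_mm)
      phi <- stats::runif(1, 30, 60) * pi / 180      # tilt from +z toward +y
      w <- c(0, sin(phi), cos(phi))                  # posterior-superior
      t_surf <- 1 / sqrt((w[2] / b)^2 + (w[3] / c_)^2)
      p0 <- (t_surf + g + rs) * w + c(stats::runif(1, -8, 8), 0, 0)
      u <- c(1, stats::runif(1, -0.3, 0.3), stats::runif(1, -0.3, 0.3))
      u <- u / sqrt(sum(u^2))
      dx <- X - p0[1]; dy <- Y - p0[2]; dz <- Z - p0[3]
      proj <- dx * u[1] + dy * u[2] + dz * u[3]
      perp2 <- dx^2 + dy^2 + dz^2 - proj^2
      perp2 <= rs^2 & abs(proj) <= 35
    })

    intestine <- draw_until_disjoint(function() {
      # bowel-to-target gap shrinks as the bladder fills (positive coupling
      # between bladder volume and small-intestine dose)
      rb_rel <- (rb - cfg$bladder_radius_mm[1]) /
        diff(cfg$bladder_radius_mm)
      g <- max(cfg$gap_mm[1],
               min(cfg$gap_mm[2],
                   cfg$gap_mm[2] - rb_rel * 0.85 * diff(cfg$gap_mm) +
                     stats::runif(1, -1.5, 1.5)))
      # "bowel bag" planning volume: a broad rounded slab whose flat lower
      # surface rests `g` above the target apex.  With a flat bottom the
      # shell intersections grow with target width as well as closeness --
      # the dome curvature sets how fast the bowel-to-target distance
      # increases away from the apex
      th <- stats::runif(1, 18, 28)            # bag thickness
      ex <- stats::runif(1, 30, 40)            # lateral half-extents
      ey <- stats::runif(1, 30, 40)
      ox <- stats::runif(1, -6, 6); oy <- stats::runif(1, -6, 6)
      super_r <- ((abs(X - ox) / ex)^4 + (abs(Y - oy) / ey)^4)
      Z >= c_ + g & Z <= c_ + g + th & super_r <= 1
    })

    ss <- structure_set(
      stats::setNames(
        list(hr, bladder, rectum, sigmoid, intestine),
        c(HRCTV, "bladder", "rectum", "sigmoid_colon", "small_intestine")
      ),
      spacing = cfg$spacing, origin = cfg$origin
    )
    attr(ss, "hrctv_radii") <- c(a, b, c_)
    ss
  })
}

#' Generate the dwell layout for one plan
#'
#' Tandem dwells step along the z axis in fixed 5 mm increments from 4 mm
#' below the superior target surface over a fixed 30 mm active length
#' (7 dwells, as an afterloader steps a fixed source train), plus two ovoid
#' dwells at the inferior-lateral target surface.  Base
#' weights are then optimized deterministically toward a uniform dose on the
#' target surface -- the counterpart of the manual/graphical optimization a
#' planner performs so the prescription isodose conforms to the HR-CTV --
#' and finally multiplied by lognormal jitter modelling residual
#' plan-to-plan optimizer variability.  The optimization sees only the
#' target surface, never the organs at risk.
#'
#' @param cfg A [phantom_config].
#' @param structures The plan's [structure_set] (target surface probes).
#' @param plan_seed Integer seed (jitter stream).
#' @param hrctv_radii HR-CTV semi-axes `(a, b, c)` in mm; defaults to the
#'   attribute stored by [generate_structures()].
#' @return Object of class `dwell_set`: list with `positions` (n x 3 matrix,
#'   mm) and `weights`.
#' @export
generate_dwells <- function(cfg, structures, plan_seed,
                            hrctv_radii = attr(structures, "hrctv_radii")) {
  a <- hrctv_radii[1]; c_ <- hrctv_radii[3]
  tz <- seq(c_ - 4, by = -5, length.out = 7)  # fixed 30 mm active length
  pos <- rbind(
    cbind(0, 0, tz),                              # tandem
    c(-(a - 4), 0, -0.6 * c_),                    # left ovoid
    c(a - 4, 0, -0.6 * c_)                        # right ovoid
  )
  base <- conformal_weights(pos, c(rep(1, length(tz)), 1.3, 1.3),
                            structures, cfg$r_min_mm)
  w <- with_seed(plan_seed + 1L,
                 base * exp(stats::rnorm(length(base), 0, cfg$weight_jitter_sd)))
  structure(list(positions = pos, weights = w), class = "dwell_set")
}

# Deterministic multiplicative update of dwell weights toward equal dose at
# the target surface voxels (Aw ~ 1): w_i <- w_i * (A' t) / (A' A w), the
# standard image-reconstruction update, which keeps weights positive and
# converges to a least-squares-like conformal loading.
conformal_weights <- function(positions, w0, structures, r_min_mm,
                              n_iter = 25L) {
  m <- structures$masks[[HRCTV]]
  surf <- m & !erode6(m)
  idx <- which(surf, arr.ind = TRUE)
  probes <- t(structures$origin + t(idx - 1) * structures$spacing)
  A <- matrix(0, nrow(probes), nrow(positions))
  for (i in seq_len(nrow(positions))) {
    r2 <- (probes[, 1] - positions[i, 1])^2 +
      (probes[, 2] - positions[i, 2])^2 +
      (probes[, 3] - positions[i, 3])^2
    A[, i] <- 1 / pmax(r2, r_min_mm^2)
  }
  w <- w0
  target <- rep(1, nrow(A))
  At1 <- crossprod(A, target)
  for (it in seq_len(n_iter)) {
    denom <- crossprod(A, A %*% w)
    w <- as.numeric(w * At1 / pmax(denom, .Machine$double.eps))
  }
  w / mean(w)
}

# 6-neighbour erosion of a 3-D logical array (faces only).
erode6 <- function(m) {
  d <- dim(m)
  sh <- function(m, ax, by) {
    out <- array(FALSE, d)
    src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    n <- d[ax]
    if (by > 0) { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
    else { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  m & sh(m, 1, 1) & sh(m, 1, -1) & sh(m, 2, 1) & sh(m, 2, -1) &
    sh(m, 3, 1) & sh(m, 3, -1)
}

#' Compute the dose grid for a dwell set
#'
#' Clipped inverse-square point-source kernel:
#' `dose(x) = sum_i w_i / max(r_i, r_min)^2` (arbitrary units before
#' prescription normalization); linear in the weights.
#'
#' @param dwells A `dwell_set`.
#' @param shape,spacing,origin Lattice definition (see [structure_set]).
#' @param r_min_mm Clip radius in mm.
#' @param coords Optional precomputed [lattice_coords()].
#' @return A [dose_grid] (unnormalized units).
#' @export
compute_dose <- function(dwells, shape, spacing, origin, r_min_mm = 1.0,
                         coords = NULL) {
  stopifnot(inherits(dwells, "dwell_set"))
  if (nrow(dwells$positions) < 1L || all(dwells$weights == 0) ||
      any(dwells$weights < 0))
    stop("dwell set must have >= 1 dwell with non-negative, not all zero weights")
  if (is.null(coords)) coords <- lattice_coords(shape, spacing, origin)
  d <- array(0, dim = shape)
  r_min2 <- r_min_mm^2
  for (i in seq_len(nrow(dwells$positions))) {
    p <- dwells$positions[i, ]
    r2 <- (coords$x - p[1])^2 + (coords$y - p[2])^2 + (coords$z - p[3])^2
    d <- d + dwells$weights[i] / pmax(r2, r_min2)
  }
  dose_grid(d, spacing, origin)
}

#' Normalize a dose grid to the prescription
#'
#' Scales the dose so that the HR-CTV D90 equals `d_prescription` exactly.
#'
#' @param dose A [dose_grid].
#' @param structures The matching [structure_set].
#' @param d_prescription Gy per fraction (default 7).
#' @return The rescaled [dose_grid].
#' @export
normalize_to_prescription <- function(dose, structures, d_prescription = 7.0) {
  dvh <- cumulative_dvh(dose, structures$masks[[HRCTV]])
  d90 <- dose_to_fraction(dvh, 0.90)
  if (d90 <= 0) stop("zero dose in HR-CTV; cannot normalize")
  dose_grid(dose$dose * (d_prescription / d90), dose$spacing, dose$origin)
}

# Feature + metric rows for one plan (one row per organ).
plan_record <- function(cfg, structures, dose, plan_id,
                        rings = derive_rings(structures)) {
  hr_dvh <- cumulative_dvh(dose, structures$masks[[HRCTV]])
  d90 <- dose_to_fraction(hr_dvh, 0.90)
  rows <- lapply(OAR_NAMES, function(organ) {
    sub <- sub_oar_volumes(rings, structures, organ)
    fv <- build_feature_vector(sub, structures, organ)
    dvh <- cumulative_dvh(dose, structures$masks[[organ]])
    d2 <- dose_at_volume(dvh, 2.0)
    df <- data.frame(plan_id = plan_id, organ = organ,
                     V_global_cm3 = unname(fv[1]),
                     d90_hrctv_Gy = d90,
                     d_prescription_Gy = cfg$d_prescription,
                     D2cm3_Gy = d2, ratio = d2 / cfg$d_prescription)
    for (k in 1:5) df[[paste0("v", k, "_cm3")]] <- unname(fv[k + 1L])
    df
  })
  do.call(rbind, rows)
}

#' Generate a synthetic phantom cohort
#'
#' Runs the full per-plan chain -- structures, dwells, dose, prescription
#' normalization, ring features, DVH metrics -- for `cfg$n_plans` plans.
#' Fully deterministic given `cfg$seed` (plan `i` uses seed
#' `cfg$seed + 1000 * i`).
#'
#' @param cfg A [phantom_config].
#' @param keep_arrays Keep per-plan structure sets and dose grids in the
#'   result?  Default `FALSE` (feature/metric table only).
#' @param progress Print a dot every 20 plans.
#' @return Object of class `suboar_cohort`: list with `config`, `plans`
#'   (data frame, one row per plan x organ: features, D2cm3, ratio,
#'   constraint verdict) and, if requested, `arrays`.
#' @export
generate_cohort <- function(cfg = phantom_config(), keep_arrays = FALSE,
                            progress = FALSE) {
  stopifnot(inherits(cfg, "phantom_config"))
  coords <- lattice_coords(cfg$shape, cfg$spacing, cfg$origin)
  thresholds <- oar_constraints_gy()
  rows <- vector("list", cfg$n_plans)
  arrays <- if (keep_arrays) vector("list", cfg$n_plans) else NULL
  for (i in seq_len(cfg$n_plans)) {
    plan_seed <- as.integer((as.numeric(cfg$seed) + 1000 * i) %% .Machine$integer.max)
    ss <- generate_structures(cfg, plan_seed, coords = coords)
    dw <- generate_dwells(cfg, ss, plan_seed)
    dose <- compute_dose(dw, cfg$shape, cfg$spacing, cfg$origin,
                         r_min_mm = cfg$r_min_mm, coords = coords)
    dose <- normalize_to_prescription(dose, ss, cfg$d_prescription)
    rec <- plan_record(cfg, ss, dose, plan_id = i)
    rec$constraint <- ifelse(rec$D2cm3_Gy < thresholds[rec$organ],
                             "pass", "fail")
    rows[[i]] <- rec
    if (keep_arrays) arrays[[i]] <- list(structures = ss, dose = dose,
                                         dwells = dw)
    if (progress && i %% 20L == 0L) cat(".")
  }
  if (progress) cat("\n")
  structure(list(config = cfg, plans = do.call(rbind, rows), arrays = arrays),
            class = "suboar_cohort")
}

#' @export
print.suboar_cohort <- function(x, ...) {
  cat("<suboar_cohort>", x$config$n_plans, "plans,",
      nrow(x$plans), "organ rows\n")
  invisible(x)
}

#' Write a cohort feature/target table as CSV
#'
#' @param cohort A `suboar_cohort` (or its `plans` data frame).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- if (inherits(cohort, "suboar_cohort")) cohort$plans else cohort
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
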