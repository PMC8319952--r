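# DVH-derived dose metrics: D2cm3, D90, EQD2, per-fraction constraints.
#
# All DVH quantities are computed from the exact voxel dose multiset (sort
# descending, accumulate voxel volumes, interpolate linearly at the volume
# crossing) rather than from a binned histogram, so results are bin-free and
# converge as the lattice is refined.

#' Create a dose grid
#'
#' @param dose 3-D numeric array, dose in Gy per fraction, all values >= 0.
#' @param spacing Voxel spacing (mm).
#' @param origin Physical coordinate of voxel `[1, 1, 1]` (mm).
#' @return Object of class `dose_grid`.
#' @export
dose_grid <- function(dose, spacing, origin = c(0, 0, 0)) {
  if (length(dim(dose)) != 3L) stop("'dose' must be a 3-D array")
  if (any(dose < 0)) stop("dose values must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive numbers")
  structure(list(dose = dose, spacing = spacing, origin = as.numeric(origin)),
            class = "dose_grid")
}

#' Cumulative dose-volume histogram of one structure
#'
#' @param dose A [dose_grid].
#' @param mask 3-D logical array on the same lattice (non-empty).
#' @param spacing Voxel spacing in mm; defaults to the dose grid's spacing.
#' @return Object of class `dvh` holding the sorted voxel dose multiset;
#'   `as.data.frame()` gives the cumulative curve `(dose_Gy, volume_cm3)`
#'   at the unique dose levels, with `volume_cm3` the volume receiving at
#'   least `dose_Gy`.
#' @export
cumulative_dvh <- function(dose, mask, spacing = dose$spacing) {
  stopifnot(inherits(dose, "dose_grid"))
  if (!identical(dim(mask), dim(dose$dose)))
    stop("dose grid and mask are on different lattices")
  if (!any(mask)) stop("empty structure")
  doses <- sort(dose$dose[mask], decreasing = TRUE)
  structure(
    list(doses_desc = doses, voxel_cm3 = voxel_volume_cm3(spacing),
         total_cm3 = length(doses) * voxel_volume_cm3(spacing)),
    class = "dvh"
  )
}

#' @export
as.data.frame.dvh <- function(x, ...) {
  lev <- unique(x$doses_desc)                # descending
  vol <- vapply(lev, function(d) sum(x$doses_desc >= d) * x$voxel_cm3,
                numeric(1))
  data.frame(dose_Gy = lev, volume_cm3 = vol)
}

#' @export
print.dvh <- function(x, ...) {
  cat("<dvh>", format(x$total_cm3), "cm3, dose range [",
      format(min(x$doses_desc)), ",", format(max(x$doses_desc)), "] Gy\n")
  invisible(x)
}

# Shared interpolation: dose received by at least `v_cm3` of the structure.
# Accumulated volume after the k hottest voxels is k * voxel_cm3; the dose at
# an intermediate volume is interpolated linearly between adjacent voxels.
.dose_at_cum_volume <- function(dvh, v_cm3) {
  d <- dvh$doses_desc
  vv <- dvh$voxel_cm3
  if (v_cm3 <= vv) return(d[1L])
  k <- ceiling(v_cm3 / vv)
  k <- min(k, length(d))
  v_lo <- (k - 1) * vv
  if (d[k - 1L] == d[k]) return(d[k])
  d[k - 1L] + (v_cm3 - v_lo) / vv * (d[k] - d[k - 1L])
}

#' Minimum dose to the hottest volume (DVx, e.g. D2cm3)
#'
#' Returns the largest dose `D` such that the volume receiving at least `D`
#' is at least `v_cm3`, with linear interpolation between voxel dose steps.
#' `dose_at_volume(dvh, 2)` is the standard brachytherapy D2cm3 metric.
#'
#' @param dvh A `dvh` from [cumulative_dvh()].
#' @param v_cm3 Volume criterion in cm^3 (default 2).
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, v_cm3 = 2.0) {
  stopifnot(inherits(dvh, "dvh"))
  if (v_cm3 <= 0) stop("'v_cm3' must be positive")
  if (dvh$total_cm3 < v_cm3)
    stop("organ smaller than volume criterion (",
         format(dvh$total_cm3), " < ", format(v_cm3), " cm3)")
  .dose_at_cum_volume(dvh, v_cm3)
}

#' Minimum dose to the hottest fraction of a volume (e.g. D90)
#'
#' @param dvh A `dvh` from [cumulative_dvh()].
#' @param fraction Volume fraction in (0, 1]; default 0.90 (the D90 used to
#'   normalize target coverage).
#' @return Dose in Gy.
#' @export
dose_to_fraction <- function(dvh, fraction = 0.90) {
  stopifnot(inherits(dvh, "dvh"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]")
  .dose_at_cum_volume(dvh, fraction * dvh$total_cm3)
}

#' Equivalent dose in 2 Gy fractions (linear-quadratic model)
#'
#' `EQD2 = n * d * (d + alpha_beta) / (2 + alpha_beta)`: the total physical
#' dose weighted by the relative biological effect per fraction.  With
#' `d = 2` Gy the factor is 1 and EQD2 equals the physical dose.
#'
#' @param n_fractions Number of fractions.
#' @param d_per_fraction Dose per fraction in Gy (>= 0).
#' @param alpha_beta Tissue alpha/beta ratio in Gy; 10 for tumour targets,
#'   3 for late-responding organs at risk.
#' @return EQD2 in Gy.
#' @export
eqd2 <- function(n_fractions, d_per_fraction, alpha_beta) {
  if (alpha_beta <= 0) stop("'alpha_beta' must be positive")
  if (n_fractions <= 0) stop("'n_fractions' must be positive")
  if (d_per_fraction < 0) stop("'d_per_fraction' must be non-negative")
  n_fractions * d_per_fraction * (d_per_fraction + alpha_beta) / (2 + alpha_beta)
}

#' Per-fraction OAR planning constraints
#'
#' Single-fraction planning aims: bladder D2cm3 < 5.2 Gy; rectum, sigmoid
#' colon and small intestine D2cm3 < 4.7 Gy (strict inequalities).
#'
#' @return Named numeric vector of thresholds in Gy per fraction.
#' @export
oar_constraints_gy <- function() {
  c(bladder = 5.2, rectum = 4.7, sigmoid_colon = 4.7, small_intestine = 4.7)
}

#' Per-plan dose metrics
#'
#' @param d90_hrctv HR-CTV D90 in Gy.
#' @param d2cm3 Named numeric, per-organ D2cm3 in Gy.
#' @param d_prescription Prescription dose in Gy per fraction (default 7).
#' @return Object of class `plan_dose_metrics` with the D2cm3/Dprescription
#'   ratio per organ.
#' @export
plan_dose_metrics <- function(d90_hrctv, d2cm3, d_prescription = 7.0) {
  if (d_prescription <= 0) stop("'d_prescription' must be positive")
  if (any(d2cm3 < 0) || d90_hrctv < 0) stop("doses must be non-negative")
  structure(
    list(d_prescription = d_prescription, d90_hrctv = d90_hrctv,
         d2cm3 = d2cm3, ratio = d2cm3 / d_prescription),
    class = "plan_dose_metrics"
  )
}

#' @export
print.plan_dose_metrics <- function(x, ...) {
  cat("<plan_dose_metrics> D90(HR-CTV) =", format(x$d90_hrctv), "Gy,",
      "prescription", format(x$d_prescription), "Gy\n")
  print(data.frame(organ = names(x$d2cm3), D2cm3_Gy = round(x$d2cm3, 3),
                   ratio = round(x$ratio, 4), row.names = NULL))
  invisible(x)
}

#' Check per-fraction OAR constraints for a plan
#'
#' @param metrics A [plan_dose_metrics] object.
#' @param thresholds Named thresholds in Gy; default [oar_constraints_gy()].
#' @return Named character vector per threshold organ: `"pass"`, `"fail"`, or
#'   `"missing"` when the plan has no D2cm3 for that organ.
#' @export
check_constraints <- function(metrics, thresholds = oar_constraints_gy()) {
  stopifnot(inherits(metrics, "plan_dose_metrics"))
  out <- character(length(thresholds))
  names(out) <- names(thresholds)
  for (organ in names(thresholds)) {
    if (!organ %in% names(metrics$d2cm3)) {
      out[organ] <- "missing"
    } else {
      out[organ] <- if (metrics$d2cm3[[organ]] < thresholds[[organ]])
        "pass" else "fail"
    }
  }
  out
}

#' Write per-plan dose metrics as CSV rows
#'
#' @param metrics_list Named list (plan id -> [plan_dose_metrics]).
#' @param path Output CSV path.
#' @return Invisibly, the data frame written (`plan_id, organ, D2cm3_Gy, ratio`).
#' @export
write_metrics_csv <- function(metrics_list, path) {
  rows <- do.call(rbind, lapply(names(metrics_list), function(id) {
    m <- metrics_list[[id]]
    data.frame(plan_id = id, organ = names(m$d2cm3),
               D2cm3_Gy = as.numeric(m$d2cm3), ratio = as.numeric(m$ratio))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
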