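# Pipeline orchestration: simulate -> features -> train/evaluate -> QA.
# Each command is a plain function over the package's module surface; the
# shell entry point (inst/cli/suboar) is a thin wrapper around these.

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if missing).
#' @param phantom A [phantom_config].
#' @param svr An [svr_config].
#' @param n_train,n_valid Training / verification group sizes.
#' @param delta_threshold QA threshold on delta = |actual - predicted| ratio,
#'   either a single number or a named per-organ vector (default 0.1).
#' @param seed Root seed; flows to the phantom config, the cohort split and
#'   the SVR fold assignment unless those carry their own.
#' @param log_level One of `"quiet"`, `"info"`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "suboar_out",
                            phantom = phantom_config(),
                            svr = svr_config(),
                            n_train = 160L, n_valid = 40L,
                            delta_threshold = 0.1,
                            seed = 20260101L,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (any(delta_threshold < 0)) stop("'delta_threshold' must be >= 0")
  seed <- as.integer(seed)
  phantom$seed <- as.integer(phantom$seed %||% seed)
  if (is.null(svr$seed)) svr$seed <- seed
  structure(
    list(out_dir = out_dir, phantom = phantom, svr = svr,
         n_train = as.integer(n_train), n_valid = as.integer(n_valid),
         delta_threshold = delta_threshold, seed = seed,
         log_level = log_level),
    class = "pipeline_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipe_log <- function(config, ...) {
  if (identical(config$log_level, "info")) message("[suboar] ", ...)
  invisible(NULL)
}

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

# Machine-readable run log: config, seed, package version.
write_run_log <- function(config, stage, path) {
  jsonlite::write_json(
    list(stage = stage, seed = config$seed,
         package_version = as.character(utils::packageVersion("suboar")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         n_train = config$n_train, n_valid = config$n_valid,
         delta_threshold = config$delta_threshold,
         phantom = unclass(config$phantom),
         svr = unclass(config$svr)),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Simulate a phantom cohort and write it to disk
#'
#' @param config A [pipeline_config].
#' @param write_volumes Also write per-plan NIfTI masks and dose grids
#'   (default `FALSE`; the cohort CSV alone feeds the model).
#' @return Invisibly, a list with the cohort object and file paths.
#' @export
cmd_simulate <- function(config, write_volumes = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  ensure_dir(config$out_dir)
  pipe_log(config, "simulating ", config$phantom$n_plans, " phantom plans")
  cohort <- generate_cohort(config$phantom, keep_arrays = write_volumes)
  csv <- file.path(config$out_dir, "cohort.csv")
  write_cohort_csv(cohort, csv)
  if (write_volumes) {
    vol_dir <- ensure_dir(file.path(config$out_dir, "volumes"))
    for (i in seq_along(cohort$arrays)) {
      rec <- cohort$arrays[[i]]
      write_structures(rec$structures,
                       file.path(vol_dir, sprintf("plan%03d_masks.nii.gz", i)))
      img <- RNifti::asNifti(rec$dose$dose)
      RNifti::pixdim(img) <- rec$dose$spacing
      RNifti::writeNifti(img, file.path(vol_dir,
                                        sprintf("plan%03d_dose.nii.gz", i)))
    }
  }
  log_path <- file.path(config$out_dir, "simulate_log.json")
  write_run_log(config, "simulate", log_path)
  pipe_log(config, "wrote ", csv)
  invisible(list(cohort = cohort, cohort_csv = csv, log = log_path))
}

#' Extract sub-OAR features from structure masks on disk
#'
#' Reads per-plan NIfTI mask volumes (as written by [cmd_simulate()] with
#' `write_volumes = TRUE`, or any files following the
#' `*_masks.nii.gz` + `.labels.json` convention) and writes the sub-volume
#' feature table.  Malformed plans are skipped with a warning; if every plan
#' fails, an error is raised.
#'
#' @param config A [pipeline_config].
#' @param masks_dir Directory of mask volumes; defaults to
#'   `<out_dir>/volumes`.
#' @return Invisibly, the feature data frame
#'   (`plan_id, organ, V_global_cm3, v1..v5_cm3`).
#' @export
cmd_features <- function(config, masks_dir = file.path(config$out_dir, "volumes")) {
  stopifnot(inherits(config, "pipeline_config"))
  files <- sort(list.files(masks_dir, pattern = "_masks\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no mask volumes found in ", masks_dir)
  rows <- list()
  for (f in files) {
    plan_id <- sub("_masks\\.nii(\\.gz)?$", "", basename(f))
    rec <- tryCatch({
      ss <- read_structures(f)
      rings <- derive_rings(ss)
      do.call(rbind, lapply(intersect(OAR_NAMES, names(ss$masks)), function(organ) {
        fv <- build_feature_vector(sub_oar_volumes(rings, ss, organ), ss, organ)
        df <- data.frame(plan_id = plan_id, organ = organ,
                         V_global_cm3 = unname(fv[1]))
        for (k in 1:5) df[[paste0("v", k, "_cm3")]] <- unname(fv[k + 1L])
        df
      }))
    }, error = function(e) {
      warning("skipping plan '", plan_id, "': ", conditionMessage(e))
      NULL
    })
    rows[[plan_id]] <- rec
  }
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stop("feature extraction failed for every plan")
  out <- do.call(rbind, rows)
  ensure_dir(config$out_dir)
  csv <- file.path(config$out_dir, "features.csv")
  utils::write.csv(out, csv, row.names = FALSE)
  pipe_log(config, "wrote ", csv, " (", length(rows), " plans)")
  invisible(out)
}

# Feature matrix + target vector for one organ from a cohort table.
organ_xy <- function(plans, organ) {
  sub <- plans[plans$organ == organ, , drop = FALSE]
  X <- as.matrix(sub[, c("V_global_cm3", paste0("v", 1:5, "_cm3"))])
  colnames(X) <- feature_names(organ)
  list(X = X, y = sub$ratio, plan_id = sub$plan_id)
}

#' Train and evaluate the four per-organ SVR models
#'
#' Splits the cohort into training / verification groups, grid-searches and
#' fits one RBF-SVR per organ on the training group, evaluates on the
#' verification group, and writes model JSON files plus a combined report.
#'
#' @param config A [pipeline_config].
#' @param cohort_csv Cohort table path; defaults to `<out_dir>/cohort.csv`.
#' @return Invisibly, list with `models`, `reports`, `split`, `summary`
#'   (data frame of per-organ training/validation statistics).
#' @export
cmd_train_eval <- function(config,
                           cohort_csv = file.path(config$out_dir, "cohort.csv")) {
  stopifnot(inherits(config, "pipeline_config"))
  plans <- read_cohort_csv(cohort_csv)
  ids <- sort(unique(plans$plan_id))
  split <- split_cohort(ids, config$n_train, config$n_valid, seed = config$seed)
  models <- list(); reports <- list(); summ <- list()
  for (organ in OAR_NAMES) {
    xy <- organ_xy(plans, organ)
    tr <- xy$plan_id %in% split$train
    model <- train_svr(xy$X[tr, , drop = FALSE], xy$y[tr], config$svr,
                       organ = organ)
    report <- evaluate_model(model, xy$X[!tr, , drop = FALSE], xy$y[!tr])
    models[[organ]] <- model
    reports[[organ]] <- report
    summ[[organ]] <- data.frame(
      organ = organ, C = model$C, gamma = model$gamma,
      training_mse = model$training_mse, training_r2 = model$training_r2,
      validation_mse = report$mse, delta_mean = report$delta_mean,
      delta_sd = report$delta_sd, paired_t = report$paired_t$t,
      paired_t_p = report$paired_t$p
    )
    pipe_log(config, sprintf(
      "%s: C=%g gamma=%g  train MSE %.5f R2 %.4f  valid delta %.4f+/-%.4f p %.3f",
      organ, model$C, model$gamma, model$training_mse, model$training_r2,
      report$delta_mean, report$delta_sd, report$paired_t$p))
  }
  summary_df <- do.call(rbind, summ)
  rownames(summary_df) <- NULL
  ensure_dir(config$out_dir)
  for (organ in OAR_NAMES)
    write_model(models[[organ]],
                file.path(config$out_dir, paste0("model_", organ, ".json")))
  utils::write.csv(summary_df, file.path(config$out_dir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(reports, function(r) list(
      organ = r$organ, mse = r$mse, r_squared = r$r_squared,
      delta_mean = r$delta_mean, delta_sd = r$delta_sd,
      paired_t = r$paired_t,
      pearson = r$pearson)),
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows"
  )
  write_run_log(config, "train_eval",
                file.path(config$out_dir, "train_eval_log.json"))
  invisible(list(models = models, reports = reports, split = split,
                 summary = summary_df))
}

#' Quality-assurance check of one plan against trained models
#'
#' Predicts the achievable D2cm3/Dprescription ratio per organ from the
#' plan's sub-OAR features and compares it with the actually planned ratio;
#' organs whose delta exceeds the configured threshold are flagged for
#' re-optimization.
#'
#' @param config A [pipeline_config] (supplies `delta_threshold`).
#' @param plan_features Data frame with one row per organ
#'   (`organ, V_global_cm3, v1..v5_cm3`).
#' @param actual_ratio Named numeric: the planned D2cm3/Dprescription per
#'   organ.
#' @param models Named list of `suboar_svr` models; defaults to reading the
#'   JSON models from `out_dir`.
#' @return Data frame per organ: predicted and actual ratio, `delta`,
#'   `verdict` (`"pass"`/`"flag"`).
#' @export
cmd_qa <- function(config, plan_features, actual_ratio, models = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  organs <- plan_features$organ
  if (is.null(models)) {
    models <- lapply(organs, function(o) {
      path <- file.path(config$out_dir, paste0("model_", o, ".json"))
      if (!file.exists(path)) stop("missing model for organ '", o, "': ", path)
      read_model(path)
    })
    names(models) <- organs
  }
  thr <- config$delta_threshold
  if (length(thr) == 1L && is.null(names(thr)))
    thr <- stats::setNames(rep(thr, length(organs)), organs)
  out <- lapply(organs, function(o) {
    row <- plan_features[plan_features$organ == o, , drop = FALSE]
    X <- as.matrix(row[, c("V_global_cm3", paste0("v", 1:5, "_cm3"))])
    colnames(X) <- feature_names(o)
    pred <- predict(models[[o]], X)
    act <- actual_ratio[[o]]
    dlt <- abs(act - pred)
    data.frame(organ = o, predicted_ratio = pred, actual_ratio = act,
               delta = dlt, threshold = thr[[o]],
               verdict = if (dlt > thr[[o]]) "flag" else "pass")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
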