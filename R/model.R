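# Per-organ epsilon-SVR with RBF kernel: grid-searched (C, gamma) by k-fold
# cross-validation on the training split, prediction of D2cm3/Dprescription
# ratios, and the evaluation report (MSE, R^2, delta, Pearson r, paired t).
#
# The quadratic program itself is solved by libsvm (via e1071); grid search,
# standardization, serialization and all statistics are implemented here.

#' SVR configuration
#'
#' @param C_grid Positive reals: candidate soft-margin cost values.
#' @param gamma_grid Positive reals: candidate RBF shape parameters.
#' @param epsilon Width of the epsilon-insensitive tube, on the
#'   dimensionless ratio scale (default 0.01, about 0.07 Gy at a 7 Gy
#'   prescription).
#' @param cv_folds Number of cross-validation folds for the grid search.
#' @param standardize Z-score features before kernel evaluation?  The RBF
#'   kernel mixes feature scales, so this defaults to `TRUE`.
#' @param tolerance Termination tolerance passed to the underlying solver.
#' @param seed Integer seed for the fold assignment (optional).
#' @return Object of class `svr_config`.
#' @export
svr_config <- function(C_grid = c(0.1, 1, 10, 100, 1000),
                       gamma_grid = c(0.001, 0.01, 0.1, 1, 10),
                       epsilon = 0.01, cv_folds = 5L, standardize = TRUE,
                       tolerance = 0.001, seed = NULL) {
  if (length(C_grid) < 1L || any(C_grid <= 0))
    stop("'C_grid' must be non-empty and positive")
  if (length(gamma_grid) < 1L || any(gamma_grid <= 0))
    stop("'gamma_grid' must be non-empty and positive")
  if (epsilon < 0) stop("'epsilon' must be >= 0")
  cv_folds <- as.integer(cv_folds)
  if (cv_folds < 2L) stop("'cv_folds' must be >= 2")
  structure(list(C_grid = sort(C_grid), gamma_grid = sort(gamma_grid),
                 epsilon = epsilon, cv_folds = cv_folds,
                 standardize = isTRUE(standardize), tolerance = tolerance,
                 seed = seed),
            class = "svr_config")
}

#' Radial basis function kernel
#'
#' `K(x, y) = exp(-gamma * ||x - y||^2)`; symmetric, `K(x, x) = 1`, values in
#' `(0, 1]`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param gamma Positive shape parameter.
#' @return Kernel value.
#' @export
rbf_kernel <- function(x, y, gamma) {
  if (length(x) != length(y)) stop("dimension mismatch")
  if (gamma <= 0) stop("'gamma' must be positive")
  exp(-gamma * sum((x - y)^2))
}

# Gram/cross-kernel matrix K[i, j] = exp(-gamma ||X[i,] - Y[j,]||^2).
rbf_cross <- function(X, Y, gamma) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Split a cohort into training and verification groups
#'
#' Random, disjoint, exhaustive split of plan identifiers, reproducible for
#' a fixed seed.
#'
#' @param plan_ids Vector of plan identifiers (or an integer cohort size).
#' @param n_train,n_valid Group sizes; must sum to the cohort size
#'   (defaults 160 / 40).
#' @param seed Integer seed.
#' @return List with `train` and `valid` id vectors.
#' @export
split_cohort <- function(plan_ids, n_train = 160L, n_valid = 40L, seed = 1L) {
  if (length(plan_ids) == 1L && is.numeric(plan_ids))
    plan_ids <- seq_len(plan_ids)
  n <- length(plan_ids)
  if (n != n_train + n_valid)
    stop("cohort size ", n, " != n_train + n_valid = ", n_train + n_valid)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = plan_ids[sort(idx)], valid = plan_ids[sort(setdiff(seq_len(n), idx))])
}

#' Train an epsilon-SVR model with grid-searched hyperparameters
#'
#' Selects `(C, gamma)` by `cv_folds`-fold cross-validation on the training
#' rows, minimizing CV mean squared error (ties broken toward smaller `C`,
#' then smaller `gamma`), then refits on all rows with the winner.  Constant
#' feature columns are dropped with a warning; a constant target yields a
#' degenerate model that predicts the constant.
#'
#' @param features Numeric matrix or data frame of predictors (>= 10 rows,
#'   no missing values).
#' @param targets Numeric response (D2cm3/Dprescription ratios).
#' @param cfg An [svr_config].
#' @param organ Optional organ label stored with the model.
#' @return Object of class `suboar_svr`.
#' @export
train_svr <- function(features, targets, cfg = svr_config(), organ = NA_character_) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as.numeric(targets)
  if (nrow(X) < 10L) stop("need at least 10 training rows")
  if (anyNA(X) || anyNA(y)) stop("missing values in features or targets")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))

  keep <- apply(X, 2L, function(col) stats::sd(col) > 0)
  if (!all(keep)) {
    warning("dropping constant feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }

  if (stats::sd(y) == 0 || ncol(X) == 0L) {
    return(structure(
      list(organ = organ, degenerate = TRUE, constant = mean(y),
           feature_names = colnames(X), dropped = names(keep)[!keep],
           epsilon = cfg$epsilon, training_mse = mse(y, rep(mean(y), length(y))),
           training_r2 = NA_real_),
      class = "suboar_svr"
    ))
  }

  center <- if (cfg$standardize) colMeans(X) else rep(0, ncol(X))
  scale_ <- if (cfg$standardize) apply(X, 2L, stats::sd) else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2L, center), 2L, scale_, `/`)

  n <- nrow(Xs)
  folds <- with_seed(cfg$seed, sample(rep(seq_len(cfg$cv_folds), length.out = n)))

  fit_one <- function(x, yy, C, gamma) {
    e1071::svm(x = x, y = yy, type = "eps-regression", kernel = "radial",
               cost = C, gamma = gamma, epsilon = cfg$epsilon,
               tolerance = cfg$tolerance, scale = FALSE)
  }

  best <- list(mse = Inf, C = NA_real_, gamma = NA_real_)
  cv_table <- NULL
  for (C in cfg$C_grid) {
    for (gamma in cfg$gamma_grid) {
      errs <- numeric(cfg$cv_folds)
      for (f in seq_len(cfg$cv_folds)) {
        tr <- folds != f
        fit <- fit_one(Xs[tr, , drop = FALSE], y[tr], C, gamma)
        pred <- as.numeric(stats::predict(fit, Xs[!tr, , drop = FALSE]))
        errs[f] <- mse(y[!tr], pred)
      }
      cv_mse <- mean(errs)
      cv_table <- rbind(cv_table,
                        data.frame(C = C, gamma = gamma, cv_mse = cv_mse))
      if (cv_mse < best$mse) best <- list(mse = cv_mse, C = C, gamma = gamma)
    }
  }

  fit <- fit_one(Xs, y, best$C, best$gamma)
  pred <- as.numeric(stats::predict(fit, Xs))

  structure(
    list(organ = organ, degenerate = FALSE,
         sv = unname(as.matrix(fit$SV)), coefs = as.numeric(fit$coefs),
         rho = as.numeric(fit$rho),
         C = best$C, gamma = best$gamma, epsilon = cfg$epsilon,
         cv_mse = best$mse, cv_table = cv_table,
         center = center, scale = scale_,
         feature_names = colnames(X), dropped = names(keep)[!keep],
         training_mse = mse(y, pred), training_r2 = r_squared(y, pred)),
    class = "suboar_svr"
  )
}

#' @export
print.suboar_svr <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<suboar_svr>", x$organ, "degenerate (constant", format(x$constant), ")\n")
    return(invisible(x))
  }
  cat(sprintf("<suboar_svr> %s: C = %g, gamma = %g, epsilon = %g, %d SVs\n",
              x$organ, x$C, x$gamma, x$epsilon, nrow(x$sv)))
  cat(sprintf("  training MSE %.5f, R^2 %.4f\n", x$training_mse, x$training_r2))
  invisible(x)
}

#' Predict D2cm3/Dprescription ratios
#'
#' Evaluates the fitted kernel expansion
#' `f(x) = sum_i alpha_i K(sv_i, x) - rho` on standardized features.
#' Multiplying the result by the prescription dose recovers the predicted
#' D2cm3 in Gy.
#'
#' @param object A `suboar_svr` model.
#' @param newdata Matrix/data frame of features (or a single feature vector).
#' @param ... Unused.
#' @return Numeric vector of predicted ratios.
#' @export
predict.suboar_svr <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(as.numeric(newdata), nrow = 1L)
       else as.matrix(newdata)
  if (isTRUE(object$degenerate))
    return(rep(object$constant, nrow(X)))
  if (!is.null(colnames(X)) && all(object$feature_names %in% colnames(X)))
    X <- X[, object$feature_names, drop = FALSE]
  if (ncol(X) != length(object$feature_names))
    stop("feature dimension mismatch: expected ",
         length(object$feature_names), ", got ", ncol(X))
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, `/`)
  K <- rbf_cross(Xs, object$sv, object$gamma)
  as.numeric(K %*% object$coefs - object$rho)
}

#' Evaluate a trained model on a verification set
#'
#' Assembles the full evaluation report: MSE, R-squared, per-plan delta with
#' mean and sd, Pearson correlation of each feature with the actual ratio,
#' and the two-sided paired t-test between predicted and actual ratios.
#'
#' @param model A `suboar_svr`.
#' @param features Verification-set feature matrix.
#' @param actual Actual D2cm3/Dprescription ratios.
#' @return Object of class `evaluation_report`.
#' @export
evaluate_model <- function(model, features, actual) {
  X <- as.matrix(features)
  if (nrow(X) < 1L) stop("empty verification set")
  predicted <- predict(model, X)
  dl <- delta_stat(actual, predicted)
  pearson <- lapply(seq_len(ncol(X)), function(j) {
    r <- tryCatch(pearson_r(X[, j], actual),
                  error = function(e) list(r = NA_real_, p = NA_real_))
    data.frame(feature = colnames(X)[j], r = r$r, p = r$p)
  })
  pearson <- do.call(rbind, pearson)
  pt <- paired_t_test(predicted, actual)
  structure(
    list(organ = model$organ,
         mse = mse(actual, predicted),
         r_squared = if (stats::sd(actual) > 0) r_squared(actual, predicted)
                     else NA_real_,
         delta = dl$delta, delta_mean = dl$mean, delta_sd = dl$sd,
         pearson = pearson, paired_t = pt,
         predicted = predicted, actual = actual),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s (n = %d)\n", x$organ, length(x$actual)))
  cat(sprintf("  MSE %.5f, R^2 %s, delta %.4f +/- %.4f\n", x$mse,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              x$delta_mean, x$delta_sd))
  cat(sprintf("  paired t = %.3f, p = %.3f (df = %d)\n",
              x$paired_t$t, x$paired_t$p, x$paired_t$df))
  invisible(x)
}

#' Serialize a trained model to JSON
#'
#' Stores support vectors, dual coefficients, bias, hyperparameters and
#' standardization constants; [read_model()] reconstructs a model whose
#' predictions are identical.
#'
#' @param model A `suboar_svr`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "suboar_svr"))
  payload <- unclass(model)
  payload$cv_table <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!isTRUE(obj$degenerate)) {
    sv <- obj$sv
    if (is.list(sv)) sv <- do.call(rbind, lapply(sv, as.numeric))
    obj$sv <- matrix(as.numeric(sv), ncol = length(obj$feature_names))
  }
  structure(obj, class = "suboar_svr")
}

# Run `expr` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
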