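#' Pair reservoir states with future target values
#'
#' Builds the supervised dataset for forecasting: predictor row `t` is the
#' reservoir state at time `t` and its target is the (rescaled) signal
#' value at time `t + shift`. The last `shift / dt` state rows have no
#' future target and are dropped.
#'
#' @param states A `reservoir_states` from [drive_reservoir()], or a plain
#'   numeric matrix of predictors (one row per time step).
#' @param target_series Numeric vector, one value per time step of the same
#'   series that drove the states (typically the rescaled target dimension).
#' @param shift Forecast horizon in time units; must be a non-negative
#'   multiple of `dt` (to within 1e-9).
#' @param dt Time step between rows.
#' @return A `shifted_dataset`: list with `predictors`, `targets`, `shift`,
#'   `shift_steps`, `dt`.
#' @export
make_shifted_dataset <- function(states, target_series, shift, dt) {
  x <- if (inherits(states, "reservoir_states")) states$states else
    as.matrix(states)
  n <- nrow(x)
  if (length(target_series) != n)
    stop("`target_series` must have one value per state row", call. = FALSE)
  if (shift < 0) stop("`shift` must be >= 0", call. = FALSE)
  k <- shift / dt
  if (abs(k - round(k)) > 1e-9)
    stop(sprintf("`shift` (%g) must be a multiple of `dt` (%g)", shift, dt),
         call. = FALSE)
  k <- as.integer(round(k))
  if (k >= n)
    stop("empty dataset: shift_steps >= number of steps", call. = FALSE)
  idx <- seq_len(n - k)
  structure(list(predictors = x[idx, , drop = FALSE],
                 targets = target_series[idx + k],
                 shift = shift, shift_steps = k, dt = dt),
            class = "shifted_dataset")
}

# Sufficient statistics of (X, y) for ridge fitting on row subset `idx`.
ridge_stats <- function(x, y, idx = NULL) {
  if (!is.null(idx)) {
    x <- x[idx, , drop = FALSE]
    y <- y[idx]
  }
  list(sxx = crossprod(x), sxy = crossprod(x, y)[, 1],
       sx = colSums(x), sy = sum(y), n = nrow(x))
}

# Solve the ridge normal equations from sufficient statistics: predictors
# centered, weights penalised, intercept unpenalised.
ridge_solve <- function(st, alpha) {
  xbar <- st$sx / st$n
  ybar <- st$sy / st$n
  gram <- st$sxx - st$n * tcrossprod(xbar)
  g <- st$sxy - st$n * xbar * ybar
  w <- tryCatch(
    solve(gram + diag(alpha, length(g)), g),
    error = function(e) {
      warning(sprintf("ill-conditioned ridge system at alpha = %g; %s",
                      alpha, conditionMessage(e)), call. = FALSE)
      qr.solve(gram + diag(alpha, length(g)), g)
    })
  list(weights = as.numeric(w), intercept = ybar - sum(xbar * w))
}

stats_subtract <- function(a, b) {
  list(sxx = a$sxx - b$sxx, sxy = a$sxy - b$sxy, sx = a$sx - b$sx,
       sy = a$sy - b$sy, n = a$n - b$n)
}

#' Fit a ridge readout with cross-validated regularisation
#'
#' Selects the L2 penalty `alpha` by k-fold cross-validation on shuffled
#' training rows (shuffling affects fold membership only, never the
#' chronological train/test boundary, which is fixed upstream). For each
#' alpha the held-out R-squared is averaged over folds; the best alpha is
#' refitted on all training rows by the ridge normal equations with centered
#' predictors, penalised weights, and an unpenalised intercept. This is the
#' deterministic, fully specified counterpart of evidence-maximising
#' Bayesian ridge: same regularisation family, explicit penalty search.
#'
#' @param dataset A `shifted_dataset` (the training portion).
#' @param alpha_grid Positive penalties to search; default 11 log-spaced
#'   points over `1e-8 ... 1e2`.
#' @param n_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @return A `ridge_readout`: list with `weights`, `intercept`, `alpha`,
#'   and `tuning_record` (data frame of alpha and mean held-out R-squared).
#' @export
fit_ridge <- function(dataset, alpha_grid = 10^seq(-8, 2, length.out = 11),
                      n_folds = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "shifted_dataset"))
  x <- dataset$predictors
  y <- dataset$targets
  n <- nrow(x)
  if (n < 2L) stop("empty or degenerate dataset", call. = FALSE)
  if (length(alpha_grid) == 0 || any(alpha_grid <= 0))
    stop("`alpha_grid` must be non-empty and positive", call. = FALSE)

  if (length(alpha_grid) > 1L) {
    n_folds <- min(as.integer(n_folds), n)
    fold_of <- with_seed(seed,
                         sample(rep_len(seq_len(n_folds), n)))
    fold_idx <- split(seq_len(n), fold_of)
    # sufficient statistics per fold; their sum is the full-data Gram, so
    # each training complement is one subtraction and the refit is free.
    # Fold submatrices are materialised one at a time to keep the peak
    # footprint at ~1/n_folds of the predictor matrix.
    fold_stats <- lapply(fold_idx, function(ix) ridge_stats(x, y, ix))
    total <- Reduce(function(a, b)
      list(sxx = a$sxx + b$sxx, sxy = a$sxy + b$sxy, sx = a$sx + b$sx,
           sy = a$sy + b$sy, n = a$n + b$n), fold_stats)
    fold_r2 <- vapply(seq_along(fold_idx), function(k) {
      train_st <- stats_subtract(total, fold_stats[[k]])
      fits <- lapply(alpha_grid, function(a) ridge_solve(train_st, a))
      w_mat <- vapply(fits, `[[`, numeric(ncol(x)), "weights")
      b_vec <- vapply(fits, `[[`, numeric(1), "intercept")
      ix <- fold_idx[[k]]
      yhat <- sweep(x[ix, , drop = FALSE] %*% w_mat, 2L, b_vec, `+`)
      yv <- y[ix]
      ss_tot <- sum((yv - mean(yv))^2)
      1 - colSums((yv - yhat)^2) / ss_tot
    }, numeric(length(alpha_grid)))
    cv_score <- rowMeans(fold_r2)
    best <- alpha_grid[which.max(cv_score)]
    tuning <- data.frame(alpha = alpha_grid, cv_score = cv_score)
    fit <- ridge_solve(total, best)
  } else {
    best <- alpha_grid
    tuning <- data.frame(alpha = alpha_grid, cv_score = NA_real_)
    fit <- ridge_solve(ridge_stats(x, y), best)
  }
  structure(list(weights = fit$weights, intercept = fit$intercept,
                 alpha = best, tuning_record = tuning),
            class = "ridge_readout")
}

#' @exportS3Method print ridge_readout
print.ridge_readout <- function(x, ...) {
  cat(sprintf("Ridge readout: %d weights, alpha = %g, intercept = %.4g\n",
              length(x$weights), x$alpha, x$intercept))
  invisible(x)
}

#' Predict from a fitted ridge readout
#' @param object A `ridge_readout`.
#' @param newdata A `shifted_dataset` or predictor matrix.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.ridge_readout <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "shifted_dataset")) newdata$predictors else
    as.matrix(newdata)
  as.numeric(x %*% object$weights) + object$intercept
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares about the observed
#' mean. May be negative when predictions do worse than the mean.
#'
#' @param observed Numeric vector, not constant, length >= 2.
#' @param predicted Numeric vector of the same length.
#' @return The R-squared value (a fraction, not a percentage).
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stop("`observed` and `predicted` must have equal length >= 2",
         call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("undefined variance: `observed` is constant", call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Score a readout on the chronological train/test partitions
#'
#' Computes R-squared on both partitions with no refitting on test. A close
#' match between the two scores is the no-overfitting signature expected
#' from a properly regularised readout.
#'
#' @param readout A `ridge_readout`.
#' @param train,test `shifted_dataset`s; the test rows must be strictly
#'   later in time than the train rows (the caller's chronological split).
#' @param metadata Optional named list carried into the result (forcing,
#'   doubling time, reservoir size, seeds, ...).
#' @return A `prediction_scores`: list with `r2_train`, `r2_test`
#'   (fractions), `shift`, `metadata`.
#' @export
evaluate_readout <- function(readout, train, test, metadata = list()) {
  stopifnot(inherits(readout, "ridge_readout"),
            inherits(train, "shifted_dataset"),
            inherits(test, "shifted_dataset"))
  if (nrow(train$predictors) == 0L || nrow(test$predictors) == 0L)
    stop("empty partition", call. = FALSE)
  structure(list(
    r2_train = r_squared(train$targets, predict(readout, train)),
    r2_test = r_squared(test$targets, predict(readout, test)),
    shift = train$shift, metadata = metadata),
    class = "prediction_scores")
}

#' @exportS3Method print prediction_scores
print.prediction_scores <- function(x, ...) {
  cat(sprintf("shift = %g: R2_tr = %.1f%%, R2_ts = %.1f%%\n",
              x$shift, 100 * x$r2_train, 100 * x$r2_test))
  invisible(x)
}

#' Serialise a fitted readout to JSON
#' @param readout A `ridge_readout`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_readout_json <- function(readout, path) {
  jsonlite::write_json(
    list(weights = readout$weights, intercept = readout$intercept,
         alpha = readout$alpha, tuning_record = readout$tuning_record),
    path, digits = NA)
  invisible(path)
}
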