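#' Specification of one full pipeline run
#'
#' Collects everything a replicate needs: the chaotic environment (Lorenz-96
#' parameters, record length `T`, step `dt`, washout), the reservoir
#' hyperparameters, the forecast horizon `shift`, the chronological
#' train/test split fraction, and the three independent seed streams
#' (environment initial state, reservoir wiring, tuning shuffle). A run is
#' fully determined by its spec.
#'
#' @param forcing Lorenz-96 forcing `F`.
#' @param n_dims Lorenz-96 dimension count `N` (default 5).
#' @param duration Recorded length `T` in time units (default 20000).
#' @param dt Integration and sampling step (default 0.01).
#' @param washout Discarded transient before recording (default 100 time
#'   units).
#' @param size Reservoir size (number of internal units).
#' @param shift Forecast horizon in time units (default 1).
#' @param split_fraction Fraction of samples used for training (default
#'   0.7); the remainder, strictly later in time, is the test set.
#' @param env_seed,reservoir_seed,tuning_seed Integer seeds for the three
#'   random streams.
#' @param spectral_radius,connectivity,input_scaling,leak_rate Reservoir
#'   hyperparameters, see [reservoir_config()].
#' @param alpha_grid,n_folds Ridge tuning controls, see [fit_ridge()].
#' @param rescale_inputs If `TRUE`, the reservoir is driven by rescaled
#'   inputs (every dimension mapped to `[-1, 1]` over the training window)
#'   instead of the raw signal. Default `FALSE`: raw inputs drive the
#'   reservoir and only the prediction target is rescaled.
#' @return A `run_spec` list.
#' @export
run_spec <- function(forcing, n_dims = 5L, duration = 20000, dt = 0.01,
                     washout = 100, size, shift = 1.0, split_fraction = 0.7,
                     env_seed = 1L, reservoir_seed = 2L, tuning_seed = 3L,
                     spectral_radius = 0.99, connectivity = 0.1,
                     input_scaling = 0.1, leak_rate = 1.0,
                     alpha_grid = 10^seq(-8, 2, length.out = 11),
                     n_folds = 5L, rescale_inputs = FALSE) {
  params <- lorenz96_params(n_dims, forcing)
  steps <- duration / dt
  if (abs(steps - round(steps)) > 1e-6)
    stop("`duration` must be a multiple of `dt`", call. = FALSE)
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("`split_fraction` must be in (0, 1)", call. = FALSE)
  if (split_fraction * duration < 10 * shift ||
      (1 - split_fraction) * duration < 10 * shift)
    stop("both partitions must cover at least 10 forecast horizons",
         call. = FALSE)
  structure(list(params = params, duration = duration, dt = dt,
                 washout = washout, size = as.integer(size), shift = shift,
                 split_fraction = split_fraction,
                 seeds = list(env = as.integer(env_seed),
                              reservoir = as.integer(reservoir_seed),
                              tuning = as.integer(tuning_seed)),
                 reservoir = list(spectral_radius = spectral_radius,
                                  connectivity = connectivity,
                                  input_scaling = input_scaling,
                                  leak_rate = leak_rate),
                 alpha_grid = alpha_grid, n_folds = as.integer(n_folds),
                 rescale_inputs = rescale_inputs),
            class = "run_spec")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

# Shared engine: one environment + one driven reservoir, scored at one or
# more forecast horizons. Returns a list of prediction_scores, one per
# shift. Sharing the state record across shifts keeps shift-profile
# comparisons paired (identical environment and reservoir).
run_pipeline <- function(spec, shifts) {
  params <- spec$params
  steps <- round(spec$duration / spec$dt)
  split_at <- floor(spec$split_fraction * steps)

  traj <- with_stage("environment", {
    init <- random_initial_state(params, spec$seeds$env)
    lorenz96_simulate(params, init, spec$duration, spec$dt, spec$washout)
  })
  states <- with_stage("reservoir", {
    config <- reservoir_config(spec$size,
                               spectral_radius = spec$reservoir$spectral_radius,
                               connectivity = spec$reservoir$connectivity,
                               input_scaling = spec$reservoir$input_scaling,
                               leak_rate = spec$reservoir$leak_rate,
                               seed = spec$seeds$reservoir)
    system <- build_reservoir(config, params$n_dims)
    inputs <- traj$values
    if (isTRUE(spec$rescale_inputs)) {
      for (d in seq_len(ncol(inputs))) {
        m <- fit_rescale(traj, d, c(1L, split_at))
        inputs[, d] <- rescale_apply(m, inputs[, d])
      }
    }
    drive_reservoir(system, inputs)
  })
  target <- with_stage("rescale", {
    map <- fit_rescale(traj, 1L, c(1L, split_at))
    rescale_apply(map, traj$values[, 1L])
  })
  state_mat <- states$states
  rm(traj, states)

  # slice predictor windows straight off the state record (one copy each);
  # pairs whose predictor and target straddle the split boundary belong to
  # neither partition, so no training target lies in the test period
  window_dataset <- function(from, to, k, shift) {
    if (to - k < from)
      stop("empty dataset: shift_steps >= partition length", call. = FALSE)
    structure(list(
      predictors = state_mat[from:(to - k), , drop = FALSE],
      targets = target[(from + k):to],
      shift = shift, shift_steps = k, dt = spec$dt),
      class = "shifted_dataset")
  }
  env <- environment()
  lapply(shifts, function(shift) {
    with_stage("readout", {
      k <- as.integer(round(shift / spec$dt))
      if (abs(shift / spec$dt - k) > 1e-9)
        stop(sprintf("`shift` (%g) must be a multiple of `dt` (%g)",
                     shift, spec$dt), call. = FALSE)
      train <- window_dataset(1L, split_at, k, shift)
      test <- window_dataset(split_at + 1L, steps, k, shift)
      # the state record is only needed to build datasets; drop it before
      # the memory-heavy fit when no further horizon will use it
      if (length(shifts) == 1L) rm(state_mat, envir = env)
      readout <- fit_ridge(train, alpha_grid = spec$alpha_grid,
                           n_folds = spec$n_folds,
                           seed = spec$seeds$tuning)
      evaluate_readout(readout, train, test,
                       metadata = list(forcing = params$forcing,
                                       size = spec$size,
                                       seeds = spec$seeds))
    })
  })
}

#' Run one full replicate
#'
#' Executes environment simulation, reservoir drive, target rescaling,
#' chronological 70/30 split, ridge tuning and scoring, all determined by
#' the spec (including its seeds). Errors name the failing stage.
#'
#' @param spec A [run_spec()].
#' @return A `prediction_scores` (see [evaluate_readout()]).
#' @export
run_replicate <- function(spec) {
  stopifnot(inherits(spec, "run_spec"))
  run_pipeline(spec, spec$shift)[[1]]
}

#' Score one replicate at several forecast horizons
#'
#' Shares a single environment trajectory and driven reservoir across all
#' horizons, so horizon comparisons are exactly paired.
#'
#' @param spec A [run_spec()]; its `shift` field is ignored.
#' @param shifts Numeric vector of forecast horizons (time units).
#' @return A list of `prediction_scores`, one per horizon.
#' @export
run_shift_profile <- function(spec, shifts) {
  stopifnot(inherits(spec, "run_spec"))
  run_pipeline(spec, shifts)
}

#' Run independent replicates and summarise test R-squared
#'
#' Each replicate gets independent environment, reservoir, and tuning seeds
#' derived from `base_seed` by counter (see [derive_seed()]), so the set is
#' reproducible and order-independent. The summary reports the minimum,
#' median, and maximum of the test R-squared as percentages (the median of
#' an even count is the mean of the middle two).
#'
#' @param spec A [run_spec()]; its seed fields are overridden per replicate.
#' @param n Number of replicates.
#' @param base_seed Integer base seed for the counter-based derivation.
#' @param partial_path Optional CSV path; if a replicate fails, results
#'   completed so far are written there before the error propagates.
#' @return A `replicate_summary`: list with `minimum`, `median`, `maximum`
#'   (percent test R-squared), `n_replicates`, `r2_test_pct` (all values),
#'   `r2_train_pct`, and `spec`.
#' @export
run_replicates <- function(spec, n, base_seed = 1L, partial_path = NULL) {
  stopifnot(inherits(spec, "run_spec"), n >= 1)
  done <- list()
  for (r in seq_len(n)) {
    spec_r <- spec
    spec_r$seeds <- list(env = derive_seed(base_seed, r, 1L),
                         reservoir = derive_seed(base_seed, r, 2L),
                         tuning = derive_seed(base_seed, r, 3L))
    done[[r]] <- tryCatch(run_replicate(spec_r), error = function(e) {
      if (!is.null(partial_path) && length(done) > 0) {
        utils::write.csv(
          data.frame(replicate = seq_along(done),
                     r2_test_pct = vapply(done, function(s)
                       100 * s$r2_test, numeric(1))),
          partial_path, row.names = FALSE)
      }
      stop(sprintf("replicate %d failed: %s", r, conditionMessage(e)),
           call. = FALSE)
    })
  }
  ts <- vapply(done, function(s) 100 * s$r2_test, numeric(1))
  tr <- vapply(done, function(s) 100 * s$r2_train, numeric(1))
  structure(list(minimum = min(ts), median = stats::median(ts),
                 maximum = max(ts), n_replicates = as.integer(n),
                 r2_test_pct = ts, r2_train_pct = tr, spec = spec),
            class = "replicate_summary")
}

#' @exportS3Method print replicate_summary
print.replicate_summary <- function(x, ...) {
  cat(sprintf(
    "Test R-squared over %d replicates (size %d): (%.1f, %.1f, %.1f)%%\n",
    x$n_replicates, x$spec$size, x$minimum, x$median, x$maximum))
  invisible(x)
}

#' Sweep forcing, forecast horizon, and reservoir size
#'
#' Runs the full pipeline over the Cartesian product of the grids, with
#' `n_replicates` independent replicates per point and per-point seeds
#' derived from `base_seed`. The divergence doubling time is estimated once
#' per forcing. Within one (forcing, size, replicate) cell all horizons
#' share the same environment and reservoir.
#'
#' @param forcings,shifts,sizes Non-empty numeric grids.
#' @param duration,dt,split_fraction,washout Shared run settings, see
#'   [run_spec()].
#' @param n_replicates Replicates per grid point (default 1).
#' @param base_seed Integer base seed.
#' @param lyapunov_horizon Horizon for the doubling-time estimate (default
#'   2000 time units).
#' @param ... Further arguments passed to [run_spec()] (reservoir
#'   hyperparameters, tuning controls).
#' @return A `sweep_result`: data frame with columns `forcing`, `dbl`,
#'   `shift`, `size`, `replicate`, `r2_train_pct`, `r2_test_pct`.
#' @export
run_sweep <- function(forcings, shifts, sizes, duration = 20000, dt = 0.01,
                      split_fraction = 0.7, washout = 100, n_replicates = 1L,
                      base_seed = 1L, lyapunov_horizon = 2000, ...) {
  if (length(forcings) == 0 || length(shifts) == 0 || length(sizes) == 0)
    stop("all grids must be non-empty", call. = FALSE)
  dbl_of <- vapply(forcings, function(f) {
    estimate_max_lyapunov(lorenz96_params(forcing = f), dt = dt,
                          horizon = lyapunov_horizon,
                          seed = derive_seed(base_seed, 0L))$dbl
  }, numeric(1))
  rows <- list()
  point <- 0L
  for (fi in seq_along(forcings)) for (si in seq_along(sizes)) {
    point <- point + 1L
    for (r in seq_len(n_replicates)) {
      spec <- run_spec(forcing = forcings[fi], duration = duration, dt = dt,
                       washout = washout, size = sizes[si],
                       split_fraction = split_fraction,
                       env_seed = derive_seed(base_seed, point, r, 1L),
                       reservoir_seed = derive_seed(base_seed, point, r, 2L),
                       tuning_seed = derive_seed(base_seed, point, r, 3L),
                       ...)
      scores <- run_pipeline(spec, shifts)
      for (k in seq_along(shifts)) {
        rows[[length(rows) + 1L]] <- data.frame(
          forcing = forcings[fi], dbl = dbl_of[fi], shift = shifts[k],
          size = sizes[si], replicate = r,
          r2_train_pct = 100 * scores[[k]]$r2_train,
          r2_test_pct = 100 * scores[[k]]$r2_test)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "settings") <- c(
    list(forcings = forcings, shifts = shifts, sizes = sizes,
         duration = duration, dt = dt, split_fraction = split_fraction,
         washout = washout, n_replicates = n_replicates,
         base_seed = base_seed, lyapunov_horizon = lyapunov_horizon),
    list(...))
  class(out) <- c("sweep_result", class(out))
  out
}

#' Map a target doubling time to a forcing value
#'
#' Bisection on the Lyapunov estimator over a forcing range: finds `F` such
#' that the estimated doubling time equals `dbl_target`. Useful for placing
#' sweep points on a doubling-time axis, since predictability is the
#' quantity of interest, not the forcing itself.
#'
#' @param dbl_target Target doubling time (time units).
#' @param range Forcing search interval (default `c(8, 12)`, where the
#'   doubling time decreases with forcing).
#' @param seed,horizon Estimator settings, see [estimate_max_lyapunov()].
#' @param tol Convergence tolerance on the forcing (default 0.01).
#' @return The forcing value.
#' @export
forcing_for_doubling_time <- function(dbl_target, range = c(8, 12), seed = 1L,
                                      horizon = 1000, tol = 0.01) {
  f <- function(forc) {
    est <- estimate_max_lyapunov(lorenz96_params(forcing = forc),
                                 horizon = horizon, seed = seed)
    # dbl decreases with forcing over the searched range
    est$dbl - dbl_target
  }
  stats::uniroot(f, interval = range, tol = tol)$root
}

#' Write sweep results or replicate summaries to CSV
#'
#' Sweep results use the fixed header
#' `forcing,dbl,shift,size,replicate,r2_train_pct,r2_test_pct`; replicate
#' summaries use `size,n,min,median,max`. Values are written at 6
#' significant digits. A JSON sidecar (`<path>.json`) records the run
#' settings and package version so a result file can be regenerated
#' exactly.
#'
#' @param result A `sweep_result` or `replicate_summary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(signif(x, 6), format = "g", digits = 6) else x
  }
  if (inherits(result, "replicate_summary")) {
    df <- data.frame(size = result$spec$size, n = result$n_replicates,
                     min = result$minimum, median = result$median,
                     max = result$maximum)
    sidecar <- list(kind = "replicate_summary",
                    spec = spec_to_list(result$spec),
                    n_replicates = result$n_replicates)
  } else if (inherits(result, "sweep_result")) {
    df <- as.data.frame(result)
    df <- df[, c("forcing", "dbl", "shift", "size", "replicate",
                 "r2_train_pct", "r2_test_pct")]
    sidecar <- list(kind = "sweep_result",
                    settings = attr(result, "settings"))
  } else stop("unsupported result type", call. = FALSE)
  df[] <- lapply(df, fmt)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar$package_version <-
    as.character(utils::packageVersion("chaosesn"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

spec_to_list <- function(spec) {
  list(forcing = spec$params$forcing, n_dims = spec$params$n_dims,
       duration = spec$duration, dt = spec$dt, washout = spec$washout,
       size = spec$size, shift = spec$shift,
       split_fraction = spec$split_fraction, reservoir = spec$reservoir,
       alpha_grid = spec$alpha_grid, n_folds = spec$n_folds,
       rescale_inputs = spec$rescale_inputs)
}

#' Read back a results CSV written by [write_results()]
#' @param path CSV path.
#' @return A data frame.
#' @export
read_results <- function(path) utils::read.csv(path)
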