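#' Lorenz-96 parameter set
#'
#' Bundles the two parameters of the cyclic Lorenz-96 system: the number of
#' state dimensions `N` and the constant forcing `F`. The system is
#' `dx_i/dt = (x_{i+1} - x_{i-2}) x_{i-1} - x_i + F` with cyclic indices, a
#' standard testbed for chaotic dynamics; it becomes increasingly chaotic as
#' the forcing rises above 8.
#'
#' @param n_dims Positive integer, number of state dimensions. Must be at
#'   least 4 so the `i - 2` coupling is meaningful. Default 5.
#' @param forcing Finite numeric, the constant forcing term. Default 8.
#' @return An object of class `lorenz96_params`.
#' @examples
#' lorenz96_params(n_dims = 5, forcing = 8.75)
#' @export
lorenz96_params <- function(n_dims = 5L, forcing = 8) {
  n_dims <- as.integer(n_dims)
  if (length(n_dims) != 1L || is.na(n_dims) || n_dims < 4L)
    stop("`n_dims` must be a single integer >= 4", call. = FALSE)
  if (length(forcing) != 1L || !is.finite(forcing))
    stop("`forcing` must be a single finite number", call. = FALSE)
  structure(list(n_dims = n_dims, forcing = as.numeric(forcing)),
            class = "lorenz96_params")
}

#' @exportS3Method print lorenz96_params
print.lorenz96_params <- function(x, ...) {
  cat(sprintf("Lorenz-96 parameters: N = %d, F = %g\n", x$n_dims, x$forcing))
  invisible(x)
}

#' Lorenz-96 time derivative
#'
#' Evaluates the right-hand side of the Lorenz-96 equations at one state.
#' Purely functional; the cyclic boundary uses `x_{0} = x_{N}`,
#' `x_{-1} = x_{N-1}` and `x_{N+1} = x_1`.
#'
#' @param state Numeric vector of length `params$n_dims`, all finite.
#' @param params A [lorenz96_params()] object.
#' @return Numeric vector of derivatives, same length as `state`.
#' @examples
#' p <- lorenz96_params(5, 8)
#' lorenz96_derivative(rep(8, 5), p)  # the all-F equilibrium: zero vector
#' @export
lorenz96_derivative <- function(state, params) {
  stopifnot(inherits(params, "lorenz96_params"))
  if (length(state) != params$n_dims)
    stop(sprintf("`state` has length %d but params$n_dims is %d",
                 length(state), params$n_dims), call. = FALSE)
  if (!all(is.finite(state)))
    stop("`state` must be finite", call. = FALSE)
  lorenz96_deriv_cpp(as.numeric(state), params$forcing)
}

#' Simulate a Lorenz-96 trajectory
#'
#' Integrates the Lorenz-96 system with fixed-step classical 4th-order
#' Runge-Kutta at step `dt` and stores the state after every step. An
#' optional washout segment is integrated first and discarded, so the
#' recorded samples sit on the attractor; the initial state is never part of
#' the record (sample `s` is the state at time `t0 + washout + s * dt`).
#'
#' @param params A [lorenz96_params()] object.
#' @param initial_state Numeric vector of length `params$n_dims`.
#' @param duration Positive length of the recorded trajectory, in time units.
#' @param dt Positive integration and sampling step (default 0.01 time
#'   units, the cadence at which the reservoir is driven downstream).
#' @param washout Non-negative transient, in time units, integrated and
#'   discarded before recording starts (default 0).
#' @param t0 Start time of the integration (before washout); metadata only.
#' @return An `env_trajectory`: list with `values` (steps x n_dims matrix),
#'   `dt`, `t0` (time of the first stored sample), and `params`.
#' @examples
#' p <- lorenz96_params(5, 8.75)
#' tr <- lorenz96_simulate(p, random_initial_state(p, 1), duration = 10)
#' dim(tr$values)
#' @export
lorenz96_simulate <- function(params, initial_state, duration, dt = 0.01,
                              washout = 0, t0 = 0) {
  stopifnot(inherits(params, "lorenz96_params"))
  if (length(initial_state) != params$n_dims || !all(is.finite(initial_state)))
    stop("`initial_state` must be a finite vector of length n_dims",
         call. = FALSE)
  if (!is.numeric(duration) || duration <= 0 || !is.numeric(dt) || dt <= 0)
    stop("`duration` and `dt` must be positive", call. = FALSE)
  n_store <- round(duration / dt)
  if (abs(n_store * dt - duration) > 1e-6 * dt)
    stop("`dt` must divide `duration` to within rounding", call. = FALSE)
  n_washout <- round(washout / dt)
  values <- lorenz96_rk4_cpp(as.numeric(initial_state), params$forcing,
                             dt, as.integer(n_store), as.integer(n_washout))
  structure(list(values = values, dt = dt, t0 = t0 + n_washout * dt,
                 params = params),
            class = "env_trajectory")
}

#' @exportS3Method print env_trajectory
print.env_trajectory <- function(x, ...) {
  cat(sprintf(
    "Lorenz-96 trajectory: %d samples x %d dims, dt = %g (duration %g)\n",
    nrow(x$values), ncol(x$values), x$dt, nrow(x$values) * x$dt))
  invisible(x)
}

#' Random initial state near the Lorenz-96 equilibrium
#'
#' Returns the equilibrium point `F * 1` perturbed by independent
#' Uniform(-0.5, 0.5) draws per dimension. This is the conventional way to
#' seed Lorenz-96 runs: the perturbed state lies in the attractor's basin,
#' and the chaotic flow forgets the particular perturbation after a short
#' transient.
#'
#' @param params A [lorenz96_params()] object.
#' @param seed Integer seed; identical seeds give identical states.
#' @return Numeric vector of length `params$n_dims`.
#' @export
random_initial_state <- function(params, seed) {
  stopifnot(inherits(params, "lorenz96_params"))
  with_seed(seed, params$forcing + stats::runif(params$n_dims, -0.5, 0.5))
}

#' Affine rescaling fitted on a training window
#'
#' Fits the affine map sending the minimum of one trajectory dimension over
#' a fitting window to -1 and the maximum to +1, the normalisation applied
#' to the prediction target before regression. Values outside the fitted
#' window may map outside `[-1, 1]`; that is intended, since the map is
#' fitted on the training period only.
#'
#' @param traj An `env_trajectory` (or any list with a `values` matrix).
#' @param dim Column index (1-based) of the dimension to rescale.
#' @param fit_interval Integer vector `c(first, last)`, 1-based inclusive
#'   sample range used for fitting.
#' @return A `rescale_map`: list with `center`, `half_range`, `fitted_on`.
#' @seealso [rescale_apply()], [rescale_invert()]
#' @export
fit_rescale <- function(traj, dim, fit_interval) {
  v <- traj$values
  if (dim < 1 || dim > ncol(v)) stop("`dim` out of range", call. = FALSE)
  i <- as.integer(fit_interval[1]); j <- as.integer(fit_interval[2])
  if (i < 1 || j > nrow(v) || j < i)
    stop("`fit_interval` must be a non-empty range within the trajectory",
         call. = FALSE)
  x <- v[i:j, dim]
  lo <- min(x); hi <- max(x)
  if (hi - lo <= 0)
    stop("degenerate range: signal is constant on the fitting interval",
         call. = FALSE)
  structure(list(center = (lo + hi) / 2, half_range = (hi - lo) / 2,
                 fitted_on = c(i, j)),
            class = "rescale_map")
}

#' Apply a fitted rescale map
#' @param map A `rescale_map` from [fit_rescale()].
#' @param x Numeric vector.
#' @return `(x - center) / half_range`.
#' @export
rescale_apply <- function(map, x) (x - map$center) / map$half_range

#' Invert a fitted rescale map
#' @param map A `rescale_map` from [fit_rescale()].
#' @param y Numeric vector on the rescaled axis.
#' @return Values on the original axis.
#' @export
rescale_invert <- function(map, y) y * map$half_range + map$center

#' Write / read a trajectory as CSV
#'
#' Plain-text round trip for trajectories: header `t,x1,...,xN`, one row per
#' sample, full double precision.
#'
#' @param traj An `env_trajectory`.
#' @param path File path.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns a list with `t` and `values` (the params
#'   are not stored in the CSV).
#' @export
write_trajectory_csv <- function(traj, path) {
  n <- nrow(traj$values)
  tt <- traj$t0 + seq_len(n) * traj$dt
  df <- data.frame(t = tt, traj$values)
  names(df) <- c("t", paste0("x", seq_len(ncol(traj$values))))
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  list(t = df[[1]], values = as.matrix(df[, -1, drop = FALSE]))
}
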