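#' Echo-state reservoir configuration
#'
#' Hyperparameters of the randomly structured recurrent network. The
#' reservoir is never trained: its recurrent weights are drawn once at
#' random and fixed, and only a linear readout of its states is fitted
#' downstream. Defaults are common echo-state choices and are all exposed
#' so a run can be matched to other implementations exactly.
#'
#' @param size Positive integer, number of internal units.
#' @param spectral_radius Positive scaling of the recurrent matrix: its
#'   largest eigenvalue magnitude after rescaling. Values just below 1 give
#'   long fading memory while keeping the echo-state property. Default 0.99.
#' @param connectivity Fraction in `(0, 1]` of non-zero recurrent entries.
#'   Default 0.1.
#' @param input_scaling Input weights are drawn
#'   Uniform(-`input_scaling`, `input_scaling`). Default 0.1.
#' @param leak_rate State-update mixing coefficient in `(0, 1]`; 1 (the
#'   default) is the plain tanh update with no leaky integration.
#' @param seed Integer seed for the random matrices.
#' @return A `reservoir_config` list.
#' @export
reservoir_config <- function(size, spectral_radius = 0.99, connectivity = 0.1,
                             input_scaling = 0.1, leak_rate = 1.0, seed = 1L) {
  size <- as.integer(size)
  if (size < 1L) stop("`size` must be >= 1", call. = FALSE)
  if (spectral_radius <= 0) stop("`spectral_radius` must be > 0", call. = FALSE)
  if (connectivity <= 0 || connectivity > 1)
    stop("`connectivity` must be in (0, 1]", call. = FALSE)
  if (leak_rate <= 0 || leak_rate > 1)
    stop("`leak_rate` must be in (0, 1]", call. = FALSE)
  if (input_scaling <= 0) stop("`input_scaling` must be > 0", call. = FALSE)
  structure(list(size = size, spectral_radius = spectral_radius,
                 connectivity = connectivity, input_scaling = input_scaling,
                 leak_rate = leak_rate, seed = as.integer(seed)),
            class = "reservoir_config")
}

#' Build a random reservoir
#'
#' Draws the fixed random matrices of the network. Recurrent weights
#' `w_rec` are Uniform(-1, 1) on a Bernoulli(`connectivity`) sparsity mask,
#' then rescaled so the measured spectral radius equals
#' `config$spectral_radius` exactly; input weights `w_in` are dense
#' Uniform(-`input_scaling`, `input_scaling`). Fully determined by
#' `config$seed`.
#'
#' @param config A [reservoir_config()].
#' @param n_inputs Number of input channels (the environment's dimensions).
#' @return A `reservoir_system`: list with `w_rec` (sparse `dgCMatrix`),
#'   `w_in` (dense matrix), and `config`.
#' @export
build_reservoir <- function(config, n_inputs) {
  stopifnot(inherits(config, "reservoir_config"))
  n_inputs <- as.integer(n_inputs)
  if (n_inputs < 1L) stop("`n_inputs` must be >= 1", call. = FALSE)
  sz <- config$size
  mats <- with_seed(config$seed, {
    mask <- stats::runif(sz * sz) < config$connectivity
    w <- numeric(sz * sz)
    w[mask] <- stats::runif(sum(mask), -1, 1)
    w_rec <- matrix(w, sz, sz)
    w_in <- matrix(stats::runif(sz * n_inputs, -config$input_scaling,
                                config$input_scaling), sz, n_inputs)
    list(w_rec = w_rec, w_in = w_in)
  })
  rho <- max(Mod(eigen(mats$w_rec, only.values = TRUE)$values))
  if (rho == 0)
    stop(paste("degenerate reservoir: recurrent matrix has zero spectral",
               "radius (all-zero or nilpotent draw); use a larger size or",
               "connectivity, or another seed"), call. = FALSE)
  w_rec <- Matrix::Matrix(mats$w_rec * (config$spectral_radius / rho),
                          sparse = TRUE)
  structure(list(w_rec = w_rec, w_in = mats$w_in, config = config),
            class = "reservoir_system")
}

#' @exportS3Method print reservoir_system
print.reservoir_system <- function(x, ...) {
  cat(sprintf(
    "Echo-state reservoir: size %d, %d inputs, rho = %g, %.1f%% dense\n",
    x$config$size, ncol(x$w_in), x$config$spectral_radius,
    100 * Matrix::nnzero(x$w_rec) / x$config$size^2))
  invisible(x)
}

#' Measured spectral radius of a reservoir's recurrent matrix
#' @param system A `reservoir_system`.
#' @return Largest eigenvalue magnitude of `w_rec`.
#' @export
spectral_radius <- function(system) {
  max(Mod(eigen(as.matrix(system$w_rec), only.values = TRUE)$values))
}

#' Drive a reservoir with an input sequence
#'
#' Runs the leaky-tanh echo-state update from the zero state:
#' `r(t+1) = (1 - a) r(t) + a tanh(W r(t) + Win u(t+1))`, one update per
#' input row. The state record is the "reservoir of perceptive
#' information": a nonlinear, fading-memory expansion of the input history
#' from which a linear readout can reconstruct (and forecast) the signal.
#'
#' @param system A `reservoir_system` from [build_reservoir()].
#' @param inputs Numeric matrix, steps x n_inputs, all finite.
#' @param initial_state Optional starting state `r(0)` (default zero).
#'   Under the echo-state property the states forget this choice after a
#'   transient, which is why no separate state washout is needed when the
#'   driving signal already starts on the attractor.
#' @return A `reservoir_states`: list with `states` (steps x size matrix,
#'   entries in `(-1, 1)` when `leak_rate = 1`) and `config`.
#' @export
drive_reservoir <- function(system, inputs, initial_state = NULL) {
  stopifnot(inherits(system, "reservoir_system"))
  inputs <- as.matrix(inputs)
  if (ncol(inputs) != ncol(system$w_in))
    stop(sprintf("inputs have %d columns but the reservoir expects %d",
                 ncol(inputs), ncol(system$w_in)), call. = FALSE)
  if (!all(is.finite(inputs)))
    stop("`inputs` must be finite", call. = FALSE)
  if (is.null(initial_state)) initial_state <- numeric(system$config$size)
  if (length(initial_state) != system$config$size)
    stop("`initial_state` must have one entry per reservoir unit",
         call. = FALSE)
  states <- drive_reservoir_cpp(system$w_rec, system$w_in, inputs,
                                system$config$leak_rate,
                                as.numeric(initial_state))
  structure(list(states = states, config = system$config),
            class = "reservoir_states")
}

#' Export / import reservoir matrices as plain text
#'
#' Writes the system to three text files under `dir` for exact-reproduction
#' audits: `w_in.csv` (dense), `w_rec.csv` (coordinate triplets
#' `row,col,value`), and `config.json`.
#'
#' @param system A `reservoir_system`.
#' @param dir Directory (created if missing).
#' @return `write_reservoir` returns `dir` invisibly; `read_reservoir`
#'   returns the reconstructed `reservoir_system`.
#' @export
write_reservoir <- function(system, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(format(as.data.frame(system$w_in), digits = 17),
                   file.path(dir, "w_in.csv"), row.names = FALSE,
                   quote = FALSE)
  trip <- Matrix::summary(system$w_rec)
  utils::write.csv(format(data.frame(row = trip$i, col = trip$j,
                                     value = trip$x), digits = 17,
                          trim = TRUE),
                   file.path(dir, "w_rec.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(unclass(system$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_reservoir
#' @export
read_reservoir <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  config <- do.call(reservoir_config, cfg)
  w_in <- as.matrix(utils::read.csv(file.path(dir, "w_in.csv")))
  dimnames(w_in) <- NULL
  trip <- utils::read.csv(file.path(dir, "w_rec.csv"))
  w_rec <- Matrix::sparseMatrix(i = trip$row, j = trip$col, x = trip$value,
                                dims = c(config$size, config$size))
  structure(list(w_rec = w_rec, w_in = w_in, config = config),
            class = "reservoir_system")
}
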