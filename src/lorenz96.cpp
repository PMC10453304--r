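#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Lorenz-96 right-hand side: dx_i/dt = (x_{i+1} - x_{i-2}) * x_{i-1} - x_i + F
// with cyclic indices. Written for small N (>= 4); no allocation in the loop.
static inline void l96_deriv(const double* x, double* dx, int n, double F) {
  for (int i = 0; i < n; ++i) {
    int ip1 = (i + 1) % n;
    int im1 = (i - 1 + n) % n;
    int im2 = (i - 2 + n) % n;
    dx[i] = (x[ip1] - x[im2]) * x[im1] - x[i] + F;
  }
}

// One classical RK4 step in place; k buffers supplied by the caller.
static inline void rk4_step(double* x, int n, double F, double dt,
                            double* k1, double* k2, double* k3, double* k4,
                            double* tmp) {
  l96_deriv(x, k1, n, F);
  for (int i = 0; i < n; ++i) tmp[i] = x[i] + 0.5 * dt * k1[i];
  l96_deriv(tmp, k2, n, F);
  for (int i = 0; i < n; ++i) tmp[i] = x[i] + 0.5 * dt * k2[i];
  l96_deriv(tmp, k3, n, F);
  for (int i = 0; i < n; ++i) tmp[i] = x[i] + dt * k3[i];
  l96_deriv(tmp, k4, n, F);
  for (int i = 0; i < n; ++i)
    x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// [[Rcpp::export]]
NumericVector lorenz96_deriv_cpp(NumericVector state, double forcing) {
  int n = state.size();
  NumericVector out(n);
  l96_deriv(REAL(state), REAL(out), n, forcing);
  return out;
}

// Integrate with fixed-step RK4. Performs `n_washout` unstored steps, then
// stores the state after each of `n_store` further steps (the initial state
// is never part of the record). Errors if any component goes non-finite.
// [[Rcpp::export]]
NumericMatrix lorenz96_rk4_cpp(NumericVector state0, double forcing,
                               double dt, int n_store, int n_washout) {
  int n = state0.size();
  std::vector<double> x(REAL(state0), REAL(state0) + n);
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);

  for (int s = 0; s < n_washout; ++s) {
    rk4_step(x.data(), n, forcing, dt, k1.data(), k2.data(), k3.data(),
             k4.data(), tmp.data());
  }
  NumericMatrix out(n_store, n);
  for (int s = 0; s < n_store; ++s) {
    rk4_step(x.data(), n, forcing, dt, k1.data(), k2.data(), k3.data(),
             k4.data(), tmp.data());
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(x[i]))
        stop("integration diverged (non-finite state) at stored step %d", s + 1);
      out(s, i) = x[i];
    }
  }
  return out;
}

// Benettin two-trajectory log-growth rates. Evolves a reference and a
// perturbed copy (initial separation d0 along `direction`, normalised here),
// renormalises the separation back to d0 every `renorm_steps` RK4 steps and
// records log(d/d0) for each interval. The caller averages the rates after
// discarding its chosen transient fraction.
// [[Rcpp::export]]
NumericVector benettin_cpp(NumericVector state0, double forcing, double dt,
                           int n_intervals, int renorm_steps, double d0,
                           NumericVector direction) {
  int n = state0.size();
  std::vector<double> x(REAL(state0), REAL(state0) + n);
  std::vector<double> y(n);
  double dirnorm = 0.0;
  for (int i = 0; i < n; ++i) dirnorm += direction[i] * direction[i];
  dirnorm = std::sqrt(dirnorm);
  if (dirnorm <= 0.0) stop("perturbation direction must be nonzero");
  for (int i = 0; i < n; ++i) y[i] = x[i] + d0 * direction[i] / dirnorm;

  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);
  NumericVector logs(n_intervals);
  for (int iv = 0; iv < n_intervals; ++iv) {
    for (int s = 0; s < renorm_steps; ++s) {
      rk4_step(x.data(), n, forcing, dt, k1.data(), k2.data(), k3.data(),
               k4.data(), tmp.data());
      rk4_step(y.data(), n, forcing, dt, k1.data(), k2.data(), k3.data(),
               k4.data(), tmp.data());
    }
    double d = 0.0;
    for (int i = 0; i < n; ++i) {
      double di = y[i] - x[i];
      d += di * di;
    }
    d = std::sqrt(d);
    if (!std::isfinite(d) || d == 0.0)
      stop("trajectory separation became degenerate during Lyapunov estimation");
    logs[iv] = std::log(d / d0);
    // pull the perturbed trajectory back to separation d0
    for (int i = 0; i < n; ++i) y[i] = x[i] + (y[i] - x[i]) * (d0 / d);
  }
  return logs;
}
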