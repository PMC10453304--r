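// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cmath>

// Leaky-tanh echo-state update driven by one input row per step:
//   r(t+1) = (1 - a) r(t) + a * tanh(W r(t) + Win u(t+1))
// starting from r(0) = 0. W is sparse (CSC), traversed by hand so the
// 10^6-step drive loop allocates nothing. Returns the steps x size record.
// [[Rcpp::export]]
arma::mat drive_reservoir_cpp(const arma::sp_mat& w_rec, const arma::mat& w_in,
                              const arma::mat& inputs, double leak_rate,
                              const arma::vec& r0) {
  const arma::uword steps = inputs.n_rows;
  const arma::uword size = w_rec.n_rows;
  const arma::uword n_in = w_in.n_cols;

  const double* wv = w_rec.values;
  const arma::uword* wri = w_rec.row_indices;
  const arma::uword* wcp = w_rec.col_ptrs;
  const double* win = w_in.memptr();   // column-major size x n_in
  const double* u = inputs.memptr();   // column-major steps x n_in

  arma::mat states(steps, size);
  std::vector<double> r(r0.begin(), r0.end()), z(size);
  for (arma::uword t = 0; t < steps; ++t) {
    // z = Win u(t)
    for (arma::uword i = 0; i < size; ++i) z[i] = 0.0;
    for (arma::uword j = 0; j < n_in; ++j) {
      const double uj = u[t + j * steps];
      const double* wj = win + j * size;
      for (arma::uword i = 0; i < size; ++i) z[i] += wj[i] * uj;
    }
    // z += W r  (CSC: accumulate column j of W scaled by r[j])
    for (arma::uword j = 0; j < size; ++j) {
      const double rj = r[j];
      if (rj != 0.0)
        for (arma::uword p = wcp[j]; p < wcp[j + 1]; ++p)
          z[wri[p]] += wv[p] * rj;
    }
    for (arma::uword i = 0; i < size; ++i) {
      r[i] = (1.0 - leak_rate) * r[i] + leak_rate * std::tanh(z[i]);
      states(t, i) = r[i];
    }
  }
  return states;
}
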