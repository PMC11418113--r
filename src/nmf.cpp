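#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Multiplicative-update NMF (Frobenius objective, Lee-Seung updates).
// V (m x n, nonnegative) ~ W (m x k) H (k x n).
// Stops when the relative improvement of the reconstruction error drops
// below `tol`, or after `max_iter` iterations.
// [[Rcpp::export(name = ".nmf_mu")]]
List nmf_mu(const arma::mat& V, arma::mat W, arma::mat H,
            const int max_iter, const double tol) {
  const double eps = 1e-12;
  double err_prev = arma::norm(V - W * H, "fro");
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // H update
    H %= (W.t() * V) / (W.t() * W * H + eps);
    // W update
    W %= (V * H.t()) / (W * H * H.t() + eps);
    double err = arma::norm(V - W * H, "fro");
    double rel = (err_prev - err) / std::max(err_prev, eps);
    err_prev = err;
    if (rel >= 0 && rel < tol) { converged = true; break; }
  }
  return List::create(_["W"] = W, _["H"] = H,
                      _["error"] = err_prev,
                      _["iterations"] = std::min(it, max_iter),
                      _["converged"] = converged);
}
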