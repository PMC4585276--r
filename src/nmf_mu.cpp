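// Multiplicative-update NNMF (Lee-Seung, squared Frobenius objective).
// The restart loop and RNG live in R; this routine is deterministic given
// (X, W0, H0). Convergence: every `check_every` iterations, stop when
// (err_prev - err) / err_init < tol, err = ||X - WH||_F (scikit-learn rule).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".nmf_mu_cpp")]]
Rcpp::List nmf_mu_cpp(const arma::mat& X, arma::mat W, arma::mat H,
                      int max_iter = 2000, double tol = 1e-6,
                      int check_every = 10) {
  const double eps = 1e-12;
  const double err_init = norm(X - W * H, "fro");
  double err_prev = err_init;
  double err = err_init;
  int it = 0;
  bool converged = false;

  while (it < max_iter) {
    H %= (W.t() * X) / ((W.t() * W) * H + eps);
    W %= (X * H.t()) / (W * (H * H.t()) + eps);
    ++it;
    if (it % check_every == 0 || it == max_iter) {
      err = norm(X - W * H, "fro");
      if ((err_prev - err) / err_init < tol) { converged = true; break; }
      err_prev = err;
    }
  }
  if (it == max_iter) err = norm(X - W * H, "fro");

  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("sse") = err * err,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
}
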