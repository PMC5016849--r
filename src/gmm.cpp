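// Hot loops of the mixture-model fit: per-component Gaussian log densities
// (E-step) and responsibility-weighted covariance accumulation (M-step).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// N x K matrix of log N(x_i; mu_k, Sigma_k). covs: list of DxD matrices
// ("full") or a K x D matrix of diagonals ("diagonal").
// [[Rcpp::export]]
arma::mat gmm_logdens_cpp(const arma::mat& x, const arma::mat& means,
                          SEXP covs, const std::string& mode) {
  const arma::uword N = x.n_rows, D = x.n_cols, K = means.n_rows;
  const double c0 = -0.5 * D * std::log(2.0 * M_PI);
  arma::mat out(N, K);
  if (mode == "full") {
    List cl(covs);
    for (arma::uword k = 0; k < K; ++k) {
      arma::mat S = as<arma::mat>(cl[k]);
      arma::mat R;
      if (!arma::chol(R, S)) {
        S.diag() += 1e-8 * arma::mean(S.diag());
        if (!arma::chol(R, S)) stop("covariance not positive definite");
      }
      arma::mat xc = x.each_row() - means.row(k);
      arma::mat z = arma::solve(arma::trimatl(R.t()), xc.t());
      out.col(k) = c0 - arma::accu(arma::log(R.diag())) -
        0.5 * arma::sum(z % z, 0).t();
    }
  } else {
    arma::mat V = as<arma::mat>(covs);  // K x D diagonals
    for (arma::uword k = 0; k < K; ++k) {
      arma::rowvec v = V.row(k);
      arma::mat xc = x.each_row() - means.row(k);
      xc.each_row() /= arma::sqrt(v);
      out.col(k) = c0 - 0.5 * arma::accu(arma::log(v)) -
        0.5 * arma::sum(xc % xc, 1);
    }
  }
  return out;
}

// Responsibility-weighted covariance matrices for the M-step.
// Returns a list of DxD matrices ("full") or a K x D matrix ("diagonal").
// [[Rcpp::export]]
SEXP gmm_mstep_covs_cpp(const arma::mat& x, const arma::mat& means,
                        const arma::mat& resp, const arma::vec& nk,
                        double ridge, const std::string& mode) {
  const arma::uword D = x.n_cols, K = means.n_rows;
  if (mode == "full") {
    List out(K);
    for (arma::uword k = 0; k < K; ++k) {
      arma::mat xc = x.each_row() - means.row(k);
      xc.each_col() %= arma::sqrt(resp.col(k));
      arma::mat S = (xc.t() * xc) / nk(k);
      S.diag() += ridge;
      out[k] = S;
    }
    return out;
  }
  arma::mat V(K, D);
  for (arma::uword k = 0; k < K; ++k) {
    arma::mat xc = x.each_row() - means.row(k);
    xc = xc % xc;
    xc.each_col() %= resp.col(k);
    V.row(k) = (arma::sum(xc, 0) / nk(k)) + ridge;
  }
  return wrap(V);
}
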