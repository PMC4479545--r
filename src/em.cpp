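// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// EM inner loop for Gaussian mixtures over the six covariance families.
// cov_type: 0 spherical, 1 diagonal, 2 full; `varying` switches between the
// equal (E..) and varying (V..) members of each pair. Responsibilities come
// in from the seeded k-means++ hard assignment; the caller applies the
// spurious-maximum guard afterwards.
// [[Rcpp::export]]
List em_loop_cpp(const arma::mat& X, const arma::mat& resp0, int cov_type,
                 bool varying, double tol, int max_iter, double floor_val) {
  const int n = X.n_rows, d = X.n_cols, K = resp0.n_cols;
  arma::mat resp = resp0;
  arma::vec weights(K, arma::fill::value(1.0 / K));
  arma::mat means(K, d, arma::fill::zeros);
  arma::vec lambda(K, arma::fill::ones);
  arma::mat V(K, d, arma::fill::ones);
  arma::cube S(d, d, K, arma::fill::zeros);
  const double log2pi = std::log(2.0 * M_PI);

  double loglik = -std::numeric_limits<double>::infinity();
  std::vector<double> trace;
  bool converged = false, singular = false;

  arma::mat ld(n, K);
  for (int iter = 0; iter < max_iter; ++iter) {
    // ---- M step
    arma::rowvec Nk = arma::sum(resp, 0);
    if (Nk.min() < 1e-10) { singular = true; break; }
    weights = Nk.t() / n;
    means = resp.t() * X;
    means.each_col() /= Nk.t();

    if (cov_type == 2) {
      arma::mat pooled(d, d, arma::fill::zeros);
      for (int k = 0; k < K; ++k) {
        arma::mat Xc = X.each_row() - means.row(k);
        arma::mat W = Xc.t() * (Xc.each_col() % resp.col(k));
        if (varying) S.slice(k) = W / Nk(k);
        else pooled += W;
      }
      if (!varying) {
        pooled /= n;
        for (int k = 0; k < K; ++k) S.slice(k) = pooled;
      }
      // eigenvalue floor where needed
      for (int k = 0; k < K; ++k) {
        arma::mat R;
        if (!arma::chol(R, S.slice(k))) {
          arma::vec ev; arma::mat evec;
          arma::eig_sym(ev, evec, S.slice(k));
          ev.transform([&](double v) {
            return v < floor_val ? floor_val : v; });
          S.slice(k) = evec * arma::diagmat(ev) * evec.t();
          if (!varying) { for (int j = 0; j < K; ++j) S.slice(j) = S.slice(k); break; }
        }
      }
    } else {
      arma::mat D(K, d);
      for (int k = 0; k < K; ++k) {
        arma::mat Xc = X.each_row() - means.row(k);
        arma::mat XX = Xc % Xc;
        D.row(k) = arma::sum(XX.each_col() % resp.col(k), 0);
      }
      if (cov_type == 1) {
        if (varying) V = D.each_col() / Nk.t();
        else V = arma::repmat(arma::sum(D, 0) / n, K, 1);
        V.transform([&](double v) { return v < floor_val ? floor_val : v; });
      } else {
        if (varying) lambda = arma::sum(D, 1) / (d * Nk.t());
        else lambda.fill(arma::accu(D) / (double)(d * n));
        lambda.transform([&](double v) {
          return v < floor_val ? floor_val : v; });
      }
    }

    // ---- E step
    for (int k = 0; k < K; ++k) {
      arma::mat Xc = X.each_row() - means.row(k);
      arma::vec quad(n);
      double logdet;
      if (cov_type == 0) {
        quad = arma::sum(Xc % Xc, 1) / lambda(k);
        logdet = d * std::log(lambda(k));
      } else if (cov_type == 1) {
        arma::rowvec v = V.row(k);
        arma::mat XX = Xc % Xc;
        quad = arma::sum(XX.each_row() / v, 1);
        logdet = arma::accu(arma::log(v));
      } else {
        arma::mat R;
        if (!arma::chol(R, S.slice(k))) { singular = true; break; }
        arma::mat Z = arma::solve(arma::trimatl(R.t()), Xc.t());
        quad = arma::sum(Z % Z, 0).t();
        logdet = 2.0 * arma::accu(arma::log(R.diag()));
      }
      ld.col(k) = std::log(weights(k)) -
        0.5 * (d * log2pi + logdet + quad);
    }
    if (singular) break;
    arma::vec m = arma::max(ld, 1);
    arma::vec lse = m + arma::log(arma::sum(arma::exp(ld.each_col() - m), 1));
    double new_loglik = arma::accu(lse);
    if (!std::isfinite(new_loglik)) { singular = true; break; }
    // a decrease means the covariance floor intervened (the update is no
    // longer an exact M step): report the fit as singular
    if (std::isfinite(loglik) && new_loglik < loglik - 1e-8) {
      singular = true; break;
    }
    resp = arma::exp(ld.each_col() - lse);
    trace.push_back(new_loglik);
    if (std::isfinite(loglik) && new_loglik - loglik < tol) {
      loglik = new_loglik;
      converged = true;
      break;
    }
    loglik = new_loglik;
  }

  return List::create(
    _["weights"] = weights, _["means"] = means,
    _["lambda"] = lambda, _["V"] = V, _["S"] = S,
    _["loglik"] = loglik, _["trace"] = trace,
    _["converged"] = converged, _["singular"] = singular,
    _["resp"] = resp);
}
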