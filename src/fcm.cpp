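#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Weighted fuzzy c-means inner loop.
//
// X : B x d data points (occupied histogram bins as (t1, t2) coordinates)
// w : B weights (bin counts); w = 1 reproduces plain per-datum FCM
// U : B x c initial memberships, rows summing to 1
// m : fuzzifier (> 1); the m == 2 path avoids pow()
//
// Each iteration performs the center update v_i = sum_k w_k u_ik^m x_k /
// sum_k w_k u_ik^m, then the membership update u_ik = 1 / sum_j
// (d_ik/d_jk)^(2/(m-1)), then evaluates J = sum_k w_k sum_i u_ik^m d_ik^2.
// Bins coinciding with a center (d^2 < 1e-12) take membership split equally
// over the coinciding centers. Stops when |J(t-1) - J(t)| <= eps.
// [[Rcpp::export]]
Rcpp::List fcm_core(const arma::mat& X, const arma::vec& w, arma::mat U,
                    double m, double eps, int max_iter) {
  const bool m2 = std::abs(m - 2.0) < 1e-12;
  const double expo = 1.0 / (m - 1.0);
  const arma::vec x2 = arma::sum(X % X, 1);

  arma::mat V;
  std::vector<double> trace;
  trace.reserve(max_iter);
  double Jprev = R_PosInf;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    arma::mat Um = m2 ? arma::mat(U % U) : arma::mat(arma::pow(U, m));
    Um.each_col() %= w;
    V = Um.t() * X;
    V.each_col() /= arma::sum(Um, 0).t();

    arma::mat D2 = -2.0 * (X * V.t());
    D2.each_col() += x2;
    D2.each_row() += arma::sum(V % V, 1).t();
    D2.transform([](double d) { return d < 0.0 ? 0.0 : d; });

    arma::mat inv = m2 ? arma::mat(1.0 / D2) : arma::mat(arma::pow(D2, -expo));
    U = inv.each_col() / arma::sum(inv, 1);
    // bins sitting exactly on a center: put all membership there
    arma::uvec zr = arma::find(arma::min(D2, 1) < 1e-12);
    for (arma::uword t = 0; t < zr.n_elem; ++t) {
      const arma::uword b = zr(t);
      arma::rowvec u(U.n_cols, arma::fill::zeros);
      arma::uvec z = arma::find(D2.row(b) < 1e-12);
      for (arma::uword s = 0; s < z.n_elem; ++s) u(z(s)) = 1.0 / z.n_elem;
      U.row(b) = u;
    }

    arma::mat Um2 = m2 ? arma::mat(U % U) : arma::mat(arma::pow(U, m));
    const double J = arma::accu(arma::sum(Um2 % D2, 1) % w);
    trace.push_back(J);
    if (std::abs(Jprev - J) <= eps) break;
    Jprev = J;
  }
  if (iter > max_iter) iter = max_iter;

  return Rcpp::List::create(Rcpp::Named("u") = U,
                            Rcpp::Named("centers") = V,
                            Rcpp::Named("objective_trace") = trace,
                            Rcpp::Named("iter") = iter);
}
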