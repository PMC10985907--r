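// Multiplicative-update NMF (Lee-Seung) with generalized Kullback-Leibler or
// Frobenius objective. One call runs a single factorization from the supplied
// initialization; multi-start logic lives in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS = 1e-12;

static double kl_div(const mat& V, const mat& WH) {
  // sum V*log(V/WH) - V + WH, with 0*log(0) = 0
  mat term = WH - V;
  uvec nz = find(V > 0);
  vec v = V.elem(nz);
  vec wh = WH.elem(nz);
  return accu(term) + accu(v % log(v / (wh + EPS)));
}

// [[Rcpp::export(name = ".nmf_mu_cpp")]]
Rcpp::List nmf_mu_cpp(const arma::mat& V, arma::mat E, arma::mat H,
                      const int max_iter, const double tol,
                      const std::string objective) {
  const bool kl = (objective == "kl");
  std::vector<double> trace;
  double obj_prev = datum::inf;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    if (kl) {
      mat WH = E * H;
      WH.transform([](double x) { return x > EPS ? x : EPS; });
      mat R = V / WH;
      H %= (E.t() * R);
      H.each_col() /= (sum(E, 0).t() + EPS);
      WH = E * H;
      WH.transform([](double x) { return x > EPS ? x : EPS; });
      R = V / WH;
      E %= (R * H.t());
      E.each_row() /= (sum(H, 1).t() + EPS);
    } else {
      H %= (E.t() * V) / (E.t() * E * H + EPS);
      E %= (V * H.t()) / (E * (H * H.t()) + EPS);
    }
    if (it % 10 == 0 || it == max_iter) {
      mat WH = E * H;
      double obj = kl ? kl_div(V, WH)
                      : 0.5 * accu(square(V - WH));
      trace.push_back(obj);
      double denom = std::abs(obj_prev) > EPS ? std::abs(obj_prev) : 1.0;
      if (std::isfinite(obj_prev) && (obj_prev - obj) / denom < tol) break;
      obj_prev = obj;
    }
  }
  mat WH = E * H;
  double obj = kl ? kl_div(V, WH) : 0.5 * accu(square(V - WH));
  return Rcpp::List::create(Rcpp::Named("E") = E, Rcpp::Named("H") = H,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("trace") = trace,
                            Rcpp::Named("iterations") = std::min(it, max_iter));
}
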