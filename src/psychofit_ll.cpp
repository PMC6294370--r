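#include <Rcpp.h>
#include <cmath>

// Binomial log-likelihood of a cumulative-Gaussian psychometric function
// with symmetric lapse, evaluated over the full (pse, sigma, lapse) grid.
// levels/n/k are the aggregated responses per stimulus level.

// [[Rcpp::export(name = ".psychofit_ll_cpp")]]
Rcpp::NumericVector psychofit_ll_cpp(Rcpp::NumericVector pse,
                                     Rcpp::NumericVector sigma,
                                     Rcpp::NumericVector lapse,
                                     Rcpp::NumericVector levels,
                                     Rcpp::NumericVector n,
                                     Rcpp::NumericVector k) {
  const int np = pse.size(), ns = sigma.size(), nl = lapse.size();
  const int nlev = levels.size();
  Rcpp::NumericVector ll(np * ns * nl);
  std::vector<double> phi(np * ns);
  const double eps = 1e-12;
  for (int i = 0; i < nlev; ++i) {
    for (int s = 0; s < ns; ++s) {
      const double inv = 1.0 / sigma[s];
      for (int p = 0; p < np; ++p) {
        double z = (levels[i] - pse[p]) * inv;
        double v = R::pnorm(z, 0.0, 1.0, 1, 0);
        if (v < eps) v = eps;
        if (v > 1.0 - eps) v = 1.0 - eps;
        phi[s * np + p] = v;
      }
    }
    for (int l = 0; l < nl; ++l) {
      const double lh = 0.5 * lapse[l], om = 1.0 - lapse[l];
      double* out = &ll[(size_t)l * np * ns];
      for (int j = 0; j < np * ns; ++j) {
        double pr = lh + om * phi[j];
        out[j] += k[i] * std::log(pr) + (n[i] - k[i]) * std::log1p(-pr);
      }
    }
  }
  ll.attr("dim") = Rcpp::IntegerVector::create(np, ns, nl);
  return ll;
}
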