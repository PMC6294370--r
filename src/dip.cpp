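#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Hartigan's dip statistic: the minimum over unimodal distribution
// functions G of sup_x |F_n(x) - G(x)|, computed by bisection on the band
// half-width d.  For a given d, feasibility is decided by scanning the
// greatest convex minorant of the upper band (left of the mode) and the
// least concave majorant of the lower band (right of the mode), plus an
// exact junction check at the candidate mode points (the optimal G may
// jump at its mode).

namespace {

struct Prep {
  std::vector<double> u;  // unique sorted values
  std::vector<double> a;  // ecdf at the value
  std::vector<double> b;  // ecdf just below the value
  int m;
  int n;
};

Prep prep(std::vector<double> x) {
  std::sort(x.begin(), x.end());
  Prep p;
  p.n = (int)x.size();
  size_t i = 0;
  while (i < x.size()) {
    size_t j = i;
    while (j < x.size() && x[j] == x[i]) ++j;
    p.u.push_back(x[i]);
    p.b.push_back((double)i / p.n);
    p.a.push_back((double)j / p.n);
    i = j;
  }
  p.m = (int)p.u.size();
  return p;
}

// minimal end value of a convex nondecreasing chain with lo <= v <= hi
// at positions xs (lower-bound propagation; validated against an LP oracle)
double amin_chain(const std::vector<double>& xs, const std::vector<double>& lo,
                  const std::vector<double>& hi) {
  int k = (int)xs.size();
  std::vector<double> LB(k);
  LB[0] = lo[0];
  for (int j = 1; j < k; ++j) {
    double best = std::max(lo[j], LB[j - 1]);
    for (int jp = 1; jp < j; ++jp) {
      for (int i = 0; i < jp; ++i) {
        double r = (xs[j] - xs[jp]) / (xs[jp] - xs[i]);
        double cand = LB[jp] + (LB[jp] - hi[i]) * r;
        if (cand > best) best = cand;
      }
    }
    LB[j] = best;
  }
  return LB[k - 1];
}

const double EPS = 1e-12;

bool feasible(const Prep& pp, double d) {
  int m = pp.m;
  if (m == 1) return true;
  std::vector<double> hi(m), lo(m);
  for (int j = 0; j < m; ++j) {
    hi[j] = pp.b[j] + d;
    lo[j] = pp.a[j] - d;
  }
  const std::vector<double>& u = pp.u;

  // K1: max k (0-based) with a convex chain on 0..k feasible
  std::vector<int> hull;
  hull.push_back(0);
  int K1 = 0;
  bool ok = true;
  for (int k = 1; k < m && ok; ++k) {
    if (hi[k - 1] < lo[k - 1] - EPS) break;  // interior gate empty
    while (hull.size() >= 2) {
      int p2 = hull[hull.size() - 1], p1 = hull[hull.size() - 2];
      if ((hi[k] - hi[p2]) * (u[p2] - u[p1]) <
          (hi[p2] - hi[p1]) * (u[k] - u[p2]))
        hull.pop_back();
      else
        break;
    }
    int p = hull.back();
    for (int j = p + 1; j < k && ok; ++j) {
      double chord = hi[p] + (hi[k] - hi[p]) * (u[j] - u[p]) / (u[k] - u[p]);
      if (chord < lo[j] - EPS) ok = false;
    }
    if (!ok) break;
    hull.push_back(k);
    K1 = k;
  }

  // K2: min k with a concave chain on k..m-1 feasible
  hull.clear();
  hull.push_back(m - 1);
  int K2 = m - 1;
  ok = true;
  for (int k = m - 2; k >= 0 && ok; --k) {
    if (hi[k + 1] < lo[k + 1] - EPS) break;
    while (hull.size() >= 2) {
      int p2 = hull[hull.size() - 1], p1 = hull[hull.size() - 2];
      if ((lo[p2] - lo[k]) * (u[p1] - u[p2]) <
          (lo[p1] - lo[p2]) * (u[p2] - u[k]))
        hull.pop_back();
      else
        break;
    }
    int p = hull.back();
    for (int j = k + 1; j < p && ok; ++j) {
      double chord = lo[k] + (lo[p] - lo[k]) * (u[j] - u[k]) / (u[p] - u[k]);
      if (chord > hi[j] + EPS) ok = false;
    }
    if (!ok) break;
    hull.push_back(k);
    K2 = k;
  }

  if (K2 > K1) return false;

  // junction: some mode point k must admit conv-end <= conc-start
  for (int k = K2; k <= K1; ++k) {
    std::vector<double> xs_v(u.begin(), u.begin() + k + 1);
    std::vector<double> lo_v(lo.begin(), lo.begin() + k + 1);
    std::vector<double> hi_v(hi.begin(), hi.begin() + k + 1);
    lo_v[k] = pp.b[k] - d;  // relaxed lower gate at the mode (jump allowed)
    double amin = amin_chain(xs_v, lo_v, hi_v);

    // concave side k..m-1, maximal start: reflect x -> -x (reversed), y -> -y
    int len = m - k;
    std::vector<double> xs_w(len), lo_w(len), hi_w(len);
    for (int j = 0; j < len; ++j) {
      int src = m - 1 - j;  // reversed
      xs_w[j] = -u[src];
      // reflected: lo' = -hi, hi' = -lo
      double hi_src = (src == k) ? pp.a[k] + d : hi[src];  // relaxed at mode
      lo_w[j] = -hi_src;
      hi_w[j] = -lo[src];
    }
    double bmax = -amin_chain(xs_w, lo_w, hi_w);
    if (amin <= bmax + EPS) return true;
  }
  return false;
}

double dip_one(const std::vector<double>& x, double tol) {
  Prep pp = prep(x);
  if (pp.m == 1) return 0.0;
  double lo = 0.0, hi = 0.25;
  if (feasible(pp, lo + 1e-12)) return 1.0 / (2.0 * pp.n);
  while (hi - lo > tol) {
    double mid = 0.5 * (lo + hi);
    if (feasible(pp, mid))
      hi = mid;
    else
      lo = mid;
  }
  return 0.5 * (lo + hi);
}

}  // namespace

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(Rcpp::NumericVector x, double tol = 1e-9) {
  std::vector<double> v = Rcpp::as<std::vector<double> >(x);
  return dip_one(v, tol);
}

// [[Rcpp::export(name = ".dip_null_cpp")]]
Rcpp::NumericVector dip_null_cpp(Rcpp::IntegerVector n, int n_replicates,
                                 double tol = 1e-9) {
  // Monte-Carlo null: dip of uniform(0,1) samples of size n, using R's RNG
  Rcpp::NumericVector out(n_replicates);
  int nn = n[0];
  for (int r = 0; r < n_replicates; ++r) {
    std::vector<double> x(nn);
    for (int i = 0; i < nn; ++i) x[i] = R::runif(0.0, 1.0);
    out[r] = dip_one(x, tol);
  }
  return out;
}
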