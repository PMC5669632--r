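// Analytic free-energy landscapes and the overdamped Brownian sampler.
// The landscape list is built and validated on the R side
// (analytic_landscape); here it is trusted.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

// cubic smoothstep and its derivative
inline double sstep(double t) { return t * t * (3.0 - 2.0 * t); }
inline double dsstep(double t) { return 6.0 * t * (1.0 - t); }

// symmetric C1 bump: 0 at u=0,1, exactly 1 at u=1/2, zero slope at all three
inline double bump(double u) {
  return (u <= 0.5) ? sstep(2.0 * u) : sstep(2.0 - 2.0 * u);
}
inline double dbump(double u) {
  return (u <= 0.5) ? 2.0 * dsstep(2.0 * u) : -2.0 * dsstep(2.0 - 2.0 * u);
}

struct Landscape {
  int family;   // 0 flat, 1 harmonic, 2 double_well, 3 permeation_map
  int dim;
  std::vector<double> k, center;          // harmonic
  double dw_center, dw_a, dw_h;           // double_well
  std::vector<double> wx, wy, depth, amp; // permeation_map
  double kt, kwall;
};

Landscape parse(const List& ls) {
  Landscape L;
  L.family = as<int>(ls["family_code"]);
  L.dim = as<int>(ls["dimension"]);
  if (L.family == 1) {
    L.k = as<std::vector<double> >(ls["k"]);
    L.center = as<std::vector<double> >(ls["center"]);
  } else if (L.family == 2) {
    L.dw_center = as<double>(ls["center"]);
    L.dw_a = as<double>(ls["half_separation"]);
    L.dw_h = as<double>(ls["barrier"]);
  } else if (L.family == 3) {
    L.wx = as<std::vector<double> >(ls["well_x"]);
    L.wy = as<std::vector<double> >(ls["well_y"]);
    L.depth = as<std::vector<double> >(ls["depths"]);
    L.amp = as<std::vector<double> >(ls["amplitudes"]);
    L.kt = as<double>(ls["k_transverse"]);
    L.kwall = as<double>(ls["k_wall"]);
  }
  return L;
}

// longitudinal valley profile, valley center line, and their x-derivatives
void pm_profile(const Landscape& L, double x, double& V, double& dV,
                double& c, double& dc) {
  const int n = (int)L.wx.size();
  if (x <= L.wx[0]) {
    double d = x - L.wx[0];
    V = L.depth[0] + 0.5 * L.kwall * d * d;
    dV = L.kwall * d;
    c = L.wy[0]; dc = 0.0;
    return;
  }
  if (x >= L.wx[n - 1]) {
    double d = x - L.wx[n - 1];
    V = L.depth[n - 1] + 0.5 * L.kwall * d * d;
    dV = L.kwall * d;
    c = L.wy[n - 1]; dc = 0.0;
    return;
  }
  int i = 0;
  while (i < n - 2 && x >= L.wx[i + 1]) ++i;
  double len = L.wx[i + 1] - L.wx[i];
  double u = (x - L.wx[i]) / len;
  double dd = L.depth[i + 1] - L.depth[i];
  double dy = L.wy[i + 1] - L.wy[i];
  V = L.depth[i] + dd * sstep(u) + L.amp[i] * bump(u);
  dV = (dd * dsstep(u) + L.amp[i] * dbump(u)) / len;
  c = L.wy[i] + dy * sstep(u);
  dc = dy * dsstep(u) / len;
}

double potential1(const Landscape& L, const double* z) {
  switch (L.family) {
  case 0: return 0.0;
  case 1: {
    double u = 0.0;
    for (int d = 0; d < L.dim; ++d) {
      double dz = z[d] - L.center[d];
      u += 0.5 * L.k[d] * dz * dz;
    }
    return u;
  }
  case 2: {
    double dz = z[0] - L.dw_center;
    double q = dz * dz - L.dw_a * L.dw_a;
    return L.dw_h * q * q / (L.dw_a * L.dw_a * L.dw_a * L.dw_a);
  }
  case 3: {
    double V, dV, c, dc;
    pm_profile(L, z[0], V, dV, c, dc);
    double dy = z[1] - c;
    return V + 0.5 * L.kt * dy * dy;
  }
  }
  return NA_REAL;
}

void gradient1(const Landscape& L, const double* z, double* g) {
  switch (L.family) {
  case 0:
    for (int d = 0; d < L.dim; ++d) g[d] = 0.0;
    break;
  case 1:
    for (int d = 0; d < L.dim; ++d) g[d] = L.k[d] * (z[d] - L.center[d]);
    break;
  case 2: {
    double dz = z[0] - L.dw_center;
    double a2 = L.dw_a * L.dw_a;
    g[0] = 4.0 * L.dw_h * dz * (dz * dz - a2) / (a2 * a2);
    break;
  }
  case 3: {
    double V, dV, c, dc;
    pm_profile(L, z[0], V, dV, c, dc);
    double dy = z[1] - c;
    g[0] = dV - L.kt * dy * dc;
    g[1] = L.kt * dy;
    break;
  }
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector ls_potential_cpp(List ls, NumericMatrix z) {
  Landscape L = parse(ls);
  const int n = z.nrow();
  NumericVector out(n);
  std::vector<double> p(L.dim);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < L.dim; ++d) p[d] = z(i, d);
    out[i] = potential1(L, p.data());
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix ls_gradient_cpp(List ls, NumericMatrix z) {
  Landscape L = parse(ls);
  const int n = z.nrow();
  NumericMatrix out(n, L.dim);
  std::vector<double> p(L.dim), g(L.dim);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < L.dim; ++d) p[d] = z(i, d);
    gradient1(L, p.data(), g.data());
    for (int d = 0; d < L.dim; ++d) out(i, d) = g[d];
  }
  return out;
}

// Overdamped Euler-Maruyama with reflecting boundaries. Draws from R's RNG
// stream so that set.seed() on the R side makes runs bit-reproducible.
// [[Rcpp::export]]
NumericMatrix bd_simulate_cpp(List ls, NumericVector bias_center,
                              NumericVector bias_k, double D, double kT,
                              double dt, int stride, int nsamples,
                              NumericVector z0, NumericVector lower,
                              NumericVector upper) {
  Landscape L = parse(ls);
  const int dim = L.dim;
  NumericMatrix out(nsamples, dim);
  std::vector<double> z(dim), g(dim);
  for (int d = 0; d < dim; ++d) z[d] = z0[d];
  const double mob = D / kT * dt;
  const double noise = std::sqrt(2.0 * D * dt);
  RNGScope scope;
  for (int s = 0; s < nsamples; ++s) {
    for (int t = 0; t < stride; ++t) {
      gradient1(L, z.data(), g.data());
      for (int d = 0; d < dim; ++d) {
        double force = g[d] + bias_k[d] * (z[d] - bias_center[d]);
        double znew = z[d] - mob * force + noise * norm_rand();
        // reflect into the closed domain
        for (int r = 0; r < 64; ++r) {
          if (znew < lower[d]) znew = 2.0 * lower[d] - znew;
          else if (znew > upper[d]) znew = 2.0 * upper[d] - znew;
          else break;
        }
        if (znew < lower[d]) znew = lower[d];
        if (znew > upper[d]) znew = upper[d];
        z[d] = znew;
      }
    }
    for (int d = 0; d < dim; ++d) out(s, d) = z[d];
  }
  return out;
}
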