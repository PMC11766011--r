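#include <Rcpp.h>
using namespace Rcpp;

// Surrogate energy terms for the coarse VSD model.
//
// Coulomb: E = C * qi * qj / (eps(r) * r), with eps(r) = eps_scale * r when
//   dielectric_mode == 0 (distance-proportional) or eps = eps_const when
//   dielectric_mode == 1.
// Lennard-Jones 12-6: E = 4 * lj_eps * ((sigma/r)^12 - (sigma/r)^6)
// Bonds (intra-helix virtual bonds and site tethers): E = k * (r - r0)^2
// Flat-bottom positional restraints: E = k * (d - r0)^2 for d > r0, else 0.
//
// Pair index vectors are 0-based.

static inline double pdist(const NumericMatrix &X, int i, int j) {
  double dx = X(i, 0) - X(j, 0);
  double dy = X(i, 1) - X(j, 1);
  double dz = X(i, 2) - X(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// [[Rcpp::export]]
NumericVector energy_terms_cpp(const NumericMatrix &X,
                               const IntegerVector &qq_i, const IntegerVector &qq_j,
                               const NumericVector &qprod,
                               double coulomb_const, int dielectric_mode,
                               double eps_param,
                               const IntegerVector &lj_i, const IntegerVector &lj_j,
                               double lj_sigma, double lj_eps,
                               const IntegerVector &b_i, const IntegerVector &b_j,
                               const NumericVector &b_len, const NumericVector &b_k,
                               const IntegerVector &fb_i, const NumericMatrix &fb_ref,
                               const NumericVector &fb_r, const NumericVector &fb_k) {
  const double RMIN = 1e-6;
  double e_coul = 0.0, e_lj = 0.0, e_bond = 0.0, e_restr = 0.0;

  for (int k = 0; k < qq_i.size(); ++k) {
    double r = pdist(X, qq_i[k], qq_j[k]);
    if (r < RMIN) r = RMIN;
    double eps = (dielectric_mode == 0) ? eps_param * r : eps_param;
    e_coul += coulomb_const * qprod[k] / (eps * r);
  }
  for (int k = 0; k < lj_i.size(); ++k) {
    double r = pdist(X, lj_i[k], lj_j[k]);
    if (r < RMIN) r = RMIN;
    double s6 = std::pow(lj_sigma / r, 6.0);
    e_lj += 4.0 * lj_eps * (s6 * s6 - s6);
  }
  for (int k = 0; k < b_i.size(); ++k) {
    double r = pdist(X, b_i[k], b_j[k]);
    double d = r - b_len[k];
    e_bond += b_k[k] * d * d;
  }
  for (int k = 0; k < fb_i.size(); ++k) {
    int i = fb_i[k];
    double dx = X(i, 0) - fb_ref(k, 0);
    double dy = X(i, 1) - fb_ref(k, 1);
    double dz = X(i, 2) - fb_ref(k, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d > fb_r[k]) {
      double over = d - fb_r[k];
      e_restr += fb_k[k] * over * over;
    }
  }
  return NumericVector::create(_["coulomb"] = e_coul, _["lj"] = e_lj,
                               _["backbone"] = e_bond, _["restraint"] = e_restr,
                               _["total"] = e_coul + e_lj + e_bond + e_restr);
}
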