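#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// First-order partial correlation r_xy.z with a clamped denominator:
// if 1 - r^2 underflows the partial is treated as 0.
static inline double partial_cor(double rxy, double rxz, double ryz) {
  double den = (1.0 - rxz * rxz) * (1.0 - ryz * ryz);
  if (den < 1e-12) return 0.0;
  return (rxy - rxz * ryz) / std::sqrt(den);
}

static inline double ratio_term(double partial, double direct) {
  if (direct == 0.0) return 0.0;
  return std::fabs(partial / direct);
}

// PCIT trio scan: for every ordered trio (x < y < z) compute the three
// first-order partial correlations and the information-theory tolerance
// eps = mean of |partial/direct|; an edge (a, b) is eliminated if for some
// third node c both |r_ab| <= |eps * r_ac| and |r_ab| <= |eps * r_bc|.
// [[Rcpp::export(name = ".pcit_flags_cpp")]]
LogicalMatrix pcit_flags_cpp(NumericMatrix r) {
  int n = r.nrow();
  LogicalMatrix sig(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      sig(i, j) = (i != j);
  if (n < 3) return sig;

  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      double rxy = r(x, y);
      for (int z = y + 1; z < n; ++z) {
        double rxz = r(x, z);
        double ryz = r(y, z);
        double p_xy = partial_cor(rxy, rxz, ryz);
        double p_xz = partial_cor(rxz, rxy, ryz);
        double p_yz = partial_cor(ryz, rxy, rxz);
        double eps = (ratio_term(p_xy, rxy) +
                      ratio_term(p_xz, rxz) +
                      ratio_term(p_yz, ryz)) / 3.0;
        // edge (x,y) against z
        if (std::fabs(rxy) <= std::fabs(eps * rxz) &&
            std::fabs(rxy) <= std::fabs(eps * ryz)) {
          sig(x, y) = sig(y, x) = false;
        }
        // edge (x,z) against y
        if (std::fabs(rxz) <= std::fabs(eps * rxy) &&
            std::fabs(rxz) <= std::fabs(eps * ryz)) {
          sig(x, z) = sig(z, x) = false;
        }
        // edge (y,z) against x
        if (std::fabs(ryz) <= std::fabs(eps * rxy) &&
            std::fabs(ryz) <= std::fabs(eps * rxz)) {
          sig(y, z) = sig(z, y) = false;
        }
      }
    }
  }
  return sig;
}
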