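#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Intermolecular RNA duplex minimum free energy.
//
// Dynamic program over (query position, reversed-target position): state
// (i, j) is the best energy of a duplex whose most 3' (query-side) pair is
// (i, j). Transitions add a nearest-neighbor stack (adjacent pair), a
// bulge (one strand gapped) or an internal loop (both gapped), with per-
// side gaps capped at max_loop. Intramolecular structure is forbidden by
// construction. The energy table indexes pair types AU,UA,CG,GC,GU,UG.

static inline int pair_type(int a, int b) {
  // bases: 0=A 1=C 2=G 3=U 4=N(unpairable)
  if (a == 0 && b == 3) return 0;  // AU
  if (a == 3 && b == 0) return 1;  // UA
  if (a == 1 && b == 2) return 2;  // CG
  if (a == 2 && b == 1) return 3;  // GC
  if (a == 2 && b == 3) return 4;  // GU
  if (a == 3 && b == 2) return 5;  // UG
  return -1;
}

// [[Rcpp::export(name = ".duplex_mfe_cpp")]]
List duplex_mfe_cpp(IntegerVector q, IntegerVector t_rev,
                    NumericMatrix stack, double bulge_open, double bulge_ext,
                    double iloop_open, double iloop_ext, double duplex_init,
                    int max_loop) {
  const int m = q.size(), n = t_rev.size();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix best(m, n);
  IntegerMatrix back_i(m, n), back_j(m, n);
  std::vector<int> ptype(m * n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) {
      best(i, j) = INF;
      back_i(i, j) = back_j(i, j) = -1;
      ptype[i * n + j] = pair_type(q[i], t_rev[j]);
    }

  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      int p = ptype[i * n + j];
      if (p < 0) continue;
      double b = duplex_init;  // open a new duplex with this pair
      int bi = -1, bj = -1;
      for (int g1 = 0; g1 <= max_loop; ++g1) {
        int ip = i - 1 - g1;
        if (ip < 0) break;
        for (int g2 = 0; g2 <= max_loop; ++g2) {
          int jp = j - 1 - g2;
          if (jp < 0) break;
          int pp = ptype[ip * n + jp];
          if (pp < 0 || !std::isfinite(best(ip, jp))) continue;
          double step;
          if (g1 == 0 && g2 == 0) step = stack(pp, p);
          else if (g1 == 0 || g2 == 0) step = bulge_open + bulge_ext * (g1 + g2);
          else step = iloop_open + iloop_ext * (g1 + g2);
          double cand = best(ip, jp) + step;
          if (cand < b) { b = cand; bi = ip; bj = jp; }
        }
      }
      best(i, j) = b;
      back_i(i, j) = bi;
      back_j(i, j) = bj;
    }
  }

  double mfe = 0.0;
  int ei = -1, ej = -1;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      if (std::isfinite(best(i, j)) && best(i, j) < mfe) {
        mfe = best(i, j);
        ei = i; ej = j;
      }

  if (ei < 0) {
    return List::create(_["mfe"] = 0.0,
                        _["pairs"] = IntegerMatrix(0, 2));
  }
  std::vector<std::pair<int, int>> trace;
  int ci = ei, cj = ej;
  while (ci >= 0) {
    trace.push_back({ci, cj});
    int ni = back_i(ci, cj), nj = back_j(ci, cj);
    ci = ni; cj = nj;
  }
  IntegerMatrix pairs(trace.size(), 2);
  for (size_t k = 0; k < trace.size(); ++k) {
    // reverse to ascending query position; map j back to original target idx
    auto pr = trace[trace.size() - 1 - k];
    pairs(k, 0) = pr.first;
    pairs(k, 1) = n - 1 - pr.second;
  }
  return List::create(_["mfe"] = mfe, _["pairs"] = pairs);
}
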