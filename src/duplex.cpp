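#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Intermolecular nearest-neighbor duplex folding.  Bases are coded A=0 C=1 G=2
// U=3.  Pair types: 0 AU, 1 UA, 2 CG, 3 GC, 4 GU, 5 UG (miRNA base first).
// The DP walks the miRNA 5'->3' and the target 3'->5'; consecutive pairs are
// scored by the stacking table, separated pairs (bulge/internal loops up to
// max_loop unpaired bases) by the loop penalty tables.

static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

static inline bool wobble_or_au(int pt) {
  return pt == 0 || pt == 1 || pt == 4 || pt == 5;
}

// [[Rcpp::export]]
List cpp_duplex_mfe(IntegerVector mir, IntegerVector tar, NumericMatrix stack_dG,
                    NumericVector bulge_dG, NumericVector internal_dG,
                    double init_dG, double au_end_dG, int max_loop) {
  int n = mir.size(), m = tar.size();
  std::vector<int> rev(m);
  for (int j = 0; j < m; ++j) rev[j] = tar[m - 1 - j];
  const double INF = 1e9;
  std::vector<double> best(n * m, INF);
  std::vector<int> np(n * m, 0), par(n * m, -1), pt(n * m, -1);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      int p = pair_type(mir[i], rev[j]);
      pt[i * m + j] = p;
      if (p < 0) continue;
      double open_end = wobble_or_au(p) ? au_end_dG : 0.0;
      best[i * m + j] = open_end;  // helix starts here
      np[i * m + j] = 1;
      for (int a = 0; a <= max_loop; ++a) {
        int pi = i - a - 1;
        if (pi < 0) break;
        for (int b = 0; b + a <= max_loop; ++b) {
          int pj = j - b - 1;
          if (pj < 0) break;
          int q = pt[pi * m + pj];
          if (q < 0 || best[pi * m + pj] >= INF / 2) continue;
          double step;
          if (a == 0 && b == 0) step = stack_dG(q, p);
          else if (a == 0 || b == 0) step = bulge_dG[a + b - 1];
          else step = internal_dG[a + b - 1];
          double v = best[pi * m + pj] + step;
          int cnt = np[pi * m + pj] + 1;
          double cur = best[i * m + j];
          if (v < cur - 1e-9 ||
              (std::abs(v - cur) <= 1e-9 && cnt > np[i * m + j])) {
            best[i * m + j] = v;
            np[i * m + j] = cnt;
            par[i * m + j] = pi * m + pj;
          }
        }
      }
    }
  double mfe = INF; int bi = -1, bnp = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      int idx = i * m + j;
      if (pt[idx] < 0 || best[idx] >= INF / 2) continue;
      double close_end = wobble_or_au(pt[idx]) ? au_end_dG : 0.0;
      double v = best[idx] + close_end + init_dG;
      if (v < mfe - 1e-9 || (std::abs(v - mfe) <= 1e-9 && np[idx] > bnp)) {
        mfe = v; bi = idx; bnp = np[idx];
      }
    }
  if (bi < 0 || mfe > 0) {
    return List::create(_["mfe"] = 0.0, _["mirna_pos"] = IntegerVector(0),
                        _["target_pos"] = IntegerVector(0));
  }
  std::vector<int> mp, tp;
  for (int idx = bi; idx >= 0; idx = par[idx]) {
    mp.push_back(idx / m);
    tp.push_back(m - 1 - (idx % m));  // back to original target coordinates
  }
  std::reverse(mp.begin(), mp.end());
  std::reverse(tp.begin(), tp.end());
  return List::create(_["mfe"] = mfe, _["mirna_pos"] = wrap(mp),
                      _["target_pos"] = wrap(tp));
}
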