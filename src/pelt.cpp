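#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Penalized least-squares optimal partitioning (PELT) for a piecewise-constant
// mean model. Missing values (NA) are bridged: they belong to the enclosing
// segment but contribute no error. Segments must contain at least `min_seg`
// non-missing observations.
//
// Cost of a segment over non-missing members: sum(y^2) - sum(y)^2 / m.
// F[t] = min_{tau} F[tau] + C(tau+1, t) + beta, F[0] = -beta.
//
// Pruning (safe for additive SSE cost) is enabled only for long series: the
// minimum-segment constraint can, in contrived ties, interact with pruning,
// so short series are solved by the unpruned exact recursion.

// [[Rcpp::export(name = ".peltSegment")]]
IntegerVector peltSegment(NumericVector y, double beta, int min_seg) {
  int n = y.size();
  std::vector<double> cs(n + 1, 0.0), css(n + 1, 0.0);
  std::vector<int> cnt(n + 1, 0);
  for (int i = 0; i < n; ++i) {
    double v = y[i];
    bool ok = !NumericVector::is_na(v);
    cs[i + 1] = cs[i] + (ok ? v : 0.0);
    css[i + 1] = css[i] + (ok ? v * v : 0.0);
    cnt[i + 1] = cnt[i] + (ok ? 1 : 0);
  }
  const double INF = R_PosInf;
  std::vector<double> F(n + 1, INF);
  std::vector<int> last(n + 1, 0);
  F[0] = -beta;
  std::vector<int> cand;
  cand.reserve(256);
  cand.push_back(0);
  bool prune = n > 512;

  for (int t = 1; t <= n; ++t) {
    double best = INF;
    int bestTau = 0;
    for (size_t k = 0; k < cand.size(); ++k) {
      int tau = cand[k];
      int m = cnt[t] - cnt[tau];
      if (m < min_seg) continue;
      double s = cs[t] - cs[tau];
      double ss = css[t] - css[tau];
      double c = ss - s * s / m;
      double val = F[tau] + c + beta;
      if (val < best) { best = val; bestTau = tau; }
    }
    F[t] = best;
    last[t] = bestTau;
    if (prune && R_finite(best)) {
      std::vector<int> keep;
      keep.reserve(cand.size() + 1);
      for (size_t k = 0; k < cand.size(); ++k) {
        int tau = cand[k];
        int m = cnt[t] - cnt[tau];
        if (m >= min_seg && t - tau >= 2 * min_seg) {
          double s = cs[t] - cs[tau];
          double ss = css[t] - css[tau];
          double c = ss - s * s / m;
          if (F[tau] + c > F[t]) continue;  // never optimal again
        }
        keep.push_back(tau);
      }
      keep.push_back(t);
      cand.swap(keep);
    } else {
      cand.push_back(t);
    }
  }

  if (!R_finite(F[n])) return IntegerVector(0);  // infeasible (too few values)
  std::vector<int> cps;
  int t = n;
  while (t > 0) {
    int tau = last[t];
    if (tau > 0) cps.push_back(tau);
    t = tau;
  }
  IntegerVector out(cps.size());
  for (size_t i = 0; i < cps.size(); ++i) out[i] = cps[cps.size() - 1 - i];
  return out;  // 1-based end indices of all segments but the last
}
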