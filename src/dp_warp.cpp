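#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dynamic-programming search for the optimal monotone, endpoint-fixed time
// warp between two square-root slope functions (SRSFs) on a common uniform
// grid. The lattice path from (0,0) to (n-1,n-1) is restricted to a set of
// coprime slope steps; the cost of a segment with slope m is the discretized
// elastic distance sum (q1[t] - sqrt(m) * q2(gamma(t)))^2, optionally plus a
// roughness penalty lambda * (sqrt(m) - 1)^2 per unit template time that
// biases ties toward the identity warp.

static inline double q_at(const NumericVector& q, double x) {
  int n = q.size();
  if (x <= 0) return q[0];
  if (x >= n - 1) return q[n - 1];
  int i = (int)std::floor(x);
  double f = x - i;
  return q[i] * (1.0 - f) + q[i + 1] * f;
}

// [[Rcpp::export(name = ".dp_warp")]]
NumericVector dp_warp(NumericVector q1, NumericVector q2, double lambda = 0.0,
                      int band = 0) {
  const int n = q1.size();
  if (q2.size() != n) stop("SRSF lengths differ");
  if (band <= 0) band = n;  // no band constraint
  // segment slopes are capped at 2 so a warped curve never undersamples
  // the source by more than a factor of two (bump peaks survive)
  const int di[] = {1, 1, 2, 2, 3, 3, 4};
  const int dj[] = {1, 2, 1, 3, 2, 4, 3};
  const int nm = 7;
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix D(n, n);
  IntegerMatrix from(n, n);
  std::fill(D.begin(), D.end(), INF);
  std::fill(from.begin(), from.end(), -1);
  D(0, 0) = 0.0;
  for (int i = 1; i < n; ++i) {
    int jlo = std::max(1, i - band), jhi = std::min(n - 1, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      double best = INF;
      int bestm = -1;
      for (int m = 0; m < nm; ++m) {
        int pi = i - di[m], pj = j - dj[m];
        if (pi < 0 || pj < 0) continue;
        if (!R_finite(D(pi, pj))) continue;
        double slope = (double)dj[m] / (double)di[m];
        double sm = std::sqrt(slope);
        double c = 0.0;
        for (int k = 1; k <= di[m]; ++k) {
          double d = q1[pi + k] - sm * q_at(q2, pj + slope * k);
          c += d * d;
        }
        c += lambda * di[m] * (sm - 1.0) * (sm - 1.0);
        double tot = D(pi, pj) + c;
        if (tot < best) { best = tot; bestm = m; }
      }
      D(i, j) = best;
      from(i, j) = bestm;
    }
  }
  // backtrack; knots of the optimal path
  std::vector<int> ki, kj;
  int i = n - 1, j = n - 1;
  ki.push_back(i); kj.push_back(j);
  while (i > 0 || j > 0) {
    int m = from(i, j);
    if (m < 0) stop("warp path backtrack failed");
    i -= di[m];
    j -= dj[m];
    ki.push_back(i); kj.push_back(j);
  }
  // linear interpolation of j over i between knots (reverse order)
  NumericVector gamma(n);
  int nk = ki.size();
  for (int k = nk - 1; k > 0; --k) {
    int i0 = ki[k], j0 = kj[k], i1 = ki[k - 1], j1 = kj[k - 1];
    for (int t = i0; t <= i1; ++t) {
      double f = (i1 == i0) ? 1.0 : (double)(t - i0) / (double)(i1 - i0);
      gamma[t] = j0 + f * (j1 - j0);
    }
  }
  gamma[0] = 0.0;
  gamma[n - 1] = n - 1;
  return gamma;
}
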