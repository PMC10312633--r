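// Core of the one-sample cluster-based sign-flip permutation test on
// channel x frequency grids. Cells are indexed frequency-fastest
// (channel-major); adjacency is 4-connectivity on the grid, with channel
// adjacency controlled per row pair (a dropped reference channel must not
// bridge its neighbours). The exhaustive null enumerates all 2^n sign
// patterns in Gray-code order so each permutation costs O(cells).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double tstat(double dot, double ssq, int n) {
  double m = dot / n;
  double v = (ssq - n * m * m) / (n - 1);
  if (v <= 0.0) return 0.0;
  return m / std::sqrt(v / n);
}

// max |sum of t| over sign-consistent connected clusters of supra-threshold
// cells; visit[] is a generation-stamped scratch array
static double maxClusterMass(const std::vector<double>& t, double thr,
                             int nch, int nfreq,
                             const std::vector<int>& row_adj,
                             std::vector<int>& visit, int& stamp,
                             std::vector<int>& stack) {
  const int P = nch * nfreq;
  ++stamp;
  double best = 0.0;
  for (int c0 = 0; c0 < P; ++c0) {
    if (visit[c0] == stamp || (t[c0] <= thr && t[c0] >= -thr)) continue;
    const int sgn = t[c0] > 0 ? 1 : -1;
    visit[c0] = stamp;
    stack.clear();
    stack.push_back(c0);
    double mass = 0.0;
    while (!stack.empty()) {
      const int u = stack.back();
      stack.pop_back();
      mass += t[u];
      const int ch = u / nfreq, f = u % nfreq;
      const int nb[4] = {f > 0 ? u - 1 : -1, f < nfreq - 1 ? u + 1 : -1,
                         (ch > 0 && row_adj[ch - 1]) ? u - nfreq : -1,
                         (ch < nch - 1 && row_adj[ch]) ? u + nfreq : -1};
      for (int k = 0; k < 4; ++k) {
        const int v = nb[k];
        if (v < 0 || visit[v] == stamp) continue;
        if ((sgn > 0 && t[v] > thr) || (sgn < 0 && t[v] < -thr)) {
          visit[v] = stamp;
          stack.push_back(v);
        }
      }
    }
    if (std::fabs(mass) > best) best = std::fabs(mass);
  }
  return best;
}

// label sign-consistent supra-threshold clusters, ids 1..K in scan order
// [[Rcpp::export]]
IntegerVector cluster_label_cpp(NumericVector tvec, int nch, int nfreq,
                                LogicalVector row_adj, double thr) {
  const int P = nch * nfreq;
  IntegerVector lab(P, 0);
  std::vector<int> adj(row_adj.begin(), row_adj.end());
  std::vector<int> stack;
  int next_id = 0;
  for (int c0 = 0; c0 < P; ++c0) {
    if (lab[c0] != 0 || (tvec[c0] <= thr && tvec[c0] >= -thr)) continue;
    const int sgn = tvec[c0] > 0 ? 1 : -1;
    ++next_id;
    lab[c0] = next_id;
    stack.clear();
    stack.push_back(c0);
    while (!stack.empty()) {
      const int u = stack.back();
      stack.pop_back();
      const int ch = u / nfreq, f = u % nfreq;
      const int nb[4] = {f > 0 ? u - 1 : -1, f < nfreq - 1 ? u + 1 : -1,
                         (ch > 0 && adj[ch - 1]) ? u - nfreq : -1,
                         (ch < nch - 1 && adj[ch]) ? u + nfreq : -1};
      for (int k = 0; k < 4; ++k) {
        const int v = nb[k];
        if (v < 0 || lab[v] != 0) continue;
        if ((sgn > 0 && tvec[v] > thr) || (sgn < 0 && tvec[v] < -thr)) {
          lab[v] = next_id;
          stack.push_back(v);
        }
      }
    }
  }
  return lab;
}

// null distribution of the max |cluster mass| under sign flips.
// xt: cells x flies matrix. exhaustive: Gray-code enumeration of all 2^n
// patterns (returned length 2^n, first entry = identity); otherwise n_perm
// random sign patterns drawn from R's RNG.
// [[Rcpp::export]]
NumericVector cluster_perm_null_cpp(NumericMatrix xt, int nch, int nfreq,
                                    LogicalVector row_adj, double thr,
                                    bool exhaustive, int n_perm) {
  const int P = xt.nrow(), n = xt.ncol();
  std::vector<int> adj(row_adj.begin(), row_adj.end());
  std::vector<double> ssq(P, 0.0), dot(P, 0.0), t(P);
  for (int j = 0; j < n; ++j) {
    const double* col = &xt(0, j);
    for (int p = 0; p < P; ++p) {
      ssq[p] += col[p] * col[p];
      dot[p] += col[p];
    }
  }
  std::vector<int> visit(P, 0), stack;
  int stamp = 0;

  if (exhaustive) {
    if (n > 30) stop("exhaustive enumeration limited to n <= 30 flies");
    const R_xlen_t N = (R_xlen_t)1 << n;
    NumericVector out(N);
    std::vector<int> sgn(n, 1);
    // |t| > thr  <=>  dot^2 > kap * ssq  (monotone algebraic equivalence),
    // so t is only evaluated for supra-threshold cells
    const double kap = thr * thr * n / (n - 1 + thr * thr);
    std::vector<double> cap(P);
    for (int p = 0; p < P; ++p) cap[p] = kap * ssq[p];
    std::vector<int> supra_stamp(P, -1), supra_idx;
    supra_idx.reserve(P);

    auto scanPerm = [&](R_xlen_t k) -> double {
      // cluster the supra cells collected for permutation k
      double best = 0.0;
      ++stamp;
      for (size_t ii = 0; ii < supra_idx.size(); ++ii) {
        const int c0 = supra_idx[ii];
        if (visit[c0] == stamp) continue;
        const int sgn0 = t[c0] > 0 ? 1 : -1;
        visit[c0] = stamp;
        stack.clear();
        stack.push_back(c0);
        double mass = 0.0;
        while (!stack.empty()) {
          const int u = stack.back();
          stack.pop_back();
          mass += t[u];
          const int ch = u / nfreq, f = u % nfreq;
          const int nb[4] = {f > 0 ? u - 1 : -1, f < nfreq - 1 ? u + 1 : -1,
                             (ch > 0 && adj[ch - 1]) ? u - nfreq : -1,
                             (ch < nch - 1 && adj[ch]) ? u + nfreq : -1};
          for (int q = 0; q < 4; ++q) {
            const int v = nb[q];
            if (v < 0 || visit[v] == stamp) continue;
            if (supra_stamp[v] == (int)k &&
                ((sgn0 > 0) == (t[v] > 0))) {
              visit[v] = stamp;
              stack.push_back(v);
            }
          }
        }
        if (std::fabs(mass) > best) best = std::fabs(mass);
      }
      return best;
    };

    supra_idx.clear();
    for (int p = 0; p < P; ++p) {
      if (dot[p] * dot[p] > cap[p]) {
        supra_stamp[p] = 0;
        t[p] = tstat(dot[p], ssq[p], n);
        supra_idx.push_back(p);
      }
    }
    out[0] = scanPerm(0);
    for (R_xlen_t k = 1; k < N; ++k) {
      int j = 0;
      while (!((k >> j) & 1)) ++j; // Gray code: flip the lowest set bit index
      const double coef = -2.0 * sgn[j];
      sgn[j] = -sgn[j];
      const double* col = &xt(0, j);
      supra_idx.clear();
      for (int p = 0; p < P; ++p) {
        const double d = dot[p] + coef * col[p];
        dot[p] = d;
        if (d * d > cap[p]) {
          supra_stamp[p] = (int)k;
          t[p] = tstat(d, ssq[p], n);
          supra_idx.push_back(p);
        }
      }
      out[k] = scanPerm(k);
    }
    return out;
  }

  NumericVector out(n_perm);
  std::vector<int> sgn(n);
  GetRNGstate();
  for (int k = 0; k < n_perm; ++k) {
    for (int j = 0; j < n; ++j) sgn[j] = unif_rand() < 0.5 ? -1 : 1;
    std::fill(dot.begin(), dot.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      const double* col = &xt(0, j);
      if (sgn[j] > 0) {
        for (int p = 0; p < P; ++p) dot[p] += col[p];
      } else {
        for (int p = 0; p < P; ++p) dot[p] -= col[p];
      }
    }
    for (int p = 0; p < P; ++p) t[p] = tstat(dot[p], ssq[p], n);
    out[k] = maxClusterMass(t, thr, nch, nfreq, adj, visit, stamp, stack);
  }
  PutRNGstate();
  return out;
}
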