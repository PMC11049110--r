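#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// wrap a phase difference into (-pi, pi]
static inline double wrap_diff(double x) {
  double w = x - 2.0 * M_PI * std::floor(x / (2.0 * M_PI) + 0.5);
  if (w <= -M_PI) w += 2.0 * M_PI;
  return w;
}

// Reliability-sorted (quality-guided) 2D phase unwrapping.
//
// Pixel reliability is the inverse of the second-difference noise measure
// (horizontal, vertical and both diagonals, each wrapped); edges between
// 4-neighbours carry the sum of their pixel reliabilities and are resolved
// in decreasing order of reliability, merging groups of already-unwrapped
// pixels with the integer 2*pi shift that makes the connecting edge
// continuous. Border pixels get the lowest reliability so they are merged
// last. On wrap-free input every shift is zero and the input is returned
// unchanged.
// [[Rcpp::export(name = ".unwrap2d")]]
NumericMatrix unwrap2d(NumericMatrix wrapped) {
  const int nr = wrapped.nrow(), nc = wrapped.ncol();
  const int n = nr * nc;
  const double *phi = wrapped.begin();

  std::vector<double> rel(n, 0.0);
  for (int j = 1; j < nc - 1; ++j) {
    for (int i = 1; i < nr - 1; ++i) {
      const int k = i + j * nr;
      const double c = phi[k];
      double H  = wrap_diff(phi[k - nr] - c) - wrap_diff(c - phi[k + nr]);
      double V  = wrap_diff(phi[k - 1]  - c) - wrap_diff(c - phi[k + 1]);
      double D1 = wrap_diff(phi[k - nr - 1] - c) - wrap_diff(c - phi[k + nr + 1]);
      double D2 = wrap_diff(phi[k - nr + 1] - c) - wrap_diff(c - phi[k + nr - 1]);
      double d = std::sqrt(H * H + V * V + D1 * D1 + D2 * D2);
      rel[k] = 1.0 / (d + 1e-12);
    }
  }

  // edges: vertical (i,i+1) then horizontal (k, k+nr)
  const int n_ed_v = (nr - 1) * nc, n_ed_h = nr * (nc - 1);
  const int n_ed = n_ed_v + n_ed_h;
  std::vector<int> ea(n_ed), eb(n_ed);
  std::vector<double> erel(n_ed);
  int e = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr - 1; ++i, ++e) {
      int k = i + j * nr;
      ea[e] = k; eb[e] = k + 1; erel[e] = rel[k] + rel[k + 1];
    }
  for (int j = 0; j < nc - 1; ++j)
    for (int i = 0; i < nr; ++i, ++e) {
      int k = i + j * nr;
      ea[e] = k; eb[e] = k + nr; erel[e] = rel[k] + rel[k + nr];
    }

  std::vector<int> order(n_ed);
  for (int t = 0; t < n_ed; ++t) order[t] = t;
  std::sort(order.begin(), order.end(),
            [&](int x, int y) { return erel[x] > erel[y]; });

  // group bookkeeping: each pixel belongs to a group holding a linked list
  std::vector<int> grp(n), nxt(n, -1), head(n), tail(n), gsize(n, 1);
  std::vector<long long> per(n, 0); // multiples of 2*pi added per pixel
  for (int k = 0; k < n; ++k) { grp[k] = k; head[k] = k; tail[k] = k; }

  for (int t = 0; t < n_ed; ++t) {
    const int id = order[t];
    int a = ea[id], b = eb[id];
    int ga = grp[a], gb = grp[b];
    if (ga == gb) continue;
    if (gsize[ga] < gsize[gb]) { std::swap(a, b); std::swap(ga, gb); }
    // shift group gb so that pixel b matches pixel a across the edge
    double target = (phi[a] + 2.0 * M_PI * (double)per[a]) -
                    (phi[b] + 2.0 * M_PI * (double)per[b]);
    long long s = (long long)std::llround(target / (2.0 * M_PI));
    for (int q = head[gb]; q != -1; q = nxt[q]) {
      per[q] += s;
      grp[q] = ga;
    }
    nxt[tail[ga]] = head[gb];
    tail[ga] = tail[gb];
    gsize[ga] += gsize[gb];
  }

  NumericMatrix out(nr, nc);
  for (int k = 0; k < n; ++k) out[k] = phi[k] + 2.0 * M_PI * (double)per[k];
  return out;
}
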