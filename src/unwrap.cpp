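// Reliability-sorting 2D phase unwrapping.
//
// Pixels are joined in decreasing order of edge reliability, where a pixel's
// reliability is the inverse of its second-difference quality measure; each
// join adds an integer multiple of 2*pi to one of the two groups so that the
// two neighbouring pixels differ by their wrapped gradient. The output is
// congruent to the input modulo 2*pi at every pixel.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double wrap_pm_pi(double x) {
  // x - 2*pi*floor((x + pi) / (2*pi)), the principal value in [-pi, pi)
  return x - 2.0 * M_PI * std::floor((x + M_PI) / (2.0 * M_PI));
}

struct Edge {
  double rel;
  int a, b;
};

// [[Rcpp::export]]
NumericMatrix unwrap2d_cpp(NumericMatrix w) {
  const int nr = w.nrow(), nc = w.ncol();
  const int N = nr * nc;
  const double TWO_PI = 2.0 * M_PI;

  std::vector<double> val(N);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) val[i + j * nr] = w(i, j);

  // reliability = 1 / second-difference quality; border pixels least reliable
  std::vector<double> rel(N);
  const double EPS = 1e-12;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int id = i + j * nr;
      if (i == 0 || i == nr - 1 || j == 0 || j == nc - 1) {
        rel[id] = EPS;
        continue;
      }
      const double c = val[id];
      const double H = wrap_pm_pi(val[id - nr] - c) - wrap_pm_pi(c - val[id + nr]);
      const double V = wrap_pm_pi(val[id - 1] - c) - wrap_pm_pi(c - val[id + 1]);
      const double D1 =
          wrap_pm_pi(val[id - nr - 1] - c) - wrap_pm_pi(c - val[id + nr + 1]);
      const double D2 =
          wrap_pm_pi(val[id - nr + 1] - c) - wrap_pm_pi(c - val[id + nr - 1]);
      const double D = std::sqrt(H * H + V * V + D1 * D1 + D2 * D2);
      rel[id] = 1.0 / (D + EPS);
    }
  }

  std::vector<Edge> edges;
  edges.reserve(2 * (size_t)N);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int id = i + j * nr;
      if (j + 1 < nc) edges.push_back({rel[id] + rel[id + nr], id, id + nr});
      if (i + 1 < nr) edges.push_back({rel[id] + rel[id + 1], id, id + 1});
    }
  }
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge& x, const Edge& y) { return x.rel > y.rel; });

  // group bookkeeping: member linked lists so the smaller group can be
  // shifted by 2*pi*k and relabelled on each merge
  std::vector<int> grp(N), head(N), tail(N), nxt(N, -1), gsize(N, 1);
  for (int i = 0; i < N; ++i) {
    grp[i] = head[i] = tail[i] = i;
  }

  for (const Edge& e : edges) {
    int ga = grp[e.a], gb = grp[e.b];
    if (ga == gb) continue;
    // keep 'ga' as the larger group; shift may flip direction
    int a = e.a, b = e.b;
    if (gsize[ga] < gsize[gb]) {
      std::swap(ga, gb);
      std::swap(a, b);
    }
    // desired unwrapped value of b: val[a] + wrapped gradient
    const double d = wrap_pm_pi(val[b] - val[a]);
    const double inc = (val[a] + d) - val[b];  // multiple of 2*pi up to fp error
    const double add = TWO_PI * std::round(inc / TWO_PI);
    if (add != 0.0)
      for (int p = head[gb]; p != -1; p = nxt[p]) val[p] += add;
    for (int p = head[gb]; p != -1; p = nxt[p]) grp[p] = ga;
    nxt[tail[ga]] = head[gb];
    tail[ga] = tail[gb];
    gsize[ga] += gsize[gb];
  }

  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = val[i + j * nr];
  return out;
}
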