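#include <Rcpp.h>
#include <vector>
#include <numeric>
#include <algorithm>
#include <queue>
using namespace Rcpp;

static inline int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Prominence-based local maxima selection (ImageJ "Find Maxima" dialect).
//
// Pixels are activated in order of decreasing intensity (ties broken by
// column-major scan order). Activated neighbouring pixels are merged with
// union-find; each component carries its peak pixel. When two components
// meet at level L, the component with the lower peak dies: its prominence is
// peak - L, and it is reported as a maximum iff prominence > tolerance.
// The last surviving component's peak has prominence peak - min(img).
//
// Within an equal-valued plateau the first-activated pixel becomes the peak;
// the R wrapper recentres accepted peaks on their plateau.
// [[Rcpp::export]]
DataFrame cpp_find_maxima(NumericMatrix img, double tolerance) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  const double* v = REAL(img);
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] > v[b];
    return a < b;
  });
  std::vector<int> parent(n, -1);
  std::vector<int> peak(n, -1);
  std::vector<int> acc_pix;
  std::vector<double> acc_prom;
  double vmin = v[ord[n - 1]];

  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  for (int k = 0; k < n; ++k) {
    int p = ord[k];
    int pr = p % nr, pc = p / nr;
    parent[p] = p;
    peak[p] = p;
    double L = v[p];
    for (int t = 0; t < 8; ++t) {
      int qr = pr + dr[t], qc = pc + dc[t];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      int q = qr + qc * nr;
      if (parent[q] < 0) continue;  // not yet activated
      int rq = find_root(parent, q);
      int rp = find_root(parent, p);
      if (rq == rp) continue;
      int pk_p = peak[rp], pk_q = peak[rq];
      // survivor: higher peak value; ties -> earlier scan order
      bool p_wins = (v[pk_p] > v[pk_q]) || (v[pk_p] == v[pk_q] && pk_p < pk_q);
      int surv = p_wins ? rp : rq;
      int lose = p_wins ? rq : rp;
      double prom = v[peak[lose]] - L;
      if (prom > tolerance) {
        acc_pix.push_back(peak[lose]);
        acc_prom.push_back(prom);
      }
      parent[lose] = surv;
      peak[surv] = p_wins ? pk_p : pk_q;
    }
  }
  // the single remaining root: the global maximum
  int r0 = find_root(parent, ord[0]);
  double prom0 = v[peak[r0]] - vmin;
  if (prom0 > tolerance) {
    acc_pix.push_back(peak[r0]);
    acc_prom.push_back(prom0);
  }
  int m = (int)acc_pix.size();
  IntegerVector row(m), col(m);
  NumericVector val(m), prominence(m);
  for (int i = 0; i < m; ++i) {
    row[i] = acc_pix[i] % nr + 1;
    col[i] = acc_pix[i] / nr + 1;
    val[i] = v[acc_pix[i]];
    prominence[i] = acc_prom[i];
  }
  return DataFrame::create(_["row"] = row, _["col"] = col,
                           _["value"] = val, _["prominence"] = prominence);
}

// Connected-component labeling of a binary mask; labels assigned in
// column-major discovery order starting at 1. connectivity: 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<int> q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(r + c * nr);
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int pr = p % nr, pc = p / nr;
        for (int t = 0; t < nnb; ++t) {
          int rr = pr + dr[t], cc = pc + dc[t];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (!mask(rr, cc) || lab(rr, cc) != 0) continue;
          lab(rr, cc) = next;
          q.push(rr + cc * nr);
        }
      }
    }
  }
  return lab;
}

// Exact 2D Gaussian KDE evaluated on a regular grid, kernel truncated at
// L grid steps (caller passes L ~ 4 bandwidths). Returns absolute density
// (sum of per-event kernels), events/nm^2 when coordinates are nm.
// [[Rcpp::export]]
NumericMatrix cpp_kde2d(NumericVector ex, NumericVector ey,
                        NumericVector gx, NumericVector gy,
                        double bw, int L) {
  const int nx = gx.size(), ny = gy.size(), n = ex.size();
  NumericMatrix mat(nx, ny);
  const double x0 = gx[0], y0 = gy[0];
  const double step = nx > 1 ? gx[1] - gx[0] : 1.0;
  const double norm = 1.0 / (2.0 * M_PI * bw * bw);
  std::vector<double> kx(2 * L + 1), ky(2 * L + 1);
  for (int e = 0; e < n; ++e) {
    int ci = (int)std::lround((ex[e] - x0) / step);
    int cj = (int)std::lround((ey[e] - y0) / step);
    int i1 = std::max(0, ci - L), i2 = std::min(nx - 1, ci + L);
    int j1 = std::max(0, cj - L), j2 = std::min(ny - 1, cj + L);
    if (i1 > i2 || j1 > j2) continue;
    for (int i = i1; i <= i2; ++i) {
      double dx = gx[i] - ex[e];
      kx[i - i1] = std::exp(-dx * dx / (2.0 * bw * bw));
    }
    for (int j = j1; j <= j2; ++j) {
      double dy = gy[j] - ey[e];
      ky[j - j1] = std::exp(-dy * dy / (2.0 * bw * bw));
    }
    for (int j = j1; j <= j2; ++j) {
      double kyv = ky[j - j1] * norm;
      for (int i = i1; i <= i2; ++i)
        mat(i, j) += kx[i - i1] * kyv;
    }
  }
  return mat;
}
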