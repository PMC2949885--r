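#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// L1 gradient magnitude of a raster: |dx| + |dy|, central differences in the
// interior, one-sided (not halved) at borders.
static inline double grad_at(const NumericMatrix& v, int i, int j) {
  const int H = v.nrow(), W = v.ncol();
  double dx, dy;
  if (W == 1)          dx = 0.0;
  else if (j == 0)     dx = std::fabs(v(i, 1) - v(i, 0));
  else if (j == W - 1) dx = std::fabs(v(i, W - 1) - v(i, W - 2));
  else                 dx = 0.5 * std::fabs(v(i, j + 1) - v(i, j - 1));
  if (H == 1)          dy = 0.0;
  else if (i == 0)     dy = std::fabs(v(1, j) - v(0, j));
  else if (i == H - 1) dy = std::fabs(v(H - 1, j) - v(H - 2, j));
  else                 dy = 0.5 * std::fabs(v(i + 1, j) - v(i - 1, j));
  return dx + dy;
}

// [[Rcpp::export]]
NumericMatrix cpp_grad_l1(NumericMatrix v) {
  const int H = v.nrow(), W = v.ncol();
  NumericMatrix g(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      g(i, j) = grad_at(v, i, j);
  return g;
}

// Forward-energy step costs at (i, j), 0-based. A difference whose neighbor
// index falls outside the grid contributes 0.
static inline void step_costs(const NumericMatrix& v, int i, int j,
                              double& cL, double& cU, double& cR) {
  const int W = v.ncol();
  const double dH = (j > 0 && j < W - 1)
    ? std::fabs(v(i, j + 1) - v(i, j - 1)) : 0.0;
  cU = dH;
  cL = dH + ((i > 0 && j > 0)     ? std::fabs(v(i - 1, j) - v(i, j - 1)) : 0.0);
  cR = dH + ((i > 0 && j < W - 1) ? std::fabs(v(i - 1, j) - v(i, j + 1)) : 0.0);
}

// [[Rcpp::export]]
NumericVector cpp_step_costs(NumericMatrix v, int i, int j) {
  double cL, cU, cR;
  step_costs(v, i, j, cL, cU, cR);
  return NumericVector::create(_["cL"] = cL, _["cU"] = cU, _["cR"] = cR);
}

// Cumulative forward-energy cost matrix (vertical seams).
// M(i,j) = P(i,j) + min(M(i-1,j-1)+CL, M(i-1,j)+CU, M(i-1,j+1)+CR),
// P = L1 gradient of the energy raster; out-of-grid predecessors are +Inf;
// ties prefer the smallest predecessor column.
// [[Rcpp::export]]
List cpp_cost_matrix(NumericMatrix v) {
  const int H = v.nrow(), W = v.ncol();
  NumericMatrix M(H, W);
  IntegerMatrix back(H, W);
  // row-contiguous working copies: R matrices are column-major but the DP
  // walks rows, so gather each row once into contiguous buffers
  std::vector<double> rprev(W), rcur(W), rnext(W), Mprev(W), Mcur(W);
  std::vector<int> bcur(W);
  const double* vp = REAL(v);
  for (int j = 0; j < W; ++j) rcur[j] = vp[(size_t)j * H];
  if (H > 1) for (int j = 0; j < W; ++j) rnext[j] = vp[(size_t)j * H + 1];
  // P at row i from the three buffered rows (one-sided at borders)
  auto grad_row = [&](int i, int j) -> double {
    double dx, dy;
    if (W == 1)          dx = 0.0;
    else if (j == 0)     dx = std::fabs(rcur[1] - rcur[0]);
    else if (j == W - 1) dx = std::fabs(rcur[W - 1] - rcur[W - 2]);
    else                 dx = 0.5 * std::fabs(rcur[j + 1] - rcur[j - 1]);
    if (H == 1)          dy = 0.0;
    else if (i == 0)     dy = std::fabs(rnext[j] - rcur[j]);
    else if (i == H - 1) dy = std::fabs(rcur[j] - rprev[j]);
    else                 dy = 0.5 * std::fabs(rnext[j] - rprev[j]);
    return dx + dy;
  };
  double* Mp = REAL(M);
  int* bp = INTEGER(back);
  for (int j = 0; j < W; ++j) {
    Mprev[j] = grad_row(0, j);
    Mp[(size_t)j * H] = Mprev[j];
    bp[(size_t)j * H] = 0;
  }
  for (int i = 1; i < H; ++i) {
    rprev.swap(rcur);
    rcur.swap(rnext);
    if (i + 1 < H)
      for (int j = 0; j < W; ++j) rnext[j] = vp[(size_t)j * H + i + 1];
    for (int j = 0; j < W; ++j) {
      const double dH = (j > 0 && j < W - 1)
        ? std::fabs(rcur[j + 1] - rcur[j - 1]) : 0.0;
      const double cU = dH;
      const double cL = dH + ((j > 0) ?
        std::fabs(rprev[j] - rcur[j - 1]) : 0.0);
      const double cR = dH + ((j < W - 1) ?
        std::fabs(rprev[j] - rcur[j + 1]) : 0.0);
      const double candL = (j > 0)     ? Mprev[j - 1] + cL : INF;
      const double candU =               Mprev[j]     + cU;
      const double candR = (j < W - 1) ? Mprev[j + 1] + cR : INF;
      double best = candL; int arg = -1;
      if (candU < best) { best = candU; arg = 0; }
      if (candR < best) { best = candR; arg = 1; }
      Mcur[j] = grad_row(i, j) + best;
      bcur[j] = arg;
    }
    for (int j = 0; j < W; ++j) {
      Mp[(size_t)j * H + i] = Mcur[j];
      bp[(size_t)j * H + i] = bcur[j];
    }
    Mprev.swap(Mcur);
  }
  return List::create(_["values"] = M, _["back"] = back);
}

// Trace the minimum seam from a cost matrix: leftmost argmin of the last
// row, then follow backpointers upward. Returns 1-based column per row.
// [[Rcpp::export]]
IntegerVector cpp_trace_seam(NumericMatrix M, IntegerMatrix back) {
  const int H = M.nrow(), W = M.ncol();
  IntegerVector seam(H);
  int j = 0;
  for (int k = 1; k < W; ++k) if (M(H - 1, k) < M(H - 1, j)) j = k;
  seam[H - 1] = j + 1;
  for (int i = H - 1; i > 0; --i) {
    j += back(i, j);
    seam[i - 1] = j + 1;
  }
  return seam;
}

// [[Rcpp::export]]
NumericMatrix cpp_remove_seam(NumericMatrix m, IntegerVector seam) {
  const int H = m.nrow(), W = m.ncol();
  if (seam.size() != H) stop("seam length must equal nrow");
  for (int i = 0; i < H; ++i)
    if (seam[i] < 1 || seam[i] > W) stop("seam index out of range");
  NumericMatrix out(H, W - 1);
  const double* src = REAL(m);
  double* dst = REAL(out);
  // column-major traversal: output column k reads input column k (rows
  // before the seam) or k+1 (rows at/after it)
  for (int k = 0; k < W - 1; ++k) {
    const double* c0 = src + (size_t)k * H;
    const double* c1 = c0 + H;
    double* o = dst + (size_t)k * H;
    for (int i = 0; i < H; ++i)
      o[i] = (k < seam[i] - 1) ? c0[i] : c1[i];
  }
  return out;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher). Sites with
// infinite cost (no background reachable through that line yet) are skipped
// when building the lower envelope.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k]))
      / (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k]))
        / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  if (k < 0) {               // no finite site on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance from every pixel to the nearest zero (background)
// pixel; 0 on background, 0 everywhere if the mask has no background.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix fg) {
  const int H = fg.nrow(), W = fg.ncol();
  NumericMatrix sq(H, W);
  bool any_bg = false;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      sq(i, j) = fg(i, j) ? INF : 0.0;
      if (!fg(i, j)) any_bg = true;
    }
  if (!any_bg) return NumericMatrix(H, W);
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int j = 0; j < W; ++j) {          // along columns
    for (int i = 0; i < H; ++i) f[i] = sq(i, j);
    dt1d(f, d, H);
    for (int i = 0; i < H; ++i) sq(i, j) = d[i];
  }
  for (int i = 0; i < H; ++i) {          // along rows
    for (int j = 0; j < W; ++j) f[j] = sq(i, j);
    dt1d(f, d, W);
    for (int j = 0; j < W; ++j) sq(i, j) = d[j];
  }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) sq(i, j) = std::sqrt(sq(i, j));
  return sq;
}

// 8-connected component labeling; labels assigned 1..K in raster-scan
// order of first encounter (column-major to match R storage is avoided:
// scan row-major so labels read top-to-bottom, left-to-right).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      while (!stack.empty()) {
        const int ci = stack.back().first, cj = stack.back().second;
        stack.pop_back();
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(std::make_pair(ni, nj));
            }
          }
      }
    }
  }
  return lab;
}
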