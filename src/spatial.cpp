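#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// 8-connected component labelling of a binary mask.
// Components are numbered 1..K in order of their first pixel in column-major
// scan order (R's native layout), which fixes the canonical region_label
// used for Voronoi tie-breaking.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * H);
      lab(r, c) = next;
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int rr = idx % H, cc = idx / H;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            const int nr = rr + dr, nc = cc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              stack.push_back(nr + nc * H);
            }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Per-region raw pixel statistics: count, centroid and central second
// moments of pixel coordinates (0-based row/col).
// Returns a K x 6 matrix: n, centroid_row, centroid_col, mu20(row var sum),
// mu02(col var sum), mu11(cross sum). Central sums, not divided by n.
// [[Rcpp::export]]
NumericMatrix cpp_region_moments(const IntegerMatrix& lab, const int K) {
  const int H = lab.nrow(), W = lab.ncol();
  std::vector<double> n(K, 0.0), sr(K, 0.0), sc(K, 0.0),
      srr(K, 0.0), scc(K, 0.0), src(K, 0.0);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const int k = lab(r, c);
      if (k > 0) {
        const int i = k - 1;
        n[i] += 1.0;
        sr[i] += r; sc[i] += c;
        srr[i] += (double)r * r;
        scc[i] += (double)c * c;
        src[i] += (double)r * c;
      }
    }
  }
  NumericMatrix out(K, 6);
  for (int i = 0; i < K; ++i) {
    out(i, 0) = n[i];
    if (n[i] > 0) {
      out(i, 1) = sr[i] / n[i];
      out(i, 2) = sc[i] / n[i];
      out(i, 3) = srr[i] - sr[i] * sr[i] / n[i];
      out(i, 4) = scc[i] - sc[i] * sc[i] / n[i];
      out(i, 5) = src[i] - sr[i] * sc[i] / n[i];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 1-D squared Euclidean distance transform under additive offsets f
// (lower envelope of parabolas, Felzenszwalb & Huttenlocher). Sites with
// f = Inf are skipped; exact for integer-valued finite inputs.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, const int n) {
  static const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = -INF;
    while (k >= 0) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    const double dq = (double)q - v[j];
    d[q] = dq * dq + f[v[j]];
  }
}

// Exact squared EDT of a single region (pixels where lab == k) over the full
// grid, written into dist (column-major).
static void region_edt(const IntegerMatrix& lab, const int k,
                       std::vector<double>& dist, const int H, const int W) {
  static const double INF = std::numeric_limits<double>::infinity();
  const int M = std::max(H, W);
  std::vector<double> f(M), d(M), z(M + 1);
  std::vector<int> v(M);
  // pass 1: within-column distance to nearest region row (two sweeps)
  for (int c = 0; c < W; ++c) {
    double run = INF;
    for (int r = 0; r < H; ++r) {
      run = (lab(r, c) == k) ? 0.0 : (run + 1.0);
      dist[r + (size_t)c * H] = run;
    }
    run = INF;
    for (int r = H - 1; r >= 0; --r) {
      run = (lab(r, c) == k) ? 0.0 : (run + 1.0);
      double& dd = dist[r + (size_t)c * H];
      if (run < dd) dd = run;
      dd = (dd == INF) ? INF : dd * dd;
    }
  }
  // pass 2: lower envelope across columns within each row
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) f[c] = dist[r + (size_t)c * H];
    dt1d(f, d, v, z, W);
    for (int c = 0; c < W; ++c) dist[r + (size_t)c * H] = d[c];
  }
}

// ---------------------------------------------------------------------------
// Area-Voronoi influence zones: assign each tissue pixel to the region whose
// pixel set is nearest (Euclidean, pixel centers); ties go to the lowest
// region label. Pixels outside the tissue mask stay 0.
// [[Rcpp::export]]
IntegerMatrix cpp_area_voronoi(const IntegerMatrix& lab,
                               const LogicalMatrix& tissue, const int K) {
  const int H = lab.nrow(), W = lab.ncol();
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> best(H * (size_t)W, INF), dist(H * (size_t)W);
  IntegerMatrix assign(H, W);
  for (int k = 1; k <= K; ++k) {
    region_edt(lab, k, dist, H, W);
    for (size_t i = 0; i < dist.size(); ++i) {
      if (dist[i] < best[i]) { // strict: first (lowest) label wins ties
        best[i] = dist[i];
        assign[i] = k;
      }
    }
  }
  for (int i = 0; i < H * W; ++i)
    if (!tissue[i]) assign[i] = 0;
  return assign;
}

// ---------------------------------------------------------------------------
// Delaunay neighbor degrees via the empty-circle angle criterion: segment
// (i,j) is a Delaunay edge iff the largest angles subtended by ij from the
// two sides of the line sum to less than pi (inscribed-angle theorem).
// O(n^3); adequate for per-slide region counts.
// [[Rcpp::export]]
IntegerVector cpp_delaunay_degrees(const NumericVector& x,
                                   const NumericVector& y) {
  const int n = x.size();
  IntegerVector deg(n);
  if (n == 2) { deg[0] = 1; deg[1] = 1; return deg; }
  if (n < 2) return deg;
  const double PI = 3.14159265358979323846;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double ax = x[i], ay = y[i], bx = x[j], by = y[j];
      double maxL = 0.0, maxR = 0.0;
      bool dead = false;
      for (int k = 0; k < n && !dead; ++k) {
        if (k == i || k == j) continue;
        const double ux = ax - x[k], uy = ay - y[k];
        const double vx = bx - x[k], vy = by - y[k];
        const double cross = ux * vy - uy * vx;
        const double dot = ux * vx + uy * vy;
        const double ang = std::atan2(std::fabs(cross), dot); // in [0, pi]
        if (std::fabs(cross) < 1e-12 * (std::fabs(dot) + 1.0)) {
          if (dot < 0.0) dead = true; // k on the open segment ij
          continue;
        }
        if (cross > 0.0) { if (ang > maxL) maxL = ang; }
        else             { if (ang > maxR) maxR = ang; }
      }
      if (!dead && maxL + maxR < PI - 1e-9) { ++deg[i]; ++deg[j]; }
    }
  }
  return deg;
}

// ---------------------------------------------------------------------------
// Mann-Whitney AUC with ties counted 1/2 (midrank formulation).
// [[Rcpp::export]]
double cpp_auc(const NumericVector& scores, const LogicalVector& truth) {
  const int n = scores.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return scores[a] < scores[b]; });
  double sumPos = 0.0;
  int n1 = 0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && scores[ord[j + 1]] == scores[ord[i]]) ++j;
    const double midrank = 0.5 * ((i + 1) + (j + 1));
    for (int t = i; t <= j; ++t) {
      if (truth[ord[t]]) { sumPos += midrank; ++n1; }
    }
    i = j + 1;
  }
  const int n0 = n - n1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  return (sumPos - n1 * (n1 + 1.0) / 2.0) / ((double)n1 * n0);
}
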