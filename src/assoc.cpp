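// Pairwise association estimators that need tight loops: the bounded
// Theil-Sen score (median of all pairwise slopes, both regressions) and the
// maximal information coefficient (equipartition + dynamic-programming
// column optimization, with an exact sweep for two-row/two-column grids).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static double median_destructive(std::vector<double> &v) {
  const size_t n = v.size();
  const size_t mid = n / 2;
  std::nth_element(v.begin(), v.begin() + mid, v.end());
  double hi = v[mid];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + mid);
  return (lo + hi) / 2.0;
}

// Median pairwise slope of y on x (pairs with equal x skipped) and of x on
// y, on already-standardized inputs; combined into a bounded signed score.
// Slopes are filled branchlessly (0/0 -> NaN, k/0 -> +-Inf) and non-finite
// entries dropped afterwards, which keeps the fill loop vectorizable.
// [[Rcpp::export]]
double theil_sen_score_cpp(NumericVector x, NumericVector y) {
  const int m = x.size();
  const size_t np = static_cast<size_t>(m) * (m - 1) / 2;
  static std::vector<double> syx, sxy;  // reused across calls
  syx.resize(np);
  sxy.resize(np);
  const double *px = x.begin(), *py = y.begin();
  size_t idx = 0;
  for (int i = 0; i < m; ++i) {
    const double xi = px[i], yi = py[i];
    for (int j = i + 1; j < m; ++j, ++idx) {
      const double dx = px[j] - xi, dy = py[j] - yi;
      syx[idx] = dy / dx;
      sxy[idx] = dx / dy;
    }
  }
  const auto drop = [](double v) { return !std::isfinite(v); };
  syx.erase(std::remove_if(syx.begin(), syx.end(), drop), syx.end());
  sxy.erase(std::remove_if(sxy.begin(), sxy.end(), drop), sxy.end());
  if (syx.empty() || sxy.empty()) return 0.0;
  const double byx = median_destructive(syx);
  const double bxy = median_destructive(sxy);
  const double prod = byx * bxy;
  if (prod <= 0.0) return 0.0;
  const double r = std::min(1.0, std::sqrt(prod));
  return (byx >= 0.0 ? r : -r);
}

// Kendall's tau-b in O(m log m): sort by (x, y), count discordant pairs as
// strict inversions of the y sequence by merge sort, apply the standard tie
// corrections: nc - nd = n0 - t_x - t_y + t_xy - 2 * inversions.
static long long merge_count(std::vector<double> &v, std::vector<double> &buf,
                             size_t lo, size_t hi) {
  if (hi - lo < 2) return 0;
  const size_t mid = lo + (hi - lo) / 2;
  long long inv = merge_count(v, buf, lo, mid) + merge_count(v, buf, mid, hi);
  size_t a = lo, b = mid, k = lo;
  while (a < mid && b < hi) {
    if (v[b] < v[a]) {  // strictly smaller from the right: inversion
      inv += static_cast<long long>(mid - a);
      buf[k++] = v[b++];
    } else {
      buf[k++] = v[a++];
    }
  }
  while (a < mid) buf[k++] = v[a++];
  while (b < hi) buf[k++] = v[b++];
  std::copy(buf.begin() + lo, buf.begin() + hi, v.begin() + lo);
  return inv;
}

static double tie_pairs(const std::vector<double> &sorted_keys) {
  double t = 0.0;
  size_t run = 1;
  for (size_t i = 1; i <= sorted_keys.size(); ++i) {
    if (i < sorted_keys.size() && sorted_keys[i] == sorted_keys[i - 1]) {
      ++run;
    } else {
      t += run * (run - 1.0) / 2.0;
      run = 1;
    }
  }
  return t;
}

// [[Rcpp::export]]
double kendall_tau_b_cpp(NumericVector xr, NumericVector yr) {
  const int m = xr.size();
  std::vector<int> idx(m);
  for (int i = 0; i < m; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (xr[a] != xr[b]) return xr[a] < xr[b];
    return yr[a] < yr[b];
  });
  // tie counts: joint (x, y), x alone, y alone
  double txy = 0.0;
  {
    size_t run = 1;
    for (int i = 1; i <= m; ++i) {
      if (i < m && xr[idx[i]] == xr[idx[i - 1]] &&
          yr[idx[i]] == yr[idx[i - 1]]) {
        ++run;
      } else {
        txy += run * (run - 1.0) / 2.0;
        run = 1;
      }
    }
  }
  std::vector<double> xs(m), ys(m);
  for (int i = 0; i < m; ++i) {
    xs[i] = xr[idx[i]];
    ys[i] = yr[idx[i]];
  }
  const double tx = tie_pairs(xs);
  std::vector<double> buf(m);
  const long long inv = merge_count(ys, buf, 0, m);  // ys now sorted
  const double ty = tie_pairs(ys);
  const double n0 = static_cast<double>(m) * (m - 1) / 2.0;
  const double denom = std::sqrt((n0 - tx) * (n0 - ty));
  if (denom == 0.0) return 0.0;
  return (n0 - tx - ty + txy - 2.0 * static_cast<double>(inv)) / denom;
}

// ---------------------------------------------------------------------------
// MIC

// Group sizes -> near-equal partition into at most b consecutive groups,
// never splitting a group. Returns the group->partition assignment.
static std::vector<int> equipartition_groups(const std::vector<int> &gsize,
                                             int m, int b) {
  std::vector<int> part(gsize.size());
  int row = 0, currsize = 0, placed = 0;
  double desired = static_cast<double>(m) / b;
  for (size_t g = 0; g < gsize.size(); ++g) {
    if (currsize != 0 && row < b - 1 &&
        std::fabs(currsize + gsize[g] - desired) >=
            std::fabs(currsize - desired)) {
      ++row;
      currsize = 0;
      desired = static_cast<double>(m - placed) / (b - row);
    }
    part[g] = row;
    currsize += gsize[g];
    placed += gsize[g];
  }
  return part;
}

static inline double xlog2(double p) { return p > 0.0 ? p * std::log2(p) : 0.0; }

// Best I(P;Q)/log2(min(cols,rows)) over column counts 2..xmax, given a fixed
// row assignment, maximized by DP over clump boundaries along x.
static double optimize_axis(const std::vector<double> &x,
                            const std::vector<int> &row, int b, int xmax,
                            int cclumps) {
  const int m = static_cast<int>(x.size());
  // order points by x
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int bb) { return x[a] < x[bb]; });
  // clumps: maximal runs of tied x (a column boundary cannot split a tie)
  std::vector<int> clump_size;
  std::vector<int> clump_of(m);
  for (int i = 0; i < m; ++i) {
    if (i == 0 || x[ord[i]] != x[ord[i - 1]]) clump_size.push_back(0);
    clump_of[i] = static_cast<int>(clump_size.size()) - 1;
    clump_size.back()++;
  }
  // coarsen to at most cclumps superclumps
  int k = static_cast<int>(clump_size.size());
  if (k > cclumps) {
    std::vector<int> sc = equipartition_groups(clump_size, m, cclumps);
    std::vector<int> new_size(sc.back() + 1, 0);
    for (int g = 0; g < k; ++g) new_size[sc[g]] += clump_size[g];
    for (int i = 0; i < m; ++i) clump_of[i] = sc[clump_of[i]];
    clump_size = new_size;
    k = static_cast<int>(clump_size.size());
  }
  if (k < 2) return 0.0;
  // cumulative row counts per clump prefix: cum[t][r] = rows of clumps 0..t-1
  std::vector<std::vector<int> > cum(k + 1, std::vector<int>(b, 0));
  for (int i = 0; i < m; ++i) cum[clump_of[i] + 1][row[ord[i]]]++;
  for (int t = 1; t <= k; ++t)
    for (int r = 0; r < b; ++r) cum[t][r] += cum[t - 1][r];
  // val(s,t) = sum_r n_r log2(n_r / n_tot) for points in clumps (s, t]
  std::vector<std::vector<double> > val(k + 1,
                                        std::vector<double>(k + 1, 0.0));
  for (int s = 0; s < k; ++s) {
    for (int t = s + 1; t <= k; ++t) {
      int tot = 0;
      for (int r = 0; r < b; ++r) tot += cum[t][r] - cum[s][r];
      double v = 0.0;
      if (tot > 0) {
        for (int r = 0; r < b; ++r) {
          const int nr = cum[t][r] - cum[s][r];
          if (nr > 0) v += nr * std::log2(static_cast<double>(nr) / tot);
        }
      }
      val[s][t] = v;
    }
  }
  // H(Q) over all points
  double hq = 0.0;
  for (int r = 0; r < b; ++r) hq -= xlog2(static_cast<double>(cum[k][r]) / m);
  // DP: G[l][t] = best sum of val over a split of clumps 1..t into l columns
  const int lmax = std::min(xmax, k);
  std::vector<std::vector<double> > G(
      lmax + 1, std::vector<double>(k + 1, -1e300));
  for (int t = 1; t <= k; ++t) G[1][t] = val[0][t];
  double best = 0.0;
  for (int l = 2; l <= lmax; ++l) {
    for (int t = l; t <= k; ++t) {
      double bst = -1e300;
      for (int s = l - 1; s < t; ++s) {
        const double cand = G[l - 1][s] + val[s][t];
        if (cand > bst) bst = cand;
      }
      G[l][t] = bst;
    }
    const double informed = hq + G[l][k] / m;
    const double norm = std::log2(static_cast<double>(std::min(l, b)));
    if (norm > 0.0) best = std::max(best, informed / norm);
  }
  return best;
}

// Exact search over all 2x2 grids (both cut points free); O(m^2).
static double best_two_by_two(const std::vector<double> &x,
                              const std::vector<double> &y) {
  const int m = static_cast<int>(x.size());
  std::vector<int> xo(m), yo(m);
  for (int i = 0; i < m; ++i) xo[i] = yo[i] = i;
  std::sort(xo.begin(), xo.end(), [&](int a, int b) { return x[a] < x[b]; });
  std::sort(yo.begin(), yo.end(), [&](int a, int b) { return y[a] < y[b]; });
  std::vector<int> yrank(m);
  for (int i = 0; i < m; ++i) yrank[yo[i]] = i;
  std::vector<int> inleft(m, 0);  // indicator over y-order positions
  std::vector<int> pref(m + 1, 0);
  double best = 0.0;
  for (int i = 1; i < m; ++i) {  // x-cut after i points (x order)
    inleft[yrank[xo[i - 1]]] = 1;
    if (x[xo[i]] == x[xo[i - 1]]) continue;  // cannot split tied x
    for (int t = 0; t < m; ++t) pref[t + 1] = pref[t] + inleft[t];
    for (int j = 1; j < m; ++j) {  // y-cut after j points (y order)
      if (y[yo[j]] == y[yo[j - 1]]) continue;
      const double n11 = pref[j], n21 = j - pref[j];
      const double n12 = i - pref[j], n22 = m - i - (j - pref[j]);
      const double pc1 = static_cast<double>(i) / m, pc2 = 1.0 - pc1;
      const double pr1 = static_cast<double>(j) / m, pr2 = 1.0 - pr1;
      double inf = xlog2(n11 / m) + xlog2(n12 / m) + xlog2(n21 / m) +
                   xlog2(n22 / m) - xlog2(pc1) - xlog2(pc2) - xlog2(pr1) -
                   xlog2(pr2);
      // inf = -H(P,Q) + H(P) + H(Q) once signs are collected:
      // xlog2 terms above are sum p log2 p; I = sum_pq - sum_p - sum_q
      if (inf > best) best = inf;  // normalization log2(2) = 1
    }
  }
  return best;
}

// [[Rcpp::export]]
double mic_score_cpp(NumericVector xr, NumericVector yr, double alpha,
                     int cgrid) {
  const int m = xr.size();
  if (m < 4) return 0.0;
  std::vector<double> x(xr.begin(), xr.end()), y(yr.begin(), yr.end());
  const double B = std::max(std::pow(static_cast<double>(m), alpha), 4.0);
  double best = best_two_by_two(x, y);
  for (int orient = 0; orient < 2; ++orient) {
    const std::vector<double> &u = orient == 0 ? x : y;
    const std::vector<double> &v = orient == 0 ? y : x;
    const int bmaxrows = static_cast<int>(std::floor(B / 2.0));
    for (int b = 2; b <= bmaxrows; ++b) {
      const int xmax = static_cast<int>(std::floor(B / b));
      if (xmax < 2) break;
      // equipartition v into b rows (ties kept together)
      std::vector<int> ord(m);
      for (int i = 0; i < m; ++i) ord[i] = i;
      std::sort(ord.begin(), ord.end(),
                [&](int a, int bb) { return v[a] < v[bb]; });
      std::vector<int> gsize;
      std::vector<int> gid(m);
      for (int i = 0; i < m; ++i) {
        if (i == 0 || v[ord[i]] != v[ord[i - 1]]) gsize.push_back(0);
        gid[i] = static_cast<int>(gsize.size()) - 1;
        gsize.back()++;
      }
      if (static_cast<int>(gsize.size()) < 2) return best;  // constant axis
      const int nrows = std::min(b, static_cast<int>(gsize.size()));
      std::vector<int> grow = equipartition_groups(gsize, m, nrows);
      std::vector<int> row(m);
      for (int i = 0; i < m; ++i) row[ord[i]] = grow[gid[i]];
      const double got =
          optimize_axis(u, row, nrows, xmax, cgrid * xmax);
      if (got > best) best = got;
    }
  }
  if (best > 1.0) best = 1.0;
  if (best < 0.0) best = 0.0;
  return best;
}
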