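#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Offsets (dr, dc) whose cell centers lie within radius_cells of the focal
// cell center. radius_cells is radius / cell_size.
static std::vector<std::pair<int, int>> disc_offsets(double radius_cells) {
  std::vector<std::pair<int, int>> off;
  int R = (int)std::floor(radius_cells + 1e-9);
  double r2 = radius_cells * radius_cells + 1e-9;
  for (int dr = -R; dr <= R; ++dr)
    for (int dc = -R; dc <= R; ++dc)
      if ((double)(dr * dr + dc * dc) <= r2) off.push_back({dr, dc});
  return off;
}

// [[Rcpp::export]]
NumericMatrix cpp_focal_stat(NumericMatrix x, double radius_cells, int stat) {
  // stat: 0 = mean over valid cells, 1 = sum over valid cells (NA treated
  // as absent mass).
  int nr = x.nrow(), nc = x.ncol();
  std::vector<std::pair<int, int>> off = disc_offsets(radius_cells);
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (stat == 0 && NumericMatrix::is_na(x(i, j))) {
        out(i, j) = NA_REAL;
        continue;
      }
      double s = 0.0;
      int n = 0;
      for (size_t k = 0; k < off.size(); ++k) {
        int r = i + off[k].first, c = j + off[k].second;
        if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
        double v = x(r, c);
        if (NumericMatrix::is_na(v)) continue;
        s += v;
        ++n;
      }
      if (stat == 0)
        out(i, j) = (n > 0) ? s / n : NA_REAL;
      else
        out(i, j) = s;
    }
  }
  return out;
}

// FRAGSTATS maximum number of like (rook) adjacencies, single count, for a
// class occupying a cells.
static double max_like_adj(int a) {
  if (a <= 1) return 0.0;
  int n = (int)std::floor(std::sqrt((double)a));
  int m = a - n * n;
  if (m == 0) return 2.0 * n * (n - 1);
  if (m <= n) return 2.0 * n * (n - 1) + 2.0 * m - 1.0;
  return 2.0 * n * (n - 1) + 2.0 * m - 2.0;
}

// Moving-window landscape metrics over a circular window, FRAGSTATS
// conventions: window truncated at the raster edge, metrics over valid
// (non-NA) in-window cells only; patches are 8-connected and clipped to
// the window.
// metric codes: 1 PLAND, 2 LPI, 3 PD, 4 ED, 5 SHDI, 6 AI.
// focal_class: class code for class-level PLAND/LPI; -1 for landscape level
// (LPI then uses the largest patch of any class).
// [[Rcpp::export]]
NumericMatrix cpp_window_metric(IntegerMatrix lc, double radius_cells,
                                int metric, int focal_class,
                                double cell_size) {
  int nr = lc.nrow(), nc = lc.ncol();
  std::vector<std::pair<int, int>> off = disc_offsets(radius_cells);
  int W = 2 * (int)std::floor(radius_cells + 1e-9) + 1;
  int halfW = W / 2;
  NumericMatrix out(nr, nc);

  // local window buffers (local coords: lr = r - i + halfW, lc = c - j + halfW)
  std::vector<int> wclass(W * W);
  std::vector<unsigned char> inwin(W * W);
  std::vector<int> lab(W * W);
  std::vector<int> stack_;
  stack_.reserve(W * W);

  const int MAXC = 256;
  std::vector<int> cnt(MAXC);

  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (IntegerMatrix::is_na(lc(i, j))) {
        out(i, j) = NA_REAL;
        continue;
      }
      std::fill(inwin.begin(), inwin.end(), 0);
      std::fill(cnt.begin(), cnt.end(), 0);
      int N = 0;
      for (size_t k = 0; k < off.size(); ++k) {
        int r = i + off[k].first, c = j + off[k].second;
        if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
        int v = lc(r, c);
        if (IntegerMatrix::is_na(v)) continue;
        int li = (off[k].first + halfW) * W + (off[k].second + halfW);
        inwin[li] = 1;
        wclass[li] = v;
        if (v >= 0 && v < MAXC) cnt[v]++;
        ++N;
      }
      if (N == 0) {
        out(i, j) = NA_REAL;
        continue;
      }
      double area_ha = N * cell_size * cell_size / 10000.0;
      double val = NA_REAL;

      if (metric == 1) {  // PLAND
        int a = (focal_class >= 0 && focal_class < MAXC) ? cnt[focal_class] : 0;
        val = 100.0 * a / N;
      } else if (metric == 5) {  // SHDI
        double h = 0.0;
        for (int k = 0; k < MAXC; ++k)
          if (cnt[k] > 0) {
            double p = (double)cnt[k] / N;
            h -= p * std::log(p);
          }
        val = h;
      } else if (metric == 4) {  // ED: m of class boundary per ha
        long edges = 0;
        for (int lr = 0; lr < W; ++lr)
          for (int lcc = 0; lcc < W; ++lcc) {
            int li = lr * W + lcc;
            if (!inwin[li]) continue;
            if (lcc + 1 < W && inwin[li + 1] && wclass[li + 1] != wclass[li])
              ++edges;
            if (lr + 1 < W && inwin[li + W] && wclass[li + W] != wclass[li])
              ++edges;
          }
        val = edges * cell_size / area_ha;
      } else if (metric == 6) {  // AI, landscape level
        std::vector<long> g(MAXC, 0);
        for (int lr = 0; lr < W; ++lr)
          for (int lcc = 0; lcc < W; ++lcc) {
            int li = lr * W + lcc;
            if (!inwin[li]) continue;
            int v = wclass[li];
            if (lcc + 1 < W && inwin[li + 1] && wclass[li + 1] == v) g[v]++;
            if (lr + 1 < W && inwin[li + W] && wclass[li + W] == v) g[v]++;
          }
        double ai = 0.0;
        for (int k = 0; k < MAXC; ++k) {
          if (cnt[k] == 0) continue;
          double mg = max_like_adj(cnt[k]);
          if (mg > 0) ai += ((double)cnt[k] / N) * ((double)g[k] / mg) * 100.0;
        }
        val = ai;
      } else if (metric == 2 || metric == 3) {  // LPI / PD via labeling
        std::fill(lab.begin(), lab.end(), 0);
        int npatch = 0, maxpatch = 0, maxpatch_focal = 0;
        for (int li = 0; li < W * W; ++li) {
          if (!inwin[li] || lab[li]) continue;
          ++npatch;
          int sz = 0, cls = wclass[li];
          stack_.clear();
          stack_.push_back(li);
          lab[li] = npatch;
          while (!stack_.empty()) {
            int cur = stack_.back();
            stack_.pop_back();
            ++sz;
            int cr = cur / W, cc = cur % W;
            for (int dr = -1; dr <= 1; ++dr)
              for (int dc = -1; dc <= 1; ++dc) {
                if (dr == 0 && dc == 0) continue;
                int rr = cr + dr, c2 = cc + dc;
                if (rr < 0 || rr >= W || c2 < 0 || c2 >= W) continue;
                int ni = rr * W + c2;
                if (inwin[ni] && !lab[ni] && wclass[ni] == cls) {
                  lab[ni] = npatch;
                  stack_.push_back(ni);
                }
              }
          }
          if (sz > maxpatch) maxpatch = sz;
          if (cls == focal_class && sz > maxpatch_focal) maxpatch_focal = sz;
        }
        if (metric == 3)
          val = npatch / area_ha * 100.0;  // patches per 100 ha
        else
          val = 100.0 *
                ((focal_class >= 0) ? maxpatch_focal : maxpatch) / N;
      }
      out(i, j) = val;
    }
  }
  return out;
}

// 8- or 4-connected component labeling of a binary mask (1 = foreground).
// Returns integer labels, 0 for background/NA.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack_;
  int next = 0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      if (mask(i, j) != TRUE || lab(i, j) != 0) continue;
      ++next;
      stack_.clear();
      stack_.push_back(i * nc + j);
      lab(i, j) = next;
      while (!stack_.empty()) {
        int cur = stack_.back();
        stack_.pop_back();
        int cr = cur / nc, cc = cur % nc;
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            if (connectivity == 4 && dr != 0 && dc != 0) continue;
            int rr = cr + dr, c2 = cc + dc;
            if (rr < 0 || rr >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(rr, c2) == TRUE && lab(rr, c2) == 0) {
              lab(rr, c2) = next;
              stack_.push_back(rr * nc + c2);
            }
          }
      }
    }
  return lab;
}
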