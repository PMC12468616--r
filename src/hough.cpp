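#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Circular Hough transform on a binary mask, gradient-voting variant:
// every edge pixel votes along its (quantised) gradient direction at all
// radii in [min_radius, max_radius]; accumulator peaks become candidate
// centres, thinned by a minimum centre distance; the radius of each
// accepted centre is the modal edge-pixel distance within the search range.
//
// Coordinates returned are 0-based with x = column, y = row, matching the
// detection-table convention used throughout the package.
// [[Rcpp::export(name = ".hough_circles_cpp")]]
NumericMatrix hough_circles_cpp(IntegerMatrix mask,
                                int min_radius, int max_radius,
                                double min_center_distance,
                                double accumulator_threshold) {
  const int ny = mask.nrow(), nx = mask.ncol();
  std::vector<int> ex, ey;          // edge pixel coords (x = col, y = row)
  std::vector<double> gx, gy;       // unit gradient at the edge pixel

  // Sobel gradient; edge = nonzero gradient magnitude on the mask image
  for (int y = 1; y < ny - 1; ++y) {
    for (int x = 1; x < nx - 1; ++x) {
      double dx = (mask(y - 1, x + 1) + 2.0 * mask(y, x + 1) + mask(y + 1, x + 1))
                - (mask(y - 1, x - 1) + 2.0 * mask(y, x - 1) + mask(y + 1, x - 1));
      double dy = (mask(y + 1, x - 1) + 2.0 * mask(y + 1, x) + mask(y + 1, x + 1))
                - (mask(y - 1, x - 1) + 2.0 * mask(y - 1, x) + mask(y - 1, x + 1));
      double mag = std::sqrt(dx * dx + dy * dy);
      if (mag > 0) {
        ex.push_back(x); ey.push_back(y);
        gx.push_back(dx / mag); gy.push_back(dy / mag);
      }
    }
  }

  IntegerMatrix acc(ny, nx);
  const int nedge = (int) ex.size();
  for (int i = 0; i < nedge; ++i) {
    for (int s = -1; s <= 1; s += 2) {        // vote both ways along the normal
      for (int r = min_radius; r <= max_radius; ++r) {
        int cx = (int) std::lround(ex[i] + s * r * gx[i]);
        int cy = (int) std::lround(ey[i] + s * r * gy[i]);
        if (cx >= 0 && cx < nx && cy >= 0 && cy < ny) acc(cy, cx) += 1;
      }
    }
  }

  // candidate centres: local maxima (8-neighbourhood) above the vote threshold
  std::vector<int> px, py, pv;
  for (int y = 1; y < ny - 1; ++y) {
    for (int x = 1; x < nx - 1; ++x) {
      int v = acc(y, x);
      if (v < accumulator_threshold) continue;
      bool ismax = true;
      for (int oy = -1; oy <= 1 && ismax; ++oy)
        for (int ox = -1; ox <= 1; ++ox) {
          if (ox == 0 && oy == 0) continue;
          int w = acc(y + oy, x + ox);
          // strict inequality against later cells breaks plateau ties row-major
          if (w > v || (w == v && (oy < 0 || (oy == 0 && ox < 0)))) { ismax = false; break; }
        }
      if (ismax) { px.push_back(x); py.push_back(y); pv.push_back(v); }
    }
  }

  std::vector<size_t> ord(px.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](size_t a, size_t b) { return pv[a] > pv[b]; });

  const double mind2 = min_center_distance * min_center_distance;
  std::vector<int> cx_out, cy_out, votes_out;
  for (size_t k = 0; k < ord.size(); ++k) {
    int x = px[ord[k]], y = py[ord[k]];
    bool ok = true;
    for (size_t j = 0; j < cx_out.size(); ++j) {
      double ddx = x - cx_out[j], ddy = y - cy_out[j];
      if (ddx * ddx + ddy * ddy < mind2) { ok = false; break; }
    }
    if (ok) { cx_out.push_back(x); cy_out.push_back(y); votes_out.push_back(pv[ord[k]]); }
  }

  // spatial buckets over edge pixels so radius estimation only touches
  // pixels near each centre
  const int bs = max_radius + 2;                   // bucket side
  const int bnx = nx / bs + 1, bny = ny / bs + 1;
  std::vector<std::vector<int>> bucket((size_t) bnx * bny);
  for (int i = 0; i < nedge; ++i)
    bucket[(size_t) (ey[i] / bs) * bnx + (ex[i] / bs)].push_back(i);

  // modal edge distance -> radius estimate per accepted centre
  const int ncirc = (int) cx_out.size();
  NumericMatrix out(ncirc, 4);
  std::vector<int> rhist(max_radius + 2);
  for (int c = 0; c < ncirc; ++c) {
    std::fill(rhist.begin(), rhist.end(), 0);
    double lim = (double) max_radius + 1.5;
    int bx = cx_out[c] / bs, by = cy_out[c] / bs;
    for (int oby = by - 1; oby <= by + 1; ++oby) {
      if (oby < 0 || oby >= bny) continue;
      for (int obx = bx - 1; obx <= bx + 1; ++obx) {
        if (obx < 0 || obx >= bnx) continue;
        for (int i : bucket[(size_t) oby * bnx + obx]) {
          double ddx = ex[i] - cx_out[c], ddy = ey[i] - cy_out[c];
          double d = std::sqrt(ddx * ddx + ddy * ddy);
          if (d <= lim) {
            int b = (int) std::lround(d);
            if (b >= min_radius && b <= max_radius) rhist[b] += 1;
          }
        }
      }
    }
    int best_r = min_radius, best_n = -1;
    for (int r = min_radius; r <= max_radius; ++r)
      if (rhist[r] > best_n) { best_n = rhist[r]; best_r = r; }
    out(c, 0) = cx_out[c];
    out(c, 1) = cy_out[c];
    out(c, 2) = best_r;
    out(c, 3) = votes_out[c];
  }
  colnames(out) = CharacterVector::create("x", "y", "radius", "votes");
  return out;
}

// Dense window sum of a numeric matrix via a summed-area table.
// mode: 0 = "same" (zero-padded, centred, odd window), 1 = "valid".
// [[Rcpp::export(name = ".sliding_sum_cpp")]]
NumericMatrix sliding_sum_cpp(NumericMatrix x, int window, int mode) {
  const int ny = x.nrow(), nx = x.ncol();
  // integral image with a zero first row/col
  std::vector<double> S((ny + 1) * (nx + 1), 0.0);
  auto at = [&](int r, int c) -> double& { return S[(size_t) r * (nx + 1) + c]; };
  for (int r = 1; r <= ny; ++r)
    for (int c = 1; c <= nx; ++c)
      at(r, c) = x(r - 1, c - 1) + at(r - 1, c) + at(r, c - 1) - at(r - 1, c - 1);

  auto boxsum = [&](int r0, int r1, int c0, int c1) {
    r0 = std::max(r0, 0); c0 = std::max(c0, 0);
    r1 = std::min(r1, ny - 1); c1 = std::min(c1, nx - 1);
    if (r1 < r0 || c1 < c0) return 0.0;
    return at(r1 + 1, c1 + 1) - at(r0, c1 + 1) - at(r1 + 1, c0) + at(r0, c0);
  };

  if (mode == 0) {
    const int h = (window - 1) / 2;
    NumericMatrix out(ny, nx);
    for (int r = 0; r < ny; ++r)
      for (int c = 0; c < nx; ++c)
        out(r, c) = boxsum(r - h, r + h, c - h, c + h);
    return out;
  }
  const int oy = ny - window + 1, ox = nx - window + 1;
  NumericMatrix out(oy, ox);
  for (int r = 0; r < oy; ++r)
    for (int c = 0; c < ox; ++c)
      out(r, c) = boxsum(r, r + window - 1, c, c + window - 1);
  return out;
}
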