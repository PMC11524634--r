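#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// reflected (mirror) boundary index
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// separable Gaussian blur, mirror boundaries
// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(const NumericMatrix& im, double sigma) {
  int H = im.nrow(), W = im.ncol();
  if (sigma <= 0) return clone(im);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; i++) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (size_t i = 0; i < k.size(); i++) k[i] /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; j++)
    for (int i = 0; i < H; i++) {
      double acc = 0.0;
      for (int d = -r; d <= r; d++) acc += k[d + r] * im(refl(i + d, H), j);
      tmp(i, j) = acc;
    }
  for (int i = 0; i < H; i++)
    for (int j = 0; j < W; j++) {
      double acc = 0.0;
      for (int d = -r; d <= r; d++) acc += k[d + r] * tmp(i, refl(j + d, W));
      out(i, j) = acc;
    }
  return out;
}

// 4-neighbour discrete Laplacian, mirror boundaries
// [[Rcpp::export]]
NumericMatrix laplacian_cpp(const NumericMatrix& im) {
  int H = im.nrow(), W = im.ncol();
  NumericMatrix out(H, W);
  for (int i = 0; i < H; i++)
    for (int j = 0; j < W; j++) {
      out(i, j) = im(refl(i - 1, H), j) + im(refl(i + 1, H), j) +
                  im(i, refl(j - 1, W)) + im(i, refl(j + 1, W)) - 4.0 * im(i, j);
    }
  return out;
}

// median filter with disc footprint of given pixel radius (radius 0 = identity)
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(const NumericMatrix& im, int radius) {
  if (radius <= 0) return clone(im);
  int H = im.nrow(), W = im.ncol();
  std::vector<int> dx, dy;
  for (int a = -radius; a <= radius; a++)
    for (int b = -radius; b <= radius; b++)
      if (a * a + b * b <= radius * radius) { dy.push_back(a); dx.push_back(b); }
  int m = (int)dx.size();
  NumericMatrix out(H, W);
  std::vector<double> buf(m);
  for (int i = 0; i < H; i++)
    for (int j = 0; j < W; j++) {
      for (int t = 0; t < m; t++) buf[t] = im(refl(i + dy[t], H), refl(j + dx[t], W));
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
      double med = buf[m / 2];
      if (m % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
        med = 0.5 * (med + lo);
      }
      out(i, j) = med;
    }
  return out;
}

// Contrast-limited adaptive histogram equalization.
// Input assumed in [0, 255]; 256 bins; tile size = kernel px; clip_limit is the
// fraction of tile pixels allowed per bin before redistribution.
// [[Rcpp::export]]
NumericMatrix clahe_cpp(const NumericMatrix& im, int kernel, double clip_limit) {
  int H = im.nrow(), W = im.ncol();
  const int NB = 256;
  if (kernel < 1) kernel = 1;
  int nty = (H + kernel - 1) / kernel, ntx = (W + kernel - 1) / kernel;
  // per-tile mapping: NB values in [0,255]
  std::vector<double> maps((size_t)nty * ntx * NB, 0.0);
  for (int ty = 0; ty < nty; ty++) {
    int y0 = ty * kernel, y1 = std::min(H, y0 + kernel);
    for (int tx = 0; tx < ntx; tx++) {
      int x0 = tx * kernel, x1 = std::min(W, x0 + kernel);
      double npix = (double)(y1 - y0) * (x1 - x0);
      std::vector<double> hist(NB, 0.0);
      for (int i = y0; i < y1; i++)
        for (int j = x0; j < x1; j++) {
          int b = (int)std::floor(im(i, j));
          if (b < 0) b = 0; if (b > NB - 1) b = NB - 1;
          hist[b] += 1.0;
        }
      double clip = std::max(1.0, clip_limit * npix);
      double excess = 0.0;
      for (int b = 0; b < NB; b++)
        if (hist[b] > clip) { excess += hist[b] - clip; hist[b] = clip; }
      double add = excess / NB;
      for (int b = 0; b < NB; b++) hist[b] += add;
      double c = 0.0;
      double* mp = &maps[((size_t)ty * ntx + tx) * NB];
      for (int b = 0; b < NB; b++) { c += hist[b]; mp[b] = 255.0 * c / npix; }
    }
  }
  // bilinear interpolation between tile mappings
  NumericMatrix out(H, W);
  for (int i = 0; i < H; i++) {
    double fy = (i - 0.5 * kernel + 0.5) / kernel;
    int ty0 = (int)std::floor(fy);
    double wy = fy - ty0;
    int ty0c = std::min(std::max(ty0, 0), nty - 1);
    int ty1c = std::min(std::max(ty0 + 1, 0), nty - 1);
    for (int j = 0; j < W; j++) {
      double fx = (j - 0.5 * kernel + 0.5) / kernel;
      int tx0 = (int)std::floor(fx);
      double wx = fx - tx0;
      int tx0c = std::min(std::max(tx0, 0), ntx - 1);
      int tx1c = std::min(std::max(tx0 + 1, 0), ntx - 1);
      int b = (int)std::floor(im(i, j));
      if (b < 0) b = 0; if (b > NB - 1) b = NB - 1;
      double m00 = maps[((size_t)ty0c * ntx + tx0c) * NB + b];
      double m01 = maps[((size_t)ty0c * ntx + tx1c) * NB + b];
      double m10 = maps[((size_t)ty1c * ntx + tx0c) * NB + b];
      double m11 = maps[((size_t)ty1c * ntx + tx1c) * NB + b];
      out(i, j) = (1 - wy) * ((1 - wx) * m00 + wx * m01) + wy * ((1 - wx) * m10 + wx * m11);
    }
  }
  return out;
}

// bilinear resize; output pixel centres mapped into source pixel-centre coords
// [[Rcpp::export]]
NumericMatrix resize_bilinear_cpp(const NumericMatrix& im, int outH, int outW) {
  int H = im.nrow(), W = im.ncol();
  NumericMatrix out(outH, outW);
  double sy = (double)H / outH, sx = (double)W / outW;
  for (int i = 0; i < outH; i++) {
    double y = (i + 0.5) * sy - 0.5;
    int i0 = (int)std::floor(y);
    double fy = y - i0;
    int i0c = std::min(std::max(i0, 0), H - 1);
    int i1c = std::min(std::max(i0 + 1, 0), H - 1);
    for (int j = 0; j < outW; j++) {
      double x = (j + 0.5) * sx - 0.5;
      int j0 = (int)std::floor(x);
      double fx = x - j0;
      int j0c = std::min(std::max(j0, 0), W - 1);
      int j1c = std::min(std::max(j0 + 1, 0), W - 1);
      out(i, j) = (1 - fy) * ((1 - fx) * im(i0c, j0c) + fx * im(i0c, j1c)) +
                  fy * ((1 - fx) * im(i1c, j0c) + fx * im(i1c, j1c));
    }
  }
  return out;
}

// local maxima with greedy non-maximum suppression at min_distance (pixels).
// Returns n x 2 matrix of 1-based (row, col).
// [[Rcpp::export]]
IntegerMatrix local_maxima_cpp(const NumericMatrix& im, int min_distance, double threshold) {
  int H = im.nrow(), W = im.ncol();
  int r = std::max(1, min_distance);
  std::vector<int> ci, cj;
  std::vector<double> cv;
  for (int i = 0; i < H; i++)
    for (int j = 0; j < W; j++) {
      double v = im(i, j);
      if (v <= threshold) continue;
      bool ismax = true;
      for (int a = -r; a <= r && ismax; a++)
        for (int b = -r; b <= r; b++) {
          if (a == 0 && b == 0) continue;
          int ii = i + a, jj = j + b;
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          double u = im(ii, jj);
          if (u > v || (u == v && (a < 0 || (a == 0 && b < 0)))) { ismax = false; break; }
        }
      if (ismax) { ci.push_back(i); cj.push_back(j); cv.push_back(v); }
    }
  // greedy suppression by descending value
  int n = (int)ci.size();
  std::vector<int> ord(n);
  for (int t = 0; t < n; t++) ord[t] = t;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (cv[a] != cv[b]) return cv[a] > cv[b];
    if (ci[a] != ci[b]) return ci[a] < ci[b];
    return cj[a] < cj[b];
  });
  std::vector<bool> keep(n, true);
  std::vector<int> out_i, out_j;
  double r2 = (double)r * r;
  for (int t = 0; t < n; t++) {
    int a = ord[t];
    if (!keep[a]) continue;
    out_i.push_back(ci[a] + 1);
    out_j.push_back(cj[a] + 1);
    for (int u = t + 1; u < n; u++) {
      int b = ord[u];
      if (!keep[b]) continue;
      double dy = ci[a] - ci[b], dx = cj[a] - cj[b];
      if (dy * dy + dx * dx <= r2) keep[b] = false;
    }
  }
  IntegerMatrix res((int)out_i.size(), 2);
  for (int t = 0; t < (int)out_i.size(); t++) { res(t, 0) = out_i[t]; res(t, 1) = out_j[t]; }
  return res;
}

// connected components, 8-connectivity
// [[Rcpp::export]]
IntegerMatrix conn_comp_cpp(const LogicalMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < H; i++)
    for (int j = 0; j < W; j++) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      next++;
      stack.clear();
      stack.push_back(i * W + j);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p / W, pj = p % W;
        for (int a = -1; a <= 1; a++)
          for (int b = -1; b <= 1; b++) {
            int ii = pi + a, jj = pj + b;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(ii * W + jj);
            }
          }
      }
    }
  return lab;
}

struct WsNode {
  double v;
  long long ord;
  int idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.v != b.v) return a.v > b.v;   // min-heap on elevation
    return a.ord > b.ord;               // FIFO among equals
  }
};

// marker-controlled watershed by priority flood on an elevation map (lower floods
// first), restricted to mask. markers: positive integer labels, 0 elsewhere.
// [[Rcpp::export]]
IntegerMatrix watershed_cpp(const NumericMatrix& elev, const IntegerMatrix& markers,
                            const LogicalMatrix& mask) {
  int H = elev.nrow(), W = elev.ncol();
  IntegerMatrix lab(H, W);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long ord = 0;
  for (int i = 0; i < H; i++)
    for (int j = 0; j < W; j++)
      if (markers(i, j) > 0 && mask(i, j)) {
        lab(i, j) = markers(i, j);
        pq.push({elev(i, j), ord++, i * W + j});
      }
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int pi = nd.idx / W, pj = nd.idx % W;
    int l = lab(pi, pj);
    for (int t = 0; t < 4; t++) {
      int ii = pi + di[t], jj = pj + dj[t];
      if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
      if (!mask(ii, jj) || lab(ii, jj) != 0) continue;
      lab(ii, jj) = l;
      pq.push({elev(ii, jj), ord++, ii * W + jj});
    }
  }
  return lab;
}

// even-odd scanline polygon fill. Polygon vertices are in pixel coordinates
// where pixel (i, j) (1-based) has centre x = j, y = i.
// [[Rcpp::export]]
LogicalMatrix fill_polygon_cpp(int H, int W, const NumericVector& xs, const NumericVector& ys) {
  LogicalMatrix out(H, W);
  int n = xs.size();
  if (n < 3) return out;
  for (int i = 1; i <= H; i++) {
    double y = (double)i;
    std::vector<double> cross;
    for (int e = 0; e < n; e++) {
      double x1 = xs[e], y1 = ys[e];
      double x2 = xs[(e + 1) % n], y2 = ys[(e + 1) % n];
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        double t = (y - y1) / (y2 - y1);
        cross.push_back(x1 + t * (x2 - x1));
      }
    }
    std::sort(cross.begin(), cross.end());
    for (size_t p = 0; p + 1 < cross.size(); p += 2) {
      int j0 = (int)std::ceil(cross[p]);
      int j1 = (int)std::floor(cross[p + 1]);
      if (std::fabs(cross[p + 1] - std::floor(cross[p + 1])) < 1e-12) j1 -= 1; // half-open
      for (int j = std::max(1, j0); j <= std::min(W, j1); j++) out(i - 1, j - 1) = true;
    }
  }
  return out;
}

// union of stadium sweeps: pixels within maxd of any segment. segs columns
// (x1, y1, x2, y2) in pixel coordinates (pixel (i,j) centre = (j, i)).
// [[Rcpp::export]]
LogicalMatrix sweep_segments_cpp(int H, int W, const NumericMatrix& segs, double maxd) {
  LogicalMatrix out(H, W);
  double r2 = maxd * maxd;
  for (int s = 0; s < segs.nrow(); s++) {
    double x1 = segs(s, 0), y1 = segs(s, 1), x2 = segs(s, 2), y2 = segs(s, 3);
    int jlo = std::max(1, (int)std::floor(std::min(x1, x2) - maxd));
    int jhi = std::min(W, (int)std::ceil(std::max(x1, x2) + maxd));
    int ilo = std::max(1, (int)std::floor(std::min(y1, y2) - maxd));
    int ihi = std::min(H, (int)std::ceil(std::max(y1, y2) + maxd));
    double dx = x2 - x1, dy = y2 - y1;
    double len2 = dx * dx + dy * dy;
    for (int i = ilo; i <= ihi; i++)
      for (int j = jlo; j <= jhi; j++) {
        if (out(i - 1, j - 1)) continue;
        double px = j - x1, py = i - y1;
        double t = len2 > 0 ? std::max(0.0, std::min(1.0, (px * dx + py * dy) / len2)) : 0.0;
        double ex = px - t * dx, ey = py - t * dy;
        if (ex * ex + ey * ey <= r2) out(i - 1, j - 1) = true;
      }
  }
  return out;
}

// iterative pairwise separation of points closer than mind, with grid hashing.
// Points reflected into [0, W] x [0, H]. Returns n x 2 (x, y).
// [[Rcpp::export]]
NumericMatrix resolve_overlaps_cpp(NumericVector x, NumericVector y, double mind,
                                   int iters, double W, double H) {
  int n = x.size();
  std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
  if (mind > 0 && n > 1) {
    double cell = mind;
    for (int it = 0; it < iters; it++) {
      int nx = std::max(1, (int)std::ceil(W / cell));
      int ny = std::max(1, (int)std::ceil(H / cell));
      std::vector<std::vector<int>> bins((size_t)nx * ny);
      for (int p = 0; p < n; p++) {
        int bx = std::min(nx - 1, std::max(0, (int)(px[p] / cell)));
        int by = std::min(ny - 1, std::max(0, (int)(py[p] / cell)));
        bins[(size_t)by * nx + bx].push_back(p);
      }
      bool moved = false;
      for (int by = 0; by < ny; by++)
        for (int bx = 0; bx < nx; bx++) {
          const std::vector<int>& A = bins[(size_t)by * nx + bx];
          for (size_t ai = 0; ai < A.size(); ai++) {
            int a = A[ai];
            for (int oy = 0; oy <= 1; oy++)
              for (int ox = (oy == 0 ? 0 : -1); ox <= 1; ox++) {
                int cx = bx + ox, cy = by + oy;
                if (cx < 0 || cx >= nx || cy < 0 || cy >= ny) continue;
                const std::vector<int>& B = bins[(size_t)cy * nx + cx];
                size_t start = (ox == 0 && oy == 0) ? ai + 1 : 0;
                for (size_t bi = start; bi < B.size(); bi++) {
                  int b = B[bi];
                  double dx = px[b] - px[a], dy = py[b] - py[a];
                  double d2 = dx * dx + dy * dy;
                  if (d2 >= mind * mind) continue;
                  double d = std::sqrt(d2);
                  double ux, uy;
                  if (d < 1e-9) { // coincident: deterministic split direction
                    double ang = 0.61803398875 * (a + 1);
                    ux = std::cos(ang); uy = std::sin(ang);
                    d = 0.0;
                  } else { ux = dx / d; uy = dy / d; }
                  double push = 0.5 * (mind - d);
                  px[a] -= push * ux; py[a] -= push * uy;
                  px[b] += push * ux; py[b] += push * uy;
                  moved = true;
                }
              }
          }
        }
      for (int p = 0; p < n; p++) {
        if (px[p] < 0) px[p] = -px[p];
        if (px[p] > W) px[p] = 2 * W - px[p];
        if (py[p] < 0) py[p] = -py[p];
        if (py[p] > H) py[p] = 2 * H - py[p];
        if (px[p] < 0) px[p] = 0; if (px[p] > W) px[p] = W;
        if (py[p] < 0) py[p] = 0; if (py[p] > H) py[p] = H;
      }
      if (!moved) break;
    }
  }
  NumericMatrix out(n, 2);
  for (int p = 0; p < n; p++) { out(p, 0) = px[p]; out(p, 1) = py[p]; }
  return out;
}

// distance (pixels) and unit direction from each query point to the nearest
// true pixel of mask. pts columns (x = col, y = row), pixel coords. Returns
// n x 3: dist, ux, uy. dist = Inf when mask empty.
// [[Rcpp::export]]
NumericMatrix nearest_mask_dist_cpp(const LogicalMatrix& mask, const NumericMatrix& pts) {
  int H = mask.nrow(), W = mask.ncol();
  std::vector<double> mx, my;
  for (int i = 0; i < H; i++)
    for (int j = 0; j < W; j++)
      if (mask(i, j)) { mx.push_back(j + 1.0); my.push_back(i + 1.0); }
  int n = pts.nrow(), m = (int)mx.size();
  NumericMatrix out(n, 3);
  for (int p = 0; p < n; p++) {
    double best = R_PosInf, bx = 0.0, by = 0.0;
    for (int q = 0; q < m; q++) {
      double dx = mx[q] - pts(p, 0), dy = my[q] - pts(p, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bx = dx; by = dy; }
    }
    if (m == 0) { out(p, 0) = R_PosInf; out(p, 1) = 0; out(p, 2) = 0; }
    else {
      double d = std::sqrt(best);
      out(p, 0) = d;
      out(p, 1) = d > 0 ? bx / d : 0.0;
      out(p, 2) = d > 0 ? by / d : 0.0;
    }
  }
  return out;
}

// render anisotropic Gaussian spots onto an image (added in place on a copy).
// cells columns: x, y (pixel coords), sx, sy (sd px), theta (rad), amplitude.
// [[Rcpp::export]]
NumericMatrix render_spots_cpp(const NumericMatrix& base, const NumericMatrix& cells) {
  NumericMatrix out = clone(base);
  int H = out.nrow(), W = out.ncol();
  for (int c = 0; c < cells.nrow(); c++) {
    double cx = cells(c, 0), cy = cells(c, 1);
    double sx = cells(c, 2), sy = cells(c, 3);
    double th = cells(c, 4), A = cells(c, 5);
    double ct = std::cos(th), st = std::sin(th);
    double ext = 4.0 * std::max(sx, sy);
    int jlo = std::max(1, (int)std::floor(cx - ext)), jhi = std::min(W, (int)std::ceil(cx + ext));
    int ilo = std::max(1, (int)std::floor(cy - ext)), ihi = std::min(H, (int)std::ceil(cy + ext));
    for (int i = ilo; i <= ihi; i++)
      for (int j = jlo; j <= jhi; j++) {
        double dx = j - cx, dy = i - cy;
        double u = ct * dx + st * dy, v = -st * dx + ct * dy;
        double e = 0.5 * (u * u / (sx * sx) + v * v / (sy * sy));
        if (e < 12.0) out(i - 1, j - 1) += A * std::exp(-e);
      }
  }
  return out;
}
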