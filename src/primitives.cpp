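#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear resize with optional box-average prefilter on integer downscale
// factors (the "average" flag of the macro's resize). Pixel-center mapping:
// src = (dst + 0.5) * scale - 0.5, clamped to the source grid.
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix img, int outH, int outW,
                                  bool average) {
  int inH = img.nrow(), inW = img.ncol();
  if (outH < 1 || outW < 1) stop("target size must be positive");
  double scaleY = (double)inH / outH, scaleX = (double)inW / outW;
  NumericMatrix src = img;
  int ky = (int)std::floor(scaleY), kx = (int)std::floor(scaleX);
  if (average && ky >= 1 && kx >= 1 && (ky >= 2 || kx >= 2) &&
      inH == outH * ky && inW == outW * kx) {
    // exact integer downscale: non-overlapping block means
    NumericMatrix out(outH, outW);
    for (int j = 0; j < outW; ++j)
      for (int i = 0; i < outH; ++i) {
        double s = 0.0;
        for (int dy = 0; dy < ky; ++dy)
          for (int dx = 0; dx < kx; ++dx)
            s += img(i * ky + dy, j * kx + dx);
        out(i, j) = s / (ky * kx);
      }
    return out;
  }
  if (average && (ky >= 2 || kx >= 2)) {
    if (ky < 1) ky = 1;
    if (kx < 1) kx = 1;
    NumericMatrix sm(inH, inW);
    // box mean of ky x kx window, anchored so the window is as centred as
    // possible; edges clamp (replicate)
    int oy = (ky - 1) / 2, ox = (kx - 1) / 2;
    for (int j = 0; j < inW; ++j) {
      for (int i = 0; i < inH; ++i) {
        double s = 0.0;
        for (int dy = 0; dy < ky; ++dy) {
          int r = clampi(i - oy + dy, 0, inH - 1);
          for (int dx = 0; dx < kx; ++dx) {
            int c = clampi(j - ox + dx, 0, inW - 1);
            s += img(r, c);
          }
        }
        sm(i, j) = s / (ky * kx);
      }
    }
    src = sm;
  }
  NumericMatrix out(outH, outW);
  for (int j = 0; j < outW; ++j) {
    double sx = (j + 0.5) * scaleX - 0.5;
    if (sx < 0) sx = 0;
    if (sx > inW - 1) sx = inW - 1;
    int x0 = (int)std::floor(sx);
    int x1 = x0 + 1 < inW ? x0 + 1 : x0;
    double fx = sx - x0;
    for (int i = 0; i < outH; ++i) {
      double sy = (i + 0.5) * scaleY - 0.5;
      if (sy < 0) sy = 0;
      if (sy > inH - 1) sy = inH - 1;
      int y0 = (int)std::floor(sy);
      int y1 = y0 + 1 < inH ? y0 + 1 : y0;
      double fy = sy - y0;
      double top = src(y0, x0) * (1 - fx) + src(y0, x1) * fx;
      double bot = src(y1, x0) * (1 - fx) + src(y1, x1) * fx;
      out(i, j) = top * (1 - fy) + bot * fy;
    }
  }
  return out;
}

// 3x3 (8-neighbourhood) binary dilation; pixels outside the frame count as
// background.
// [[Rcpp::export]]
IntegerMatrix cpp_dilate(IntegerMatrix mask, int iterations) {
  if (iterations < 0) stop("iterations must be >= 0");
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix cur = clone(mask);
  for (int it = 0; it < iterations; ++it) {
    IntegerMatrix nxt(H, W);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        int v = 0;
        for (int dj = -1; dj <= 1 && !v; ++dj) {
          int c = j + dj;
          if (c < 0 || c >= W) continue;
          for (int di = -1; di <= 1; ++di) {
            int r = i + di;
            if (r < 0 || r >= H) continue;
            if (cur(r, c)) { v = 1; break; }
          }
        }
        nxt(i, j) = v;
      }
    }
    cur = nxt;
  }
  return cur;
}

// Dual of cpp_dilate: 3x3 minimum filter, outside-frame treated as background
// (so foreground touching the border erodes).
// [[Rcpp::export]]
IntegerMatrix cpp_erode(IntegerMatrix mask, int iterations) {
  if (iterations < 0) stop("iterations must be >= 0");
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix cur = clone(mask);
  for (int it = 0; it < iterations; ++it) {
    IntegerMatrix nxt(H, W);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        if (!cur(i, j)) { nxt(i, j) = 0; continue; }
        int v = 1;
        for (int dj = -1; dj <= 1 && v; ++dj) {
          int c = j + dj;
          for (int di = -1; di <= 1; ++di) {
            int r = i + di;
            if (r < 0 || r >= H || c < 0 || c >= W || !cur(r, c)) {
              v = 0; break;
            }
          }
        }
        nxt(i, j) = v;
      }
    }
    cur = nxt;
  }
  return cur;
}

// Yokoi connectivity number for 8-connected foreground. n[8] holds the
// 8-neighbourhood in counterclockwise order starting east:
// E, NE, N, NW, W, SW, S, SE. The pixel is simple iff the number equals 1.
static inline int yokoi8(const int *n) {
  int c = 0;
  for (int k = 0; k < 8; k += 2) {
    int a = 1 - n[k];
    int b = (1 - n[k]) * (1 - n[(k + 1) % 8]) * (1 - n[(k + 2) % 8]);
    c += a - b;
  }
  return c;
}

// Sequential simple-point thinning with directional sub-passes (N, S, E, W
// border pixels in turn). Deleting only simple points preserves the
// 8-connected component structure exactly; requiring at least two foreground
// neighbours preserves line endpoints. Runs to idempotence.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix m = clone(mask);
  // direction offsets for the border test: N, S, E, W neighbour
  int ddr[4] = {-1, 1, 0, 0};
  int ddc[4] = {0, 0, 1, -1};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; ++d) {
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          if (!m(i, j)) continue;
          int br = i + ddr[d], bc = j + ddc[d];
          int bval = (br < 0 || br >= H || bc < 0 || bc >= W) ? 0 : m(br, bc);
          if (bval) continue;  // not a border pixel in this direction
          // gather neighbourhood: E, NE, N, NW, W, SW, S, SE
          int er[8] = {0, -1, -1, -1, 0, 1, 1, 1};
          int ec[8] = {1, 1, 0, -1, -1, -1, 0, 1};
          int n[8], B = 0;
          for (int k = 0; k < 8; ++k) {
            int r = i + er[k], c = j + ec[k];
            n[k] = (r < 0 || r >= H || c < 0 || c >= W) ? 0 : (m(r, c) ? 1 : 0);
            B += n[k];
          }
          if (B < 2) continue;        // keep endpoints and isolated pixels
          if (yokoi8(n) != 1) continue;  // not simple: would alter topology
          m(i, j) = 0;
          changed = true;
        }
      }
    }
  }
  return m;
}

// Flood fill: connected set of pixels whose value differs from the seed
// pixel's value by at most tol. conn is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_flood(NumericMatrix img, int seedRow, int seedCol,
                        double tol, int conn) {
  int H = img.nrow(), W = img.ncol();
  if (seedRow < 0 || seedRow >= H || seedCol < 0 || seedCol >= W)
    stop("seed outside image");
  if (conn != 4 && conn != 8) stop("conn must be 4 or 8");
  double v0 = img(seedRow, seedCol);
  IntegerMatrix out(H, W);
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(seedRow, seedCol));
  out(seedRow, seedCol) = 1;
  int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = conn == 4 ? dr4 : dr8;
  const int *dc = conn == 4 ? dc4 : dc8;
  while (!stack.empty()) {
    std::pair<int, int> p = stack.back();
    stack.pop_back();
    for (int k = 0; k < conn; ++k) {
      int r = p.first + dr[k], c = p.second + dc[k];
      if (r < 0 || r >= H || c < 0 || c >= W || out(r, c)) continue;
      if (std::fabs(img(r, c) - v0) <= tol) {
        out(r, c) = 1;
        stack.push_back(std::make_pair(r, c));
      }
    }
  }
  return out;
}

// Connected-component labelling of a binary mask (labels 1..n, 0 background).
// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix mask, int conn) {
  int H = mask.nrow(), W = mask.ncol();
  if (conn != 4 && conn != 8) stop("conn must be 4 or 8");
  IntegerMatrix lab(H, W);
  int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = conn == 4 ? dr4 : dr8;
  const int *dc = conn == 4 ? dc4 : dc8;
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(std::make_pair(i, j));
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < conn; ++k) {
          int r = p.first + dr[k], c = p.second + dc[k];
          if (r < 0 || r >= H || c < 0 || c >= W) continue;
          if (mask(r, c) && !lab(r, c)) {
            lab(r, c) = next;
            stack.push_back(std::make_pair(r, c));
          }
        }
      }
    }
  }
  return lab;
}

// Windowed texture statistics over square (2r+1)^2 neighbourhoods with edge
// replication (index clamping), for 8-bit images. Returns one row per pixel
// in column-major (R) order; columns are mean, median, variance, entropy for
// each radius in turn. Entropy is Shannon entropy (bits) of the 256-bin
// window histogram; variance uses the n divisor.
// [[Rcpp::export]]
NumericMatrix cpp_window_stats(IntegerMatrix img, IntegerVector radii) {
  int H = img.nrow(), W = img.ncol();
  int nr = radii.size();
  R_xlen_t npx = (R_xlen_t)H * W;
  NumericMatrix out(npx, 4 * nr);
  int rmax = 0;
  for (int k = 0; k < nr; ++k) {
    if (radii[k] < 1) stop("radii must be positive");
    if (radii[k] > rmax) rmax = radii[k];
  }
  int nmax = (2 * rmax + 1) * (2 * rmax + 1);
  std::vector<double> lut(nmax + 1, 0.0);  // c * log2(c)
  for (int c = 2; c <= nmax; ++c) lut[c] = c * std::log2((double)c);

  for (int k = 0; k < nr; ++k) {
    int r = radii[k];
    int side = 2 * r + 1, n = side * side;
    int khalf = (n + 1) / 2;
    double log2n = std::log2((double)n);
    int hist[256];
    for (int i = 0; i < H; ++i) {
      // initialise window at column 0
      std::fill(hist, hist + 256, 0);
      long long sum = 0, sumsq = 0;
      double entS = 0.0;
      for (int dx = -r; dx <= r; ++dx) {
        int c = clampi(dx, 0, W - 1);
        for (int dy = -r; dy <= r; ++dy) {
          int rr = clampi(i + dy, 0, H - 1);
          int v = img(rr, c);
          entS += lut[hist[v] + 1] - lut[hist[v]];
          hist[v]++;
          sum += v;
          sumsq += (long long)v * v;
        }
      }
      for (int j = 0; j < W; ++j) {
        if (j > 0) {
          int cOld = clampi(j - 1 - r, 0, W - 1);
          int cNew = clampi(j + r, 0, W - 1);
          for (int dy = -r; dy <= r; ++dy) {
            int rr = clampi(i + dy, 0, H - 1);
            int v = img(rr, cOld);
            entS += lut[hist[v] - 1] - lut[hist[v]];
            hist[v]--;
            sum -= v;
            sumsq -= (long long)v * v;
            v = img(rr, cNew);
            entS += lut[hist[v] + 1] - lut[hist[v]];
            hist[v]++;
            sum += v;
            sumsq += (long long)v * v;
          }
        }
        double mean = (double)sum / n;
        double var = ((double)sumsq - (double)sum * sum / n) / n;
        if (var < 0) var = 0;
        double ent = log2n - entS / n;
        if (ent < 1e-9) ent = 0;  // clear float residue on uniform windows
        int cum = 0, med = 0;
        for (int v = 0; v < 256; ++v) {
          cum += hist[v];
          if (cum >= khalf) { med = v; break; }
        }
        R_xlen_t row = (R_xlen_t)i + (R_xlen_t)j * H;
        out(row, 4 * k) = mean;
        out(row, 4 * k + 1) = med;
        out(row, 4 * k + 2) = var;
        out(row, 4 * k + 3) = ent;
      }
    }
  }
  return out;
}

// Separable Gaussian blur, kernel radius ceil(3*sigma), edge replication.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += kern[i + r];
  }
  for (int i = 0; i <= 2 * r; ++i) kern[i] /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double v = 0.0;
      for (int d = -r; d <= r; ++d) v += kern[d + r] * img(clampi(i + d, 0, H - 1), j);
      tmp(i, j) = v;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double v = 0.0;
      for (int d = -r; d <= r; ++d) v += kern[d + r] * tmp(i, clampi(j + d, 0, W - 1));
      out(i, j) = v;
    }
  return out;
}

// Moore-neighbour boundary trace of the component containing the topmost,
// leftmost foreground pixel. Returns the closed outer contour as 0-based
// (x, y) pixel centres, one row per contour pixel, clockwise, with Jacob's
// stopping criterion.
// [[Rcpp::export]]
IntegerMatrix cpp_trace_boundary(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  int si = -1, sj = -1;
  for (int i = 0; i < H && si < 0; ++i)
    for (int j = 0; j < W; ++j)
      if (mask(i, j)) { si = i; sj = j; break; }
  if (si < 0) return IntegerMatrix(0, 2);
  // Moore neighbourhood in clockwise order starting west:
  // W, NW, N, NE, E, SE, S, SW
  int mr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  int mc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  // reverse lookup from (dr+1, dc+1) to Moore index
  int ridx[3][3];
  for (int k = 0; k < 8; ++k) ridx[mr[k] + 1][mc[k] + 1] = k;
  bool any = false;
  for (int k = 0; k < 8; ++k) {
    int r = si + mr[k], c = sj + mc[k];
    if (r >= 0 && r < H && c >= 0 && c < W && mask(r, c)) { any = true; break; }
  }
  if (!any) {
    IntegerMatrix out(1, 2);
    out(0, 0) = sj; out(0, 1) = si;
    return out;
  }
  std::vector<std::pair<int, int> > contour;
  contour.push_back(std::make_pair(si, sj));
  int ci = si, cj = sj;
  int back = 0;  // start backtrack: the west neighbour (background or OOB)
  int firstMove = -1;
  size_t guard = (size_t)H * W * 8 + 16;
  while (guard--) {
    int found = -1, prevBg = back;
    for (int t = 1; t <= 8; ++t) {
      int k = (back + t) % 8;
      int r = ci + mr[k], c = cj + mc[k];
      if (r >= 0 && r < H && c >= 0 && c < W && mask(r, c)) { found = k; break; }
      prevBg = k;
    }
    if (found < 0) break;
    // background cell scanned just before the move, in absolute coords
    int pr = ci + mr[prevBg], pc = cj + mc[prevBg];
    bool atStart = (ci + mr[found] == si && cj + mc[found] == sj);
    if (atStart && firstMove >= 0 && found == firstMove) break;
    if (firstMove < 0) firstMove = found;
    ci += mr[found];
    cj += mc[found];
    if (!atStart) contour.push_back(std::make_pair(ci, cj));
    back = ridx[pr - ci + 1][pc - cj + 1];
  }
  IntegerMatrix out(contour.size(), 2);
  for (size_t k = 0; k < contour.size(); ++k) {
    out(k, 0) = contour[k].second;  // x = col
    out(k, 1) = contour[k].first;   // y = row
  }
  return out;
}
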