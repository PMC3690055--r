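// Frame-motion feature kernels: Sobel edge maps, Shi-Tomasi corners,
// pyramidal Lucas-Kanade tracking, and the synthetic pan renderer.
// Images are column-major R matrices (rows = y, cols = x), intensities 0-255.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Image {
  int h, w;
  std::vector<float> px; // column-major, px[x * h + y]
  float at(int y, int x) const { // replicate border
    if (y < 0) y = 0; else if (y >= h) y = h - 1;
    if (x < 0) x = 0; else if (x >= w) x = w - 1;
    return px[(size_t)x * h + y];
  }
  float atf(int y, int x) const { return px[(size_t)x * h + y]; }
  float &ref(int y, int x) { return px[(size_t)x * h + y]; }
  void alloc(int hh, int ww) { h = hh; w = ww; px.assign((size_t)h * w, 0.f); }
};

Image from_matrix(const NumericMatrix &m) {
  Image im;
  im.h = m.nrow(); im.w = m.ncol();
  im.px.assign(m.begin(), m.end());
  return im;
}

// bilinear sample, clamped to the border
inline float interp(const Image &im, float x, float y) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 < 0) x0 = 0; else if (x0 > im.w - 2) x0 = im.w - 2;
  if (y0 < 0) y0 = 0; else if (y0 > im.h - 2) y0 = im.h - 2;
  float ax = x - x0, ay = y - y0;
  if (ax < 0) ax = 0; else if (ax > 1) ax = 1;
  if (ay < 0) ay = 0; else if (ay > 1) ay = 1;
  const float *c0 = &im.px[(size_t)x0 * im.h + y0];
  const float *c1 = c0 + im.h;
  return (1 - ay) * ((1 - ax) * c0[0] + ax * c1[0]) +
         ay * ((1 - ax) * c0[1] + ax * c1[1]);
}

// 3x3 Sobel responses; replicate border
void sobel_xy(const Image &im, Image &gx, Image &gy) {
  gx.alloc(im.h, im.w);
  gy.alloc(im.h, im.w);
  const int h = im.h, w = im.w;
  for (int x = 1; x < w - 1; ++x) {
    const float *pl = &im.px[(size_t)(x - 1) * h];
    const float *pc = &im.px[(size_t)x * h];
    const float *pr = &im.px[(size_t)(x + 1) * h];
    float *ox = &gx.px[(size_t)x * h];
    float *oy = &gy.px[(size_t)x * h];
    for (int y = 1; y < h - 1; ++y) {
      ox[y] = (pr[y - 1] + 2 * pr[y] + pr[y + 1]) -
              (pl[y - 1] + 2 * pl[y] + pl[y + 1]);
      oy[y] = (pl[y + 1] + 2 * pc[y + 1] + pr[y + 1]) -
              (pl[y - 1] + 2 * pc[y - 1] + pr[y - 1]);
    }
  }
  for (int x = 0; x < w; ++x) { // borders via clamped access
    for (int y = 0; y < h; y += (x == 0 || x == w - 1) ? 1 : h - 1) {
      float a = im.at(y - 1, x - 1), b = im.at(y - 1, x), c = im.at(y - 1, x + 1);
      float d = im.at(y, x - 1), f = im.at(y, x + 1);
      float g = im.at(y + 1, x - 1), hh = im.at(y + 1, x), i = im.at(y + 1, x + 1);
      gx.ref(y, x) = (c + 2 * f + i) - (a + 2 * d + g);
      gy.ref(y, x) = (g + 2 * hh + i) - (a + 2 * b + c);
      if (h == 1) break;
    }
  }
}

Image sobel_mag(const Image &im) {
  Image gx, gy, out;
  sobel_xy(im, gx, gy);
  out.h = im.h; out.w = im.w;
  out.px.resize(im.px.size());
  for (size_t i = 0; i < im.px.size(); ++i)
    out.px[i] = std::sqrt(gx.px[i] * gx.px[i] + gy.px[i] * gy.px[i]);
  return out;
}

// downsample by 2 after [1 2 1]/4 separable smoothing
Image pyr_down(const Image &im) {
  const int h = im.h, w = im.w;
  Image tmp; tmp.alloc(h, w); // vertical pass
  for (int x = 0; x < w; ++x) {
    const float *p = &im.px[(size_t)x * h];
    float *o = &tmp.px[(size_t)x * h];
    o[0] = 0.75f * p[0] + 0.25f * p[1 < h ? 1 : 0];
    for (int y = 1; y < h - 1; ++y)
      o[y] = 0.25f * p[y - 1] + 0.5f * p[y] + 0.25f * p[y + 1];
    if (h > 1) o[h - 1] = 0.25f * p[h - 2] + 0.75f * p[h - 1];
  }
  Image tmp2; tmp2.alloc(h, w); // horizontal pass
  for (int x = 0; x < w; ++x) {
    int xl = x > 0 ? x - 1 : 0, xr = x < w - 1 ? x + 1 : w - 1;
    const float *pl = &tmp.px[(size_t)xl * h];
    const float *pc = &tmp.px[(size_t)x * h];
    const float *pr = &tmp.px[(size_t)xr * h];
    float *o = &tmp2.px[(size_t)x * h];
    for (int y = 0; y < h; ++y)
      o[y] = 0.25f * pl[y] + 0.5f * pc[y] + 0.25f * pr[y];
  }
  Image out; out.alloc((h + 1) / 2, (w + 1) / 2);
  for (int x = 0; x < out.w; ++x)
    for (int y = 0; y < out.h; ++y)
      out.ref(y, x) = tmp2.atf(std::min(2 * y, h - 1), std::min(2 * x, w - 1));
  return out;
}

// image pyramid with per-level central-difference gradient maps
struct Pyramid {
  std::vector<Image> img, gx, gy;
  void build(const Image &base, int levels) {
    img.clear(); gx.clear(); gy.clear();
    img.push_back(base);
    for (int l = 1; l < levels; ++l) img.push_back(pyr_down(img.back()));
    gx.resize(levels); gy.resize(levels);
    for (int l = 0; l < levels; ++l) {
      const Image &im = img[l];
      gx[l].alloc(im.h, im.w);
      gy[l].alloc(im.h, im.w);
      for (int x = 1; x < im.w - 1; ++x) {
        const float *pl = &im.px[(size_t)(x - 1) * im.h];
        const float *pc = &im.px[(size_t)x * im.h];
        const float *pr = &im.px[(size_t)(x + 1) * im.h];
        float *ox = &gx[l].px[(size_t)x * im.h];
        float *oy = &gy[l].px[(size_t)x * im.h];
        for (int y = 1; y < im.h - 1; ++y) {
          ox[y] = 0.5f * (pr[y] - pl[y]);
          oy[y] = 0.5f * (pc[y + 1] - pc[y - 1]);
        }
      }
    }
  }
};

struct Corner { float x, y, score; };

// Shi-Tomasi minimum-eigenvalue corners with 3x3 tensor window,
// non-maximum suppression and greedy min-distance thinning.
std::vector<Corner> detect_corners(const Image &im, int max_corners,
                                   double quality, double min_dist, int border) {
  Image gx, gy;
  sobel_xy(im, gx, gy);
  const int h = im.h, w = im.w;
  if (border < 2) border = 2;
  Image eig; eig.alloc(h, w);
  float maxeig = 0.f;
  for (int x = border; x < w - border; ++x) {
    float *e = &eig.px[(size_t)x * h];
    for (int y = border; y < h - border; ++y) {
      float sxx = 0, syy = 0, sxy = 0;
      for (int dx = -1; dx <= 1; ++dx) {
        const float *cgx = &gx.px[(size_t)(x + dx) * h + y];
        const float *cgy = &gy.px[(size_t)(x + dx) * h + y];
        for (int dy = -1; dy <= 1; ++dy) {
          float ix = cgx[dy], iy = cgy[dy];
          sxx += ix * ix; syy += iy * iy; sxy += ix * iy;
        }
      }
      float tr = sxx + syy;
      float det = std::sqrt((sxx - syy) * (sxx - syy) + 4 * sxy * sxy);
      float mev = 0.5f * (tr - det);
      e[y] = mev;
      if (mev > maxeig) maxeig = mev;
    }
  }
  std::vector<Corner> cand;
  float thr = (float)(quality * maxeig);
  for (int x = border; x < w - border; ++x) {
    const float *e = &eig.px[(size_t)x * h];
    for (int y = border; y < h - border; ++y) {
      float v = e[y];
      if (v < thr || v <= 0) continue;
      bool ismax = true;
      for (int dx = -1; dx <= 1 && ismax; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          if (eig.atf(y + dy, x + dx) > v) { ismax = false; break; }
      if (ismax) cand.push_back({(float)x, (float)y, v});
    }
  }
  std::sort(cand.begin(), cand.end(),
            [](const Corner &a, const Corner &b) { return a.score > b.score; });
  std::vector<Corner> out;
  double md2 = min_dist * min_dist;
  for (const Corner &c : cand) {
    bool ok = true;
    for (const Corner &o : out) {
      double dx = c.x - o.x, dy = c.y - o.y;
      if (dx * dx + dy * dy < md2) { ok = false; break; }
    }
    if (ok) {
      out.push_back(c);
      if ((int)out.size() >= max_corners) break;
    }
  }
  return out;
}

// Sample a win x win window centred at float (cx, cy) into out (column by
// column), with the bilinear weights hoisted out of the pixel loop. The
// centre is clamped so the window stays inside the image.
static void sample_window(const Image &im, float cx, float cy, int r, float *out) {
  float lo = (float)(r + 1);
  if (cx < lo) cx = lo;
  if (cx > im.w - r - 2.f) cx = (float)(im.w - r - 2);
  if (cy < lo) cy = lo;
  if (cy > im.h - r - 2.f) cy = (float)(im.h - r - 2);
  int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy);
  float ax = cx - x0, ay = cy - y0;
  float w00 = (1 - ax) * (1 - ay), w01 = ax * (1 - ay);
  float w10 = (1 - ax) * ay, w11 = ax * ay;
  const int n = 2 * r + 1;
  int k = 0;
  for (int u = -r; u <= r; ++u) {
    const float *c0 = &im.px[(size_t)(x0 + u) * im.h + (y0 - r)];
    const float *c1 = c0 + im.h;
    for (int v = 0; v < n; ++v, ++k)
      out[k] = w00 * c0[v] + w01 * c1[v] + w10 * c0[v + 1] + w11 * c1[v + 1];
  }
}

// pyramidal Lucas-Kanade: track one point from pyramid p0 into p1
bool lk_track_point(const Pyramid &p0, const Pyramid &p1,
                    float px, float py, int win, int max_iter, double eps,
                    float &dx_out, float &dy_out) {
  const int r = win / 2;
  const int npix = win * win;
  float gx_acc = 0.f, gy_acc = 0.f;
  const int levels = (int)p0.img.size();
  std::vector<float> T(npix), Ix(npix), Iy(npix), W(npix);
  const double eps2 = eps * eps;
  for (int L = levels - 1; L >= 0; --L) {
    const Image &I0 = p0.img[L], &I1 = p1.img[L];
    float cx = px / (float)(1 << L), cy = py / (float)(1 << L);
    // a window leaving the image at a coarse level skips that level
    // (tracking starts at the next finer one); at level 0 it is a failure
    if (cx < r + 1 || cy < r + 1 || cx > I0.w - r - 2 || cy > I0.h - r - 2) {
      if (L == 0) return false;
      gx_acc *= 2.f; gy_acc *= 2.f;
      continue;
    }
    sample_window(I0, cx, cy, r, T.data());
    sample_window(p0.gx[L], cx, cy, r, Ix.data());
    sample_window(p0.gy[L], cx, cy, r, Iy.data());
    float g11 = 0, g12 = 0, g22 = 0;
    for (int k = 0; k < npix; ++k) {
      g11 += Ix[k] * Ix[k]; g12 += Ix[k] * Iy[k]; g22 += Iy[k] * Iy[k];
    }
    float det = g11 * g22 - g12 * g12;
    float tr = g11 + g22;
    float mev = 0.5f * (tr - std::sqrt((g11 - g22) * (g11 - g22) + 4 * g12 * g12));
    if (det <= 1e-6f || mev < 1e-4f * npix) return false;
    float vx = 0.f, vy = 0.f;
    for (int it = 0; it < max_iter; ++it) {
      float tx = cx + gx_acc + vx, ty = cy + gy_acc + vy;
      if (tx < r + 1 || ty < r + 1 || tx > I1.w - r - 2 || ty > I1.h - r - 2) {
        if (L == 0) return false;
        break; // drifted out at a coarse level: hand over as-is
      }
      sample_window(I1, tx, ty, r, W.data());
      float b1 = 0, b2 = 0;
      for (int k = 0; k < npix; ++k) {
        float d = T[k] - W[k];
        b1 += d * Ix[k]; b2 += d * Iy[k];
      }
      float ddx = (g22 * b1 - g12 * b2) / det;
      float ddy = (g11 * b2 - g12 * b1) / det;
      vx += ddx; vy += ddy;
      if (ddx * ddx + ddy * ddy < eps2) break;
    }
    if (L > 0) { gx_acc = 2.f * (gx_acc + vx); gy_acc = 2.f * (gy_acc + vy); }
    else { gx_acc += vx; gy_acc += vy; }
  }
  dx_out = gx_acc; dy_out = gy_acc;
  return true;
}

double mean_abs_diff(const Image &a, const Image &b) {
  double s = 0;
  for (size_t i = 0; i < a.px.size(); ++i) s += std::fabs((double)a.px[i] - b.px[i]);
  return s / (double)a.px.size();
}

} // namespace

// [[Rcpp::export(name = ".cpp_sobel_mag")]]
NumericMatrix cpp_sobel_mag(NumericMatrix img) {
  Image im = from_matrix(img);
  Image out = sobel_mag(im);
  NumericMatrix res(im.h, im.w);
  std::copy(out.px.begin(), out.px.end(), res.begin());
  return res;
}

// [[Rcpp::export(name = ".cpp_corners")]]
NumericMatrix cpp_corners(NumericMatrix img, int max_corners, double quality,
                          double min_dist, int border) {
  Image im = from_matrix(img);
  std::vector<Corner> cs = detect_corners(im, max_corners, quality, min_dist, border);
  NumericMatrix res((int)cs.size(), 3);
  for (size_t i = 0; i < cs.size(); ++i) {
    res(i, 0) = cs[i].x; res(i, 1) = cs[i].y; res(i, 2) = cs[i].score;
  }
  colnames(res) = CharacterVector::create("x", "y", "score");
  return res;
}

// [[Rcpp::export(name = ".cpp_track")]]
NumericMatrix cpp_track(NumericMatrix prev, NumericMatrix nxt, NumericMatrix pts,
                        int win, int levels, int max_iter, double eps) {
  Pyramid p0, p1;
  p0.build(from_matrix(prev), levels);
  p1.build(from_matrix(nxt), levels);
  int n = pts.nrow();
  NumericMatrix res(n, 3);
  for (int i = 0; i < n; ++i) {
    float dx = 0, dy = 0;
    bool ok = lk_track_point(p0, p1, (float)pts(i, 0), (float)pts(i, 1),
                             win, max_iter, eps, dx, dy);
    res(i, 0) = dx; res(i, 1) = dy; res(i, 2) = ok ? 1.0 : 0.0;
  }
  colnames(res) = CharacterVector::create("dx", "dy", "status");
  return res;
}

// Per-pair features over a whole frame stack (h x w x n integer array).
// Columns: pixel_diff, edge_diff, mv_avg_mag, mv_count (min_mag applied).
// Edge maps and pyramids are computed once per frame and shared between
// the two pairs each frame participates in.
// [[Rcpp::export(name = ".cpp_video_features")]]
NumericMatrix cpp_video_features(IntegerVector frames, int max_corners,
                                 double quality, double min_dist, int win,
                                 int levels, int max_iter, double eps,
                                 double min_mag) {
  IntegerVector dim = frames.attr("dim");
  int h = dim[0], w = dim[1], n = dim[2];
  if (n < 2) stop("need at least two frames");
  // corners must keep their window inside the image at every pyramid level
  int border = (win / 2 + 2) << (levels - 1);
  while (border > 2 && (2 * border >= w - 2 || 2 * border >= h - 2)) border /= 2;
  NumericMatrix res(n - 1, 4);

  auto frame_at = [&](int i) {
    Image im; im.h = h; im.w = w;
    im.px.resize((size_t)h * w);
    const int *base = frames.begin() + (size_t)i * h * w;
    for (size_t k = 0; k < im.px.size(); ++k) im.px[k] = (float)base[k];
    return im;
  };

  Image cur = frame_at(0);
  Image cur_edge = sobel_mag(cur);
  Pyramid cur_pyr; cur_pyr.build(cur, levels);
  for (int i = 1; i < n; ++i) {
    Image nxt = frame_at(i);
    Image nxt_edge = sobel_mag(nxt);
    Pyramid nxt_pyr; nxt_pyr.build(nxt, levels);
    res(i - 1, 0) = mean_abs_diff(cur, nxt);
    res(i - 1, 1) = mean_abs_diff(cur_edge, nxt_edge);
    std::vector<Corner> cs = detect_corners(cur, max_corners, quality, min_dist, border);
    double mag_sum = 0; int cnt = 0;
    for (const Corner &c : cs) {
      float dx = 0, dy = 0;
      if (lk_track_point(cur_pyr, nxt_pyr, c.x, c.y, win, max_iter, eps, dx, dy)) {
        double mag = std::sqrt((double)dx * dx + (double)dy * dy);
        if (mag >= min_mag) { mag_sum += mag; ++cnt; }
      }
    }
    res(i - 1, 2) = cnt > 0 ? mag_sum / cnt : 0.0;
    res(i - 1, 3) = cnt;
    cur = std::move(nxt);
    cur_edge = std::move(nxt_edge);
    cur_pyr = std::move(nxt_pyr);
  }
  colnames(res) = CharacterVector::create("pixel_diff", "edge_diff",
                                          "mv_avg_mag", "mv_count");
  return res;
}

// Render frames by cropping a texture at float offsets with bilinear
// sampling. ox/oy are 0-based top-left positions of the crop window in the
// texture; the offset is constant within a frame, so the bilinear weights
// are hoisted out of the pixel loop.
// [[Rcpp::export(name = ".cpp_render_pan")]]
IntegerVector cpp_render_pan(NumericMatrix texture, NumericVector ox,
                             NumericVector oy, int w, int h) {
  Image tex = from_matrix(texture);
  int n = ox.size();
  IntegerVector out((size_t)h * w * n);
  out.attr("dim") = IntegerVector::create(h, w, n);
  for (int i = 0; i < n; ++i) {
    int x0 = (int)std::floor(ox[i]), y0 = (int)std::floor(oy[i]);
    float ax = (float)(ox[i] - x0), ay = (float)(oy[i] - y0);
    if (x0 < 0 || y0 < 0 || x0 + w + 1 > tex.w || y0 + h + 1 > tex.h)
      stop("crop window outside texture");
    float w00 = (1 - ax) * (1 - ay), w01 = ax * (1 - ay);
    float w10 = (1 - ax) * ay, w11 = ax * ay;
    int *base = out.begin() + (size_t)i * h * w;
    for (int x = 0; x < w; ++x) {
      const float *c0 = &tex.px[(size_t)(x0 + x) * tex.h + y0];
      const float *c1 = c0 + tex.h;
      int *o = base + (size_t)x * h;
      for (int y = 0; y < h; ++y) {
        float v = w00 * c0[y] + w01 * c1[y] + w10 * c0[y + 1] + w11 * c1[y + 1];
        int iv = (int)(v + 0.5f);
        if (iv < 0) iv = 0; else if (iv > 255) iv = 255;
        o[y] = iv;
      }
    }
  }
  return out;
}
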