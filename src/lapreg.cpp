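#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---- FAST-9/16 circle offsets (x = col, y = row), standard Bresenham circle r=3 ----
static const int CIRC_X[16] = { 0,  1,  2,  3,  3,  3,  2,  1,  0, -1, -2, -3, -3, -3, -2, -1};
static const int CIRC_Y[16] = {-3, -3, -2, -1,  0,  1,  2,  3,  3,  3,  2,  1,  0, -1, -2, -3};

// 256-pair binary test pattern in [-13,13]^2, generated once from a fixed LCG so the
// descriptor layout is identical on every platform.
static int PAT[256][4];
static bool pat_ready = false;
static void init_pattern() {
  if (pat_ready) return;
  uint64_t s = 88172645463325252ULL;
  for (int i = 0; i < 256; i++) {
    for (int k = 0; k < 4; k++) {
      // xorshift64
      s ^= s << 13; s ^= s >> 7; s ^= s << 17;
      PAT[i][k] = (int)(s % 27) - 13;
    }
  }
  pat_ready = true;
}

struct KP { int x; int y; double score; };

// [[Rcpp::export]]
List cpp_detect_orb(IntegerMatrix img, LogicalMatrix mask, int max_kp,
                    int fast_threshold, int border) {
  init_pattern();
  const int H = img.nrow(), W = img.ncol();
  std::vector<double> scoremap((size_t)H * W, 0.0);
  std::vector<KP> cands;

  // FAST-9/16 detection with a contrast score for ranking
  int circ[16];
  for (int y = 3; y < H - 3; y++) {
    for (int x = 3; x < W - 3; x++) {
      const int p = img(y, x);
      int nb = 0, nd = 0;
      for (int k = 0; k < 16; k++) {
        circ[k] = img(y + CIRC_Y[k], x + CIRC_X[k]);
        if (circ[k] > p + fast_threshold) nb++;
        else if (circ[k] < p - fast_threshold) nd++;
      }
      if (nb < 9 && nd < 9) continue;
      // check for 9 contiguous (wrap-around)
      bool corner = false;
      for (int sign = 0; sign < 2 && !corner; sign++) {
        int run = 0;
        for (int k = 0; k < 16 + 9; k++) {
          const int v = circ[k % 16];
          const bool on = sign == 0 ? (v > p + fast_threshold) : (v < p - fast_threshold);
          run = on ? run + 1 : 0;
          if (run >= 9) { corner = true; break; }
        }
      }
      if (!corner) continue;
      double sc = 0.0;
      for (int k = 0; k < 16; k++) {
        const double d = std::abs(circ[k] - p) - fast_threshold;
        if (d > 0) sc += d;
      }
      scoremap[(size_t)y * W + x] = sc;
    }
  }
  // 3x3 non-maximum suppression; keep masked, in-border maxima
  for (int y = 3; y < H - 3; y++) {
    for (int x = 3; x < W - 3; x++) {
      const double sc = scoremap[(size_t)y * W + x];
      if (sc <= 0) continue;
      bool ismax = true;
      for (int dy = -1; dy <= 1 && ismax; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (dx == 0 && dy == 0) continue;
          const double o = scoremap[(size_t)(y + dy) * W + (x + dx)];
          if (o > sc || (o == sc && (dy < 0 || (dy == 0 && dx < 0)))) { ismax = false; break; }
        }
      if (!ismax) continue;
      if (x < border || x >= W - border || y < border || y >= H - border) continue;
      if (!mask(y, x)) continue;
      KP k; k.x = x; k.y = y; k.score = sc;
      cands.push_back(k);
    }
  }
  std::sort(cands.begin(), cands.end(), [](const KP& a, const KP& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.y != b.y) return a.y < b.y;
    return a.x < b.x;
  });
  const int N = std::min((int)cands.size(), max_kp);

  NumericVector xs(N), ys(N), resp(N), ang(N);
  IntegerMatrix desc(N, 32);
  const int R_OR = 15; // orientation patch radius (intensity centroid)
  for (int i = 0; i < N; i++) {
    const int x = cands[i].x, y = cands[i].y;
    xs[i] = x; ys[i] = y; resp[i] = cands[i].score;
    double m01 = 0.0, m10 = 0.0;
    for (int dy = -R_OR; dy <= R_OR; dy++)
      for (int dx = -R_OR; dx <= R_OR; dx++) {
        if (dx * dx + dy * dy > R_OR * R_OR) continue;
        const double v = img(y + dy, x + dx);
        m10 += dx * v; m01 += dy * v;
      }
    const double theta = std::atan2(m01, m10);
    ang[i] = theta;
    const double c = std::cos(theta), s = std::sin(theta);
    int byte = 0, bit = 0, acc = 0;
    for (int k = 0; k < 256; k++) {
      const int x1 = (int)std::lround(PAT[k][0] * c - PAT[k][1] * s);
      const int y1 = (int)std::lround(PAT[k][0] * s + PAT[k][1] * c);
      const int x2 = (int)std::lround(PAT[k][2] * c - PAT[k][3] * s);
      const int y2 = (int)std::lround(PAT[k][2] * s + PAT[k][3] * c);
      const int v1 = img(y + y1, x + x1), v2 = img(y + y2, x + x2);
      if (v1 < v2) acc |= (1 << bit);
      if (++bit == 8) { desc(i, byte++) = acc; acc = 0; bit = 0; }
    }
  }
  return List::create(_["x"] = xs, _["y"] = ys, _["response"] = resp,
                      _["angle"] = ang, _["descriptors"] = desc);
}

// Nearest neighbour in b (by Hamming distance over byte rows) for every row of a.
// Ties resolved toward the smaller index. Returns 1-based indices.
// [[Rcpp::export]]
List cpp_hamming_nn(IntegerMatrix a, IntegerMatrix b) {
  const int na = a.nrow(), nb = b.nrow(), nbytes = a.ncol();
  if (b.ncol() != nbytes) stop("descriptor widths differ");
  IntegerVector idx(na), dist(na);
  std::vector<uint8_t> bb((size_t)nb * nbytes);
  for (int j = 0; j < nb; j++)
    for (int c = 0; c < nbytes; c++) bb[(size_t)j * nbytes + c] = (uint8_t)b(j, c);
  std::vector<uint8_t> arow(nbytes);
  for (int i = 0; i < na; i++) {
    for (int c = 0; c < nbytes; c++) arow[c] = (uint8_t)a(i, c);
    int best = -1, bestd = INT32_MAX;
    const uint8_t* bp = bb.data();
    for (int j = 0; j < nb; j++, bp += nbytes) {
      int d = 0;
      for (int c = 0; c < nbytes; c++) d += __builtin_popcount((unsigned)(arow[c] ^ bp[c]));
      if (d < bestd) { bestd = d; best = j; }
    }
    idx[i] = best + 1; dist[i] = bestd;
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Bilinear sampling of a single-channel image at 0-based (x, y) positions.
// valid marks samples whose position lies inside [0, W-1] x [0, H-1].
// [[Rcpp::export]]
List cpp_bilinear_sample(NumericMatrix img, NumericVector xs, NumericVector ys) {
  const int H = img.nrow(), W = img.ncol();
  const R_xlen_t n = xs.size();
  NumericVector out(n);
  LogicalVector valid(n);
  for (R_xlen_t i = 0; i < n; i++) {
    const double x = xs[i], y = ys[i];
    if (!(x >= 0.0 && x <= W - 1.0 && y >= 0.0 && y <= H - 1.0)) {
      out[i] = NA_REAL; valid[i] = false; continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    if (x0 > W - 2) x0 = W - 2;
    if (y0 > H - 2) y0 = H - 2;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    const double fx = x - x0, fy = y - y0;
    out[i] = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x0 + 1)) +
             fy * ((1 - fx) * img(y0 + 1, x0) + fx * img(y0 + 1, x0 + 1));
    valid[i] = true;
  }
  return List::create(_["values"] = out, _["valid"] = valid);
}
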