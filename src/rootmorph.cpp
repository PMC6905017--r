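#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Windowed median with truncated windows at the image border and the lower
// median for even-count windows (deterministic integer output).
// [[Rcpp::export]]
IntegerMatrix cpp_median_filter(const IntegerMatrix& img, int wh, int ww) {
  const int H = img.nrow(), W = img.ncol();
  const int hr = wh / 2, hc = ww / 2;
  IntegerMatrix out(H, W);
  std::vector<int> buf;
  buf.reserve(wh * ww);
  for (int r = 0; r < H; ++r) {
    const int r0 = std::max(0, r - hr), r1 = std::min(H - 1, r + hr);
    for (int c = 0; c < W; ++c) {
      const int c0 = std::max(0, c - hc), c1 = std::min(W - 1, c + hc);
      buf.clear();
      for (int cc = c0; cc <= c1; ++cc)
        for (int rr = r0; rr <= r1; ++rr)
          buf.push_back(img(rr, cc));
      const int k = (static_cast<int>(buf.size()) - 1) / 2;  // lower median
      std::nth_element(buf.begin(), buf.begin() + k, buf.end());
      out(r, c) = buf[k];
    }
  }
  return out;
}

// Minkowski dilation: stamp the structuring element over every foreground
// pixel. Off-image contributions are discarded (image support is the window).
// [[Rcpp::export]]
IntegerMatrix cpp_dilate(const IntegerMatrix& a, const IntegerMatrix& se) {
  const int H = a.nrow(), W = a.ncol();
  const int sh = se.nrow(), sw = se.ncol();
  const int hr = sh / 2, hc = sw / 2;
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (a(r, c) == 0) continue;
      for (int j = 0; j < sw; ++j)
        for (int i = 0; i < sh; ++i) {
          if (se(i, j) == 0) continue;
          const int rr = r + i - hr, cc = c + j - hc;
          if (rr >= 0 && rr < H && cc >= 0 && cc < W) out(rr, cc) = 1;
        }
    }
  return out;
}

// Set-theoretic erosion: z survives iff every element cell, translated to z,
// lands on foreground. Cells outside the image count as background.
// [[Rcpp::export]]
IntegerMatrix cpp_erode(const IntegerMatrix& a, const IntegerMatrix& se) {
  const int H = a.nrow(), W = a.ncol();
  const int sh = se.nrow(), sw = se.ncol();
  const int hr = sh / 2, hc = sw / 2;
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      bool ok = true;
      for (int j = 0; j < sw && ok; ++j)
        for (int i = 0; i < sh && ok; ++i) {
          if (se(i, j) == 0) continue;
          const int rr = r + i - hr, cc = c + j - hc;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W || a(rr, cc) == 0)
            ok = false;
        }
      out(r, c) = ok ? 1 : 0;
    }
  return out;
}

static inline int px(const IntegerMatrix& m, int r, int c) {
  if (r < 0 || r >= m.nrow() || c < 0 || c >= m.ncol()) return 0;
  return m(r, c) != 0 ? 1 : 0;
}

// Neighbours in Zhang-Suen order P2..P9: N, NE, E, SE, S, SW, W, NW.
static void neighbours(const IntegerMatrix& m, int r, int c, int* p) {
  p[0] = px(m, r - 1, c);     p[1] = px(m, r - 1, c + 1);
  p[2] = px(m, r, c + 1);     p[3] = px(m, r + 1, c + 1);
  p[4] = px(m, r + 1, c);     p[5] = px(m, r + 1, c - 1);
  p[6] = px(m, r, c - 1);     p[7] = px(m, r - 1, c - 1);
}

static inline int transitions(const int* p) {
  int a = 0;
  for (int i = 0; i < 8; ++i) a += (p[i] == 0 && p[(i + 1) % 8] == 1);
  return a;
}

// Zhang-Suen thinning followed by a sequential cleanup pass that removes
// deletable pixels from any remaining 2x2 foreground blocks, so the skeleton
// satisfies the one-pixel-width (no solid 2x2 block) invariant.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(const IntegerMatrix& a) {
  const int H = a.nrow(), W = a.ncol();
  IntegerMatrix m = clone(a);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) m(r, c) = m(r, c) != 0 ? 1 : 0;

  // Classic two-subiteration parallel peeling: candidates are evaluated on
  // the pass-start snapshot, so exactly one boundary layer peels per pass
  // and the skeleton stays centred. When the kill list is applied, a pixel
  // whose neighbours have all just been deleted is kept: this is inert for
  // ordinary layer peeling but prevents the pure-parallel pathology of
  // annihilating a small component outright (e.g. a 2 x 2 remnant of a
  // disk losing all four pixels at once).
  int p[8];
  bool changed = true;
  int guard = 0;
  while (changed && guard++ < 4 * (H + W)) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      IntegerMatrix snap = clone(m);
      std::vector<std::pair<int, int> > cand;
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          if (snap(r, c) == 0) continue;
          neighbours(snap, r, c, p);
          int b = 0;
          for (int i = 0; i < 8; ++i) b += p[i];
          if (b < 2 || b > 6) continue;
          if (transitions(p) != 1) continue;
          // p[0]=P2(N), p[2]=P4(E), p[4]=P6(S), p[6]=P8(W)
          if (sub == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          cand.push_back(std::make_pair(r, c));
        }
      for (size_t i = 0; i < cand.size(); ++i) {
        const int r = cand[i].first, c = cand[i].second;
        neighbours(m, r, c, p);
        int b = 0;
        for (int k = 0; k < 8; ++k) b += p[k];
        if (b < 1) continue;  // last pixel of its component: keep it
        m(r, c) = 0;
        changed = true;
      }
    }
  }

  // Cleanup: sequentially delete simple pixels belonging to 2x2 blocks.
  for (int pass = 0; pass < 8; ++pass) {
    bool any = false;
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        if (m(r, c) == 0) continue;
        bool inblock = false;
        for (int dr = -1; dr <= 0 && !inblock; ++dr)
          for (int dc = -1; dc <= 0 && !inblock; ++dc)
            if (px(m, r + dr, c + dc) && px(m, r + dr + 1, c + dc) &&
                px(m, r + dr, c + dc + 1) && px(m, r + dr + 1, c + dc + 1))
              inblock = true;
        if (!inblock) continue;
        neighbours(m, r, c, p);
        int b = 0;
        for (int i = 0; i < 8; ++i) b += p[i];
        if (b >= 2 && transitions(p) == 1) { m(r, c) = 0; any = true; }
      }
    if (!any) break;
  }
  return m;
}

// Chain-code step counts over the skeleton adjacency graph, each edge once.
// Axial edges (distance 1) -> N1. A diagonal edge (distance sqrt 2) is counted
// only when both shared orthogonal neighbours are background; otherwise the
// path runs through the axial neighbour and the diagonal is a shortcut chord.
// [[Rcpp::export]]
IntegerVector cpp_chain_counts(const IntegerMatrix& s) {
  const int H = s.nrow(), W = s.ncol();
  int n1 = 0, n2 = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (px(s, r, c) == 0) continue;
      if (px(s, r, c + 1)) ++n1;      // east
      if (px(s, r + 1, c)) ++n1;      // south
      if (px(s, r + 1, c + 1) && !px(s, r, c + 1) && !px(s, r + 1, c))
        ++n2;                         // south-east
      if (px(s, r + 1, c - 1) && !px(s, r, c - 1) && !px(s, r + 1, c))
        ++n2;                         // south-west
    }
  return IntegerVector::create(Named("n1") = n1, Named("n2") = n2);
}
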