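// Core raster primitives: 8-connected labelling, per-component morphology,
// 5x5 chamfer distance transform, marker-constrained watershed and the
// multi-threshold score-map sweep. Matrices follow R conventions: column-major,
// (row, col) = (y, x), 0-based on the C++ side.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// chamfer step weights: orthogonal, diagonal, knight move (5x5 neighbourhood)
static const double CH_A = 1.0, CH_B = 1.4, CH_C = 2.1969;

// ---------------------------------------------------------------- labelling

static int labelBuffer(const std::vector<char>& mask, int nr, int nc,
                       std::vector<int>& lab) {
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      int p = i + j * nr;
      if (!mask[p] || lab[p]) continue;
      ++next;
      lab[p] = next;
      stack.push_back(p);
      while (!stack.empty()) {
        int q = stack.back();
        stack.pop_back();
        int qi = q % nr, qj = q / nr;
        for (int k = 0; k < 8; ++k) {
          int ni = qi + DR8[k], nj = qj + DC8[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          int np = ni + nj * nr;
          if (mask[np] && !lab[np]) {
            lab[np] = next;
            stack.push_back(np);
          }
        }
      }
    }
  }
  return next;
}

// [[Rcpp::export(name = ".ccLabel8")]]
IntegerMatrix ccLabel8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> m((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      m[i + (size_t)j * nr] = (mask(i, j) == TRUE);
  std::vector<int> lab((size_t)nr * nc);
  int n = labelBuffer(m, nr, nc, lab);
  IntegerMatrix out(nr, nc);
  std::copy(lab.begin(), lab.end(), out.begin());
  out.attr("nlab") = n;
  return out;
}

// ------------------------------------------------------- hole (hollowness)

// Fills holeArea[l] with the total area of background regions enclosed by
// component l. Background connectivity is 4 (dual of 8-connected foreground).
static void holeAreas(const std::vector<int>& lab, int nr, int nc, int nlab,
                      std::vector<double>& holeArea) {
  holeArea.assign(nlab + 1, 0.0);
  std::vector<char> vis((size_t)nr * nc, 0);
  std::vector<int> stack;
  // flood outer background from the border
  for (int i = 0; i < nr; ++i)
    for (int j : {0, nc - 1}) {
      int p = i + j * nr;
      if (!lab[p] && !vis[p]) { vis[p] = 1; stack.push_back(p); }
    }
  for (int j = 0; j < nc; ++j)
    for (int i : {0, nr - 1}) {
      int p = i + j * nr;
      if (!lab[p] && !vis[p]) { vis[p] = 1; stack.push_back(p); }
    }
  static const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    int p = stack.back();
    stack.pop_back();
    int pi = p % nr, pj = p / nr;
    for (int k = 0; k < 4; ++k) {
      int ni = pi + dr4[k], nj = pj + dc4[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      int np = ni + nj * nr;
      if (!lab[np] && !vis[np]) { vis[np] = 1; stack.push_back(np); }
    }
  }
  // remaining background = holes; attribute each hole to the smallest
  // adjacent label (holes of distinct components cannot merge)
  std::vector<int> hole;
  for (int j0 = 0; j0 < nc; ++j0)
    for (int i0 = 0; i0 < nr; ++i0) {
      int p0 = i0 + j0 * nr;
      if (lab[p0] || vis[p0]) continue;
      hole.clear();
      vis[p0] = 1;
      stack.push_back(p0);
      int owner = 0;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        hole.push_back(p);
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < 8; ++k) {
          int ni = pi + DR8[k], nj = pj + DC8[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          int np = ni + nj * nr;
          if (lab[np]) {
            if (owner == 0 || lab[np] < owner) owner = lab[np];
          } else if (!vis[np] && DR8[k] * DC8[k] == 0) {
            vis[np] = 1;
            stack.push_back(np);
          }
        }
      }
      if (owner > 0) holeArea[owner] += (double)hole.size();
    }
}

// ------------------------------------------------------- perimeter (Moore)

// Outer-contour arc length by Moore-neighbour tracing with backtracking;
// orthogonal steps weigh 1, diagonal steps sqrt(2). Isolated pixel -> 1.
static double moorePerimeter(const std::vector<int>& lab, int nr, int nc,
                             int L, int si, int sj) {
  static const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  static const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};  // N NE E SE S SW W NW
  auto isL = [&](int i, int j) {
    return i >= 0 && i < nr && j >= 0 && j < nc && lab[i + (size_t)j * nr] == L;
  };
  bool alone = true;
  for (int k = 0; k < 8; ++k)
    if (isL(si + dr[k], sj + dc[k])) { alone = false; break; }
  if (alone) return 1.0;

  double per = 0.0;
  int ci = si, cj = sj;
  int bk = 6;  // start pixel is topmost-leftmost: its W neighbour is background
  int firstFound = -1;
  long maxIter = 4L * nr * nc + 16;
  for (long it = 0; it < maxIter; ++it) {
    int found = -1;
    for (int s = 1; s <= 8; ++s) {
      int k = (bk + s) % 8;
      if (isL(ci + dr[k], cj + dc[k])) { found = k; break; }
    }
    if (found < 0) break;
    // Jacob's criterion: stop when the first transition out of the start
    // pixel repeats (the artificial initial backtrack state need not recur)
    if (it > 0 && ci == si && cj == sj && found == firstFound) break;
    if (it == 0) firstFound = found;
    int ni = ci + dr[found], nj = cj + dc[found];
    int pb = (found + 7) % 8;                 // last background cell scanned
    int bi = ci + dr[pb], bj = cj + dc[pb];
    int ddr = bi - ni, ddc = bj - nj, nbk = 0;
    for (int k = 0; k < 8; ++k)
      if (dr[k] == ddr && dc[k] == ddc) { nbk = k; break; }
    per += (dr[found] != 0 && dc[found] != 0) ? M_SQRT2 : 1.0;
    ci = ni; cj = nj; bk = nbk;
  }
  return std::max(per, 1.0);
}

// ----------------------------------------------------------- convex hull

struct Pt { double x, y; };

static double cross3(const Pt& o, const Pt& a, const Pt& b) {
  return (a.x - o.x) * (b.y - o.y) - (a.y - o.y) * (b.x - o.x);
}

// Monotone-chain hull area over boundary pixel centres
static double hullArea(std::vector<Pt>& pts) {
  size_t n = pts.size();
  if (n < 3) return 0.0;
  std::sort(pts.begin(), pts.end(), [](const Pt& a, const Pt& b) {
    return a.x < b.x || (a.x == b.x && a.y < b.y);
  });
  pts.erase(std::unique(pts.begin(), pts.end(), [](const Pt& a, const Pt& b) {
              return a.x == b.x && a.y == b.y;
            }), pts.end());
  n = pts.size();
  if (n < 3) return 0.0;
  std::vector<Pt> h(2 * n);
  size_t k = 0;
  for (size_t i = 0; i < n; ++i) {
    while (k >= 2 && cross3(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  size_t lower = k + 1;
  for (size_t i = n - 1; i-- > 0;) {
    while (k >= lower && cross3(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  h.resize(k - 1);
  double a = 0.0;
  for (size_t i = 0; i < h.size(); ++i) {
    const Pt& p = h[i];
    const Pt& q = h[(i + 1) % h.size()];
    a += p.x * q.y - q.x * p.y;
  }
  return std::fabs(a) / 2.0;
}

// ----------------------------------------------------------- full features

// [[Rcpp::export(name = ".regionFeaturesCpp")]]
NumericMatrix regionFeaturesCpp(IntegerMatrix labmat, int nlab) {
  int nr = labmat.nrow(), nc = labmat.ncol();
  std::vector<int> lab((size_t)nr * nc);
  std::copy(labmat.begin(), labmat.end(), lab.begin());

  std::vector<double> area(nlab + 1, 0), sx(nlab + 1, 0), sy(nlab + 1, 0),
      sxx(nlab + 1, 0), syy(nlab + 1, 0), sxy(nlab + 1, 0);
  std::vector<int> startI(nlab + 1, -1), startJ(nlab + 1, -1);
  std::vector<std::vector<Pt>> corners(nlab + 1);

  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      int L = lab[i + (size_t)j * nr];
      if (!L) continue;
      double x = j, y = i;
      area[L] += 1; sx[L] += x; sy[L] += y;
      sxx[L] += x * x; syy[L] += y * y; sxy[L] += x * y;
      if (startI[L] < 0) { startI[L] = i; startJ[L] = j; }
      bool boundary = false;
      for (int k = 0; k < 8 && !boundary; ++k) {
        int ni = i + DR8[k], nj = j + DC8[k];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc ||
            lab[ni + (size_t)nj * nr] != L)
          boundary = true;
      }
      if (boundary) corners[L].push_back({x, y});
    }
  }

  std::vector<double> holes;
  holeAreas(lab, nr, nc, nlab, holes);

  NumericMatrix out(nlab, 10);
  colnames(out) = CharacterVector::create(
      "area", "perimeter", "convex_area", "convexity", "aspect_ratio",
      "hollowness", "equiv_radius", "circularity", "cx", "cy");
  for (int L = 1; L <= nlab; ++L) {
    double a = area[L];
    double per = moorePerimeter(lab, nr, nc, L, startI[L], startJ[L]);
    double ha = hullArea(corners[L]);
    if (ha < a) ha = a;  // hull over pixel corners always covers the pixels
    double mx = sx[L] / a, my = sy[L] / a;
    // pixel-extent variance (1/12) regularises degenerate components
    double cxx = sxx[L] / a - mx * mx + 1.0 / 12.0;
    double cyy = syy[L] / a - my * my + 1.0 / 12.0;
    double cxy = sxy[L] / a - mx * my;
    double tr = (cxx + cyy) / 2.0;
    double det = std::sqrt(std::max(0.0, (cxx - cyy) * (cxx - cyy) / 4.0 + cxy * cxy));
    double l1 = tr + det, l2 = std::max(tr - det, 1e-9);
    out(L - 1, 0) = a;
    out(L - 1, 1) = per;
    out(L - 1, 2) = ha;
    out(L - 1, 3) = std::min(1.0, a / ha);
    out(L - 1, 4) = std::sqrt(l1 / l2);
    out(L - 1, 5) = holes[L] / a;
    out(L - 1, 6) = std::sqrt(a / M_PI);
    out(L - 1, 7) = 4.0 * M_PI * a / (per * per);
    out(L - 1, 8) = mx;
    out(L - 1, 9) = my;
  }
  return out;
}

// ----------------------------------------------------------- score map

// Multi-threshold sweep: binarise at each threshold, label 8-connected
// components, screen with the reject-stage rules (minimal equivalent radius,
// aspect ratio, hollowness) and add one vote per pixel of every surviving
// component. Mirrors screenRegion() on the R side.
// [[Rcpp::export(name = ".scoremapCpp")]]
IntegerMatrix scoremapCpp(NumericMatrix grey, NumericVector thresholds,
                          double rMin, double aspectMax, double hollowMax) {
  int nr = grey.nrow(), nc = grey.ncol();
  size_t np = (size_t)nr * nc;
  IntegerMatrix votes(nr, nc);
  std::vector<char> mask(np);
  std::vector<int> lab(np);
  double minArea = M_PI * rMin * rMin;

  for (int ti = 0; ti < thresholds.size(); ++ti) {
    double t = thresholds[ti];
    bool any = false;
    for (size_t p = 0; p < np; ++p) {
      mask[p] = grey[p] >= t;
      any = any || mask[p];
    }
    if (!any) continue;
    int nlab = labelBuffer(mask, nr, nc, lab);
    if (!nlab) continue;

    std::vector<double> area(nlab + 1, 0), sx(nlab + 1, 0), sy(nlab + 1, 0),
        sxx(nlab + 1, 0), syy(nlab + 1, 0), sxy(nlab + 1, 0);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        int L = lab[i + (size_t)j * nr];
        if (!L) continue;
        double x = j, y = i;
        area[L] += 1; sx[L] += x; sy[L] += y;
        sxx[L] += x * x; syy[L] += y * y; sxy[L] += x * y;
      }
    std::vector<double> holes;
    holeAreas(lab, nr, nc, nlab, holes);

    std::vector<char> pass(nlab + 1, 0);
    bool anyPass = false;
    for (int L = 1; L <= nlab; ++L) {
      double a = area[L];
      if (a < minArea) continue;
      double mx = sx[L] / a, my = sy[L] / a;
      double cxx = sxx[L] / a - mx * mx + 1.0 / 12.0;
      double cyy = syy[L] / a - my * my + 1.0 / 12.0;
      double cxy = sxy[L] / a - mx * my;
      double tr = (cxx + cyy) / 2.0;
      double det = std::sqrt(std::max(0.0, (cxx - cyy) * (cxx - cyy) / 4.0 + cxy * cxy));
      double aspect = std::sqrt((tr + det) / std::max(tr - det, 1e-9));
      if (aspect > aspectMax) continue;
      if (holes[L] / a > hollowMax) continue;
      pass[L] = 1;
      anyPass = true;
    }
    if (!anyPass) continue;
    for (size_t p = 0; p < np; ++p)
      if (lab[p] && pass[lab[p]]) ++votes[p];
  }
  return votes;
}

// ----------------------------------------------------------- chamfer

// Two-pass chamfer distance transform on a 5x5 neighbourhood,
// a = 1 (orthogonal), b = 1.4 (diagonal), c = 2.1969 (knight move).
// [[Rcpp::export(name = ".chamferCpp")]]
NumericMatrix chamferCpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double BIG = 1e15;
  NumericMatrix d(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      d(i, j) = mask(i, j) ? BIG : 0.0;

  static const int fr[8] = {0, -1, -1, -1, -1, -1, -2, -2};
  static const int fc[8] = {-1, 0, -1, 1, -2, 2, -1, 1};
  static const double fw[8] = {CH_A, CH_A, CH_B, CH_B, CH_C, CH_C, CH_C, CH_C};

  // distances are measured to in-image background pixels; masks handed to
  // the watershed always carry a background rim, so no border special-case
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      for (int k = 0; k < 8; ++k) {
        int ni = i + fr[k], nj = j + fc[k];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        double w = d(ni, nj) + fw[k];
        if (w < v) v = w;
      }
      d(i, j) = v;
    }
  for (int i = nr - 1; i >= 0; --i)
    for (int j = nc - 1; j >= 0; --j) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      for (int k = 0; k < 8; ++k) {
        int ni = i - fr[k], nj = j - fc[k];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        double w = d(ni, nj) + fw[k];
        if (w < v) v = w;
      }
      d(i, j) = v;
    }
  return d;
}

// Closed-form chamfer metric between two points on an obstacle-free grid.
// [[Rcpp::export(name = ".chamferPointCpp")]]
double chamferPointCpp(double dr, double dc) {
  double x = std::fabs(dr), y = std::fabs(dc);
  if (y > x) std::swap(x, y);
  if (x >= 2.0 * y) return CH_C * y + CH_A * (x - 2.0 * y);
  return CH_C * (x - y) + CH_B * (2.0 * y - x);
}

// ----------------------------------------------------------- watershed

struct Claim {
  double v, md;
  int r, c, lab;
};
struct ClaimCmp {
  bool operator()(const Claim& a, const Claim& b) const {
    if (a.v != b.v) return a.v < b.v;    // top() = highest distance value
    if (a.md != b.md) return a.md > b.md;  // then nearest marker wins ties
    if (a.r != b.r) return a.r > b.r;    // then (row, column) scan order
    if (a.c != b.c) return a.c > b.c;
    return a.lab > b.lab;
  }
};

// Marker-constrained watershed on a distance map. Regions grow downhill-or-
// flat from their markers; a region may not exceed kappaArea*pi*peak^2 pixels
// nor claim pixels farther (chamfer point metric) than kappaDist*peak from
// its original marker. markers: n x 3 matrix (row, col, peak), 1-based.
// [[Rcpp::export(name = ".watershedCpp")]]
IntegerMatrix watershedCpp(NumericMatrix dist, NumericMatrix markers,
                           double kappaArea, double kappaDist) {
  int nr = dist.nrow(), nc = dist.ncol();
  int nm = markers.nrow();
  IntegerMatrix lab(nr, nc);
  std::vector<double> peak(nm + 1, 0), areaLim(nm + 1, 0), distLim(nm + 1, 0);
  std::vector<int> mr(nm + 1, 0), mc(nm + 1, 0), area(nm + 1, 0);
  std::priority_queue<Claim, std::vector<Claim>, ClaimCmp> pq;

  for (int m = 0; m < nm; ++m) {
    int L = m + 1;
    mr[L] = (int)markers(m, 0) - 1;
    mc[L] = (int)markers(m, 1) - 1;
    peak[L] = markers(m, 2);
    areaLim[L] = kappaArea * M_PI * peak[L] * peak[L];
    distLim[L] = kappaDist * peak[L];
    pq.push({dist(mr[L], mc[L]), 0.0, mr[L], mc[L], L});
  }

  while (!pq.empty()) {
    Claim cl = pq.top();
    pq.pop();
    if (lab(cl.r, cl.c)) continue;
    int L = cl.lab;
    if (area[L] + 1 > areaLim[L]) continue;
    if (cl.md >= distLim[L] && !(cl.r == mr[L] && cl.c == mc[L])) continue;
    lab(cl.r, cl.c) = L;
    ++area[L];
    double v = dist(cl.r, cl.c);
    for (int k = 0; k < 8; ++k) {
      int ni = cl.r + DR8[k], nj = cl.c + DC8[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (lab(ni, nj)) continue;
      double nv = dist(ni, nj);
      if (nv <= 0.0 || nv > v) continue;  // downhill-or-flat growth only
      pq.push({nv, chamferPointCpp(ni - mr[L], nj - mc[L]), ni, nj, L});
    }
  }
  return lab;
}
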