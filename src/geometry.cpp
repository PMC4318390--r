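// Exact smallest enclosing ball (Welzl) and branch-and-bound best-match
// search. All coordinates are Angstrom; balls are exact up to ~1e-12
// relative tolerance on containment checks.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Ball {
  double c[3];
  double r;  // < 0 means "empty"
};

inline double dist2(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

inline bool contains(const Ball& B, const double* p, double eps) {
  if (B.r < 0) return false;
  double rr = B.r + eps;
  return dist2(B.c, p) <= rr * rr;
}

Ball ball_empty() { Ball b; b.c[0] = b.c[1] = b.c[2] = 0.0; b.r = -1.0; return b; }

Ball ball1(const double* p) {
  Ball b; b.c[0] = p[0]; b.c[1] = p[1]; b.c[2] = p[2]; b.r = 0.0; return b;
}

Ball ball2(const double* p, const double* q) {
  Ball b;
  for (int i = 0; i < 3; ++i) b.c[i] = 0.5 * (p[i] + q[i]);
  b.r = 0.5 * std::sqrt(dist2(p, q));
  return b;
}

inline void cross(const double* u, const double* v, double* w) {
  w[0] = u[1] * v[2] - u[2] * v[1];
  w[1] = u[2] * v[0] - u[0] * v[2];
  w[2] = u[0] * v[1] - u[1] * v[0];
}

// circumscribed circle of a triangle in 3D (all three on the boundary);
// invalid (r < 0) when the points are collinear
Ball ball3(const double* a, const double* b, const double* c) {
  double B[3], C[3];
  for (int i = 0; i < 3; ++i) { B[i] = b[i] - a[i]; C[i] = c[i] - a[i]; }
  double B2 = B[0]*B[0] + B[1]*B[1] + B[2]*B[2];
  double C2 = C[0]*C[0] + C[1]*C[1] + C[2]*C[2];
  double BxC[3];
  cross(B, C, BxC);
  double denom = 2.0 * (BxC[0]*BxC[0] + BxC[1]*BxC[1] + BxC[2]*BxC[2]);
  double scale = std::max({B2, C2, 1e-12});
  if (denom <= 1e-12 * scale * scale) return ball_empty();
  double t[3] = { B2 * C[0] - C2 * B[0], B2 * C[1] - C2 * B[1], B2 * C[2] - C2 * B[2] };
  double off[3];
  cross(t, BxC, off);
  Ball out;
  double r2 = 0.0;
  for (int i = 0; i < 3; ++i) {
    off[i] /= denom;
    out.c[i] = a[i] + off[i];
    r2 += off[i] * off[i];
  }
  out.r = std::sqrt(r2);
  return out;
}

// circumscribed sphere of four points; invalid when coplanar
Ball ball4(const double* a, const double* b, const double* c, const double* d) {
  double M[3][3], rhs[3];
  const double* pts[3] = { b, c, d };
  for (int i = 0; i < 3; ++i) {
    rhs[i] = 0.0;
    for (int j = 0; j < 3; ++j) {
      M[i][j] = pts[i][j] - a[j];
      rhs[i] += (pts[i][j] * pts[i][j] - a[j] * a[j]);
    }
    rhs[i] *= 0.5;
  }
  double det =
      M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
      M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
      M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
  double scale = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) scale = std::max(scale, std::fabs(M[i][j]));
  if (std::fabs(det) <= 1e-10 * std::max(scale * scale * scale, 1e-12)) return ball_empty();
  Ball out;
  for (int k = 0; k < 3; ++k) {
    double Mk[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) Mk[i][j] = (j == k) ? rhs[i] : M[i][j];
    double dk =
        Mk[0][0] * (Mk[1][1] * Mk[2][2] - Mk[1][2] * Mk[2][1]) -
        Mk[0][1] * (Mk[1][0] * Mk[2][2] - Mk[1][2] * Mk[2][0]) +
        Mk[0][2] * (Mk[1][0] * Mk[2][1] - Mk[1][1] * Mk[2][0]);
    out.c[k] = dk / det;
  }
  out.r = std::sqrt(dist2(out.c, a));
  return out;
}

const double EPS = 1e-10;

// exact minimum enclosing ball of at most 4 points: smallest candidate
// ball determined by a subset that contains them all
Ball meb_upto4(const std::vector<const double*>& P) {
  int n = (int)P.size();
  if (n == 0) return ball_empty();
  Ball best = ball_empty();
  auto consider = [&](const Ball& b) {
    if (b.r < 0) return;
    for (int i = 0; i < n; ++i)
      if (!contains(b, P[i], EPS)) return;
    if (best.r < 0 || b.r < best.r) best = b;
  };
  for (int i = 0; i < n; ++i) consider(ball1(P[i]));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) consider(ball2(P[i], P[j]));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      for (int k = j + 1; k < n; ++k) consider(ball3(P[i], P[j], P[k]));
  if (n == 4) consider(ball4(P[0], P[1], P[2], P[3]));
  return best;
}

Ball welzl_rec(std::vector<const double*>& P, int n, std::vector<const double*>& R) {
  if (n == 0 || R.size() == 4) return meb_upto4(R);
  Ball D = welzl_rec(P, n - 1, R);
  const double* p = P[n - 1];
  if (D.r >= 0 && contains(D, p, EPS)) return D;
  R.push_back(p);
  Ball D2 = welzl_rec(P, n - 1, R);
  R.pop_back();
  // move-to-front: points found on the boundary are consulted early
  std::rotate(P.begin(), P.begin() + (n - 1), P.begin() + n);
  return D2;
}

Ball meb(std::vector<const double*> P) {
  int n = (int)P.size();
  if (n == 0) return ball_empty();
  if (n <= 4) return meb_upto4(P);
  // fixed-seed shuffle: deterministic output, expected-linear behaviour
  std::mt19937 rng(88172645u);
  std::shuffle(P.begin(), P.end(), rng);
  std::vector<const double*> R;
  R.reserve(4);
  return welzl_rec(P, n, R);
}

// ----- best match ------------------------------------------------------

struct BestState {
  double radius;
  std::vector<int> idx;  // chosen point row (0-based) per pattern slot
};

// row-contiguous coordinate buffer (3 doubles per point)
struct PointBuf {
  std::vector<double> buf;  // 3 doubles per point
  int n;
  explicit PointBuf(const NumericMatrix& X) : n(X.nrow()) {
    buf.resize(3 * (size_t)n);
    for (int i = 0; i < n; ++i) {
      buf[3 * (size_t)i + 0] = X(i, 0);
      buf[3 * (size_t)i + 1] = X(i, 1);
      buf[3 * (size_t)i + 2] = X(i, 2);
    }
  }
  const double* pt(int i) const { return &buf[3 * (size_t)i]; }
};

void enumerate_slots_buf(const PointBuf& P,
                         const std::vector<std::vector<int>>& cand,
                         size_t slot,
                         std::vector<const double*>& chosen,
                         std::vector<int>& chosen_idx,
                         BestState& best) {
  Ball pre = meb(chosen);
  if (!chosen.empty() && pre.r >= best.radius) return;
  if (slot == cand.size()) {
    if (pre.r < best.radius) {
      best.radius = pre.r;
      best.idx = chosen_idx;
    }
    return;
  }
  for (int row : cand[slot]) {
    chosen.push_back(P.pt(row));
    chosen_idx.push_back(row);
    enumerate_slots_buf(P, cand, slot + 1, chosen, chosen_idx, best);
    chosen.pop_back();
    chosen_idx.pop_back();
  }
}

// MEB of three points: the diametral ball of the farthest pair, or the
// circumscribed circle when that ball misses the third point
inline Ball meb3_fast(const double* a, const double* b, const double* c) {
  double dab = dist2(a, b), dac = dist2(a, c), dbc = dist2(b, c);
  const double *p = a, *q = b, *s = c;
  if (dac >= dab && dac >= dbc) { q = c; s = b; }
  else if (dbc >= dab && dbc >= dac) { p = b; q = c; s = a; }
  Ball two = ball2(p, q);
  if (contains(two, s, EPS)) return two;
  Ball tri = ball3(a, b, c);
  if (tri.r >= 0) return tri;
  return two;  // collinear: the diametral ball is the answer
}

// exact minimum over all combinations (one occurrence per pattern slot)
BestState best_match_core(const PointBuf& P,
                          const std::vector<std::vector<int>>& occ,
                          double exhaustive_limit) {
  size_t k = occ.size();
  BestState best;
  best.radius = std::numeric_limits<double>::infinity();
  if (k == 1) {
    best.radius = 0.0;
    best.idx.assign(1, occ[0][0]);
    return best;
  }
  if (k == 2) {
    double best2 = std::numeric_limits<double>::infinity();
    int bi = -1, bj = -1;
    for (int i : occ[0])
      for (int j : occ[1]) {
        double d = dist2(P.pt(i), P.pt(j));
        if (d < best2) { best2 = d; bi = i; bj = j; }
      }
    best.radius = 0.5 * std::sqrt(best2);
    best.idx = {bi, bj};
    return best;
  }
  double prod = 1.0;
  for (const auto& o : occ) prod *= (double)o.size();

  if (k == 3 && prod <= exhaustive_limit) {
    for (int i : occ[0]) {
      const double* a = P.pt(i);
      for (int j : occ[1]) {
        const double* b = P.pt(j);
        double rab = 0.5 * std::sqrt(dist2(a, b));
        if (rab >= best.radius) continue;
        for (int l : occ[2]) {
          const double* c = P.pt(l);
          double lb = 0.5 * std::sqrt(std::max(dist2(a, c), dist2(b, c)));
          if (lb >= best.radius || rab >= best.radius) continue;
          Ball m = meb3_fast(a, b, c);
          if (m.r < best.radius) {
            best.radius = m.r;
            best.idx = {i, j, l};
          }
        }
      }
    }
    return best;
  }

  if (prod <= exhaustive_limit) {
    std::vector<const double*> chosen;
    std::vector<int> chosen_idx;
    enumerate_slots_buf(P, occ, 0, chosen, chosen_idx, best);
    return best;
  }

  // branch and bound: anchor on each occurrence of the rarest slot
  size_t anchor_slot = 0;
  for (size_t j = 1; j < k; ++j)
    if (occ[j].size() < occ[anchor_slot].size()) anchor_slot = j;

  struct Anchor { int row; double lb; };
  std::vector<Anchor> anchors;
  anchors.reserve(occ[anchor_slot].size());
  for (int a : occ[anchor_slot]) {
    double lb = 0.0;
    for (size_t j = 0; j < k; ++j) {
      if (j == anchor_slot) continue;
      double dmin = std::numeric_limits<double>::infinity();
      for (int u : occ[j]) dmin = std::min(dmin, dist2(P.pt(a), P.pt(u)));
      lb = std::max(lb, 0.5 * std::sqrt(dmin));
    }
    anchors.push_back({a, lb});
  }
  std::sort(anchors.begin(), anchors.end(),
            [](const Anchor& x, const Anchor& y) { return x.lb < y.lb; });

  for (const Anchor& an : anchors) {
    if (an.lb >= best.radius) break;  // sorted: no later anchor can win
    // every point of a combination with radius < incumbent lies within
    // 2*incumbent of the anchor
    double lim = 2.0 * best.radius;
    double lim2 = lim * lim;
    std::vector<std::vector<int>> cand;
    cand.reserve(k - 1);
    bool feasible = true;
    for (size_t j = 0; j < k && feasible; ++j) {
      if (j == anchor_slot) continue;
      std::vector<int> cj;
      for (int u : occ[j])
        if (std::isinf(best.radius) || dist2(P.pt(an.row), P.pt(u)) <= lim2)
          cj.push_back(u);
      if (cj.empty()) feasible = false;
      std::sort(cj.begin(), cj.end(), [&](int x, int y) {
        return dist2(P.pt(an.row), P.pt(x)) < dist2(P.pt(an.row), P.pt(y));
      });
      cand.push_back(std::move(cj));
    }
    if (!feasible) continue;
    std::vector<const double*> chosen{P.pt(an.row)};
    std::vector<int> chosen_idx{an.row};
    BestState local = best;
    enumerate_slots_buf(P, cand, 0, chosen, chosen_idx, local);
    if (local.radius < best.radius) {
      // re-insert anchor slot at its original position
      best.radius = local.radius;
      best.idx.assign(k, -1);
      best.idx[anchor_slot] = local.idx[0];
      size_t pos = 1;
      for (size_t j = 0; j < k; ++j) {
        if (j == anchor_slot) continue;
        best.idx[j] = local.idx[pos++];
      }
    }
  }
  return best;
}

std::vector<std::vector<int>> occurrences(const IntegerVector& labels,
                                          const IntegerVector& pattern) {
  std::vector<std::vector<int>> occ(pattern.size());
  for (int j = 0; j < pattern.size(); ++j) {
    for (int i = 0; i < labels.size(); ++i)
      if (labels[i] == pattern[j]) occ[(size_t)j].push_back(i);
  }
  return occ;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_meb")]]
List cpp_meb(NumericMatrix pts) {
  if (pts.nrow() < 1) stop("minimum enclosing ball needs at least one point");
  PointBuf P(pts);
  std::vector<const double*> ptrs(P.n);
  for (int i = 0; i < P.n; ++i) ptrs[(size_t)i] = P.pt(i);
  Ball b = meb(ptrs);
  return List::create(_["center"] = NumericVector::create(b.c[0], b.c[1], b.c[2]),
                      _["radius"] = b.r);
}

// [[Rcpp::export(name = ".cpp_best_match")]]
List cpp_best_match(NumericMatrix coords, IntegerVector labels,
                    IntegerVector pattern, double exhaustive_limit = 5000.0) {
  if (coords.nrow() != labels.size()) stop("coords/labels length mismatch");
  auto occ = occurrences(labels, pattern);
  for (const auto& o : occ)
    if (o.empty())
      return List::create(_["radius"] = NA_REAL,
                          _["indices"] = IntegerVector(0),
                          _["center"] = NumericVector(0));
  PointBuf P(coords);
  BestState best = best_match_core(P, occ, exhaustive_limit);
  std::vector<const double*> chosen;
  for (int i : best.idx) chosen.push_back(P.pt(i));
  Ball b = meb(chosen);
  IntegerVector idx(best.idx.size());
  for (size_t i = 0; i < best.idx.size(); ++i) idx[(R_xlen_t)i] = best.idx[i] + 1;
  return List::create(_["radius"] = best.radius,
                      _["indices"] = idx,
                      _["center"] = NumericVector::create(b.c[0], b.c[1], b.c[2]));
}

// batch interface used by the miner: one call per structure computes the
// best-match radius and chosen rows for every pattern supported there
// [[Rcpp::export(name = ".cpp_pattern_radii")]]
List cpp_pattern_radii(NumericMatrix coords, IntegerVector labels,
                       List patterns, double exhaustive_limit = 5000.0) {
  PointBuf P(coords);
  int m = patterns.size();
  NumericVector radii(m);
  List indices(m);
  for (int p = 0; p < m; ++p) {
    IntegerVector pat = patterns[p];
    auto occ = occurrences(labels, pat);
    bool missing = false;
    for (const auto& o : occ)
      if (o.empty()) { missing = true; break; }
    if (missing) {
      radii[p] = NA_REAL;
      indices[p] = IntegerVector(0);
      continue;
    }
    BestState best = best_match_core(P, occ, exhaustive_limit);
    radii[p] = best.radius;
    IntegerVector idx(best.idx.size());
    for (size_t i = 0; i < best.idx.size(); ++i) idx[(R_xlen_t)i] = best.idx[i] + 1;
    indices[p] = idx;
  }
  return List::create(_["radii"] = radii, _["indices"] = indices);
}
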