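// Geometric kernel: segment-triangle piercing predicates and the per-chain
// smoothing turn.  All predicates are conservative: anything within eps of
// the triangle counts as piercing, so a doubtful move is refused rather
// than risking a strand passage.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

struct V3 {
  double x, y, z;
};

static inline V3 v3(double x, double y, double z) {
  V3 v; v.x = x; v.y = y; v.z = z; return v;
}
static inline V3 vsub(const V3& a, const V3& b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 vadd(const V3& a, const V3& b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 vscale(const V3& a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
static inline double vdot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 vcross(const V3& a, const V3& b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double vnorm2(const V3& a) { return vdot(a, a); }
static inline double vnorm(const V3& a) { return std::sqrt(vnorm2(a)); }
static inline double vdist(const V3& a, const V3& b) { return vnorm(vsub(a, b)); }

static double distPointSeg(const V3& p, const V3& a, const V3& b) {
  V3 ab = vsub(b, a);
  double denom = vnorm2(ab);
  if (denom <= 0.0) return vdist(p, a);
  double t = vdot(vsub(p, a), ab) / denom;
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  return vdist(p, vadd(a, vscale(ab, t)));
}

// closest distance between segments [p1,q1] and [p2,q2] (Eberly-style clamped)
static double distSegSeg(const V3& p1, const V3& q1, const V3& p2, const V3& q2) {
  V3 d1 = vsub(q1, p1), d2 = vsub(q2, p2), r = vsub(p1, p2);
  double a = vnorm2(d1), e = vnorm2(d2), f = vdot(d2, r);
  double s, t;
  const double EPSN = 1e-14;
  if (a <= EPSN && e <= EPSN) return vdist(p1, p2);
  if (a <= EPSN) {
    s = 0.0;
    t = f / e; t = std::max(0.0, std::min(1.0, t));
  } else {
    double c = vdot(d1, r);
    if (e <= EPSN) {
      t = 0.0;
      s = std::max(0.0, std::min(1.0, -c / a));
    } else {
      double b = vdot(d1, d2);
      double denom = a * e - b * b;
      if (denom > EPSN) s = std::max(0.0, std::min(1.0, (b * f - c * e) / denom));
      else s = 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) {
        t = 0.0;
        s = std::max(0.0, std::min(1.0, -c / a));
      } else if (t > 1.0) {
        t = 1.0;
        s = std::max(0.0, std::min(1.0, (b - c) / a));
      }
    }
  }
  V3 c1 = vadd(p1, vscale(d1, s));
  V3 c2 = vadd(p2, vscale(d2, t));
  return vdist(c1, c2);
}

static double distPointTri(const V3& p, const V3& a, const V3& b, const V3& c) {
  V3 ab = vsub(b, a), ac = vsub(c, a), n = vcross(ab, ac);
  double n2 = vnorm2(n);
  if (n2 <= 1e-20) {
    // degenerate: distance to the three edges
    double d = distPointSeg(p, a, b);
    d = std::min(d, distPointSeg(p, b, c));
    d = std::min(d, distPointSeg(p, a, c));
    return d;
  }
  V3 ap = vsub(p, a);
  double dplane = vdot(ap, n) / std::sqrt(n2);
  // barycentric coordinates of the in-plane projection
  double d00 = vdot(ab, ab), d01 = vdot(ab, ac), d11 = vdot(ac, ac);
  double d20 = vdot(ap, ab), d21 = vdot(ap, ac);
  double denom = d00 * d11 - d01 * d01;
  double v = (d11 * d20 - d01 * d21) / denom;
  double w = (d00 * d21 - d01 * d20) / denom;
  double u = 1.0 - v - w;
  if (u >= 0.0 && v >= 0.0 && w >= 0.0) return std::fabs(dplane);
  double d = distPointSeg(p, a, b);
  d = std::min(d, distPointSeg(p, b, c));
  d = std::min(d, distPointSeg(p, a, c));
  return d;
}

// strict transversal crossing of the triangle interior
static bool segCrossesTriProper(const V3& p, const V3& q,
                                const V3& a, const V3& b, const V3& c) {
  V3 n = vcross(vsub(b, a), vsub(c, a));
  if (vnorm2(n) <= 1e-20) return false;  // degenerate triangle handled elsewhere
  double d1 = vdot(n, vsub(p, a));
  double d2 = vdot(n, vsub(q, a));
  if (!(d1 * d2 < 0.0)) return false;   // both endpoints on one side / touching
  double t = d1 / (d1 - d2);
  V3 x = vadd(p, vscale(vsub(q, p), t));
  // strictly inside: consistent orientation against all three edges
  double s1 = vdot(n, vcross(vsub(b, a), vsub(x, a)));
  double s2 = vdot(n, vcross(vsub(c, b), vsub(x, b)));
  double s3 = vdot(n, vcross(vsub(a, c), vsub(x, c)));
  return (s1 > 0.0 && s2 > 0.0 && s3 > 0.0) || (s1 < 0.0 && s2 < 0.0 && s3 < 0.0);
}

static double distSegTri(const V3& p, const V3& q,
                         const V3& a, const V3& b, const V3& c) {
  if (segCrossesTriProper(p, q, a, b, c)) return 0.0;
  double d = std::min(distPointTri(p, a, b, c), distPointTri(q, a, b, c));
  d = std::min(d, distSegSeg(p, q, a, b));
  d = std::min(d, distSegSeg(p, q, b, c));
  d = std::min(d, distSegSeg(p, q, a, c));
  return d;
}

static bool triDegenerate(const V3& a, const V3& b, const V3& c, double areaTol) {
  V3 n = vcross(vsub(b, a), vsub(c, a));
  return 0.5 * vnorm(n) <= areaTol;
}

// does segment [p,q] pierce triangle (a,b,c)?  eps-conservative.
static bool segPierces(const V3& p, const V3& q,
                       const V3& a, const V3& b, const V3& c,
                       double eps) {
  if (triDegenerate(a, b, c, 1e-12)) {
    // zero-area triangle: piercing reduces to eps-proximity to its edges
    double d = distSegSeg(p, q, a, b);
    d = std::min(d, distSegSeg(p, q, b, c));
    d = std::min(d, distSegSeg(p, q, a, c));
    return d <= eps;
  }
  return distSegTri(p, q, a, b, c) <= eps;
}

static const double VERTEX_MATCH_TOL = 1e-9;   // endpoint == triangle vertex
static const double TRIM_LEN = 1e-4;           // Angstrom shaved off a shared vertex

static inline bool sameVertex(const V3& a, const V3& b) {
  return std::fabs(a.x - b.x) <= VERTEX_MATCH_TOL &&
         std::fabs(a.y - b.y) <= VERTEX_MATCH_TOL &&
         std::fabs(a.z - b.z) <= VERTEX_MATCH_TOL;
}

// Test one obstacle segment against a triangle, with shared-vertex handling:
// a segment whose both endpoints are triangle vertices is a triangle side
// (never a piercer); a segment sharing one vertex is tested after trimming
// a small neighbourhood of the shared endpoint so that the unavoidable
// touch at the vertex is not reported, but a genuine pass through the
// triangle interior is.
static bool segPiercesShared(V3 p, V3 q,
                             const V3& a, const V3& b, const V3& c,
                             double eps) {
  bool pShared = sameVertex(p, a) || sameVertex(p, b) || sameVertex(p, c);
  bool qShared = sameVertex(q, a) || sameVertex(q, b) || sameVertex(q, c);
  if (pShared && qShared) return false;
  double len = vdist(p, q);
  if (pShared || qShared) {
    if (len <= 3.0 * TRIM_LEN) return false;  // microscopic neighbour stub
    double f = TRIM_LEN / len;
    if (pShared) p = vadd(p, vscale(vsub(q, p), f));
    else q = vadd(q, vscale(vsub(p, q), f));
  }
  return segPierces(p, q, a, b, c, eps);
}

// Soup layout: k x 3 coordinate matrix; rows of NaN separate chains.
// A segment is any pair of consecutive non-NaN rows.
static inline bool rowNa(const NumericMatrix& m, int r) {
  return ISNAN(m(r, 0));
}

// [[Rcpp::export]]
bool cpp_seg_tri_pierce(NumericVector p, NumericVector q,
                        NumericVector a, NumericVector b, NumericVector c,
                        double eps) {
  return segPierces(v3(p[0], p[1], p[2]), v3(q[0], q[1], q[2]),
                    v3(a[0], a[1], a[2]), v3(b[0], b[1], b[2]),
                    v3(c[0], c[1], c[2]), eps);
}

// [[Rcpp::export]]
bool cpp_tri_degenerate(NumericVector a, NumericVector b, NumericVector c,
                        double areaTol) {
  return triDegenerate(v3(a[0], a[1], a[2]), v3(b[0], b[1], b[2]),
                       v3(c[0], c[1], c[2]), areaTol);
}

// skip: 1-based indices of soup rows that START a segment to be excluded
// outright (the triangle's own sides).
// [[Rcpp::export]]
bool cpp_tri_pierced_soup(NumericMatrix tri, NumericMatrix soup,
                          double eps, IntegerVector skip) {
  V3 a = v3(tri(0, 0), tri(0, 1), tri(0, 2));
  V3 b = v3(tri(1, 0), tri(1, 1), tri(1, 2));
  V3 c = v3(tri(2, 0), tri(2, 1), tri(2, 2));
  std::vector<bool> skipRow;
  int m = soup.nrow();
  skipRow.assign(m, false);
  for (int i = 0; i < skip.size(); ++i) {
    int r = skip[i] - 1;
    if (r >= 0 && r < m) skipRow[r] = true;
  }
  for (int r = 0; r + 1 < m; ++r) {
    if (skipRow[r] || rowNa(soup, r) || rowNa(soup, r + 1)) continue;
    V3 p = v3(soup(r, 0), soup(r, 1), soup(r, 2));
    V3 q = v3(soup(r + 1, 0), soup(r + 1, 1), soup(r + 1, 2));
    if (segPiercesShared(p, q, a, b, c, eps)) return true;
  }
  return false;
}

// ---------------------------------------------------------------------------
// One smoothing turn for one chain.
//
// chain:      n x 3 bead coordinates of the chain being worked on
// obstacles:  NaN-separated soup of every *other* frozen segment
//             (other chains; and, in subchain mode, the flanks)
// lo, hi:     1-based indices of the fixed boundary beads; movable beads are
//             strictly inside (lo, hi)
// allow_moves: FALSE restricts the turn to deletions (reduce_beads)
//
// Returns per-bead action (0 none, 1 delete, 2 move) and move targets.
//
// The turn evaluates every movable bead against the frozen configuration
// (deletion first, then midpoint displacement, each guarded by triangle
// piercing tests), selects a pairwise non-adjacent subset by a
// reversal-invariant priority (distance to nearest fixed end, then
// coordinate-lexicographic order), and finally re-checks every selected
// action against the post-action segments of all other selected actions.
// The surviving set can therefore be applied simultaneously: any sequential
// application order yields the same result, and each intermediate
// configuration was covered by the guards.
// ---------------------------------------------------------------------------

struct Candidate {
  int idx;        // 0-based bead index
  int action;     // 1 delete, 2 move
  V3 target;      // for moves
  int prio;       // distance to nearest fixed end
};

// [[Rcpp::export]]
List cpp_chain_turn(NumericMatrix chain, NumericMatrix obstacles,
                    int lo, int hi, double eps, double move_tol,
                    bool allow_moves, int escape_level = 0,
                    bool candidates_only = false,
                    Nullable<NumericVector> ball = R_NilValue) {
  int n = chain.nrow();
  // optional confinement ball (cx, cy, cz, r): move targets outside it are
  // refused, so escape expansions cannot blow the geometry up
  bool hasBall = false; V3 bc = v3(0, 0, 0); double br = 0.0;
  if (ball.isNotNull()) {
    NumericVector bv(ball);
    bc = v3(bv[0], bv[1], bv[2]); br = bv[3]; hasBall = true;
  }
  std::vector<V3> bead(n);
  for (int i = 0; i < n; ++i) bead[i] = v3(chain(i, 0), chain(i, 1), chain(i, 2));

  // segment soup: self segments first (index = start bead), then obstacles
  struct Seg { V3 p, q; int selfStart; };  // selfStart = 0-based bead index, -1 if obstacle
  std::vector<Seg> segs;
  segs.reserve(n + obstacles.nrow());
  for (int i = 0; i + 1 < n; ++i) {
    Seg s; s.p = bead[i]; s.q = bead[i + 1]; s.selfStart = i;
    segs.push_back(s);
  }
  int m = obstacles.nrow();
  for (int r = 0; r + 1 < m; ++r) {
    if (rowNa(obstacles, r) || rowNa(obstacles, r + 1)) continue;
    Seg s;
    s.p = v3(obstacles(r, 0), obstacles(r, 1), obstacles(r, 2));
    s.q = v3(obstacles(r + 1, 0), obstacles(r + 1, 1), obstacles(r + 1, 2));
    s.selfStart = -1;
    segs.push_back(s);
  }

  // triangle unpierced by every segment except the excluded self sides
  // (ex1, ex2 are 0-based self segment-start indices, -1 for none)
  auto triFreeReal = [&](const V3& a, const V3& b, const V3& c, int ex1, int ex2) {
    for (size_t k = 0; k < segs.size(); ++k) {
      int ss = segs[k].selfStart;
      if (ss >= 0 && (ss == ex1 || ss == ex2)) continue;
      if (segPiercesShared(segs[k].p, segs[k].q, a, b, c, eps)) return false;
    }
    return true;
  };

  int lo0 = lo - 1, hi0 = hi - 1;  // 0-based fixed bounds
  std::vector<Candidate> cand;
  for (int i = lo0 + 1; i <= hi0 - 1; ++i) {
    const V3& prev = bead[i - 1];
    const V3& cur = bead[i];
    const V3& nxt = bead[i + 1];
    // deletion: triangle (prev, cur, nxt); sides are self segments i-1 and i
    if (triFreeReal(prev, cur, nxt, i - 1, i)) {
      Candidate cd; cd.idx = i; cd.action = 1; cd.target = cur;
      cd.prio = std::min(i - lo0, hi0 - i);
      cand.push_back(cd);
      continue;
    }
    if (!allow_moves) continue;
    // Move targets, all symmetric under chain reversal and guarded by the
    // two swept triangles (prev, cur, tgt) and (cur, tgt, nxt); the
    // mover's own segments i-1 and i are part of the motion, excluded.
    //   straight:  toward the neighbour midpoint or the perpendicular
    //              foot on the chord, with halving fractional fallback
    //   rotation:  side-step about the chord axis (+/- angle pairs; the
    //              admissible target ranked by |angle|, ties broken by
    //              coordinate order - invariant under reversal, which
    //              maps +theta about the axis to -theta about the
    //              flipped axis)
    //   expansion: away from the chord midpoint, the only move that can
    //              open a dense tangle threaded by long segments
    // escape_level orders and widens the repertoire; level 0 (normal
    // passes) is contraction only, higher levels are engaged when the
    // run stagnates or revisits a configuration.
    V3 mid = vscale(vadd(prev, nxt), 0.5);
    V3 chord = vsub(nxt, prev);
    double c2 = vnorm2(chord);
    // foot of the perpendicular, written about the midpoint so that chain
    // reversal (chord -> -chord, s -> -s) reproduces it bit for bit
    double s = (c2 > 0.0) ? vdot(vsub(cur, mid), chord) / c2 : 1.0;
    bool haveFoot = (std::fabs(s) < 0.45);
    V3 foot = haveFoot ? vadd(mid, vscale(chord, s)) : mid;

    bool placed = false;
    V3 chosen;
    auto admissible = [&](const V3& tgt) {
      if (vdist(tgt, cur) <= move_tol) return false;
      if (vdist(tgt, prev) <= eps || vdist(tgt, nxt) <= eps) return false;
      if (hasBall && vdist(tgt, bc) > br) return false;
      return triFreeReal(prev, cur, tgt, i - 1, i) &&
             triFreeReal(cur, tgt, nxt, i - 1, i);
    };
    auto tryStraight = [&](const V3& towards) {
      if (placed) return;
      if (vdist(towards, cur) <= move_tol) return;
      for (double frac = 1.0; frac >= 0.12; frac *= 0.5) {
        V3 tgt = vadd(cur, vscale(vsub(towards, cur), frac));
        if (vdist(tgt, cur) <= move_tol) break;
        if (admissible(tgt)) { chosen = tgt; placed = true; break; }
      }
    };
    auto tryRotations = [&](const double* radii, int nrad, bool largeFirst) {
      if (placed || !haveFoot) return;
      double an = vnorm(chord);
      if (an <= eps) return;
      V3 axisv = vscale(chord, 1.0 / an);
      V3 rad = vsub(cur, foot);
      if (vnorm(rad) <= 10.0 * move_tol) return;
      V3 perp = vcross(axisv, rad);  // |perp| == |rad|
      const double angs[11] = { 30.0, -30.0, 60.0, -60.0, 90.0, -90.0,
                                120.0, -120.0, 150.0, -150.0, 180.0 };
      for (int ridx = 0; ridx < nrad && !placed; ++ridx) {
        V3 best; bool have = false; double bestRank = 0.0;
        for (int aidx = 0; aidx < 11; ++aidx) {
          double th = std::fabs(angs[aidx]) * 3.14159265358979323846 / 180.0;
          double sgn = (angs[aidx] < 0) ? -1.0 : 1.0;
          V3 rr = vscale(rad, radii[ridx]);
          V3 pp = vscale(perp, radii[ridx]);
          V3 tgt = vadd(foot, vadd(vscale(rr, std::cos(th)),
                                   vscale(pp, sgn * std::sin(th))));
          if (!admissible(tgt)) continue;
          double ab = std::fabs(angs[aidx]);
          double rank = largeFirst ? -ab : ab;
          bool better = false;
          if (!have || rank < bestRank - 1e-9) better = true;
          else if (std::fabs(rank - bestRank) <= 1e-9) {
            if (tgt.x != best.x) better = tgt.x < best.x;
            else if (tgt.y != best.y) better = tgt.y < best.y;
            else better = tgt.z < best.z;
          }
          if (better) { best = tgt; bestRank = rank; have = true; }
        }
        if (have) { chosen = best; placed = true; }
      }
    };
    auto tryExpansion = [&](const double* fac, int nfac) {
      for (int eidx = 0; eidx < nfac && !placed; ++eidx) {
        V3 tgt = vadd(cur, vscale(vsub(cur, mid), fac[eidx]));
        if (admissible(tgt)) { chosen = tgt; placed = true; }
      }
    };

    static const double rad10[2] = { 1.0, 0.5 };
    static const double rad21[3] = { 2.0, 1.0, 0.5 };
    static const double rad42[4] = { 4.0, 2.0, 1.0, 0.5 };
    static const double exp10[2] = { 1.0, 0.5 };
    static const double exp21[3] = { 2.0, 1.0, 0.5 };
    static const double exp42[4] = { 4.0, 2.0, 1.0, 0.5 };
    static const double exp84[5] = { 8.0, 4.0, 2.0, 1.0, 0.5 };
    if (escape_level <= 0) {
      tryStraight(mid); tryStraight(foot);
    } else if (escape_level == 1) {
      tryStraight(mid); tryStraight(foot);
      tryRotations(rad10, 2, false);
      tryExpansion(exp10, 2);
    } else if (escape_level == 2) {
      tryExpansion(exp21, 3);
      tryRotations(rad10, 2, true);
      tryStraight(mid); tryStraight(foot);
    } else if (escape_level == 3) {
      tryExpansion(exp42, 4);
      tryRotations(rad21, 3, true);
      tryStraight(mid); tryStraight(foot);
    } else {
      tryExpansion(exp84, 5);
      tryRotations(rad42, 4, true);
      tryStraight(mid); tryStraight(foot);
    }
    if (placed) {
      Candidate cd; cd.idx = i; cd.action = 2; cd.target = chosen;
      cd.prio = std::min(i - lo0, hi0 - i);
      cand.push_back(cd);
    }
  }

  // reversal-invariant deterministic order: nearest fixed end first, then
  // coordinate-lexicographic, then index (coords of distinct beads tie only
  // if geometrically coincident, which valid chains exclude for neighbours)
  std::sort(cand.begin(), cand.end(), [&](const Candidate& A, const Candidate& B) {
    if (A.prio != B.prio) return A.prio < B.prio;
    const V3& a = bead[A.idx];
    const V3& b = bead[B.idx];
    if (a.x != b.x) return a.x < b.x;
    if (a.y != b.y) return a.y < b.y;
    if (a.z != b.z) return a.z < b.z;
    return A.idx < B.idx;
  });

  if (candidates_only) {
    // expose the full frozen-admissible candidate list in priority order
    int nc = (int)cand.size();
    IntegerVector cidx(nc), cact(nc);
    NumericMatrix ctgt(nc, 3);
    for (int k = 0; k < nc; ++k) {
      cidx[k] = cand[k].idx + 1;
      cact[k] = cand[k].action;
      ctgt(k, 0) = cand[k].target.x;
      ctgt(k, 1) = cand[k].target.y;
      ctgt(k, 2) = cand[k].target.z;
    }
    return List::create(_["idx"] = cidx, _["act"] = cact, _["tgt"] = ctgt);
  }

  // greedy pairwise non-adjacent selection
  std::vector<Candidate> sel;
  std::vector<bool> taken(n, false);
  for (size_t k = 0; k < cand.size(); ++k) {
    int i = cand[k].idx;
    if ((i > 0 && taken[i - 1]) || taken[i] || (i + 1 < n && taken[i + 1])) continue;
    taken[i] = true;
    sel.push_back(cand[k]);
  }

  // co-move guard: post-action segments of every selected action
  std::vector<std::pair<V3, V3> > post;
  std::vector<int> postOwner;
  for (size_t k = 0; k < sel.size(); ++k) {
    const Candidate& cd = sel[k];
    if (cd.action == 1) {
      post.push_back(std::make_pair(bead[cd.idx - 1], bead[cd.idx + 1]));
      postOwner.push_back(cd.idx);
    } else {
      post.push_back(std::make_pair(bead[cd.idx - 1], cd.target));
      postOwner.push_back(cd.idx);
      post.push_back(std::make_pair(cd.target, bead[cd.idx + 1]));
      postOwner.push_back(cd.idx);
    }
  }
  auto postClean = [&](const V3& a, const V3& b, const V3& c, int owner) {
    for (size_t k = 0; k < post.size(); ++k) {
      if (postOwner[k] == owner) continue;
      if (segPiercesShared(post[k].first, post[k].second, a, b, c, eps)) return false;
    }
    return true;
  };

  IntegerVector action(n, 0);
  NumericMatrix target(n, 3);
  int applied = 0;
  for (size_t k = 0; k < sel.size(); ++k) {
    const Candidate& cd = sel[k];
    const V3& prev = bead[cd.idx - 1];
    const V3& cur = bead[cd.idx];
    const V3& nxt = bead[cd.idx + 1];
    bool ok;
    if (cd.action == 1) {
      ok = postClean(prev, cur, nxt, cd.idx);
    } else {
      ok = postClean(prev, cur, cd.target, cd.idx) &&
           postClean(cur, cd.target, nxt, cd.idx);
    }
    if (!ok) continue;
    action[cd.idx] = cd.action;
    target(cd.idx, 0) = cd.target.x;
    target(cd.idx, 1) = cd.target.y;
    target(cd.idx, 2) = cd.target.z;
    ++applied;
  }

  // co-move deadlock: every selected action vetoed another.  A single
  // action needs no co-move guard (its frozen-configuration guard is
  // rigorous on its own), so apply the top-priority candidate alone; the
  // priority order is reversal-invariant, keeping determinism and the
  // mirrored-trajectory property.
  if (applied == 0 && !sel.empty()) {
    const Candidate& cd = sel[0];
    action[cd.idx] = cd.action;
    target(cd.idx, 0) = cd.target.x;
    target(cd.idx, 1) = cd.target.y;
    target(cd.idx, 2) = cd.target.z;
  }

  return List::create(_["action"] = action, _["target"] = target);
}
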