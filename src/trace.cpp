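// Monte Carlo path tracer over a triangle scene with a discretised sky
// dome, bi-Lambertian leaf scattering with side-specific coefficients and
// a diffusely reflective ground. Energy is tracked by weight splitting:
// at every interaction the absorbed fraction is deposited and the ray
// continues with the scattered remainder, so the energy budget
// (absorbed + ground + escaped + truncated == incident) closes exactly.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
  Vec3 operator+(const Vec3 &o) const { return {x + o.x, y + o.y, z + o.z}; }
  Vec3 operator-(const Vec3 &o) const { return {x - o.x, y - o.y, z - o.z}; }
  Vec3 operator*(double s) const { return {x * s, y * s, z * s}; }
};

inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline Vec3 normalize(const Vec3 &a) {
  double n = std::sqrt(dot(a, a));
  return {a.x / n, a.y / n, a.z / n};
}

// xorshift-based generator: identical streams on every platform.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {
    for (int i = 0; i < 4; ++i) next();
  }
  uint64_t next() {
    uint64_t x = s;
    x ^= x << 13;
    x ^= x >> 7;
    x ^= x << 17;
    return s = x;
  }
  double uniform() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

struct Tri {
  Vec3 a, e1, e2, n; // vertex, edges, unit normal
};

struct Box {
  Vec3 lo, hi;
  void grow(const Vec3 &p) {
    lo.x = std::min(lo.x, p.x); lo.y = std::min(lo.y, p.y);
    lo.z = std::min(lo.z, p.z);
    hi.x = std::max(hi.x, p.x); hi.y = std::max(hi.y, p.y);
    hi.z = std::max(hi.z, p.z);
  }
};

struct BvhNode {
  Box box;
  int left, right;   // children, or -1 for leaf
  int start, count;  // triangle range for leaves
};

struct Bvh {
  std::vector<Tri> tris;
  std::vector<int> order;
  std::vector<BvhNode> nodes;
  std::vector<Vec3> centroids;

  int build(int start, int count) {
    BvhNode node;
    node.box = {{1e30, 1e30, 1e30}, {-1e30, -1e30, -1e30}};
    for (int i = start; i < start + count; ++i) {
      const Tri &t = tris[order[i]];
      node.box.grow(t.a);
      node.box.grow(t.a + t.e1);
      node.box.grow(t.a + t.e2);
    }
    int idx = (int)nodes.size();
    nodes.push_back(node);
    if (count <= 4) {
      nodes[idx].left = nodes[idx].right = -1;
      nodes[idx].start = start;
      nodes[idx].count = count;
      return idx;
    }
    Vec3 ext = node.box.hi - node.box.lo;
    int axis = 0;
    if (ext.y > ext.x) axis = 1;
    if (ext.z > (axis == 0 ? ext.x : ext.y)) axis = 2;
    int mid = start + count / 2;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count, [&](int a, int b) {
                       const Vec3 &ca = centroids[a], &cb = centroids[b];
                       double va = axis == 0 ? ca.x : (axis == 1 ? ca.y : ca.z);
                       double vb = axis == 0 ? cb.x : (axis == 1 ? cb.y : cb.z);
                       return va < vb;
                     });
    int l = build(start, mid - start);
    int r = build(mid, start + count - mid);
    nodes[idx].left = l;
    nodes[idx].right = r;
    nodes[idx].start = -1;
    nodes[idx].count = 0;
    return idx;
  }

  static bool hitBox(const Box &b, const Vec3 &o, const Vec3 &inv,
                     double tmax) {
    double t0 = 0.0, t1 = tmax;
    double tx0 = (b.lo.x - o.x) * inv.x, tx1 = (b.hi.x - o.x) * inv.x;
    if (tx0 > tx1) std::swap(tx0, tx1);
    t0 = std::max(t0, tx0); t1 = std::min(t1, tx1);
    double ty0 = (b.lo.y - o.y) * inv.y, ty1 = (b.hi.y - o.y) * inv.y;
    if (ty0 > ty1) std::swap(ty0, ty1);
    t0 = std::max(t0, ty0); t1 = std::min(t1, ty1);
    double tz0 = (b.lo.z - o.z) * inv.z, tz1 = (b.hi.z - o.z) * inv.z;
    if (tz0 > tz1) std::swap(tz0, tz1);
    t0 = std::max(t0, tz0); t1 = std::min(t1, tz1);
    return t0 <= t1;
  }

  // nearest hit; returns triangle index (into tris) or -1
  int intersect(const Vec3 &o, const Vec3 &d, double &tBest) const {
    if (nodes.empty()) return -1;
    Vec3 inv = {1.0 / (d.x != 0 ? d.x : 1e-300),
                1.0 / (d.y != 0 ? d.y : 1e-300),
                1.0 / (d.z != 0 ? d.z : 1e-300)};
    int best = -1;
    tBest = 1e30;
    std::vector<int> stack;
    stack.reserve(64);
    stack.push_back(0);
    while (!stack.empty()) {
      int ni = stack.back();
      stack.pop_back();
      const BvhNode &node = nodes[ni];
      if (!hitBox(node.box, o, inv, tBest)) continue;
      if (node.left < 0) {
        for (int i = node.start; i < node.start + node.count; ++i) {
          int ti = order[i];
          const Tri &t = tris[ti];
          // Moller-Trumbore
          Vec3 p = cross(d, t.e2);
          double det = dot(t.e1, p);
          if (std::fabs(det) < 1e-14) continue;
          double invDet = 1.0 / det;
          Vec3 s = o - t.a;
          double u = dot(s, p) * invDet;
          if (u < -1e-9 || u > 1 + 1e-9) continue;
          Vec3 q = cross(s, t.e1);
          double v = dot(d, q) * invDet;
          if (v < -1e-9 || u + v > 1 + 1e-9) continue;
          double tt = dot(t.e2, q) * invDet;
          if (tt > 1e-7 && tt < tBest) {
            tBest = tt;
            best = ti;
          }
        }
      } else {
        stack.push_back(node.left);
        stack.push_back(node.right);
      }
    }
    return best;
  }
};

Vec3 cosineHemisphere(const Vec3 &n, Rng &rng) {
  double u1 = rng.uniform(), u2 = rng.uniform();
  double r = std::sqrt(u1), phi = 2.0 * M_PI * u2;
  double lx = r * std::cos(phi), ly = r * std::sin(phi);
  double lz = std::sqrt(std::max(0.0, 1.0 - u1));
  Vec3 t = std::fabs(n.x) > 0.9 ? Vec3{0, 1, 0} : Vec3{1, 0, 0};
  Vec3 b1 = normalize(cross(n, t));
  Vec3 b2 = cross(n, b1);
  return normalize(b1 * lx + b2 * ly + n * lz);
}

} // namespace

// [[Rcpp::export(name = ".trace_cpp")]]
List trace_cpp(NumericMatrix tri, IntegerVector surface_id,
               IntegerVector material, NumericMatrix sky_dir,
               NumericVector sky_w, NumericVector launch_rect,
               double z_top, NumericVector optics, int n_rays,
               int max_depth, double seed) {
  int nt = tri.nrow();
  int nsurf = 0;
  for (int i = 0; i < nt; ++i) nsurf = std::max(nsurf, surface_id[i]);

  Bvh bvh;
  bvh.tris.resize(nt);
  bvh.order.resize(nt);
  bvh.centroids.resize(nt);
  for (int i = 0; i < nt; ++i) {
    Vec3 a = {tri(i, 0), tri(i, 1), tri(i, 2)};
    Vec3 b = {tri(i, 3), tri(i, 4), tri(i, 5)};
    Vec3 c = {tri(i, 6), tri(i, 7), tri(i, 8)};
    Tri t;
    t.a = a;
    t.e1 = b - a;
    t.e2 = c - a;
    t.n = normalize(cross(t.e1, t.e2));
    bvh.tris[i] = t;
    bvh.order[i] = i;
    bvh.centroids[i] = (a + b + c) * (1.0 / 3.0);
  }
  if (nt > 0) bvh.build(0, nt);

  double ad_r = optics[0], ad_t = optics[1], ab_r = optics[2],
         ab_t = optics[3], g_r = optics[4], g_t = optics[5];
  double x0 = launch_rect[0], x1 = launch_rect[1], y0 = launch_rect[2],
         y1 = launch_rect[3];

  int npatch = sky_dir.nrow();
  std::vector<double> cumw(npatch);
  double acc = 0;
  for (int i = 0; i < npatch; ++i) {
    acc += sky_w[i];
    cumw[i] = acc;
  }

  std::vector<double> absorbed(nsurf, 0.0);
  double groundAbs = 0, groundFlux = 0, escaped = 0, escapedPrimary = 0,
         truncated = 0;
  double w0 = 1.0 / n_rays;

  Rng rng((uint64_t)seed * 2654435761ULL + 12345ULL);

  for (int r = 0; r < n_rays; ++r) {
    double u = rng.uniform() * acc;
    int pi = (int)(std::lower_bound(cumw.begin(), cumw.end(), u) -
                   cumw.begin());
    if (pi >= npatch) pi = npatch - 1;
    Vec3 d = normalize({sky_dir(pi, 0), sky_dir(pi, 1), sky_dir(pi, 2)});
    double tx = x0 + rng.uniform() * (x1 - x0);
    double ty = y0 + rng.uniform() * (y1 - y0);
    // aim at (tx, ty, 0), start above the scene
    double s = (z_top - 0.0) / (-d.z);
    Vec3 o = {tx + d.x * -s, ty + d.y * -s, z_top};
    double w = w0;
    bool primary = true;

    for (int depth = 0; depth <= max_depth; ++depth) {
      double tHit;
      int hit = bvh.intersect(o, d, tHit);
      if (hit < 0) {
        escaped += w;
        if (primary) escapedPrimary += w;
        w = 0;
        break;
      }
      primary = false;
      Vec3 p = o + d * tHit;
      const Tri &t = bvh.tris[hit];
      if (material[hit] == 2) { // ground
        groundFlux += w;
        groundAbs += w * (1.0 - g_r - g_t);
        double wr = w * g_r;
        double wt = w * g_t;
        if (wt > 0) escaped += wt; // transmitted below the ground plane
        w = wr;
        if (w <= 0) break;
        if (depth == max_depth) { truncated += w; w = 0; break; }
        Vec3 n = t.n.z >= 0 ? t.n : t.n * -1.0;
        d = cosineHemisphere(n, rng);
        o = p + d * 1e-7;
      } else { // leaf
        bool front = dot(d, t.n) < 0; // adaxial side faces +normal
        double rr = front ? ad_r : ab_r;
        double tt = front ? ad_t : ab_t;
        int sid = surface_id[hit] - 1;
        absorbed[sid] += w * (1.0 - rr - tt);
        double wc = w * (rr + tt);
        if (wc <= 0) { w = 0; break; }
        if (depth == max_depth) { truncated += wc; w = 0; break; }
        bool reflect = rng.uniform() < rr / (rr + tt);
        Vec3 nIn = front ? t.n : t.n * -1.0; // normal on incoming side
        Vec3 axis = reflect ? nIn : nIn * -1.0;
        d = cosineHemisphere(axis, rng);
        o = p + d * 1e-7;
        w = wc;
      }
    }
    if (w > 0) truncated += w; // depth loop exhausted with pending weight
  }

  return List::create(
      _["absorbed"] = NumericVector(absorbed.begin(), absorbed.end()),
      _["ground_absorbed"] = groundAbs, _["ground_flux"] = groundFlux,
      _["escaped"] = escaped, _["escaped_primary"] = escapedPrimary,
      _["truncated"] = truncated);
}
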