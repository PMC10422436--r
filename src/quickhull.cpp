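// 3D convex hull volume by the quickhull algorithm.
// Triangular faces carry outward plane normals, neighbour links across each
// edge, and an "outside set" of unassigned points; the horizon of the furthest
// outside point is found by flood fill over neighbour links.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_map>

using namespace Rcpp;

namespace {

struct Face {
  int v[3];              // vertex indices, counter-clockwise seen from outside
  int nb[3];             // neighbour face across edge (v[i], v[(i+1)%3])
  double n[3];           // outward unit normal
  double off;            // plane offset: n . x = off
  std::vector<int> out;  // outside point set
  int far_pt;
  double far_d;
  bool alive;
};

struct Hull {
  const double* px; const double* py; const double* pz;
  int n;
  std::vector<Face> faces;
  double eps;

  double dist(int f, int p) const {
    const Face& F = faces[f];
    return F.n[0] * px[p] + F.n[1] * py[p] + F.n[2] * pz[p] - F.off;
  }

  void set_plane(Face& F) {
    double ax = px[F.v[1]] - px[F.v[0]], ay = py[F.v[1]] - py[F.v[0]],
           az = pz[F.v[1]] - pz[F.v[0]];
    double bx = px[F.v[2]] - px[F.v[0]], by = py[F.v[2]] - py[F.v[0]],
           bz = pz[F.v[2]] - pz[F.v[0]];
    double nx = ay * bz - az * by, ny = az * bx - ax * bz,
           nz = ax * by - ay * bx;
    double len = std::sqrt(nx * nx + ny * ny + nz * nz);
    if (len <= 0) { nx = ny = 0; nz = 1; len = 1; }
    F.n[0] = nx / len; F.n[1] = ny / len; F.n[2] = nz / len;
    F.off = F.n[0] * px[F.v[0]] + F.n[1] * py[F.v[0]] + F.n[2] * pz[F.v[0]];
  }

  int edge_index(const Face& F, int a, int b) const {
    for (int i = 0; i < 3; ++i)
      if (F.v[i] == a && F.v[(i + 1) % 3] == b) return i;
    return -1;
  }

  // distribute each candidate point to the first face it lies outside of
  void distribute(const std::vector<int>& face_ids,
                  const std::vector<int>& cand) {
    for (int f : face_ids) {
      Face& F = faces[f];
      F.far_pt = -1; F.far_d = eps;
    }
    for (int p : cand) {
      for (int f : face_ids) {
        double d = dist(f, p);
        if (d > eps) {
          Face& F = faces[f];
          F.out.push_back(p);
          if (d > F.far_d) { F.far_d = d; F.far_pt = p; }
          break;
        }
      }
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".quickhull3d")]]
List quickhull3d(NumericVector x, NumericVector y, NumericVector z) {
  const int n = x.size();
  if (n < 4) stop("convex hull needs at least 4 points");

  Hull H;
  H.px = REAL(x); H.py = REAL(y); H.pz = REAL(z); H.n = n;

  double scale = 0;
  for (int i = 0; i < n; ++i) {
    scale = std::max(scale, std::fabs(H.px[i]));
    scale = std::max(scale, std::fabs(H.py[i]));
    scale = std::max(scale, std::fabs(H.pz[i]));
  }
  if (scale <= 0) scale = 1;
  H.eps = 1e-10 * scale;

  // initial simplex: extreme pair along x (tie-broken by y, z), furthest point
  // from that line, then furthest from the resulting plane
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (H.px[i] < H.px[i0] || (H.px[i] == H.px[i0] && (H.py[i] < H.py[i0] ||
        (H.py[i] == H.py[i0] && H.pz[i] < H.pz[i0])))) i0 = i;
    if (H.px[i] > H.px[i1] || (H.px[i] == H.px[i1] && (H.py[i] > H.py[i1] ||
        (H.py[i] == H.py[i1] && H.pz[i] > H.pz[i1])))) i1 = i;
  }
  double ax = H.px[i1] - H.px[i0], ay = H.py[i1] - H.py[i0],
         az = H.pz[i1] - H.pz[i0];
  double alen2 = ax * ax + ay * ay + az * az;
  if (alen2 <= H.eps * H.eps) stop("degenerate hull: points are coincident");

  int i2 = -1; double best = 0;
  for (int i = 0; i < n; ++i) {
    double wx = H.px[i] - H.px[i0], wy = H.py[i] - H.py[i0],
           wz = H.pz[i] - H.pz[i0];
    double cx = ay * wz - az * wy, cy = az * wx - ax * wz,
           cz = ax * wy - ay * wx;
    double d2 = (cx * cx + cy * cy + cz * cz) / alen2;
    if (d2 > best) { best = d2; i2 = i; }
  }
  if (i2 < 0 || std::sqrt(best) <= H.eps)
    stop("degenerate hull: points are collinear");

  double bx = H.px[i2] - H.px[i0], by = H.py[i2] - H.py[i0],
         bz = H.pz[i2] - H.pz[i0];
  double nx = ay * bz - az * by, ny = az * bx - ax * bz, nz = ax * by - ay * bx;
  double nlen = std::sqrt(nx * nx + ny * ny + nz * nz);
  nx /= nlen; ny /= nlen; nz /= nlen;
  double off = nx * H.px[i0] + ny * H.py[i0] + nz * H.pz[i0];

  int i3 = -1; best = 0;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(nx * H.px[i] + ny * H.py[i] + nz * H.pz[i] - off);
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0 || best <= H.eps)
    stop("degenerate hull: points are coplanar");

  // orient the tetrahedron i0 i1 i2 i3 so faces point away from its centroid
  double s = nx * H.px[i3] + ny * H.py[i3] + nz * H.pz[i3] - off;
  if (s > 0) std::swap(i1, i2);  // make i3 lie below face (i0,i1,i2)

  int tv[4] = { i0, i1, i2, i3 };
  int fv[4][3] = { {0, 1, 2}, {0, 3, 1}, {1, 3, 2}, {2, 3, 0} };
  H.faces.resize(4);
  for (int f = 0; f < 4; ++f) {
    Face& F = H.faces[f];
    for (int k = 0; k < 3; ++k) F.v[k] = tv[fv[f][k]];
    F.alive = true;
    H.set_plane(F);
  }
  // neighbour links by shared directed edges
  for (int f = 0; f < 4; ++f)
    for (int k = 0; k < 3; ++k) {
      int a = H.faces[f].v[k], b = H.faces[f].v[(k + 1) % 3];
      for (int g = 0; g < 4; ++g) {
        if (g == f) continue;
        if (H.edge_index(H.faces[g], b, a) >= 0) { H.faces[f].nb[k] = g; break; }
      }
    }

  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  H.distribute({0, 1, 2, 3}, all);

  std::vector<int> pending;
  for (int f = 0; f < 4; ++f)
    if (H.faces[f].far_pt >= 0) pending.push_back(f);

  std::vector<int> visible, horizon_face, horizon_edge;
  std::vector<char> seen;

  while (!pending.empty()) {
    int f0 = pending.back(); pending.pop_back();
    Face& F0 = H.faces[f0];
    if (!F0.alive || F0.far_pt < 0) continue;
    int apex = F0.far_pt;

    // flood fill the faces visible from the apex
    visible.clear(); horizon_face.clear(); horizon_edge.clear();
    seen.assign(H.faces.size(), 0);
    std::vector<int> stack{ f0 };
    seen[f0] = 1;
    while (!stack.empty()) {
      int f = stack.back(); stack.pop_back();
      visible.push_back(f);
      for (int k = 0; k < 3; ++k) {
        int g = H.faces[f].nb[k];
        if (seen[g]) continue;
        if (H.dist(g, apex) > H.eps) {
          seen[g] = 1;
          stack.push_back(g);
        } else {
          // horizon edge: record as seen from the neighbour g
          horizon_face.push_back(g);
          int a = H.faces[f].v[k], b = H.faces[f].v[(k + 1) % 3];
          horizon_edge.push_back(H.edge_index(H.faces[g], b, a));
        }
      }
    }

    // gather candidate points from all visible faces
    std::vector<int> cand;
    for (int f : visible) {
      Face& F = H.faces[f];
      for (int p : F.out) if (p != apex) cand.push_back(p);
      F.out.clear(); F.alive = false;
    }

    // build the new cone of faces around the apex
    std::unordered_map<int, int> by_first;  // horizon start vertex -> new face
    std::vector<int> created;
    for (size_t e = 0; e < horizon_face.size(); ++e) {
      int g = horizon_face[e], ei = horizon_edge[e];
      int a = H.faces[g].v[ei], b = H.faces[g].v[(ei + 1) % 3];
      Face F;
      F.v[0] = b; F.v[1] = a; F.v[2] = apex;  // reverse of g's edge
      F.nb[0] = g;
      F.nb[1] = F.nb[2] = -1;
      F.alive = true;
      H.set_plane(F);
      int id = (int)H.faces.size();
      H.faces.push_back(F);
      H.faces[g].nb[ei] = id;
      by_first[b] = id;
      created.push_back(id);
    }
    // stitch new faces: edge (a, apex) of one face meets edge (apex, a) of the
    // face whose horizon edge starts at a
    for (int id : created) {
      Face& F = H.faces[id];
      int a = F.v[1], b = F.v[0];
      F.nb[1] = by_first[a];                 // edge (a, apex)
      // edge (apex, b): the face whose v[1] == b, i.e. whose horizon edge ends
      // at b; that face has first vertex b's predecessor -- find via map by a
      // simpler rule: neighbour across (apex, b) is the face starting at b
      // only if its v[1]... build reverse map instead
      (void)b;
    }
    // second pass for nb[2] using a map keyed on v[1]
    {
      std::unordered_map<int, int> by_second;
      for (int id : created) by_second[H.faces[id].v[1]] = id;
      for (int id : created) {
        Face& F = H.faces[id];
        F.nb[2] = by_second[F.v[0]];         // edge (apex, v[0])
      }
    }

    H.distribute(created, cand);
    for (int id : created)
      if (H.faces[id].far_pt >= 0) pending.push_back(id);
  }

  // volume and area over surviving faces, anchored at the input centroid
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) { cx += H.px[i]; cy += H.py[i]; cz += H.pz[i]; }
  cx /= n; cy /= n; cz /= n;

  double vol = 0, area = 0;
  int nfaces = 0;
  std::vector<char> on_hull(n, 0);
  for (const Face& F : H.faces) {
    if (!F.alive) continue;
    ++nfaces;
    for (int k = 0; k < 3; ++k) on_hull[F.v[k]] = 1;
    double ax1 = H.px[F.v[0]] - cx, ay1 = H.py[F.v[0]] - cy,
           az1 = H.pz[F.v[0]] - cz;
    double ax2 = H.px[F.v[1]] - cx, ay2 = H.py[F.v[1]] - cy,
           az2 = H.pz[F.v[1]] - cz;
    double ax3 = H.px[F.v[2]] - cx, ay3 = H.py[F.v[2]] - cy,
           az3 = H.pz[F.v[2]] - cz;
    vol += (ax1 * (ay2 * az3 - az2 * ay3) -
            ay1 * (ax2 * az3 - az2 * ax3) +
            az1 * (ax2 * ay3 - ay2 * ax3)) / 6.0;
    double ex1 = ax2 - ax1, ey1 = ay2 - ay1, ez1 = az2 - az1;
    double ex2 = ax3 - ax1, ey2 = ay3 - ay1, ez2 = az3 - az1;
    double qx = ey1 * ez2 - ez1 * ey2, qy = ez1 * ex2 - ex1 * ez2,
           qz = ex1 * ey2 - ey1 * ex2;
    area += 0.5 * std::sqrt(qx * qx + qy * qy + qz * qz);
  }
  int nvert = 0;
  for (int i = 0; i < n; ++i) nvert += on_hull[i];

  return List::create(_["volume"] = vol, _["area"] = area,
                      _["n_faces"] = nfaces, _["n_vertices"] = nvert);
}
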