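#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double fval(const NumericVector &m, int nx, int ny, int nz,
                          int x, int y, int z) {
  if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0.0;
  return m[x + nx * (y + (R_xlen_t)ny * z)];
}

struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { V3 v = {x, y, z}; return v; }
static inline V3 sub(V3 a, V3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 cross(V3 a, V3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double norm(V3 a) { return std::sqrt(dot(a, a)); }
static inline V3 mid(V3 a, V3 b) {
  return v3(0.5 * (a.x + b.x), 0.5 * (a.y + b.y), 0.5 * (a.z + b.z));
}
static inline double triarea(V3 a, V3 b, V3 c) {
  return 0.5 * norm(cross(sub(b, a), sub(c, a)));
}

static inline V3 lerp(V3 a, V3 b, double va, double vb, double level) {
  double t = (vb == va) ? 0.5 : (level - va) / (vb - va);
  if (t < 0) t = 0; if (t > 1) t = 1;
  return v3(a.x + t * (b.x - a.x), a.y + t * (b.y - a.y),
            a.z + t * (b.z - a.z));
}

// Surface area of the `level` isosurface of a scalar field by marching
// tetrahedra with linear edge interpolation: each cube of 8 neighbouring
// voxel centres is split into six tetrahedra sharing the main diagonal.
// The volume outside the grid counts as 0, so surfaces close at the
// border. A binary 0/1 field reproduces the midpoint (voxel-face smoothed)
// mesh; an anti-aliased field yields a sub-voxel-accurate mesh.
// [[Rcpp::export]]
double cpp_mesh_area(NumericVector field, int nx, int ny, int nz,
                     double sx, double sy, double sz, double level) {
  static const int cornerOff[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  // six tetrahedra around the 0-7 diagonal
  static const int tets[6][4] = {
    {0,5,1,7},{0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7}};
  double area = 0.0;
  for (int z = -1; z < nz; ++z)
    for (int y = -1; y < ny; ++y)
      for (int x = -1; x < nx; ++x) {
        double val[8];
        V3 pos[8];
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          int cx = x + cornerOff[c][0], cy = y + cornerOff[c][1],
              cz = z + cornerOff[c][2];
          val[c] = fval(field, nx, ny, nz, cx, cy, cz);
          pos[c] = v3(cx * sx, cy * sy, cz * sz);
          if (val[c] > level) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          int ins[4], outs[4];
          int nin = 0, nout = 0;
          for (int k = 0; k < 4; ++k) {
            int vtx = tets[t][k];
            if (val[vtx] > level) ins[nin++] = vtx; else outs[nout++] = vtx;
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            // triangle towards the minority vertex
            int apex = (nin == 1) ? ins[0] : outs[0];
            int *oth = (nin == 1) ? outs : ins;
            area += triarea(
              lerp(pos[apex], pos[oth[0]], val[apex], val[oth[0]], level),
              lerp(pos[apex], pos[oth[1]], val[apex], val[oth[1]], level),
              lerp(pos[apex], pos[oth[2]], val[apex], val[oth[2]], level));
          } else { // 2-2: quad on the four crossing edges
            int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
            V3 mac = lerp(pos[a], pos[c], val[a], val[c], level);
            V3 mad = lerp(pos[a], pos[d], val[a], val[d], level);
            V3 mbd = lerp(pos[b], pos[d], val[b], val[d], level);
            V3 mbc = lerp(pos[b], pos[c], val[b], val[c], level);
            area += triarea(mac, mad, mbd) + triarea(mac, mbd, mbc);
          }
        }
      }
  return area;
}

// ---- incremental 3D convex hull (volume only) --------------------------
// Points are expected to be jittered R-side so that degenerate (coplanar)
// configurations from the voxel grid are broken deterministically.

struct Face { int a, b, c; bool alive; };

static inline double orient(const std::vector<V3> &p, const Face &f, int q) {
  V3 n = cross(sub(p[f.b], p[f.a]), sub(p[f.c], p[f.a]));
  return dot(n, sub(p[q], p[f.a]));
}

static bool build_hull(NumericMatrix pts, std::vector<V3> &p,
                       std::vector<Face> &faces) {
  int n = pts.nrow();
  if (n < 4) return false;
  p.resize(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    p[i] = v3(pts(i, 0), pts(i, 1), pts(i, 2));
    scale = std::max(scale, std::abs(p[i].x));
    scale = std::max(scale, std::abs(p[i].y));
    scale = std::max(scale, std::abs(p[i].z));
  }
  double eps = 1e-10 * std::max(1.0, scale * scale * scale);

  // initial simplex: extremes on x, then farthest from line, then plane
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (p[i].x < p[i0].x) i0 = i;
    if (p[i].x > p[i1].x) i1 = i;
  }
  if (i0 == i1) return false;
  int i2 = -1; double best = eps;
  for (int i = 0; i < n; ++i) {
    double d = norm(cross(sub(p[i1], p[i0]), sub(p[i], p[i0])));
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) return false;
  int i3 = -1; best = eps;
  V3 nrm = cross(sub(p[i1], p[i0]), sub(p[i2], p[i0]));
  for (int i = 0; i < n; ++i) {
    double d = std::abs(dot(nrm, sub(p[i], p[i0])));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) return false;

  V3 centroid = v3((p[i0].x + p[i1].x + p[i2].x + p[i3].x) / 4.0,
                   (p[i0].y + p[i1].y + p[i2].y + p[i3].y) / 4.0,
                   (p[i0].z + p[i1].z + p[i2].z + p[i3].z) / 4.0);
  int idx4[4][3] = {{i0,i1,i2},{i0,i1,i3},{i0,i2,i3},{i1,i2,i3}};
  p.push_back(centroid);
  int ic = (int)p.size() - 1;
  for (int f = 0; f < 4; ++f) {
    Face fc = {idx4[f][0], idx4[f][1], idx4[f][2], true};
    if (orient(p, fc, ic) > 0) std::swap(fc.b, fc.c); // outward normal
    faces.push_back(fc);
  }

  for (int q = 0; q < n; ++q) {
    if (q == i0 || q == i1 || q == i2 || q == i3) continue;
    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); ++f)
      if (faces[f].alive && orient(p, faces[f], q) > eps)
        visible.push_back((int)f);
    if (visible.empty()) continue;
    // horizon: directed edges of visible faces whose reverse is not visible
    std::vector<std::pair<int,int> > edges;
    for (size_t k = 0; k < visible.size(); ++k) {
      const Face &f = faces[visible[k]];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int j = 0; j < 3; ++j) edges.push_back(std::make_pair(e[j][0], e[j][1]));
    }
    for (size_t k = 0; k < visible.size(); ++k) faces[visible[k]].alive = false;
    for (size_t k = 0; k < edges.size(); ++k) {
      bool horizon = true;
      for (size_t m = 0; m < edges.size(); ++m)
        if (edges[m].first == edges[k].second && edges[m].second == edges[k].first) {
          horizon = false; break;
        }
      if (horizon) {
        Face nf = {edges[k].first, edges[k].second, q, true};
        faces.push_back(nf);
      }
    }
  }

  return true;
}

// [[Rcpp::export]]
double cpp_convhull_volume(NumericMatrix pts) {
  std::vector<V3> p;
  std::vector<Face> faces;
  if (!build_hull(pts, p, faces)) return 0.0;
  double vol = 0.0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    const Face &fc = faces[f];
    vol += dot(p[fc.a], cross(p[fc.b], p[fc.c])) / 6.0;
  }
  return std::abs(vol);
}

// Number of query points lying inside (or on) the convex hull of pts.
// Used to rasterize the hull on the voxel grid so that digitization
// effects cancel in volume ratios.
// [[Rcpp::export]]
int cpp_convhull_inside_count(NumericMatrix pts, NumericMatrix queries,
                              double tol) {
  std::vector<V3> p;
  std::vector<Face> faces;
  if (!build_hull(pts, p, faces)) return 0;
  std::vector<int> live;
  for (size_t f = 0; f < faces.size(); ++f)
    if (faces[f].alive) live.push_back((int)f);
  int count = 0;
  for (int q = 0; q < queries.nrow(); ++q) {
    V3 pt = v3(queries(q, 0), queries(q, 1), queries(q, 2));
    bool inside = true;
    for (size_t k = 0; k < live.size(); ++k) {
      const Face &f = faces[live[k]];
      V3 nrm = cross(sub(p[f.b], p[f.a]), sub(p[f.c], p[f.a]));
      double nn = norm(nrm);
      if (nn == 0) continue;
      if (dot(nrm, sub(pt, p[f.a])) / nn > tol) { inside = false; break; }
    }
    if (inside) ++count;
  }
  return count;
}

// Largest pairwise Euclidean distance among points (maximum 3D diameter).
// [[Rcpp::export]]
double cpp_max_pairwise(NumericMatrix pts) {
  int n = pts.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(i,0) - pts(j,0), dy = pts(i,1) - pts(j,1),
             dz = pts(i,2) - pts(j,2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
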