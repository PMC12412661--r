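// Geometry kernels: nearest-neighbour queries, tube distance fields, and
// isosurface extraction by tetrahedral decomposition of the voxel grid.

#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// For each query point, index (1-based) of and distance to the nearest
// reference point. Brute force; adequate for the problem sizes used here.
// [[Rcpp::export]]
List nearest_point_cpp(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  std::vector<double> rx(nr), ry(nr), rz(nr);
  for (int j = 0; j < nr; ++j) {
    rx[j] = ref(j, 0); ry[j] = ref(j, 1); rz[j] = ref(j, 2);
  }
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = 1e300;
    int bj = 0;
    for (int j = 0; j < nr; ++j) {
      const double dx = qx - rx[j], dy = qy - ry[j], dz = qz - rz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Signed tube field on a grid: for each voxel center,
// min_j (|x - c_j| - r_j) over centerline samples c_j with local radii r_j.
// Negative inside the lumen.
// [[Rcpp::export]]
NumericVector tube_field_cpp(IntegerVector dims, NumericVector spacing,
                             NumericVector origin, NumericMatrix curve,
                             NumericVector radii) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int m = curve.nrow();
  NumericVector out((long)nx * ny * nz);
  out.attr("dim") = dims;
  std::vector<double> cx(m), cy(m), cz(m), r(m);
  for (int j = 0; j < m; ++j) {
    cx[j] = curve(j, 0); cy[j] = curve(j, 1); cz[j] = curve(j, 2);
    r[j] = radii[j];
  }
  long o = 0;
  for (int l = 0; l < nz; ++l) {
    const double z = origin[2] + l * spacing[2];
    for (int jj = 0; jj < ny; ++jj) {
      const double y = origin[1] + jj * spacing[1];
      for (int i = 0; i < nx; ++i, ++o) {
        const double x = origin[0] + i * spacing[0];
        double best = 1e300;
        for (int j = 0; j < m; ++j) {
          const double dx = x - cx[j], dy = y - cy[j], dz = z - cz[j];
          const double d = std::sqrt(dx * dx + dy * dy + dz * dz) - r[j];
          if (d < best) best = d;
        }
        out[o] = best;
      }
    }
  }
  return out;
}

// ---- Isosurface by marching tetrahedra ----
// Each grid cube is split into 6 tetrahedra around the main diagonal
// (corner 0 to corner 7); the split is identical in every cube, so faces of
// neighbouring cubes are triangulated consistently and the result is
// watertight wherever the surface does not hit the grid boundary.
// "Inside" is value > level. Surface vertices are interpolated on edges and
// deduplicated by grid-edge key, triangles oriented with normals pointing
// outward (from inside to outside).

struct MTState {
  std::unordered_map<long long, int> edge_id;
  std::vector<double> verts;   // x,y,z triples
  std::vector<int> tris;       // 1-based vertex ids
};

static int edge_vertex(MTState& st, long long ga, long long gb, double va,
                       double vb, const double* pa, const double* pb,
                       double level) {
  if (gb < ga) { std::swap(ga, gb); std::swap(va, vb);
                 const double* t = pa; pa = pb; pb = t; }
  long long key = ga * 100000000LL + gb;  // grids here are far below 1e8 voxels
  auto it = st.edge_id.find(key);
  if (it != st.edge_id.end()) return it->second;
  double t = (level - va) / (vb - va);
  if (t < 1e-6) t = 1e-6;
  if (t > 1 - 1e-6) t = 1 - 1e-6;
  st.verts.push_back(pa[0] + t * (pb[0] - pa[0]));
  st.verts.push_back(pa[1] + t * (pb[1] - pa[1]));
  st.verts.push_back(pa[2] + t * (pb[2] - pa[2]));
  int id = (int)(st.verts.size() / 3);
  st.edge_id[key] = id;
  return id;
}

static void emit_tri(MTState& st, int a, int b, int c,
                     const double* inside_pt) {
  // orient so the normal points away from the inside corner
  const double* pa = &st.verts[3 * (a - 1)];
  const double* pb = &st.verts[3 * (b - 1)];
  const double* pc = &st.verts[3 * (c - 1)];
  double u[3] = {pb[0] - pa[0], pb[1] - pa[1], pb[2] - pa[2]};
  double v[3] = {pc[0] - pa[0], pc[1] - pa[1], pc[2] - pa[2]};
  double n[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                 u[0] * v[1] - u[1] * v[0]};
  double w[3] = {inside_pt[0] - pa[0], inside_pt[1] - pa[1],
                 inside_pt[2] - pa[2]};
  double dot = n[0] * w[0] + n[1] * w[1] + n[2] * w[2];
  if (dot > 0) std::swap(b, c);
  st.tris.push_back(a); st.tris.push_back(b); st.tris.push_back(c);
}

// [[Rcpp::export]]
List marching_tetrahedra_cpp(NumericVector field, double level,
                             NumericVector spacing, NumericVector origin) {
  IntegerVector d = field.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const double* f = field.begin();
  MTState st;
  // cube corners: bit 0 -> +x, bit 1 -> +y, bit 2 -> +z
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                                 {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  double cpos[8][3];
  double cval[8];
  long long gid[8];
  for (int l = 0; l + 1 < nz; ++l)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        for (int c = 0; c < 8; ++c) {
          const int ci = i + (c & 1), cj = j + ((c >> 1) & 1),
                    cl = l + ((c >> 2) & 1);
          gid[c] = ci + (long long)nx * (cj + (long long)ny * cl);
          cval[c] = f[gid[c]];
          cpos[c][0] = origin[0] + ci * spacing[0];
          cpos[c][1] = origin[1] + cj * spacing[1];
          cpos[c][2] = origin[2] + cl * spacing[2];
        }
        for (int t = 0; t < 6; ++t) {
          const int* T = tets[t];
          int in[4], nin = 0;
          for (int c = 0; c < 4; ++c)
            in[c] = cval[T[c]] > level ? (++nin, 1) : 0;
          if (nin == 0 || nin == 4) continue;
          int A[4], B[4], na = 0, nb = 0;
          for (int c = 0; c < 4; ++c)
            if (in[c]) A[na++] = T[c]; else B[nb++] = T[c];
          if (nin == 1 || nin == 3) {
            const int apex = (nin == 1) ? A[0] : B[0];
            const int* others = (nin == 1) ? B : A;
            int e[3];
            for (int c = 0; c < 3; ++c)
              e[c] = edge_vertex(st, gid[apex], gid[others[c]], cval[apex],
                                 cval[others[c]], cpos[apex], cpos[others[c]],
                                 level);
            const double* ip = (nin == 1) ? cpos[A[0]] : cpos[A[0]];
            emit_tri(st, e[0], e[1], e[2], ip);
          } else {
            // 2 inside, 2 outside: quad on the 4 crossing edges
            int e00 = edge_vertex(st, gid[A[0]], gid[B[0]], cval[A[0]],
                                  cval[B[0]], cpos[A[0]], cpos[B[0]], level);
            int e01 = edge_vertex(st, gid[A[0]], gid[B[1]], cval[A[0]],
                                  cval[B[1]], cpos[A[0]], cpos[B[1]], level);
            int e10 = edge_vertex(st, gid[A[1]], gid[B[0]], cval[A[1]],
                                  cval[B[0]], cpos[A[1]], cpos[B[0]], level);
            int e11 = edge_vertex(st, gid[A[1]], gid[B[1]], cval[A[1]],
                                  cval[B[1]], cpos[A[1]], cpos[B[1]], level);
            emit_tri(st, e00, e01, e11, cpos[A[0]]);
            emit_tri(st, e00, e11, e10, cpos[A[0]]);
          }
        }
      }
  const int nv = (int)(st.verts.size() / 3);
  const int nf = (int)(st.tris.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int v = 0; v < nv; ++v)
    for (int c = 0; c < 3; ++c) V(v, c) = st.verts[3 * v + c];
  for (int t = 0; t < nf; ++t)
    for (int c = 0; c < 3; ++c) F(t, c) = st.tris[3 * t + c];
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Uniform-grid accelerated nearest neighbour: same contract as
// nearest_point_cpp but O(n) bucketing for large query sets.
// [[Rcpp::export]]
List nearest_point_grid_cpp(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  double lo[3], hi[3];
  for (int c = 0; c < 3; ++c) { lo[c] = 1e300; hi[c] = -1e300; }
  for (int j = 0; j < nr; ++j)
    for (int c = 0; c < 3; ++c) {
      lo[c] = std::min(lo[c], ref(j, c));
      hi[c] = std::max(hi[c], ref(j, c));
    }
  // aim for ~2 points per cell
  int ncell = (int)std::cbrt(std::max(1.0, nr / 2.0));
  if (ncell < 1) ncell = 1;
  if (ncell > 128) ncell = 128;
  double cs[3];
  for (int c = 0; c < 3; ++c) {
    double span = hi[c] - lo[c];
    cs[c] = span > 0 ? span / ncell : 1.0;
  }
  std::vector<std::vector<int>> cells(ncell * ncell * ncell);
  auto cell_of = [&](double x, double y, double z, int* g) {
    double p[3] = {x, y, z};
    for (int c = 0; c < 3; ++c) {
      int v = (int)((p[c] - lo[c]) / cs[c]);
      g[c] = v < 0 ? 0 : (v >= ncell ? ncell - 1 : v);
    }
  };
  int g[3];
  for (int j = 0; j < nr; ++j) {
    cell_of(ref(j, 0), ref(j, 1), ref(j, 2), g);
    cells[g[0] + ncell * (g[1] + ncell * g[2])].push_back(j);
  }
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    cell_of(qx, qy, qz, g);
    double best = 1e300;
    int bj = -1;
    for (int ring = 0; ring < 2 * ncell; ++ring) {
      // scan the shell of cells at Chebyshev distance `ring`
      bool any = false;
      for (int dz = -ring; dz <= ring; ++dz) {
        int cz = g[2] + dz;
        if (cz < 0 || cz >= ncell) continue;
        for (int dy = -ring; dy <= ring; ++dy) {
          int cy = g[1] + dy;
          if (cy < 0 || cy >= ncell) continue;
          for (int dx = -ring; dx <= ring; ++dx) {
            if (std::max(std::abs(dx), std::max(std::abs(dy),
                                                std::abs(dz))) != ring)
              continue;
            int cx = g[0] + dx;
            if (cx < 0 || cx >= ncell) continue;
            any = true;
            for (int j : cells[cx + ncell * (cy + ncell * cz)]) {
              const double ddx = qx - ref(j, 0), ddy = qy - ref(j, 1),
                           ddz = qz - ref(j, 2);
              const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 < best) { best = d2; bj = j; }
            }
          }
        }
      }
      if (bj >= 0) {
        // found a candidate: one extra ring guarantees correctness only if
        // the candidate distance is within `ring` cells; check explicitly
        double safe = (double)ring * std::min(cs[0], std::min(cs[1], cs[2]));
        if (std::sqrt(best) <= safe || ring >= 2 * ncell - 1) break;
      }
      if (!any && bj >= 0) break;
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// 6-connected component labels of a binary volume (0 stays 0; foreground
// voxels get 1-based component ids). Linear-time BFS.
// [[Rcpp::export]]
IntegerVector label_components_cpp(NumericVector label) {
  IntegerVector d = label.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const long n = (long)nx * ny * nz;
  IntegerVector comp(n);
  comp.attr("dim") = d;
  const double* lab = label.begin();
  std::vector<long> queue;
  int next_id = 0;
  for (long s = 0; s < n; ++s) {
    if (lab[s] == 0 || comp[s] != 0) continue;
    ++next_id;
    comp[s] = next_id;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      const long v = queue.back();
      queue.pop_back();
      const int i = v % nx, j = (v / nx) % ny, k = (int)(v / ((long)nx * ny));
      const int di[6] = {1, -1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, 1, -1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, 1, -1};
      for (int o = 0; o < 6; ++o) {
        const int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const long w = ii + (long)nx * (jj + (long)ny * kk);
        if (lab[w] != 0 && comp[w] == 0) {
          comp[w] = next_id;
          queue.push_back(w);
        }
      }
    }
  }
  return comp;
}
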