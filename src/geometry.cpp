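#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// 8-connected component labeling of a binary mask by breadth-first search.
// Returns an integer matrix: 0 = background, 1..k = component id.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int cur = 0;
  std::queue<std::pair<int,int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++cur;
      lab(i, j) = cur;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = cur;
              q.push(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}

// z-directed pseudo signed distance field of a closed triangle mesh,
// sampled on the tensor grid xs x ys x zs. Negative inside, positive
// outside; magnitude is the vertical distance to the nearest surface
// crossing along the grid column (capped by the z range for empty columns).
// faces are 1-based triangle vertex indices.
// [[Rcpp::export]]
NumericVector cpp_mesh_zfield(NumericMatrix verts, IntegerMatrix faces,
                              NumericVector xs, NumericVector ys,
                              NumericVector zs) {
  int nx = xs.size(), ny = ys.size(), nz = zs.size();
  int nf = faces.nrow();
  double zr = zs[nz - 1] - zs[0] + 1.0;
  NumericVector field((R_xlen_t)nx * ny * nz);
  int odd_columns = 0;
  // bucket triangles by the grid columns their xy-bbox covers
  double x0 = xs[0], y0 = ys[0];
  double hx = nx > 1 ? xs[1] - xs[0] : 1.0;
  double hy = ny > 1 ? ys[1] - ys[0] : 1.0;
  std::vector< std::vector<int> > bucket((size_t)nx * ny);
  for (int f = 0; f < nf; ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    double xmin = std::min(verts(a, 0), std::min(verts(b, 0), verts(c, 0)));
    double xmax = std::max(verts(a, 0), std::max(verts(b, 0), verts(c, 0)));
    double ymin = std::min(verts(a, 1), std::min(verts(b, 1), verts(c, 1)));
    double ymax = std::max(verts(a, 1), std::max(verts(b, 1), verts(c, 1)));
    int i0 = std::max(0, (int)std::ceil((xmin - x0) / hx));
    int i1 = std::min(nx - 1, (int)std::floor((xmax - x0) / hx));
    int j0 = std::max(0, (int)std::ceil((ymin - y0) / hy));
    int j1 = std::min(ny - 1, (int)std::floor((ymax - y0) / hy));
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i)
        bucket[(size_t)i + (size_t)nx * j].push_back(f);
  }
  std::vector<double> cross;
  for (int iy = 0; iy < ny; ++iy) {
    double py = ys[iy];
    for (int ix = 0; ix < nx; ++ix) {
      double px = xs[ix];
      cross.clear();
      const std::vector<int>& cand = bucket[(size_t)ix + (size_t)nx * iy];
      for (size_t fi = 0; fi < cand.size(); ++fi) {
        int f = cand[fi];
        int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
        double ax = verts(a, 0), ay = verts(a, 1);
        double bx = verts(b, 0), by = verts(b, 1);
        double cx = verts(c, 0), cy = verts(c, 1);
        double d = (bx - ax) * (cy - ay) - (cx - ax) * (by - ay);
        if (std::fabs(d) < 1e-300) continue; // vertical triangle
        double u = ((px - ax) * (cy - ay) - (cx - ax) * (py - ay)) / d;
        double v = ((bx - ax) * (py - ay) - (px - ax) * (by - ay)) / d;
        if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
        double z = verts(a, 2) + u * (verts(b, 2) - verts(a, 2)) +
                   v * (verts(c, 2) - verts(a, 2));
        cross.push_back(z);
      }
      std::sort(cross.begin(), cross.end());
      bool usable = !cross.empty();
      if (usable && (cross.size() % 2 != 0)) {
        ++odd_columns;
        usable = false; // numerically ambiguous column, treat as outside
      }
      for (int iz = 0; iz < nz; ++iz) {
        double z = zs[iz];
        double val;
        if (!usable) {
          val = zr;
        } else {
          // parity: number of crossings above z
          size_t above = cross.end() -
            std::upper_bound(cross.begin(), cross.end(), z);
          double dmin = zr;
          for (size_t k = 0; k < cross.size(); ++k) {
            double dd = std::fabs(cross[k] - z);
            if (dd < dmin) dmin = dd;
          }
          val = (above % 2 == 1) ? -dmin : dmin;
        }
        field[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] = val;
      }
    }
  }
  field.attr("odd_columns") = odd_columns;
  return field;
}

static inline std::uint64_t edge_key(int a, int b) {
  if (a > b) std::swap(a, b);
  return (static_cast<std::uint64_t>(a) << 32) | static_cast<std::uint32_t>(b);
}

struct MTState {
  std::unordered_map<std::uint64_t, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

static int interp_vertex(MTState& st, int ga, int gb,
                         const double* px, const double* py, const double* pz,
                         const double* fv, double iso) {
  std::uint64_t key = edge_key(ga, gb);
  std::unordered_map<std::uint64_t, int>::iterator it = st.vmap.find(key);
  if (it != st.vmap.end()) return it->second;
  double va = fv[ga], vb = fv[gb];
  double t = (iso - va) / (vb - va);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  st.vx.push_back(px[ga] + t * (px[gb] - px[ga]));
  st.vy.push_back(py[ga] + t * (py[gb] - py[ga]));
  st.vz.push_back(pz[ga] + t * (pz[gb] - pz[ga]));
  int id = (int)st.vx.size(); // 1-based
  st.vmap[key] = id;
  return id;
}

static void emit_tri(MTState& st, int a, int b, int c,
                     double ox, double oy, double oz) {
  // orient so the normal points along (ox,oy,oz), the local outward direction
  double ax = st.vx[a - 1], ay = st.vy[a - 1], az = st.vz[a - 1];
  double ux = st.vx[b - 1] - ax, uy = st.vy[b - 1] - ay, uz = st.vz[b - 1] - az;
  double wx = st.vx[c - 1] - ax, wy = st.vy[c - 1] - ay, wz = st.vz[c - 1] - az;
  double nxv = uy * wz - uz * wy;
  double nyv = uz * wx - ux * wz;
  double nzv = ux * wy - uy * wx;
  if (nxv * ox + nyv * oy + nzv * oz < 0) std::swap(b, c);
  st.f0.push_back(a); st.f1.push_back(b); st.f2.push_back(c);
}

// Marching tetrahedra over a scalar grid (negative = inside). Returns a
// closed triangle mesh of the iso-level surface, provided the surface does
// not touch the grid boundary. field is laid out x-fastest.
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims,
                       NumericVector xs, NumericVector ys, NumericVector zs,
                       double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> fv(field.begin(), field.end());
  // nudge exact-iso samples to keep triangles non-degenerate
  double scale = 0.0;
  for (size_t i = 0; i < fv.size(); ++i)
    scale = std::max(scale, std::fabs(fv[i]));
  double eps = (scale > 0 ? scale : 1.0) * 1e-12;
  for (size_t i = 0; i < fv.size(); ++i)
    if (fv[i] == iso) fv[i] = iso + eps;
  // grid point coordinates, flattened like the field
  std::vector<double> px((size_t)nx * ny * nz), py(px.size()), pz(px.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t g = (size_t)i + (size_t)nx * (j + (size_t)ny * k);
        px[g] = xs[i]; py[g] = ys[j]; pz[g] = zs[k];
      }
  // 6-tetrahedra decomposition of the unit cube along diagonal 0-7
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
  };
  MTState st;
  int corner[8];
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          corner[c] = ci + nx * (cj + ny * ck);
        }
        // skip cells with uniform sign
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          if (fv[corner[c]] < iso) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          int g[4];
          bool in[4];
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            g[c] = corner[tets[t][c]];
            in[c] = fv[g[c]] < iso;
            if (in[c]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          // local outward direction: centroid(outside) - centroid(inside)
          double cix = 0, ciy = 0, ciz = 0, cox = 0, coy = 0, coz = 0;
          for (int c = 0; c < 4; ++c) {
            if (in[c]) { cix += px[g[c]]; ciy += py[g[c]]; ciz += pz[g[c]]; }
            else       { cox += px[g[c]]; coy += py[g[c]]; coz += pz[g[c]]; }
          }
          double ox = cox / (4 - nin) - cix / nin;
          double oy = coy / (4 - nin) - ciy / nin;
          double oz = coz / (4 - nin) - ciz / nin;
          if (nin == 1 || nin == 3) {
            int apex = -1;
            for (int c = 0; c < 4; ++c)
              if (in[c] == (nin == 1)) { apex = c; break; }
            int e[3], m = 0;
            for (int c = 0; c < 4; ++c) {
              if (c == apex) continue;
              e[m++] = interp_vertex(st, g[apex], g[c], &px[0], &py[0], &pz[0],
                                     &fv[0], iso);
            }
            emit_tri(st, e[0], e[1], e[2], ox, oy, oz);
          } else { // nin == 2
            int pin[2], pout[2], mi = 0, mo = 0;
            for (int c = 0; c < 4; ++c) {
              if (in[c]) pin[mi++] = c; else pout[mo++] = c;
            }
            int A = interp_vertex(st, g[pin[0]], g[pout[0]], &px[0], &py[0],
                                  &pz[0], &fv[0], iso);
            int B = interp_vertex(st, g[pin[0]], g[pout[1]], &px[0], &py[0],
                                  &pz[0], &fv[0], iso);
            int C = interp_vertex(st, g[pin[1]], g[pout[1]], &px[0], &py[0],
                                  &pz[0], &fv[0], iso);
            int D = interp_vertex(st, g[pin[1]], g[pout[0]], &px[0], &py[0],
                                  &pz[0], &fv[0], iso);
            emit_tri(st, A, B, C, ox, oy, oz);
            emit_tri(st, A, C, D, ox, oy, oz);
          }
        }
      }
    }
  }
  int nv = (int)st.vx.size(), nf = (int)st.f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i];
  }
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = st.f0[i]; F(i, 1) = st.f1[i]; F(i, 2) = st.f2[i];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
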