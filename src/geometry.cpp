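// Geometry kernels: voxelisation, nearest-neighbour queries, point-to-surface
// distances and Poisson-disc candidate filtering. All distances are in the
// units of the input coordinates (millimetres throughout the package).
#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Deterministic sub-cell jitter applied to ray origins so that rays never pass
// exactly through mesh vertices/edges (parity test ties). Tiny relative to any
// sensible voxel spacing.
static const double RAY_JX = 1.0e-7 * 1.2345;
static const double RAY_JY = 1.0e-7 * 2.6789;

// [[Rcpp::export]]
LogicalVector cpp_voxel_occupancy(NumericMatrix verts, IntegerMatrix faces,
                                  NumericVector origin, double spacing,
                                  IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nf = faces.nrow();
  // crossings[ix + nx*iy] -> z values where the vertical ray crosses the mesh
  std::vector< std::vector<double> > crossings((size_t)nx * ny);

  for (int f = 0; f < nf; ++f) {
    const int a = faces(f, 0), b = faces(f, 1), c = faces(f, 2);
    const double ax = verts(a,0), ay = verts(a,1), az = verts(a,2);
    const double bx = verts(b,0), by = verts(b,1), bz = verts(b,2);
    const double cx = verts(c,0), cy = verts(c,1), cz = verts(c,2);
    const double xmin = std::min(ax, std::min(bx, cx));
    const double xmax = std::max(ax, std::max(bx, cx));
    const double ymin = std::min(ay, std::min(by, cy));
    const double ymax = std::max(ay, std::max(by, cy));
    int i0 = std::max(0, (int)std::floor((xmin - origin[0]) / spacing - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil((xmax - origin[0]) / spacing));
    int j0 = std::max(0, (int)std::floor((ymin - origin[1]) / spacing - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((ymax - origin[1]) / spacing));
    for (int j = j0; j <= j1; ++j) {
      const double py = origin[1] + (j + 0.5) * spacing + RAY_JY;
      for (int i = i0; i <= i1; ++i) {
        const double px = origin[0] + (i + 0.5) * spacing + RAY_JX;
        // 2-D edge functions of the xy-projection
        const double e0 = (bx - ax) * (py - ay) - (by - ay) * (px - ax);
        const double e1 = (cx - bx) * (py - by) - (cy - by) * (px - bx);
        const double e2 = (ax - cx) * (py - cy) - (ay - cy) * (px - cx);
        const bool inside = (e0 > 0 && e1 > 0 && e2 > 0) ||
                            (e0 < 0 && e1 < 0 && e2 < 0);
        if (!inside) continue;
        const double area2 = e0 + e1 + e2; // signed doubled area of projection
        if (std::fabs(area2) < 1e-300) continue; // vertical triangle
        // barycentric interpolation of z at (px, py)
        const double z = (e1 * az + e2 * bz + e0 * cz) / area2;
        crossings[(size_t)i + (size_t)nx * j].push_back(z);
      }
    }
  }

  LogicalVector occ((R_xlen_t)nx * ny * nz);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      std::vector<double>& cr = crossings[(size_t)i + (size_t)nx * j];
      if (cr.empty()) continue;
      std::sort(cr.begin(), cr.end());
      for (int k = 0; k < nz; ++k) {
        const double zc = origin[2] + (k + 0.5) * spacing;
        // parity of crossings below the cell centre
        size_t below = std::lower_bound(cr.begin(), cr.end(), zc) - cr.begin();
        if (below % 2 == 1)
          occ[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  return occ;
}

// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double x = a(i,0), y = a(i,1), z = a(i,2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = x - b(j,0), dy = y - b(j,1), dz = z - b(j,2);
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_knn(NumericMatrix query, NumericMatrix ref, int k) {
  const int n = query.nrow(), m = ref.nrow();
  if (k > m) k = m;
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector< std::pair<double,int> > d2(m);
  for (int i = 0; i < n; ++i) {
    const double x = query(i,0), y = query(i,1), z = query(i,2);
    for (int j = 0; j < m; ++j) {
      const double dx = x - ref(j,0), dy = y - ref(j,1), dz = z - ref(j,2);
      d2[j] = std::make_pair(dx*dx + dy*dy + dz*dz, j);
    }
    std::partial_sort(d2.begin(), d2.begin() + k, d2.end());
    for (int j = 0; j < k; ++j) {
      idx(i, j) = d2[j].second + 1; // 1-based for R
      dist(i, j) = std::sqrt(d2[j].first);
    }
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

static inline double clamp01(double v) {
  return v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
}

// Closest-point distance from p to triangle (a, b, c); Ericson, RTCD ch. 5.
static double point_tri_dist2(const double* p, const double* a,
                              const double* b, const double* c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i]-a[i]; ac[i] = c[i]-a[i]; ap[i] = p[i]-a[i]; }
  const double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  const double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) { q[0]=a[0]; q[1]=a[1]; q[2]=a[2]; }
  else {
    double bp[3]; for (int i = 0; i < 3; ++i) bp[i] = p[i]-b[i];
    const double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    const double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) { q[0]=b[0]; q[1]=b[1]; q[2]=b[2]; }
    else {
      const double vc = d1*d4 - d3*d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        const double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) q[i] = a[i] + v*ab[i];
      } else {
        double cp[3]; for (int i = 0; i < 3; ++i) cp[i] = p[i]-c[i];
        const double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
        const double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
        if (d6 >= 0.0 && d5 <= d6) { q[0]=c[0]; q[1]=c[1]; q[2]=c[2]; }
        else {
          const double vb = d5*d2 - d1*d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            const double w = d2 / (d2 - d6);
            for (int i = 0; i < 3; ++i) q[i] = a[i] + w*ac[i];
          } else {
            const double va = d3*d6 - d5*d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int i = 0; i < 3; ++i) q[i] = b[i] + w*(c[i]-b[i]);
            } else {
              const double denom = 1.0 / (va + vb + vc);
              const double v = clamp01(vb * denom), w = clamp01(vc * denom);
              for (int i = 0; i < 3; ++i) q[i] = a[i] + ab[i]*v + ac[i]*w;
            }
          }
        }
      }
    }
  }
  const double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix points, NumericMatrix verts,
                                  IntegerMatrix faces) {
  const int np = points.nrow(), nf = faces.nrow();
  // per-triangle bounding sphere (centroid + radius) for cheap rejection
  std::vector<double> cxv(nf), cyv(nf), czv(nf), rad(nf);
  for (int f = 0; f < nf; ++f) {
    const int a = faces(f,0), b = faces(f,1), c = faces(f,2);
    const double cx = (verts(a,0)+verts(b,0)+verts(c,0))/3.0;
    const double cy = (verts(a,1)+verts(b,1)+verts(c,1))/3.0;
    const double cz = (verts(a,2)+verts(b,2)+verts(c,2))/3.0;
    double r2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      const int v = faces(f,k);
      const double dx = verts(v,0)-cx, dy = verts(v,1)-cy, dz = verts(v,2)-cz;
      r2 = std::max(r2, dx*dx+dy*dy+dz*dz);
    }
    cxv[f]=cx; cyv[f]=cy; czv[f]=cz; rad[f]=std::sqrt(r2);
  }
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = { points(i,0), points(i,1), points(i,2) };
    double best = R_PosInf, bestd = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      const double dx = p[0]-cxv[f], dy = p[1]-cyv[f], dz = p[2]-czv[f];
      const double dcen = std::sqrt(dx*dx+dy*dy+dz*dz);
      const double lower = dcen - rad[f];
      if (lower >= bestd) continue;
      double av[3] = { verts(faces(f,0),0), verts(faces(f,0),1), verts(faces(f,0),2) };
      double bv[3] = { verts(faces(f,1),0), verts(faces(f,1),1), verts(faces(f,1),2) };
      double cv[3] = { verts(faces(f,2),0), verts(faces(f,2),1), verts(faces(f,2),2) };
      const double d2 = point_tri_dist2(p, av, bv, cv);
      if (d2 < best) { best = d2; bestd = std::sqrt(d2); }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

static inline int64_t hash_key(int ix, int iy, int iz) {
  return ((int64_t)ix * 73856093LL) ^ ((int64_t)iy * 19349663LL) ^
         ((int64_t)iz * 83492791LL);
}

// Greedy Poisson-disc thinning: keep candidates (in order) at least rmin apart.
// [[Rcpp::export]]
LogicalVector cpp_poisson_filter(NumericMatrix pts, double rmin) {
  const int n = pts.nrow();
  LogicalVector keep(n);
  const double cell = rmin;
  std::unordered_map<int64_t, std::vector<int> > grid;
  const double r2 = rmin * rmin;
  for (int i = 0; i < n; ++i) {
    const double x = pts(i,0), y = pts(i,1), z = pts(i,2);
    const int ix = (int)std::floor(x/cell), iy = (int)std::floor(y/cell),
              iz = (int)std::floor(z/cell);
    bool ok = true;
    for (int dx = -1; dx <= 1 && ok; ++dx)
      for (int dy = -1; dy <= 1 && ok; ++dy)
        for (int dz = -1; dz <= 1 && ok; ++dz) {
          auto it = grid.find(hash_key(ix+dx, iy+dy, iz+dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            const double ddx = x-pts(j,0), ddy = y-pts(j,1), ddz = z-pts(j,2);
            if (ddx*ddx+ddy*ddy+ddz*ddz < r2) { ok = false; break; }
          }
        }
    if (ok) {
      keep[i] = true;
      grid[hash_key(ix, iy, iz)].push_back(i);
    }
  }
  return keep;
}
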