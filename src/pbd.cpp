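// Position-based-dynamics solver core. Gauss-Seidel projection of distance,
// global volume (inflatable overpressure), shape-matching cluster and
// inter-body particle collision constraints, with a semi-implicit predictor
// and velocity update from position deltas. Deterministic: fixed iteration
// order, no randomness.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int64_t hash_key(int ix, int iy, int iz) {
  return ((int64_t)ix * 73856093LL) ^ ((int64_t)iy * 19349663LL) ^
         ((int64_t)iz * 83492791LL);
}

static inline void cross3(const double* u, const double* v, double* out) {
  out[0] = u[1]*v[2] - u[2]*v[1];
  out[1] = u[2]*v[0] - u[0]*v[2];
  out[2] = u[0]*v[1] - u[1]*v[0];
}

// Enclosed volume of the oriented triangle set over current positions.
static double signed_volume(const arma::mat& x, const arma::imat& faces) {
  double v = 0.0;
  for (arma::uword f = 0; f < faces.n_rows; ++f) {
    const arma::uword a = faces(f,0), b = faces(f,1), c = faces(f,2);
    double cr[3];
    const double av[3] = { x(a,0), x(a,1), x(a,2) };
    const double bv[3] = { x(b,0), x(b,1), x(b,2) };
    const double cv[3] = { x(c,0), x(c,1), x(c,2) };
    cross3(bv, cv, cr);
    v += av[0]*cr[0] + av[1]*cr[1] + av[2]*cr[2];
  }
  return v / 6.0;
}

// Rodrigues rotation matrix about unit axis by angle.
static arma::mat33 axis_angle(const arma::vec3& axis, double angle) {
  const double c = std::cos(angle), s = std::sin(angle), t = 1.0 - c;
  const double x = axis(0), y = axis(1), z = axis(2);
  arma::mat33 R;
  R(0,0) = t*x*x + c;   R(0,1) = t*x*y - s*z; R(0,2) = t*x*z + s*y;
  R(1,0) = t*x*y + s*z; R(1,1) = t*y*y + c;   R(1,2) = t*y*z - s*x;
  R(2,0) = t*x*z - s*y; R(2,1) = t*y*z + s*x; R(2,2) = t*z*z + c;
  return R;
}

// Polar rotation factor of a 3x3 moment matrix by warm-started rotation
// extraction (Mueller et al. style): stays in SO(3), handles degeneracy by
// leaving the warm start unchanged.
static void polar_rotation(const arma::mat33& A, arma::mat33& R,
                           int max_iter = 12, double tol = 1e-5) {
  for (int it = 0; it < max_iter; ++it) {
    arma::vec3 omega(arma::fill::zeros);
    double denom = 0.0;
    for (int c = 0; c < 3; ++c) {
      const arma::vec3 rc = R.col(c);
      const arma::vec3 ac = A.col(c);
      omega += arma::cross(rc, ac);
      denom += arma::dot(rc, ac);
    }
    omega /= (std::fabs(denom) + 1e-9);
    const double w = arma::norm(omega);
    if (w < tol) break;
    R = axis_angle(omega / w, w) * R;
  }
}

// [[Rcpp::export]]
List cpp_pbd_run(NumericMatrix pos_in, NumericMatrix prev_in,
                 NumericVector invmass_in, IntegerVector body,
                 double radius, NumericMatrix rest_in,
                 IntegerMatrix dist_ij, NumericVector dist_rest,
                 NumericVector dist_stiff,
                 IntegerMatrix vol_faces_in, double vol_v0, double vol_kp,
                 double vol_stiff,
                 IntegerVector cl_ptr, IntegerVector cl_members,
                 NumericMatrix cl_offsets, NumericVector cl_stiff,
                 List cfg) {
  const int n = pos_in.nrow();
  arma::mat x(pos_in.begin(), n, 3);
  arma::mat prev(prev_in.begin(), n, 3);
  arma::vec w(invmass_in.begin(), n);
  arma::mat rest(rest_in.begin(), n, 3);
  arma::imat vfaces(vol_faces_in.nrow(), 3);
  for (int f = 0; f < vol_faces_in.nrow(); ++f)
    for (int k = 0; k < 3; ++k) vfaces(f,k) = vol_faces_in(f,k);

  const double dt = as<double>(cfg["time_step"]);
  const int iters = as<int>(cfg["solver_iterations"]);
  const double damping = as<double>(cfg["damping"]);
  NumericVector gravity = cfg["gravity"];
  const double margin = as<double>(cfg["collision_margin"]);
  const double tol = as<double>(cfg["equilibrium_tolerance"]);
  const int max_steps = as<int>(cfg["max_steps"]);
  const bool collide = as<bool>(cfg["collide"]);

  const int nd = dist_ij.nrow();
  // iteration-corrected stiffness so Table-1 values are iteration independent
  std::vector<double> kd(nd);
  for (int c = 0; c < nd; ++c)
    kd[c] = 1.0 - std::pow(1.0 - dist_stiff[c], 1.0 / iters);
  const double kv = 1.0 - std::pow(1.0 - vol_stiff, 1.0 / iters);
  const int ncl = cl_ptr.size() - 1;
  std::vector<double> kc(ncl > 0 ? ncl : 0);
  for (int c = 0; c < ncl; ++c)
    kc[c] = 1.0 - std::pow(1.0 - cl_stiff[c], 1.0 / iters);

  // rest centroids of clusters are implied by offsets summing to zero
  const double dc = 2.0 * radius + margin;   // contact distance
  const double dc2 = dc * dc;
  // candidate pairs are gathered once per step with a slack radius so the
  // list stays valid while positions move during the iterations
  const double search = 1.5 * dc;
  const double search2 = search * search;
  const double cell = search;

  // warm-started per-cluster rotations
  std::vector<arma::mat33> cl_R(ncl > 0 ? ncl : 0, arma::eye(3, 3));
  arma::mat grad(n, 3, arma::fill::zeros);
  std::vector<int> pair_i, pair_j;
  std::vector<double> pair_dc;

  arma::mat step_start(n, 3);
  double residual = NA_REAL;
  bool converged = false;
  int steps = 0;

  for (int step = 0; step < max_steps; ++step) {
    ++steps;
    step_start = x;
    // predict
    for (int i = 0; i < n; ++i) {
      if (w(i) <= 0.0) continue;
      for (int k = 0; k < 3; ++k) {
        double v = (x(i,k) - prev(i,k)) / dt;
        v = v * (1.0 - damping) + gravity[k] * dt;
        prev(i,k) = x(i,k);
        x(i,k) += v * dt;
      }
    }
    for (int i = 0; i < n; ++i)
      if (w(i) <= 0.0) { prev(i,0)=x(i,0); prev(i,1)=x(i,1); prev(i,2)=x(i,2); }

    // gather inter-body candidate contact pairs for this step
    if (collide) {
      pair_i.clear();
      pair_j.clear();
      pair_dc.clear();
      std::unordered_map<int64_t, std::vector<int> > grid;
      grid.reserve((size_t)n * 2);
      for (int i = 0; i < n; ++i)
        grid[hash_key((int)std::floor(x(i,0)/cell),
                      (int)std::floor(x(i,1)/cell),
                      (int)std::floor(x(i,2)/cell))].push_back(i);
      for (int i = 0; i < n; ++i) {
        const int ix = (int)std::floor(x(i,0)/cell);
        const int iy = (int)std::floor(x(i,1)/cell);
        const int iz = (int)std::floor(x(i,2)/cell);
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              auto it = grid.find(hash_key(ix+dx, iy+dy, iz+dz));
              if (it == grid.end()) continue;
              for (int j : it->second) {
                if (j <= i) continue;
                if (body[i] == body[j]) continue;
                if (w(i) + w(j) <= 0.0) continue;
                const double ddx = x(i,0)-x(j,0), ddy = x(i,1)-x(j,1),
                             ddz = x(i,2)-x(j,2);
                if (ddx*ddx + ddy*ddy + ddz*ddz >= search2) continue;
                // pairs closer than the contact distance in the rest pose
                // are adjacent structures: they may not approach beyond
                // their rest separation, but are not pushed apart
                const double rx = rest(i,0)-rest(j,0);
                const double ry = rest(i,1)-rest(j,1);
                const double rz = rest(i,2)-rest(j,2);
                const double rd = std::sqrt(rx*rx + ry*ry + rz*rz);
                pair_i.push_back(i);
                pair_j.push_back(j);
                pair_dc.push_back(std::min(dc, rd));
              }
            }
      }
    }

    for (int it = 0; it < iters; ++it) {
      // distance constraints (cloth springs)
      for (int c = 0; c < nd; ++c) {
        const int i = dist_ij(c,0), j = dist_ij(c,1);
        const double wi = w(i), wj = w(j);
        const double wsum = wi + wj;
        if (wsum <= 0.0) continue;
        double d[3] = { x(i,0)-x(j,0), x(i,1)-x(j,1), x(i,2)-x(j,2) };
        const double len = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
        if (len < 1e-9) continue; // direction undefined
        const double s = kd[c] * (len - dist_rest[c]) / (len * wsum);
        for (int k = 0; k < 3; ++k) {
          x(i,k) -= wi * s * d[k];
          x(j,k) += wj * s * d[k];
        }
      }
      // global volume (overpressure) constraint
      if (vfaces.n_rows > 0 && kv > 0.0) {
        const double V = signed_volume(x, vfaces);
        const double C = V - vol_kp * vol_v0;
        grad.zeros();
        for (arma::uword f = 0; f < vfaces.n_rows; ++f) {
          const arma::uword a = vfaces(f,0), b = vfaces(f,1), c2 = vfaces(f,2);
          const double av[3] = { x(a,0), x(a,1), x(a,2) };
          const double bv[3] = { x(b,0), x(b,1), x(b,2) };
          const double cv[3] = { x(c2,0), x(c2,1), x(c2,2) };
          double g[3];
          cross3(bv, cv, g);
          for (int k = 0; k < 3; ++k) grad(a,k) += g[k] / 6.0;
          cross3(cv, av, g);
          for (int k = 0; k < 3; ++k) grad(b,k) += g[k] / 6.0;
          cross3(av, bv, g);
          for (int k = 0; k < 3; ++k) grad(c2,k) += g[k] / 6.0;
        }
        double denom = 0.0;
        for (int i = 0; i < n; ++i) {
          if (w(i) <= 0.0) continue;
          denom += w(i) * (grad(i,0)*grad(i,0) + grad(i,1)*grad(i,1) +
                           grad(i,2)*grad(i,2));
        }
        if (denom > 1e-12) {
          const double s = C / denom;
          for (int i = 0; i < n; ++i) {
            if (w(i) <= 0.0) continue;
            for (int k = 0; k < 3; ++k)
              x(i,k) -= kv * s * w(i) * grad(i,k);
          }
        }
      }
      // shape-matching clusters (soft bodies)
      for (int c = 0; c < ncl; ++c) {
        const int m0 = cl_ptr[c], m1 = cl_ptr[c+1];
        const int nm = m1 - m0;
        if (nm < 3 || kc[c] <= 0.0) continue;
        double cen[3] = {0,0,0};
        for (int m = m0; m < m1; ++m) {
          const int i = cl_members[m];
          cen[0] += x(i,0); cen[1] += x(i,1); cen[2] += x(i,2);
        }
        cen[0] /= nm; cen[1] /= nm; cen[2] /= nm;
        arma::mat33 A(arma::fill::zeros);
        for (int m = m0; m < m1; ++m) {
          const int i = cl_members[m];
          const double px[3] = { x(i,0)-cen[0], x(i,1)-cen[1], x(i,2)-cen[2] };
          for (int r = 0; r < 3; ++r)
            for (int s = 0; s < 3; ++s)
              A(r,s) += px[r] * cl_offsets(m, s);
        }
        polar_rotation(A, cl_R[c]);
        const arma::mat33& R = cl_R[c];
        for (int m = m0; m < m1; ++m) {
          const int i = cl_members[m];
          if (w(i) <= 0.0) continue;
          for (int r = 0; r < 3; ++r) {
            const double goal = R(r,0)*cl_offsets(m,0) + R(r,1)*cl_offsets(m,1) +
                                R(r,2)*cl_offsets(m,2) + cen[r];
            x(i,r) += kc[c] * (goal - x(i,r));
          }
        }
      }
      // inter-body particle collisions over the per-step candidate pairs
      if (collide) {
        for (size_t p = 0; p < pair_i.size(); ++p) {
          const int i = pair_i[p], j = pair_j[p];
          const double pdc = pair_dc[p];
          const double wsum = w(i) + w(j);
          double d[3] = { x(i,0)-x(j,0), x(i,1)-x(j,1), x(i,2)-x(j,2) };
          const double d2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
          if (d2 >= pdc * pdc) continue;
          double len = std::sqrt(d2);
          if (len < 1e-9) { d[0] = 1.0; d[1] = 0.0; d[2] = 0.0; len = 1.0; }
          const double s = (pdc - len) / (len * wsum);
          for (int k = 0; k < 3; ++k) {
            x(i,k) += w(i) * s * d[k];
            x(j,k) -= w(j) * s * d[k];
          }
        }
      }
    }

    // non-finite guard
    if (!x.is_finite()) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          if (!std::isfinite(x(i,k)))
            stop("non-finite position at particle %d after step %d", i + 1, steps);
    }

    residual = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dx = x(i,0)-step_start(i,0), dy = x(i,1)-step_start(i,1),
                   dz = x(i,2)-step_start(i,2);
      residual = std::max(residual, std::sqrt(dx*dx+dy*dy+dz*dz));
    }
    if (tol > 0.0 && residual < tol) { converged = true; break; }
  }

  return List::create(_["positions"] = wrap(x),
                      _["previous_positions"] = wrap(prev),
                      _["steps"] = steps,
                      _["residual"] = residual,
                      _["converged"] = converged);
}
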