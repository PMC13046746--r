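#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double MU0 = 4.0e-7 * M_PI; // vacuum permeability, T m / A

// Complete elliptic integrals K(m), E(m) with parameter m = k^2 in [0, 1),
// by the arithmetic-geometric mean. ~8 iterations to double precision.
static inline void ellipke_agm(double m, double &K, double &E) {
  double a = 1.0, b = std::sqrt(1.0 - m), c = std::sqrt(m);
  double sum = 0.5 * c * c; // 2^{-1} c_0^2
  double pow2 = 0.5;
  for (int it = 0; it < 40 && c > 1e-17; ++it) {
    double an = 0.5 * (a + b);
    c = 0.5 * (a - b);
    b = std::sqrt(a * b);
    a = an;
    pow2 *= 2.0;
    sum += pow2 * c * c;
  }
  K = M_PI / (2.0 * a);
  E = K * (1.0 - sum);
}

// Magnetostatic field of an ideal circular filament (radius a, amp-turns I,
// centred at `center` with unit normal `axis`), evaluated at `points` (m).
// Closed form in cylindrical coordinates via complete elliptic integrals.
// Returns an n x 3 matrix of B in tesla (RMS in == RMS out).
// [[Rcpp::export]]
NumericMatrix coil_field_cpp(NumericMatrix points, NumericVector center,
                             NumericVector axis, double radius,
                             double amp_turns, double min_filament_dist) {
  const int n = points.nrow();
  NumericMatrix B(n, 3);
  const double a = radius, I = amp_turns;

  // orthonormal frame (e1, e2, e3 = axis)
  double e3[3] = {axis[0], axis[1], axis[2]};
  double e1[3];
  if (std::fabs(e3[0]) < 0.9) { e1[0] = 1.0; e1[1] = 0.0; e1[2] = 0.0; }
  else                        { e1[0] = 0.0; e1[1] = 1.0; e1[2] = 0.0; }
  double d = e1[0]*e3[0] + e1[1]*e3[1] + e1[2]*e3[2];
  for (int k = 0; k < 3; ++k) e1[k] -= d * e3[k];
  double ne1 = std::sqrt(e1[0]*e1[0] + e1[1]*e1[1] + e1[2]*e1[2]);
  for (int k = 0; k < 3; ++k) e1[k] /= ne1;
  double e2[3] = {e3[1]*e1[2] - e3[2]*e1[1],
                  e3[2]*e1[0] - e3[0]*e1[2],
                  e3[0]*e1[1] - e3[1]*e1[0]};

  for (int i = 0; i < n; ++i) {
    double dx = points(i,0) - center[0];
    double dy = points(i,1) - center[1];
    double dz = points(i,2) - center[2];
    double z  = dx*e3[0] + dy*e3[1] + dz*e3[2];
    double x1 = dx*e1[0] + dy*e1[1] + dz*e1[2];
    double x2 = dx*e2[0] + dy*e2[1] + dz*e2[2];
    double rho = std::sqrt(x1*x1 + x2*x2);

    double filament_dist = std::sqrt((rho - a)*(rho - a) + z*z);
    if (filament_dist < min_filament_dist)
      stop("point %d is on (or within %g m of) the coil filament", i + 1,
           min_filament_dist);

    double Bz, Brho;
    if (rho < 1e-12 * a) {
      double s = a*a + z*z;
      Bz = MU0 * I * a * a / (2.0 * s * std::sqrt(s));
      Brho = 0.0;
    } else {
      double dplus  = (a + rho)*(a + rho) + z*z;
      double dminus = (a - rho)*(a - rho) + z*z;
      double m = 4.0 * a * rho / dplus;
      double K, E;
      ellipke_agm(m, K, E);
      double common = MU0 * I / (2.0 * M_PI * std::sqrt(dplus));
      Bz   = common * (K + E * (a*a - rho*rho - z*z) / dminus);
      Brho = common * (z / rho) * (-K + E * (a*a + rho*rho + z*z) / dminus);
    }
    double c1 = (rho > 0) ? x1 / rho : 0.0;
    double c2 = (rho > 0) ? x2 / rho : 0.0;
    for (int k = 0; k < 3; ++k)
      B(i,k) = Brho * (c1 * e1[k] + c2 * e2[k]) + Bz * e3[k];
  }
  return B;
}

// Worst-case (minimax over implant orientation) and best-case available
// field per point. Bflat is an n x P x 3 array (R layout, flattened):
// P wand-pose field vectors at each of n points. `dirs` are the fine
// unit-sphere sample directions (icosphere vertices); `coarse` is a small
// direction set evaluated first to seed the candidate list. The fine sweep
// uses early termination: poses are scanned in decreasing |B| order and a
// direction is abandoned as soon as its running max exceeds the worst kept
// basin candidate, since it can no longer enter the candidate list.
// Returns n x 2: W (worst case), M (best case).
// [[Rcpp::export]]
NumericMatrix minimax_field_cpp(NumericVector Bflat, int n, int P,
                                NumericMatrix dirs, NumericMatrix coarse) {
  const int D = dirs.nrow(), D0 = coarse.nrow();
  NumericMatrix out(n, 2);
  const double *B = Bflat.begin();

  // contiguous copies of the direction sets
  std::vector<double> fx(D), fy(D), fz(D), cx(D0), cy(D0), cz(D0);
  for (int d = 0; d < D; ++d) { fx[d]=dirs(d,0); fy[d]=dirs(d,1); fz[d]=dirs(d,2); }
  for (int d = 0; d < D0; ++d) { cx[d]=coarse(d,0); cy[d]=coarse(d,1); cz[d]=coarse(d,2); }

  std::vector<double> bx(P), by(P), bz(P), nb(P);
  std::vector<double> sx(P), sy(P), sz(P), sn(P);
  std::vector<int> ord(P);

  for (int i = 0; i < n; ++i) {
    double M = 0.0;
    for (int p = 0; p < P; ++p) {
      bx[p] = B[i + (size_t)n * (p + (size_t)P * 0)];
      by[p] = B[i + (size_t)n * (p + (size_t)P * 1)];
      bz[p] = B[i + (size_t)n * (p + (size_t)P * 2)];
      nb[p] = std::sqrt(bx[p]*bx[p] + by[p]*by[p] + bz[p]*bz[p]);
      if (nb[p] > M) M = nb[p];
    }
    // strongest poses first: maximizes early termination below
    for (int p = 0; p < P; ++p) ord[p] = p;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return nb[a] > nb[b]; });
    for (int p = 0; p < P; ++p) {
      sx[p] = bx[ord[p]]; sy[p] = by[ord[p]]; sz[p] = bz[ord[p]];
      sn[p] = nb[ord[p]];
    }

    // fine sweep keeping the best candidate in each of up to NKEEP distinct
    // basins (mutual angle > 15 degrees): the global minimum can sit in a
    // narrow valley whose sampled floor is above a broad basin's floor, so a
    // single incumbent would discard the right start for refinement
    const int NKEEP = 6;
    const double cos15 = 0.96592582628906829; // cos(15 deg)
    double ex[NKEEP], ey[NKEEP], ez[NKEEP], eh[NKEEP];
    int m = 0;
    auto thr = [&]() {
      if (m < NKEEP) return R_PosInf;
      double t = eh[0];
      for (int k = 1; k < NKEEP; ++k) if (eh[k] > t) t = eh[k];
      return t;
    };
    auto keep = [&](double axv, double ayv, double azv, double h) {
      for (int k = 0; k < m; ++k) {
        if (std::fabs(axv*ex[k] + ayv*ey[k] + azv*ez[k]) > cos15) {
          if (h < eh[k]) { ex[k]=axv; ey[k]=ayv; ez[k]=azv; eh[k]=h; }
          return;
        }
      }
      if (m < NKEEP) { ex[m]=axv; ey[m]=ayv; ez[m]=azv; eh[m]=h; ++m; return; }
      int worst = 0;
      for (int k = 1; k < NKEEP; ++k) if (eh[k] > eh[worst]) worst = k;
      if (h < eh[worst]) { ex[worst]=axv; ey[worst]=ayv; ez[worst]=azv; eh[worst]=h; }
    };
    // seed with the best coarse direction
    {
      double hc = R_PosInf; int dc = 0;
      for (int d = 0; d < D0; ++d) {
        double h = 0.0;
        for (int p = 0; p < P; ++p) {
          double v = std::fabs(sx[p]*cx[d] + sy[p]*cy[d] + sz[p]*cz[d]);
          if (v > h) h = v;
        }
        if (h < hc) { hc = h; dc = d; }
      }
      keep(cx[dc], cy[dc], cz[dc], hc);
    }
    for (int d = 0; d < D; ++d) {
      double t = thr();
      double h = 0.0;
      for (int p = 0; p < P; ++p) {
        if (sn[p] <= h) break;          // |B.a| <= |B|: max settled
        double v = std::fabs(sx[p]*fx[d] + sy[p]*fy[d] + sz[p]*fz[d]);
        if (v > h) {
          h = v;
          if (h > t) break;             // cannot enter the candidate list
        }
      }
      if (h <= t) keep(fx[d], fy[d], fz[d], h);
    }
    double W = eh[0];
    for (int k = 1; k < m; ++k) if (eh[k] < W) W = eh[k];

    // local pattern-search refinement: 8-point tangent-plane stencil with a
    // shrinking, *rotating* step (a fixed stencil can miss the narrow descent
    // cone at kinks of the piecewise-smooth minimax surface), started from
    // every kept basin candidate, since a single start can land in the
    // wrong valley.
    if (W > 0) {
      auto hfull = [&](double axv, double ayv, double azv) {
        double h = 0.0;
        for (int p = 0; p < P; ++p) {
          if (sn[p] <= h) break;
          double v = std::fabs(sx[p]*axv + sy[p]*ayv + sz[p]*azv);
          if (v > h) h = v;
        }
        return h;
      };
      auto refine = [&](double a0x, double a0y, double a0z, double h0) {
        double ux, uy, uz;
        if (std::fabs(a0x) < 0.9) { ux = 1; uy = 0; uz = 0; }
        else                      { ux = 0; uy = 1; uz = 0; }
        double dp = ux*a0x + uy*a0y + uz*a0z;
        ux -= dp*a0x; uy -= dp*a0y; uz -= dp*a0z;
        double un = std::sqrt(ux*ux + uy*uy + uz*uz);
        ux /= un; uy /= un; uz /= un;
        double wx = a0y*uz - a0z*uy, wy = a0z*ux - a0x*uz, wz = a0x*uy - a0y*ux;
        auto hval = [&](double cu, double cw) {
          double axv = a0x + cu*ux + cw*wx;
          double ayv = a0y + cu*uy + cw*wy;
          double azv = a0z + cu*uz + cw*wz;
          double an = std::sqrt(axv*axv + ayv*ayv + azv*azv);
          return hfull(axv/an, ayv/an, azv/an);
        };
        double cu = 0, cw = 0, step = 0.035, phi = 0.0, h = h0; // ~2 degrees
        int fails = 0;
        while (step > 1e-5) {
          double bu = cu, bw = cw, bh = h;
          for (int s = 0; s < 8; ++s) {
            double ang = phi + s * (M_PI / 4);
            double du = step * std::cos(ang), dw = step * std::sin(ang);
            double hv = hval(cu + du, cw + dw);
            if (hv < bh) { bh = hv; bu = cu + du; bw = cw + dw; }
          }
          if (bh < h) { h = bh; cu = bu; cw = bw; fails = 0; }
          else {
            // rotate the stencil first (golden angle): the descent cone at a
            // kink can be narrower than the 22.5-degree stencil half-spacing,
            // so shrinking immediately would stall; shrink after 3 misses
            phi += 0.39996;
            if (++fails >= 3) { step *= 0.5; fails = 0; }
          }
        }
        return h;
      };

      // refine candidates in ascending floor order; a basin whose sampled
      // floor already exceeds 1.5x the best refined value cannot plausibly
      // descend below it (observed descents from a level-4 floor are < 4%)
      std::vector<int> eord(m);
      for (int k = 0; k < m; ++k) eord[k] = k;
      std::sort(eord.begin(), eord.end(),
                [&](int a, int b) { return eh[a] < eh[b]; });
      for (int k = 0; k < m; ++k) {
        int e = eord[k];
        if (eh[e] > 1.5 * W) break;
        double h = refine(ex[e], ey[e], ez[e], eh[e]);
        if (h < W) W = h;
      }
    }

    out(i,0) = W;
    out(i,1) = M;
  }
  return out;
}

// --- mesh geometry helpers ------------------------------------------------

// Parity (ray-crossing) voxelization. Voxel centers at
// origin + (index + 0.5) * spacing, 0-based indices, x fastest (R array
// order). For each (y,z) column the x-crossings of all triangles are
// collected by 2-D point-in-triangle rasterization, then each center is
// inside iff an odd number of crossings lies beyond it. Column coordinates
// get a tiny deterministic nudge so that centers never sit exactly on a
// projected edge.
// [[Rcpp::export]]
LogicalVector voxel_mask_cpp(NumericMatrix V, IntegerMatrix F,
                             NumericVector origin, double spacing,
                             IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nF = F.nrow();
  const double eps = 1e-7 * spacing;

  std::vector< std::vector<double> > cross((size_t)ny * nz);

  for (int f = 0; f < nF; ++f) {
    int i0 = F(f,0) - 1, i1 = F(f,1) - 1, i2 = F(f,2) - 1;
    double ax = V(i0,0), ay = V(i0,1), az = V(i0,2);
    double bxv = V(i1,0), byv = V(i1,1), bzv = V(i1,2);
    double cxv = V(i2,0), cyv = V(i2,1), czv = V(i2,2);

    double ymin = std::min(ay, std::min(byv, cyv));
    double ymax = std::max(ay, std::max(byv, cyv));
    double zmin = std::min(az, std::min(bzv, czv));
    double zmax = std::max(az, std::max(bzv, czv));

    int j0 = std::max(0, (int)std::floor((ymin - origin[1]) / spacing - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((ymax - origin[1]) / spacing - 0.5));
    int k0 = std::max(0, (int)std::floor((zmin - origin[2]) / spacing - 0.5));
    int k1 = std::min(nz - 1, (int)std::ceil((zmax - origin[2]) / spacing - 0.5));

    // 2-D (y,z) edge functions; denominator = signed doubled area
    double det = (byv - ay) * (czv - az) - (cyv - ay) * (bzv - az);
    if (std::fabs(det) < 1e-30) continue; // projected-degenerate triangle

    for (int j = j0; j <= j1; ++j) {
      double py = origin[1] + (j + 0.5) * spacing + eps;
      for (int k = k0; k <= k1; ++k) {
        double pz = origin[2] + (k + 0.5) * spacing + eps * 0.618;
        double w0 = ((byv - py) * (czv - pz) - (cyv - py) * (bzv - pz)) / det;
        double w1 = ((cyv - py) * (az  - pz) - (ay  - py) * (czv - pz)) / det;
        double w2 = 1.0 - w0 - w1;
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        double xc = w0 * ax + w1 * bxv + w2 * cxv;
        cross[(size_t)j + (size_t)ny * k].push_back(xc);
      }
    }
  }

  LogicalVector mask((size_t)nx * ny * nz, false);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      std::vector<double> &cc = cross[(size_t)j + (size_t)ny * k];
      if (cc.empty()) continue;
      std::sort(cc.begin(), cc.end());
      size_t m = cc.size();
      for (int i = 0; i < nx; ++i) {
        double xc = origin[0] + (i + 0.5) * spacing;
        // count crossings strictly beyond the center
        size_t beyond = cc.end() -
          std::upper_bound(cc.begin(), cc.end(), xc);
        if (beyond % 2 == 1)
          mask[(size_t)i + (size_t)nx * (j + (size_t)ny * k)] = true;
        (void)m;
      }
    }
  }
  return mask;
}

// Parity containment test for arbitrary points (ray along +x,
// Moller-Trumbore). Independent of the column-rasterized voxelizer's
// bookkeeping but same principle; the R-level winding-number test is the
// fully independent oracle.
// [[Rcpp::export]]
LogicalVector points_inside_cpp(NumericMatrix P, NumericMatrix V,
                                IntegerMatrix F) {
  const int n = P.nrow(), nF = F.nrow();
  LogicalVector inside(n, false);
  for (int i = 0; i < n; ++i) {
    double ox = P(i,0), oy = P(i,1) + 1e-9, oz = P(i,2) + 1.618e-9;
    int count = 0;
    for (int f = 0; f < nF; ++f) {
      int i0 = F(f,0)-1, i1 = F(f,1)-1, i2 = F(f,2)-1;
      double e1x = V(i1,0)-V(i0,0), e1y = V(i1,1)-V(i0,1), e1z = V(i1,2)-V(i0,2);
      double e2x = V(i2,0)-V(i0,0), e2y = V(i2,1)-V(i0,1), e2z = V(i2,2)-V(i0,2);
      // ray dir (1,0,0): h = d x e2 = (0, -e2z, e2y)
      double det = e1y * (-e2z) + e1z * e2y;
      if (std::fabs(det) < 1e-30) continue;
      double inv = 1.0 / det;
      double sx = ox - V(i0,0), sy = oy - V(i0,1), sz = oz - V(i0,2);
      double u = (sy * (-e2z) + sz * e2y) * inv;
      if (u < 0 || u > 1) continue;
      // q = s x e1
      double qx = sy*e1z - sz*e1y, qy = sz*e1x - sx*e1z, qz = sx*e1y - sy*e1x;
      double v = qx * inv; // d . q with d=(1,0,0)
      if (v < 0 || u + v > 1) continue;
      double t = (e2x*qx + e2y*qy + e2z*qz) * inv;
      if (t > 1e-12) ++count;
    }
    inside[i] = (count % 2 == 1);
  }
  return inside;
}

// First-hit distance of rays from a common origin (Moller-Trumbore); the
// OUTERMOST intersection is returned so that scalp placement starts outside
// any local concavity. Returns n x 2: t (NA if no hit) and face index.
// [[Rcpp::export]]
NumericMatrix ray_mesh_cpp(NumericVector orig, NumericMatrix Dirs,
                           NumericMatrix V, IntegerMatrix F) {
  const int n = Dirs.nrow(), nF = F.nrow();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double dx = Dirs(i,0), dy = Dirs(i,1), dz = Dirs(i,2);
    double tbest = NA_REAL; int fbest = NA_INTEGER;
    for (int f = 0; f < nF; ++f) {
      int i0 = F(f,0)-1, i1 = F(f,1)-1, i2 = F(f,2)-1;
      double e1x = V(i1,0)-V(i0,0), e1y = V(i1,1)-V(i0,1), e1z = V(i1,2)-V(i0,2);
      double e2x = V(i2,0)-V(i0,0), e2y = V(i2,1)-V(i0,1), e2z = V(i2,2)-V(i0,2);
      double hx = dy*e2z - dz*e2y, hy = dz*e2x - dx*e2z, hz = dx*e2y - dy*e2x;
      double det = e1x*hx + e1y*hy + e1z*hz;
      if (std::fabs(det) < 1e-30) continue;
      double inv = 1.0 / det;
      double sx = orig[0]-V(i0,0), sy = orig[1]-V(i0,1), sz = orig[2]-V(i0,2);
      double u = (sx*hx + sy*hy + sz*hz) * inv;
      if (u < -1e-12 || u > 1 + 1e-12) continue;
      double qx = sy*e1z - sz*e1y, qy = sz*e1x - sx*e1z, qz = sx*e1y - sy*e1x;
      double v = (dx*qx + dy*qy + dz*qz) * inv;
      if (v < -1e-12 || u + v > 1 + 1e-12) continue;
      double t = (e2x*qx + e2y*qy + e2z*qz) * inv;
      if (t > 1e-9 && (!R_finite(tbest) || t > tbest)) { tbest = t; fbest = f + 1; }
    }
    out(i,0) = tbest; out(i,1) = fbest;
  }
  return out;
}

static inline double point_segment_dist2(double px, double py, double pz,
                                         double ax, double ay, double az,
                                         double bx, double by, double bz) {
  double abx = bx-ax, aby = by-ay, abz = bz-az;
  double apx = px-ax, apy = py-ay, apz = pz-az;
  double t = (apx*abx + apy*aby + apz*abz) /
             (abx*abx + aby*aby + abz*abz + 1e-300);
  t = std::max(0.0, std::min(1.0, t));
  double dx = apx - t*abx, dy = apy - t*aby, dz = apz - t*abz;
  return dx*dx + dy*dy + dz*dz;
}

// Unsigned distance from each point to the triangle mesh (closest point is
// either the interior plane projection or on one of the three edges).
// [[Rcpp::export]]
NumericVector dist_to_mesh_cpp(NumericMatrix P, NumericMatrix V,
                               IntegerMatrix F) {
  const int n = P.nrow(), nF = F.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = P(i,0), py = P(i,1), pz = P(i,2);
    double best = R_PosInf;
    for (int f = 0; f < nF; ++f) {
      int i0 = F(f,0)-1, i1 = F(f,1)-1, i2 = F(f,2)-1;
      double ax = V(i0,0), ay = V(i0,1), az = V(i0,2);
      double bx = V(i1,0), by = V(i1,1), bz = V(i1,2);
      double cx = V(i2,0), cy = V(i2,1), cz = V(i2,2);
      double e1x = bx-ax, e1y = by-ay, e1z = bz-az;
      double e2x = cx-ax, e2y = cy-ay, e2z = cz-az;
      double nxv = e1y*e2z - e1z*e2y, nyv = e1z*e2x - e1x*e2z,
             nzv = e1x*e2y - e1y*e2x;
      double nn = nxv*nxv + nyv*nyv + nzv*nzv;
      double d2;
      if (nn < 1e-300) {
        d2 = point_segment_dist2(px,py,pz, ax,ay,az, bx,by,bz);
      } else {
        double apx = px-ax, apy = py-ay, apz = pz-az;
        double dist_plane = (apx*nxv + apy*nyv + apz*nzv);
        // barycentric of projection
        double qx = px - dist_plane*nxv/nn, qy = py - dist_plane*nyv/nn,
               qz = pz - dist_plane*nzv/nn;
        double aqx = qx-ax, aqy = qy-ay, aqz = qz-az;
        double d11 = e1x*e1x + e1y*e1y + e1z*e1z;
        double d12 = e1x*e2x + e1y*e2y + e1z*e2z;
        double d22 = e2x*e2x + e2y*e2y + e2z*e2z;
        double r1 = aqx*e1x + aqy*e1y + aqz*e1z;
        double r2 = aqx*e2x + aqy*e2y + aqz*e2z;
        double den = d11*d22 - d12*d12;
        double u = (d22*r1 - d12*r2) / den;
        double v = (d11*r2 - d12*r1) / den;
        if (u >= 0 && v >= 0 && u + v <= 1) {
          d2 = dist_plane * dist_plane / nn;
        } else {
          d2 = point_segment_dist2(px,py,pz, ax,ay,az, bx,by,bz);
          d2 = std::min(d2, point_segment_dist2(px,py,pz, ax,ay,az, cx,cy,cz));
          d2 = std::min(d2, point_segment_dist2(px,py,pz, bx,by,bz, cx,cy,cz));
        }
      }
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
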