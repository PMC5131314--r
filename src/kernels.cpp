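#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel (iz,iy,ix), 1-based on the R side, has physical centre
// ((iz-0.5)*dz, (iy-0.5)*dy, (ix-0.5)*dx) micrometres. Arrays are stored in
// R's column-major order with dim = (nz, ny, nx).

static inline R_xlen_t lin_idx(int iz, int iy, int ix, int nz, int ny) {
  return (R_xlen_t)iz + (R_xlen_t)nz * ((R_xlen_t)iy + (R_xlen_t)ny * (R_xlen_t)ix);
}

// Paint concentric follicle regions into an integer volume over the ellipsoid
// bounding box. Region codes: 1 theca, 2 gap, 3 granulosa, 4 lumen (antrum).
// rot is the 3x3 body-to-world rotation (columns = body axes in world (z,y,x)
// coords); thickness t(u) = t_base * (1 + mod_amp * f(u)) with f a fixed
// low-order angular field parameterized by coef (length 4, each in [-1,1],
// combined so |f| <= 1).
// [[Rcpp::export]]
List cpp_paint_follicle(IntegerVector region, IntegerVector labels, int label_id,
                        NumericVector center, NumericVector semi, NumericMatrix rot,
                        NumericVector spacing, NumericVector thick,
                        double gap_w, double gran_w, int overlap_tol) {
  IntegerVector dim = region.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  double a = semi[0], b = semi[1], c = semi[2];
  double t_base = thick[0], mod_amp = thick[1];
  double c1 = thick[2], c2 = thick[3], c3 = thick[4], c4 = thick[5];
  double rmax = a;
  // bounding box in voxel indices (0-based here)
  int z0 = std::max(0, (int)std::floor((center[0] - rmax) / dz) - 1);
  int z1 = std::min(nz - 1, (int)std::ceil((center[0] + rmax) / dz));
  int y0 = std::max(0, (int)std::floor((center[1] - rmax) / dy) - 1);
  int y1 = std::min(ny - 1, (int)std::ceil((center[1] + rmax) / dy));
  int x0 = std::max(0, (int)std::floor((center[2] - rmax) / dx) - 1);
  int x1 = std::min(nx - 1, (int)std::ceil((center[2] + rmax) / dx));
  long overlap = 0;
  long painted = 0;
  for (int ix = x0; ix <= x1; ++ix) {
    double px = (ix + 0.5) * dx - center[2];
    for (int iy = y0; iy <= y1; ++iy) {
      double py = (iy + 0.5) * dy - center[1];
      for (int iz = z0; iz <= z1; ++iz) {
        double pz = (iz + 0.5) * dz - center[0];
        // body-frame coords: rot^T * p  (rot columns are body axes)
        double bx = rot(0,0)*pz + rot(1,0)*py + rot(2,0)*px;
        double by = rot(0,1)*pz + rot(1,1)*py + rot(2,1)*px;
        double bz = rot(0,2)*pz + rot(1,2)*py + rot(2,2)*px;
        double r = std::sqrt(bx*bx + by*by + bz*bz);
        double R_out;
        if (r < 1e-9) {
          R_out = c; // direction undefined at centre; any radius > 0 works
        } else {
          double ux = bx / r, uy = by / r, uz = bz / r;
          double q = (ux*ux)/(a*a) + (uy*uy)/(b*b) + (uz*uz)/(c*c);
          R_out = 1.0 / std::sqrt(q);
        }
        if (r > R_out) continue;
        double t = t_base;
        if (mod_amp > 0 && r > 1e-9) {
          double ux = bx / r, uy = by / r, uz = bz / r;
          // smooth degree-2 angular field, |f| <= 1 by construction
          double f = 0.5 * (c1 * 2.0*ux*uy + c2 * 2.0*uy*uz + c3 * 2.0*ux*uz
                            + c4 * (1.5*uz*uz - 0.5));
          t = t_base * (1.0 + mod_amp * f);
        }
        double r_theca_in = R_out - t;
        int code;
        if (r_theca_in <= 0 || r > r_theca_in) code = 1;        // theca (solid if small)
        else if (r > r_theca_in - gap_w) code = 2;               // delamination gap
        else if (r > r_theca_in - gap_w - gran_w) code = 3;      // granulosa lining
        else code = 4;                                           // antral lumen
        R_xlen_t k = lin_idx(iz, iy, ix, nz, ny);
        if (labels[k] != 0 && labels[k] != label_id) { overlap++; continue; }
        region[k] = code;
        labels[k] = label_id;
        painted++;
      }
    }
  }
  return List::create(_["painted"] = (double)painted, _["overlap"] = (double)overlap,
                      _["clipped"] = (z0 == 0 || z1 == nz-1 || y0 == 0 || y1 == ny-1 ||
                                      x0 == 0 || x1 == nx-1));
}

// Plain rotated-ellipsoid voxelization: logical mask, same geometry rules.
// [[Rcpp::export]]
LogicalVector cpp_voxelize_ellipsoid(NumericVector center, NumericVector semi,
                                     NumericMatrix rot, NumericVector spacing,
                                     IntegerVector shape) {
  int nz = shape[0], ny = shape[1], nx = shape[2];
  double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  LogicalVector out((R_xlen_t)nz * ny * nx);
  out.attr("dim") = shape;
  double a = semi[0], b = semi[1], c = semi[2];
  double ia2 = 1.0/(a*a), ib2 = 1.0/(b*b), ic2 = 1.0/(c*c);
  double rmax = a;
  int z0 = std::max(0, (int)std::floor((center[0]-rmax)/dz)-1);
  int z1 = std::min(nz-1, (int)std::ceil((center[0]+rmax)/dz));
  int y0 = std::max(0, (int)std::floor((center[1]-rmax)/dy)-1);
  int y1 = std::min(ny-1, (int)std::ceil((center[1]+rmax)/dy));
  int x0 = std::max(0, (int)std::floor((center[2]-rmax)/dx)-1);
  int x1 = std::min(nx-1, (int)std::ceil((center[2]+rmax)/dx));
  for (int ix = x0; ix <= x1; ++ix) {
    double px = (ix + 0.5)*dx - center[2];
    for (int iy = y0; iy <= y1; ++iy) {
      double py = (iy + 0.5)*dy - center[1];
      for (int iz = z0; iz <= z1; ++iz) {
        double pz = (iz + 0.5)*dz - center[0];
        double bx = rot(0,0)*pz + rot(1,0)*py + rot(2,0)*px;
        double by = rot(0,1)*pz + rot(1,1)*py + rot(2,1)*px;
        double bz = rot(0,2)*pz + rot(1,2)*py + rot(2,2)*px;
        double q = bx*bx*ia2 + by*by*ib2 + bz*bz*ic2;
        if (q <= 1.0) out[lin_idx(iz, iy, ix, nz, ny)] = true;
      }
    }
  }
  return out;
}

// Capsule (tube around a polyline) voxelization for blood-vessel phantoms.
// [[Rcpp::export]]
LogicalVector cpp_voxelize_tube(NumericMatrix pts, double radius,
                                NumericVector spacing, IntegerVector shape) {
  int nz = shape[0], ny = shape[1], nx = shape[2];
  double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  LogicalVector out((R_xlen_t)nz * ny * nx);
  out.attr("dim") = shape;
  int nseg = pts.nrow() - 1;
  for (int s = 0; s < nseg; ++s) {
    double az = pts(s,0), ay = pts(s,1), ax = pts(s,2);
    double bz2 = pts(s+1,0), by2 = pts(s+1,1), bx2 = pts(s+1,2);
    double lo_z = std::min(az,bz2)-radius, hi_z = std::max(az,bz2)+radius;
    double lo_y = std::min(ay,by2)-radius, hi_y = std::max(ay,by2)+radius;
    double lo_x = std::min(ax,bx2)-radius, hi_x = std::max(ax,bx2)+radius;
    int z0 = std::max(0,(int)std::floor(lo_z/dz)-1), z1 = std::min(nz-1,(int)std::ceil(hi_z/dz));
    int y0 = std::max(0,(int)std::floor(lo_y/dy)-1), y1 = std::min(ny-1,(int)std::ceil(hi_y/dy));
    int x0 = std::max(0,(int)std::floor(lo_x/dx)-1), x1 = std::min(nx-1,(int)std::ceil(hi_x/dx));
    double vz = bz2-az, vy = by2-ay, vx = bx2-ax;
    double vv = vz*vz+vy*vy+vx*vx;
    double r2 = radius*radius;
    for (int ix = x0; ix <= x1; ++ix) {
      double px = (ix+0.5)*dx;
      for (int iy = y0; iy <= y1; ++iy) {
        double py = (iy+0.5)*dy;
        for (int iz = z0; iz <= z1; ++iz) {
          double pz = (iz+0.5)*dz;
          double wz = pz-az, wy = py-ay, wx = px-ax;
          double t = vv > 0 ? (wz*vz+wy*vy+wx*vx)/vv : 0.0;
          t = std::max(0.0, std::min(1.0, t));
          double qz = wz-t*vz, qy = wy-t*vy, qx = wx-t*vx;
          if (qz*qz+qy*qy+qx*qx <= r2) out[lin_idx(iz,iy,ix,nz,ny)] = true;
        }
      }
    }
  }
  return out;
}

// 3D connected-component labelling (BFS), connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, int connectivity) {
  IntegerVector dim = mask.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);
  lab.attr("dim") = dim;
  std::vector<int> oz, oy, ox;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        oz.push_back(a); oy.push_back(b); ox.push_back(c);
      }
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    cur++;
    lab[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t k = stack.back(); stack.pop_back();
      int iz = (int)(k % nz);
      int iy = (int)((k / nz) % ny);
      int ix = (int)(k / ((R_xlen_t)nz * ny));
      for (size_t m = 0; m < oz.size(); ++m) {
        int jz = iz + oz[m], jy = iy + oy[m], jx = ix + ox[m];
        if (jz < 0 || jz >= nz || jy < 0 || jy >= ny || jx < 0 || jx >= nx) continue;
        R_xlen_t kk = lin_idx(jz, jy, jx, nz, ny);
        if (mask[kk] && lab[kk] == 0) { lab[kk] = cur; stack.push_back(kk); }
      }
    }
  }
  return lab;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher lower envelope).
static void edt1d(std::vector<double>& f, std::vector<double>& d, double step,
                  std::vector<int>& v, std::vector<double>& z) {
  int n = (int)f.size();
  d.assign(n, 0.0);
  v.assign(n, 0); z.assign(n + 1, 0.0);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY; z[1] = INFINITY;
  double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + s2*q*q) - (f[p] + s2*p*p)) / (2.0*s2*q - 2.0*s2*p);
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s; z[k+1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k+1] < q) k++;
    int p = v[k];
    d[q] = s2*(q - p)*(q - p) + f[p];
  }
}

// Exact anisotropic 3D Euclidean distance transform: distance (micrometres)
// from every true voxel to the nearest false voxel; 0 on background.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, NumericVector spacing) {
  IntegerVector dim = mask.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  out.attr("dim") = dim;
  const double INF = 1e30;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;
  std::vector<double> f, d; std::vector<int> v; std::vector<double> zbuf;
  // pass along z
  f.resize(nz);
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy) {
      R_xlen_t base = lin_idx(0, iy, ix, nz, ny);
      for (int iz = 0; iz < nz; ++iz) f[iz] = out[base + iz];
      edt1d(f, d, spacing[0], v, zbuf);
      for (int iz = 0; iz < nz; ++iz) out[base + iz] = d[iz];
    }
  // pass along y
  f.resize(ny);
  for (int ix = 0; ix < nx; ++ix)
    for (int iz = 0; iz < nz; ++iz) {
      for (int iy = 0; iy < ny; ++iy) f[iy] = out[lin_idx(iz, iy, ix, nz, ny)];
      edt1d(f, d, spacing[1], v, zbuf);
      for (int iy = 0; iy < ny; ++iy) out[lin_idx(iz, iy, ix, nz, ny)] = d[iy];
    }
  // pass along x
  f.resize(nx);
  for (int iy = 0; iy < ny; ++iy)
    for (int iz = 0; iz < nz; ++iz) {
      for (int ix = 0; ix < nx; ++ix) f[ix] = out[lin_idx(iz, iy, ix, nz, ny)];
      edt1d(f, d, spacing[2], v, zbuf);
      for (int ix = 0; ix < nx; ++ix) out[lin_idx(iz, iy, ix, nz, ny)] = std::sqrt(d[ix]);
    }
  return out;
}

// For each outer-boundary pixel, squared physical distance to the nearest
// inner-boundary pixel, in one 2D plane. Bucketed grid search with an
// expanding ring; exact (verifies one ring beyond the current best).
// Coordinates are integer pixel indices; dy/dx the in-plane spacings.
// [[Rcpp::export]]
NumericVector cpp_nearest_boundary_sq(IntegerMatrix outer, IntegerMatrix inner,
                                      double dy, double dx) {
  int n = outer.nrow(), m = inner.nrow();
  NumericVector res(n);
  if (m == 0) return res;
  // bucket inner points on their own pixel grid
  int ymin = inner(0,0), ymax = inner(0,0), xmin = inner(0,1), xmax = inner(0,1);
  for (int j = 1; j < m; ++j) {
    ymin = std::min(ymin, inner(j,0)); ymax = std::max(ymax, inner(j,0));
    xmin = std::min(xmin, inner(j,1)); xmax = std::max(xmax, inner(j,1));
  }
  const int cell = 8; // pixels per bucket side
  int gy = (ymax - ymin) / cell + 1, gx = (xmax - xmin) / cell + 1;
  std::vector< std::vector<int> > buckets((size_t)gy * gx);
  for (int j = 0; j < m; ++j) {
    int by = (inner(j,0) - ymin) / cell, bx = (inner(j,1) - xmin) / cell;
    buckets[(size_t)by * gx + bx].push_back(j);
  }
  double minsp = std::min(dy, dx);
  for (int i = 0; i < n; ++i) {
    int py = outer(i,0), px = outer(i,1);
    int cy = std::min(std::max((py - ymin) / cell, 0), gy - 1);
    int cx = std::min(std::max((px - xmin) / cell, 0), gx - 1);
    double best = INFINITY;
    int maxring = std::max(gy, gx);
    for (int ring = 0; ring <= maxring; ++ring) {
      // once a candidate is found, one extra ring guarantees exactness
      if (best < INFINITY) {
        double safe = (double)(ring - 1) * cell * minsp;
        if (safe > 0 && safe * safe > best) break;
      }
      bool any = false;
      for (int by = cy - ring; by <= cy + ring; ++by) {
        if (by < 0 || by >= gy) continue;
        for (int bx = cx - ring; bx <= cx + ring; ++bx) {
          if (bx < 0 || bx >= gx) continue;
          if (std::max(std::abs(by - cy), std::abs(bx - cx)) != ring) continue;
          any = true;
          const std::vector<int>& B = buckets[(size_t)by * gx + bx];
          for (size_t t = 0; t < B.size(); ++t) {
            int j = B[t];
            double ddy = dy * (double)(py - inner(j,0));
            double ddx = dx * (double)(px - inner(j,1));
            double sq = ddy*ddy + ddx*ddx;
            if (sq < best) best = sq;
          }
        }
      }
      if (!any && best < INFINITY) break;
    }
    res[i] = best;
  }
  return res;
}
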