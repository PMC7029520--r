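// Finite-volume discretization and conjugate-gradient solution of the
// quasi-static volume-conduction problem  div(sigma grad V) = 0  on a
// structured grid (uniform in-plane spacing, graded axial spacing), with
// diagonal anisotropic conductivity tensors per tissue, thin-sheet face
// impedances for perineurium, insulating crack faces for electrode
// substrates, and Dirichlet conditions on the grounded outer cylinder.
//
// Units: coordinates arrive in mm and are converted to m internally;
// conductivities S/m; sheet resistances Ohm*m^2; currents A; potentials V.

#include <Rcpp.h>
#include <R_ext/Lapack.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------- polygons

static inline bool point_in_poly(double px, double py,
                                 const double* x, const double* y, int n) {
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if (((y[i] > py) != (y[j] > py)) &&
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]))
      inside = !inside;
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_poly(NumericVector px, NumericVector py,
                                 NumericMatrix poly) {
  int np = px.size(), n = poly.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = poly(i, 0); y[i] = poly(i, 1); }
  LogicalVector out(np);
  for (int k = 0; k < np; ++k)
    out[k] = point_in_poly(px[k], py[k], x.data(), y.data(), n);
  return out;
}

static inline double seg_point_dist2(double px, double py, double ax, double ay,
                                     double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double L2 = dx * dx + dy * dy;
  double t = L2 > 0 ? ((px - ax) * dx + (py - ay) * dy) / L2 : 0.0;
  if (t < 0) t = 0; if (t > 1) t = 1;
  double qx = ax + t * dx - px, qy = ay + t * dy - py;
  return qx * qx + qy * qy;
}

// Distance from points to a polygon boundary (edges), in the same units.
// [[Rcpp::export]]
NumericVector cpp_dist_to_poly(NumericVector px, NumericVector py,
                               NumericMatrix poly) {
  int np = px.size(), n = poly.nrow();
  NumericVector out(np);
  for (int k = 0; k < np; ++k) {
    double best = R_PosInf;
    for (int i = 0, j = n - 1; i < n; j = i++) {
      double d2 = seg_point_dist2(px[k], py[k], poly(j, 0), poly(j, 1),
                                  poly(i, 0), poly(i, 1));
      if (d2 < best) best = d2;
    }
    out[k] = std::sqrt(best);
  }
  return out;
}

static inline double cross3(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

static bool segs_intersect(double p1x, double p1y, double p2x, double p2y,
                           double q1x, double q1y, double q2x, double q2y) {
  double d1 = cross3(q1x, q1y, q2x, q2y, p1x, p1y);
  double d2 = cross3(q1x, q1y, q2x, q2y, p2x, p2y);
  double d3 = cross3(p1x, p1y, p2x, p2y, q1x, q1y);
  double d4 = cross3(p1x, p1y, p2x, p2y, q2x, q2y);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return true;
  return false;
}

// Any proper edge-pair intersection between two closed polygons.
// [[Rcpp::export]]
bool cpp_polys_edges_intersect(NumericMatrix a, NumericMatrix b) {
  int na = a.nrow(), nb = b.nrow();
  for (int i = 0, i2 = na - 1; i < na; i2 = i++)
    for (int j = 0, j2 = nb - 1; j < nb; j2 = j++)
      if (segs_intersect(a(i2, 0), a(i2, 1), a(i, 0), a(i, 1),
                         b(j2, 0), b(j2, 1), b(j, 0), b(j, 1)))
        return true;
  return false;
}

// Self-intersection test for a closed polygon (non-adjacent edge pairs).
// [[Rcpp::export]]
bool cpp_poly_self_intersects(NumericMatrix a) {
  int n = a.nrow();
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (i == j || i2 == j || i == j2) continue;
      if (segs_intersect(a(i, 0), a(i, 1), a(i2, 0), a(i2, 1),
                         a(j, 0), a(j, 1), a(j2, 0), a(j2, 1)))
        return true;
    }
  }
  return false;
}

// Tissue label for each (x, y) cell center: 0 saline, 1 epineurium,
// 2 + f for the endoneurium of fascicle f (0-based).
// [[Rcpp::export]]
IntegerVector cpp_label_grid(NumericVector xs, NumericVector ys,
                             NumericMatrix outline, List fascicles) {
  int nx = xs.size(), ny = ys.size(), nf = fascicles.size();
  int no = outline.nrow();
  std::vector<double> ox(no), oy(no);
  for (int i = 0; i < no; ++i) { ox[i] = outline(i, 0); oy[i] = outline(i, 1); }
  std::vector<std::vector<double> > fx(nf), fy(nf);
  std::vector<double> bx0(nf), bx1(nf), by0(nf), by1(nf);
  for (int f = 0; f < nf; ++f) {
    NumericMatrix p = fascicles[f];
    int n = p.nrow();
    fx[f].resize(n); fy[f].resize(n);
    double x0 = R_PosInf, x1 = R_NegInf, y0 = R_PosInf, y1 = R_NegInf;
    for (int i = 0; i < n; ++i) {
      fx[f][i] = p(i, 0); fy[f][i] = p(i, 1);
      x0 = std::min(x0, p(i, 0)); x1 = std::max(x1, p(i, 0));
      y0 = std::min(y0, p(i, 1)); y1 = std::max(y1, p(i, 1));
    }
    bx0[f] = x0; bx1[f] = x1; by0[f] = y0; by1[f] = y1;
  }
  IntegerVector lab(nx * ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double X = xs[i], Y = ys[j];
      int l = 0;
      if (point_in_poly(X, Y, ox.data(), oy.data(), no)) {
        l = 1;
        for (int f = 0; f < nf; ++f) {
          if (X < bx0[f] || X > bx1[f] || Y < by0[f] || Y > by1[f]) continue;
          if (point_in_poly(X, Y, fx[f].data(), fy[f].data(),
                            (int)fx[f].size())) { l = 2 + f; break; }
        }
      }
      lab[i + nx * j] = l;
    }
  }
  return lab;
}

// ------------------------------------------------------------------ solver

struct Cracks {
  // rows: axis (0 = plane normal along x, 1 = along y), c, o_min, o_max,
  // z_min, z_max; all mm
  NumericMatrix m;
  Cracks(NumericMatrix mm) : m(mm) {}
  bool cut_x(double xlo, double xhi, double y, double z) const {
    for (int k = 0; k < m.nrow(); ++k)
      if (m(k, 0) == 0 && m(k, 1) > xlo && m(k, 1) < xhi &&
          y >= m(k, 2) && y <= m(k, 3) && z >= m(k, 4) && z <= m(k, 5))
        return true;
    return false;
  }
  bool cut_y(double ylo, double yhi, double x, double z) const {
    for (int k = 0; k < m.nrow(); ++k)
      if (m(k, 0) == 1 && m(k, 1) > ylo && m(k, 1) < yhi &&
          x >= m(k, 2) && x <= m(k, 3) && z >= m(k, 4) && z <= m(k, 5))
        return true;
    return false;
  }
};

// [[Rcpp::export]]
List cpp_solve_leadfield(NumericVector xs, NumericVector ys,
                         NumericVector zedges, IntegerVector label2d,
                         NumericMatrix tissue_sigma,  // label -> (sig_t, sig_z)
                         NumericVector peri_res,      // per fascicle, Ohm m^2
                         NumericMatrix cracks_m, LogicalVector mask,
                         NumericVector vb, IntegerVector src_idx,
                         NumericVector src_w, double I_src, double tol,
                         int maxit) {
  const double MM = 1e-3;
  int nx = xs.size(), ny = ys.size(), nz = zedges.size() - 1;
  size_t N = (size_t)nx * ny * nz;
  double hx = (nx > 1) ? (xs[1] - xs[0]) * MM : MM;
  double hy = (ny > 1) ? (ys[1] - ys[0]) * MM : MM;
  std::vector<double> zc(nz), dz(nz);
  for (int k = 0; k < nz; ++k) {
    zc[k] = 0.5 * (zedges[k] + zedges[k + 1]);
    dz[k] = (zedges[k + 1] - zedges[k]) * MM;
  }
  Cracks cr(cracks_m);

  std::vector<double> Gx((size_t)(nx - 1) * ny * nz, 0.0);
  std::vector<double> Gy((size_t)nx * (ny - 1) * nz, 0.0);
  std::vector<double> Gz((size_t)nx * ny * (nz > 1 ? nz - 1 : 0), 0.0);
  std::vector<double> diag(N, 0.0), b(N, 0.0);

  auto sigT = [&](int lab) { return tissue_sigma(lab, 0); };
  auto sigZ = [&](int lab) { return tissue_sigma(lab, 1); };
  auto sheet = [&](int la, int lb) {
    double r = 0.0;
    if (la != lb) {
      if (la >= 2) r += peri_res[la - 2];
      if (lb >= 2) r += peri_res[lb - 2];
    }
    return r;
  };

  // x faces
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        int la = label2d[i + nx * j], lb = label2d[i + 1 + nx * j];
        if (cr.cut_x(xs[i], xs[i + 1], ys[j], zc[k])) continue;
        double R = 0.5 * hx / sigT(la) + 0.5 * hx / sigT(lb) + sheet(la, lb);
        Gx[(size_t)i + (size_t)(nx - 1) * (j + (size_t)ny * k)] =
            hy * dz[k] / R;
      }
  // y faces
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx; ++i) {
        int la = label2d[i + nx * j], lb = label2d[i + nx * (j + 1)];
        if (cr.cut_y(ys[j], ys[j + 1], xs[i], zc[k])) continue;
        double R = 0.5 * hy / sigT(la) + 0.5 * hy / sigT(lb) + sheet(la, lb);
        Gy[(size_t)i + (size_t)nx * (j + (size_t)(ny - 1) * k)] =
            hx * dz[k] / R;
      }
  // z faces (labels identical along z; no sheets or cracks)
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int la = label2d[i + nx * j];
        double R = 0.5 * dz[k] / sigZ(la) + 0.5 * dz[k + 1] / sigZ(la);
        Gz[(size_t)i + (size_t)nx * (j + (size_t)ny * k)] = hx * hy / R;
      }

  auto IDX = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  };

  // Branchless per-cell coupling arrays: for each masked cell the
  // conductance to each of its six neighbors (zero towards Dirichlet or
  // out-of-grid neighbors, whose contribution goes to diag and b instead).
  size_t sxy = (size_t)nx * ny;
  std::vector<double> Gxm(N, 0.0), Gxp(N, 0.0), Gym(N, 0.0), Gyp(N, 0.0),
      Gzm(N, 0.0), Gzp(N, 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = IDX(i, j, k);
        if (!mask[id]) { diag[id] = 1.0; continue; }
        double d = 0.0, g;
        if (i > 0) {
          g = Gx[(size_t)(i - 1) + (size_t)(nx - 1) * (j + (size_t)ny * k)];
          d += g;
          if (mask[id - 1]) Gxm[id] = g; else b[id] += g * vb[id - 1];
        }
        if (i < nx - 1) {
          g = Gx[(size_t)i + (size_t)(nx - 1) * (j + (size_t)ny * k)];
          d += g;
          if (mask[id + 1]) Gxp[id] = g; else b[id] += g * vb[id + 1];
        }
        if (j > 0) {
          g = Gy[(size_t)i + (size_t)nx * ((j - 1) + (size_t)(ny - 1) * k)];
          d += g;
          if (mask[id - nx]) Gym[id] = g; else b[id] += g * vb[id - nx];
        }
        if (j < ny - 1) {
          g = Gy[(size_t)i + (size_t)nx * (j + (size_t)(ny - 1) * k)];
          d += g;
          if (mask[id + nx]) Gyp[id] = g; else b[id] += g * vb[id + nx];
        }
        if (k > 0) {
          g = Gz[(size_t)i + (size_t)nx * (j + (size_t)ny * (k - 1))];
          d += g;
          if (mask[id - sxy]) Gzm[id] = g; else b[id] += g * vb[id - sxy];
        }
        if (k < nz - 1) {
          g = Gz[(size_t)i + (size_t)nx * (j + (size_t)ny * k)];
          d += g;
          if (mask[id + sxy]) Gzp[id] = g; else b[id] += g * vb[id + sxy];
        }
        diag[id] = d;
      }
  for (size_t id = 0; id < N; ++id) if (!mask[id]) b[id] = 0.0;

  for (int s = 0; s < src_idx.size(); ++s) b[src_idx[s]] += I_src * src_w[s];

  // Jacobi-preconditioned conjugate gradients on padded vectors (the pad
  // and all non-mask entries stay exactly zero, so the stencil needs no
  // bounds or mask checks).
  size_t Np = N + 2 * sxy;
  std::vector<double> xv(Np, 0.0), rv(Np, 0.0), pv(Np, 0.0), Apv(Np, 0.0);
  double* x = xv.data() + sxy;
  double* r = rv.data() + sxy;
  double* p = pv.data() + sxy;
  double* Ap = Apv.data() + sxy;
  std::vector<double> idiag(N);
  for (size_t id = 0; id < N; ++id) idiag[id] = 1.0 / diag[id];

  double bnorm = 0.0;
  for (size_t id = 0; id < N; ++id) bnorm += b[id] * b[id];
  bnorm = std::sqrt(bnorm);
  double relres = 0.0;
  int it = 0;
  if (bnorm > 0) {
    double rz = 0.0;
    for (size_t id = 0; id < N; ++id) {
      r[id] = b[id];
      p[id] = r[id] * idiag[id];
      rz += r[id] * p[id];
    }
    for (it = 0; it < maxit; ++it) {
      double pAp = 0.0;
      for (size_t id = 0; id < N; ++id) {
        double acc = diag[id] * p[id]
          - Gxm[id] * p[id - 1] - Gxp[id] * p[id + 1]
          - Gym[id] * p[id - nx] - Gyp[id] * p[id + nx]
          - Gzm[id] * p[id - sxy] - Gzp[id] * p[id + sxy];
        Ap[id] = acc;
        pAp += p[id] * acc;
      }
      double alpha = rz / pAp;
      double rn = 0.0;
      for (size_t id = 0; id < N; ++id) {
        x[id] += alpha * p[id];
        r[id] -= alpha * Ap[id];
        rn += r[id] * r[id];
      }
      relres = std::sqrt(rn) / bnorm;
      if (relres < tol) { ++it; break; }
      double rz_new = 0.0;
      for (size_t id = 0; id < N; ++id) rz_new += r[id] * r[id] * idiag[id];
      double beta = rz_new / rz;
      rz = rz_new;
      for (size_t id = 0; id < N; ++id) p[id] = r[id] * idiag[id] + beta * p[id];
    }
  }

  NumericVector V(N);
  for (size_t id = 0; id < N; ++id) V[id] = mask[id] ? x[id] : vb[id];
  return List::create(_["V"] = V, _["iterations"] = it, _["relres"] = relres);
}

// Trilinear interpolation on a grid with uniform x/y and arbitrary ascending
// z cell centers. Points outside the hull of cell centers give NA.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector xs, NumericVector ys,
                            NumericVector zs, NumericVector V,
                            NumericVector px, NumericVector py,
                            NumericVector pz) {
  int nx = xs.size(), ny = ys.size(), nz = zs.size();
  int np = px.size();
  double hx = xs[1] - xs[0], hy = ys[1] - ys[0];
  NumericVector out(np);
  for (int q = 0; q < np; ++q) {
    double X = px[q], Y = py[q], Z = pz[q];
    if (X < xs[0] || X > xs[nx - 1] || Y < ys[0] || Y > ys[ny - 1] ||
        Z < zs[0] || Z > zs[nz - 1]) { out[q] = NA_REAL; continue; }
    int i = (int)std::floor((X - xs[0]) / hx);
    int j = (int)std::floor((Y - ys[0]) / hy);
    if (i >= nx - 1) i = nx - 2;
    if (j >= ny - 1) j = ny - 2;
    int k = 0, hi = nz - 1;
    while (hi - k > 1) { int mid = (k + hi) / 2; if (zs[mid] <= Z) k = mid; else hi = mid; }
    double tx = (X - xs[i]) / hx, ty = (Y - ys[j]) / hy;
    double tz = (zs[k + 1] > zs[k]) ? (Z - zs[k]) / (zs[k + 1] - zs[k]) : 0.0;
    auto at = [&](int a, int bb, int c) {
      return V[(size_t)a + (size_t)nx * (bb + (size_t)ny * c)];
    };
    double c00 = at(i, j, k) * (1 - tx) + at(i + 1, j, k) * tx;
    double c10 = at(i, j + 1, k) * (1 - tx) + at(i + 1, j + 1, k) * tx;
    double c01 = at(i, j, k + 1) * (1 - tx) + at(i + 1, j, k + 1) * tx;
    double c11 = at(i, j + 1, k + 1) * (1 - tx) + at(i + 1, j + 1, k + 1) * tx;
    out[q] = (c00 * (1 - ty) + c10 * ty) * (1 - tz) +
             (c01 * (1 - ty) + c11 * ty) * tz;
  }
  return out;
}
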