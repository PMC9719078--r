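// Numerical kernels for the alignment/docking objective.
// Everything here has a plain-R counterpart in R/ used as the readable
// reference; tests assert agreement between the two routes.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double PI4_3 = 4.0 * M_PI / 3.0;
static const double COULOMB = 332.0637;  // kcal mol^-1 A e^-2
// Mehler-Solmajer sigmoidal distance-dependent dielectric
static const double MS_A = -8.5525, MS_B = 86.9525, MS_LAM = 0.003627,
                    MS_K = 7.7839;
static const double DESOLV_SIG = 3.6;   // A
static const double NB_CUTOFF = 8.0;    // A
static const double R_CLAMP = 0.75;     // A, keeps r^-12 finite in minimization

static inline double ms_eps(double r) {
  return MS_A + MS_B / (1.0 + MS_K * std::exp(-MS_LAM * MS_B * r));
}

static inline double lens_volume(double rA, double rB, double d) {
  if (d >= rA + rB) return 0.0;
  double rmin = rA < rB ? rA : rB;
  if (d <= std::fabs(rA - rB)) return PI4_3 * rmin * rmin * rmin;
  double s = rA + rB - d;
  double diff = rA - rB;
  return M_PI * s * s * (d * d + 2.0 * d * (rA + rB) - 3.0 * diff * diff) /
         (12.0 * d);
}

// [[Rcpp::export]]
NumericVector cpp_sphere_overlap(NumericVector rA, NumericVector rB,
                                 NumericVector d) {
  int n = rA.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = lens_volume(rA[i], rB[i], d[i]);
  return out;
}

// All-pairs overlap-volume shape numerator with a cross-type factor.
// Radii arrive already multiplied by radius_scale.
// [[Rcpp::export]]
List cpp_shape_overlap(NumericMatrix xq, NumericVector rq, IntegerVector tq,
                       NumericMatrix xr, NumericVector rr, IntegerVector tr,
                       double cross_factor) {
  int nq = xq.nrow(), nr = xr.nrow();
  // per-atom match scores: each atom contributes its best-overlap partner,
  // symmetrized over the two molecules (all-pairs summation saturates for
  // any dense overlay because bonded neighbors' spheres interpenetrate)
  std::vector<double> best_q(nq, 0.0), best_r(nr, 0.0);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nr; ++j) {
      double dx = xq(i, 0) - xr(j, 0);
      double dy = xq(i, 1) - xr(j, 1);
      double dz = xq(i, 2) - xr(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d >= rq[i] + rr[j]) continue;
      double v = lens_volume(rq[i], rr[j], d);
      if (tq[i] != tr[j]) v *= cross_factor;
      if (v > best_q[i]) best_q[i] = v;
      if (v > best_r[j]) best_r[j] = v;
    }
  }
  double num = 0.0;
  for (int i = 0; i < nq; ++i) num += best_q[i];
  for (int j = 0; j < nr; ++j) num += best_r[j];
  num *= 0.5;
  double vq = 0.0, vr = 0.0;
  for (int i = 0; i < nq; ++i) vq += PI4_3 * rq[i] * rq[i] * rq[i];
  for (int j = 0; j < nr; ++j) vr += PI4_3 * rr[j] * rr[j] * rr[j];
  return List::create(_["numerator"] = num, _["vol_query"] = vq,
                      _["vol_ref"] = vr);
}

static inline double dihedral(const NumericMatrix& x, int p, int a, int b,
                              int q) {
  double b1[3], b2[3], b3[3];
  for (int k = 0; k < 3; ++k) {
    b1[k] = x(a, k) - x(p, k);
    b2[k] = x(b, k) - x(a, k);
    b3[k] = x(q, k) - x(b, k);
  }
  double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1], b1[2] * b2[0] - b1[0] * b2[2],
                  b1[0] * b2[1] - b1[1] * b2[0]};
  double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1], b2[2] * b3[0] - b2[0] * b3[2],
                  b2[0] * b3[1] - b2[1] * b3[0]};
  double nb2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
  double m[3] = {n1[1] * b2[2] - n1[2] * b2[1], n1[2] * b2[0] - n1[0] * b2[2],
                 n1[0] * b2[1] - n1[1] * b2[0]};
  double xx = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
  double yy = (m[0] * n2[0] + m[1] * n2[1] + m[2] * n2[2]) / nb2;
  return std::atan2(yy, xx);
}

// [[Rcpp::export]]
double cpp_dihedral(NumericMatrix x, int p, int a, int b, int q) {
  return dihedral(x, p, a, b, q);
}

static void rotate_about_axis(NumericMatrix& x, const IntegerVector& moved,
                              int a, int b, double angle) {
  double ax = x(b, 0) - x(a, 0), ay = x(b, 1) - x(a, 1), az = x(b, 2) - x(a, 2);
  double n = std::sqrt(ax * ax + ay * ay + az * az);
  if (n < 1e-12) return;
  ax /= n; ay /= n; az /= n;
  double c = std::cos(angle), s = std::sin(angle), t = 1.0 - c;
  double R[3][3] = {
      {t * ax * ax + c, t * ax * ay - s * az, t * ax * az + s * ay},
      {t * ax * ay + s * az, t * ay * ay + c, t * ay * az - s * ax},
      {t * ax * az - s * ay, t * ay * az + s * ax, t * az * az + c}};
  for (int ii = 0; ii < moved.size(); ++ii) {
    int i = moved[ii];
    double vx = x(i, 0) - x(a, 0), vy = x(i, 1) - x(a, 1),
           vz = x(i, 2) - x(a, 2);
    x(i, 0) = x(a, 0) + R[0][0] * vx + R[0][1] * vy + R[0][2] * vz;
    x(i, 1) = x(a, 1) + R[1][0] * vx + R[1][1] * vy + R[1][2] * vz;
    x(i, 2) = x(a, 2) + R[2][0] * vx + R[2][1] * vy + R[2][2] * vz;
  }
}

// Realize Cartesian coordinates from a DOF vector: set each rotatable
// torsion to its target dihedral (tree order), then rotate the whole
// molecule about its centroid by the rotation vector and move the centroid
// to `trans`. `tor_p/a/b/q` and `moved` are 0-based.
// [[Rcpp::export]]
NumericMatrix cpp_realize(NumericMatrix base, IntegerVector tor_p,
                          IntegerVector tor_a, IntegerVector tor_b,
                          IntegerVector tor_q, List moved,
                          NumericVector torsions, NumericVector rotvec,
                          NumericVector trans, bool apply_rigid) {
  NumericMatrix x = clone(base);
  int nt = torsions.size();
  for (int t = 0; t < nt; ++t) {
    double cur = dihedral(x, tor_p[t], tor_a[t], tor_b[t], tor_q[t]);
    // right-hand rotation of the moved set about a->b decreases the signed
    // dihedral p-a-b-q, hence the reversed delta
    double delta = cur - torsions[t];
    IntegerVector mv = moved[t];
    rotate_about_axis(x, mv, tor_a[t], tor_b[t], delta);
  }
  if (!apply_rigid) return x;
  int n = x.nrow();
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) { cx += x(i, 0); cy += x(i, 1); cz += x(i, 2); }
  cx /= n; cy /= n; cz /= n;
  double theta = std::sqrt(rotvec[0] * rotvec[0] + rotvec[1] * rotvec[1] +
                           rotvec[2] * rotvec[2]);
  double R[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  if (theta > 1e-12) {
    double ax = rotvec[0] / theta, ay = rotvec[1] / theta,
           az = rotvec[2] / theta;
    double c = std::cos(theta), s = std::sin(theta), tt = 1.0 - c;
    R[0][0] = tt * ax * ax + c;      R[0][1] = tt * ax * ay - s * az;
    R[0][2] = tt * ax * az + s * ay; R[1][0] = tt * ax * ay + s * az;
    R[1][1] = tt * ay * ay + c;      R[1][2] = tt * ay * az - s * ax;
    R[2][0] = tt * ax * az - s * ay; R[2][1] = tt * ay * az + s * ax;
    R[2][2] = tt * az * az + c;
  }
  for (int i = 0; i < n; ++i) {
    double vx = x(i, 0) - cx, vy = x(i, 1) - cy, vz = x(i, 2) - cz;
    x(i, 0) = trans[0] + R[0][0] * vx + R[0][1] * vy + R[0][2] * vz;
    x(i, 1) = trans[1] + R[1][0] * vx + R[1][1] * vy + R[1][2] * vz;
    x(i, 2) = trans[2] + R[2][0] * vx + R[2][1] * vy + R[2][2] * vz;
  }
  return x;
}

// Ligand intramolecular nonbonded terms over a precomputed pair list.
// ljA/ljB are 12-6 (or 12-10 when is_hb) coefficients; qqc = 332.0637*qi*qj;
// dsc = (S_i V_j + S_j V_i). Returns sums split by hb and 1-4 status:
// [vdw, hb, qq, ds, vdw14, hb14, qq14, ds14].
// [[Rcpp::export]]
NumericVector cpp_pair_energy(NumericMatrix x, IntegerVector pi,
                              IntegerVector pj, NumericVector ljA,
                              NumericVector ljB, LogicalVector is_hb,
                              LogicalVector is_14, NumericVector qqc,
                              NumericVector dsc) {
  NumericVector out(8);
  int np = pi.size();
  for (int k = 0; k < np; ++k) {
    int i = pi[k], j = pj[k];
    double dx = x(i, 0) - x(j, 0), dy = x(i, 1) - x(j, 1),
           dz = x(i, 2) - x(j, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r > NB_CUTOFF) continue;
    double rc = r < R_CLAMP ? R_CLAMP : r;
    double inv2 = 1.0 / (rc * rc);
    double inv6 = inv2 * inv2 * inv2;
    double inv12 = inv6 * inv6;
    int off = is_14[k] ? 4 : 0;
    double e;
    if (is_hb[k]) {
      e = ljA[k] * inv12 - ljB[k] * inv6 * inv2 * inv2;  // 12-10
      out[off + 1] += e;
    } else {
      e = ljA[k] * inv12 - ljB[k] * inv6;                // 12-6
      out[off + 0] += e;
    }
    out[off + 2] += qqc[k] / (ms_eps(rc) * rc);
    out[off + 3] += dsc[k] * std::exp(-r * r / (2.0 * DESOLV_SIG * DESOLV_SIG));
  }
  return out;
}

// Trilinear interpolation of stacked channel grids at arbitrary points.
// grid is channel-major: value(ch, ix, iy, iz) =
//   grid[ch*nx*ny*nz + ix + nx*(iy + ny*iz)].
// Points outside the grid are clamped to the boundary.
// [[Rcpp::export]]
NumericMatrix cpp_grid_interp(NumericVector grid, IntegerVector dims,
                              NumericVector origin, double spacing,
                              NumericMatrix pts, IntegerVector channels) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int npts = pts.nrow(), nch = channels.size();
  long nxyz = (long)nx * ny * nz;
  NumericMatrix out(npts, nch);
  for (int p = 0; p < npts; ++p) {
    double fx = (pts(p, 0) - origin[0]) / spacing;
    double fy = (pts(p, 1) - origin[1]) / spacing;
    double fz = (pts(p, 2) - origin[2]) / spacing;
    if (fx < 0) fx = 0; if (fx > nx - 1) fx = nx - 1;
    if (fy < 0) fy = 0; if (fy > ny - 1) fy = ny - 1;
    if (fz < 0) fz = 0; if (fz > nz - 1) fz = nz - 1;
    int ix = (int)fx, iy = (int)fy, iz = (int)fz;
    if (ix >= nx - 1) ix = nx - 2; if (iy >= ny - 1) iy = ny - 2;
    if (iz >= nz - 1) iz = nz - 2;
    if (ix < 0) ix = 0; if (iy < 0) iy = 0; if (iz < 0) iz = 0;
    double tx = fx - ix, ty = fy - iy, tz = fz - iz;
    for (int c = 0; c < nch; ++c) {
      long base = (long)channels[c] * nxyz;
      double v = 0.0;
      for (int dx = 0; dx < 2; ++dx)
        for (int dy = 0; dy < 2; ++dy)
          for (int dz2 = 0; dz2 < 2; ++dz2) {
            double w = (dx ? tx : 1 - tx) * (dy ? ty : 1 - ty) *
                       (dz2 ? tz : 1 - tz);
            long idx = base + (ix + dx) + (long)nx * ((iy + dy) +
                       (long)ny * (iz + dz2));
            v += w * grid[idx];
          }
      out(p, c) = v;
    }
  }
  return out;
}

// RMSD of A (rows permuted) against B for each candidate atom permutation.
// perms: n_perm x N, 0-based; returns one RMSD per permutation.
// [[Rcpp::export]]
NumericVector cpp_rmsd_perms(NumericMatrix A, NumericMatrix B,
                             IntegerMatrix perms) {
  int np = perms.nrow(), n = B.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      int ai = perms(p, i);
      double dx = A(ai, 0) - B(i, 0), dy = A(ai, 1) - B(i, 1),
             dz = A(ai, 2) - B(i, 2);
      ss += dx * dx + dy * dy + dz * dz;
    }
    out[p] = std::sqrt(ss / n);
  }
  return out;
}

static double interp_channel(const NumericVector& grid, int nx, int ny,
                             int nz, const NumericVector& origin,
                             double spacing, const double* pt, int chan) {
  double fx = (pt[0] - origin[0]) / spacing;
  double fy = (pt[1] - origin[1]) / spacing;
  double fz = (pt[2] - origin[2]) / spacing;
  if (fx < 0) fx = 0;
  if (fx > nx - 1) fx = nx - 1;
  if (fy < 0) fy = 0;
  if (fy > ny - 1) fy = ny - 1;
  if (fz < 0) fz = 0;
  if (fz > nz - 1) fz = nz - 1;
  int ix = (int)fx, iy = (int)fy, iz = (int)fz;
  if (ix > nx - 2) ix = nx - 2;
  if (iy > ny - 2) iy = ny - 2;
  if (iz > nz - 2) iz = nz - 2;
  double tx = fx - ix, ty = fy - iy, tz = fz - iz;
  long nxyz = (long)nx * ny * nz;
  long base = (long)chan * nxyz;
  double v = 0.0;
  for (int dx = 0; dx < 2; ++dx)
    for (int dy = 0; dy < 2; ++dy)
      for (int dz = 0; dz < 2; ++dz) {
        double w = (dx ? tx : 1 - tx) * (dy ? ty : 1 - ty) *
                   (dz ? tz : 1 - tz);
        v += w * grid[base + (ix + dx) +
                      (long)nx * ((iy + dy) + (long)ny * (iz + dz))];
      }
  return v;
}

// One-shot objective evaluation: realize + shape + energy (+ grid terms in
// dock mode). The hot path of CSA local minimization; agrees with the
// R-level route (asserted in tests).
// [[Rcpp::export]]
NumericVector cpp_eval_objective(List S, NumericMatrix base,
                                 NumericVector torsions,
                                 NumericVector rotvec, NumericVector trans,
                                 bool energy_only) {
  NumericMatrix x = cpp_realize(base, S["tor_p"], S["tor_a"], S["tor_b"],
                                S["tor_q"], S["tor_moved"], torsions, rotvec,
                                trans, true);
  // ligand pair terms
  IntegerVector pi = S["pi"], pj = S["pj"];
  NumericVector ljA = S["ljA"], ljB = S["ljB"], qqc = S["qqc"],
                dsc = S["dsc"];
  LogicalVector is_hb = S["is_hb"], is_14 = S["is_14"];
  NumericVector sums = cpp_pair_energy(x, pi, pj, ljA, ljB, is_hb, is_14,
                                       qqc, dsc);
  NumericVector tV = S["tV"], tn = S["tn"], tph = S["tphase"],
                tV1 = S["tV1"];
  double bonded = 0.0;
  for (int t = 0; t < torsions.size(); ++t)
    bonded += tV[t] / 2.0 * (1.0 + std::cos(tn[t] * torsions[t] - tph[t])) +
              tV1[t] / 2.0 * (1.0 + std::cos(torsions[t]));
  NumericVector w = S["w"];  // w1..w8, w11
  double e = w[3] * sums[0] + w[4] * sums[1] + w[5] * sums[2] +
             w[6] * sums[3] +
             w[7] * (w[3] * sums[4] + w[4] * sums[5] + w[5] * sums[6] +
                     w[6] * sums[7]) + w[8] * bonded;
  bool dock = as<bool>(S["dock"]);
  if (dock) {
    NumericVector grid = S["grid"];
    IntegerVector gd = S["gdims"];
    NumericVector gorigin = S["gorigin"];
    double gspacing = as<double>(S["gspacing"]);
    IntegerVector ch_vdw = S["ch_vdw"], ch_hb = S["ch_hb"];
    int ch_elec = as<int>(S["ch_elec"]), ch_sv = as<int>(S["ch_sv"]),
        ch_ss = as<int>(S["ch_ss"]);
    NumericVector qi = S["qi"], Si = S["Si"], Vi = S["Vi"];
    NumericVector blo = S["box_lo"], bhi = S["box_hi"];
    double wall = as<double>(S["wall_k"]);
    IntegerVector heavy = S["heavy"];
    int n = x.nrow();
    double vdw = 0, hb = 0, qq = 0, ds = 0;
    double pt[3];
    for (int i = 0; i < n; ++i) {
      pt[0] = x(i, 0); pt[1] = x(i, 1); pt[2] = x(i, 2);
      vdw += interp_channel(grid, gd[0], gd[1], gd[2], gorigin, gspacing,
                            pt, ch_vdw[i]);
      hb += interp_channel(grid, gd[0], gd[1], gd[2], gorigin, gspacing,
                           pt, ch_hb[i]);
      qq += qi[i] * interp_channel(grid, gd[0], gd[1], gd[2], gorigin,
                                   gspacing, pt, ch_elec);
      ds += Si[i] * interp_channel(grid, gd[0], gd[1], gd[2], gorigin,
                                   gspacing, pt, ch_sv) +
            Vi[i] * interp_channel(grid, gd[0], gd[1], gd[2], gorigin,
                                   gspacing, pt, ch_ss);
    }
    double pen = 0;
    for (int k = 0; k < heavy.size(); ++k) {
      int i = heavy[k];
      for (int c = 0; c < 3; ++c) {
        double over = x(i, c) - bhi[c];
        if (over > 0) pen += over * over;
        over = blo[c] - x(i, c);
        if (over > 0) pen += over * over;
      }
    }
    e += vdw + w[0] * hb + w[1] * qq + w[2] * ds + wall * pen;
  }
  if (energy_only) return NumericVector::create(e, NA_REAL, e);
  // shape score against the static reference
  IntegerVector qh = S["qh"];
  NumericVector q_rad = S["q_rad"];
  IntegerVector q_type = S["q_type"];
  NumericMatrix r_xyz = S["r_xyz"];
  NumericVector r_rad = S["r_rad"];
  IntegerVector r_type = S["r_type"];
  double cross = as<double>(S["cross_factor"]);
  double sfloor = as<double>(S["s_floor"]);
  int nq = qh.size(), nr = r_xyz.nrow();
  double num = 0, vq = 0, vr = 0;
  std::vector<double> best_q(nq, 0.0), best_r(nr, 0.0);
  for (int a = 0; a < nq; ++a) {
    int i = qh[a];
    vq += PI4_3 * q_rad[a] * q_rad[a] * q_rad[a];
    for (int b = 0; b < nr; ++b) {
      double dx = x(i, 0) - r_xyz(b, 0), dy = x(i, 1) - r_xyz(b, 1),
             dz = x(i, 2) - r_xyz(b, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d >= q_rad[a] + r_rad[b]) continue;
      double v = lens_volume(q_rad[a], r_rad[b], d);
      if (q_type[a] != r_type[b]) v *= cross;
      if (v > best_q[a]) best_q[a] = v;
      if (v > best_r[b]) best_r[b] = v;
    }
  }
  for (int a = 0; a < nq; ++a) num += best_q[a];
  for (int b = 0; b < nr; ++b) num += best_r[b];
  num *= 0.5;
  for (int b = 0; b < nr; ++b) vr += PI4_3 * r_rad[b] * r_rad[b] * r_rad[b];
  double s = num / (vq > vr ? vq : vr);
  if (s > 1) s = 1;
  double sf = s < sfloor ? sfloor : s;
  double eal = e == 0 ? 0 : (e > 0 ? e / sf : sf * e);
  return NumericVector::create(eal, s, e);
}
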