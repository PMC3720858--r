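// Hot numerical kernels: soft-sphere clash energy, rigid block rotation
// about a bond axis, and the CCD closure sweep loop. Coordinate matrices
// are (3 * nres) x 3 with atoms in chain order N1, CA1, C1, N2, ...
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void rotate_block(NumericMatrix &xyz, int first, int last,
                                const double *o, const double *axis,
                                double theta_rad) {
  double n = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] +
                       axis[2] * axis[2]);
  double k0 = axis[0] / n, k1 = axis[1] / n, k2 = axis[2] / n;
  double ct = std::cos(theta_rad), st = std::sin(theta_rad);
  for (int r = first; r <= last; ++r) {
    double p0 = xyz(r, 0) - o[0], p1 = xyz(r, 1) - o[1],
           p2 = xyz(r, 2) - o[2];
    double cx = k1 * p2 - k2 * p1;
    double cy = k2 * p0 - k0 * p2;
    double cz = k0 * p1 - k1 * p0;
    double kd = k0 * p0 + k1 * p1 + k2 * p2;
    xyz(r, 0) = o[0] + p0 * ct + cx * st + k0 * kd * (1 - ct);
    xyz(r, 1) = o[1] + p1 * ct + cy * st + k1 * kd * (1 - ct);
    xyz(r, 2) = o[2] + p2 * ct + cz * st + k2 * kd * (1 - ct);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_rotate_block(NumericMatrix xyz, int first0,
                               NumericVector origin, NumericVector axis,
                               double theta_deg) {
  NumericMatrix out = clone(xyz);
  rotate_block(out, first0, out.nrow() - 1, origin.begin(), axis.begin(),
               theta_deg * M_PI / 180.0);
  return out;
}

// [[Rcpp::export]]
double cpp_clash_energy(NumericMatrix xyz, double sigma, double k,
                        int exclude_bonds, double cutoff) {
  int m = xyz.nrow();
  double contact = 2.0 * sigma, e = 0.0;
  double lim = std::min(contact, cutoff);
  for (int i = 0; i < m; ++i) {
    for (int j = i + exclude_bonds + 1; j < m; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < lim * lim) {
        double d = std::sqrt(d2);
        double ov = contact - d;
        e += k * ov * ov;
      }
    }
  }
  return e;
}

static inline double anchor_rms_cpp(const NumericMatrix &xyz, int anc0,
                                    const NumericMatrix &targets) {
  double s = 0.0;
  for (int j = 0; j < 3; ++j) {
    double dx = xyz(anc0 + j, 0) - targets(j, 0);
    double dy = xyz(anc0 + j, 1) - targets(j, 1);
    double dz = xyz(anc0 + j, 2) - targets(j, 2);
    s += dx * dx + dy * dy + dz * dz;
  }
  return std::sqrt(s / 3.0);
}

// CCD sweeps over phi/psi of residues start..end (1-based), anchors are
// N/CA/C of residue end+1. phi of residue 1 is skipped (undefined).
// Returns the updated coordinates, the per-dihedral total rotation
// applied (so the caller can update its dihedral bookkeeping), the sweep
// count and the final RMS anchor deviation.
// [[Rcpp::export]]
List cpp_ccd(NumericMatrix xyz_in, int start, int end,
             NumericMatrix targets, double tol, int max_iter) {
  NumericMatrix xyz = clone(xyz_in);
  int natoms = xyz.nrow();
  int anc0 = 3 * end; // 0-based first anchor atom (N of residue end+1)
  int nres_loop = end - start + 1;
  NumericVector dphi(nres_loop), dpsi(nres_loop);
  double dev = anchor_rms_cpp(xyz, anc0, targets);
  int sweeps = 0;
  while (dev > tol && sweeps < max_iter) {
    for (int i = start; i <= end; ++i) {
      for (int w = 0; w < 2; ++w) {
        if (w == 0 && i == 1) continue; // phi of residue 1 undefined
        int fromi, toi, first;
        if (w == 0) { // phi: N(i) -> CA(i), moves from C(i)
          fromi = 3 * (i - 1);
          toi = fromi + 1;
          first = fromi + 2;
        } else { // psi: CA(i) -> C(i), moves from N(i+1)
          fromi = 3 * (i - 1) + 1;
          toi = fromi + 1;
          first = fromi + 2;
        }
        double o[3] = {xyz(fromi, 0), xyz(fromi, 1), xyz(fromi, 2)};
        double ax[3] = {xyz(toi, 0) - o[0], xyz(toi, 1) - o[1],
                        xyz(toi, 2) - o[2]};
        double an = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] +
                              ax[2] * ax[2]);
        double u0 = ax[0] / an, u1 = ax[1] / an, u2 = ax[2] / an;
        double a = 0.0, b = 0.0;
        for (int j = 0; j < 3; ++j) {
          double p0 = xyz(anc0 + j, 0) - o[0];
          double p1 = xyz(anc0 + j, 1) - o[1];
          double p2 = xyz(anc0 + j, 2) - o[2];
          double pd = p0 * u0 + p1 * u1 + p2 * u2;
          double r0 = p0 - pd * u0, r1 = p1 - pd * u1, r2 = p2 - pd * u2;
          double s = std::sqrt(r0 * r0 + r1 * r1 + r2 * r2);
          if (s < 1e-9) continue;
          double rh0 = r0 / s, rh1 = r1 / s, rh2 = r2 / s;
          double t0 = u1 * rh2 - u2 * rh1;
          double t1 = u2 * rh0 - u0 * rh2;
          double t2 = u0 * rh1 - u1 * rh0;
          double f0 = targets(j, 0) - o[0] - pd * u0;
          double f1 = targets(j, 1) - o[1] - pd * u1;
          double f2 = targets(j, 2) - o[2] - pd * u2;
          a += s * (f0 * rh0 + f1 * rh1 + f2 * rh2);
          b += s * (f0 * t0 + f1 * t1 + f2 * t2);
        }
        if (a == 0.0 && b == 0.0) continue;
        double theta = std::atan2(b, a);
        if (std::fabs(theta) < 1e-14) continue;
        rotate_block(xyz, first, natoms - 1, o, ax, theta);
        double deg = theta * 180.0 / M_PI;
        if (w == 0) dphi[i - start] += deg; else dpsi[i - start] += deg;
      }
    }
    ++sweeps;
    dev = anchor_rms_cpp(xyz, anc0, targets);
  }
  return List::create(_["xyz"] = xyz, _["dphi"] = dphi, _["dpsi"] = dpsi,
                      _["sweeps"] = sweeps, _["deviation"] = dev);
}
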