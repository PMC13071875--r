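#include <Rcpp.h>
using namespace Rcpp;

// Empirical intermolecular score over receptor-ligand atom pairs within a
// cutoff: softened 12-6 Lennard-Jones (minimum at the sum of vdW radii,
// repulsion capped per pair), Coulomb with distance-dependent dielectric
// eps(r) = slope * r, and a linear penalty for pair distances below
// clash_scale * (r_i + r_j).  Poses are given as an absolute centroid
// position plus a unit quaternion applied about the ligand centroid.

static inline void quat_to_mat(const double *q, double R[9]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  double n = std::sqrt(w * w + x * x + y * y + z * z);
  w /= n; x /= n; y /= n; z /= n;
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z);     R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y);     R[7] = 2 * (y * z + w * x);     R[8] = 1 - 2 * (x * x + y * y);
}

// [[Rcpp::export(name = ".score_poses_cpp")]]
NumericMatrix score_poses_cpp(NumericMatrix rec_xyz, NumericVector rec_q,
                              NumericVector rec_r, NumericMatrix lig_local,
                              NumericVector lig_q, NumericVector lig_r,
                              NumericMatrix trans, NumericMatrix quat,
                              double cutoff, double epsilon, double coulomb_k,
                              double dielectric_slope, double repulsion_cap,
                              double clash_scale, double clash_k) {
  const int nr = rec_xyz.nrow(), nl = lig_local.nrow(), np = trans.nrow();
  NumericMatrix out(np, 4);  // lj, elec, clash, total
  const double cut2 = cutoff * cutoff;
  std::vector<double> lx(nl), ly(nl), lz(nl);
  for (int p = 0; p < np; ++p) {
    double q[4] = {quat(p, 0), quat(p, 1), quat(p, 2), quat(p, 3)};
    double R[9];
    quat_to_mat(q, R);
    const double tx = trans(p, 0), ty = trans(p, 1), tz = trans(p, 2);
    for (int i = 0; i < nl; ++i) {
      const double ax = lig_local(i, 0), ay = lig_local(i, 1), az = lig_local(i, 2);
      lx[i] = R[0] * ax + R[1] * ay + R[2] * az + tx;
      ly[i] = R[3] * ax + R[4] * ay + R[5] * az + ty;
      lz[i] = R[6] * ax + R[7] * ay + R[8] * az + tz;
    }
    double lj = 0, elec = 0, clash = 0;
    for (int i = 0; i < nl; ++i) {
      for (int j = 0; j < nr; ++j) {
        const double dx = lx[i] - rec_xyz(j, 0);
        const double dy = ly[i] - rec_xyz(j, 1);
        const double dz = lz[i] - rec_xyz(j, 2);
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 > cut2) continue;
        const double r = std::sqrt(std::max(d2, 1e-12));
        const double rm = lig_r[i] + rec_r[j];
        const double s2 = (rm * rm) / (r * r);
        const double s6 = s2 * s2 * s2;
        double e_lj = epsilon * (s6 * s6 - 2.0 * s6);
        if (e_lj > repulsion_cap) e_lj = repulsion_cap;
        lj += e_lj;
        elec += coulomb_k * lig_q[i] * rec_q[j] / (dielectric_slope * r * r);
        const double rc = clash_scale * rm;
        if (r < rc) clash += clash_k * (rc - r);
      }
    }
    out(p, 0) = lj;
    out(p, 1) = elec;
    out(p, 2) = clash;
    out(p, 3) = lj + elec + clash;
  }
  colnames(out) = CharacterVector::create("lj", "electrostatic", "clash", "total");
  return out;
}
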