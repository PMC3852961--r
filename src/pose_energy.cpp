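#include <Rcpp.h>
using namespace Rcpp;

// Membrane pseudo-energy of a set of scoring centres under many poses.
//
// A pose is (rot_x, rot_y, dz) with p' = R_y * R_x * p + (0,0,dz); only the
// transformed z-coordinate matters for the depth-sliced potential, so just
// the third row of R_y * R_x is evaluated:
//   z' = -sin(ry)*x + cos(ry)*sin(rx)*y + cos(ry)*cos(rx)*z + dz
// Depths are binned into half-open slices [lo, lo+width) spanning
// [-half_thickness, half_thickness); centres outside the slab contribute 0.
//
// coords: n x 3, aa: 1-based row index into energy, energy: 20 x n_slices.
// [[Rcpp::export]]
NumericVector pose_energies_cpp(NumericMatrix coords, IntegerVector aa,
                                NumericMatrix energy,
                                NumericVector rot_x, NumericVector rot_y,
                                NumericVector dz,
                                double half_thickness, double slice_width) {
  const int n = coords.nrow();
  const int m = rot_x.size();
  const int ns = energy.ncol();
  if (aa.size() != n) stop("aa length must match coords rows");
  if (rot_y.size() != m || dz.size() != m) stop("pose vectors must agree");
  const double deg = M_PI / 180.0;
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    const double a = rot_x[j] * deg, b = rot_y[j] * deg;
    const double sa = std::sin(a), ca = std::cos(a);
    const double sb = std::sin(b), cb = std::cos(b);
    const double r31 = -sb, r32 = cb * sa, r33 = cb * ca, d = dz[j];
    double e = 0.0;
    for (int i = 0; i < n; ++i) {
      const double z = r31 * coords(i, 0) + r32 * coords(i, 1) +
                       r33 * coords(i, 2) + d;
      const double u = (z + half_thickness) / slice_width;
      if (u >= 0.0 && u < ns) {
        const int s = static_cast<int>(u);
        e += energy(aa[i] - 1, s);
      }
    }
    out[j] = e;
  }
  return out;
}
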