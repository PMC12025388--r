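#include <Rcpp.h>
using namespace Rcpp;

// Grid integration of percent buried volume.
//
// coords: atom positions relative to the sphere center (n x 3), already
// restricted to atoms that can intersect the probe sphere. radii: scaled
// van der Waals radii, same order. The cube [-R, R]^3 is discretized with
// cell size <= spacing; a cell counts as buried when its center lies
// inside the probe sphere and inside at least one atom sphere.
// Returns c(buried cells, sphere cells).
// [[Rcpp::export]]
NumericVector buried_volume_grid_cpp(NumericMatrix coords,
                                     NumericVector radii,
                                     double sphere_radius,
                                     double spacing) {
  const int n_atoms = coords.nrow();
  const int n = (int)std::ceil(2.0 * sphere_radius / spacing);
  const double h = 2.0 * sphere_radius / n;
  const double R2 = sphere_radius * sphere_radius;

  std::vector<double> ax(n_atoms), ay(n_atoms), az(n_atoms), r2(n_atoms);
  for (int a = 0; a < n_atoms; ++a) {
    ax[a] = coords(a, 0);
    ay[a] = coords(a, 1);
    az[a] = coords(a, 2);
    r2[a] = radii[a] * radii[a];
  }

  long long in_sphere = 0, buried = 0;
  for (int i = 0; i < n; ++i) {
    const double x = -sphere_radius + (i + 0.5) * h;
    for (int j = 0; j < n; ++j) {
      const double y = -sphere_radius + (j + 0.5) * h;
      const double xy2 = x * x + y * y;
      if (xy2 > R2) continue;  // whole z-column outside only if xy2 > R2
      for (int k = 0; k < n; ++k) {
        const double z = -sphere_radius + (k + 0.5) * h;
        if (xy2 + z * z > R2) continue;
        ++in_sphere;
        for (int a = 0; a < n_atoms; ++a) {
          const double dx = x - ax[a], dy = y - ay[a], dz = z - az[a];
          if (dx * dx + dy * dy + dz * dz <= r2[a]) {
            ++buried;
            break;
          }
        }
      }
    }
  }
  return NumericVector::create((double)buried, (double)in_sphere);
}
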