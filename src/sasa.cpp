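#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley point-occlusion kernel. coords: n x 3; rad: solvent-expanded
// radii (vdw + probe); lattice: m x 3 unit-sphere sample points. Returns the
// accessible area of each expanded sphere in A^2.
// [[Rcpp::export]]
NumericVector sasa_kernel(NumericMatrix coords, NumericVector rad,
                          NumericMatrix lattice) {
  const int n = coords.nrow();
  const int m = lattice.nrow();
  NumericVector area(n);
  std::vector<double> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = coords(i, 0);
    cy[i] = coords(i, 1);
    cz[i] = coords(i, 2);
  }
  std::vector<int> nb;
  nb.reserve(256);
  for (int i = 0; i < n; ++i) {
    const double ri = rad[i];
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = cx[j] - cx[i];
      const double dy = cy[j] - cy[i];
      const double dz = cz[j] - cz[i];
      const double rr = ri + rad[j];
      if (dx * dx + dy * dy + dz * dz < rr * rr) nb.push_back(j);
    }
    int visible = 0;
    for (int k = 0; k < m; ++k) {
      const double px = cx[i] + ri * lattice(k, 0);
      const double py = cy[i] + ri * lattice(k, 1);
      const double pz = cz[i] + ri * lattice(k, 2);
      bool occluded = false;
      for (size_t q = 0; q < nb.size(); ++q) {
        const int j = nb[q];
        const double dx = px - cx[j];
        const double dy = py - cy[j];
        const double dz = pz - cz[j];
        if (dx * dx + dy * dy + dz * dz < rad[j] * rad[j]) {
          occluded = true;
          break;
        }
      }
      if (!occluded) ++visible;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double(visible) / double(m));
  }
  return area;
}
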