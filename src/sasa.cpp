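#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley sphere sampling: fraction of quadrature points on each
// atom's solvent-extended sphere (radius r_i + probe) not inside any
// neighbour's extended sphere, times the extended sphere area. The point
// set is passed in from R (deterministic golden-spiral), so results carry
// no randomness.
// [[Rcpp::export(name = ".sasaEngine")]]
NumericVector sasa_engine(NumericMatrix xyz, NumericVector radii,
                          double probe, NumericMatrix pts) {
  const int n = xyz.nrow();
  const int np = pts.nrow();
  NumericVector out(n);
  std::vector<double> rext(n);
  for (int i = 0; i < n; ++i) rext[i] = radii[i] + probe;

  std::vector<int> nb;
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    nb.clear();
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xi - xyz(j, 0);
      const double dy = yi - xyz(j, 1);
      const double dz = zi - xyz(j, 2);
      const double rr = rext[i] + rext[j];
      if (dx * dx + dy * dy + dz * dz < rr * rr) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < np; ++k) {
      const double px = xi + rext[i] * pts(k, 0);
      const double py = yi + rext[i] * pts(k, 1);
      const double pz = zi + rext[i] * pts(k, 2);
      bool buried = false;
      for (std::size_t m = 0; m < nb.size(); ++m) {
        const int j = nb[m];
        const double dx = px - xyz(j, 0);
        const double dy = py - xyz(j, 1);
        const double dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rext[j] * rext[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++acc;
    }
    out[i] = 4.0 * M_PI * rext[i] * rext[i] *
             (static_cast<double>(acc) / np);
  }
  return out;
}
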