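#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley exposure counts.
//
// For each atom i, a quasi-uniform unit point set (rows of `sphere`) is
// scaled to radius r_i + probe around the atom centre; a point is occluded
// when it lies strictly inside the probe-inflated sphere of any other atom.
// Neighbour pruning uses the exact bound d(i,j) < (r_i + r_j + 2 probe):
// beyond it no test point of i can fall inside sphere j, so far-away atoms
// leave the count bitwise unchanged (this is what makes the buried-surface
// zero test exact for separated groups).
//
// [[Rcpp::export(name = ".sasaExposedCounts")]]
IntegerVector sasa_exposed_counts(NumericMatrix xyz, NumericVector radii,
                                  double probe, NumericMatrix sphere) {
  const int n = xyz.nrow();
  const int m = sphere.nrow();
  IntegerVector out(n);
  std::vector<int> nb;
  std::vector<double> nbx, nby, nbz, nbr2;
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    nb.clear(); nbx.clear(); nby.clear(); nbz.clear(); nbr2.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double rj = radii[j] + probe;
      const double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi,
                   dz = xyz(j, 2) - zi;
      const double cut = ri + rj;
      if (dx * dx + dy * dy + dz * dz < cut * cut) {
        nb.push_back(j);
        nbx.push_back(xyz(j, 0)); nby.push_back(xyz(j, 1));
        nbz.push_back(xyz(j, 2)); nbr2.push_back(rj * rj);
      }
    }
    int exposed = 0;
    const int nn = (int) nb.size();
    for (int k = 0; k < m; ++k) {
      const double px = xi + ri * sphere(k, 0);
      const double py = yi + ri * sphere(k, 1);
      const double pz = zi + ri * sphere(k, 2);
      bool occ = false;
      for (int q = 0; q < nn; ++q) {
        const double dx = px - nbx[q], dy = py - nby[q], dz = pz - nbz[q];
        if (dx * dx + dy * dy + dz * dz < nbr2[q]) { occ = true; break; }
      }
      if (!occ) ++exposed;
    }
    out[i] = exposed;
  }
  return out;
}
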