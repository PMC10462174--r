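#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley point-burial kernel. For each atom, quasi-uniform sphere
// points (golden-spiral construction, deterministic) are placed at radius
// r_i + probe; the fraction not buried inside any neighbour's expanded
// sphere, times 4*pi*(r_i+probe)^2, is that atom's accessible area.
// Neighbour search uses a uniform cell grid with cell size 2*(r_max+probe),
// so only the 27 surrounding cells need scanning; the result is independent
// of the grid parameters.
// [[Rcpp::export(name = ".sasa_per_atom")]]
NumericVector sasa_per_atom(NumericMatrix xyz, NumericVector radii,
                            double probe, int npoints) {
  const int n = xyz.nrow();
  NumericVector area(n);
  if (n == 0) return area;

  // golden-spiral unit sphere points
  std::vector<double> px(npoints), py(npoints), pz(npoints);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < npoints; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / npoints;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    px[k] = r * std::cos(phi);
    py[k] = r * std::sin(phi);
    pz[k] = z;
  }

  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  const double cell = std::max(1e-6, 2.0 * (rmax + probe));

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = xyz(0, d); hi[d] = xyz(0, d); }
  for (int i = 1; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], xyz(i, d));
      hi[d] = std::max(hi[d], xyz(i, d));
    }
  int nc[3];
  for (int d = 0; d < 3; ++d)
    nc[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cell) + 1);

  auto cell_of = [&](int i, int d) {
    int c = (int)std::floor((xyz(i, d) - lo[d]) / cell);
    return std::min(std::max(c, 0), nc[d] - 1);
  };
  std::vector<std::vector<int> > grid((size_t)nc[0] * nc[1] * nc[2]);
  for (int i = 0; i < n; ++i) {
    int cx = cell_of(i, 0), cy = cell_of(i, 1), cz = cell_of(i, 2);
    grid[(size_t)(cx * nc[1] + cy) * nc[2] + cz].push_back(i);
  }

  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    nbr.clear();
    int cx = cell_of(i, 0), cy = cell_of(i, 1), cz = cell_of(i, 2);
    for (int dx = -1; dx <= 1; ++dx) {
      int ax = cx + dx; if (ax < 0 || ax >= nc[0]) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int ay = cy + dy; if (ay < 0 || ay >= nc[1]) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          int az = cz + dz; if (az < 0 || az >= nc[2]) continue;
          const std::vector<int>& cl =
            grid[(size_t)(ax * nc[1] + ay) * nc[2] + az];
          for (size_t t = 0; t < cl.size(); ++t) {
            int j = cl[t];
            if (j == i) continue;
            double rj = radii[j] + probe;
            double ddx = xyz(j, 0) - xi, ddy = xyz(j, 1) - yi,
                   ddz = xyz(j, 2) - zi;
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            double rs = ri + rj;
            if (d2 < rs * rs) nbr.push_back(j);
          }
        }
      }
    }
    int exposed = 0;
    for (int k = 0; k < npoints; ++k) {
      double qx = xi + ri * px[k], qy = yi + ri * py[k], qz = zi + ri * pz[k];
      bool buried = false;
      for (size_t t = 0; t < nbr.size(); ++t) {
        int j = nbr[t];
        double rj = radii[j] + probe;
        double ddx = qx - xyz(j, 0), ddy = qy - xyz(j, 1),
               ddz = qz - xyz(j, 2);
        if (ddx * ddx + ddy * ddy + ddz * ddz < rj * rj) {
          buried = true;
          break;
        }
      }
      if (!buried) ++exposed;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)exposed / npoints;
  }
  return area;
}
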