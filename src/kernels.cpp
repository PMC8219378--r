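#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Cell-list neighbour search between two point sets with optional
// orthorhombic minimum-image periodicity. Returns 1-based index pairs
// (i into A, j into B) at distance <= cutoff (closed boundary).
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix A, NumericMatrix B,
                                 double cutoff, NumericVector box) {
  const int na = A.nrow(), nb = B.nrow();
  const bool periodic = box.size() == 3;
  const double cut2 = cutoff * cutoff;

  double lo[3], ext[3];
  if (periodic) {
    for (int d = 0; d < 3; ++d) { lo[d] = 0.0; ext[d] = box[d]; }
  } else {
    for (int d = 0; d < 3; ++d) {
      double mn = R_PosInf, mx = R_NegInf;
      for (int i = 0; i < na; ++i) { mn = std::min(mn, A(i, d)); mx = std::max(mx, A(i, d)); }
      for (int i = 0; i < nb; ++i) { mn = std::min(mn, B(i, d)); mx = std::max(mx, B(i, d)); }
      lo[d] = mn; ext[d] = std::max(mx - mn, 1e-9);
    }
  }

  int nc[3];
  double csz[3];
  for (int d = 0; d < 3; ++d) {
    nc[d] = std::max(1, (int)std::floor(ext[d] / cutoff));
    csz[d] = ext[d] / nc[d];
  }
  const int ncell = nc[0] * nc[1] * nc[2];

  // wrap a coordinate into the box (periodic) or clamp to grid (open)
  auto cellcoord = [&](double x, int d) {
    double rel = x - lo[d];
    if (periodic) {
      rel -= std::floor(rel / ext[d]) * ext[d];
    }
    int c = (int)std::floor(rel / csz[d]);
    if (c < 0) c = 0;
    if (c >= nc[d]) c = nc[d] - 1;
    return c;
  };

  std::vector<int> head(ncell, -1), nxt(nb, -1);
  for (int j = 0; j < nb; ++j) {
    int c = (cellcoord(B(j, 0), 0) * nc[1] + cellcoord(B(j, 1), 1)) * nc[2] +
            cellcoord(B(j, 2), 2);
    nxt[j] = head[c];
    head[c] = j;
  }

  std::vector<int> out_i, out_j;
  std::vector<int> cells;
  cells.reserve(27);
  for (int i = 0; i < na; ++i) {
    int ca[3] = {cellcoord(A(i, 0), 0), cellcoord(A(i, 1), 1), cellcoord(A(i, 2), 2)};
    cells.clear();
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int cx = ca[0] + dx, cy = ca[1] + dy, cz = ca[2] + dz;
          if (periodic) {
            cx = (cx % nc[0] + nc[0]) % nc[0];
            cy = (cy % nc[1] + nc[1]) % nc[1];
            cz = (cz % nc[2] + nc[2]) % nc[2];
          } else {
            if (cx < 0 || cx >= nc[0] || cy < 0 || cy >= nc[1] ||
                cz < 0 || cz >= nc[2]) continue;
          }
          cells.push_back((cx * nc[1] + cy) * nc[2] + cz);
        }
    std::sort(cells.begin(), cells.end());
    cells.erase(std::unique(cells.begin(), cells.end()), cells.end());
    for (int c : cells) {
      for (int j = head[c]; j >= 0; j = nxt[j]) {
        double d2 = 0.0;
        for (int d = 0; d < 3; ++d) {
          double dd = A(i, d) - B(j, d);
          if (periodic) dd -= box[d] * std::round(dd / box[d]);
          d2 += dd * dd;
        }
        if (d2 <= cut2) {
          out_i.push_back(i + 1);
          out_j.push_back(j + 1);
        }
      }
    }
  }

  IntegerMatrix out(out_i.size(), 2);
  for (size_t k = 0; k < out_i.size(); ++k) {
    out(k, 0) = out_i[k];
    out(k, 1) = out_j[k];
  }
  return out;
}

// Deterministic quasi-uniform sphere points (golden spiral, fixed
// orientation), as an n x 3 matrix of unit vectors.
// [[Rcpp::export]]
NumericMatrix cpp_sphere_points(int n) {
  NumericMatrix pts(n, 3);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - 2.0 * (i + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * i;
    pts(i, 0) = r * std::cos(phi);
    pts(i, 1) = r * std::sin(phi);
    pts(i, 2) = z;
  }
  return pts;
}

// Shrake-Rupley per-atom solvent-accessible surface area (A^2).
// A surface point of atom i is exposed iff it lies strictly outside every
// other atom's probe-inflated sphere. No periodic images.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix xyz, NumericVector radii,
                       double probe, int n_points) {
  const int n = xyz.nrow();
  NumericMatrix pts = cpp_sphere_points(n_points);
  NumericVector area(n);
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;

  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        double dd = xyz(i, d) - xyz(j, d);
        d2 += dd * dd;
      }
      double rr = R[i] + R[j];
      if (d2 < rr * rr) nbr.push_back(j);
    }
    int exposed = 0;
    for (int p = 0; p < n_points; ++p) {
      double px = xyz(i, 0) + R[i] * pts(p, 0);
      double py = xyz(i, 1) + R[i] * pts(p, 1);
      double pz = xyz(i, 2) + R[i] * pts(p, 2);
      bool occ = false;
      for (int j : nbr) {
        double dx = px - xyz(j, 0), dy = py - xyz(j, 1), dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) { occ = true; break; }
      }
      if (!occ) ++exposed;
    }
    area[i] = 4.0 * M_PI * R[i] * R[i] * (double)exposed / n_points;
  }
  return area;
}

// Interaction energy of a set of mobile beads with the (immobile) lipid
// field plus the z<0 half-space wall, for Metropolis deltas:
//   elec: screened Coulomb between charged mobile beads and charged
//         lipids, with the distance clamped at the contact distance sigma
//         (beads are finite spheres; the clamp keeps the attraction
//         bounded so the finite soft core can actually exclude volume)
//   ev:   soft-core repulsion k_ev*(1 - r/sigma)^2 for r < sigma,
//         mobile beads vs lipid beads, plus wall k_ev*z^2 for z < 0
// Bond terms are handled by the caller. Returns elec + ev.
// [[Rcpp::export]]
double cpp_mobile_energy(NumericMatrix mov, NumericVector mov_q,
                         NumericMatrix lip, NumericVector lip_q,
                         double debye, double dielectric, double coulomb,
                         double sigma, double k_ev) {
  const int nm = mov.nrow(), nl = lip.nrow();
  const double sig2 = sigma * sigma;
  double elec = 0.0, ev = 0.0;
  for (int i = 0; i < nm; ++i) {
    const double qi = mov_q[i];
    const double xi = mov(i, 0), yi = mov(i, 1), zi = mov(i, 2);
    if (zi < 0.0) ev += k_ev * zi * zi;
    for (int j = 0; j < nl; ++j) {
      double dx = xi - lip(j, 0), dy = yi - lip(j, 1), dz = zi - lip(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      bool near = d2 < sig2;
      bool charged = qi != 0.0 && lip_q[j] != 0.0;
      if (!near && !charged) continue;
      double r = std::sqrt(d2);
      if (charged) {
        double rc = std::max(r, sigma);
        elec += coulomb * qi * lip_q[j] * std::exp(-rc / debye) / (dielectric * rc);
      }
      if (near) {
        double t = 1.0 - r / sigma;
        ev += k_ev * t * t;
      }
    }
  }
  return elec + ev;
}
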