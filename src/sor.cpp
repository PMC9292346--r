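// Red-black successive over-relaxation for the Dirichlet-Laplace problem on
// uniform grids: axisymmetric (rho, z) with the 1/rho term and the rho = 0
// axis handled by symmetry, and Cartesian 3-D. The residual is the maximum
// absolute Gauss-Seidel displacement (volts).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List sor_axisym_cpp(NumericMatrix value, IntegerMatrix mask,
                    double hr, double hz, double omega,
                    double tol, int max_iter) {
  const int nr = value.nrow(), nz = value.ncol();
  NumericMatrix phi = clone(value);
  const double ar = 1.0 / (hr * hr), az = 1.0 / (hz * hz);

  std::vector<double> aE(nr), aW(nr), inv_denom(nr);
  aE[0] = 4.0 * ar; aW[0] = 0.0;
  inv_denom[0] = 1.0 / (4.0 * ar + 2.0 * az);
  for (int i = 1; i < nr; ++i) {
    const double rho = i * hr;
    aE[i] = ar * (1.0 + hr / (2.0 * rho));
    aW[i] = ar * (1.0 - hr / (2.0 * rho));
    inv_denom[i] = 1.0 / (2.0 * ar + 2.0 * az);
  }

  double resid = R_PosInf, prev = R_PosInf;
  bool diverged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    resid = 0.0;
    for (int color = 0; color < 2; ++color) {
      for (int j = 1; j < nz - 1; ++j) {
        const int istart = ((j + color) % 2 + 2) % 2;  // (i+j) % 2 == color
        for (int i = istart; i < nr - 1; i += 2) {
          if (mask(i, j) != 0) continue;
          double s;
          if (i == 0)
            s = aE[0] * phi(1, j) + az * (phi(0, j - 1) + phi(0, j + 1));
          else
            s = aE[i] * phi(i + 1, j) + aW[i] * phi(i - 1, j)
              + az * (phi(i, j - 1) + phi(i, j + 1));
          const double d = s * inv_denom[i] - phi(i, j);
          const double ad = std::fabs(d);
          if (ad > resid) resid = ad;
          phi(i, j) += omega * d;
        }
      }
    }
    if (resid < tol) break;
    if (it % 100 == 0) {
      if (resid > prev) { diverged = true; break; }
      prev = resid;
    }
  }
  if (it > max_iter) it = max_iter;
  return List::create(_["phi"] = phi, _["residual"] = resid,
                      _["iterations"] = it,
                      _["converged"] = (resid < tol) && !diverged,
                      _["diverged"] = diverged);
}

// [[Rcpp::export]]
List sor_cart3_cpp(NumericVector value, IntegerVector mask, IntegerVector dims,
                   double hx, double hy, double hz, double omega,
                   double tol, int max_iter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector phi = clone(value);
  const double ax = 1.0 / (hx * hx), ay = 1.0 / (hy * hy), az = 1.0 / (hz * hz);
  const double inv_denom = 1.0 / (2.0 * (ax + ay + az));
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  double resid = R_PosInf, prev = R_PosInf;
  bool diverged = false;
  int it = 0;
  double *p = REAL(phi);
  int *m = INTEGER(mask);
  for (it = 1; it <= max_iter; ++it) {
    resid = 0.0;
    for (int color = 0; color < 2; ++color) {
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          const R_xlen_t base = k * sz + j * sy;
          const int istart = 1 + ((1 + j + k + color) % 2);
          for (int i = istart; i < nx - 1; i += 2) {
            const R_xlen_t id = base + i;
            if (m[id] != 0) continue;
            const double s = ax * (p[id - sx] + p[id + sx])
                           + ay * (p[id - sy] + p[id + sy])
                           + az * (p[id - sz] + p[id + sz]);
            const double d = s * inv_denom - p[id];
            const double ad = std::fabs(d);
            if (ad > resid) resid = ad;
            p[id] += omega * d;
          }
        }
      }
    }
    if (resid < tol) break;
    if (it % 100 == 0) {
      if (resid > prev) { diverged = true; break; }
      prev = resid;
    }
  }
  if (it > max_iter) it = max_iter;
  phi.attr("dim") = dims;
  return List::create(_["phi"] = phi, _["residual"] = resid,
                      _["iterations"] = it,
                      _["converged"] = (resid < tol) && !diverged,
                      _["diverged"] = diverged);
}

// Maximum absolute discrete-Laplace defect (scaled to volts) on interior
// nodes; used for analytic-potential Laplacian checks.
// [[Rcpp::export]]
double laplace_defect_axisym_cpp(NumericMatrix phi, IntegerMatrix mask,
                                 double hr, double hz) {
  const int nr = phi.nrow(), nz = phi.ncol();
  const double ar = 1.0 / (hr * hr), az = 1.0 / (hz * hz);
  double worst = 0.0;
  for (int j = 1; j < nz - 1; ++j) {
    for (int i = 0; i < nr - 1; ++i) {
      if (mask(i, j) != 0) continue;
      double s, denom;
      if (i == 0) {
        s = 4.0 * ar * phi(1, j) + az * (phi(0, j - 1) + phi(0, j + 1));
        denom = 4.0 * ar + 2.0 * az;
      } else {
        const double rho = i * hr;
        s = ar * (1.0 + hr / (2.0 * rho)) * phi(i + 1, j)
          + ar * (1.0 - hr / (2.0 * rho)) * phi(i - 1, j)
          + az * (phi(i, j - 1) + phi(i, j + 1));
        denom = 2.0 * ar + 2.0 * az;
      }
      const double d = std::fabs(s / denom - phi(i, j));
      if (d > worst) worst = d;
    }
  }
  return worst;
}
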