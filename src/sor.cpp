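#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Red-black successive over-relaxation sweep for the variable-coefficient
// linearized Poisson-Boltzmann stencil:
//   (sum_f eps_f) phi0 + diagk*phi0 = sum_f eps_f phi_f + src
// Arrays are flattened 3D grids (i fastest), eps[xyz][n] is the face
// dielectric between node n and its +x/+y/+z neighbour, diagk holds the
// eps_s*kappa^2*h^2 ion term and src the scaled charge density. Boundary
// nodes are Dirichlet and never updated.
// [[Rcpp::export]]
List sor_solve(NumericVector phi_init, NumericVector epsx, NumericVector epsy,
               NumericVector epsz, NumericVector diagk, NumericVector src,
               int nx, int ny, int nz, double omega, double tol,
               int max_iter) {
  NumericVector phi = clone(phi_init);
  const int nxy = nx * ny;
  double rel = R_PosInf;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    double maxdel = 0.0, maxphi = 0.0;
    for (int color = 0; color < 2; ++color) {
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          const int base = j * nx + k * nxy;
          int istart = 1 + ((1 + j + k + color) & 1);
          for (int i = istart; i < nx - 1; i += 2) {
            const int n = base + i;
            const double eE = epsx[n], eW = epsx[n - 1];
            const double eN = epsy[n], eS = epsy[n - nx];
            const double eU = epsz[n], eD = epsz[n - nxy];
            const double den = eE + eW + eN + eS + eU + eD + diagk[n];
            const double num = eE * phi[n + 1] + eW * phi[n - 1] +
                               eN * phi[n + nx] + eS * phi[n - nx] +
                               eU * phi[n + nxy] + eD * phi[n - nxy] + src[n];
            const double del = num / den - phi[n];
            phi[n] += omega * del;
            const double adel = std::fabs(del);
            if (adel > maxdel) maxdel = adel;
            const double aphi = std::fabs(phi[n]);
            if (aphi > maxphi) maxphi = aphi;
          }
        }
      }
    }
    rel = maxdel / std::max(maxphi, 1e-300);
    if (rel <= tol) break;
  }
  return List::create(_["phi"] = phi, _["iters"] = std::min(iter, max_iter),
                      _["rel_residual"] = rel,
                      _["converged"] = rel <= tol);
}
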