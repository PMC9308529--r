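#include <Rcpp.h>
using namespace Rcpp;

// Harmonic-mean interface conductivity; 0 when either side insulates.
static inline double hmean(double a, double b) {
  double s = a + b;
  return s > 0.0 ? 2.0 * a * b / s : 0.0;
}

// Synchronous (Jacobi) explicit finite-difference iteration of the Pennes
// bioheat equation until the max node-wise change drops below tol.
// rhocp = rho*cp per pixel, perf = wb*rho_b*cp_b per pixel.
// [[Rcpp::export]]
List solve_bioheat_cpp(NumericMatrix t0, NumericMatrix k,
                       NumericMatrix rhocp, NumericMatrix qm,
                       NumericMatrix perf, LogicalMatrix fixed,
                       double dt, double dx, double t_boundary, double t_a,
                       double tol, int max_iters, int log_every) {
  int nr = t0.nrow(), nc = t0.ncol();
  NumericMatrix cur(clone(t0)), nxt(nr, nc);

  // face conductivities are constant over the iteration: precompute
  NumericMatrix kR(nr, nc), kD(nr, nc); // toward larger col / larger row
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      kR(i, j) = (j + 1 < nc) ? hmean(k(i, j), k(i, j + 1)) : 0.0;
      kD(i, j) = (i + 1 < nr) ? hmean(k(i, j), k(i + 1, j)) : 0.0;
    }

  double dx2 = dx * dx, delta = R_PosInf;
  bool conv = false;
  int iter = 0;
  while (iter < max_iters) {
    ++iter;
    delta = 0.0;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        double tn;
        if (fixed(i, j)) {
          tn = t_boundary;
        } else {
          double t = cur(i, j);
          double diff =
            (j + 1 < nc ? kR(i, j) * (cur(i, j + 1) - t) : 0.0) +
            (j > 0 ? kR(i, j - 1) * (cur(i, j - 1) - t) : 0.0) +
            (i + 1 < nr ? kD(i, j) * (cur(i + 1, j) - t) : 0.0) +
            (i > 0 ? kD(i - 1, j) * (cur(i - 1, j) - t) : 0.0);
          tn = t + dt / (rhocp(i, j) * dx2) * diff +
               dt / rhocp(i, j) * (perf(i, j) * (t_a - t) + qm(i, j));
        }
        double d = tn - cur(i, j);
        if (d < 0) d = -d;
        if (d > delta) delta = d;
        nxt(i, j) = tn;
      }
    }
    std::swap(cur, nxt);
    if (log_every > 0 && iter % log_every == 0)
      Rcout << "sweep " << iter << ": max delta " << delta << "\n";
    if (delta < tol) { conv = true; break; }
    if (iter % 5000 == 0) checkUserInterrupt();
  }
  return List::create(_["temps"] = cur, _["iterations"] = iter,
                      _["delta"] = delta, _["converged"] = conv);
}
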