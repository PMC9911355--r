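#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// One full dual sweep (f then g) at a fixed eps. Returns the max-norm change.
// The e^{f/eps} factor is cancelled analytically, giving
//   f_k = eps*log(a_k) - eps * LSE( {(g_l - C_kl)/eps : l in row k}, -rho/eps )
// and symmetrically for g. Masked (zero-mass) rows/columns carry -Inf duals.
static double sweep(const IntegerVector& row_ptr, const IntegerVector& col_idx,
                    const NumericVector& cost_r,
                    const IntegerVector& col_ptr, const IntegerVector& row_idx,
                    const NumericVector& cost_c,
                    const NumericVector& loga, const NumericVector& logb,
                    NumericVector& f, NumericVector& g,
                    double eps, double rho) {
  const double ninf = -std::numeric_limits<double>::infinity();
  const double mrho = -rho / eps;
  double change = 0.0;
  const int nrow = loga.size(), ncol = logb.size();
  for (int k = 0; k < nrow; ++k) {
    if (loga[k] == ninf) continue;
    double m = mrho;
    for (int p = row_ptr[k]; p < row_ptr[k + 1]; ++p) {
      double gl = g[col_idx[p]];
      if (gl == ninf) continue;
      double t = (gl - cost_r[p]) / eps;
      if (t > m) m = t;
    }
    double s = std::exp(mrho - m);
    for (int p = row_ptr[k]; p < row_ptr[k + 1]; ++p) {
      double gl = g[col_idx[p]];
      if (gl == ninf) continue;
      s += std::exp((gl - cost_r[p]) / eps - m);
    }
    double fn = eps * loga[k] - eps * (m + std::log(s));
    if (!std::isfinite(fn)) stop("non-finite dual in Sinkhorn f-update (stabilization failure)");
    double d = std::fabs(fn - f[k]);
    if (d > change) change = d;
    f[k] = fn;
  }
  for (int l = 0; l < ncol; ++l) {
    if (logb[l] == ninf) continue;
    double m = mrho;
    for (int p = col_ptr[l]; p < col_ptr[l + 1]; ++p) {
      double fk = f[row_idx[p]];
      if (fk == ninf) continue;
      double t = (fk - cost_c[p]) / eps;
      if (t > m) m = t;
    }
    double s = std::exp(mrho - m);
    for (int p = col_ptr[l]; p < col_ptr[l + 1]; ++p) {
      double fk = f[row_idx[p]];
      if (fk == ninf) continue;
      s += std::exp((fk - cost_c[p]) / eps - m);
    }
    double gn = eps * logb[l] - eps * (m + std::log(s));
    if (!std::isfinite(gn)) stop("non-finite dual in Sinkhorn g-update (stabilization failure)");
    double d = std::fabs(gn - g[l]);
    if (d > change) change = d;
    g[l] = gn;
  }
  return change;
}

// Stabilized Sinkhorn with epsilon annealing: the entropic coefficient is
// halved from eps_init down to eps, warm-starting the duals at each level,
// which avoids the slow transient of cold starts at small eps. Levels above
// the target use a proportional tolerance (1e-3 * level eps); only the final
// level runs to `tol`. Setting eps_init <= eps disables annealing.
// Pointers (row_ptr/col_ptr) are 0-based CSR/CSC over the finite-cost support.
// [[Rcpp::export]]
List cot_sinkhorn(IntegerVector row_ptr, IntegerVector col_idx, NumericVector cost_r,
                  IntegerVector col_ptr, IntegerVector row_idx, NumericVector cost_c,
                  NumericVector loga, NumericVector logb,
                  double eps, double rho, double tol, int max_iter,
                  double eps_init) {
  const int nrow = loga.size(), ncol = logb.size();
  const double ninf = -std::numeric_limits<double>::infinity();
  NumericVector f(nrow, 0.0), g(ncol, 0.0);
  for (int k = 0; k < nrow; ++k) if (loga[k] == ninf) f[k] = ninf;
  for (int l = 0; l < ncol; ++l) if (logb[l] == ninf) g[l] = ninf;

  int it_total = 0;
  double change = R_PosInf;
  bool converged = false;

  double eps_cur = (eps_init > eps) ? eps_init : eps;
  while (true) {
    const bool final_level = (eps_cur <= eps);
    const double level_tol = final_level ? tol : std::max(tol, 1e-3 * eps_cur);
    while (it_total < max_iter) {
      ++it_total;
      change = sweep(row_ptr, col_idx, cost_r, col_ptr, row_idx, cost_c,
                     loga, logb, f, g, eps_cur, rho);
      if (change < level_tol) break;
    }
    if (final_level) {
      converged = (change < tol);
      break;
    }
    if (it_total >= max_iter) break;
    eps_cur = std::max(eps, eps_cur / 2.0);
  }

  return List::create(_["f"] = f, _["g"] = g,
                      _["iterations"] = it_total,
                      _["converged"] = converged,
                      _["dual_change"] = change);
}
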