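#include <Rcpp.h>
using namespace Rcpp;

// Gauss-Seidel sweeps of the tug-of-war dynamic programming update
//   u(i) <- alpha/d_i * sum_j w_ij u(j) + (1-alpha)/2 * (min_N u + max_N u)
// over the unlabeled vertices, in index order, until the sup-norm change of
// one full sweep falls below tol. W is the symmetric weight matrix in CSC
// form (slots p, i, x of a dgCMatrix); the diagonal is zero, so column i
// enumerates the open neighborhood of vertex i.
// [[Rcpp::export]]
List plap_sweep_cpp(IntegerVector Wp, IntegerVector Wi, NumericVector Wx,
                    NumericVector deg, IntegerVector unlabeled,
                    NumericVector u0, double alpha, double tol,
                    int max_iter) {
  NumericVector u = clone(u0);
  const int m = unlabeled.size();
  double res = R_PosInf;
  bool conv = false;
  int it = 0;
  while (it < max_iter) {
    ++it;
    res = 0.0;
    for (int a = 0; a < m; ++a) {
      const int i = unlabeled[a];
      double s = 0.0, mn = R_PosInf, mx = R_NegInf;
      for (int ptr = Wp[i]; ptr < Wp[i + 1]; ++ptr) {
        const double uj = u[Wi[ptr]];
        s += Wx[ptr] * uj;
        if (uj < mn) mn = uj;
        if (uj > mx) mx = uj;
      }
      const double unew =
          alpha * s / deg[i] + 0.5 * (1.0 - alpha) * (mn + mx);
      const double d = std::abs(unew - u[i]);
      if (d > res) res = d;
      u[i] = unew;
    }
    if (res < tol) {
      conv = true;
      break;
    }
  }
  return List::create(_["u"] = u, _["iterations"] = it, _["residual"] = res,
                      _["converged"] = conv);
}
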