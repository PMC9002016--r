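#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Coordinate descent for the lasso subproblem
//   min_b  0.5 b' V b - b' s + lam ||b||_1
// V is PD with positive diagonal. b is modified in place (warm start).
static void lasso_cd(const mat& V, const vec& s, double lam, vec& b,
                     double tol, int max_iter) {
  const uword q = b.n_elem;
  for (int it = 0; it < max_iter; ++it) {
    double maxd = 0.0;
    for (uword j = 0; j < q; ++j) {
      double old = b(j);
      // partial residual: gradient component with b_j removed
      double r = s(j) - dot(V.col(j), b) + V(j, j) * old;
      double bj = 0.0;
      if (r > lam)       bj = (r - lam) / V(j, j);
      else if (r < -lam) bj = (r + lam) / V(j, j);
      b(j) = bj;
      double d = std::fabs(bj - old);
      if (d > maxd) maxd = d;
    }
    if (maxd < tol) break;
  }
}

// Block coordinate descent for the graphical lasso
//   max_{Theta PD}  log det Theta - tr(S Theta) - lam * sum_{i != j} |theta_ij|
// Diagonal is unpenalized (W keeps diag(S) throughout). Returns the estimated
// covariance W, precision Theta, convergence flag and sweep count. B_init
// allows warm starts along a penalty path (columns are the p regression
// coefficient vectors of length p-1).
// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double lam, double tol, int max_iter,
                      Rcpp::Nullable<Rcpp::NumericMatrix> W_init = R_NilValue,
                      Rcpp::Nullable<Rcpp::NumericMatrix> B_init = R_NilValue) {
  const uword p = S.n_rows;
  mat W(p, p), B(p - 1, p, fill::zeros);
  if (W_init.isNotNull()) {
    W = Rcpp::as<mat>(W_init.get());
    W.diag() = S.diag();  // diagonal is fixed by the unpenalized-diagonal KKT
  } else {
    W = S;
  }
  if (B_init.isNotNull()) B = Rcpp::as<mat>(B_init.get());

  const double inner_tol = tol * 0.05 + 1e-12;
  bool converged = false;
  int sweeps = 0;

  uvec idx_all = regspace<uvec>(0, p - 1);
  for (int it = 0; it < max_iter; ++it) {
    ++sweeps;
    double maxd = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec rest = find(idx_all != j);
      mat V = W.submat(rest, rest);
      vec s12 = S.col(j);
      s12 = s12.elem(rest);
      vec b = B.col(j);
      lasso_cd(V, s12, lam, b, inner_tol, 1000);
      B.col(j) = b;
      vec w12 = V * b;
      for (uword k = 0; k < p - 1; ++k) {
        double d = std::fabs(W(rest(k), j) - w12(k));
        if (d > maxd) maxd = d;
        W(rest(k), j) = w12(k);
        W(j, rest(k)) = w12(k);
      }
    }
    if (maxd < tol) { converged = true; break; }
  }

  // Recover Theta column-wise: theta_jj = 1/(w_jj - w12' b), theta_.j = -b theta_jj
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec rest = find(idx_all != j);
    vec b = B.col(j);
    vec w12(p - 1);
    for (uword k = 0; k < p - 1; ++k) w12(k) = W(rest(k), j);
    double tjj = 1.0 / (W(j, j) - dot(w12, b));
    Theta(j, j) = tjj;
    for (uword k = 0; k < p - 1; ++k) Theta(rest(k), j) = -b(k) * tjj;
  }
  // Symmetrize, preserving the exact-zero pattern agreed by both columns
  mat Theta_s = 0.5 * (Theta + Theta.t());
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j)
      if (Theta(i, j) == 0.0 && Theta(j, i) == 0.0) {
        Theta_s(i, j) = 0.0;
        Theta_s(j, i) = 0.0;
      }

  return Rcpp::List::create(
      Rcpp::Named("w") = W,
      Rcpp::Named("theta") = Theta_s,
      Rcpp::Named("B") = B,
      Rcpp::Named("iterations") = sweeps,
      Rcpp::Named("converged") = converged);
}
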