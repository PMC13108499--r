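#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Graphical lasso by block coordinate descent (Friedman, Hastie & Tibshirani
// 2008). Estimates a sparse precision matrix Theta maximizing the penalized
// Gaussian log-likelihood  log det Theta - tr(S Theta) - rho * ||Theta||_1
// (off-diagonal penalty). Each outer sweep solves, for every column j, the
// lasso subproblem on the current covariance estimate W by coordinate
// descent. Warm starts are supported through W_init/Theta_init so a penalty
// path can be fit cheaply.
//
// Returns W (estimated covariance), Theta (precision), the number of outer
// sweeps used, and a convergence flag.
// [[Rcpp::export]]
Rcpp::List glasso_fit(const arma::mat& S, double rho,
                      Rcpp::Nullable<Rcpp::NumericMatrix> W_init = R_NilValue,
                      int maxit = 200, double tol = 1e-4,
                      int inner_maxit = 200, double inner_tol = 1e-6) {
  const uword p = S.n_rows;
  mat W;
  if (W_init.isNotNull()) {
    W = Rcpp::as<mat>(W_init.get());
  } else {
    W = S;
    W.diag() = S.diag() + rho;
  }
  // B stores, per column j, the lasso coefficients beta (p-1 vector embedded
  // with a zero at position j) for warm-started inner solves.
  mat B(p, p, fill::zeros);

  const double dmean = mean(abs(S.diag()));
  const double thresh = tol * (dmean > 0 ? dmean : 1.0);
  bool converged = false;
  int sweep = 0;

  for (sweep = 0; sweep < maxit; ++sweep) {
    double max_change = 0.0;
    for (uword j = 0; j < p; ++j) {
      // coordinate descent on: min 0.5 b'W11 b - b's12 + rho |b|_1
      vec b = B.col(j);
      b(j) = 0.0;
      for (int it = 0; it < inner_maxit; ++it) {
        double delta = 0.0;
        for (uword k = 0; k < p; ++k) {
          if (k == j) continue;
          double wkk = W(k, k);
          if (wkk <= 0) continue;
          // gradient residual excluding k's own contribution
          double g = S(k, j) - dot(W.col(k), b) + wkk * b(k);
          double bnew;
          if (g > rho) bnew = (g - rho) / wkk;
          else if (g < -rho) bnew = (g + rho) / wkk;
          else bnew = 0.0;
          double d = std::abs(bnew - b(k));
          if (d > delta) delta = d;
          b(k) = bnew;
        }
        if (delta < inner_tol) break;
      }
      b(j) = 0.0;
      B.col(j) = b;
      vec w12 = W * b;       // W11 * beta, with the j-th row contributing 0
      w12(j) = W(j, j);      // keep diagonal
      vec old = W.col(j);
      W.col(j) = w12;
      W.row(j) = w12.t();
      W(j, j) = S(j, j) + rho;
      double ch = abs(w12 - old).max();
      if (ch > max_change) max_change = ch;
    }
    if (max_change < thresh) { converged = true; break; }
  }

  // recover Theta from W and the regression coefficients
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    vec b = B.col(j);
    // b(j) = 0, so the dot skips the diagonal: denom = w22 - w12'beta
    double denom = W(j, j) - dot(W.col(j), b);
    double theta_jj = 1.0 / denom;
    Theta(j, j) = theta_jj;
    for (uword k = 0; k < p; ++k) {
      if (k == j) continue;
      Theta(k, j) = -b(k) * theta_jj;
    }
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("Theta") = Theta,
                            Rcpp::Named("sweeps") = sweep + 1,
                            Rcpp::Named("converged") = converged);
}
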