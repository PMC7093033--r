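// Block-tridiagonal Gaussian smoother for the variational state posterior.
//
// The variational factor q(c) over the latent calcium chain is a Gaussian
// whose precision is block tridiagonal: each frame contributes an
// observation block G'WG, frame 1 the initial-state precision, and each
// transition r = 2..R an effective precision P_r (the responsibility-mixed
// combination of the transition noise precision V and the expected mark
// precisions) with a linear offset b_r from the expected mark means.
// One forward block-elimination pass and one backward substitution pass
// return the marginal means, marginal covariances, lag-one cross
// covariances Cov(c_r, c_{r+1}), the innovation covariances
// Cov(c_r - F c_{r-1}) and log det of the joint precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List bt_smoother_cpp(const arma::mat& Jinit, const arma::vec& hinit,
                           const arma::mat& Phi, const arma::mat& Hobs,
                           const arma::mat& F, const arma::mat& P_stack,
                           const arma::mat& b_stack) {
  const uword R = Hobs.n_rows;
  const uword d = Phi.n_rows;
  if (P_stack.n_rows != R - 1 || b_stack.n_rows != R - 1)
    Rcpp::stop("P_stack and b_stack must have R - 1 rows");

  // Reconstruct per-frame transition precisions P_r (r = 2..R).
  std::vector<mat> P(R - 1);
  for (uword r = 0; r < R - 1; ++r)
    P[r] = symmatu(reshape(P_stack.row(r).t(), d, d));

  // Diagonal blocks J_rr, off-diagonal blocks M_r = J_{r,r+1} = -F' P_{r+1},
  // and the information vector h.
  std::vector<mat> U(R);      // Schur complements from forward elimination
  std::vector<mat> Uchol(R);  // their Cholesky factors
  mat g(d, R);                // eliminated information vectors
  const mat Ft = F.t();

  double logdetJ = 0.0;
  mat Jprev;  // not needed beyond loop; U holds Schur complements

  for (uword r = 0; r < R; ++r) {
    mat Jrr = Phi;
    vec hr = Hobs.row(r).t();
    if (r == 0) { Jrr += Jinit; hr += hinit; }
    if (r >= 1) { Jrr += P[r - 1]; hr += b_stack.row(r - 1).t(); }
    if (r + 1 < R) { Jrr += Ft * P[r] * F; hr -= Ft * b_stack.row(r).t(); }
    Jrr = symmatu(Jrr);
    if (r == 0) {
      U[0] = Jrr;
      g.col(0) = hr;
    } else {
      // M_{r-1} = J_{r-1,r} = -F' P_r ; J_{r,r-1} = M'_{r-1}
      mat M = -Ft * P[r - 1];          // block (r-1, r)
      mat Uinv_M;                       // U_{r-1}^{-1} M
      if (!solve(Uinv_M, symmatu(U[r - 1]), M, solve_opts::likely_sympd))
        Rcpp::stop("state posterior: singular block at frame %d", r);
      U[r] = symmatu(Jrr - M.t() * Uinv_M);
      g.col(r) = hr - Uinv_M.t() * g.col(r - 1);
    }
    mat C;
    if (!chol(C, symmatu(U[r])))
      Rcpp::stop("state posterior: non-positive-definite block at frame %d", r + 1);
    Uchol[r] = C;
    logdetJ += 2.0 * accu(log(C.diag()));
  }

  mat mu(R, d);
  mat sigma(R, d * d);
  mat cross(R - 1, d * d);     // vec(Cov(c_r, c_{r+1}))
  mat covdelta(R - 1, d * d);  // vec(Cov(c_r - F c_{r-1})), r = 2..R

  // Backward pass.
  mat Sig_next;  // Sigma_{r+1}
  {
    mat Uinv = inv_sympd(symmatu(U[R - 1]));
    Sig_next = Uinv;
    mu.row(R - 1) = (Uinv * g.col(R - 1)).t();
    sigma.row(R - 1) = vectorise(Uinv).t();
  }
  for (uword rr = R - 1; rr-- > 0;) {
    mat M = -Ft * P[rr];  // J_{rr, rr+1}
    mat Uinv = inv_sympd(symmatu(U[rr]));
    mat A = Uinv * M;     // U_r^{-1} J_{r,r+1}
    vec mur = Uinv * g.col(rr) - A * mu.row(rr + 1).t();
    mat Crs = -A * Sig_next;                 // Cov(c_r, c_{r+1})
    mat Sig_r = symmatu(Uinv + A * Sig_next * A.t());
    mu.row(rr) = mur.t();
    sigma.row(rr) = vectorise(Sig_r).t();
    cross.row(rr) = vectorise(Crs).t();
    // innovation covariance for transition rr+1 (frame index rr+2, 1-based)
    mat Cd = Sig_next + F * Sig_r * Ft - Crs.t() * Ft - F * Crs;
    covdelta.row(rr) = vectorise(symmatu(Cd)).t();
    Sig_next = Sig_r;
  }

  return Rcpp::List::create(
    Rcpp::Named("mu") = mu,
    Rcpp::Named("sigma") = sigma,
    Rcpp::Named("cross") = cross,
    Rcpp::Named("covdelta") = covdelta,
    Rcpp::Named("logdetJ") = logdetJ);
}

// Innovation covariances Cov(c_{r+1} - F c_r) for a given transition matrix,
// from the stored marginal and lag-one cross covariance stacks.
// [[Rcpp::export]]
arma::mat covdelta_cpp(const arma::mat& F, const arma::mat& sigma_stack,
                       const arma::mat& cross_stack) {
  const uword R = sigma_stack.n_rows;
  const uword d = F.n_rows;
  mat out(R - 1, d * d);
  const mat Ft = F.t();
  for (uword r = 0; r + 1 < R; ++r) {
    mat Sp = reshape(sigma_stack.row(r).t(), d, d);
    mat Sn = reshape(sigma_stack.row(r + 1).t(), d, d);
    mat Cr = reshape(cross_stack.row(r).t(), d, d);  // Cov(c_r, c_{r+1})
    mat Cd = Sn + F * Sp * Ft - Cr.t() * Ft - F * Cr;
    out.row(r) = vectorise(symmatu(Cd)).t();
  }
  return out;
}
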