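#' Evidence lower bound of the variational posterior
#'
#' Computes `E_q[log p(y, c, z, pi, u_kappa | u_x)] - E_q[log q]` under the
#' current factors, itemized for debugging. All expectations are closed-form
#' given the conjugate family choices. The joint is the augmented model of
#' the gamma-process posterior (with the `beta*` rate correction attached to
#' the spike factors), so the bound is monotone under every coordinate update
#' and bounded above by the log normalizer of that augmented joint.
#'
#' @param post An `mpp_posterior`.
#' @param movie `R x d_y` frame matrix.
#' @param stim A [stimulus_series()].
#' @param terms Return the named term breakdown instead of the scalar?
#' @return Scalar ELBO, or a named numeric vector of terms.
#' @export
compute_elbo <- function(post, movie, stim, terms = FALSE) {
  stopifnot(inherits(post, "mpp_posterior"), inherits(stim, "stimulus_series"))
  d <- post$d_kappa
  R <- post$R
  K <- post$K
  assert_matrix(movie, nrow = R, name = "movie")
  ss <- post$ss
  pr <- post$prior

  lw <- qz_log_weights(post, stim)
  act <- lw$act
  zet <- post$zeta[2:R, act, drop = FALSE]
  w0 <- pmax(1 - rowSums(zet), 0)

  # expected complete log joint: transition and spike factors
  t_trans <- sum(w0 * lw$logw0)
  t_spike <- if (length(act) > 0) sum(zet * lw$logwk) else 0
  # ... minus the parts of logwk that belong to E[log p(z | pi)] bookkeeping:
  # nothing to remove; logwk already is the full per-event term of the joint.

  # initial state
  Sig1 <- matrix(post$sigma_c[1, ], d, d)
  Jinit <- solve_spd(ss$sigma_init, what = "sigma_init")
  dev1 <- post$mu_c[1, ] - ss$mu_init
  t_init <- -(d / 2) * log(2 * pi) -
    0.5 * logdet_spd(ss$sigma_init, "sigma_init") -
    0.5 * (sum(Jinit * Sig1) + drop(crossprod(dev1, Jinit %*% dev1)))

  # observation term
  S_cov <- sym(matrix(colSums(post$sigma_c), d, d))
  resid2 <- colSums((movie - post$mu_c %*% t(ss$G))^2) + row_quad(ss$G, S_cov)
  t_obs <- 0.5 * R * sum(log(ss$W_diag)) - (R * ss$d_y / 2) * log(2 * pi) -
    0.5 * sum(ss$W_diag * resid2)

  # Dirichlet prior and entropy
  Elogpi <- lw$Elogpi
  a0K <- pr$alpha0 / K
  t_dir_prior <- lgamma(pr$alpha0) - K * lgamma(a0K) + (a0K - 1) * sum(Elogpi)
  alpha <- post$dir_alpha
  e_log_qpi <- lgamma(sum(alpha)) - sum(lgamma(alpha)) +
    sum((alpha - 1) * Elogpi)

  # Normal--Wishart prior and variational energies (all K; inactive factors
  # equal the prior so their prior and entropy contributions cancel)
  nwx_all <- nw_expectations(post)
  nw_energy <- function(m0, gamma0, nu0, S0, e) {
    quad <- d / e$gamma +
      drop(crossprod(e$m - m0, e$EL %*% (e$m - m0)))
    (d / 2) * (log(gamma0) - log(2 * pi)) + 0.5 * e$Eldet -
      0.5 * gamma0 * quad +
      (nu0 / 2) * logdet_spd(S0, "S") - (nu0 * d / 2) * log(2) -
      lmvgamma(nu0 / 2, d) + ((nu0 - d - 1) / 2) * e$Eldet -
      0.5 * sum(S0 * e$EL)
  }
  t_nw_prior <- 0
  e_log_qu <- 0
  for (k in seq_len(K)) {
    e <- nwx_all[[k]]
    t_nw_prior <- t_nw_prior +
      nw_energy(pr$m_kappa, pr$gamma_kappa, pr$nu_kappa, pr$S_kappa, e)
    e_log_qu <- e_log_qu +
      nw_energy(e$m, e$gamma, e$nu, post$nw$S[[k]], e)
  }

  # entropies of q(c) and q(z)
  e_log_qc <- 0.5 * post$logdetJ - (R * d / 2) * log(2 * pi) - R * d / 2
  xlogx <- function(p) ifelse(p > 1e-12, p * log(p), 0)
  e_log_qz <- sum(xlogx(w0)) + if (length(act) > 0) sum(xlogx(zet)) else 0

  out <- c(init = t_init, transition = t_trans, spike = t_spike,
           observation = t_obs, dir_prior = t_dir_prior, nw_prior = t_nw_prior,
           neg_e_log_qc = -e_log_qc, neg_e_log_qz = -e_log_qz,
           neg_e_log_qpi = -e_log_qpi, neg_e_log_qu = -e_log_qu)
  if (terms) out else sum(out)
}
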