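#' Variational posterior object
#'
#' Container for the four variational factors and the current hyperparameters
#' of the coordinate-ascent scheme. The factorization is
#' `q(c) q(z) q(pi) q(u_kappa)`:
#' a Gaussian chain over the latent calcium states (marginal means `mu_c`,
#' marginal covariances `sigma_c`, lag-one cross covariances `sigma_cross`),
#' independent per-frame spike responsibilities `zeta` (row r gives the
#' probability that frame r carries a spike of component k; the no-spike
#' probability is one minus the row sum), a Dirichlet over the mixture
#' weights, and independent Normal--Wishart factors over each component's
#' mark kernel parameters. Stimulus kernels `stim_params` and the state-space
#' matrices are point-estimated hyperparameters.
#'
#' Covariance stacks are stored row-wise: row r of `sigma_c` is
#' `vec(Sigma_r)` (column-major), row r of `sigma_cross` is
#' `vec(Cov(c_r, c_{r+1}))`, and row r of `covdelta` is
#' `vec(Cov(c_{r+1} - F c_r))` for the transition into frame r + 1.
#'
#' @name mpp_posterior
NULL

new_mpp_posterior <- function(mu_c, sigma_c, sigma_cross, covdelta, logdetJ,
                              zeta, dir_alpha, nw, stim_params, ss, prior,
                              active, seed, elbo_trace = numeric(0)) {
  structure(list(
    mu_c = mu_c, sigma_c = sigma_c, sigma_cross = sigma_cross,
    covdelta = covdelta, logdetJ = logdetJ,
    zeta = zeta, dir_alpha = dir_alpha, nw = nw,
    stim_params = stim_params, ss = ss, prior = prior,
    active = active, seed = seed, elbo_trace = elbo_trace,
    d_kappa = ncol(mu_c), K = length(dir_alpha), R = nrow(mu_c)),
    class = "mpp_posterior")
}

#' @export
print.mpp_posterior <- function(x, ...) {
  cat(sprintf(
    "<mpp_posterior> R = %d frames, d_kappa = %d, K = %d (%d active), %d sweeps\n",
    x$R, x$d_kappa, x$K, sum(x$active), length(x$elbo_trace)))
  if (length(x$elbo_trace) > 0)
    cat(sprintf("  final ELBO: %.4f\n", x$elbo_trace[length(x$elbo_trace)]))
  invisible(x)
}

#' Marginal covariance of one frame's state
#'
#' @param post An `mpp_posterior`.
#' @param r Frame index.
#' @return `d_kappa x d_kappa` covariance matrix.
#' @export
state_covariance <- function(post, r) {
  matrix(post$sigma_c[r, ], post$d_kappa, post$d_kappa)
}

# Normal--Wishart posterior expectations used in every update:
# E[Lambda_k] = nu_k S_k^-1, E[Lambda_k mu_k] = E[Lambda_k] m_k,
# E[log det Lambda_k].
nw_expectations <- function(post, which = seq_len(post$K)) {
  lapply(which, function(k) {
    S <- post$nw$S[[k]]
    EL <- post$nw$nu[k] * solve_spd(S, what = sprintf("S[%d]", k))
    list(EL = sym(EL),
         ELm = drop(EL %*% post$nw$m[k, ]),
         Eldet = e_logdet_wishart(post$nw$nu[k], S),
         m = post$nw$m[k, ], gamma = post$nw$gamma[k], nu = post$nw$nu[k])
  })
}

# Per-frame log weights of the spike indicator options (r = 2..R):
# column 0 is the no-spike option, one column per active component.
# Also returns the pieces reused by the ELBO.
qz_log_weights <- function(post, stim, nwx = NULL) {
  d <- post$d_kappa
  R <- post$R
  act <- which(post$active)
  Fm <- post$ss$F
  V <- post$ss$V
  d_mat <- post$mu_c[2:R, , drop = FALSE] -
    post$mu_c[1:(R - 1), , drop = FALSE] %*% t(Fm)
  quad0 <- drop(post$covdelta %*% as.numeric(V)) + row_quad(d_mat, V)
  logw0 <- 0.5 * logdet_spd(V, "V") - (d / 2) * log(2 * pi) - 0.5 * quad0
  Elogpi <- digamma(post$dir_alpha) - digamma(sum(post$dir_alpha))
  if (is.null(nwx)) nwx <- nw_expectations(post, act)
  logwk <- NULL
  if (length(act) > 0) {
    logwk <- matrix(-Inf, R - 1, length(act))
    xr <- if (stim$d_x == 1) stim$values[2:R] else stim$values[2:R, , drop = FALSE]
    for (i in seq_along(act)) {
      k <- act[i]
      e <- nwx[[i]]
      quad <- drop(post$covdelta %*% as.numeric(e$EL)) +
        row_quad(sweep(d_mat, 2, e$m), e$EL)
      logwk[, i] <- Elogpi[k] +
        beta_star(post$stim_params[[k]], stim, post$prior$beta0, log = TRUE) +
        0.5 * e$Eldet - (d / 2) * log(2 * pi) -
        0.5 * (d / e$gamma + quad) +
        dstim(xr, post$stim_params[[k]], log = TRUE) + log(stim$delta)
    }
  }
  list(logw0 = logw0, logwk = logwk, act = act, d_mat = d_mat, nwx = nwx,
       Elogpi = Elogpi)
}
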