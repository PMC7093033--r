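#' Fit the deconvolution model by coordinate-ascent variational inference
#'
#' Runs [vi_initialize()] followed by `n_iter` full update sweeps in fixed
#' order: states q(c), spike indicators q(z), mixture weights q(pi), mark
#' kernels q(u_kappa), stimulus kernels (empirical Bayes), then the
#' state-space hyperparameters. After each sweep, components whose expected
#' spike count falls below `prune_threshold` are deactivated (they keep their
#' prior values and stop contributing), which realizes the automatic model
#' selection of the weighted-gamma-process prior. The ELBO is recorded once
#' per sweep; stopping is iteration-count based.
#'
#' @param movie `R x d_y` frame matrix.
#' @param stim A [stimulus_series()].
#' @param prior A [prior_spec()] or `NULL` for the scale-matched default.
#' @param d_kappa Latent state dimension (default 40).
#' @param K Mixture truncation level (default 20).
#' @param n_iter Number of full sweeps (default 10); 0 returns the
#'   initialization unchanged.
#' @param seed Integer seed controlling every random element.
#' @param prune_threshold Expected-spike-count floor below which a component
#'   is deactivated after a sweep.
#' @param update_alpha0 Also maximize the Dirichlet concentration `alpha0`
#'   numerically each sweep? Off by default.
#' @param verbose Emit per-sweep ELBO and active-component counts?
#' @return An `mpp_posterior` with a populated `elbo_trace`.
#' @export
mpp_fit <- function(movie, stim, prior = NULL, d_kappa = 40, K = 20,
                    n_iter = 10, seed = 1L, prune_threshold = 0.5,
                    update_alpha0 = FALSE, verbose = FALSE) {
  post <- vi_initialize(movie, stim, prior = prior, d_kappa = d_kappa,
                        K = K, seed = seed)
  if (n_iter == 0) return(post)
  for (it in seq_len(n_iter)) {
    post <- tryCatch({
      p <- update_q_c(post, movie, stim)
      p <- update_q_z(p, stim)
      p <- update_q_pi(p)
      p <- update_q_u_kappa(p)
      p <- update_stim_params(p, stim)
      p <- update_state_space(p, movie)
      if (update_alpha0) p <- maximize_alpha0(p)
      p
    }, error = function(e)
      stop(sprintf("sweep %d: %s", it, conditionMessage(e)), call. = FALSE))
    # the trace records the ascent: ELBO after the coordinate updates,
    # before the discrete pruning move
    elbo <- compute_elbo(post, movie, stim)
    post$elbo_trace <- c(post$elbo_trace, elbo)
    post <- prune_components(post, prune_threshold)
    if (verbose)
      message(sprintf("sweep %2d: ELBO %.4f, active components %d",
                      it, elbo, sum(post$active)))
  }
  post
}

#' Deactivate components with negligible expected spike counts
#'
#' @param post An `mpp_posterior`.
#' @param threshold Expected-spike-count floor.
#' @return The posterior with updated `active`, responsibilities and factors.
#' @export
prune_components <- function(post, threshold = 0.5) {
  stopifnot(inherits(post, "mpp_posterior"))
  Nk <- colSums(post$zeta)
  drop <- post$active & (Nk < threshold)
  if (!any(drop)) return(post)
  pr <- post$prior
  for (k in which(drop)) {
    post$active[k] <- FALSE
    post$zeta[, k] <- 0
    post$nw$m[k, ] <- pr$m_kappa
    post$nw$gamma[k] <- pr$gamma_kappa
    post$nw$nu[k] <- pr$nu_kappa
    post$nw$S[[k]] <- pr$S_kappa
    post$dir_alpha[k] <- pr$alpha0 / post$K
  }
  post
}

# Optional 1-d empirical-Bayes maximization of the Dirichlet concentration.
maximize_alpha0 <- function(post) {
  Elogpi <- digamma(post$dir_alpha) - digamma(sum(post$dir_alpha))
  K <- post$K
  obj <- function(a0)
    lgamma(a0) - K * lgamma(a0 / K) + (a0 / K - 1) * sum(Elogpi)
  opt <- stats::optimize(obj, c(1e-3, 1e3), maximum = TRUE)
  if (obj(opt$maximum) > obj(post$prior$alpha0))
    post$prior$alpha0 <- opt$maximum
  post
}
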