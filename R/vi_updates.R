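#' Update the Gaussian state factor q(c)
#'
#' Exact coordinate-ascent update of the state chain: given the current spike
#' responsibilities and Normal--Wishart factors, the optimal q(c) is the
#' Gaussian whose block-tridiagonal precision mixes, at each transition, the
#' transition-noise precision `V` (with the no-spike probability) and the
#' expected mark precisions (with the responsibilities), plus the observation
#' information `G' W G` at every frame and the initial-state precision at
#' frame 1. Computed by one forward block-elimination pass and one backward
#' smoothing pass; returns updated marginal means, covariances and lag-one
#' cross covariances.
#'
#' @param post An `mpp_posterior`.
#' @param movie `R x d_y` frame matrix.
#' @param stim A [stimulus_series()] (unused by the linear algebra but kept
#'   for a uniform update signature).
#' @return The posterior with updated `mu_c`, `sigma_c`, `sigma_cross`,
#'   `covdelta` and `logdetJ`.
#' @export
update_q_c <- function(post, movie, stim = NULL) {
  stopifnot(inherits(post, "mpp_posterior"))
  d <- post$d_kappa
  R <- post$R
  assert_matrix(movie, nrow = R, name = "movie")
  ss <- post$ss
  act <- which(post$active)
  WG <- ss$W_diag * ss$G
  Phi <- sym(crossprod(ss$G, WG))
  Hobs <- movie %*% WG
  zet <- post$zeta[2:R, act, drop = FALSE]
  w0 <- pmax(1 - rowSums(zet), 0)
  P_stack <- outer(w0, as.numeric(ss$V))
  b_stack <- matrix(0, R - 1, d)
  if (length(act) > 0) {
    nwx <- nw_expectations(post, act)
    EL_stack <- vapply(nwx, function(e) as.numeric(e$EL), numeric(d * d))
    ELm_stack <- vapply(nwx, function(e) e$ELm, numeric(d))
    P_stack <- P_stack + zet %*% t(matrix(EL_stack, d * d))
    b_stack <- zet %*% t(matrix(ELm_stack, d))
  }
  Jinit <- solve_spd(ss$sigma_init, what = "sigma_init")
  sm <- bt_smoother_cpp(Jinit, drop(Jinit %*% ss$mu_init), Phi, Hobs,
                        ss$F, P_stack, b_stack)
  post$mu_c <- sm$mu
  post$sigma_c <- sm$sigma
  post$sigma_cross <- sm$cross
  post$covdelta <- sm$covdelta
  post$logdetJ <- sm$logdetJ
  post
}

#' Update the spike responsibilities q(z)
#'
#' For each frame r >= 2, the K + 1 options (no spike, or a spike of one
#' active component) receive unnormalized log weights: the no-spike option the
#' expected Gaussian transition log density, and component k the expected log
#' mark density of the innovation under its Normal--Wishart factor plus the
#' Dirichlet log-weight expectation, the `log beta*` rate correction, the
#' stimulus kernel log density and `log delta`. Expectations over q(c) use the
#' innovation means and covariances (which involve the lag-one cross
#' covariances). Rows are normalized by log-sum-exp.
#'
#' @param post An `mpp_posterior`.
#' @param stim A [stimulus_series()].
#' @return The posterior with an updated `zeta`.
#' @export
update_q_z <- function(post, stim) {
  stopifnot(inherits(post, "mpp_posterior"), inherits(stim, "stimulus_series"))
  lw <- qz_log_weights(post, stim)
  allw <- cbind(lw$logw0, lw$logwk)
  if (any(!is.finite(row_logsumexp(allw))))
    stop(sprintf("all spike-indicator weights are -Inf at frame %d",
                 which(!is.finite(row_logsumexp(allw)))[1] + 1L))
  norm <- row_logsumexp(allw)
  zeta <- matrix(0, post$R, post$K)
  if (length(lw$act) > 0)
    zeta[2:post$R, lw$act] <- exp(lw$logwk - norm)
  post$zeta <- zeta
  post
}

#' Update the mixture-weight factor q(pi)
#'
#' Conjugate Dirichlet update: `alpha_k = alpha0 / K + sum_r zeta_rk`
#' (inactive components keep the prior mass `alpha0 / K`).
#'
#' @param post An `mpp_posterior`.
#' @return The posterior with updated `dir_alpha`.
#' @export
update_q_pi <- function(post) {
  stopifnot(inherits(post, "mpp_posterior"))
  post$dir_alpha <- post$prior$alpha0 / post$K + colSums(post$zeta)
  post
}

#' Update the mark-kernel factors q(u_kappa)
#'
#' Conjugate Normal--Wishart update with soft pseudo-observations: component k
#' sees pseudo-count `N_k = sum_r zeta_rk` and the responsibility-weighted
#' first and second moments of the innovations `c_r - F c_{r-1}` under q(c)
#' (second moments include the innovation covariances). Components with no
#' expected spikes fall back to the prior.
#'
#' @param post An `mpp_posterior`.
#' @return The posterior with updated `nw` parameters.
#' @export
update_q_u_kappa <- function(post) {
  stopifnot(inherits(post, "mpp_posterior"))
  d <- post$d_kappa
  R <- post$R
  pr <- post$prior
  Fm <- post$ss$F
  d_mat <- post$mu_c[2:R, , drop = FALSE] -
    post$mu_c[1:(R - 1), , drop = FALSE] %*% t(Fm)
  for (k in seq_len(post$K)) {
    if (!post$active[k]) next
    zk <- post$zeta[2:R, k]
    Nk <- sum(zk)
    if (Nk < 1e-12) {
      post$nw$m[k, ] <- pr$m_kappa
      post$nw$gamma[k] <- pr$gamma_kappa
      post$nw$nu[k] <- pr$nu_kappa
      post$nw$S[[k]] <- pr$S_kappa
      next
    }
    sbar <- colSums(zk * d_mat) / Nk
    # sum_r zeta_rk E[delta_r delta_r'] = weighted innovation covariances
    # plus the weighted outer products of the innovation means
    Mk <- matrix(colSums(zk * post$covdelta), d, d) + crossprod(sqrt(zk) * d_mat)
    gam <- pr$gamma_kappa + Nk
    post$nw$m[k, ] <- (pr$gamma_kappa * pr$m_kappa + Nk * sbar) / gam
    post$nw$gamma[k] <- gam
    post$nw$nu[k] <- pr$nu_kappa + Nk
    dev0 <- sbar - pr$m_kappa
    S <- pr$S_kappa + (Mk - Nk * tcrossprod(sbar)) +
      (pr$gamma_kappa * Nk / gam) * tcrossprod(dev0)
    post$nw$S[[k]] <- sym(S)
  }
  post
}

# Empirical-Bayes objective for one component's stimulus kernel:
# Q_k(u) = N_k log beta*(u) + sum_r zeta_rk log f^x(x_r | u).
stim_objective <- function(kernel, stim, zk, xr, beta0) {
  Nk <- sum(zk)
  val <- Nk * beta_star(kernel, stim, beta0, log = TRUE) +
    sum(zk * dstim(xr, kernel, log = TRUE))
  if (!is.finite(val)) -1e300 else val
}

#' Update the stimulus kernels (empirical Bayes)
#'
#' For each active component, maximizes the responsibility-weighted objective
#' `N_k log beta*(u) + sum_r zeta_rk log f^x(x_r | u)` over the kernel
#' location and scale, by bounded quasi-Newton optimization from a
#' weighted-moment warm start (circular mean and a standard concentration
#' approximation for von Mises). The update never decreases the objective:
#' if the optimizer proposal is worse than the current kernel, the current
#' kernel is kept. Components whose expected spike count is below `floor`
#' are left unchanged (they are about to be pruned).
#'
#' @param post An `mpp_posterior`.
#' @param stim A [stimulus_series()].
#' @param floor Minimum expected spike count for an update.
#' @return The posterior with updated `stim_params`.
#' @export
update_stim_params <- function(post, stim, floor = 1e-6) {
  stopifnot(inherits(post, "mpp_posterior"), inherits(stim, "stimulus_series"))
  R <- post$R
  xr <- if (stim$d_x == 1) stim$values[2:R] else stim$values[2:R, , drop = FALSE]
  for (k in seq_len(post$K)) {
    if (!post$active[k]) next
    zk <- post$zeta[2:R, k]
    Nk <- sum(zk)
    if (Nk < floor) next
    cur <- post$stim_params[[k]]
    fam <- cur$family
    if (fam == "gaussian") {
      dx <- length(cur$mu)
      xm <- if (dx == 1) matrix(xr, ncol = 1) else xr
      wm <- colSums(zk * xm) / Nk
      wv <- sum(zk * rowSums(sweep(xm, 2, wm)^2)) / (Nk * dx)
      scale2 <- max(stats::var(as.numeric(stim$values)), 1e-12)
      start <- c(wm, log(1 / max(wv, 1e-3 * scale2)))
      rng <- range(stim$values)
      span <- max(rng[2] - rng[1], sqrt(scale2))
      lower <- c(rep(rng[1] - span, dx), log(1e-4 / scale2))
      upper <- c(rep(rng[2] + span, dx), log(1e8 / scale2))
      make <- function(par) stim_kernel("gaussian", par[seq_len(dx)],
                                        exp(par[dx + 1]))
    } else {
      Cbar <- sum(zk * cos(xr)) / Nk
      Sbar <- sum(zk * sin(xr)) / Nk
      mu0 <- atan2(Sbar, Cbar)
      Rbar <- min(sqrt(Cbar^2 + Sbar^2), 0.999)
      # standard two-regime approximation to the inverse of I1/I0
      tau0 <- if (Rbar < 0.53) 2 * Rbar + Rbar^3 + 5 * Rbar^5 / 6
              else if (Rbar < 0.85) -0.4 + 1.39 * Rbar + 0.43 / (1 - Rbar)
              else 1 / (Rbar^3 - 4 * Rbar^2 + 3 * Rbar)
      start <- c(mu0, log(max(tau0, 1e-3)))
      lower <- c(-2 * pi, log(1e-4))
      upper <- c(2 * pi, log(500))
      make <- function(par) stim_kernel("von_mises", wrap_angle(par[1]),
                                        exp(par[2]))
    }
    start <- pmin(pmax(start, lower), upper)
    neg_obj <- function(par)
      -stim_objective(make(par), stim, zk, xr, post$prior$beta0)
    opt <- tryCatch(
      stats::optim(start, neg_obj, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) NULL)
    cand <- list(cur, make(start))
    if (!is.null(opt)) cand <- c(cand, list(make(opt$par)))
    vals <- vapply(cand, stim_objective, numeric(1),
                   stim = stim, zk = zk, xr = xr, beta0 = post$prior$beta0)
    post$stim_params[[k]] <- cand[[which.max(vals)]]
  }
  post
}

#' Update the state-space hyperparameters (M-step)
#'
#' Maximizes the expected complete log joint over `(F, V, G, W, mu_init,
#' sigma_init)` given the current variational factors. `F` solves the exact
#' stationarity condition, a linear system in `vec(F)` that mixes the
#' no-spike transition precision `V` and each component's expected mark
#' precision through a Kronecker decomposition with K + 1 terms; `V` is the
#' no-spike-weighted expected innovation second moment (at the new `F`); `G`
#' and the diagonal `W` come from per-pixel least squares of the movie on the
#' expected states with second moments; the initial moments copy q(c_1).
#'
#' @param post An `mpp_posterior`.
#' @param movie `R x d_y` frame matrix.
#' @param ridge Relative ridge jitter for near-degenerate second-moment
#'   matrices.
#' @return The posterior with an updated `ss`.
#' @export
update_state_space <- function(post, movie, ridge = 1e-9) {
  stopifnot(inherits(post, "mpp_posterior"))
  d <- post$d_kappa
  R <- post$R
  assert_matrix(movie, nrow = R, name = "movie")
  ss <- post$ss
  act <- which(post$active)
  mu <- post$mu_c
  mu_prev <- mu[1:(R - 1), , drop = FALSE]
  mu_next <- mu[2:R, , drop = FALSE]
  sig_prev <- post$sigma_c[1:(R - 1), , drop = FALSE]
  sig_next <- post$sigma_c[2:R, , drop = FALSE]
  cross <- post$sigma_cross                      # vec(Cov(c_r, c_{r+1}))
  zet <- post$zeta[2:R, act, drop = FALSE]
  w0 <- pmax(1 - rowSums(zet), 0)

  wsum_mat <- function(w, stack) matrix(colSums(w * stack), d, d)
  nwx <- if (length(act) > 0) nw_expectations(post, act) else list()
  # aggregated weighted second moments per responsibility group: the no-spike
  # group (precision V, zero mean) and one group per active component
  # (precision E[Lambda_k], mean m_k)
  group_stats <- function(w) {
    list(A = sym(wsum_mat(w, sig_prev) + crossprod(sqrt(w) * mu_prev)),
         Snn = sym(wsum_mat(w, sig_next) + crossprod(sqrt(w) * mu_next)),
         C = t(wsum_mat(w, cross)) + crossprod(w * mu_next, mu_prev),
         mun = colSums(w * mu_next), mup = colSums(w * mu_prev), N = sum(w))
  }
  groups <- c(list(c(group_stats(w0), list(P = ss$V, m = rep(0, d)))),
              lapply(seq_along(act), function(i)
                c(group_stats(zet[, i]),
                  list(P = nwx[[i]]$EL, m = nwx[[i]]$m))))
  # F-dependent part of the expected complete log joint
  f_objective <- function(Fm) {
    sum(vapply(groups, function(g) {
      dv <- g$mun - drop(Fm %*% g$mup)
      E <- g$Snn - tcrossprod(g$C, Fm) - tcrossprod(Fm, g$C) +
        Fm %*% g$A %*% t(Fm) -
        tcrossprod(dv, g$m) - tcrossprod(g$m, dv) + g$N * tcrossprod(g$m)
      -0.5 * sum(g$P * E)
    }, numeric(1)))
  }
  Mbig <- Reduce(`+`, lapply(groups, function(g) kronecker(g$A, g$P)))
  RHS <- Reduce(`+`, lapply(groups, function(g)
    g$P %*% g$C - tcrossprod(drop(g$P %*% g$m), g$mup)))
  Mbig <- sym(Mbig) + diag(ridge * max(diag(Mbig), 1), d * d)
  Fnew <- matrix(solve(Mbig, as.numeric(RHS)), d, d)
  # guard: with near-singular second moments the ridge-regularized solve can
  # stray from the stationary point; keep the old F if it scores better
  if (f_objective(Fnew) < f_objective(ss$F)) Fnew <- ss$F

  # V: no-spike-weighted expected innovation scatter at the new F
  sw0 <- sum(w0)
  if (sw0 > 1e-8) {
    S2 <- wsum_mat(w0, sig_next) + Fnew %*% wsum_mat(w0, sig_prev) %*% t(Fnew) -
      t(wsum_mat(w0, cross)) %*% t(Fnew) - Fnew %*% wsum_mat(w0, cross)
    dm <- mu_next - mu_prev %*% t(Fnew)
    Vinv <- sym(S2 + crossprod(sqrt(w0) * dm)) / sw0
    Vinv <- Vinv + diag(ridge * max(diag(Vinv), 1), d)
    Vnew <- solve_spd(Vinv, what = "expected innovation scatter")
  } else {
    Vnew <- ss$V
  }

  # G, W: per-pixel weighted least squares on expected states
  S_all <- sym(matrix(colSums(post$sigma_c), d, d) + crossprod(mu))
  S_all_r <- S_all + diag(ridge * max(diag(S_all), 1), d)
  Gnew <- t(solve_spd(S_all_r, crossprod(mu, movie),
                      what = "state second moment"))
  S_cov <- sym(matrix(colSums(post$sigma_c), d, d))
  pixel_resid2 <- function(G) {
    colSums((movie - mu %*% t(G))^2) + row_quad(G, S_cov)
  }
  r2_new <- pixel_resid2(Gnew)
  r2_old <- pixel_resid2(ss$G)
  # guard as for F: keep the old G if the ridge solve scored worse
  if (sum(ss$W_diag * r2_new) > sum(ss$W_diag * r2_old)) {
    Gnew <- ss$G
    r2_new <- r2_old
  }
  Wnew <- 1 / pmax(r2_new / R, 1e-10 * mean(movie^2) + 1e-12)

  sigma1 <- sym(matrix(post$sigma_c[1, ], d, d))
  sigma1 <- sigma1 + diag(ridge * max(diag(sigma1), 1), d)
  post$ss <- state_space_params(Fnew, sym(Vnew), Gnew, Wnew,
                                mu[1, ], sigma1, check_stable = FALSE)
  # the stored innovation covariances depend on F; refresh them
  post$covdelta <- covdelta_cpp(Fnew, post$sigma_c, post$sigma_cross)
  post
}
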