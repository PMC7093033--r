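test_that("state update matches the dense joint-Gaussian oracle", {
  # R = 3, d = 1, d_y = 1, all responsibilities zero: plain tridiagonal chain
  set.seed(21)
  movie <- matrix(rnorm(3), 3, 1)
  stim <- stimulus_series(rnorm(3), delta = 0.1)
  post <- suppressWarnings(vi_initialize(movie, stim, d_kappa = 1, K = 1,
                                         seed = 1))
  post$zeta[] <- 0
  post <- update_q_c(post, movie, stim)
  or <- dense_chain_oracle(post, movie)
  expect_equal(post$mu_c, or$mu, tolerance = 1e-10)
  for (r in 1:3)
    expect_equal(state_covariance(post, r), or$sigma[[r]], tolerance = 1e-10)

  # random small instances with mixed responsibilities
  for (s in 1:5) {
    inst <- random_small_instance(400 + s)
    post <- inst$post
    post$zeta[2:post$R, seq_len(post$K)] <-
      matrix(runif((post$R - 1) * post$K, 0, 0.9 / post$K),
             post$R - 1, post$K)
    post <- update_q_c(post, inst$movie, inst$stim)
    or <- dense_chain_oracle(post, inst$movie)
    expect_equal(post$mu_c, or$mu, tolerance = 1e-8)
    for (r in seq_len(post$R))
      expect_equal(state_covariance(post, r), or$sigma[[r]], tolerance = 1e-8)
    for (r in seq_len(post$R - 1))
      expect_equal(matrix(post$sigma_cross[r, ], post$d_kappa, post$d_kappa),
                   or$cross[[r]], tolerance = 1e-8)
    expect_equal(post$logdetJ, or$logdetJ, tolerance = 1e-8)
  }
})

test_that("noiseless-observation limit pins the states to G^-1 y", {
  set.seed(22)
  d <- 2
  movie <- matrix(rnorm(10 * d), 10, d)
  stim <- stimulus_series(rnorm(10), delta = 0.1)
  post <- suppressWarnings(vi_initialize(movie, stim, d_kappa = d, K = 1,
                                         seed = 1))
  G <- matrix(c(1, 0.3, -0.2, 1), 2)
  post$ss <- state_space_params(diag(0.5, d), diag(1, d), G,
                                rep(1e10, d), rep(0, d), diag(1, d))
  post$zeta[] <- 0
  post <- update_q_c(post, movie, stim)
  expect_equal(post$mu_c, t(solve(G, t(movie))), tolerance = 1e-4)
})

test_that("responsibility rows are normalized and respect likelihood limits", {
  inst <- random_small_instance(31)
  post <- update_q_c(inst$post, inst$movie, inst$stim)
  post <- update_q_z(post, inst$stim)
  zet <- post$zeta[2:post$R, , drop = FALSE]
  expect_true(all(zet >= 0))
  expect_true(all(rowSums(zet) <= 1 + 1e-12))
  expect_equal(post$zeta[1, ], rep(0, post$K))

  # dominant-likelihood limit: innovation exactly at a component's mean with
  # a huge expected precision and tiny V forces zeta -> 1 for it
  d <- 2
  movie <- matrix(0, 6, d)
  stim <- stimulus_series(rep(0.1, 6), delta = 0.1)
  post <- suppressWarnings(vi_initialize(movie, stim, d_kappa = d, K = 1,
                                         seed = 1))
  mu_mark <- c(3, -2)
  post$mu_c <- matrix(0, 6, d)
  post$mu_c[4, ] <- mu_mark  # innovation at frame 4 equals mu_mark (F = 0.5I)
  post$mu_c[5, ] <- 0.5 * mu_mark
  post$ss$F <- diag(0.5, d)
  post$sigma_c[] <- rep(as.numeric(diag(1e-10, d)), each = 6)
  post$sigma_cross[] <- 0
  post$covdelta <- mppdeconv:::covdelta_cpp(post$ss$F, post$sigma_c,
                                            post$sigma_cross)
  post$ss$V <- diag(1e-4, d)  # tiny noise precision: noise can explain much
  post$nw$m[1, ] <- mu_mark
  post$nw$nu[1] <- 1e6
  post$nw$S[[1]] <- diag(1e2, d)  # E[Lambda] = 1e4 I, huge
  post$nw$gamma[1] <- 1e6
  post <- update_q_z(post, stim)
  expect_gt(post$zeta[4, 1], 1 - 1e-6)

  # symmetric components equidistant from the innovation split evenly
  post2 <- suppressWarnings(vi_initialize(movie, stim, d_kappa = d, K = 2,
                                          seed = 1))
  post2$mu_c <- matrix(0, 6, d)
  post2$mu_c[4, ] <- c(1, 0)
  post2$sigma_c[] <- rep(as.numeric(diag(1e-8, d)), each = 6)
  post2$sigma_cross[] <- 0
  post2$ss$F <- diag(0.5, d)
  post2$covdelta <- mppdeconv:::covdelta_cpp(post2$ss$F, post2$sigma_c,
                                             post2$sigma_cross)
  post2$nw$m[1, ] <- c(1, 1); post2$nw$m[2, ] <- c(1, -1)
  post2$nw$S[[1]] <- post2$nw$S[[2]] <- diag(post2$prior$nu_kappa, d)
  post2$nw$nu[1] <- post2$nw$nu[2] <- post2$prior$nu_kappa
  post2$nw$gamma[1] <- post2$nw$gamma[2] <- 1
  post2$dir_alpha <- c(2, 2)
  post2$stim_params[[2]] <- post2$stim_params[[1]]
  post2 <- update_q_z(post2, stim)
  expect_equal(post2$zeta[4, 1], post2$zeta[4, 2], tolerance = 1e-10)
})

test_that("Dirichlet update adds soft counts to the prior mass", {
  inst <- random_small_instance(41)
  post <- inst$post
  K <- post$K
  post$zeta[] <- 0
  post <- update_q_pi(post)
  expect_equal(post$dir_alpha, rep(post$prior$alpha0 / K, K))

  post$zeta[2, 1] <- 0.6
  post$zeta[3, 1] <- 0.4
  post$prior$alpha0 <- 1
  post <- update_q_pi(post)
  expect_equal(post$dir_alpha[1], 1 / K + 5 / 5)
  # conservation
  expect_equal(sum(post$dir_alpha), post$prior$alpha0 + sum(post$zeta))
})

test_that("mark-kernel update reduces to the conjugate posterior", {
  inst <- random_small_instance(51)
  post <- inst$post
  pr <- post$prior
  # no expected spikes: posterior equals the prior
  post$zeta[] <- 0
  post <- update_q_u_kappa(post)
  expect_equal(post$nw$m[1, ], pr$m_kappa)
  expect_equal(post$nw$gamma[1], pr$gamma_kappa)
  expect_equal(post$nw$nu[1], pr$nu_kappa)
  expect_equal(post$nw$S[[1]], pr$S_kappa)

  # hard assignments + point-mass q(c): textbook Normal--Wishart posterior
  # on the explicit innovation list
  d <- post$d_kappa
  R <- post$R
  post$sigma_c[] <- 0
  post$sigma_cross[] <- 0
  post$covdelta <- mppdeconv:::covdelta_cpp(post$ss$F, post$sigma_c,
                                            post$sigma_cross)
  hard <- seq(2, R, by = 2)
  post$zeta[] <- 0
  post$zeta[hard, 1] <- 1
  post <- update_q_u_kappa(post)
  innov <- post$mu_c[2:R, , drop = FALSE] -
    post$mu_c[1:(R - 1), , drop = FALSE] %*% t(post$ss$F)
  or <- nw_posterior_oracle(innov[hard - 1, , drop = FALSE],
                            pr$m_kappa, pr$gamma_kappa, pr$nu_kappa,
                            pr$S_kappa)
  expect_equal(post$nw$m[1, ], or$m, tolerance = 1e-10)
  expect_equal(post$nw$gamma[1], or$gamma)
  expect_equal(post$nw$nu[1], or$nu)
  expect_equal(post$nw$S[[1]], or$S, tolerance = 1e-10)
})

test_that("Normal--Wishart expectations match Monte-Carlo moments", {
  set.seed(61)
  d <- 3
  S <- crossprod(matrix(rnorm(d * d), d)) + diag(d)
  nu <- d + 6
  draws <- stats::rWishart(4000, df = nu, Sigma = solve(S))
  EL_mc <- apply(draws, c(1, 2), mean)
  expect_equal(EL_mc, nu * solve(S), tolerance = 0.1)
  ldet_mc <- mean(apply(draws, 3, function(L) determinant(L)$modulus))
  expect_equal(ldet_mc, mppdeconv:::e_logdet_wishart(nu, S), tolerance = 0.05)
})

test_that("stimulus-kernel update maximizes the weighted objective", {
  # responsibilities concentrated at one frame: location moves to that
  # stimulus value
  R <- 20
  x <- seq(-2, 2, length.out = R)
  stim <- stimulus_series(x, delta = 0.1)
  movie <- matrix(rnorm(R * 2), R, 2)
  post <- suppressWarnings(vi_initialize(movie, stim, d_kappa = 2, K = 1,
                                         seed = 1))
  post$zeta[] <- 0
  post$zeta[10, 1] <- 1
  post <- update_stim_params(post, stim)
  expect_equal(post$stim_params[[1]]$mu, x[10], tolerance = 0.05)

  # beta0 -> 0 flattens beta*: update approaches the weighted Gaussian MLE
  post2 <- suppressWarnings(vi_initialize(movie, stim, d_kappa = 2, K = 1,
                                          seed = 1))
  zk <- runif(R - 1)
  post2$zeta[] <- 0
  post2$zeta[2:R, 1] <- zk / sum(zk) * 3
  post2$prior$beta0 <- 1e-9
  post2 <- update_stim_params(post2, stim)
  w <- post2$zeta[2:R, 1]
  wm <- sum(w * x[2:R]) / sum(w)
  wv <- sum(w * (x[2:R] - wm)^2) / sum(w)
  expect_equal(post2$stim_params[[1]]$mu, wm, tolerance = 1e-3)
  expect_equal(post2$stim_params[[1]]$tau, 1 / wv, tolerance = 0.01)

  # the objective never decreases across the update
  for (s in 1:5) {
    inst <- random_small_instance(600 + s)
    post <- update_q_c(inst$post, inst$movie, inst$stim)
    post <- update_q_z(post, inst$stim)
    xr <- inst$stim$values[2:post$R]
    for (k in which(post$active & colSums(post$zeta) > 1e-6)) {
      before <- mppdeconv:::stim_objective(post$stim_params[[k]], inst$stim,
                                           post$zeta[2:post$R, k], xr,
                                           post$prior$beta0)
      p2 <- update_stim_params(post, inst$stim)
      after <- mppdeconv:::stim_objective(p2$stim_params[[k]], inst$stim,
                                          p2$zeta[2:p2$R, k], xr,
                                          p2$prior$beta0)
      expect_gte(after, before - 1e-10)
    }
  }
})

test_that("state-space M-step recovers noiseless dynamics and noise scales", {
  # exact q(c) on a noise-free chain with known F, all zeta = 0
  set.seed(71)
  d <- 2
  Ftrue <- matrix(c(0.7, 0.15, -0.1, 0.6), 2)
  R <- 60
  C <- matrix(0, R, d)
  C[1, ] <- c(2, -1)
  for (r in 2:R) C[r, ] <- drop(Ftrue %*% C[r - 1, ]) + rnorm(d, sd = 1e-6)
  movie <- C  # identity observation
  stim <- stimulus_series(rnorm(R), delta = 0.1)
  post <- suppressWarnings(vi_initialize(movie, stim, d_kappa = d, K = 1,
                                         seed = 1))
  post$zeta[] <- 0
  post$mu_c <- C
  post$sigma_c[] <- 0
  post$sigma_cross[] <- 0
  post$covdelta <- mppdeconv:::covdelta_cpp(post$ss$F, post$sigma_c,
                                            post$sigma_cross)
  post <- update_state_space(post, movie)
  expect_equal(post$ss$F, Ftrue, tolerance = 1e-4)

  # W recovers the inverse residual variance of known observation noise
  set.seed(72)
  v <- 0.04
  Gtrue <- t(cbind(diag(1, d), matrix(0.5, d, 1)))  # 3 pixels x 2 states
  noisy <- C %*% t(Gtrue) + matrix(rnorm(R * 3, sd = sqrt(v)), R, 3)
  post2 <- suppressWarnings(vi_initialize(noisy, stim, d_kappa = d, K = 1,
                                          seed = 1))
  post2$zeta[] <- 0
  post2$mu_c <- C
  post2$sigma_c[] <- 0
  post2$sigma_cross[] <- 0
  post2$ss$G <- Gtrue
  post2$ss$W_diag <- rep(1, 3)
  post2$covdelta <- mppdeconv:::covdelta_cpp(post2$ss$F, post2$sigma_c,
                                             post2$sigma_cross)
  post2 <- update_state_space(post2, noisy)
  expect_equal(mean(1 / post2$ss$W_diag), v, tolerance = 0.35)
})

test_that("ELBO is bounded above by the toy model evidence", {
  set.seed(81)
  for (rep in 1:3) {
    movie <- matrix(rnorm(2, sd = 1), 2, 1)
    stim <- stimulus_series(rnorm(2), delta = 0.2)
    post <- suppressWarnings(vi_initialize(movie, stim, d_kappa = 1, K = 1,
                                           seed = rep))
    # make the toy well-conditioned and fixed
    post$ss <- state_space_params(matrix(0.6), matrix(2), matrix(1.1),
                                  3, 0.2, matrix(0.8))
    post$prior <- prior_spec(1, 1, 1, 0.5, 0.5, 3, matrix(2))
    post$nw$m[1, ] <- 0.5; post$nw$gamma[1] <- 0.5
    post$nw$nu[1] <- 3; post$nw$S[[1]] <- matrix(2)
    log_evidence <- toy_log_evidence(post, movie, stim)
    for (sweep in 1:3) {
      post <- update_q_c(post, movie, stim)
      post <- update_q_z(post, stim)
      post <- update_q_pi(post)
      post <- update_q_u_kappa(post)
      elbo <- compute_elbo(post, movie, stim)
      expect_lt(elbo, log_evidence + 0.02)
    }
    # the converged bound is reasonably tight for this tiny model
    expect_gt(elbo, log_evidence - 2)
  }
})

test_that("every coordinate update is monotone in the ELBO", {
  for (s in 1:8) {
    inst <- random_small_instance(700 + s)
    post <- inst$post
    e <- compute_elbo(post, inst$movie, inst$stim)
    steps <- list(
      function(p) update_q_c(p, inst$movie, inst$stim),
      function(p) update_q_z(p, inst$stim),
      update_q_pi,
      update_q_u_kappa,
      function(p) update_stim_params(p, inst$stim),
      function(p) update_state_space(p, inst$movie))
    for (sw in 1:2) for (f in steps) {
      post <- f(post)
      enew <- compute_elbo(post, inst$movie, inst$stim)
      expect_gte(enew, e - 1e-8 * max(1, abs(e)))
      e <- enew
    }
  }
})

test_that("fitting is deterministic and returns the initialization at n_iter = 0", {
  sim <- tiny_scene(seed = 6)
  p0 <- mpp_fit(sim$movie, sim$stim, d_kappa = 10, K = 6, n_iter = 0, seed = 3)
  init <- vi_initialize(sim$movie, sim$stim, d_kappa = 10, K = 6, seed = 3)
  expect_identical(p0$mu_c, init$mu_c)
  expect_identical(p0$zeta, init$zeta)

  pa <- mpp_fit(sim$movie, sim$stim, d_kappa = 10, K = 6, n_iter = 3, seed = 3)
  pb <- mpp_fit(sim$movie, sim$stim, d_kappa = 10, K = 6, n_iter = 3, seed = 3)
  expect_identical(pa$mu_c, pb$mu_c)
  expect_identical(pa$zeta, pb$zeta)
  expect_identical(pa$elbo_trace, pb$elbo_trace)
  # the ELBO trace is recorded once per sweep and ends above its start
  expect_length(pa$elbo_trace, 3)
  expect_gt(pa$elbo_trace[3], pa$elbo_trace[1])
})

test_that("degenerate and deficient movies initialize gracefully", {
  stim <- stimulus_series(rnorm(8), delta = 0.1)
  zero <- matrix(0, 8, 5)
  expect_warning(post <- vi_initialize(zero, stim, d_kappa = 3, K = 2,
                                       seed = 1), "rank")
  expect_equal(post$mu_c, matrix(0, 8, 3))
  expect_equal(post$zeta, matrix(0, 8, 2))

  # rank-1 movie with d_kappa = 2
  rank1 <- outer(rnorm(8), c(1, 2, 3))
  expect_warning(post2 <- vi_initialize(rank1, stim, d_kappa = 3, K = 2,
                                        seed = 1), "rank")
  expect_equal(post2$d_kappa, 3)
})

test_that("initialization does not undersegment the reference scene", {
  # cluster count at init is at least the number of spiking ground-truth
  # components (over-segmentation is allowed and pruned later)
  for (s in 1:3) {
    sim <- tiny_scene(seed = 20 + s, n_neurons = 3, T_obs = 60)
    post <- vi_initialize(sim$movie, sim$stim, d_kappa = 10, K = 8,
                          seed = 20 + s)
    n_spiking <- sum(lengths(sim$truth$spikes_per_component) > 0)
    expect_gte(sum(colSums(post$zeta) > 0), n_spiking - 1)
  }
})
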