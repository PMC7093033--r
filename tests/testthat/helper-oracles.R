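# Independent oracles and shared fixtures, built in code at test time.

# Dense joint-Gaussian oracle for the state chain posterior: assembles the
# full R*d x R*d precision matrix and information vector directly from the
# model definition and inverts it. Independent of the C++ smoother.
dense_chain_oracle <- function(post, movie) {
  d <- post$d_kappa
  R <- post$R
  ss <- post$ss
  act <- which(post$active)
  nwx <- mppdeconv:::nw_expectations(post, act)
  zet <- post$zeta[2:R, act, drop = FALSE]
  w0 <- 1 - rowSums(zet)
  P <- lapply(seq_len(R - 1), function(r) {
    M <- w0[r] * ss$V
    for (j in seq_along(act)) M <- M + zet[r, j] * nwx[[j]]$EL
    M
  })
  b <- lapply(seq_len(R - 1), function(r) {
    v <- rep(0, d)
    for (j in seq_along(act)) v <- v + zet[r, j] * nwx[[j]]$ELm
    v
  })
  WG <- ss$W_diag * ss$G
  Phi <- crossprod(ss$G, WG)
  idx <- function(r) ((r - 1) * d + 1):(r * d)
  J <- matrix(0, R * d, R * d)
  h <- rep(0, R * d)
  Jinit <- solve(ss$sigma_init)
  for (r in seq_len(R)) {
    J[idx(r), idx(r)] <- J[idx(r), idx(r)] + Phi
    h[idx(r)] <- h[idx(r)] + crossprod(WG, movie[r, ])
  }
  J[idx(1), idx(1)] <- J[idx(1), idx(1)] + Jinit
  h[idx(1)] <- h[idx(1)] + Jinit %*% ss$mu_init
  for (r in 2:R) {
    J[idx(r), idx(r)] <- J[idx(r), idx(r)] + P[[r - 1]]
    J[idx(r - 1), idx(r - 1)] <- J[idx(r - 1), idx(r - 1)] +
      t(ss$F) %*% P[[r - 1]] %*% ss$F
    J[idx(r - 1), idx(r)] <- J[idx(r - 1), idx(r)] - t(ss$F) %*% P[[r - 1]]
    J[idx(r), idx(r - 1)] <- J[idx(r), idx(r - 1)] - P[[r - 1]] %*% ss$F
    h[idx(r)] <- h[idx(r)] + b[[r - 1]]
    h[idx(r - 1)] <- h[idx(r - 1)] - t(ss$F) %*% b[[r - 1]]
  }
  Sig <- solve(J)
  mu <- matrix(Sig %*% h, R, d, byrow = TRUE)
  list(mu = mu,
       sigma = lapply(seq_len(R), function(r)
         Sig[idx(r), idx(r), drop = FALSE]),
       cross = lapply(seq_len(R - 1), function(r)
         Sig[idx(r), idx(r + 1), drop = FALSE]),
       logdetJ = as.numeric(determinant(J)$modulus))
}

# Textbook Normal--Wishart posterior given an explicit sample matrix X
# (inverse-scale Wishart parameterization, E[Lambda] = nu * S^-1).
nw_posterior_oracle <- function(X, m0, gamma0, nu0, S0) {
  n <- nrow(X)
  xbar <- colMeans(X)
  scatter <- crossprod(sweep(X, 2, xbar))
  gamma_n <- gamma0 + n
  dev <- xbar - m0
  list(m = (gamma0 * m0 + n * xbar) / gamma_n,
       gamma = gamma_n,
       nu = nu0 + n,
       S = S0 + scatter + (gamma0 * n / gamma_n) * tcrossprod(dev))
}

# Small, fast simulation scene for unit tests.
tiny_scene <- function(seed = 1, n_neurons = 3, T_obs = 40, px = 14,
                       d_kappa = 10) {
  simulation_study(seed, sim_config(n_neurons = n_neurons, T_obs = T_obs,
                                    height = px, width = px,
                                    d_kappa = d_kappa))
}

# Random small, well-posed instance for update/ELBO property tests: a short
# noisy movie with a couple of genuine jump events so every factor is
# exercised away from degenerate corners.
random_small_instance <- function(seed) {
  set.seed(seed)
  R <- sample(6:10, 1)
  d <- sample(1:3, 1)
  dy <- d + sample(1:3, 1)
  K <- sample(1:3, 1)
  movie <- matrix(rnorm(R * dy, sd = 0.3), R, dy)
  jump_frames <- sample(2:R, min(2, R - 1))
  movie[jump_frames, ] <- movie[jump_frames, ] + rnorm(dy, sd = 2)
  stim <- stimulus_series(rnorm(R), delta = 0.2)
  post <- suppressWarnings(
    vi_initialize(movie, stim, d_kappa = d, K = K, seed = seed))
  list(post = post, movie = movie, stim = stim)
}

# Numeric-integration upper bound for the ELBO on a 2-frame, d = 1, d_y = 1,
# K = 1 toy: log of the integral of the augmented joint over (c, z, mu,
# lambda), with the Gaussian c-integral done in closed form and (mu, lambda)
# on a quadrature grid. pi is degenerate at 1 for K = 1.
toy_log_evidence <- function(post, movie, stim, n_mu = 201, n_lam = 201) {
  stopifnot(post$d_kappa == 1, post$R == 2, post$K == 1)
  ss <- post$ss
  pr <- post$prior
  y <- movie[, 1]
  Fv <- ss$F[1, 1]
  V <- ss$V[1, 1]
  W <- ss$W_diag[1]
  G <- ss$G[1, 1]
  Ji <- 1 / ss$sigma_init[1, 1]
  mi <- ss$mu_init[1]
  x2 <- if (stim$d_x == 1) stim$values[2] else stim$values[2, ]
  kern <- post$stim_params[[1]]
  lbs <- beta_star(kern, stim, pr$beta0, log = TRUE)
  lfx <- dstim(x2, kern, log = TRUE)

  # Gaussian c-integral for given transition precision P and offset o
  # (exponent: -(1/2) c' J c + h' c + const)
  c_integral <- function(P, o, extra_const) {
    J11 <- Ji + W * G^2 + Fv * P * Fv
    J22 <- W * G^2 + P
    J12 <- -Fv * P
    h1 <- Ji * mi + W * G * y[1] - Fv * o
    h2 <- W * G * y[2] + o
    detJ <- J11 * J22 - J12^2
    Sig11 <- J22 / detJ; Sig22 <- J11 / detJ; Sig12 <- -J12 / detJ
    quad <- 0.5 * (h1^2 * Sig11 + 2 * h1 * h2 * Sig12 + h2^2 * Sig22)
    base <- 0.5 * log(Ji) - 0.5 * log(2 * pi) +
      sum(0.5 * log(W) - 0.5 * log(2 * pi) - 0.5 * W * y^2) -
      0.5 * Ji * mi^2
    base + extra_const + quad + log(2 * pi) - 0.5 * log(detJ)
  }
  # z = 0: transition N(delta | 0, V)
  lz0 <- c_integral(V, 0, 0.5 * log(V) - 0.5 * log(2 * pi))
  # z = 1: spike factor beta* N(delta | mu, lambda) f^x delta, on a grid
  # over the Normal--Wishart prior for (mu, lambda)
  m0 <- pr$m_kappa[1]; g0 <- pr$gamma_kappa
  nu0 <- pr$nu_kappa; S0 <- pr$S_kappa[1, 1]
  # lambda ~ Gamma(shape nu0/2, rate S0/2)
  pl <- seq(1 / (2 * n_lam), 1 - 1 / (2 * n_lam), length.out = n_lam)
  lam <- qgamma(pl, shape = nu0 / 2, rate = S0 / 2)
  vals <- matrix(-Inf, n_lam, n_mu)
  for (i in seq_len(n_lam)) {
    sd_mu <- 1 / sqrt(g0 * lam[i])
    mus <- seq(m0 - 8 * sd_mu, m0 + 8 * sd_mu, length.out = n_mu)
    dmu <- mus[2] - mus[1]
    lw_mu <- dnorm(mus, m0, sd_mu, log = TRUE) + log(dmu)
    lz1 <- vapply(mus, function(mu)
      c_integral(lam[i], lam[i] * mu,
                 lbs + lfx + log(stim$delta) +
                   0.5 * log(lam[i]) - 0.5 * log(2 * pi) -
                   0.5 * lam[i] * mu^2),
      numeric(1))
    vals[i, ] <- lz1 + lw_mu - log(n_lam)
  }
  lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  lse(c(lz0, as.numeric(vals)))
}
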