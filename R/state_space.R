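#' Linear-Gaussian state-space parameters of the movie model
#'
#' The latent calcium state `c_r` (dimension `d_kappa`, much smaller than the
#' pixel count) follows a vector autoregression with jumps: at spike frames
#' the mark is added deterministically (`c_r = F c_{r-1} + kappa_r`); at
#' non-spike frames `c_r = F c_{r-1} + v_r` with `v_r` zero-mean Gaussian
#' noise of precision `V`. Each frame is observed as `y_r = G c_r + w_r` with
#' diagonal observation precision `W`. Following the precision convention used
#' throughout this package, the second parameter of every Gaussian here is a
#' precision matrix; `sigma_init` is the initial-state covariance (its inverse
#' is the precision that enters the model).
#'
#' @param F Transition matrix (`d_kappa x d_kappa`), spectral radius < 1.
#' @param V Transition noise precision (`d_kappa x d_kappa`, s.p.d.).
#' @param G Observation matrix (`d_y x d_kappa`).
#' @param W_diag Strictly positive observation precision diagonal (length
#'   `d_y`).
#' @param mu_init Initial state mean.
#' @param sigma_init Initial state covariance (s.p.d.).
#' @param check_stable Error if the spectral radius of `F` is >= 1?
#' @return An object of class `state_space_params`.
#' @export
state_space_params <- function(F, V, G, W_diag, mu_init, sigma_init,
                               check_stable = TRUE) {
  d <- nrow(as.matrix(F))
  F <- assert_matrix(as.matrix(F), d, d, "F")
  V <- assert_matrix(as.matrix(V), d, d, "V")
  G <- assert_matrix(as.matrix(G), ncol = d, name = "G")
  W_diag <- as.numeric(W_diag)
  if (length(W_diag) != nrow(G)) stop("'W_diag' must have one entry per pixel")
  if (any(!is.finite(W_diag)) || any(W_diag <= 0))
    stop("'W_diag' must be strictly positive")
  mu_init <- as.numeric(mu_init)
  if (length(mu_init) != d) stop("'mu_init' has the wrong length")
  sigma_init <- assert_matrix(as.matrix(sigma_init), d, d, "sigma_init")
  chol_spd(V, "V")
  chol_spd(sigma_init, "sigma_init")
  if (check_stable) {
    rho <- max(Mod(eigen(F, only.values = TRUE)$values))
    if (rho >= 1) stop(sprintf("spectral radius of F is %.3f (>= 1)", rho))
  }
  structure(list(F = F, V = sym(V), G = G, W_diag = W_diag,
                 mu_init = mu_init, sigma_init = sym(sigma_init),
                 d_kappa = d, d_y = nrow(G)),
            class = "state_space_params")
}

#' @export
print.state_space_params <- function(x, ...) {
  cat(sprintf("<state_space_params> d_kappa = %d, d_y = %d\n", x$d_kappa, x$d_y))
  invisible(x)
}

#' Prior specification for the mixture of weighted gamma processes
#'
#' Truncated (K-component) mixture-of-gamma-process prior on the intensity
#' mixing measure: concentration `alpha0`, weight scale `beta0`, and a
#' Normal--Wishart base measure over each component's mark kernel parameters
#' `(mu^kappa, Lambda^kappa)` with location `m_kappa`, scale factor
#' `gamma_kappa`, degrees of freedom `nu_kappa > d_kappa - 1` and scale matrix
#' `S_kappa` (the Wishart here is inverse-scale parameterized, so the prior
#' mean precision is `nu_kappa * solve(S_kappa)`).
#'
#' @param alpha0 Concentration (> 0).
#' @param beta0 Weight scale (> 0).
#' @param K Truncation level (>= 1).
#' @param m_kappa Normal--Wishart location vector (length `d_kappa`).
#' @param gamma_kappa Positive scalar strength of the location prior.
#' @param nu_kappa Degrees of freedom (> `d_kappa - 1`).
#' @param S_kappa Symmetric positive definite scale matrix.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(alpha0, beta0, K, m_kappa, gamma_kappa, nu_kappa, S_kappa) {
  if (!is.finite(alpha0) || alpha0 <= 0) stop("'alpha0' must be positive")
  if (!is.finite(beta0) || beta0 <= 0) stop("'beta0' must be positive")
  K <- as.integer(K)
  if (K < 1) stop("'K' must be at least 1")
  m_kappa <- as.numeric(m_kappa)
  d <- length(m_kappa)
  if (!is.finite(gamma_kappa) || gamma_kappa <= 0) stop("'gamma_kappa' must be positive")
  if (!is.finite(nu_kappa) || nu_kappa <= d - 1)
    stop("'nu_kappa' must exceed d_kappa - 1")
  S_kappa <- assert_matrix(as.matrix(S_kappa), d, d, "S_kappa")
  chol_spd(S_kappa, "S_kappa")
  structure(list(alpha0 = alpha0, beta0 = beta0, K = K, m_kappa = m_kappa,
                 gamma_kappa = gamma_kappa, nu_kappa = nu_kappa,
                 S_kappa = sym(S_kappa), d_kappa = d),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf(
    "<prior_spec> K = %d, alpha0 = %g, beta0 = %g, d_kappa = %d, nu = %g, gamma = %g\n",
    x$K, x$alpha0, x$beta0, x$d_kappa, x$nu_kappa, x$gamma_kappa))
  invisible(x)
}

#' Default prior, scale-matched to data at initialization
#'
#' Weakly informative defaults: `alpha0 = 1`, `beta0 = 1`, `m_kappa = 0`,
#' `gamma_kappa = 0.01`, `nu_kappa = d_kappa + 2`, and
#' `S_kappa = nu_kappa * Sigma_hat` where `Sigma_hat` is a data-driven scale
#' for the mark distribution (supplied by the initializer as the pooled
#' covariance of detected spike innovations), so the prior mean precision is
#' `solve(Sigma_hat)`.
#'
#' @param d_kappa Mark dimension.
#' @param K Truncation level.
#' @param sigma_hat Mark-scale matrix (defaults to the identity).
#' @param alpha0,beta0 Gamma-process scalars.
#' @return A [prior_spec()].
#' @export
default_prior <- function(d_kappa, K, sigma_hat = diag(d_kappa),
                          alpha0 = 1, beta0 = 1) {
  nu <- d_kappa + 2
  prior_spec(alpha0 = alpha0, beta0 = beta0, K = K,
             m_kappa = rep(0, d_kappa), gamma_kappa = 1e-2,
             nu_kappa = nu, S_kappa = nu * sym(as.matrix(sigma_hat)))
}
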