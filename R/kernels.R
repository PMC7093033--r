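#' Gaussian mark kernel parameters
#'
#' The mark attached to each spike is the vector of fluorescence injected into
#' the latent calcium state; its distribution for one neuron is multivariate
#' normal with mean `mu` (the mean fluorescent footprint in state space) and
#' precision matrix `lambda`.
#'
#' @param mu Numeric mean vector of length `d_kappa`.
#' @param lambda Symmetric positive definite precision matrix
#'   (`d_kappa x d_kappa`).
#' @return An object of class `mark_kernel`.
#' @export
mark_kernel <- function(mu, lambda) {
  mu <- as.numeric(mu)
  if (is.null(dim(lambda))) lambda <- diag(as.numeric(lambda), length(mu))
  assert_matrix(lambda, length(mu), length(mu), "lambda")
  if (max(abs(lambda - t(lambda))) > 1e-8 * max(1, max(abs(lambda))))
    stop("mark precision matrix must be symmetric")
  chol_spd(lambda, "mark precision matrix")
  structure(list(mu = mu, lambda = sym(lambda)), class = "mark_kernel")
}

#' Stimulus kernel parameters
#'
#' The normalized tuning curve of one neuron: a probability density over the
#' stimulus space. Two families are supported: `"gaussian"` on the real line
#' (with `tau` the precision) and `"von_mises"` on the circle (with `tau` the
#' concentration). Both integrate to one over their domain.
#'
#' @param family `"gaussian"` or `"von_mises"`.
#' @param mu Location: mean for Gaussian, centre angle in `(-pi, pi]` for
#'   von Mises.
#' @param tau Positive scale parameter: precision (Gaussian) or concentration
#'   (von Mises).
#' @return An object of class `stim_kernel`.
#' @export
stim_kernel <- function(family = c("gaussian", "von_mises"), mu, tau) {
  family <- match.arg(family)
  mu <- as.numeric(mu)
  tau <- as.numeric(tau)
  if (length(tau) != 1 || !is.finite(tau) || tau <= 0)
    stop("'tau' must be a single positive number")
  if (family == "von_mises") {
    if (length(mu) != 1) stop("von Mises kernels require a scalar angle")
    mu <- wrap_angle(mu)
  }
  structure(list(family = family, mu = mu, tau = tau), class = "stim_kernel")
}

#' Evaluate the Gaussian mark density
#'
#' Density of a mark under the precision-parameterized multivariate normal
#' `N(kappa | mu, Lambda)`. Computation is carried out in log space; with mark
#' dimensions around 40 the linear-space density underflows routinely.
#'
#' @param kappa Numeric vector (one mark) or a matrix with one mark per row.
#' @param kernel A [mark_kernel()].
#' @param log Return the log density?
#' @return Density value(s), one per mark.
#' @export
dmark <- function(kappa, kernel, log = FALSE) {
  stopifnot(inherits(kernel, "mark_kernel"))
  if (is.null(dim(kappa))) kappa <- matrix(kappa, nrow = 1)
  d <- length(kernel$mu)
  assert_matrix(kappa, ncol = d, name = "kappa")
  dev <- sweep(kappa, 2, kernel$mu)
  ld <- logdet_spd(kernel$lambda, "mark precision matrix")
  out <- 0.5 * ld - (d / 2) * log(2 * pi) - 0.5 * row_quad(dev, kernel$lambda)
  if (log) out else exp(out)
}

#' Evaluate the stimulus kernel density
#'
#' Gaussian: `N(x | mu, tau)` with `tau` a precision. Von Mises:
#' `VM(x | mu, tau)` with `tau` a concentration; as `tau -> 0` this tends to
#' the uniform density `1/(2*pi)`. The von Mises normalization uses the
#' exponentially scaled Bessel function so that large concentrations do not
#' overflow.
#'
#' @param x Numeric vector of stimulus values (angles in radians for
#'   von Mises).
#' @param kernel A [stim_kernel()].
#' @param log Return the log density?
#' @return Density value(s).
#' @export
dstim <- function(x, kernel, log = FALSE) {
  stopifnot(inherits(kernel, "stim_kernel"))
  dx <- length(kernel$mu)
  if (dx > 1) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    assert_matrix(x, ncol = dx, name = "x")
  } else {
    x <- as.numeric(x)
  }
  out <- switch(kernel$family,
    gaussian = if (dx == 1) {
      stats::dnorm(x, kernel$mu, sd = 1 / sqrt(kernel$tau), log = TRUE)
    } else {
      # isotropic: product of univariate normals with shared precision tau
      dev <- sweep(x, 2, kernel$mu)
      (dx / 2) * (log(kernel$tau) - log(2 * pi)) - 0.5 * kernel$tau * rowSums(dev^2)
    },
    von_mises = {
      tau <- kernel$tau
      # log I0(tau) = log(besselI(tau, 0, scaled)) + tau
      log_i0 <- log(besselI(tau, 0, expon.scaled = TRUE)) + tau
      tau * cos(x - kernel$mu) - log(2 * pi) - log_i0
    })
  if (log) out else exp(out)
}

#' Rate-correction factor of the posterior mixing measure
#'
#' For a stimulus kernel with parameter `theta^x`, the gamma-process posterior
#' rescales component weights by
#' `beta*(theta^x) = beta0 / (1 + beta0 * T * int f^x(x | theta^x) eta(dx))`,
#' where `eta` is the empirical measure of the observed stimulus path,
#' approximated by the uniform-weight sum over the sampled frames. `beta*`
#' always lies in `(0, beta0]` and decreases as the kernel overlaps the
#' occupied stimulus region more.
#'
#' @param kernel A [stim_kernel()].
#' @param stim A [stimulus_series()].
#' @param beta0 Positive prior scale of the weighted gamma process.
#' @param log Return `log beta*`?
#' @return Scalar `beta*` (or its log).
#' @export
beta_star <- function(kernel, stim, beta0, log = FALSE) {
  stopifnot(inherits(stim, "stimulus_series"))
  if (!is.finite(beta0) || beta0 <= 0) stop("'beta0' must be positive")
  if (stim$R < 1) stop("empty stimulus series")
  I <- mean(dstim(stim$values, kernel))
  out <- log(beta0) - log1p(beta0 * stim$T * I)
  if (log) out else exp(out)
}
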