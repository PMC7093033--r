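# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
sym <- function(M) (M + t(M)) / 2

#' Run code under a given RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible 31-bit sub-seed from a base seed and a stream label.
#' @noRd
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 69069 + h * 1013) %% 2147483629L + 1)
}

#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Row-wise log-sum-exp of a matrix.
#' @noRd
row_logsumexp <- function(X) {
  m <- do.call(pmax, c(as.data.frame(X), list(-Inf)))
  m + log(rowSums(exp(X - m)))
}

#' Cholesky with symmetrization and an informative error.
#' @noRd
chol_spd <- function(M, what = "matrix") {
  out <- tryCatch(chol(sym(M)), error = function(e) NULL)
  if (is.null(out)) stop(sprintf("%s is not positive definite", what), call. = FALSE)
  out
}

#' Solve A x = b for symmetric positive definite A.
#' @noRd
solve_spd <- function(A, b = NULL, what = "matrix") {
  R <- chol_spd(A, what)
  if (is.null(b)) chol2inv(R) else backsolve(R, forwardsolve(t(R), b))
}

#' log-determinant of a symmetric positive definite matrix.
#' @noRd
logdet_spd <- function(M, what = "matrix") 2 * sum(log(diag(chol_spd(M, what))))

#' Multivariate log-gamma.
#' @noRd
lmvgamma <- function(a, d) {
  (d * (d - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}

#' E of log det Lambda under Wishart(nu, S^-1) (inverse-scale parameterization,
#' so E(Lambda) = nu * S^-1).
#' @noRd
e_logdet_wishart <- function(nu, S) {
  d <- nrow(S)
  sum(digamma((nu + 1 - seq_len(d)) / 2)) + d * log(2) - logdet_spd(S, "Wishart scale")
}

#' Stack of per-row outer products: row r of the result is vec(x_r x_r^T).
#' @noRd
row_outer_stack <- function(X) {
  d <- ncol(X)
  idx <- expand.grid(i = seq_len(d), j = seq_len(d))
  X[, idx$i, drop = FALSE] * X[, idx$j, drop = FALSE]
}

#' Row-wise quadratic form x_r^T A x_r.
#' @noRd
row_quad <- function(X, A) rowSums((X %*% A) * X)

#' Check for a numeric matrix of given dimensions.
#' @noRd
assert_matrix <- function(M, nrow = NULL, ncol = NULL, name = "matrix") {
  if (!is.matrix(M) || !is.numeric(M))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (!is.null(nrow) && nrow(M) != nrow)
    stop(sprintf("'%s' must have %d rows", name, nrow), call. = FALSE)
  if (!is.null(ncol) && ncol(M) != ncol)
    stop(sprintf("'%s' must have %d columns", name, ncol), call. = FALSE)
  invisible(M)
}

#' Wrap angles into (-pi, pi].
#' @noRd
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}
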