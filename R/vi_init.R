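#' Initialize the variational posterior from the raw movie
#'
#' Deterministic (given `seed`) data-driven starting point for the coordinate
#' ascent. The scheme: (1) a rank-`d_kappa` truncated SVD of the movie matrix
#' provides the observation matrix and the initial state trajectory; (2) the
#' calcium decay factor is the median lag-one autocorrelation of the leading
#' temporal components, clipped into (0, 1), giving `F = rho I`; (3)
#' transition and observation precisions come from residual moments; (4)
#' spike-candidate frames are innovation-norm outliers (robust z-score), and
#' their innovation vectors are grouped into model-based clusters (count selected
#' by BIC, capped at `K`) that
#' seed the responsibilities and, through hard-assignment conjugate updates,
#' the Normal--Wishart factors; (5) stimulus kernel locations are spread over
#' the observed stimulus range. When no prior is supplied, [default_prior()]
#' is scale-matched to the pooled covariance of the detected spike
#' innovations.
#'
#' @param movie `R x d_y` frame matrix (R >= 2).
#' @param stim A [stimulus_series()] with matching frame count.
#' @param prior A [prior_spec()], or `NULL` to build the scale-matched
#'   default.
#' @param d_kappa Latent state dimension.
#' @param K Mixture truncation level.
#' @param seed Integer seed for the clustering sub-stream.
#' @param outlier_z Robust z-score above which an innovation is a spike
#'   candidate.
#' @return An `mpp_posterior`.
#' @export
vi_initialize <- function(movie, stim, prior = NULL, d_kappa = 40, K = 20,
                          seed = 1L, outlier_z = 5) {
  assert_matrix(movie, name = "movie")
  stopifnot(inherits(stim, "stimulus_series"))
  R <- nrow(movie)
  dy <- ncol(movie)
  if (R < 2) stop("the movie needs at least two frames")
  if (stim$R != R) stop("'movie' and 'stim' disagree on the frame count")
  d <- min(d_kappa, R, dy)

  # truncated SVD via the smaller Gram matrix
  small_side <- if (R <= dy) "frames" else "pixels"
  if (small_side == "frames") {
    eg <- eigen(tcrossprod(movie) / dy, symmetric = TRUE)
  } else {
    eg <- eigen(crossprod(movie) / R, symmetric = TRUE)
  }
  ev <- pmax(eg$values[seq_len(d)], 0)
  tol <- max(ev, 0) * 1e-12
  rank <- sum(ev > tol)
  if (rank < d)
    warning(sprintf("movie has numerical rank %d < d_kappa = %d; %s",
                    rank, d, "deficient state directions start at zero"))
  if (small_side == "frames") {
    U <- eg$vectors[, seq_len(d), drop = FALSE]
    sv <- sqrt(ev * dy)
    mu_c <- U * rep(sv, each = R)
    G <- crossprod(movie, U)
    G[, sv > 0] <- sweep(G[, sv > 0, drop = FALSE], 2, sv[sv > 0], "/")
  } else {
    G <- eg$vectors[, seq_len(d), drop = FALSE]
    mu_c <- movie %*% G
    sv <- sqrt(ev * R)
  }
  if (rank < d) {
    # orthonormal-ish placeholder columns for deficient directions
    idx <- which(ev <= tol)
    G[, idx] <- 0
    G[cbind(((idx - 1) %% dy) + 1, idx)] <- 1
    mu_c[, idx] <- 0
  }

  # decay factor from leading temporal components
  n_top <- max(2L, ceiling(d / 4))
  acs <- vapply(seq_len(min(n_top, d)), function(j) {
    v <- mu_c[, j]
    if (stats::sd(v) < 1e-12) return(NA_real_)
    stats::cor(v[-1], v[-R])
  }, numeric(1))
  rho <- stats::median(acs, na.rm = TRUE)
  if (!is.finite(rho)) rho <- 0.8
  rho <- min(max(rho, 0.05), 0.995)
  Fm <- diag(rho, d)

  innov <- mu_c[2:R, , drop = FALSE] - rho * mu_c[1:(R - 1), , drop = FALSE]
  s <- rowSums(innov^2)
  med <- stats::median(s)
  madv <- stats::mad(s)
  flagged <- if (madv > 0) which((s - med) / madv > outlier_z) else integer(0)

  # responsibilities and mark clusters; the cluster count is selected by BIC
  # (capped at K) so that neurons are not split across seed components
  zeta <- matrix(0, R, K)
  counts <- numeric(K)
  if (length(flagged) > 0) {
    cl <- with_seed(derive_seed(seed, "init_cluster"),
                    cluster_innovations(innov[flagged, , drop = FALSE], K))
    zeta[cbind(flagged + 1L, cl)] <- 0.9
    counts <- tabulate(cl, nbins = K)
  }

  # prior, scale-matched to the within-cluster spike-innovation covariance
  # (the mark noise scale, not the between-neuron spread)
  if (is.null(prior)) {
    pooled <- NULL
    if (length(flagged) >= 2) {
      Xf <- innov[flagged, , drop = FALSE]
      means <- rowsum(Xf, cl) / as.numeric(table(cl))
      centred <- Xf - means[as.character(cl), , drop = FALSE]
      df <- length(flagged) - length(unique(cl))
      if (df >= 1) pooled <- crossprod(centred) / df
    }
    if (is.null(pooled)) pooled <- stats::cov(innov)
    scale0 <- mean(diag(pooled))
    if (!is.finite(scale0) || scale0 <= 0) scale0 <- 1
    pooled <- sym(pooled) + diag(1e-4 * scale0 + 1e-12, d)
    prior <- default_prior(d, K, sigma_hat = pooled)
  } else {
    if (prior$d_kappa != d) stop("'prior' has the wrong mark dimension")
    if (prior$K != K) stop("'prior' has the wrong truncation level")
  }

  # Normal--Wishart factors: hard-assignment conjugate posteriors per cluster
  nw <- list(m = matrix(rep(prior$m_kappa, each = K), K, d),
             gamma = rep(prior$gamma_kappa, K),
             nu = rep(prior$nu_kappa, K),
             S = rep(list(prior$S_kappa), K))
  if (length(flagged) > 0) {
    for (k in which(counts > 0)) {
      rows <- innov[flagged[cl == k], , drop = FALSE]
      Nk <- nrow(rows)
      xb <- colMeans(rows)
      gam <- prior$gamma_kappa + Nk
      nw$m[k, ] <- (prior$gamma_kappa * prior$m_kappa + Nk * xb) / gam
      nw$gamma[k] <- gam
      nw$nu[k] <- prior$nu_kappa + Nk
      scatter <- crossprod(sweep(rows, 2, xb))
      dev0 <- xb - prior$m_kappa
      nw$S[[k]] <- sym(prior$S_kappa + scatter +
                         (prior$gamma_kappa * Nk / gam) * tcrossprod(dev0))
    }
  }

  # stimulus kernels spread over the observed range
  stim_params <- lapply(seq_len(K), function(k) {
    if (stim$circular) {
      stim_kernel("von_mises", -pi + 2 * pi * (k - 0.5) / K, 2)
    } else if (stim$d_x == 1) {
      q <- stats::quantile(stim$values, (k - 0.5) / K, names = FALSE)
      spread <- max(diff(range(stim$values)), 1e-6)
      stim_kernel("gaussian", q, (8 / spread)^2)
    } else {
      qv <- apply(stim$values, 2, stats::quantile, probs = (k - 0.5) / K)
      spread <- max(apply(stim$values, 2, function(v) diff(range(v))), 1e-6)
      stim_kernel("gaussian", qv, (8 / spread)^2)
    }
  })

  # residual observation precision
  resid <- movie - mu_c %*% t(G)
  # variance floor relative to the movie power guards overfitted pixels
  wfloor <- 1e-10 * mean(movie^2) + 1e-12
  W_diag <- 1 / pmax(colMeans(resid^2), wfloor)

  # transition precision from non-candidate innovations
  quiet <- setdiff(seq_len(R - 1), flagged)
  Vcov <- if (length(quiet) >= 2) stats::cov(innov[quiet, , drop = FALSE])
          else diag(1, d)
  vscale <- mean(diag(Vcov))
  if (!is.finite(vscale) || vscale <= 0) vscale <- 1
  V <- solve_spd(sym(Vcov) + diag(1e-4 * vscale + 1e-12, d),
                 what = "innovation covariance")

  vbar <- mean(apply(mu_c, 2, stats::var))
  if (!is.finite(vbar) || vbar <= 0) vbar <- 1
  ss <- state_space_params(Fm, V, G, W_diag, mu_c[1, ], diag(vbar, d),
                           check_stable = FALSE)

  eps <- 1e-6 * max(vbar, 1e-6)
  sigma_c <- matrix(rep(as.numeric(diag(eps, d)), each = R), R, d * d)
  sigma_cross <- matrix(0, R - 1, d * d)
  covdelta <- covdelta_cpp(Fm, sigma_c, sigma_cross)
  post <- new_mpp_posterior(
    mu_c = mu_c, sigma_c = sigma_c, sigma_cross = sigma_cross,
    covdelta = covdelta, logdetJ = -R * d * log(eps),
    zeta = zeta, dir_alpha = prior$alpha0 / K + colSums(zeta),
    nw = nw, stim_params = stim_params, ss = ss, prior = prior,
    active = rep(TRUE, K), seed = seed)
  post
}

# Group spike-candidate innovation vectors into clusters, selecting the
# cluster count by BIC over spherical Gaussian mixtures (capped at k_max).
# The vectors are first projected onto their leading principal components
# (mark means span a low-dimensional subspace while the estimation noise is
# broad-band, so the projection sharpens the cluster separation). Falls back
# to a deterministic hierarchical cut if model-based clustering fails.
cluster_innovations <- function(X, k_max) {
  n <- nrow(X)
  if (n == 1) return(1L)
  pc <- stats::prcomp(X)
  ev <- pc$sdev^2
  keep <- ev > max(5 * stats::median(ev), 0.02 * ev[1])
  m <- min(max(sum(keep), 1), n - 1, ncol(X))
  Xp <- pc$x[, seq_len(m), drop = FALSE]
  g_max <- min(k_max, n - 1)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the calling frame
  fit <- tryCatch(
    suppressWarnings(
      mclust::Mclust(Xp, G = seq_len(g_max), modelNames = c("EII", "VII"),
                     verbose = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit) && !is.null(fit$classification))
    return(as.integer(fit$classification))
  # deterministic fallback: complete-linkage tree cut at k_max groups
  as.integer(stats::cutree(stats::hclust(stats::dist(Xp)),
                           k = min(k_max, n)))
}
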