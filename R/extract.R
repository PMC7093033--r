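#' Extract 0-1 spike trains from the posterior
#'
#' Frame r carries a spike of component k iff `zeta_rk` exceeds `threshold`
#' and k is the responsibility argmax at that frame, so at most one spike is
#' assigned per frame.
#'
#' @param post An `mpp_posterior`.
#' @param threshold Responsibility threshold in (0, 1); default 0.5.
#' @return Named list (one element per active component, names `"k<index>"`)
#'   of integer frame vectors.
#' @export
extract_spikes <- function(post, threshold = 0.5) {
  stopifnot(inherits(post, "mpp_posterior"))
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")
  act <- which(post$active)
  out <- stats::setNames(vector("list", length(act)), paste0("k", act))
  if (length(act) == 0) return(out)
  z <- post$zeta[, act, drop = FALSE]
  winner <- max.col(z, ties.method = "first")
  best <- z[cbind(seq_len(nrow(z)), winner)]
  hit <- which(best > threshold)
  for (i in seq_along(act))
    out[[i]] <- hit[winner[hit] == i]
  out
}

#' Extract footprints and binary ROI masks
#'
#' The footprint of component k is `G m_k`, the observation-mapped posterior
#' mean mark. The ROI mask keeps pixels whose (negatives-clipped) footprint
#' value exceeds `mask_quantile` times its own maximum.
#'
#' @param post An `mpp_posterior`.
#' @param mask_quantile Fraction of the per-component maximum used as the
#'   binarization level (default 0.7).
#' @return List with `footprints` (d_y x n_active matrix) and `masks`
#'   (logical d_y x n_active matrix); empty masks are flagged with a warning.
#' @export
extract_footprints <- function(post, mask_quantile = 0.7) {
  stopifnot(inherits(post, "mpp_posterior"))
  act <- which(post$active)
  G <- post$ss$G
  fp <- G %*% t(post$nw$m[act, , drop = FALSE])
  colnames(fp) <- paste0("k", act)
  masks <- apply(fp, 2, function(v) {
    v <- pmax(v, 0)
    if (max(v) <= 0) return(rep(FALSE, length(v)))
    v > mask_quantile * max(v)
  })
  masks <- matrix(as.logical(masks), nrow(fp), ncol(fp),
                  dimnames = dimnames(fp))
  if (ncol(masks) > 0 && any(colSums(masks) == 0))
    warning("some components have an all-nonpositive footprint (empty ROI)")
  list(footprints = fp, masks = masks)
}

#' Extract per-component rates and tuning curves
#'
#' The posterior atom weight of component k is
#' `lambda_k = beta*(u_k^x) * (alpha0 / K + sum_r zeta_rk)`; the tuning curve
#' at stimulus x is `lambda_k * f_x(x | u_k^x)`.
#'
#' @param post An `mpp_posterior`.
#' @param stim A [stimulus_series()].
#' @return List with `rates` (named vector, spikes/s) and `kernels` (list of
#'   [stim_kernel()] objects), one entry per active component.
#' @export
extract_tuning <- function(post, stim) {
  stopifnot(inherits(post, "mpp_posterior"), inherits(stim, "stimulus_series"))
  act <- which(post$active)
  rates <- vapply(act, function(k) {
    bs <- beta_star(post$stim_params[[k]], stim, post$prior$beta0)
    bs * (post$prior$alpha0 / post$K + sum(post$zeta[, k]))
  }, numeric(1))
  names(rates) <- paste0("k", act)
  list(rates = rates,
       kernels = stats::setNames(post$stim_params[act], paste0("k", act)))
}

#' Denoised movie
#'
#' The variational expectation of each frame, `G mu_r^c`.
#'
#' @param post An `mpp_posterior`.
#' @return `R x d_y` matrix.
#' @export
denoise_movie <- function(post) {
  stopifnot(inherits(post, "mpp_posterior"))
  post$mu_c %*% t(post$ss$G)
}

#' Full deconvolution result
#'
#' Bundles the variational expectations of the hidden variables into the
#' deliverables: 0-1 spike trains, footprints and ROI masks, rates, tuning
#' kernels and the denoised movie.
#'
#' @param post An `mpp_posterior`.
#' @param stim A [stimulus_series()].
#' @param threshold Spike responsibility threshold.
#' @param mask_quantile ROI binarization level.
#' @param denoised Include the denoised movie (can be large)?
#' @return An object of class `mpp_deconvolution`.
#' @export
deconvolve <- function(post, stim, threshold = 0.5, mask_quantile = 0.7,
                       denoised = FALSE) {
  fp <- extract_footprints(post, mask_quantile)
  tun <- extract_tuning(post, stim)
  structure(list(
    spikes = extract_spikes(post, threshold),
    footprints = fp$footprints,
    roi_masks = fp$masks,
    rates = tun$rates,
    tuning = tun$kernels,
    denoised = if (denoised) denoise_movie(post) else NULL,
    component_ids = which(post$active)),
    class = "mpp_deconvolution")
}

#' @export
print.mpp_deconvolution <- function(x, ...) {
  cat(sprintf("<mpp_deconvolution> %d components, %d spikes total\n",
              length(x$component_ids), sum(lengths(x$spikes))))
  invisible(x)
}
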