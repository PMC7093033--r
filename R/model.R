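#' Marked spike sequence
#'
#' A sparse record of the hidden jump sequence: the frames at which spikes
#' occurred (each frame bin holds at most one spike, and frame 1 never carries
#' one because jumps enter the state recursion from frame 2) together with the
#' mark vector of each spike.
#'
#' @param frames Integer vector of event frames, strictly increasing, each in
#'   `2..R`.
#' @param marks Numeric matrix with one mark per row (`length(frames) x
#'   d_kappa`); may have zero rows for an empty sequence.
#' @param R Total number of frames.
#' @param d_kappa Mark dimension (required when `frames` is empty).
#' @return An object of class `marked_spikes`.
#' @export
marked_spikes <- function(frames, marks, R, d_kappa = NULL) {
  frames <- as.integer(frames)
  if (is.null(dim(marks))) marks <- matrix(marks, nrow = length(frames))
  if (length(frames) == 0 && is.null(d_kappa) && ncol(marks) == 0)
    stop("'d_kappa' is required for an empty sequence")
  d_kappa <- d_kappa %||% ncol(marks)
  assert_matrix(marks, nrow = length(frames), ncol = d_kappa, name = "marks")
  if (length(frames) > 0) {
    if (any(frames < 2L) || any(frames > R))
      stop("event frames must lie in 2..R")
    if (any(diff(frames) <= 0))
      stop("event frames must be strictly increasing (at most one per frame)")
  }
  structure(list(frames = frames, marks = marks, R = as.integer(R),
                 d_kappa = as.integer(d_kappa)),
            class = "marked_spikes")
}

#' @export
print.marked_spikes <- function(x, ...) {
  cat(sprintf("<marked_spikes> %d events over %d frames (d_kappa = %d)\n",
              length(x$frames), x$R, x$d_kappa))
  invisible(x)
}

#' Finite mixture intensity model for marked spikes
#'
#' A finite materialization of the mixing measure: `K` components, each with a
#' non-negative rate weight (spikes per second), a Gaussian mark kernel and a
#' stimulus kernel. The conditional intensity at mark `kappa` and stimulus `x`
#' is `sum_k rate_k * f_kappa(kappa | k) * f_x(x | k)`.
#'
#' @param rates Numeric vector of K non-negative rates.
#' @param mark_kernels List of K [mark_kernel()] objects.
#' @param stim_kernels List of K [stim_kernel()] objects.
#' @return An object of class `intensity_model`.
#' @export
intensity_model <- function(rates, mark_kernels, stim_kernels) {
  rates <- as.numeric(rates)
  K <- length(rates)
  if (K < 1) stop("need at least one component")
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be finite and non-negative")
  stopifnot(length(mark_kernels) == K, length(stim_kernels) == K)
  lapply(mark_kernels, function(k) stopifnot(inherits(k, "mark_kernel")))
  lapply(stim_kernels, function(k) stopifnot(inherits(k, "stim_kernel")))
  d_kappa <- length(mark_kernels[[1]]$mu)
  structure(list(rates = rates, mark_kernels = mark_kernels,
                 stim_kernels = stim_kernels, K = K, d_kappa = d_kappa),
            class = "intensity_model")
}

#' @export
print.intensity_model <- function(x, ...) {
  cat(sprintf("<intensity_model> K = %d components, d_kappa = %d, total rate %.3g /s\n",
              x$K, x$d_kappa, sum(x$rates)))
  invisible(x)
}

#' Conditional intensity of the marked point process
#'
#' Evaluates `lambda(kappa | x) = sum_k rate_k f_kappa(kappa | k) f_x(x | k)`,
#' the instantaneous event rate per second and per unit mark volume at mark
#' `kappa` when the stimulus is `x`.
#'
#' @param kappa A mark vector.
#' @param x A scalar stimulus value (vector for multivariate stimuli).
#' @param model An [intensity_model()].
#' @param per_component Return the K per-component contributions instead of
#'   their sum?
#' @return Intensity value, or a K-vector of contributions.
#' @export
eval_intensity <- function(kappa, x, model, per_component = FALSE) {
  stopifnot(inherits(model, "intensity_model"))
  contrib <- vapply(seq_len(model$K), function(k) {
    if (model$rates[k] == 0) return(0)
    model$rates[k] * dmark(kappa, model$mark_kernels[[k]]) *
      dstim(x, model$stim_kernels[[k]])
  }, numeric(1))
  if (per_component) contrib else sum(contrib)
}

#' Tuning curve of one mixture component
#'
#' Integrating the component intensity over the mark space leaves
#' `rate_k * f_x(x | k)`: the firing rate of neuron `k` as a function of the
#' stimulus (the mark kernel integrates to one and drops out).
#'
#' @param model An [intensity_model()].
#' @param k Component index.
#' @param grid Stimulus values at which to evaluate the curve.
#' @return Numeric vector of rates (spikes per second) on `grid`.
#' @export
tuning_curve <- function(model, k, grid) {
  stopifnot(inherits(model, "intensity_model"))
  if (k < 1 || k > model$K) stop("component index out of range")
  model$rates[k] * dstim(grid, model$stim_kernels[[k]])
}

#' Discretized marked point-process log-likelihood
#'
#' Log-likelihood of the mixture intensity given an observed marked spike
#' sequence and stimulus path, in the binned form: the compensator
#' `-T * sum_k rate_k * mean_r f_x(x_r | k)` (the mark kernel integrates out;
#' the stimulus integral uses the empirical occupancy measure) plus
#' `sum_events log(lambda(kappa_r | x_r) * delta)`.
#'
#' @param spikes A [marked_spikes()].
#' @param stim A [stimulus_series()] with the same number of frames.
#' @param model An [intensity_model()].
#' @return Scalar log-likelihood; `-Inf` (with a warning) if some event has
#'   zero intensity.
#' @export
marked_pp_loglik <- function(spikes, stim, model) {
  stopifnot(inherits(spikes, "marked_spikes"), inherits(stim, "stimulus_series"),
            inherits(model, "intensity_model"))
  if (spikes$R != stim$R) stop("'spikes' and 'stim' disagree on the frame count")
  mean_fx <- vapply(model$stim_kernels,
                    function(kern) mean(dstim(stim$values, kern)), numeric(1))
  compensator <- -stim$T * sum(model$rates * mean_fx)
  if (length(spikes$frames) == 0) return(compensator)
  xr <- if (stim$d_x == 1) stim$values[spikes$frames]
        else stim$values[spikes$frames, , drop = FALSE]
  # log intensity per event, via per-component log contributions
  log_contrib <- vapply(seq_len(model$K), function(k) {
    if (model$rates[k] == 0) return(rep(-Inf, length(spikes$frames)))
    log(model$rates[k]) + dmark(spikes$marks, model$mark_kernels[[k]], log = TRUE) +
      dstim(xr, model$stim_kernels[[k]], log = TRUE)
  }, numeric(length(spikes$frames)))
  log_contrib <- matrix(log_contrib, nrow = length(spikes$frames))
  log_lambda <- apply(log_contrib, 1, logsumexp)
  if (any(!is.finite(log_lambda))) {
    warning("an observed mark has zero intensity; log-likelihood is -Inf")
    return(-Inf)
  }
  compensator + sum(log_lambda + log(stim$delta))
}
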