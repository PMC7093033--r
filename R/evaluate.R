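#' F-measure
#'
#' Weighted harmonic mean of precision and recall:
#' `F_beta = (1 + beta^2) P R / (beta^2 P + R)`; returns 0 when both are 0.
#' As `beta^2 -> 0` the measure tends to the precision, as `beta^2 -> Inf`
#' to the recall.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @param beta_sq Positive weight `beta^2` (default 0.3).
#' @return F-measure in `[0, 1]`.
#' @export
f_measure <- function(precision, recall, beta_sq = 0.3) {
  stopifnot(beta_sq > 0)
  ifelse(precision == 0 & recall == 0, 0,
         (1 + beta_sq) * precision * recall / (beta_sq * precision + recall))
}

#' Match estimated to true spike frames
#'
#' Greedy one-to-one matching by increasing frame distance within a tolerance
#' window; unmatched estimates count as false positives, unmatched truths as
#' false negatives.
#'
#' @param true_frames,est_frames Integer frame vectors.
#' @param tol_frames Non-negative matching tolerance (default 1).
#' @return Named vector `c(TP, FP, FN)`.
#' @export
match_spikes <- function(true_frames, est_frames, tol_frames = 1) {
  stopifnot(tol_frames >= 0)
  nt <- length(true_frames)
  ne <- length(est_frames)
  if (nt == 0 || ne == 0)
    return(c(TP = 0, FP = ne, FN = nt))
  dist <- abs(outer(true_frames, est_frames, "-"))
  pairs <- which(dist <= tol_frames, arr.ind = TRUE)
  tp <- 0
  if (nrow(pairs) > 0) {
    ord <- order(dist[pairs])
    used_t <- logical(nt)
    used_e <- logical(ne)
    for (i in ord) {
      ti <- pairs[i, 1]; ei <- pairs[i, 2]
      if (!used_t[ti] && !used_e[ei]) {
        used_t[ti] <- TRUE; used_e[ei] <- TRUE; tp <- tp + 1
      }
    }
  }
  c(TP = tp, FP = ne - tp, FN = nt - tp)
}

# Greedy one-to-one component matching by decreasing cosine similarity of
# footprints. Returns an integer map: est index per true component (NA if
# unmatched).
match_components <- function(true_fp, est_fp) {
  nt <- ncol(true_fp)
  ne <- ncol(est_fp)
  map <- rep(NA_integer_, nt)
  if (nt == 0 || ne == 0) return(map)
  nrm <- function(M) sweep(M, 2, pmax(sqrt(colSums(M^2)), 1e-12), "/")
  sim <- crossprod(nrm(true_fp), nrm(est_fp))
  for (step in seq_len(min(nt, ne))) {
    ij <- arrayInd(which.max(sim), dim(sim))
    if (sim[ij] <= 0) break
    map[ij[1]] <- ij[2]
    sim[ij[1], ] <- -Inf
    sim[, ij[2]] <- -Inf
  }
  map
}

#' Pixelwise ROI confusion counts under component matching
#'
#' Matches estimated to true components greedily by footprint cosine
#' similarity (using the masks as 0-1 footprints when no real-valued
#' footprints are given), then counts pixel true/false positives and false
#' negatives per matched pair. Unmatched true components contribute all their
#' pixels as false negatives, unmatched estimated components all theirs as
#' false positives.
#'
#' @param true_masks,est_masks Logical `d_y x n` matrices (one column per
#'   component), on the same pixel grid.
#' @param true_fp,est_fp Optional real-valued footprints for the matching.
#' @return A data frame with one row per component (matched pairs and
#'   unmatched singletons): columns `TP`, `FP`, `FN`, `true_id`, `est_id`.
#' @export
match_rois <- function(true_masks, est_masks,
                       true_fp = NULL, est_fp = NULL) {
  true_masks <- as.matrix(true_masks)
  est_masks <- as.matrix(est_masks)
  if (nrow(true_masks) != nrow(est_masks))
    stop("mask matrices are on different pixel grids")
  map <- match_components(
    if (is.null(true_fp)) true_masks + 0 else true_fp,
    if (is.null(est_fp)) est_masks + 0 else est_fp)
  rows <- list()
  for (t in seq_len(ncol(true_masks))) {
    e <- map[t]
    if (is.na(e)) {
      rows[[length(rows) + 1]] <-
        data.frame(TP = 0, FP = 0, FN = sum(true_masks[, t]),
                   true_id = t, est_id = NA_integer_)
    } else {
      tp <- sum(true_masks[, t] & est_masks[, e])
      rows[[length(rows) + 1]] <-
        data.frame(TP = tp, FP = sum(est_masks[, e]) - tp,
                   FN = sum(true_masks[, t]) - tp,
                   true_id = t, est_id = e)
    }
  }
  for (e in setdiff(seq_len(ncol(est_masks)), map[!is.na(map)])) {
    rows[[length(rows) + 1]] <-
      data.frame(TP = 0, FP = sum(est_masks[, e]), FN = 0,
                 true_id = NA_integer_, est_id = e)
  }
  do.call(rbind, rows)
}

#' Chi-squared threshold spike detection on a real-valued trace
#'
#' Standardizes the trace by its sample mean and variance and flags frames
#' whose squared standardized value exceeds the upper `chi2_upper_tail`
#' quantile of the chi-squared distribution with one degree of freedom
#' (about 10.83 at the default 0.1% tail).
#'
#' @param trace Numeric series (length >= 2).
#' @param chi2_upper_tail Upper tail probability (default 0.001).
#' @return Integer vector of flagged frames.
#' @export
threshold_spike_detect <- function(trace, chi2_upper_tail = 0.001) {
  trace <- as.numeric(trace)
  if (length(trace) < 2) stop("'trace' needs at least two frames")
  v <- stats::var(trace)
  if (v == 0) {
    warning("constant trace; no detections")
    return(integer(0))
  }
  d2 <- (trace - mean(trace))^2 / v
  cutoff <- stats::qchisq(chi2_upper_tail, df = 1, lower.tail = FALSE)
  which(d2 > cutoff)
}

#' Maximum-likelihood tuning curve of an unmarked Poisson spike train
#'
#' Fits the inhomogeneous-Poisson tuning model `lambda(x) = lambda f_x(x |
#' mu, tau)` to a detected spike train by maximizing the discretized
#' log-likelihood `sum_i log(lambda f_x(x_i)) - lambda T mean_r f_x(x_r)`
#' over `(lambda, mu, tau)`. The rate is profiled out analytically
#' (`lambda_hat = n / (T mean_r f_x(x_r))`) inside the kernel optimization.
#'
#' @param spike_frames Integer frames with at least one spike.
#' @param stim A [stimulus_series()].
#' @param family Stimulus kernel family.
#' @return List with `rate` (spikes/s), `kernel` (a [stim_kernel()]) and
#'   `loglik` (at the optimum, including the `delta` convention of
#'   [pp_loglik_given_spikes()]).
#' @export
fit_tuning_mle <- function(spike_frames, stim,
                           family = c("gaussian", "von_mises")) {
  family <- match.arg(family)
  stopifnot(inherits(stim, "stimulus_series"))
  n <- length(spike_frames)
  if (n < 1) stop("need at least one spike")
  xi <- if (stim$d_x == 1) stim$values[spike_frames]
        else stim$values[spike_frames, , drop = FALSE]
  profile_obj <- function(kern) {
    mf <- mean(dstim(stim$values, kern))
    if (mf <= 0) return(-1e300)
    val <- sum(dstim(xi, kern, log = TRUE)) + n * log(n / (stim$T * mf)) - n
    if (is.finite(val)) val else -1e300
  }
  if (family == "gaussian") {
    dx <- if (is.matrix(xi)) ncol(xi) else 1
    xm <- if (is.matrix(xi)) xi else matrix(xi, ncol = 1)
    wm <- colMeans(xm)
    wv <- max(mean(rowSums(sweep(xm, 2, wm)^2)) / dx, 1e-8)
    start <- c(wm, log(1 / wv))
    scale2 <- max(stats::var(as.numeric(stim$values)), 1e-12)
    rng <- range(stim$values)
    span <- max(rng[2] - rng[1], sqrt(scale2))
    lower <- c(rep(rng[1] - span, dx), log(1e-4 / scale2))
    upper <- c(rep(rng[2] + span, dx), log(1e8 / scale2))
    make <- function(par) stim_kernel("gaussian", par[seq_len(dx)],
                                      exp(par[dx + 1]))
  } else {
    mu0 <- atan2(mean(sin(xi)), mean(cos(xi)))
    start <- c(mu0, log(2))
    lower <- c(-2 * pi, log(1e-4))
    upper <- c(2 * pi, log(500))
    make <- function(par) stim_kernel("von_mises", wrap_angle(par[1]),
                                      exp(par[2]))
  }
  opt <- stats::optim(pmin(pmax(start, lower), upper),
                      function(par) -profile_obj(make(par)),
                      method = "L-BFGS-B", lower = lower, upper = upper)
  if (opt$convergence != 0)
    stop(sprintf("tuning-curve optimizer did not converge (code %d): %s",
                 opt$convergence, opt$message))
  kern <- make(opt$par)
  rate <- n / (stim$T * mean(dstim(stim$values, kern)))
  list(rate = rate, kernel = kern,
       loglik = pp_loglik_given_spikes(spike_frames, stim,
                                       list(list(rate = rate, kernel = kern))))
}

#' Pooled point-process log-likelihood of a spike train under tuning curves
#'
#' Treats the pooled spike train as one unmarked inhomogeneous Poisson
#' process with intensity `lambda(x) = sum_k lambda_k f_x(x | u_k)` and
#' evaluates `sum_i log(lambda(x_i) delta) - T mean_r lambda(x_r)` (the
#' compensator integrates against the empirical stimulus occupancy; the bin
#' width `delta` is included in the event terms — this convention is fixed
#' and shared with [fit_tuning_mle()]).
#'
#' @param spike_frames Integer frame vector (possibly empty).
#' @param stim A [stimulus_series()].
#' @param tuning_list Non-empty list of `list(rate =, kernel =)` pairs.
#' @return Scalar log-likelihood; `-Inf` (with a warning) if the intensity
#'   vanishes at a spike.
#' @export
pp_loglik_given_spikes <- function(spike_frames, stim, tuning_list) {
  stopifnot(inherits(stim, "stimulus_series"))
  if (length(tuning_list) == 0) stop("'tuning_list' must be non-empty")
  lam <- function(x) {
    vals <- vapply(tuning_list, function(tc)
      tc$rate * dstim(x, tc$kernel), numeric(NROW(x)))
    rowSums(matrix(vals, nrow = NROW(x)))
  }
  comp <- -stim$T * mean(lam(stim$values))
  if (length(spike_frames) == 0) return(comp)
  xi <- if (stim$d_x == 1) stim$values[spike_frames]
        else stim$values[spike_frames, , drop = FALSE]
  li <- lam(xi)
  if (any(li <= 0)) {
    warning("intensity vanishes at an observed spike; log-likelihood is -Inf")
    return(-Inf)
  }
  comp + sum(log(li * stim$delta))
}

#' Correlation image of a movie
#'
#' For every pixel, the mean Pearson correlation of its temporal trace with
#' its 8-connected neighbours (edge pixels use the neighbours that exist);
#' constant traces contribute 0 by convention. High values mark pixel groups
#' that co-fluctuate, i.e. likely neuron locations.
#'
#' @param movie `R x d_y` frame matrix, row-major vectorized frames.
#' @param height,width Frame dimensions with `height * width = d_y`.
#' @return `height x width` matrix of mean neighbour correlations.
#' @export
correlation_image <- function(movie, height, width) {
  assert_matrix(movie, ncol = height * width, name = "movie")
  R <- nrow(movie)
  sds <- apply(movie, 2, stats::sd)
  Z <- sweep(movie, 2, colMeans(movie))
  ok <- sds > 0
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2, sds[ok], "/")
  Z[, !ok] <- 0
  # pixel (i, j) -> column (i-1)*width + j
  corsum <- matrix(0, height, width)
  n_nb <- matrix(0, height, width)
  zarr <- array(Z, c(R, width, height))  # [frame, col, row] given row-major vec
  zarr <- aperm(zarr, c(1, 3, 2))        # [frame, row, col]
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ri <- seq_len(height); rj <- seq_len(width)
    vi <- ri + di; vj <- rj + dj
    keep_i <- vi >= 1 & vi <= height
    keep_j <- vj >= 1 & vj <= width
    a <- zarr[, ri[keep_i], rj[keep_j], drop = FALSE]
    b <- zarr[, vi[keep_i], vj[keep_j], drop = FALSE]
    cc <- apply(a * b, c(2, 3), sum) / (R - 1)
    corsum[ri[keep_i], rj[keep_j]] <- corsum[ri[keep_i], rj[keep_j]] + cc
    n_nb[ri[keep_i], rj[keep_j]] <- n_nb[ri[keep_i], rj[keep_j]] + 1
  }
  out <- corsum / n_nb
  # convention: pixels with constant traces score 0
  const_px <- matrix(!ok[matrix(seq_len(height * width), height, width,
                                byrow = TRUE)], height, width)
  out[const_px] <- 0
  out
}

#' Score a deconvolution result against simulation ground truth
#'
#' Matches estimated components to the truth by footprint cosine similarity,
#' then reports per-component and mean spike F-measures (greedy frame
#' matching within `tol_frames`) and pixelwise ROI F-measures (true
#' footprints binarized with the same quantile rule as the estimates).
#' Unmatched components on either side enter the means with F = 0.
#'
#' @param truth An `mpp_ground_truth` from [simulation_study()].
#' @param decon An `mpp_deconvolution` from [deconvolve()].
#' @param beta_sq F-measure weight (default 0.3).
#' @param tol_frames Spike matching tolerance in frames (default 1).
#' @param mask_quantile ROI binarization level applied to the true
#'   footprints (default 0.7, matching [extract_footprints()]).
#' @return An object of class `mpp_evaluation`: per-component and mean spike
#'   and ROI F-measures, the component matching, and the settings used.
#' @export
evaluate_deconvolution <- function(truth, decon, beta_sq = 0.3,
                                   tol_frames = 1, mask_quantile = 0.7) {
  stopifnot(inherits(truth, "mpp_ground_truth"),
            inherits(decon, "mpp_deconvolution"))
  true_fp <- truth$footprints
  est_fp <- decon$footprints
  map <- match_components(true_fp, est_fp)
  n_true <- ncol(true_fp)
  n_est <- ncol(est_fp)

  spike_f <- numeric(0)
  for (t in seq_len(n_true)) {
    cm <- if (is.na(map[t])) c(TP = 0, FP = 0, FN = length(truth$spikes_per_component[[t]]))
          else match_spikes(truth$spikes_per_component[[t]],
                            decon$spikes[[map[t]]], tol_frames)
    P <- if (cm["TP"] + cm["FP"] > 0) cm["TP"] / (cm["TP"] + cm["FP"]) else 0
    Rc <- if (cm["TP"] + cm["FN"] > 0) cm["TP"] / (cm["TP"] + cm["FN"]) else 0
    spike_f <- c(spike_f, f_measure(P, Rc, beta_sq))
  }
  extra_est <- setdiff(seq_len(n_est), map[!is.na(map)])
  spike_f <- c(spike_f, rep(0, length(extra_est)))

  true_masks <- apply(true_fp, 2, function(v) {
    v <- pmax(v, 0)
    if (max(v) <= 0) rep(FALSE, length(v)) else v > mask_quantile * max(v)
  })
  true_masks <- matrix(as.logical(true_masks), nrow(true_fp), n_true)
  roi <- match_rois(true_masks, decon$roi_masks, true_fp, est_fp)
  roi_f <- apply(roi, 1, function(r) {
    P <- if (r["TP"] + r["FP"] > 0) r["TP"] / (r["TP"] + r["FP"]) else 0
    Rc <- if (r["TP"] + r["FN"] > 0) r["TP"] / (r["TP"] + r["FN"]) else 0
    f_measure(P, Rc, beta_sq)
  })

  structure(list(
    spike_f_per_component = unname(spike_f),
    spike_f_mean = mean(spike_f),
    roi_f_per_component = unname(roi_f),
    roi_f_mean = mean(roi_f),
    matching = map,
    n_true = n_true, n_est = n_est,
    beta_sq = beta_sq, tol_frames = tol_frames,
    mask_quantile = mask_quantile), class = "mpp_evaluation")
}

#' @export
print.mpp_evaluation <- function(x, ...) {
  cat(sprintf(
    "<mpp_evaluation> %d true / %d estimated components\n  mean spike F = %.3f, mean ROI F = %.3f (beta^2 = %g)\n",
    x$n_true, x$n_est, x$spike_f_mean, x$roi_f_mean, x$beta_sq))
  invisible(x)
}
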