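#' Sample a marked spike sequence from the mixture intensity
#'
#' Discretized sampling of the marked inhomogeneous Poisson process: each frame
#' bin of width `delta` holds at most one spike; the spike probability at
#' frame r is `p_r = delta * sum_k rate_k f_x(x_r | k)`. Given a spike, the
#' component is drawn with probability proportional to `rate_k f_x(x_r | k)`
#' and the mark from the component's Gaussian mark kernel.
#'
#' @param model An [intensity_model()].
#' @param stim A [stimulus_series()].
#' @param seed Integer seed.
#' @return A list with `spikes` (a [marked_spikes()]) and `assignments`
#'   (integer component label per event).
#' @export
sample_marked_spikes <- function(model, stim, seed = 1L) {
  stopifnot(inherits(model, "intensity_model"), inherits(stim, "stimulus_series"))
  R <- stim$R
  # K x (R-1) matrix of rate_k * f_x(x_r | k) at frames 2..R
  xr <- if (stim$d_x == 1) stim$values[2:R] else stim$values[2:R, , drop = FALSE]
  rate_fx <- vapply(seq_len(model$K), function(k)
    model$rates[k] * dstim(xr, model$stim_kernels[[k]]), numeric(R - 1))
  rate_fx <- matrix(rate_fx, nrow = R - 1)
  p <- stim$delta * rowSums(rate_fx)
  if (any(p > 1))
    stop(sprintf(
      "per-bin spike probability exceeds 1 at frame %d (p = %.3f); use a smaller delta",
      which(p > 1)[1] + 1L, max(p)))
  with_seed(seed, {
    hit <- which(stats::runif(R - 1) < p)
    if (length(hit) == 0) {
      return(list(spikes = marked_spikes(integer(0),
                                         matrix(0, 0, model$d_kappa), R),
                  assignments = integer(0)))
    }
    assignments <- vapply(hit, function(r)
      sample.int(model$K, 1, prob = rate_fx[r, ]), integer(1))
    draws <- vapply(assignments, function(k) {
      kern <- model$mark_kernels[[k]]
      L <- chol(solve_spd(kern$lambda, what = "mark precision"))
      kern$mu + drop(t(L) %*% stats::rnorm(model$d_kappa))
    }, numeric(model$d_kappa))
    marks <- if (model$d_kappa == 1) matrix(draws, ncol = 1) else t(draws)
    list(spikes = marked_spikes(hit + 1L, marks, R), assignments = assignments)
  })
}

#' Generate latent calcium states given a spike sequence
#'
#' Simulates the jump vector autoregression: `c_1` from the initial Gaussian;
#' at event frames `c_r = F c_{r-1} + kappa_r` with no transition noise (the
#' jump branch replaces the noise); at non-event frames `c_r = F c_{r-1} +
#' v_r` with `v_r ~ N(0, V)` (precision `V`).
#'
#' @param spikes A [marked_spikes()].
#' @param ss A [state_space_params()].
#' @param seed Integer seed.
#' @param noise_free Suppress transition noise and draw `c_1` at its mean
#'   (deterministic recursion)?
#' @return An `R x d_kappa` state matrix.
#' @export
generate_calcium <- function(spikes, ss, seed = 1L, noise_free = FALSE) {
  stopifnot(inherits(spikes, "marked_spikes"), inherits(ss, "state_space_params"))
  d <- ss$d_kappa
  if (spikes$d_kappa != d) stop("mark dimension disagrees with the state space")
  R <- spikes$R
  is_event <- logical(R)
  is_event[spikes$frames] <- TRUE
  mark_of <- integer(R)
  mark_of[spikes$frames] <- seq_along(spikes$frames)
  Lv <- if (!noise_free) chol(solve_spd(ss$V, what = "V")) else NULL
  with_seed(seed, {
    C <- matrix(0, R, d)
    C[1, ] <- if (noise_free) ss$mu_init
              else ss$mu_init + drop(t(chol(ss$sigma_init)) %*% stats::rnorm(d))
    for (r in 2:R) {
      drift <- ss$F %*% C[r - 1, ]
      C[r, ] <- if (is_event[r]) {
        drift + spikes$marks[mark_of[r], ]
      } else if (noise_free) {
        drift
      } else {
        drift + t(Lv) %*% stats::rnorm(d)
      }
    }
    C
  })
}

#' Render the observed movie from latent calcium states
#'
#' Applies the observation model `y_r = G c_r + w_r` with `w_r` zero-mean
#' Gaussian noise of diagonal precision `W`.
#'
#' @param calcium `R x d_kappa` state matrix.
#' @param ss A [state_space_params()].
#' @param seed Integer seed.
#' @param noise_free Return `G c_r` exactly?
#' @return An `R x d_y` frame matrix.
#' @export
render_movie <- function(calcium, ss, seed = 1L, noise_free = FALSE) {
  stopifnot(inherits(ss, "state_space_params"))
  calcium <- assert_matrix(as.matrix(calcium), ncol = ss$d_kappa, name = "calcium")
  mean_movie <- calcium %*% t(ss$G)
  if (noise_free) return(mean_movie)
  sds <- 1 / sqrt(ss$W_diag)
  with_seed(seed, {
    noise <- matrix(stats::rnorm(length(mean_movie)), nrow(mean_movie)) *
      rep(sds, each = nrow(mean_movie))
    mean_movie + noise
  })
}

#' Configuration of the simulation study scene
#'
#' Defaults reproduce the design of the package's reference simulation:
#' nine stimulus-tuned neurons observed for 150 s at 10 Hz on a 40 x 40 pixel
#' grid, with Gaussian receptive fields spread over the stimulus range and
#' spatial footprints that partially overlap. See the methods vignette for the
#' rationale behind each value.
#'
#' @param n_neurons Number of ground-truth neurons.
#' @param T_obs Observation length in seconds.
#' @param delta Sampling interval in seconds.
#' @param height,width Frame size in pixels.
#' @param d_kappa Latent state dimension.
#' @param rate Mean rate weight per neuron (spikes/s).
#' @param blob_sigma Footprint blob standard deviation in pixels.
#' @param mark_amplitude Mean mark magnitude (peak fluorescence of a spike).
#' @param mark_sd Within-neuron mark fluctuation (per state dimension).
#' @param rf_sd Receptive field standard deviation on the stimulus axis.
#' @param decay AR(1) calcium decay factor per frame.
#' @param trans_sd Transition noise standard deviation per state dimension.
#' @param obs_sd Observation noise standard deviation per pixel.
#' @param complement_scale Relative scale of the non-footprint columns of `G`.
#' @param stimulus_kind Passed to [sample_stimulus()].
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_neurons = 9, T_obs = 150, delta = 0.1,
                       height = 40, width = 40, d_kappa = 40,
                       rate = 0.4, blob_sigma = 3,
                       mark_amplitude = 1, mark_sd = 0.05,
                       rf_sd = 0.3, decay = 0.8, trans_sd = 0.02,
                       obs_sd = 0.05, complement_scale = 1,
                       stimulus_kind = "smooth_1d") {
  cfg <- as.list(environment())
  if (d_kappa < n_neurons) stop("'d_kappa' must be at least 'n_neurons'")
  structure(cfg, class = "sim_config")
}

# Gaussian blob image, vectorized row-major (pixel (i, j) -> (i-1)*width + j).
blob_image <- function(center_rc, height, width, sigma) {
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  img <- exp(-((rows - center_rc[1])^2 + (cols - center_rc[2])^2) / (2 * sigma^2))
  as.numeric(t(img))  # row-major vectorization
}

# Deterministic, partially overlapping footprint centres on a 3 x 3-ish grid
# with alternating jitter so that several neighbour pairs overlap.
footprint_centers <- function(n, height, width) {
  g <- ceiling(sqrt(n))
  rr <- seq(height / (g + 1), g * height / (g + 1), length.out = g)
  cc <- seq(width / (g + 1), g * width / (g + 1), length.out = g)
  grid <- expand.grid(r = rr, c = cc)[seq_len(n), ]
  jit <- 0.22 * min(height, width) / (g + 1) *
    cbind(rep_len(c(1, -1, 0), n), rep_len(c(-1, 1, 1, 0), n))
  as.matrix(grid) + jit
}

#' Build the ground-truth scene of the simulation study
#'
#' Constructs the full generative configuration behind [simulation_study()]:
#' the state space (observation matrix whose leading columns are the neuron
#' footprint blobs, completed by an orthogonal complement so the low-rank
#' premise holds by construction) and the mixture intensity (one component per
#' neuron, mark means on the footprint axes, receptive field centres spread
#' over the stimulus range).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (used for the orthogonal complement of `G`).
#' @return List with `model` (an [intensity_model()]) and `ss`
#'   (a [state_space_params()]).
#' @export
simulation_scene <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_neurons
  d <- config$d_kappa
  dy <- config$height * config$width
  centers <- footprint_centers(n, config$height, config$width)
  B <- vapply(seq_len(n), function(k)
    blob_image(centers[k, ], config$height, config$width, config$blob_sigma),
    numeric(dy))
  G <- with_seed(derive_seed(seed, "scene_G"), {
    Qr <- matrix(stats::rnorm(dy * (d - n)), dy)
    # orthogonalize the complement against the blobs and itself
    Q <- qr.Q(qr(cbind(B, Qr)))[, (n + 1):d, drop = FALSE]
    cbind(B, config$complement_scale * Q)
  })
  mark_kernels <- lapply(seq_len(n), function(k) {
    mu <- rep(0, d); mu[k] <- config$mark_amplitude
    mark_kernel(mu, diag(1 / config$mark_sd^2, d))
  })
  # receptive-field centres spread over the core of the stimulus range
  mu_x <- if (config$stimulus_kind == "circular_track") {
    seq(-pi, pi, length.out = n + 1)[seq_len(n)]
  } else {
    seq(-1.6, 1.6, length.out = n)
  }
  stim_kernels <- lapply(seq_len(n), function(k)
    stim_kernel(if (config$stimulus_kind == "circular_track") "von_mises" else "gaussian",
                mu_x[k],
                if (config$stimulus_kind == "circular_track") 1 / config$rf_sd^2
                else 1 / config$rf_sd^2))
  model <- intensity_model(rep(config$rate, n), mark_kernels, stim_kernels)
  ss <- state_space_params(
    F = diag(config$decay, d),
    V = diag(1 / config$trans_sd^2, d),
    G = G,
    W_diag = rep(1 / config$obs_sd^2, dy),
    mu_init = rep(0, d),
    sigma_init = diag(config$trans_sd^2 / (1 - config$decay^2), d))
  list(model = model, ss = ss)
}

#' Generate the reference simulation study data set
#'
#' Draws one full synthetic recording from the generative model under the
#' [sim_config()] scene: stimulus path, marked spikes with component labels,
#' latent calcium, and the noisy movie. All randomness derives
#' deterministically from `seed`.
#'
#' @param seed Integer seed.
#' @param config A [sim_config()].
#' @return A list with `movie` (R x d_y matrix), `stim`
#'   (a [stimulus_series()]) and `truth` (class `mpp_ground_truth`): spike
#'   frames per component, the marked sequence, assignments, calcium states,
#'   footprints `G mu_k`, the generating [intensity_model()] and
#'   [state_space_params()], frame geometry and the seed.
#' @export
simulation_study <- function(seed = 1L, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  R <- round(config$T_obs / config$delta)
  scene <- simulation_scene(config, seed)
  stim <- sample_stimulus(config$stimulus_kind, R, config$delta,
                          seed = derive_seed(seed, "stimulus"))
  sp <- sample_marked_spikes(scene$model, stim, seed = derive_seed(seed, "spikes"))
  calcium <- generate_calcium(sp$spikes, scene$ss, seed = derive_seed(seed, "calcium"))
  movie <- render_movie(calcium, scene$ss, seed = derive_seed(seed, "movie"))
  spikes_per_component <- lapply(seq_len(config$n_neurons), function(k)
    sp$spikes$frames[sp$assignments == k])
  footprints <- vapply(seq_len(config$n_neurons), function(k)
    drop(scene$ss$G %*% scene$model$mark_kernels[[k]]$mu),
    numeric(nrow(scene$ss$G)))
  truth <- structure(list(
    spikes_per_component = spikes_per_component,
    marks = sp$spikes,
    assignments = sp$assignments,
    calcium = calcium,
    footprints = footprints,
    model = scene$model,
    ss = scene$ss,
    height = config$height, width = config$width,
    config = config, rng_seed = seed), class = "mpp_ground_truth")
  list(movie = movie, stim = stim, truth = truth)
}

#' @export
print.mpp_ground_truth <- function(x, ...) {
  cat(sprintf("<mpp_ground_truth> %d neurons, %d spikes, %d x %d px, seed %d\n",
              length(x$spikes_per_component), length(x$marks$frames),
              x$height, x$width, x$rng_seed))
  invisible(x)
}
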