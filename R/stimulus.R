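#' External stimulus series
#'
#' The covariate sampled once per movie frame: `values[r]` (or row `r` for a
#' multivariate stimulus) is the stimulus at the end of the r-th frame bin
#' `((r-1)*delta, r*delta]`. The series also represents the empirical
#' occupancy measure of the stimulus path, with uniform weight `1/R` on each
#' sampled value; that measure is what the point-process compensator and the
#' `beta*` correction integrate against.
#'
#' @param values Numeric vector of length `R`, or an `R x d_x` matrix.
#' @param delta Sampling interval in seconds (> 0).
#' @param circular Are the values angles on the circle? If `TRUE` they are
#'   wrapped into `(-pi, pi]`.
#' @return An object of class `stimulus_series` with fields `values`, `delta`,
#'   `T` (observation length `R * delta`), `R` and `d_x`.
#' @export
stimulus_series <- function(values, delta, circular = FALSE) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0)
    stop("'delta' must be a single positive number")
  if (is.null(dim(values))) {
    values <- as.numeric(values)
    R <- length(values)
    d_x <- 1L
  } else {
    values <- as.matrix(values)
    R <- nrow(values)
    d_x <- ncol(values)
  }
  if (R < 2) stop("a stimulus series needs at least two frames")
  if (anyNA(values) || any(!is.finite(values))) stop("stimulus values must be finite")
  if (circular) {
    if (d_x != 1) stop("circular stimuli must be one-dimensional")
    values <- wrap_angle(values)
  }
  structure(
    list(values = values, delta = delta, T = R * delta, R = R,
         d_x = d_x, circular = circular),
    class = "stimulus_series")
}

#' @export
print.stimulus_series <- function(x, ...) {
  cat(sprintf("<stimulus_series> R = %d frames, delta = %g s, T = %g s, d_x = %d%s\n",
              x$R, x$delta, x$T, x$d_x, if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Simulate an external stimulus path
#'
#' Two generators covering the study designs this package targets:
#' `"smooth_1d"` is a slowly varying bounded real series (an
#' Ornstein--Uhlenbeck walk reflected at `+/- bound`), emulating a smoothly
#' drifting analogue stimulus; `"circular_track"` is monotone lap running on
#' the circle `(-pi, pi]` with small speed fluctuations, emulating an animal
#' on a circular treadmill.
#'
#' @param kind `"smooth_1d"` or `"circular_track"`.
#' @param R Number of frames (>= 2).
#' @param delta Sampling interval in seconds.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param tau_s Correlation time of the OU walk in seconds (smooth_1d).
#' @param sd_s Stationary standard deviation of the OU walk (smooth_1d).
#' @param bound Reflection boundary (smooth_1d).
#' @param lap_time Mean seconds per lap (circular_track).
#' @param speed_jitter Relative standard deviation of instantaneous speed
#'   (circular_track); 0 gives perfectly uniform laps.
#' @return A [stimulus_series()].
#' @export
sample_stimulus <- function(kind = c("smooth_1d", "circular_track"),
                            R, delta, seed = 1L,
                            tau_s = 10, sd_s = 1.5, bound = 2,
                            lap_time = 30, speed_jitter = 0.2) {
  kind <- match.arg(kind)
  if (R < 2) stop("'R' must be at least 2")
  with_seed(seed, {
    if (kind == "smooth_1d") {
      a <- exp(-delta / tau_s)
      innov_sd <- sd_s * sqrt(1 - a^2)
      x <- numeric(R)
      x[1] <- stats::rnorm(1, 0, sd_s)
      eps <- stats::rnorm(R - 1, 0, innov_sd)
      for (r in 2:R) x[r] <- a * x[r - 1] + eps[r - 1]
      # reflect into [-bound, bound]
      y <- (x + bound) %% (4 * bound)
      y <- ifelse(y > 2 * bound, 4 * bound - y, y) - bound
      stimulus_series(pmin(pmax(y, -bound), bound), delta)
    } else {
      base_speed <- 2 * pi / lap_time
      speeds <- base_speed * pmax(1 + speed_jitter * stats::rnorm(R), 0)
      theta <- cumsum(c(stats::runif(1, -pi, pi), speeds[-1] * delta))
      stimulus_series(wrap_angle(theta), delta, circular = TRUE)
    }
  })
}
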