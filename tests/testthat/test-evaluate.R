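test_that("F-measure matches the weighted harmonic form and its limits", {
  expect_equal(f_measure(0.7, 0.7, 0.3), 0.7)
  expect_equal(f_measure(0.7, 0.7, 5), 0.7)
  expect_equal(f_measure(1, 0, 0.3), 0)
  expect_equal(f_measure(0, 0, 0.3), 0)
  expect_equal(f_measure(0.9, 0.5, 0.3), 0.585 / 0.77)
  # beta^2 -> 0 gives precision, beta^2 -> Inf gives recall
  expect_equal(f_measure(0.8, 0.3, 1e-9), 0.8, tolerance = 1e-6)
  expect_equal(f_measure(0.8, 0.3, 1e9), 0.3, tolerance = 1e-6)
})

test_that("spike matching is greedy one-to-one within tolerance", {
  expect_equal(match_spikes(c(5, 9, 20), c(5, 9, 20), 0),
               c(TP = 3, FP = 0, FN = 0))
  expect_equal(match_spikes(c(5, 9), c(50, 90), 1),
               c(TP = 0, FP = 2, FN = 2))
  # the documented enumeration case: truths {10, 12}, estimates {11}, tol 1
  expect_equal(match_spikes(c(10, 12), 11, 1), c(TP = 1, FP = 0, FN = 1))
  expect_equal(match_spikes(integer(0), c(3, 4), 1),
               c(TP = 0, FP = 2, FN = 0))
  # nearest pairs are matched first (greedy, not globally optimal): the
  # exact (11, 11) pair wins, leaving 10 and 12 too far from each other
  expect_equal(match_spikes(c(10, 11), c(11, 12), 1),
               c(TP = 1, FP = 1, FN = 1))
})

test_that("ROI matching counts pixel confusion under component pairing", {
  m <- matrix(FALSE, 16, 2)
  m[1:4, 1] <- TRUE
  m[9:12, 2] <- TRUE
  same <- match_rois(m, m)
  expect_true(all(same$FP == 0 & same$FN == 0))
  expect_equal(same$TP, c(4, 4))

  disj <- matrix(FALSE, 16, 2)
  disj[5:8, 1] <- TRUE
  disj[13:16, 2] <- TRUE
  r <- match_rois(m, disj)
  expect_true(all(r$TP == 0))

  half <- m
  half[1:2, 1] <- FALSE
  half[15:16, 1] <- TRUE  # half overlapping, equal size
  r2 <- match_rois(m[, 1, drop = FALSE], half[, 1, drop = FALSE])
  expect_equal(unname(r2$TP / (r2$TP + r2$FP)), 0.5)
  expect_equal(unname(r2$TP / (r2$TP + r2$FN)), 0.5)
  expect_error(match_rois(m, m[1:8, ]), "pixel grids")
})

test_that("chi-squared threshold detection uses the standardized square", {
  expect_warning(out <- threshold_spike_detect(rep(1, 50)), "constant")
  expect_length(out, 0)

  tr <- rep(0, 200)
  tr[77] <- 100
  expect_equal(threshold_spike_detect(tr), 77L)

  # nominal false-positive calibration on a Gaussian null: the squared
  # standardized value exceeds the chi2_1 upper-alpha quantile with
  # probability alpha
  set.seed(5)
  n <- 2e5
  hits <- length(threshold_spike_detect(rnorm(n), 0.001))
  expect_lt(abs(hits - n * 0.001), 3 * sqrt(n * 0.001))
  # the cutoff is computed, not hard-coded: a different tail moves it
  tr2 <- rnorm(5000)
  expect_gt(length(threshold_spike_detect(tr2, 0.05)),
            length(threshold_spike_detect(tr2, 0.001)))
})

test_that("tuning-curve MLE recovers the generating parameters", {
  # spikes at a single stimulus value: location goes there
  R <- 500
  x <- seq(-2, 2, length.out = R)
  stim <- stimulus_series(x, delta = 0.1)
  at <- which.min(abs(x - 0.73))
  fit <- fit_tuning_mle(rep(at, 5) + 0:4, stim, "gaussian")
  expect_equal(fit$kernel$mu, 0.75, tolerance = 0.1)

  # profile rate identity: lambda_hat = n / (T mean f)
  n <- 8
  mf <- mean(dstim(stim$values, fit$kernel))
  expect_equal(fit$rate, length(rep(at, 5) + 0:4) / (stim$T * mf),
               tolerance = 1e-8)
  expect_error(fit_tuning_mle(integer(0), stim), "at least one")
})

test_that("pooled point-process likelihood follows its closed identities", {
  R <- 300
  stim <- stimulus_series(seq(-1.5, 1.5, length.out = R), delta = 0.1)
  tun <- list(list(rate = 2, kernel = stim_kernel("gaussian", 0, 2)),
              list(rate = 1, kernel = stim_kernel("gaussian", 0.5, 4)))
  lam_bar <- mean(2 * dstim(stim$values, tun[[1]]$kernel) +
                    1 * dstim(stim$values, tun[[2]]$kernel))
  expect_equal(pp_loglik_given_spikes(integer(0), stim, tun),
               -stim$T * lam_bar)

  spikes <- c(120, 150, 160, 190)
  ll <- pp_loglik_given_spikes(spikes, stim, tun)
  tun2 <- lapply(tun, function(tc) { tc$rate <- 2 * tc$rate; tc })
  ll2 <- pp_loglik_given_spikes(spikes, stim, tun2)
  expect_equal(ll2 - ll, length(spikes) * log(2) - stim$T * lam_bar,
               tolerance = 1e-10)

  # concave in the rates: numeric second derivative is negative
  f <- function(r) {
    t3 <- tun; t3[[1]]$rate <- r
    pp_loglik_given_spikes(spikes, stim, t3)
  }
  h <- 1e-3
  second <- (f(2 + h) - 2 * f(2) + f(2 - h)) / h^2
  expect_lt(second, 0)

  # true tuning scores above a stimulus-shuffled tuning on simulated spikes
  sim <- tiny_scene(seed = 12, n_neurons = 2)
  tun_true <- lapply(seq_len(2), function(k)
    list(rate = sim$truth$model$rates[k],
         kernel = sim$truth$model$stim_kernels[[k]]))
  pooled <- sort(sim$truth$marks$frames)
  ll_true <- pp_loglik_given_spikes(pooled, sim$stim, tun_true)
  set.seed(1)
  stim_sh <- sim$stim
  stim_sh$values <- sample(stim_sh$values)
  ll_sh <- pp_loglik_given_spikes(pooled, stim_sh, tun_true)
  expect_gt(ll_true, ll_sh)
})

test_that("correlation image highlights co-fluctuating pixels", {
  h <- 8; w <- 9
  expect_true(all(correlation_image(matrix(2, 40, h * w), h, w) == 0))

  set.seed(7)
  noise <- matrix(rnorm(200 * h * w), 200)
  ci_noise <- correlation_image(noise, h, w)
  expect_lt(max(abs(ci_noise)), 0.35)
  expect_lt(abs(mean(ci_noise)), 0.02)

  # one blinking blob: elevated exactly on the blob pixels
  blink <- noise * 0.2
  blob_px <- as.integer(outer(3:5, (2:4 - 1) * w, "+"))  # rows 2..4, cols 3..5
  trace <- rep(c(0, 5), length.out = 200)
  blink[, blob_px] <- blink[, blob_px] + trace
  ci <- correlation_image(blink, h, w)
  on <- matrix(FALSE, h, w)
  on[2:4, 3:5] <- TRUE
  expect_gt(ci[3, 4], 0.9)          # interior blob pixel: all neighbours blink
  expect_gt(min(ci[on]), 0.25)      # blob corners still clearly elevated
  expect_gt(mean(ci[on]), mean(ci[!on]) + 0.4)
  expect_lt(max(ci[!on]), 0.35)
})

test_that("deconvolution scoring matches hand-computed F on a constructed case", {
  sim <- tiny_scene(seed = 13)
  post <- mpp_fit(sim$movie, sim$stim, d_kappa = 10, K = 6, n_iter = 6,
                  seed = 13)
  dec <- deconvolve(post, sim$stim)
  ev <- evaluate_deconvolution(sim$truth, dec)
  expect_s3_class(ev, "mpp_evaluation")
  expect_true(all(ev$spike_f_per_component >= 0 &
                    ev$spike_f_per_component <= 1))
  expect_true(all(ev$roi_f_per_component >= 0 & ev$roi_f_per_component <= 1))
  # injective matching
  mm <- ev$matching[!is.na(ev$matching)]
  expect_false(any(duplicated(mm)))

  # perfect self-match: feeding the truth back scores F = 1 on spikes
  self <- dec
  self$spikes <- sim$truth$spikes_per_component
  self$footprints <- sim$truth$footprints
  self$roi_masks <- apply(sim$truth$footprints, 2, function(v)
    v > 0.7 * max(v))
  ev_self <- evaluate_deconvolution(sim$truth, self)
  expect_equal(ev_self$spike_f_mean, 1)
  expect_equal(ev_self$roi_f_mean, 1)
})
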