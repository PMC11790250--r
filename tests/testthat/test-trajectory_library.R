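# Library learning: filtering, extraction, warping, averaging, smoothing,
# assembly, and section adaptation.

test_that("Gaussian filtering matches the unit-area kernel definition", {
  sigma <- 25
  counts <- numeric(1001); counts[501] <- 1     # single spike mid-trial
  r <- gaussian_filter_rates(counts, sigma)
  expect_equal(r[501], 1000 / (sigma * sqrt(2 * pi)), tolerance = 1e-4)
  expect_equal(which.max(r), 501L)
  expect_equal(sum(r) / 1000, 1, tolerance = 1e-6)  # unit area in spikes
  # edge renormalization: a constant-rate stream stays flat at the borders
  flat <- gaussian_filter_rates(rep(1, 300), sigma)
  expect_equal(flat, rep(1000, 300), tolerance = 1e-9)
})

test_that("window extraction yields the configured trajectory length", {
  trials <- toy_trials(T = 1400, tmove = 400)
  # the -350..+750 ms window around movement onset spans 1101 samples
  cfg <- training_config(sigma_ms = 25, window_start = -350, window_end = 750)
  tens <- build_rates_from_trials(trials, cfg)
  expect_true(all(vapply(tens, `[[`, integer(1), "Kc") == 1101L))
  expect_equal(dim(tens[[1]]$rates), c(3L, 1101L, 4L))
  expect_equal(dim(tens[[1]]$behavior), c(2L, 1101L, 4L))
})

test_that("extraction errors are labeled", {
  trials <- toy_trials(T = 700, tmove = 300)
  expect_error(build_rates_from_trials(trials,
    training_config(window_start = -350, window_end = 300)),
    "trial 1.*exceeds trial extent")
  expect_error(build_rates_from_trials(trials,
    training_config(align_event = "tgo", window_start = -10, window_end = 10)),
    "missing alignment event 'tgo'")
})

test_that("uniform warp resamples to the median duration, matching a linear oracle", {
  set.seed(3)
  N <- 2
  mk_trial <- function(Tlen) {
    list(spikes = matrix(rpois(N * Tlen, 0.02), N, Tlen),
         behavior = matrix(rnorm(2 * Tlen), 2, Tlen))
  }
  t1 <- mk_trial(900); t2 <- mk_trial(1100)
  trials <- trial_set(list(t1$spikes, t2$spikes),
                      list(t1$behavior, t2$behavior),
                      condition = c(1L, 1L),
                      events = list(c(tstart = 0, tstop = 899),
                                    c(tstart = 0, tstop = 1099)))
  cfg <- training_config(sigma_ms = 20, window_start = 0, window_end = 0,
                         align_event = "tstart", end_event = "tstop",
                         warp_mode = "uniform")
  tens <- build_rates_from_trials(trials, cfg)
  expect_equal(tens[[1]]$Kc, 1000L)
  # independent linear-interpolation oracle via approx()
  raw <- gaussian_filter_rates(t2$spikes[1, ], 20)
  oracle <- approx(seq_along(raw), raw, xout = seq(1, length(raw), length.out = 1000))$y
  expect_equal(tens[[1]]$rates[1, , 2], oracle, tolerance = 1e-10)
})

test_that("Type I and Type II averaging agree on identical trials and R = 1", {
  set.seed(7)
  one <- matrix(runif(5 * 30, 0, 40), 5, 30)
  tens <- list(list(rates = array(rep(one, 6), dim = c(5, 30, 6))))
  t1 <- average_trials(tens, "TypeI")
  t2 <- average_trials(tens, "TypeII")
  expect_equal(t1[[1]], one)
  expect_equal(t2[[1]], one, tolerance = 1e-10)
  single <- list(list(rates = array(one, dim = c(5, 30, 1))))
  expect_equal(average_trials(single, "TypeII")[[1]], one, tolerance = 1e-10)
})

test_that("Type II averaging matches an explicit SVD oracle", {
  set.seed(42)
  N <- 5; K <- 20; R <- 8
  tens <- list(list(rates = array(runif(N * K * R, 0, 50), dim = c(N, K, R))),
               list(rates = array(runif(N * K * R, 0, 50), dim = c(N, K, R))))
  cfg <- training_config(soft_norm_constant = 5)
  got <- average_trials(tens, "TypeII", cfg)

  # oracle: explicit soft-norm from Type I averages, rank-1 SVD, reversal
  typeI <- lapply(tens, function(e) apply(e$rates, c(1, 2), mean))
  cat_t1 <- do.call(cbind, typeI)
  rng <- apply(cat_t1, 1, function(r) diff(range(r)))
  sc <- 1 / (rng + 5)
  off <- rowMeans(cat_t1 * sc)
  for (ci in 1:2) {
    X <- tens[[ci]]$rates
    Xn <- X * sc - off
    Xin <- t(matrix(Xn, N * K, R))
    sv <- svd(Xin)
    Xout <- sv$u[, 1, drop = FALSE] %*% t(sv$u[, 1, drop = FALSE]) %*% Xin
    rec <- array(t(Xout), dim = c(N, K, R))
    rec <- (rec + off) / sc
    expect_equal(got[[ci]], apply(rec, c(1, 2), mean), tolerance = 1e-10)
  }
})

test_that("averaging rejects degenerate inputs", {
  expect_error(average_trials(list(list(rates = array(0, c(2, 3, 0))))), "R >= 1")
  bad <- array(c(NaN, runif(11)), c(2, 3, 2))
  expect_error(average_trials(list(list(rates = bad))), "non-finite")
})

test_that("full-dimensional smoothing is the identity and projections are idempotent", {
  lib <- random_library(N = 6, C = 3, K = 40, seed = 2)
  sm <- smooth_library(lib$rates, training_config(d_neural = "full",
                                                  d_condition = "full"))
  expect_equal(sm, lib$rates, tolerance = 1e-10)

  cfg2 <- training_config(d_neural = 2, d_condition = "full")
  once <- smooth_library(lib$rates, cfg2, rectify = FALSE)
  twice <- smooth_library(once, cfg2, rectify = FALSE)
  expect_equal(twice, once, tolerance = 1e-8)
  # variance non-increasing under the projection
  v_in <- sum(do.call(cbind, lib$rates)^2)
  expect_lte(sum(do.call(cbind, once)^2), v_in * (1 + 1e-12))
})

test_that("neuron smoothing matches an independent PCA oracle", {
  lib <- random_library(N = 6, C = 3, K = 30, tau = 19, seed = 9)
  cfg <- training_config(d_neural = 2, d_condition = "full",
                         soft_norm_constant = 5)
  got <- smooth_library(lib$rates, cfg, rectify = FALSE)
  X <- do.call(cbind, lib$rates)
  rng <- apply(X, 1, function(r) diff(range(r)))
  sc <- 1 / (rng + 5); off <- rowMeans(X * sc)
  Xn <- X * sc - off
  W <- svd(Xn)$u[, 1:2]
  Xo <- (W %*% (t(W) %*% Xn) + off) / sc
  expect_equal(do.call(cbind, got), Xo, tolerance = 1e-10)
})

test_that("condition smoothing is skipped with a warning when Kc differ", {
  set.seed(1)
  rates <- list(matrix(runif(40, 0, 30), 4, 10), matrix(runif(48, 0, 30), 4, 12))
  expect_warning(smooth_library(rates, training_config(d_condition = 1)),
                 "condition smoothing skipped")
  expect_error(smooth_library(list(matrix(runif(40), 4, 10)),
                              training_config(d_neural = 10)),
               "exceeds neuron count")
})

test_that("circular behavior averaging handles wrap, equivariance, and matches its oracle", {
  # two near-constant traces at 350 and 10 degrees -> mean at 0, not 180
  K <- 50
  z <- array(0, c(1, K, 2))
  z[1, , 1] <- 350 * pi / 180
  z[1, , 2] <- 10 * pi / 180
  avg <- average_behavior(list(list(behavior = z)), circular = TRUE)[[1]]
  expect_equal(max(abs(circ_dist(avg[1, ], 0))), 0, tolerance = 1e-10)

  # rotation equivariance and the unwrap-average-rewrap oracle
  set.seed(4)
  R <- 5
  base <- cumsum(rnorm(K, 0.05, 0.02))            # smooth increasing phase
  lat <- sapply(seq_len(R), function(r) base + rnorm(1, 0, 0.3) + cumsum(rnorm(K, 0, 0.01)))
  zz <- array(wrap_angle(lat), c(1, K, R))
  zz[1, , ] <- wrap_angle(t(t(lat)))
  got <- average_behavior(list(list(behavior = zz)), circular = TRUE)[[1]]
  oracle <- wrap_angle(rowMeans(lat))             # truth from unwrapped latents
  expect_equal(max(abs(circ_dist(got[1, ], oracle))), 0, tolerance = 1e-10)

  th <- 1.23
  rot <- zz; rot[1, , ] <- wrap_angle(zz[1, , ] + th)
  got_rot <- average_behavior(list(list(behavior = rot)), circular = TRUE)[[1]]
  expect_equal(max(abs(circ_dist(got_rot[1, ], got[1, ] + th))), 0,
               tolerance = 1e-10)
})

test_that("library assembly enforces invariants and exposes the state mask", {
  lib <- tiny_library(K = 1000, tau = 299)
  mask <- valid_state_mask(lib)
  expect_equal(sum(mask[[1]]), 701L)
  # iterating the state-transition lookup tau times lands at k - tau
  k <- 1000L
  for (i in seq_len(299)) k <- state_transition(lib, 1L, k)
  expect_equal(k, 1000L - 299L)
  expect_error(assemble_library(lib$rates, lib$behavior, tau = 1200),
               "no valid states")
  bad <- lib$rates; bad[[1]][1, 1] <- -1
  expect_error(assemble_library(bad, lib$behavior, tau = 10), "non-negative")
  expect_error(assemble_library(lib$rates, lib$behavior[1], tau = 10),
               "same number of conditions")
})

test_that("section adaptation satisfies its limits and matches a normal-equation oracle", {
  lib <- random_library(N = 4, C = 2, K = 30, tau = 19, seed = 21)
  X <- do.call(cbind, lib$rates)

  # identity-inducing inputs return the session library
  same <- list(lib$rates)
  ad <- adapt_library_sections(lib, same, section_adapt_config(ridge_lambda = 1))
  expect_equal(do.call(cbind, ad[[1]]$rates), X, tolerance = 1e-8)

  # huge lambda: adapted rates = session rates + per-section mean residual
  set.seed(22)
  Y <- lapply(lib$rates, function(m) m + matrix(rnorm(length(m), 2, 1), nrow(m)))
  ad2 <- adapt_library_sections(lib, list(Y),
                                section_adapt_config(ridge_lambda = 1e12,
                                                     rectify = FALSE))
  mu1 <- rowMeans(do.call(cbind, Y) - X)
  expect_equal(do.call(cbind, ad2[[1]]$rates), X + mu1, tolerance = 1e-6)

  # closed form matches a brute-force weighted least-squares oracle
  w <- rep(c(1, 4), length.out = ncol(X))        # designated-epoch weighting
  lambda <- 100
  cfgA <- section_adapt_config(ridge_lambda = lambda, epoch_weights = w,
                               rectify = FALSE)
  got <- do.call(cbind, adapt_library_sections(lib, list(Y), cfgA)[[1]]$rates)
  rng <- apply(X, 1, function(r) diff(range(r)))
  Lm <- diag(1 / (rng + 5))
  P <- Lm %*% X - rowMeans(Lm %*% X)
  Qd <- (do.call(cbind, Y) - X) - rowMeans(do.call(cbind, Y) - X)
  S <- diag(w)
  W <- Qd %*% S %*% t(P) %*% solve(P %*% S %*% t(P) + lambda * diag(nrow(X)))
  b <- rowMeans(do.call(cbind, Y) - X) - W %*% rowMeans(Lm %*% X)
  oracle <- (W %*% Lm + diag(nrow(X))) %*% X + as.vector(b)
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("learn_library runs the full pipeline and keeps rates non-negative", {
  trials <- toy_trials(N = 4, C = 2, R = 3, T = 700, tmove = 300)
  cfg <- training_config(sigma_ms = 20, window_start = -200, window_end = 300,
                         averaging_mode = "TypeII", d_neural = 3)
  lib <- learn_library(trials, cfg, tau = 99, delta_ms = 20)
  expect_s3_class(lib, "trajectory_library")
  expect_equal(lib$Kc, c(501L, 501L))
  expect_true(all(vapply(lib$rates, function(m) all(m >= 0), logical(1))))
  expect_equal(lib$behavior_names, c("pos", "osc"))
})
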