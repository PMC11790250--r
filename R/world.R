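# Trajectory-world generator: a low-dimensional latent world with known
# (condition, index, blend-weight) ground truth for recovery tests.

#' Configuration for a synthetic trajectory world
#'
#' @param n_neurons,n_conditions,duration_ms world dimensions (defaults
#'   100 neurons, 5 conditions, 1000 ms trajectories)
#' @param latent_dim latent dimensionality of each trajectory (default 3)
#' @param n_basis number of smooth temporal basis functions (default 4)
#' @param target_rate_mean mean firing rate target, spikes/s (default 20)
#' @param n_behaviors behavioral variables read out from the latents
#'   (default 2)
#' @return a `world_config` list
#' @export
world_config <- function(n_neurons = 100, n_conditions = 5, duration_ms = 1000,
                         latent_dim = 3, n_basis = 4, target_rate_mean = 20,
                         n_behaviors = 2) {
  structure(as.list(environment()), class = "world_config")
}

#' Build a synthetic world and labelled test trials
#'
#' Latent trajectories are smooth random curves (low-frequency sinusoidal
#' basis with random coefficients); rates are a softplus readout of random
#' neuron loadings, scaled to the target mean rate; behavior is a linear
#' readout of the latents. The library assembled from the noiseless rates
#' equals the generative rates exactly. Test trials come in three kinds,
#' each with per-millisecond ground-truth (condition, index, alpha) labels:
#' exact replays, uniformly time-dilated replays (+/- 10-20%), and fixed-
#' alpha blends of two conditions' rates (alpha defined on expected counts,
#' matching the interpolation model).
#'
#' @param config a [world_config()]
#' @param seed RNG seed; all outputs are reproducible from it
#' @param n_replays,n_dilated,n_blends test-trial counts per kind
#' @param blend_alphas alphas used for blend trials (recycled)
#' @param tau history extent for the assembled library (default 299,
#'   i.e. a 300 ms window)
#' @return a `synthetic_world`: `library`, `rates` (per condition),
#'   `behavior`, `trials` (each with `counts`, `kind`, and ground truth
#'   `c1`, `c2`, `alpha`, `k_schedule`), and the generator internals
#' @export
make_world_and_trials <- function(config = world_config(), seed = 1,
                                  n_replays = 5, n_dilated = 3, n_blends = 5,
                                  blend_alphas = c(0.25, 0.5, 0.75),
                                  tau = 299) {
  set.seed(seed)
  C <- config$n_conditions; N <- config$n_neurons
  Tlen <- config$duration_ms; d <- config$latent_dim
  tt <- seq_len(Tlen) / Tlen
  basis <- sapply(seq_len(config$n_basis), function(b)
    sin(pi * b * tt + stats::runif(1, 0, pi)))
  loadings <- matrix(stats::rnorm(N * d), N, d)
  beh_map <- matrix(stats::rnorm(config$n_behaviors * d), config$n_behaviors, d)

  # Condition structure: latent basis coefficients vary smoothly around a
  # ring of conditions (as reaches to neighboring targets do), plus a small
  # idiosyncratic per-condition component. Neighboring conditions therefore
  # have similar trajectories and blends of neighbors stay near the mesh.
  coefA <- matrix(stats::rnorm(d * config$n_basis), config$n_basis, d)
  coefB <- matrix(stats::rnorm(d * config$n_basis), config$n_basis, d)
  coefG <- matrix(stats::rnorm(d * config$n_basis), config$n_basis, d)

  softplus <- function(x) log1p(exp(x))
  rates <- vector("list", C); behavior <- vector("list", C)
  for (c in seq_len(C)) {
    th <- 2 * pi * (c - 1L) / C
    coefs <- coefA * cos(th) + coefB * sin(th) + coefG +
      0.3 * matrix(stats::rnorm(d * config$n_basis), config$n_basis, d)
    lat <- t(basis %*% coefs)                     # d x T
    drive <- loadings %*% lat                     # N x T
    drive <- (drive - rowMeans(drive)) / pmax(apply(drive, 1, stats::sd), 1e-9)
    r <- softplus(drive)
    rates[[c]] <- r * config$target_rate_mean / mean(r)
    behavior[[c]] <- beh_map %*% lat
  }
  library <- assemble_library(rates, behavior, tau = tau, delta_ms = 20)

  trials <- list(); i <- 0L
  mk <- function(counts, kind, c1, c2, alpha, k_schedule) {
    list(counts = counts, kind = kind, c1 = c1, c2 = c2, alpha = alpha,
         k_schedule = k_schedule)
  }
  for (r in seq_len(n_replays)) {
    c1 <- ((r - 1L) %% C) + 1L
    i <- i + 1L
    trials[[i]] <- mk(.sample_spikes_one(rates[[c1]], spiking_model("poisson")),
                      "replay", c1, NA_integer_, 0, seq_len(Tlen))
  }
  for (r in seq_len(n_dilated)) {
    c1 <- ((r - 1L) %% C) + 1L
    f <- sample(c(-1, 1), 1) * stats::runif(1, 0.10, 0.20) + 1
    Td <- round(Tlen * f)
    sched <- pmin(pmax(round(seq_len(Td) / f), 1L), Tlen)
    i <- i + 1L
    trials[[i]] <- mk(.sample_spikes_one(rates[[c1]][, sched, drop = FALSE],
                                         spiking_model("poisson")),
                      "dilated", c1, NA_integer_, 0, sched)
  }
  for (r in seq_len(n_blends)) {
    c1 <- ((r - 1L) %% C) + 1L
    c2 <- (c1 %% C) + 1L
    alpha <- blend_alphas[((r - 1L) %% length(blend_alphas)) + 1L]
    blended <- (1 - alpha) * rates[[c1]] + alpha * rates[[c2]]
    i <- i + 1L
    trials[[i]] <- mk(.sample_spikes_one(blended, spiking_model("poisson")),
                      "blend", c1, c2, alpha, seq_len(Tlen))
  }
  structure(list(
    library = library, rates = rates, behavior = behavior, trials = trials,
    config = config, seed = seed, loadings = loadings, beh_map = beh_map
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  kinds <- table(vapply(x$trials, `[[`, character(1), "kind"))
  cat(sprintf("<synthetic_world> %d conditions, %d neurons, %d ms; test trials: %s\n",
              x$config$n_conditions, x$config$n_neurons, x$config$duration_ms,
              paste(names(kinds), kinds, sep = "=", collapse = ", ")))
  invisible(x)
}
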