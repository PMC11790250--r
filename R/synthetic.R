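# Synthetic spiking/behavior data with known ground truth: reach-like
# kinematics, rates as random affine functions of z-scored kinematics, and
# Poisson or gamma-interval spike sampling.

#' Generate smooth reach-like kinematic trials
#'
#' Minimum-jerk reaches from the origin to per-condition targets equally
#' spaced on a circle, with trial-to-trial jitter in amplitude and movement
#' duration. Velocity and acceleration are the analytic derivatives of
#' position.
#'
#' @param n_conditions number of reach directions
#' @param n_trials trials per condition
#' @param duration_ms trial length (default 1200); movement onset at
#'   `onset_ms` (default 400), nominal movement duration `move_ms`
#'   (default 600)
#' @param amplitude_mm reach amplitude (default 80)
#' @param amp_jitter_sd,dur_jitter_sd trial-to-trial multiplicative jitter
#'   SDs for amplitude and duration (default 0.05 each)
#' @param onset_ms,move_ms movement onset and nominal duration in ms
#' @param seed RNG seed
#' @return list with `trials` (per trial: `kin` 6 x T matrix with rows
#'   px, py, vx, vy, ax, ay), `condition`, `events` (tmove per trial),
#'   `targets` (n_conditions x 2)
#' @export
generate_kinematics <- function(n_conditions, n_trials, duration_ms = 1200,
                                amplitude_mm = 80, amp_jitter_sd = 0.05,
                                dur_jitter_sd = 0.05, onset_ms = 400,
                                move_ms = 600, seed = 1) {
  stopifnot(n_conditions >= 1, n_trials >= 1, duration_ms > onset_ms + 10)
  set.seed(seed)
  ang <- 2 * pi * (seq_len(n_conditions) - 1L) / n_conditions
  targets <- amplitude_mm * cbind(cos(ang), sin(ang))
  trials <- list(); condition <- integer(0); events <- list()
  i <- 0L
  for (c in seq_len(n_conditions)) {
    for (r in seq_len(n_trials)) {
      i <- i + 1L
      amp <- stats::rnorm(1, 1, amp_jitter_sd)
      dur <- max(100, round(move_ms * stats::rnorm(1, 1, dur_jitter_sd)))
      dur <- min(dur, duration_ms - onset_ms - 1L)
      tt <- seq_len(duration_ms) - 1L         # sample times, ms
      s <- pmin(pmax((tt - onset_ms) / dur, 0), 1)
      # minimum-jerk position profile and its exact time derivatives
      pos_p <- 10 * s^3 - 15 * s^4 + 6 * s^5
      vel_p <- (30 * s^2 - 60 * s^3 + 30 * s^4) / dur * 1000      # per s
      acc_p <- (60 * s - 180 * s^2 + 120 * s^3) / dur^2 * 1e6     # per s^2
      moving <- s > 0 & s < 1
      vel_p[!moving] <- 0; acc_p[!moving] <- 0
      tgt <- amp * targets[c, ]
      kin <- rbind(px = tgt[1] * pos_p, py = tgt[2] * pos_p,
                   vx = tgt[1] * vel_p, vy = tgt[2] * vel_p,
                   ax = tgt[1] * acc_p, ay = tgt[2] * acc_p)
      trials[[i]] <- list(kin = kin)
      condition[i] <- c
      events[[i]] <- c(tmove = onset_ms)
    }
  }
  list(trials = trials, condition = condition, events = events,
       targets = targets, onset_ms = onset_ms, duration_ms = duration_ms)
}

#' Kinematic encoding model
#'
#' @param n_neurons number of simulated neurons
#' @param target_rate_mean,target_rate_sd per-neuron firing-rate mean and
#'   SD targets in spikes/s (defaults 20 and 8, typical of motor cortical
#'   units; the SD keeps the pre-rectification rate mass essentially
#'   non-negative)
#' @param rate_multiplier overall rate scaling (1, 5 or 10 in the source
#'   simulations; default 1)
#' @param seed RNG seed for the random weights
#' @return an object of class `encoding_model` with `weights` (N x 6) and
#'   `offsets` (N)
#' @export
encoding_model <- function(n_neurons, target_rate_mean = 20, target_rate_sd = 8,
                           rate_multiplier = 1, seed = 1) {
  set.seed(seed)
  structure(list(
    weights = matrix(stats::rnorm(n_neurons * 6), n_neurons, 6),
    offsets = rep(target_rate_mean, n_neurons),
    target_rate_mean = target_rate_mean, target_rate_sd = target_rate_sd,
    rate_multiplier = rate_multiplier
  ), class = "encoding_model")
}

#' Simulate firing rates as affine functions of z-scored kinematics
#'
#' Kinematic channels are z-scored across all trials and samples; each
#' neuron's raw drive is its random weighted sum of the z-scored kinematics;
#' the drive is rescaled per neuron so that the firing-rate mean and SD hit
#' the model's targets, then rectified at 0 and scaled by `rate_multiplier`.
#'
#' @param kinematics output of [generate_kinematics()]
#' @param model an [encoding_model()]
#' @return list of per-trial N x T rate matrices (spikes/s)
#' @export
simulate_rates <- function(kinematics, model) {
  K <- do.call(cbind, lapply(kinematics$trials, function(tr) tr$kin))
  mu <- rowMeans(K); sd <- apply(K, 1L, stats::sd)
  if (any(sd == 0)) .stopf("zero-variance kinematic channel; cannot z-score")
  lens <- vapply(kinematics$trials, function(tr) ncol(tr$kin), integer(1))
  drive <- model$weights %*% ((K - mu) / sd)
  dmu <- rowMeans(drive); dsd <- apply(drive, 1L, stats::sd)
  dsd[dsd == 0] <- 1                         # zero weights -> constant offset
  rates <- (drive - dmu) / dsd * model$target_rate_sd + model$offsets
  rates <- pmax(rates, 0) * model$rate_multiplier
  ends <- cumsum(lens); starts <- ends - lens + 1L
  lapply(seq_along(lens), function(i) rates[, starts[i]:ends[i], drop = FALSE])
}

#' Spiking model
#'
#' @param kind "poisson" (exponential-interval) or "gamma_interval"
#'   (inter-spike intervals gamma with shape 2 and rate 2*lambda, giving the
#'   same long-run rate but more regular spiking)
#' @param gamma_shape shape parameter for gamma-interval spiking (default 2)
#' @return an object of class `spiking_model`
#' @export
spiking_model <- function(kind = c("poisson", "gamma_interval"), gamma_shape = 2) {
  kind <- match.arg(kind)
  structure(list(kind = kind, gamma_shape = gamma_shape), class = "spiking_model")
}

#' Sample spike trains from time-varying rates
#'
#' Poisson spiking draws independent per-millisecond Poisson counts with
#' mean rate/1000 (exact for an inhomogeneous Poisson process at 1 kHz
#' resolution). Gamma-interval spiking time-rescales a unit-mean gamma
#' renewal process (shape a, rate a) through the cumulative intensity, so a
#' constant rate lambda yields ISIs ~ Gamma(a, a*lambda).
#'
#' @param rates N x T matrix (spikes/s) or list of such matrices (per trial)
#' @param model a [spiking_model()]
#' @param seed RNG seed
#' @return counts matrix/list matching the input shape
#' @export
sample_spikes <- function(rates, model = spiking_model(), seed = 1) {
  set.seed(seed)
  if (is.list(rates)) {
    out <- vector("list", length(rates))
    for (i in seq_along(rates)) out[[i]] <- .sample_spikes_one(rates[[i]], model)
    return(out)
  }
  .sample_spikes_one(rates, model)
}

.sample_spikes_one <- function(rates, model) {
  rates <- as.matrix(rates)
  if (any(rates < 0)) .stopf("negative rates")
  N <- nrow(rates); Tlen <- ncol(rates)
  out <- matrix(0L, N, Tlen)
  if (model$kind == "poisson") {
    out[] <- stats::rpois(N * Tlen, as.vector(rates) / 1000)
    return(out)
  }
  a <- model$gamma_shape
  for (n in seq_len(N)) {
    cum <- cumsum(rates[n, ] / 1000)          # cumulative intensity per sample
    tot <- cum[Tlen]
    if (tot <= 0) next
    # unit-mean gamma renewal thresholds in rescaled time
    n_max <- max(10, ceiling(tot + 6 * sqrt(tot)))
    thr <- cumsum(stats::rgamma(n_max, shape = a, rate = a))
    while (thr[length(thr)] < tot)
      thr <- c(thr, thr[length(thr)] + cumsum(stats::rgamma(n_max, shape = a, rate = a)))
    thr <- thr[thr <= tot]
    if (length(thr) == 0L) next
    idx <- findInterval(thr, cum, left.open = TRUE) + 1L
    tb <- tabulate(idx, nbins = Tlen)
    out[n, ] <- tb
  }
  out
}
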