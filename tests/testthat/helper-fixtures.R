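# Small in-code fixtures used across test files.

# A tiny deterministic library: C conditions of smooth positive rates.
tiny_library <- function(N = 4, C = 2, K = 120, tau = 39, delta_ms = 20,
                         M = 2, circular = rep(FALSE, M), seed = 11) {
  set.seed(seed)
  tt <- seq_len(K) / K
  rates <- lapply(seq_len(C), function(c) {
    t(sapply(seq_len(N), function(n)
      20 + 15 * sin(2 * pi * (tt + n / N + c / C)) + 2 * n))
  })
  behavior <- lapply(seq_len(C), function(c) {
    b <- t(sapply(seq_len(M), function(m) cos(2 * pi * (tt + m / M)) * c))
    if (any(circular)) b[circular, ] <- wrap_angle(b[circular, , drop = FALSE] * pi)
    b
  })
  assemble_library(rates, behavior, tau = tau, delta_ms = delta_ms,
                   circular = circular)
}

# Random library with arbitrary positive rates (for property tests).
random_library <- function(N = 5, C = 3, K = 100, tau = 39, delta_ms = 20,
                           seed = 1, max_rate = 60) {
  set.seed(seed)
  rates <- lapply(seq_len(C), function(c)
    matrix(stats::runif(N * K, 0, max_rate), N, K))
  behavior <- lapply(seq_len(C), function(c) matrix(stats::rnorm(2 * K), 2, K))
  assemble_library(rates, behavior, tau = tau, delta_ms = delta_ms)
}

# Random spike stream at 1 kHz.
random_stream <- function(N, T, seed = 1, rate = 30) {
  set.seed(seed)
  matrix(stats::rpois(N * T, rate / 1000), N, T)
}

# Poisson stream replaying a library condition's rates.
replay_stream <- function(library, c, seed = 1) {
  set.seed(seed)
  R <- library$rates[[c]]
  matrix(stats::rpois(length(R), as.vector(R) / 1000), nrow(R), ncol(R))
}

# Minimal trial_set: constant-ish rates per condition plus behavior ramps.
toy_trials <- function(N = 3, C = 2, R = 4, T = 700, tmove = 300, seed = 5) {
  set.seed(seed)
  spikes <- list(); behavior <- list(); condition <- integer(0); events <- list()
  i <- 0L
  for (c in seq_len(C)) for (r in seq_len(R)) {
    i <- i + 1L
    lam <- (10 + 5 * c) * (1 + 0.3 * sin(2 * pi * seq_len(T) / T + c))
    spikes[[i]] <- t(sapply(seq_len(N), function(n)
      stats::rpois(T, lam * (0.5 + n / N) / 1000)))
    behavior[[i]] <- rbind(seq_len(T) / T * c, cos(2 * pi * seq_len(T) / T) * c)
    condition[i] <- c
    events[[i]] <- c(tmove = tmove)
  }
  trial_set(spikes, behavior, condition, events,
            behavior_names = c("pos", "osc"))
}
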