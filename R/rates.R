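# Single-trial rate estimation: Gaussian filtering, window extraction,
# uniform time-warping, and formatting into per-condition tensors.

#' Gaussian-filter a spike count sequence into a firing rate
#'
#' Convolves 1 kHz spike counts with a Gaussian kernel (standard deviation
#' `sigma_ms`, truncated at +/- 4 sigma) and rescales to spikes/s. Near trial
#' boundaries the kernel is renormalized over the in-range portion so rates do
#' not dip spuriously at the edges.
#'
#' @param counts numeric vector (or N x T matrix) of per-millisecond counts
#' @param sigma_ms Gaussian standard deviation in ms
#' @return rates in spikes/s, same shape as `counts`
#' @export
gaussian_filter_rates <- function(counts, sigma_ms) {
  .check_scalar_num(sigma_ms, "sigma_ms", lower = 1e-9)
  if (is.matrix(counts)) {
    out <- counts
    for (n in seq_len(nrow(counts))) out[n, ] <- gaussian_filter_rates(counts[n, ], sigma_ms)
    return(out)
  }
  half <- ceiling(4 * sigma_ms)
  kern <- exp(-((-half:half)^2) / (2 * sigma_ms^2))
  Tlen <- length(counts)
  num <- stats::convolve(counts, rev(kern), type = "open")
  den <- stats::convolve(rep(1, Tlen), rev(kern), type = "open")
  keep <- (half + 1L):(half + Tlen)
  1000 * num[keep] / den[keep]
}

# Linear resampling of each row of a matrix to n_out samples.
resample_linear <- function(x, n_out) {
  n_in <- ncol(x)
  if (n_in < 2L) .stopf("cannot resample a trace with fewer than 2 samples")
  pos <- seq(1, n_in, length.out = n_out)
  lo <- pmin(floor(pos), n_in - 1L)
  w <- pos - lo
  x[, lo, drop = FALSE] * rep(1 - w, each = nrow(x)) +
    x[, lo + 1L, drop = FALSE] * rep(w, each = nrow(x))
}

#' Filter, extract and align training trials into per-condition tensors
#'
#' Filters each trial's spikes into 1 kHz single-trial rates, extracts the
#' configured event-relative window from rates and behavior, optionally
#' time-warps trials uniformly (linear resampling to the per-condition median
#' duration), and stacks trials of the same condition into tensors.
#'
#' @param trials a [trial_set()]
#' @param cfg a [training_config()]
#' @return list with one element per condition, each containing `rates`
#'   (N x Kc x R array, spikes/s), `behavior` (M x Kc x R array), and `Kc`
#' @export
build_rates_from_trials <- function(trials, cfg) {
  stopifnot(inherits(trials, "trial_set"), inherits(cfg, "training_config"))
  C <- max(trials$condition)
  per_trial <- vector("list", trials$n_trials)
  for (i in seq_len(trials$n_trials)) {
    ev <- trials$events[[i]]
    if (!cfg$align_event %in% names(ev))
      .stopf("trial %d is missing alignment event '%s'", i, cfg$align_event)
    t0 <- ev[[cfg$align_event]] + cfg$window_start
    if (is.null(cfg$end_event)) {
      t1 <- ev[[cfg$align_event]] + cfg$window_end
    } else {
      if (!cfg$end_event %in% names(ev))
        .stopf("trial %d is missing alignment event '%s'", i, cfg$end_event)
      t1 <- ev[[cfg$end_event]] + cfg$window_end
    }
    Tlen <- ncol(trials$spikes[[i]])
    # window samples are 0-based times t0..t1 inclusive
    if (t0 < 0 || t1 >= Tlen || t1 < t0)
      .stopf("trial %d: extraction window [%s, %s] exceeds trial extent [0, %d)",
             i, t0, t1, Tlen)
    idx <- (t0:t1) + 1L
    rates <- gaussian_filter_rates(trials$spikes[[i]], cfg$sigma_ms)[, idx, drop = FALSE]
    beh <- trials$behavior[[i]][, idx, drop = FALSE]
    per_trial[[i]] <- list(rates = rates, behavior = beh)
  }

  out <- vector("list", C)
  for (c in seq_len(C)) {
    ids <- which(trials$condition == c)
    lens <- vapply(ids, function(i) ncol(per_trial[[i]]$rates), integer(1))
    if (cfg$warp_mode == "uniform") {
      if (any(lens < 2L))
        .stopf("condition %d: uniform warp requested but a trial has < 2 samples", c)
      Kc <- as.integer(round(stats::median(lens)))
      mats_r <- lapply(ids, function(i) resample_linear(per_trial[[i]]$rates, Kc))
      mats_b <- lapply(ids, function(i) resample_linear(per_trial[[i]]$behavior, Kc))
    } else {
      if (length(unique(lens)) != 1L)
        .stopf("condition %d: trials have unequal extracted lengths {%s}; use warp_mode='uniform' or a single-event window",
               c, paste(unique(lens), collapse = ","))
      Kc <- lens[1L]
      mats_r <- lapply(ids, function(i) per_trial[[i]]$rates)
      mats_b <- lapply(ids, function(i) per_trial[[i]]$behavior)
    }
    R <- length(ids)
    out[[c]] <- list(
      rates = array(unlist(mats_r), dim = c(trials$n_neurons, Kc, R)),
      behavior = array(unlist(mats_b), dim = c(trials$n_behaviors, Kc, R)),
      Kc = Kc
    )
  }
  out
}
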