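#' Trial-structured training data
#'
#' Bundles per-trial spiking activity, aligned behavioral time series,
#' condition labels, and named alignment events into a validated container.
#' Spiking is stored canonically as 1 kHz count matrices (neurons x samples);
#' spike-timestamp input (lists of millisecond event times per neuron) is
#' converted on construction. Behavior is stored as variables x samples
#' matrices on the same 1 kHz time base.
#'
#' @param spikes list with one element per trial: either an N x T matrix of
#'   non-negative integer counts at 1 kHz, or a list of N numeric vectors of
#'   spike times in milliseconds (0 <= t < T). Sub-millisecond timestamps are
#'   floored with a warning.
#' @param behavior list with one element per trial: M x T numeric matrix,
#'   same T as the trial's spikes.
#' @param condition integer vector of condition labels, one per trial;
#'   must be contiguous positive integers 1..C.
#' @param events list with one element per trial: named numeric vector of
#'   event times (ms from trial start), e.g. `c(tmove = 400)`.
#' @param behavior_names character vector of length M.
#' @param circular logical vector of length M marking circular variables
#'   (stored in radians, principal interval `[0, 2*pi)`).
#' @return an object of class `trial_set`
#' @export
trial_set <- function(spikes, behavior, condition, events,
                      behavior_names = NULL, circular = NULL) {
  n_trials <- length(spikes)
  if (length(behavior) != n_trials || length(condition) != n_trials ||
      length(events) != n_trials)
    .stopf("spikes, behavior, condition and events must have one entry per trial (got %d, %d, %d, %d)",
           n_trials, length(behavior), length(condition), length(events))
  if (n_trials == 0L) .stopf("trial_set needs at least one trial")

  condition <- as.integer(condition)
  if (any(is.na(condition)) || any(condition < 1L))
    .stopf("condition labels must be positive integers")
  cs <- sort(unique(condition))
  if (!identical(cs, seq_len(max(cs))))
    .stopf("condition labels must be contiguous 1..C; observed {%s}",
           paste(cs, collapse = ","))

  spikes <- lapply(seq_len(n_trials), function(i) {
    s <- spikes[[i]]
    Tlen <- ncol(as.matrix(behavior[[i]]))
    if (is.list(s)) s <- .times_to_counts(s, Tlen, trial = i)
    s <- as.matrix(s)
    if (any(s < 0)) .stopf("negative spike counts in trial %d", i)
    if (ncol(s) != Tlen)
      .stopf("trial %d: spikes span %d samples but behavior spans %d",
             i, ncol(s), Tlen)
    storage.mode(s) <- "integer"
    s
  })
  N <- nrow(spikes[[1L]])
  M <- nrow(as.matrix(behavior[[1L]]))
  for (i in seq_len(n_trials)) {
    if (nrow(spikes[[i]]) != N)
      .stopf("trial %d has %d neurons; expected %d", i, nrow(spikes[[i]]), N)
    behavior[[i]] <- as.matrix(behavior[[i]])
    if (nrow(behavior[[i]]) != M)
      .stopf("trial %d has %d behavioral variables; expected %d",
             i, nrow(behavior[[i]]), M)
    if (any(!is.finite(behavior[[i]])))
      .stopf("non-finite behavior in trial %d", i)
    ev <- events[[i]]
    if (is.null(names(ev)) || any(!nzchar(names(ev))))
      .stopf("trial %d: events must be a named numeric vector", i)
  }
  behavior_names <- behavior_names %||% paste0("var", seq_len(M))
  circular <- circular %||% rep(FALSE, M)
  if (length(behavior_names) != M || length(circular) != M)
    .stopf("behavior_names and circular must have length M = %d", M)

  structure(list(
    spikes = spikes, behavior = behavior,
    condition = condition, events = events,
    n_neurons = N, n_behaviors = M, n_trials = n_trials,
    behavior_names = behavior_names, circular = as.logical(circular)
  ), class = "trial_set")
}

.times_to_counts <- function(times_by_neuron, Tlen, trial) {
  N <- length(times_by_neuron)
  out <- matrix(0L, N, Tlen)
  for (n in seq_len(N)) {
    tt <- times_by_neuron[[n]]
    if (length(tt) == 0L) next
    if (any(tt != floor(tt)))
      .warnf("trial %d neuron %d: sub-millisecond spike times floored", trial, n)
    tt <- floor(tt)
    if (any(tt < 0 | tt >= Tlen))
      .stopf("trial %d neuron %d: spike time outside recording bounds [0, %d)",
             trial, n, Tlen)
    tb <- tabulate(tt + 1L, nbins = Tlen)
    out[n, ] <- tb
  }
  out
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials, %d neurons, %d behavioral variables, %d conditions\n",
              x$n_trials, x$n_neurons, x$n_behaviors, max(x$condition)))
  invisible(x)
}

#' Configuration for learning idealized trajectories
#'
#' @param sigma_ms standard deviation (ms) of the Gaussian used to filter
#'   spikes into single-trial rates. Must be > 0.
#' @param window_start,window_end extraction boundaries in ms relative to
#'   `align_event` (start) and to `end_event` if given, else `align_event`
#'   (end). `window_start < window_end` required when both are relative to
#'   the same event.
#' @param align_event name of the event all trials are aligned to.
#' @param end_event optional second event; when set, the extraction window
#'   runs from `align_event + window_start` to `end_event + window_end` and
#'   trial lengths may differ within a condition (use `warp_mode = "uniform"`).
#' @param averaging_mode "TypeI" (arithmetic mean over trials) or "TypeII"
#'   (rank-1 trial-space PCA reconstruction before averaging, robust to
#'   outlier trials).
#' @param d_neural,d_condition smoothing dimensionalities for PCA smoothing
#'   across neurons / conditions; `"full"` disables that smoothing stage.
#' @param soft_norm_constant soft-normalization constant in spikes/s
#'   (per-neuron scale is 1 / (rate range + constant)). Default 5.
#' @param warp_mode "none" or "uniform" (linear resampling of each trial to
#'   the per-condition median duration).
#' @return an object of class `training_config`
#' @export
training_config <- function(sigma_ms = 25, window_start = -350, window_end = 750,
                            align_event = "tmove", end_event = NULL,
                            averaging_mode = c("TypeII", "TypeI"),
                            d_neural = "full", d_condition = "full",
                            soft_norm_constant = 5,
                            warp_mode = c("none", "uniform")) {
  .check_scalar_num(sigma_ms, "sigma_ms", lower = 1e-9)
  averaging_mode <- match.arg(averaging_mode)
  warp_mode <- match.arg(warp_mode)
  if (is.null(end_event) && window_start >= window_end)
    .stopf("window_start (%s) must be < window_end (%s)", window_start, window_end)
  .check_scalar_num(soft_norm_constant, "soft_norm_constant", lower = 0)
  structure(list(
    sigma_ms = sigma_ms, window_start = window_start, window_end = window_end,
    align_event = align_event, end_event = end_event,
    averaging_mode = averaging_mode,
    d_neural = d_neural, d_condition = d_condition,
    soft_norm_constant = soft_norm_constant, warp_mode = warp_mode
  ), class = "training_config")
}
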