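# Scoring of decoded behavior and estimated neural states, channel quality
# filtering, and the neuron-dropping robustness harness.

#' Coefficient of determination, optionally circular
#'
#' Standard R2 = 1 - SSE/SST. For circular variables, circular distances and
#' the circular mean are substituted: R2 = 1 - sum d_circ(yhat, y)^2 /
#' sum d_circ(ybar_circ, y)^2.
#'
#' @param predicted,truth numeric vectors
#' @param circular treat values as angles in radians
#' @return R2, or NA with a warning when the truth has zero variance
#' @export
r_squared <- function(predicted, truth, circular = FALSE) {
  ok <- is.finite(predicted) & is.finite(truth)
  predicted <- predicted[ok]; truth <- truth[ok]
  if (length(truth) == 0L) return(NA_real_)
  if (circular) {
    sse <- sum(circ_dist(predicted, truth)^2)
    sst <- sum(circ_dist(circ_mean(truth), truth)^2)
  } else {
    sse <- sum((predicted - truth)^2)
    sst <- sum((truth - mean(truth))^2)
  }
  if (sst == 0) {
    .warnf("zero-variance truth: R2 undefined")
    return(NA_real_)
  }
  1 - sse / sst
}

#' Score decoded behavior against ground truth
#'
#' Subsamples both series to the evaluation resolution (sample-taking every
#' `resolution_ms`), computes R2 and MAE per behavioral variable (circular
#' variables use circular distances/means), and averages within named
#' groups.
#'
#' @param decoded T x M matrix, or a `mint_estimates` object (its invalid
#'   warm-up rows are excluded automatically)
#' @param truth T x M matrix of ground-truth behavior
#' @param groups named list of integer variable-index vectors (default: one
#'   group per variable)
#' @param circular logical vector of length M
#' @param resolution_ms evaluation resolution (default 5)
#' @return a `score_report`: `per_variable` (R2, MAE), `per_group` (mean R2,
#'   MAE), `resolution_ms`, `n_samples`
#' @export
score_decode <- function(decoded, truth, groups = NULL, circular = NULL,
                         resolution_ms = 5) {
  valid <- NULL
  if (inherits(decoded, "mint_estimates")) {
    valid <- decoded$valid
    decoded <- decoded$behavior
  }
  decoded <- as.matrix(decoded); truth <- as.matrix(truth)
  if (!all(dim(decoded) == dim(truth)))
    .stopf("decoded (%dx%d) and truth (%dx%d) must be aligned",
           nrow(decoded), ncol(decoded), nrow(truth), ncol(truth))
  M <- ncol(truth)
  circular <- circular %||% rep(FALSE, M)
  keep <- seq(1L, nrow(truth), by = resolution_ms)
  if (!is.null(valid)) keep <- keep[valid[keep]]
  per_var <- data.frame(variable = colnames(truth) %||% paste0("var", seq_len(M)),
                        r2 = NA_real_, mae = NA_real_)
  for (m in seq_len(M)) {
    p <- decoded[keep, m]; y <- truth[keep, m]
    per_var$r2[m] <- r_squared(p, y, circular[m])
    per_var$mae[m] <- if (circular[m]) mean(abs(circ_dist(p, y))) else mean(abs(p - y))
  }
  groups <- groups %||% stats::setNames(as.list(seq_len(M)), per_var$variable)
  per_group <- data.frame(
    group = names(groups),
    r2 = vapply(groups, function(ix) mean(per_var$r2[ix]), numeric(1)),
    mae = vapply(groups, function(ix) mean(per_var$mae[ix]), numeric(1))
  )
  structure(list(per_variable = per_var, per_group = per_group,
                 resolution_ms = resolution_ms, n_samples = length(keep)),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> %d samples at %d ms resolution\n",
              x$n_samples, x$resolution_ms))
  print(x$per_group, row.names = FALSE)
  invisible(x)
}

#' Score neural-state (rate) estimates: bits/spike and PSTH R2
#'
#' bits/spike is the Poisson log-likelihood improvement of the rate
#' estimates over each neuron's mean rate, normalized by the total spike
#' count and expressed in base 2:
#' `(logL(estimates) - logL(mean rates)) / (total spikes * log 2)`.
#' PSTH R2 averages rate estimates across trials of the same condition and
#' computes the per-neuron R2 against the empirical trial-averaged rates,
#' averaged over neurons.
#'
#' @param estimates per-trial list (or single matrix) of N x B rate
#'   estimates in spikes/s at `bin_ms` resolution
#' @param spikes matching per-trial list (or matrix) of N x B binned counts
#' @param bin_ms bin width of both inputs
#' @param condition optional per-trial condition labels (enables PSTH R2)
#' @return list with `bits_per_spike` (NA with warning when there are no
#'   spikes), `psth_r2` (NA when conditions are unavailable), and
#'   `total_spikes`
#' @export
score_state_estimate <- function(estimates, spikes, bin_ms, condition = NULL) {
  if (!is.list(estimates)) estimates <- list(as.matrix(estimates))
  if (!is.list(spikes)) spikes <- list(as.matrix(spikes))
  stopifnot(length(estimates) == length(spikes))
  N <- nrow(estimates[[1L]])
  mu_all <- do.call(cbind, estimates) * bin_ms / 1000   # expected counts
  s_all <- do.call(cbind, spikes)
  if (!all(dim(mu_all) == dim(s_all)))
    .stopf("estimates and spikes must share shape")
  total <- sum(s_all)
  if (total == 0) {
    .warnf("zero total spikes: bits/spike undefined")
    bps <- NA_real_
  } else {
    mu0 <- rowMeans(s_all)                               # per-neuron mean count/bin
    ll <- sum(stats::dpois(s_all, pmax(mu_all, 1e-12), log = TRUE))
    ll0 <- sum(stats::dpois(s_all, pmax(mu0, 1e-12), log = TRUE))
    bps <- (ll - ll0) / (total * log(2))
  }
  psth_r2 <- NA_real_
  if (!is.null(condition)) {
    conds <- sort(unique(condition))
    est_psth <- list(); emp_psth <- list()
    for (cc in conds) {
      ids <- which(condition == cc)
      est_psth[[as.character(cc)]] <- Reduce(`+`, estimates[ids]) / length(ids)
      emp_psth[[as.character(cc)]] <-
        Reduce(`+`, spikes[ids]) / length(ids) * 1000 / bin_ms
    }
    est_cat <- do.call(cbind, est_psth); emp_cat <- do.call(cbind, emp_psth)
    r2s <- vapply(seq_len(N), function(n)
      suppressWarnings(r_squared(est_cat[n, ], emp_cat[n, ])), numeric(1))
    psth_r2 <- mean(r2s, na.rm = TRUE)
  }
  list(bits_per_spike = bps, psth_r2 = psth_r2, total_spikes = total)
}

#' Signal-to-noise channel filter
#'
#' SNR per channel is the range of the trial-averaged rate divided by the
#' standard deviation of the single-trial residuals (filtered rate minus the
#' trial average), with the SD floored at `sd_floor` so channels whose
#' residuals are quiet only because they barely fire are still rejected.
#' Channels with SNR > `threshold` are retained.
#'
#' @param trial_rates list of per-trial N x T filtered-rate matrices
#' @param trial_averages list of per-condition N x T trial-averaged rates
#' @param condition per-trial condition labels
#' @param sd_floor residual-SD floor in spikes/s (default 5)
#' @param threshold retention threshold (default 2)
#' @return list with logical `mask`, numeric `snr`
#' @export
snr_filter <- function(trial_rates, trial_averages, condition,
                       sd_floor = 5, threshold = 2) {
  N <- nrow(trial_rates[[1L]])
  avg_cat <- do.call(cbind, trial_averages)
  rng <- apply(avg_cat, 1L, function(r) diff(range(r)))
  resid <- do.call(cbind, lapply(seq_along(trial_rates), function(i)
    trial_rates[[i]] - trial_averages[[condition[i]]]))
  rsd <- apply(resid, 1L, stats::sd)
  snr <- rng / pmax(rsd, sd_floor)
  list(mask = snr > threshold, snr = snr)
}

#' Neuron-dropping robustness experiment
#'
#' For each neuron count in `counts_grid` and each repeat, drops a random
#' subset of neurons and decodes the test stream(s). "undetected" mode
#' zeroes the dropped neurons' spikes without informing the decoder;
#' "known" mode additionally masks them in the likelihood (equivalent to
#' removing them from library and stream). Performance is the group-mean
#' decoding R2 against the supplied truth.
#'
#' @param library a `trajectory_library`
#' @param streams list of N x T test spike streams
#' @param truths list of matching T x M ground-truth behavior matrices
#' @param counts_grid neuron counts to retain (subset of 1..N)
#' @param repeats random subsets per count (default 50)
#' @param mode "undetected" or "known"
#' @param cfg a [decoder_config()]
#' @param seed RNG seed
#' @param circular logical vector of length M
#' @return data.frame with columns `n_neurons`, `mean_r2`, `sd_r2`
#' @export
neuron_drop_experiment <- function(library, streams, truths, counts_grid,
                                   repeats = 50, mode = c("undetected", "known"),
                                   cfg = decoder_config(), seed = 1,
                                   circular = NULL) {
  mode <- match.arg(mode)
  N <- library$n_neurons
  if (any(counts_grid < 1L | counts_grid > N))
    .stopf("counts_grid values must lie in [1, %d]", N)
  set.seed(seed)
  rows <- list()
  for (m in counts_grid) {
    r2s <- numeric(repeats)
    for (rep_i in seq_len(repeats)) {
      keep <- sort(sample.int(N, m))
      mask <- seq_len(N) %in% keep
      cfg_i <- cfg
      cfg_i$active_mask <- if (mode == "known") mask else NULL
      vals <- vapply(seq_along(streams), function(s) {
        str_i <- streams[[s]]
        str_i[!mask, ] <- 0L
        est <- decode(library, str_i, cfg_i)
        rep <- score_decode(est, truths[[s]], circular = circular)
        mean(rep$per_group$r2, na.rm = TRUE)
      }, numeric(1))
      r2s[rep_i] <- mean(vals)
    }
    rows[[length(rows) + 1L]] <- data.frame(n_neurons = m, mean_r2 = mean(r2s),
                                            sd_r2 = stats::sd(r2s))
  }
  do.call(rbind, rows)
}
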