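# The online/offline decoding loop: ingest millisecond spike counts, refresh
# state log-likelihoods once per completed bin, advance estimates
# deterministically between bins, and emit millisecond-resolution neural and
# behavioral estimates.

#' Decoder configuration
#'
#' @param delta_ms bin width in ms (default 20)
#' @param window_ms spiking-history window; must be a positive multiple of
#'   `delta_ms` (default 300, i.e. tau_prime = 14)
#' @param interp interpolation mode: "condition" (default; index refinement
#'   of the best state plus interpolation to the best admissible state under
#'   the policy), "index", "library", or "off"
#' @param policy a [candidate_policy()]
#' @param causal decode causally (TRUE) or acausally via [decode_acausal()]
#' @param lag_ms output lag in ms; positive delays emission, negative
#'   emits predictively (default 0)
#' @param rate_floor,clip_floor lookup-table regularization (spikes/s;
#'   log-probability floor)
#' @param grid_step,max_count lookup-table rate increment and max per-bin
#'   count
#' @param lambda_max rate-axis upper bound; default NULL sizes it to 1.2 x
#'   the largest library rate
#' @param active_mask optional logical vector: neurons contributing to the
#'   likelihood (known-loss masking)
#' @param emit_rates include the blended N-vector of rates in each estimate
#' @return an object of class `decoder_config`
#' @export
decoder_config <- function(delta_ms = 20, window_ms = 300,
                           interp = c("condition", "index", "library", "off"),
                           policy = candidate_policy(), causal = TRUE,
                           lag_ms = 0, rate_floor = 1, clip_floor = log(1e-6),
                           grid_step = 0.1, max_count = 20, lambda_max = NULL,
                           active_mask = NULL, emit_rates = FALSE) {
  interp <- match.arg(interp)
  .check_scalar_num(delta_ms, "delta_ms", lower = 1)
  .check_scalar_num(window_ms, "window_ms", lower = delta_ms)
  if (window_ms %% delta_ms != 0)
    .stopf("window_ms (%s) must be a positive multiple of delta_ms (%s)",
           window_ms, delta_ms)
  structure(list(delta_ms = as.integer(delta_ms),
                 window_ms = as.integer(window_ms),
                 tau_prime = as.integer(window_ms / delta_ms) - 1L,
                 interp = interp, policy = policy, causal = causal,
                 lag_ms = as.integer(lag_ms),
                 rate_floor = rate_floor, clip_floor = clip_floor,
                 grid_step = grid_step, max_count = max_count,
                 lambda_max = lambda_max, active_mask = active_mask,
                 emit_rates = emit_rates),
            class = "decoder_config")
}

#' Create a streaming decoder
#'
#' Builds the lookup table (sized to the library's rate range unless
#' `cfg$lambda_max` is given), discretizes the library, and initializes the
#' recursive accumulator and spike buffers. Feed samples with
#' [decoder_step()].
#'
#' @param library a `trajectory_library`
#' @param cfg a [decoder_config()]
#' @param table optional prebuilt `likelihood_table`
#' @return a `mint_decoder` environment
#' @export
mint_decoder <- function(library, cfg = decoder_config(), table = NULL) {
  stopifnot(inherits(library, "trajectory_library"))
  tau <- cfg$window_ms - 1L       # delta = 0 history extent in samples
  if (any(library$Kc < tau + 1L))
    .stopf("window_ms = %d leaves no valid states in condition(s) %s",
           cfg$window_ms, paste(which(library$Kc < tau + 1L), collapse = ","))
  if (is.null(table)) {
    lmax <- cfg$lambda_max %||% max(1.2 * max(unlist(lapply(library$rates, max))),
                                    cfg$rate_floor + cfg$grid_step)
    table <- build_lookup_table(lambda_min = 0, lambda_max = lmax,
                                grid_step = cfg$grid_step,
                                max_count = cfg$max_count,
                                delta_ms = cfg$delta_ms,
                                clip_floor = cfg$clip_floor,
                                rate_floor = cfg$rate_floor)
  }
  rate_index <- discretize_library_rates(library, table)
  dec <- new.env(parent = emptyenv())
  dec$library <- library
  dec$cfg <- cfg
  dec$table <- table
  dec$rate_index <- rate_index
  dec$acc <- likelihood_accumulator(rate_index, table, cfg$tau_prime)
  dec$binbuf <- matrix(0L, library$n_neurons, cfg$tau_prime + 1L)
  dec$cur <- integer(library$n_neurons)
  dec$delta <- 0L
  dec$t <- 0L
  dec$est <- NULL
  if (!is.null(cfg$active_mask)) set_active_neurons(dec, cfg$active_mask)
  class(dec) <- "mint_decoder"
  dec
}

#' Set the active-neuron mask of a decoder
#'
#' Masked-out neurons contribute nothing to any likelihood (known-loss
#' handling); no retraining occurs and the mask takes effect at the next
#' completed bin.
#'
#' @param dec a `mint_decoder`
#' @param mask logical vector of length N; at least one TRUE
#' @return the decoder, invisibly
#' @export
set_active_neurons <- function(dec, mask) {
  mask <- as.logical(mask)
  if (length(mask) != dec$library$n_neurons)
    .stopf("mask length %d; library has %d neurons", length(mask),
           dec$library$n_neurons)
  if (!any(mask)) .stopf("active-neuron mask must retain at least one neuron")
  dec$acc$active <- mask
  invisible(dec)
}

#' Advance the decoder by one millisecond of spiking
#'
#' On bin completion (every `delta_ms` samples) the recursive accumulator is
#' refreshed, the most likely state is selected and refined by
#' interpolation; between bins the estimate's provenance indices advance
#' deterministically along their trajectories (interpolation weights frozen),
#' holding at trajectory ends.
#'
#' @param dec a `mint_decoder`
#' @param counts integer vector of per-neuron spike counts for this sample
#' @return an estimate record: list with `time`, `valid`, `behavior`,
#'   `loglik`, `provenance` (c1, k1, c2, k2, alpha), and `rates` when
#'   `emit_rates` is set. Records before a full history has accrued
#'   (`time <= window_ms - 1`) are warm-up records with `valid = FALSE`.
#' @export
decoder_step <- function(dec, counts) {
  if (length(counts) != dec$library$n_neurons)
    .stopf("counts length %d; library has %d neurons", length(counts),
           dec$library$n_neurons)
  if (any(counts < 0)) .stopf("negative spike counts")
  dec$t <- dec$t + 1L
  dec$cur <- dec$cur + as.integer(counts)
  dec$delta <- dec$delta + 1L
  if (dec$delta == dec$cfg$delta_ms) {
    # bin completes at this sample: delta resets to 0
    dec$delta <- 0L
    tp1 <- dec$cfg$tau_prime + 1L
    dec$binbuf <- cbind(dec$binbuf[, -1L, drop = FALSE], dec$cur)
    accumulator_push(dec$acc, dec$cur)
    dec$cur <- integer(dec$library$n_neurons)
    if (dec$t >= dec$cfg$window_ms) {  # t > tau, full history available
      dec$est <- refine_estimate(dec$acc, dec$binbuf, dec$cfg$policy,
                                 mode = dec$cfg$interp)
    }
  } else if (!is.null(dec$est)) {
    dec$est <- .advance_estimate(dec$est, dec$library, by = 1L)
  }
  .emit(dec)
}

.emit <- function(dec) {
  M <- dec$library$n_behaviors
  if (is.null(dec$est)) {
    rec <- list(time = dec$t, valid = FALSE,
                behavior = rep(NA_real_, M), loglik = NA_real_,
                provenance = rep(NA_real_, 5L))
    if (dec$cfg$emit_rates) rec$rates <- rep(NA_real_, dec$library$n_neurons)
    return(rec)
  }
  res <- dec$est
  p1 <- res$pairs[[1L]]
  p2 <- if (length(res$pairs) > 1L) res$pairs[[2L]] else p1
  rec <- list(time = dec$t, valid = TRUE,
              behavior = .estimate_behavior(res, dec$library),
              loglik = res$value,
              provenance = c(p1$c, p1$k1, p2$c, p2$k1,
                             if (length(res$pairs) > 1L) res$alpha_top else p1$alpha))
  if (dec$cfg$emit_rates) rec$rates <- .estimate_rates(res, dec$library)
  rec
}

# Full provenance row (9 numbers) for reconstruction:
# c1, k11, k12, alpha1, c2, k21, k22, alpha2, alpha_top
.prov_full <- function(res) {
  p1 <- res$pairs[[1L]]
  if (length(res$pairs) > 1L) {
    p2 <- res$pairs[[2L]]
    c(p1$c, p1$k1, p1$k2, p1$alpha, p2$c, p2$k1, p2$k2, p2$alpha, res$alpha_top)
  } else {
    c(p1$c, p1$k1, p1$k2, p1$alpha, p1$c, p1$k1, p1$k2, p1$alpha, 0)
  }
}

.res_from_prov <- function(row) {
  structure(list(
    pairs = list(list(c = row[1L], k1 = row[2L], k2 = row[3L], alpha = row[4L]),
                 list(c = row[5L], k1 = row[6L], k2 = row[7L], alpha = row[8L])),
    alpha_top = row[9L], value = NA_real_, iterations = NA_integer_),
    class = "interpolation_result")
}

#' Decode a spike stream (batch, causal)
#'
#' Runs [decoder_step()] over every sample of a 1 kHz stream. Streaming and
#' batch invocation are the same code path and agree exactly.
#'
#' @param library a `trajectory_library`
#' @param stream N x T matrix of per-millisecond counts, or a list with
#'   `counts` pre-binned at `delta_ms` (millisecond updates then reduce to
#'   the deterministic-advance branch within each bin)
#' @param cfg a [decoder_config()]
#' @param table optional prebuilt `likelihood_table`
#' @return a `mint_estimates` object: `time` (T), `valid` (T), `behavior`
#'   (T x M), `loglik` (T), `provenance` (T x 5), `prov_full` (T x 9),
#'   optionally `rates` (T x N)
#' @export
decode <- function(library, stream, cfg = decoder_config(), table = NULL) {
  if (is.list(stream) && !is.null(stream$counts)) {
    # pre-binned input: expand each bin into delta_ms-1 zeros plus the bin
    # total at the bin's final sample (identical likelihoods, since only
    # per-bin sums enter the model)
    cb <- as.matrix(stream$counts)
    D <- cfg$delta_ms
    ex <- matrix(0L, nrow(cb), ncol(cb) * D)
    ex[, seq_len(ncol(cb)) * D] <- as.integer(cb)
    stream <- ex
  }
  stream <- as.matrix(stream)
  Tlen <- ncol(stream)
  M <- library$n_behaviors; N <- library$n_neurons
  out <- list(time = seq_len(Tlen), valid = logical(Tlen),
              behavior = matrix(NA_real_, Tlen, M,
                                dimnames = list(NULL, library$behavior_names)),
              loglik = rep(NA_real_, Tlen),
              provenance = matrix(NA_real_, Tlen, 5L,
                                  dimnames = list(NULL, c("c1", "k1", "c2", "k2", "alpha"))),
              prov_full = matrix(NA_real_, Tlen, 9L))
  if (cfg$emit_rates) out$rates <- matrix(NA_real_, Tlen, N)
  if (Tlen == 0L) return(structure(out, class = "mint_estimates",
                                   delta_ms = cfg$delta_ms, window_ms = cfg$window_ms))
  dec <- mint_decoder(library, cfg, table)
  for (t in seq_len(Tlen)) {
    rec <- decoder_step(dec, stream[, t])
    out$valid[t] <- rec$valid
    out$behavior[t, ] <- rec$behavior
    out$loglik[t] <- rec$loglik
    out$provenance[t, ] <- rec$provenance
    if (rec$valid) out$prov_full[t, ] <- .prov_full(dec$est)
    if (cfg$emit_rates) out$rates[t, ] <- rec$rates
  }
  if (cfg$lag_ms != 0L) out <- .shift_estimates(out, cfg$lag_ms)
  structure(out, class = "mint_estimates", delta_ms = cfg$delta_ms,
            window_ms = cfg$window_ms)
}

.shift_estimates <- function(out, lag) {
  Tlen <- length(out$time)
  src <- seq_len(Tlen) - lag
  ok <- src >= 1L & src <= Tlen
  shift_mat <- function(m) {
    res <- matrix(NA_real_, Tlen, ncol(m), dimnames = dimnames(m))
    res[ok, ] <- m[src[ok], , drop = FALSE]
    res
  }
  out$behavior <- shift_mat(out$behavior)
  out$provenance <- shift_mat(out$provenance)
  out$prov_full <- shift_mat(out$prov_full)
  if (!is.null(out$rates)) out$rates <- shift_mat(out$rates)
  out$loglik <- ifelse(ok, out$loglik[pmax(pmin(src, Tlen), 1L)], NA_real_)
  out$valid <- ok & out$valid[pmax(pmin(src, Tlen), 1L)]
  out
}

#' @export
print.mint_estimates <- function(x, ...) {
  cat(sprintf("<mint_estimates> %d samples (%d valid), %d behavioral variables\n",
              length(x$time), sum(x$valid), ncol(x$behavior)))
  invisible(x)
}

#' Decode a finite segment acausally
#'
#' Interior estimates use spiking windows centered on the estimated moment
#' (the acausal estimate at t equals the causal estimate at t + window/2).
#' Boundary estimates freeze the nearest feasible estimate's interpolation
#' parameters and propagate its provenance backward/forward along the
#' trajectories.
#'
#' @inheritParams decode
#' @return a `mint_estimates` object
#' @export
decode_acausal <- function(library, stream, cfg = decoder_config(), table = NULL) {
  stream <- as.matrix(stream)
  Tlen <- ncol(stream)
  shift <- cfg$window_ms %/% 2L
  causal <- decode(library, stream, cfg, table)
  out <- causal
  valid_rows <- which(causal$valid)
  if (length(valid_rows) == 0L) return(out)   # nothing feasible to propagate
  first_v <- valid_rows[1L]; last_v <- valid_rows[length(valid_rows)]
  for (t in seq_len(Tlen)) {
    s <- t + shift
    if (s >= first_v && s <= last_v) {
      src <- s; off <- 0L
    } else if (s < first_v) {
      src <- first_v; off <- s - first_v     # rewind
    } else {
      src <- last_v; off <- s - last_v       # advance
    }
    res <- .res_from_prov(causal$prov_full[src, ])
    if (off != 0L) res <- .advance_estimate(res, library, by = off)
    out$valid[t] <- TRUE
    out$behavior[t, ] <- .estimate_behavior(res, library)
    out$loglik[t] <- causal$loglik[src]
    p1 <- res$pairs[[1L]]; p2 <- res$pairs[[2L]]
    out$provenance[t, ] <- c(p1$c, p1$k1, p2$c, p2$k1, res$alpha_top)
    out$prov_full[t, ] <- .prov_full(res)
    if (!is.null(out$rates)) out$rates[t, ] <- .estimate_rates(res, library)
  }
  out
}

#' Predict held-out neuron rates from an estimate's provenance
#'
#' Applies the direct (c, k, alpha) association to a library partition over
#' different neurons: held-out rates are the same convex blend of the
#' held-out library states at the provenance indices, floored at 0.1
#' spikes/s.
#'
#' @param prov either an `interpolation_result` or a 9-number full-provenance
#'   row (see `prov_full` in [decode()] output)
#' @param heldout_library a `trajectory_library` sharing (c, k) indexing with
#'   the decoding library (e.g. from [split_library()])
#' @param floor minimum rate (default 0.1 spikes/s)
#' @return numeric vector of held-out rates
#' @export
predict_heldout_rates <- function(prov, heldout_library, floor = 0.1) {
  res <- if (inherits(prov, "interpolation_result")) prov else .res_from_prov(prov)
  for (p in res$pairs) {
    if (p$c > heldout_library$n_conditions || p$k1 > heldout_library$Kc[p$c] ||
        p$k2 > heldout_library$Kc[p$c])
      .stopf("provenance (c = %d, k = %d) outside the held-out partition", p$c, max(p$k1, p$k2))
  }
  pmax(.estimate_rates(res, heldout_library), floor)
}
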