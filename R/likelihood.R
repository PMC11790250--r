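# Poisson log-likelihood machinery: the precomputed lookup table, library
# rate discretization, spike binning, the direct per-state sum, and the
# recursive per-bin accumulator over the downsampled state set.

#' Build the clipped Poisson log-likelihood lookup table
#'
#' Entry (s, v) holds `max(clip_floor, log Pois(s | rate_grid[v] * delta_ms/1000))`,
#' the log-probability of observing s spikes in one bin from a neuron whose
#' rate is the v-th grid value. Rates below `rate_floor` are raised to the
#' floor at grid-index assignment time (see [discretize_library_rates()]),
#' which together with the clip keeps a spurious spike from a near-silent
#' neuron from dominating the state decision.
#'
#' @param lambda_min,lambda_max rate-axis bounds in spikes/s
#' @param grid_step rate-axis increment in spikes/s (default 0.1)
#' @param max_count largest per-bin spike count S (default 20); observed
#'   counts above S are clamped with a warning
#' @param delta_ms bin width in ms (default 20)
#' @param clip_floor lower clip for log-likelihoods (default log(1e-6))
#' @param rate_floor minimum rate (spikes/s) used at index assignment
#'   (default 1)
#' @return an object of class `likelihood_table`; `$entries` is an
#'   (S+1) x (V+1) matrix with counts in rows, grid rates in columns
#' @export
build_lookup_table <- function(lambda_min = 0, lambda_max = 200, grid_step = 0.1,
                               max_count = 20, delta_ms = 20,
                               clip_floor = log(1e-6), rate_floor = 1) {
  .check_scalar_num(lambda_min, "lambda_min", lower = 0)
  .check_scalar_num(lambda_max, "lambda_max", lower = lambda_min + 1e-12)
  if (!is.numeric(grid_step) || grid_step <= 0) .stopf("grid_step must be positive")
  .check_scalar_num(max_count, "max_count", lower = 1)
  rate_grid <- seq(lambda_min, lambda_max, by = grid_step)
  mu <- rate_grid * delta_ms / 1000           # expected count per bin
  counts <- 0:max_count
  entries <- outer(counts, mu, function(s, m) stats::dpois(s, m, log = TRUE))
  entries <- pmax(entries, clip_floor)
  structure(list(
    entries = entries, rate_grid = rate_grid,
    lambda_min = lambda_min, lambda_max = lambda_max, grid_step = grid_step,
    max_count = as.integer(max_count), delta_ms = as.integer(delta_ms),
    clip_floor = clip_floor, rate_floor = rate_floor
  ), class = "likelihood_table")
}

#' @export
print.likelihood_table <- function(x, ...) {
  cat(sprintf("<likelihood_table> %d x %d (counts 0-%d, rates %g-%g spikes/s by %g, %d ms bins)\n",
              nrow(x$entries), ncol(x$entries), x$max_count,
              x$lambda_min, x$lambda_max, x$grid_step, x$delta_ms))
  invisible(x)
}

#' Discretize library rates onto the lookup table's rate grid
#'
#' For every neuron n, condition c and sample j >= delta_ms, computes the
#' bin-averaged rate (mean of the delta_ms per-sample rates ending at j,
#' spikes/s), floors it at the table's `rate_floor`, and assigns the nearest
#' rate-grid index. Also records the downsampled state set (indices k
#' divisible by delta_ms) used by the recursive update.
#'
#' @param library a `trajectory_library`
#' @param table a `likelihood_table`
#' @return an object of class `rate_index_library` with per-condition
#'   bin-averaged rates `lam` (N x Kc, NA for j < delta_ms), grid indices
#'   `vidx` (0-based), downsampled index matrices `vds` (N x K'), and the
#'   count `Kds` of downsampled states per condition
#' @export
discretize_library_rates <- function(library, table) {
  stopifnot(inherits(library, "trajectory_library"),
            inherits(table, "likelihood_table"))
  D <- table$delta_ms
  if (D != library$delta_ms)
    .warnf("table bin width (%d ms) differs from library bin width (%d ms)",
           D, library$delta_ms)
  lam <- vector("list", library$n_conditions)
  vidx <- vector("list", library$n_conditions)
  vds <- vector("list", library$n_conditions)
  for (c in seq_len(library$n_conditions)) {
    X <- library$rates[[c]]
    K <- ncol(X)
    cs <- cbind(0, t(apply(X, 1L, cumsum)))      # N x (K+1)
    L <- matrix(NA_real_, nrow(X), K)
    if (K >= D) {
      j <- D:K
      L[, j] <- (cs[, j + 1L, drop = FALSE] - cs[, j - D + 1L, drop = FALSE]) / D
    }
    L <- pmax(L, table$rate_floor)
    over <- which(L > table$lambda_max, arr.ind = TRUE)
    if (nrow(over))
      .stopf("condition %d: bin-averaged rate %.2f spikes/s for neuron %d exceeds the table's lambda_max (%g); rebuild the table with a larger range",
             c, max(L, na.rm = TRUE), over[which.max(L[over]), 1L], table$lambda_max)
    V <- round((L - table$lambda_min) / table$grid_step)
    V[!is.na(V)] <- pmin(pmax(V[!is.na(V)], 0), length(table$rate_grid) - 1L)
    storage.mode(V) <- "integer"
    lam[[c]] <- L; vidx[[c]] <- V
    kds <- seq(D, K, by = D)
    vds[[c]] <- V[, kds, drop = FALSE]
  }
  structure(list(
    lam = lam, vidx = vidx, vds = vds,
    Kds = vapply(vds, ncol, integer(1)),
    delta_ms = D, n_conditions = library$n_conditions,
    n_neurons = library$n_neurons
  ), class = "rate_index_library")
}

#' Bin a 1 kHz spike stream into delta_ms spike counts
#'
#' Bins are half-open windows right-aligned to the stream: bin i' holds the
#' counts of samples (i'-1)*delta_ms + 1 .. i'*delta_ms. Trailing samples
#' that do not complete a bin are reported as the remainder `delta`.
#'
#' @param stream N x T matrix of per-millisecond counts
#' @param delta_ms bin width in ms
#' @return list with `counts` (N x n_bins), `delta` (samples past the last
#'   complete bin) and `remainder` (N x delta matrix of unbinned counts)
#' @export
bin_spikes <- function(stream, delta_ms) {
  stream <- as.matrix(stream)
  if (any(stream < 0)) .stopf("negative spike counts in stream")
  Tlen <- ncol(stream)
  nb <- Tlen %/% delta_ms
  delta <- Tlen - nb * delta_ms
  counts <- matrix(0L, nrow(stream), nb)
  if (nb > 0) {
    grp <- rep(seq_len(nb), each = delta_ms)
    binned <- t(rowsum(t(stream[, seq_len(nb * delta_ms), drop = FALSE]), grp))
    counts <- matrix(as.integer(binned), nrow(stream), nb)
  }
  list(counts = counts, delta = delta,
       remainder = stream[, nb * delta_ms + seq_len(delta), drop = FALSE])
}

# r-term for one bin: per-condition vectors over downsampled states.
# counts: N integer (clamped to S); active: logical N or NULL.
.r_terms <- function(rate_index, table, counts, active = NULL) {
  S1 <- nrow(table$entries)
  Lvec <- as.vector(table$entries)
  counts <- pmin(as.integer(counts), table$max_count)
  lapply(seq_len(rate_index$n_conditions), function(c) {
    V <- rate_index$vds[[c]]
    if (!is.null(active)) {
      V <- V[active, , drop = FALSE]
      s <- counts[active]
    } else s <- counts
    if (nrow(V) == 0L) return(numeric(ncol(V)))
    idx <- V * S1 + s + 1L              # column-major flat index; s recycles down columns
    .colSums(Lvec[idx], nrow(V), ncol(V))
  })
}

#' Direct spike-history log-likelihood of one library state
#'
#' Sums clipped table entries over all neurons and all `tau_prime + 1` bins
#' of history for the state (c, k): the log-likelihood that the observed
#' binned counts arose from the rate history ending at (c, k). Terms whose
#' library column index is non-positive contribute 0 (boundary rule).
#'
#' @param counts_history N x (tau_prime + 1) matrix of binned counts, oldest
#'   bin first
#' @param rate_index a `rate_index_library`
#' @param table a `likelihood_table`
#' @param c,k condition and time index of the queried state (k > tau
#'   required for a fully-backed history)
#' @param delta samples elapsed since the last completed bin (default 0)
#' @param active optional logical mask of contributing neurons
#' @param count_retrievals if TRUE, attach the number of table retrievals
#'   performed as attribute "retrievals"
#' @return scalar log-likelihood
#' @export
log_likelihood_direct <- function(counts_history, rate_index, table, c, k,
                                  delta = 0, active = NULL,
                                  count_retrievals = FALSE) {
  counts_history <- as.matrix(counts_history)
  tp <- ncol(counts_history) - 1L
  D <- table$delta_ms
  tau <- delta + D * (tp + 1L) - 1L
  if (k <= tau)
    .stopf("state k = %d lacks a full history (tau = %d)", k, tau)
  V <- rate_index$vidx[[c]]
  q <- 0; nret <- 0L
  neurons <- if (is.null(active)) seq_len(nrow(counts_history)) else which(active)
  for (ip in 0:tp) {
    j <- k - delta - D * ip
    if (j <= 0) next
    s <- pmin(counts_history[neurons, tp + 1L - ip], table$max_count)
    q <- q + sum(table$entries[cbind(s + 1L, V[neurons, j] + 1L)])
    nret <- nret + length(neurons)
  }
  if (count_retrievals) attr(q, "retrievals") <- nret
  q
}

#' Create a recursive log-likelihood accumulator
#'
#' Maintains, for every condition, the running log-likelihood vector over the
#' downsampled state set. Each completed bin updates all state
#' log-likelihoods in O(N x states) via the recursion
#' `q[t', k'] = q[t'-1, k'-1] + r[t', k'] - r[t'-tau'-1, k'-tau'-1]`,
#' where r is the per-bin, per-state sum of table entries; out-of-range
#' terms are zero.
#'
#' @param rate_index a `rate_index_library`
#' @param table a `likelihood_table`
#' @param tau_prime number of history bins minus one (window is
#'   `(tau_prime+1) * delta_ms` ms)
#' @return an accumulator environment; see [accumulator_push()] and
#'   [most_likely_state()]
#' @export
likelihood_accumulator <- function(rate_index, table, tau_prime) {
  acc <- new.env(parent = emptyenv())
  acc$rate_index <- rate_index
  acc$table <- table
  acc$tau_prime <- as.integer(tau_prime)
  acc$q <- lapply(rate_index$Kds, function(K) numeric(K))
  acc$rhist <- vector("list", tau_prime + 1L)   # ring of r-term lists
  acc$bin <- 0L
  acc$active <- NULL
  class(acc) <- "likelihood_accumulator"
  acc
}

#' Push one completed bin of counts into the accumulator
#'
#' @param acc a [likelihood_accumulator()]
#' @param counts N integer spike counts for the newly completed bin
#' @return the accumulator, invisibly (updated in place)
#' @export
accumulator_push <- function(acc, counts) {
  if (any(counts > acc$table$max_count))
    .warnf("spike count(s) above table max (%d) clamped", acc$table$max_count)
  r_now <- .r_terms(acc$rate_index, acc$table, counts, acc$active)
  tp1 <- acc$tau_prime + 1L
  slot <- (acc$bin %% tp1) + 1L        # slot holds r from tau'+1 bins ago (if any)
  r_old <- if (acc$bin >= tp1) acc$rhist[[slot]] else NULL
  for (c in seq_along(acc$q)) {
    K <- length(acc$q[[c]])
    if (K == 0L) next
    q_shift <- c(0, acc$q[[c]][-K])
    sub <- numeric(K)
    if (!is.null(r_old)) {
      n_back <- K - tp1
      if (n_back > 0) sub[(tp1 + 1L):K] <- r_old[[c]][seq_len(n_back)]
    }
    acc$q[[c]] <- q_shift + r_now[[c]] - sub
  }
  acc$rhist[[slot]] <- r_now
  acc$bin <- acc$bin + 1L
  invisible(acc)
}

#' Most likely library state under the current accumulator
#'
#' Argmax of the recursive log-likelihoods over the downsampled valid state
#' set (states with full history, k' > tau_prime). Exact ties are broken to
#' the lowest condition, then the lowest index.
#'
#' @param acc a [likelihood_accumulator()]
#' @return list with `c`, `k_ds` (downsampled index k'), `k` (= k' *
#'   delta_ms), and `loglik`
#' @export
most_likely_state <- function(acc) {
  best <- NULL
  for (c in seq_along(acc$q)) {
    K <- length(acc$q[[c]])
    first_valid <- acc$tau_prime + 1L
    if (K < first_valid) next
    qv <- acc$q[[c]][first_valid:K]
    i <- which.max(qv)
    if (is.null(best) || qv[i] > best$loglik) {
      best <- list(c = c, k_ds = first_valid + i - 1L, loglik = qv[i])
    }
  }
  if (is.null(best)) .stopf("no valid candidate states (empty downsampled state set)")
  best$k <- best$k_ds * acc$rate_index$delta_ms
  best
}
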