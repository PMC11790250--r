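#' Assemble paired neural and behavioral trajectory libraries
#'
#' Pairs each neural state (column k of condition c's rate matrix) with the
#' behavioral state at the same (c, k), records the history extent `tau`
#' (samples) and bin width `delta_ms`, and marks as valid candidate states
#' only those with a full state history (k > tau).
#'
#' @param rates list of per-condition N x Kc rate matrices (spikes/s, 1 kHz)
#' @param behavior list of per-condition M x Kc behavior matrices
#' @param tau history extent in samples; a decoder using bin width `delta_ms`
#'   and `tau_prime + 1` bins of history has `tau = delta_ms*(tau_prime+1) - 1`
#' @param delta_ms bin width in ms (default 20)
#' @param circular logical vector of length M marking circular variables
#' @param neuron_ids,behavior_names optional identifier vectors
#' @return an object of class `trajectory_library`
#' @export
assemble_library <- function(rates, behavior, tau, delta_ms = 20,
                             circular = NULL, neuron_ids = NULL,
                             behavior_names = NULL) {
  C <- length(rates)
  if (length(behavior) != C)
    .stopf("rates and behavior must have the same number of conditions (%d vs %d)",
           C, length(behavior))
  .check_scalar_num(tau, "tau", lower = 0)
  .check_scalar_num(delta_ms, "delta_ms", lower = 1)
  tau <- as.integer(tau); delta_ms <- as.integer(delta_ms)
  N <- nrow(rates[[1L]]); M <- nrow(behavior[[1L]])
  Kc <- integer(C)
  for (c in seq_len(C)) {
    rates[[c]] <- as.matrix(rates[[c]]); behavior[[c]] <- as.matrix(behavior[[c]])
    if (nrow(rates[[c]]) != N) .stopf("condition %d: neuron count mismatch", c)
    if (nrow(behavior[[c]]) != M) .stopf("condition %d: behavior count mismatch", c)
    if (ncol(rates[[c]]) != ncol(behavior[[c]]))
      .stopf("condition %d: rates span %d samples but behavior spans %d",
             c, ncol(rates[[c]]), ncol(behavior[[c]]))
    if (any(!is.finite(rates[[c]])) || any(rates[[c]] < 0))
      .stopf("condition %d: rates must be finite and non-negative", c)
    Kc[c] <- ncol(rates[[c]])
  }
  short <- which(Kc < tau + 1L)
  if (length(short))
    .stopf("tau = %d leaves no valid states in condition(s) %s (Kc = %s)",
           tau, paste(short, collapse = ","), paste(Kc[short], collapse = ","))
  circular <- circular %||% rep(FALSE, M)
  structure(list(
    rates = rates, behavior = behavior, tau = tau, delta_ms = delta_ms,
    n_neurons = N, n_behaviors = M, n_conditions = C, Kc = Kc,
    circular = as.logical(circular),
    neuron_ids = neuron_ids %||% paste0("n", seq_len(N)),
    behavior_names = behavior_names %||% paste0("var", seq_len(M)),
    sampling_rate_hz = 1000L, version = 1L
  ), class = "trajectory_library")
}

#' @export
print.trajectory_library <- function(x, ...) {
  cat(sprintf("<trajectory_library> %d conditions, %d neurons, %d behavioral variables\n",
              x$n_conditions, x$n_neurons, x$n_behaviors))
  cat(sprintf("  Kc: %s | tau = %d samples | bin = %d ms | valid states: %d\n",
              paste(range(x$Kc), collapse = "-"), x$tau, x$delta_ms,
              sum(pmax(x$Kc - x$tau, 0L))))
  invisible(x)
}

#' Valid candidate-state mask (k > tau) per condition
#' @param library a `trajectory_library`
#' @return list of logical vectors, one per condition
#' @export
valid_state_mask <- function(library) {
  lapply(library$Kc, function(K) seq_len(K) > library$tau)
}

#' State-transition lookup: the predecessor of state (c, k)
#'
#' Trajectories are deterministic: each state's unique predecessor is the
#' previous state on the same trajectory.
#' @param library a `trajectory_library`
#' @param c condition index
#' @param k time index (k > 1)
#' @return the index k - 1
#' @export
state_transition <- function(library, c, k) {
  if (c < 1L || c > library$n_conditions) .stopf("condition %d out of range", c)
  if (k <= 1L || k > library$Kc[c]) .stopf("state k = %d has no predecessor in condition %d", k, c)
  k - 1L
}

#' Learn a trajectory library from trial-structured training data
#'
#' Convenience pipeline: Gaussian filtering and window extraction,
#' Type I/II trial averaging, PCA smoothing, circular-aware behavior
#' averaging, and library assembly.
#'
#' @param trials a [trial_set()]
#' @param cfg a [training_config()]
#' @param tau history extent in samples (see [assemble_library()])
#' @param delta_ms bin width in ms
#' @return a `trajectory_library`
#' @export
learn_library <- function(trials, cfg = training_config(), tau, delta_ms = 20) {
  tensors <- build_rates_from_trials(trials, cfg)
  xbar <- average_trials(tensors, mode = cfg$averaging_mode, cfg = cfg)
  xbar <- smooth_library(xbar, cfg)
  zbar <- average_behavior(tensors, circular = trials$circular)
  assemble_library(xbar, zbar, tau = tau, delta_ms = delta_ms,
                   circular = trials$circular,
                   behavior_names = trials$behavior_names)
}

#' Partition a library by neurons (e.g. held-in / held-out)
#'
#' @param library a `trajectory_library`
#' @param neurons integer indices of neurons to keep
#' @return a `trajectory_library` over the selected neurons, sharing (c, k)
#'   indexing with the input
#' @export
split_library <- function(library, neurons) {
  neurons <- as.integer(neurons)
  if (any(neurons < 1L | neurons > library$n_neurons))
    .stopf("neuron indices out of range 1..%d", library$n_neurons)
  out <- library
  out$rates <- lapply(library$rates, function(X) X[neurons, , drop = FALSE])
  out$n_neurons <- length(neurons)
  out$neuron_ids <- library$neuron_ids[neurons]
  out
}

#' Configuration for session-section library adaptation
#'
#' @param ridge_lambda L2 penalty on the section transform weights
#'   (default 100, >= 0)
#' @param epoch_weights per-sample observation weights: either NULL (all 1),
#'   a numeric vector over the concatenated library columns, or a list of
#'   per-condition vectors. Weighted samples (e.g. weight 4 on a designated
#'   task epoch) make the transform prioritize fitting those samples.
#' @param soft_norm_constant soft-normalization constant (spikes/s) for the
#'   diagonal normalizer applied to session-wide rates
#' @param rectify rectify adapted rates at 0 (default TRUE)
#' @return an object of class `section_adapt_config`
#' @export
section_adapt_config <- function(ridge_lambda = 100, epoch_weights = NULL,
                                 soft_norm_constant = 5, rectify = TRUE) {
  .check_scalar_num(ridge_lambda, "ridge_lambda", lower = 0)
  structure(list(ridge_lambda = ridge_lambda, epoch_weights = epoch_weights,
                 soft_norm_constant = soft_norm_constant, rectify = rectify),
            class = "section_adapt_config")
}

#' Adapt a session-wide library to session sections
#'
#' For each section d with section-specific rate estimates Y(c, d), learns an
#' affine transform of the session-wide rates, `Y_adapted = (W(d) L + I) X + b(d)`,
#' where L is the diagonal soft-normalizer of the session rates X. W(d) and
#' b(d) come from a weighted ridge regression of the rate residuals Y - X on
#' the normalized session rates, in closed form:
#' `W(d) = Q(d) S P' (P S P' + lambda I)^-1`, `b(d) = mu1(d) - W(d) mu2`,
#' with Q(d) the column-centered residuals, P the column-centered normalized
#' session rates, S the diagonal observation weights, mu1(d)/mu2 the
#' respective column means.
#'
#' @param library a `trajectory_library` (session-wide rates)
#' @param section_estimates list over sections; each element a list of
#'   per-condition N x Kc rate matrices (same N, C, Kc as `library`)
#' @param cfg a [section_adapt_config()]
#' @return list of per-section `trajectory_library` objects
#' @export
adapt_library_sections <- function(library, section_estimates,
                                   cfg = section_adapt_config()) {
  X <- do.call(cbind, library$rates)           # N x K
  N <- nrow(X); K <- ncol(X)
  w <- cfg$epoch_weights
  if (is.null(w)) w <- rep(1, K)
  if (is.list(w)) w <- unlist(w)
  if (length(w) != K) .stopf("epoch_weights must cover all %d library samples", K)
  if (any(w <= 0)) .stopf("epoch_weights must be positive")

  lam_diag <- soft_norm_factors(X, cfg$soft_norm_constant)$scale
  LX <- X * lam_diag                           # Lambda %*% X
  mu2 <- rowMeans(LX)
  P <- LX - mu2
  PSPt <- P %*% (w * t(P))                     # P S P'
  A <- PSPt + diag(cfg$ridge_lambda, N)
  if (cfg$ridge_lambda == 0 && rcond(A) < 1e-12)
    .stopf("normal equations are singular with ridge_lambda = 0; use ridge_lambda > 0")

  ends <- cumsum(library$Kc); starts <- ends - library$Kc + 1L
  lapply(section_estimates, function(Yc_list) {
    if (length(Yc_list) != library$n_conditions)
      .stopf("section estimates must cover all %d conditions", library$n_conditions)
    Y <- do.call(cbind, Yc_list)
    if (!identical(dim(Y), dim(X)))
      .stopf("section estimates must share N and Kc with the library")
    Resid <- Y - X
    mu1 <- rowMeans(Resid)
    Q <- Resid - mu1
    W <- (Q %*% (w * t(P))) %*% solve(A)
    b <- mu1 - W %*% mu2
    adapted <- (W %*% LX + X) + as.vector(b)
    if (cfg$rectify) adapted <- pmax(adapted, 0)
    out <- library
    out$rates <- lapply(seq_len(library$n_conditions), function(c)
      adapted[, starts[c]:ends[c], drop = FALSE])
    out
  })
}
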