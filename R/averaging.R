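# Trial averaging: Type I (arithmetic mean) and Type II (rank-1 trial-space
# PCA reconstruction before averaging), plus circular-aware behavior averaging.

.as_tensor_list <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) list(list(rates = x)) else
    lapply(x, function(e) if (is.list(e)) e else list(rates = e))
}

#' Average single-trial rates across trials
#'
#' Type I averaging is the arithmetic mean over the trial dimension. Type II
#' averaging first soft-normalizes and mean-centers single-trial rates (using
#' scale and offset computed from the Type I averages across all conditions),
#' reconstructs each condition's trials from the first trial-space principal
#' component (a rank-1 reconstruction of the R x (N*Kc) trial matrix), undoes
#' the normalization, and then averages across trials. The rank-1 step
#' suppresses outlier trials without materially changing typical averages.
#'
#' @param tensors per-condition list as returned by [build_rates_from_trials()]
#'   (elements with an N x Kc x R `rates` array), or a single such array.
#' @param mode "TypeI" or "TypeII"
#' @param cfg a [training_config()] (supplies `soft_norm_constant`)
#' @return list of per-condition N x Kc rate matrices
#' @export
average_trials <- function(tensors, mode = c("TypeI", "TypeII"), cfg = training_config()) {
  mode <- match.arg(mode)
  tensors <- .as_tensor_list(tensors)
  for (e in tensors) {
    d <- dim(e$rates)
    if (is.null(d) || length(d) != 3L || d[3L] < 1L)
      .stopf("each condition needs an N x Kc x R rates array with R >= 1")
    if (any(!is.finite(e$rates))) .stopf("non-finite rates in input tensor")
  }
  type1 <- lapply(tensors, function(e) apply(e$rates, c(1L, 2L), mean))
  if (mode == "TypeI") return(type1)

  f <- soft_norm_factors(do.call(cbind, type1), cfg$soft_norm_constant)
  lapply(tensors, function(e) {
    d <- dim(e$rates)
    N <- d[1L]; Kc <- d[2L]; R <- d[3L]
    # normalize each trial with the global per-neuron factors
    norm <- e$rates * f$scale - f$offset  # scale/offset recycle over neuron dim
    Xin <- t(matrix(norm, N * Kc, R))     # R x (N*Kc), one row per trial
    sv <- svd(Xin, nu = 1L, nv = 0L)
    W <- sv$u                              # first trial-space PC (R x 1)
    Xout <- W %*% (t(W) %*% Xin)
    rec <- array(t(Xout), dim = c(N, Kc, R))
    rec <- (rec + f$offset) / f$scale
    apply(rec, c(1L, 2L), mean)
  })
}

#' Average behavioral variables across trials
#'
#' Linear variables are averaged arithmetically. Circular variables (radians)
#' are unwrapped along time within each trial, branch-aligned across trials
#' (each trial is shifted by the multiple of 2*pi that brings it closest to
#' the first trial), averaged, and re-wrapped to `[0, 2*pi)`.
#'
#' @param tensors per-condition list with M x Kc x R `behavior` arrays (as
#'   returned by [build_rates_from_trials()]), or a single such array.
#' @param circular logical vector of length M marking circular variables
#' @return list of per-condition M x Kc behavior matrices
#' @export
average_behavior <- function(tensors, circular = NULL) {
  if (is.array(tensors) && length(dim(tensors)) == 3L)
    tensors <- list(list(behavior = tensors))
  tensors <- lapply(tensors, function(e) if (is.list(e)) e else list(behavior = e))
  M <- dim(tensors[[1L]]$behavior)[1L]
  circular <- circular %||% rep(FALSE, M)
  lapply(tensors, function(e) {
    Z <- e$behavior
    if (any(!is.finite(Z))) .stopf("non-finite behavior in input tensor")
    d <- dim(Z); R <- d[3L]
    out <- apply(Z, c(1L, 2L), mean)
    for (m in which(circular)) {
      un <- sapply(seq_len(R), function(r) unwrap_phase(Z[m, , r]))
      un <- matrix(un, ncol = R)
      ref <- un[, 1L]
      for (r in seq_len(R)[-1L]) {
        shift <- 2 * pi * round(mean(ref - un[, r]) / (2 * pi))
        un[, r] <- un[, r] + shift
      }
      out[m, ] <- wrap_angle(rowMeans(un))
    }
    out
  })
}
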