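# PCA-based smoothing of trial-averaged rates across neurons and conditions.

.top_pcs <- function(X, D) {
  # principal axes of the rows of X (observations in columns); X is already
  # mean-centered by the soft-normalization step, so plain SVD is used
  sv <- svd(X, nu = min(D, nrow(X)), nv = 0L)
  sv$u
}

#' Smooth a library of trial-averaged rates across neurons and/or conditions
#'
#' Rates are soft-normalized and mean-centered per neuron, concatenated across
#' conditions, and projected onto the top `d_neural` neural principal
#' components. Optionally (equal trajectory lengths only) the result is
#' reformatted with one row per condition and projected onto the top
#' `d_condition` condition principal components. Normalization is then
#' reversed and rates are rectified at zero. `"full"` for either
#' dimensionality skips that projection.
#'
#' @param rate_mats list of per-condition N x Kc rate matrices
#' @param cfg a [training_config()] (`d_neural`, `d_condition`,
#'   `soft_norm_constant`)
#' @param rectify rectify negative values at 0 (default TRUE; disable only
#'   for numerical comparisons against linear oracles)
#' @return list of smoothed per-condition N x Kc rate matrices
#' @export
smooth_library <- function(rate_mats, cfg = training_config(), rectify = TRUE) {
  N <- nrow(rate_mats[[1L]])
  C <- length(rate_mats)
  Kc <- vapply(rate_mats, ncol, integer(1))
  d_neural <- cfg$d_neural
  d_condition <- cfg$d_condition

  f <- soft_norm_factors(do.call(cbind, rate_mats), cfg$soft_norm_constant)
  Xin <- soft_norm_apply(do.call(cbind, rate_mats), f)  # N x sum(Kc)

  if (!identical(d_neural, "full")) {
    if (d_neural > N) .stopf("d_neural (%d) exceeds neuron count (%d)", d_neural, N)
    W <- .top_pcs(Xin, d_neural)
    Xin <- W %*% (t(W) %*% Xin)
  }

  if (!identical(d_condition, "full")) {
    if (length(unique(Kc)) != 1L) {
      .warnf("condition smoothing skipped: trajectory lengths differ across conditions (Kc = {%s})",
             paste(unique(Kc), collapse = ","))
    } else {
      if (d_condition > C)
        .stopf("d_condition (%d) exceeds condition count (%d)", d_condition, C)
      ends <- cumsum(Kc)
      starts <- ends - Kc + 1L
      Xc <- t(sapply(seq_len(C), function(c) as.vector(Xin[, starts[c]:ends[c]])))
      Xc <- matrix(Xc, nrow = C)               # C x (N*Kc)
      W <- .top_pcs(Xc, d_condition)
      Xc <- W %*% (t(W) %*% Xc)
      for (c in seq_len(C)) Xin[, starts[c]:ends[c]] <- matrix(Xc[c, ], N, Kc[c])
    }
  }

  Xout <- soft_norm_revert(Xin, f)
  if (rectify) Xout <- pmax(Xout, 0)
  ends <- cumsum(Kc); starts <- ends - Kc + 1L
  lapply(seq_len(C), function(c) Xout[, starts[c]:ends[c], drop = FALSE])
}
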