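# Interpolation between candidate states: the concave spike log-likelihood
# over convex combinations of two rate histories, Newton's method for the
# blend weight, and candidate-selection policy.

#' Candidate-selection policy for interpolation
#'
#' @param n_candidates number of high-likelihood states considered (>= 2
#'   when interpolation beyond index refinement is enabled)
#' @param exclusion_rule how the second (and later) candidates are
#'   restricted relative to ones already chosen: "different_condition"
#'   (must lie on a different trajectory), "min_separation" (may share a
#'   trajectory if at least `min_separation_ms` away), or
#'   "different_library" (must carry a different `library_tags` group)
#' @param min_separation_ms minimum index gap (ms) for "min_separation"
#' @param library_tags optional integer/character tag per condition grouping
#'   conditions into libraries (for "different_library")
#' @return an object of class `candidate_policy`
#' @export
candidate_policy <- function(n_candidates = 2,
                             exclusion_rule = c("different_condition",
                                                "min_separation",
                                                "different_library"),
                             min_separation_ms = 1000,
                             library_tags = NULL) {
  exclusion_rule <- match.arg(exclusion_rule)
  .check_scalar_num(n_candidates, "n_candidates", lower = 2)
  .check_scalar_num(min_separation_ms, "min_separation_ms", lower = 0)
  structure(list(n_candidates = as.integer(n_candidates),
                 exclusion_rule = exclusion_rule,
                 min_separation_ms = min_separation_ms,
                 library_tags = library_tags),
            class = "candidate_policy")
}

#' Spike log-likelihood of a blended rate history, with derivatives
#'
#' For per-bin expected-count histories mu1 and mu2 (neurons x bins) and
#' observed binned counts, evaluates at blend weight alpha the objective
#' `sum log Pois(s | (1-alpha) mu1 + alpha mu2)` together with its first and
#' second derivatives in alpha. The second derivative is
#' `-sum s * ((mu2 - mu1) / mu)^2 <= 0`: the objective is concave. Blended
#' means are floored at `mu_floor` (the lookup path's rate floor expressed
#' as a per-bin count); floored terms are constant in alpha.
#'
#' @param alpha blend weight in `[0, 1]`
#' @param mu1,mu2 per-bin expected counts for the two candidates
#'   (N x (tau_prime+1) matrices)
#' @param counts observed binned counts, same shape
#' @param mu_floor minimum per-bin expected count (default 1 spike/s in
#'   20 ms bins = 0.02)
#' @return list with `value`, `grad`, `hess`
#' @export
interpolation_objective <- function(alpha, mu1, mu2, counts, mu_floor = 0.02) {
  mu <- (1 - alpha) * mu1 + alpha * mu2
  d <- mu2 - mu1
  floored <- mu < mu_floor
  mu[floored] <- mu_floor
  d[floored] <- 0
  value <- sum(counts * log(mu) - mu - lgamma(counts + 1))
  grad <- sum((counts / mu - 1) * d)
  hess <- -sum(counts * (d / mu)^2)
  list(value = value, grad = grad, hess = hess)
}

#' Maximize the blended log-likelihood over alpha by Newton's method
#'
#' Starts at alpha = 0.5 with iterates clamped to `[0, 1]` (the objective is
#' concave, so Newton converges from any start). Stops when the iterate
#' moves less than 0.01, saturates at 0 or 1 (a clamped iterate whose
#' gradient points outward, i.e. the boundary is the constrained optimum;
#' a clamped iterate with an inward gradient keeps iterating), or after 10
#' iterations. A (numerically) linear objective skips the Newton step and
#' returns the better endpoint; an exact tie returns 0.
#'
#' @inheritParams interpolation_objective
#' @param tol stopping tolerance on the change in alpha (default 0.01)
#' @param max_iter iteration cap (default 10)
#' @return `alpha_hat` with attributes `iterations` and `value`
#' @export
optimize_alpha <- function(mu1, mu2, counts, mu_floor = 0.02,
                           tol = 0.01, max_iter = 10) {
  ob <- function(a) interpolation_objective(a, mu1, mu2, counts, mu_floor)
  alpha <- 0.5
  iter <- 0L
  repeat {
    o <- ob(alpha)
    if (o$hess > -1e-12) {                    # linear (or constant) in alpha
      v0 <- ob(0)$value; v1 <- ob(1)$value
      alpha <- if (v1 > v0) 1 else 0          # exact tie -> first candidate
      o <- if (alpha == 1) list(value = v1) else list(value = v0)
      break
    }
    # saturation: at a boundary whose gradient points outward
    if ((alpha == 0 && o$grad <= 0) || (alpha == 1 && o$grad >= 0)) break
    if (iter >= max_iter) break
    iter <- iter + 1L
    alpha_new <- min(1, max(0, alpha - o$grad / o$hess))
    moved <- abs(alpha_new - alpha)
    if (moved < tol) {
      alpha <- alpha_new
      o <- ob(alpha)
      break
    }
    alpha <- alpha_new
  }
  structure(alpha, iterations = iter, value = o$value)
}

# --- candidate utilities used by the decoder -------------------------------

# Per-bin expected-count history (N x (tau_prime+1), oldest bin first) for
# library state (c, k) with k = delta_ms * k_ds.
.state_mu <- function(rate_index, c, k, tau_prime) {
  D <- rate_index$delta_ms
  cols <- k - D * (tau_prime:0)
  rate_index$lam[[c]][, cols, drop = FALSE] * D / 1000
}

# Admissibility of state (c2, k2) as an additional candidate given already
# selected states (list of c/k pairs), under a candidate_policy.
.admissible <- function(c2, k2, chosen, policy) {
  for (ch in chosen) {
    ok <- switch(policy$exclusion_rule,
      different_condition = c2 != ch$c,
      min_separation = (c2 != ch$c) || (abs(k2 - ch$k) >= policy$min_separation_ms),
      different_library = {
        tags <- policy$library_tags
        if (is.null(tags)) .stopf("exclusion_rule 'different_library' needs library_tags")
        tags[c2] != tags[ch$c]
      })
    if (!ok) return(FALSE)
  }
  TRUE
}

# Top-n admissible candidates from the accumulator's q vectors.
.select_candidates <- function(acc, policy, n) {
  D <- acc$rate_index$delta_ms
  first_valid <- acc$tau_prime + 1L
  all_states <- do.call(rbind, lapply(seq_along(acc$q), function(c) {
    K <- length(acc$q[[c]])
    if (K < first_valid) return(NULL)
    kds <- first_valid:K
    cbind(c, kds, acc$q[[c]][kds])
  }))
  ord <- order(-all_states[, 3L], all_states[, 1L], all_states[, 2L])
  chosen <- list()
  for (i in ord) {
    c <- all_states[i, 1L]; k <- all_states[i, 2L] * D
    if (length(chosen) == 0L || .admissible(c, k, chosen, policy))
      chosen[[length(chosen) + 1L]] <- list(c = c, k = k, k_ds = all_states[i, 2L],
                                            loglik = all_states[i, 3L])
    if (length(chosen) >= n) break
  }
  chosen
}

# Index refinement: interpolate state (c, k_ds) with the better in-range
# neighbor (k_ds +/- 1). Returns a refined candidate: base state, neighbor,
# alpha, blended mu history, and objective value.
.index_refine <- function(acc, cand, counts_hist, mu_floor) {
  D <- acc$rate_index$delta_ms
  tp <- acc$tau_prime
  c <- cand$c; kds <- cand$k_ds
  K <- length(acc$q[[c]])
  nbrs <- c(kds - 1L, kds + 1L)
  nbrs <- nbrs[nbrs >= tp + 1L & nbrs <= K]
  mu1 <- .state_mu(acc$rate_index, c, kds * D, tp)
  if (!is.null(acc$active)) {
    mu1 <- mu1[acc$active, , drop = FALSE]
    counts_hist <- counts_hist[acc$active, , drop = FALSE]
  }
  if (length(nbrs) == 0L) {
    val <- interpolation_objective(0, mu1, mu1, counts_hist, mu_floor)$value
    return(list(c = c, k1 = kds * D, k2 = kds * D, alpha = 0, mu = mu1,
                value = val, iterations = 0L))
  }
  k2ds <- nbrs[which.max(acc$q[[c]][nbrs])]
  mu2 <- .state_mu(acc$rate_index, c, k2ds * D, tp)
  if (!is.null(acc$active)) mu2 <- mu2[acc$active, , drop = FALSE]
  a <- optimize_alpha(mu1, mu2, counts_hist, mu_floor)
  list(c = c, k1 = kds * D, k2 = k2ds * D, alpha = as.numeric(a),
       mu = (1 - as.numeric(a)) * mu1 + as.numeric(a) * mu2,
       value = attr(a, "value"), iterations = attr(a, "iterations"))
}

#' Refine the most likely state by interpolation
#'
#' Stage 1 (index refinement): the best state is interpolated with whichever
#' of its two neighbors (one bin width away along the same trajectory) has
#' the larger log-likelihood. Stage 2 (condition/library refinement, when
#' `mode` is "condition" or "library"): additional candidates are picked by
#' log-likelihood under the policy's exclusion rule, each is index-refined,
#' every unordered pair of refined candidates is interpolated, and the pair
#' with the best objective wins. If no admissible second candidate exists,
#' the index-refined estimate is returned with a notice attribute.
#'
#' @param acc a [likelihood_accumulator()] that has absorbed the current bin
#' @param counts_hist N x (tau_prime+1) matrix of binned counts (oldest
#'   first), the same history the accumulator has seen
#' @param policy a [candidate_policy()]
#' @param mode "off", "index", "condition", or "library"
#' @param mu_floor per-bin expected-count floor for blending
#' @return an `interpolation_result`: fields `pairs` (one or two index-refined
#'   candidates: c, k1, k2, alpha), `alpha_top` (between the two pairs),
#'   `value` (objective at the optimum), `iterations`
#' @export
refine_estimate <- function(acc, counts_hist, policy = candidate_policy(),
                            mode = c("condition", "index", "off", "library"),
                            mu_floor = NULL) {
  mode <- match.arg(mode)
  D <- acc$rate_index$delta_ms
  mu_floor <- mu_floor %||% (acc$table$rate_floor * D / 1000)
  best <- most_likely_state(acc)
  if (mode == "off") {
    return(structure(list(
      pairs = list(list(c = best$c, k1 = best$k, k2 = best$k, alpha = 0)),
      alpha_top = 0, value = best$loglik, iterations = 0L),
      class = "interpolation_result"))
  }
  counts_hist <- pmin(counts_hist, acc$table$max_count)
  cand1 <- list(c = best$c, k_ds = best$k_ds, k = best$k)
  ref1 <- .index_refine(acc, cand1, counts_hist, mu_floor)
  if (mode == "index") {
    return(structure(list(
      pairs = list(ref1[c("c", "k1", "k2", "alpha")]),
      alpha_top = 0, value = ref1$value, iterations = ref1$iterations),
      class = "interpolation_result"))
  }
  cands <- .select_candidates(acc, policy, policy$n_candidates)
  if (length(cands) < 2L) {
    res <- structure(list(
      pairs = list(ref1[c("c", "k1", "k2", "alpha")]),
      alpha_top = 0, value = ref1$value, iterations = ref1$iterations),
      class = "interpolation_result")
    attr(res, "notice") <- "no admissible second candidate under the policy"
    return(res)
  }
  refined <- lapply(cands, function(cd) .index_refine(acc, cd, counts_hist, mu_floor))
  ch <- if (!is.null(acc$active)) counts_hist[acc$active, , drop = FALSE] else counts_hist
  best_pair <- NULL
  for (i in seq_len(length(refined) - 1L)) {
    for (j in (i + 1L):length(refined)) {
      a <- optimize_alpha(refined[[i]]$mu, refined[[j]]$mu, ch, mu_floor)
      if (is.null(best_pair) || attr(a, "value") > best_pair$value) {
        best_pair <- list(i = i, j = j, alpha = as.numeric(a),
                          value = attr(a, "value"),
                          iterations = attr(a, "iterations"))
      }
    }
  }
  ri <- refined[[best_pair$i]]; rj <- refined[[best_pair$j]]
  structure(list(
    pairs = list(ri[c("c", "k1", "k2", "alpha")], rj[c("c", "k1", "k2", "alpha")]),
    alpha_top = best_pair$alpha, value = best_pair$value,
    iterations = best_pair$iterations),
    class = "interpolation_result")
}

# --- evaluating an interpolation_result against a library -------------------

# Blended neural state (N rates) at the current indices of an estimate tree.
.estimate_rates <- function(res, library) {
  rate_of_pair <- function(p) {
    x1 <- library$rates[[p$c]][, p$k1]
    x2 <- library$rates[[p$c]][, p$k2]
    (1 - p$alpha) * x1 + p$alpha * x2
  }
  r1 <- rate_of_pair(res$pairs[[1L]])
  if (length(res$pairs) == 1L) return(r1)
  r2 <- rate_of_pair(res$pairs[[2L]])
  (1 - res$alpha_top) * r1 + res$alpha_top * r2
}

# Blended behavioral state (M values); circular variables blend across the
# lesser angle at every pairwise combination.
.estimate_behavior <- function(res, library) {
  blend <- function(z1, z2, alpha) {
    out <- (1 - alpha) * z1 + alpha * z2
    for (m in which(library$circular))
      out[m] <- circ_blend(z1[m], z2[m], alpha)
    out
  }
  beh_of_pair <- function(p) {
    z1 <- library$behavior[[p$c]][, p$k1]
    z2 <- library$behavior[[p$c]][, p$k2]
    blend(z1, z2, p$alpha)
  }
  b1 <- beh_of_pair(res$pairs[[1L]])
  if (length(res$pairs) == 1L) return(b1)
  blend(b1, beh_of_pair(res$pairs[[2L]]), res$alpha_top)
}

# Advance every leaf index of an estimate by `by` samples, clamping at
# trajectory ends (negative `by` rewinds, clamping at 1).
.advance_estimate <- function(res, library, by = 1L) {
  held <- FALSE
  res$pairs <- lapply(res$pairs, function(p) {
    K <- library$Kc[p$c]
    nk1 <- p$k1 + by; nk2 <- p$k2 + by
    if (nk1 > K || nk2 > K || nk1 < 1L || nk2 < 1L) held <<- TRUE
    p$k1 <- min(max(nk1, 1L), K)
    p$k2 <- min(max(nk2, 1L), K)
    p
  })
  attr(res, "held") <- held
  res
}
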