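# Lookup table, library discretization, binning, direct log-likelihood, and
# the recursive per-bin update.

# Direct Poisson oracle for one state: hand-summed dpois over neurons/bins,
# with the same rate floor and clip as the table path.
oracle_loglik <- function(counts_hist, library, table, c, k, delta = 0) {
  tp <- ncol(counts_hist) - 1L
  D <- table$delta_ms
  q <- 0
  for (ip in 0:tp) {
    j <- k - delta - D * ip
    if (j <= 0) next
    lam <- sapply(seq_len(nrow(counts_hist)), function(n)
      mean(library$rates[[c]][n, (j - D + 1):j]))
    lam <- pmax(lam, table$rate_floor)
    v <- round((lam - table$lambda_min) / table$grid_step)
    lam_g <- table$lambda_min + v * table$grid_step
    s <- pmin(counts_hist[, tp + 1L - ip], table$max_count)
    q <- q + sum(pmax(dpois(s, lam_g * D / 1000, log = TRUE), table$clip_floor))
  }
  q
}

test_that("lookup table has the documented dimensions and closed-form entries", {
  tab <- build_lookup_table(0, 200, 0.1, max_count = 20, delta_ms = 20)
  expect_equal(dim(tab$entries), c(21L, 2001L))
  expect_equal(length(tab$rate_grid), 2001L)
  # rate 50 spikes/s in a 20 ms bin has expected count 1: log P(s=1) = -1
  v50 <- which(tab$rate_grid == 50)
  expect_equal(tab$entries[2, v50], -1)
  # clipping floor respected and attained
  expect_true(all(tab$entries >= log(1e-6)))
  expect_equal(min(tab$entries), log(1e-6))
  expect_true(all(tab$entries <= 0))
  # for a fixed rate, the entry is maximized at the count nearest the mean
  mu <- tab$rate_grid[v50] * 20 / 1000
  expect_equal(which.max(tab$entries[, v50]) - 1L, round(mu))
  expect_error(build_lookup_table(0, 100, grid_step = 0), "positive")
})

test_that("library discretization bin-averages and snaps to the nearest grid value", {
  N <- 3; K <- 100
  rates <- list(rbind(rep(50, K), seq(0, 99, length.out = K), rep(0.2, K)))
  beh <- list(matrix(0, 1, K))
  lib <- assemble_library(rates, beh, tau = 39, delta_ms = 20)
  tab <- build_lookup_table(0, 150, 0.1, delta_ms = 20)
  ri <- discretize_library_rates(lib, tab)
  # constant 50 spikes/s: every defined bin-average is 50 and maps to 50.0
  expect_true(all(ri$lam[[1]][1, 20:K] == 50))
  expect_true(all(tab$rate_grid[ri$vidx[[1]][1, 20:K] + 1L] == 50))
  # linear ramp: bin average equals the midpoint of the bin's samples
  j <- 60L
  expect_equal(ri$lam[[1]][2, j], mean(rates[[1]][2, (j - 19):j]))
  # sub-floor rates are raised to the floor before index assignment
  expect_true(all(ri$lam[[1]][3, 20:K] == tab$rate_floor))
  # nearest-grid-index property vs exhaustive search
  set.seed(8)
  lib2 <- random_library(N = 4, C = 2, K = 80, tau = 19, seed = 8)
  ri2 <- discretize_library_rates(lib2, tab)
  for (pick in 1:25) {
    c <- sample(2, 1); n <- sample(4, 1); j <- sample(20:80, 1)
    lam <- ri2$lam[[c]][n, j]
    best <- which.min(abs(tab$rate_grid - lam)) - 1L
    expect_equal(abs(tab$rate_grid[ri2$vidx[[c]][n, j] + 1L] - lam),
                 abs(tab$rate_grid[best + 1L] - lam))
  }
  # rates beyond the table range are refused with advice
  hot <- assemble_library(list(matrix(500, 2, 60)), list(matrix(0, 1, 60)),
                          tau = 19, delta_ms = 20)
  expect_error(discretize_library_rates(hot, tab), "lambda_max")
})

test_that("binning respects window membership and conserves spikes", {
  stream <- matrix(0L, 1, 45)
  stream[1, c(1, 6, 20)] <- 1L               # spikes at t = 0, 5, 19 ms
  b <- bin_spikes(stream, 20)
  expect_equal(b$counts[1, ], c(3L, 0L))
  expect_equal(b$delta, 5L)
  set.seed(2)
  s2 <- matrix(rpois(300, 0.5), 3, 100)
  b2 <- bin_spikes(s2, 20)
  expect_equal(sum(b2$counts) + sum(b2$remainder), sum(s2))
  expect_equal(bin_spikes(s2, 1)$counts, matrix(as.integer(s2), 3, 100))
  expect_error(bin_spikes(matrix(-1, 1, 10), 5), "negative")
})

test_that("direct log-likelihood matches closed forms and counts retrievals", {
  lib <- tiny_library(N = 3, C = 2, K = 120, tau = 39)
  tab <- build_lookup_table(0, 100, 0.1, delta_ms = 20)
  ri <- discretize_library_rates(lib, tab)
  # all-zero counts: q = -sum of per-bin expected (grid) counts
  zeros <- matrix(0L, 3, 2)
  q <- log_likelihood_direct(zeros, ri, tab, c = 1, k = 40)
  expected <- 0
  for (ip in 0:1) {
    j <- 40 - 20 * ip
    lam_g <- tab$rate_grid[ri$vidx[[1]][, j] + 1L]
    expected <- expected - sum(lam_g * 20 / 1000)
  }
  expect_equal(q, expected, tolerance = 1e-12)
  # random instance vs hand-computed Poisson sum
  set.seed(5)
  ch <- matrix(rpois(6, 1.0), 3, 2)
  expect_equal(log_likelihood_direct(ch, ri, tab, c = 2, k = 77),
               oracle_loglik(ch, lib, tab, c = 2, k = 77), tolerance = 1e-12)
  # 200 neurons x 10 bins = 2000 table retrievals
  big <- assemble_library(list(matrix(20, 200, 250)), list(matrix(0, 1, 250)),
                          tau = 199, delta_ms = 20)
  rib <- discretize_library_rates(big, tab)
  qb <- log_likelihood_direct(matrix(0L, 200, 10), rib, tab, c = 1, k = 200,
                              count_retrievals = TRUE)
  expect_equal(attr(qb, "retrievals"), 2000L)
  expect_error(log_likelihood_direct(zeros, ri, tab, c = 1, k = 30),
               "lacks a full history")
})

test_that("recursive update equals the direct sum for random libraries and streams", {
  tab <- build_lookup_table(0, 100, 0.1, delta_ms = 20)
  for (seed in 1:6) {
    lib <- random_library(N = sample(3:8, 1), C = sample(1:3, 1), K = 140,
                          tau = 59, seed = seed, max_rate = 80)
    ri <- discretize_library_rates(lib, tab)
    tp <- 2L                                  # 3-bin window
    acc <- likelihood_accumulator(ri, tab, tp)
    set.seed(seed + 100)
    nb <- 7L
    bins <- matrix(rpois(lib$n_neurons * nb, 0.6), lib$n_neurons, nb)
    hist <- matrix(0L, lib$n_neurons, tp + 1L)
    for (b in seq_len(nb)) {
      hist <- cbind(hist[, -1, drop = FALSE], bins[, b])
      accumulator_push(acc, bins[, b])
      if (b >= tp + 1L) {
        for (c in seq_len(lib$n_conditions)) {
          for (kp in (tp + 1L):ri$Kds[c]) {
            expect_equal(acc$q[[c]][kp],
                         log_likelihood_direct(hist, ri, tab, c, kp * 20L),
                         tolerance = 1e-9)
          }
        }
      }
    }
  }
})

test_that("first bin equals the single-bin r term and zero bins only add zero-count terms", {
  lib <- tiny_library(N = 3, C = 1, K = 120, tau = 59)
  tab <- build_lookup_table(0, 100, 0.1, delta_ms = 20)
  ri <- discretize_library_rates(lib, tab)
  acc <- likelihood_accumulator(ri, tab, 2L)
  s1 <- c(1L, 0L, 2L)
  accumulator_push(acc, s1)
  r1 <- sapply(seq_len(ri$Kds[1]), function(kp)
    sum(tab$entries[cbind(s1 + 1L, ri$vds[[1]][, kp] + 1L)]))
  expect_equal(acc$q[[1]], r1, tolerance = 1e-12)
  q_before <- acc$q[[1]]
  accumulator_push(acc, c(0L, 0L, 0L))
  zero_terms <- sapply(seq_len(ri$Kds[1]), function(kp)
    sum(tab$entries[cbind(1L, ri$vds[[1]][, kp] + 1L)]))
  expect_equal(acc$q[[1]], c(0, q_before[-length(q_before)]) + zero_terms,
               tolerance = 1e-12)
})

test_that("most_likely_state is a brute-force argmax with lexicographic ties", {
  lib <- random_library(N = 5, C = 3, K = 120, tau = 59, seed = 33)
  tab <- build_lookup_table(0, 100, 0.1, delta_ms = 20)
  ri <- discretize_library_rates(lib, tab)
  tp <- 2L
  acc <- likelihood_accumulator(ri, tab, tp)
  set.seed(44)
  hist <- matrix(0L, 5, tp + 1L)
  for (b in 1:5) {
    s <- rpois(5, 0.8)
    hist <- cbind(hist[, -1, drop = FALSE], s)
    accumulator_push(acc, s)
  }
  got <- most_likely_state(acc)
  best <- NULL
  for (c in 1:3) for (kp in (tp + 1L):ri$Kds[c]) {
    q <- log_likelihood_direct(hist, ri, tab, c, kp * 20L)
    if (is.null(best) || q > best$q + 1e-12) best <- list(c = c, kp = kp, q = q)
  }
  expect_equal(got$c, best$c)
  expect_equal(got$k_ds, best$kp)
  expect_equal(got$loglik, best$q, tolerance = 1e-9)

  # exact tie between two conditions -> lowest condition wins
  dup <- assemble_library(list(lib$rates[[2]], lib$rates[[2]]),
                          list(lib$behavior[[2]], lib$behavior[[2]]),
                          tau = 59, delta_ms = 20)
  rid <- discretize_library_rates(dup, tab)
  acc2 <- likelihood_accumulator(rid, tab, tp)
  for (b in 1:4) accumulator_push(acc2, rpois(5, 0.5))
  expect_equal(most_likely_state(acc2)$c, 1L)
})

test_that("a neuron with state-independent rate shifts q uniformly and keeps the argmax", {
  lib <- random_library(N = 4, C = 2, K = 120, tau = 59, seed = 3)
  withc <- assemble_library(
    lapply(lib$rates, function(m) rbind(m, 25)),
    lib$behavior, tau = 59, delta_ms = 20)
  tab <- build_lookup_table(0, 100, 0.1, delta_ms = 20)
  ri1 <- discretize_library_rates(lib, tab)
  ri2 <- discretize_library_rates(withc, tab)
  acc1 <- likelihood_accumulator(ri1, tab, 2L)
  acc2 <- likelihood_accumulator(ri2, tab, 2L)
  set.seed(9)
  for (b in 1:5) {
    s <- rpois(4, 0.7)
    accumulator_push(acc1, s)
    accumulator_push(acc2, c(s, rpois(1, 0.5)))
  }
  valid <- 3:length(acc1$q[[1]])   # k' >= tau'+1; earlier states lack history
  d <- (acc2$q[[1]] - acc1$q[[1]])[valid]
  expect_lt(diff(range(d)), 1e-9)
  d2 <- (acc2$q[[2]] - acc1$q[[2]])[valid]
  expect_equal(d[1], d2[1], tolerance = 1e-9)
  expect_equal(most_likely_state(acc1)[c("c", "k_ds")],
               most_likely_state(acc2)[c("c", "k_ds")])
})
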