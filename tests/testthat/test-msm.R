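# a reversible K-state matrix with prescribed stationary distribution
# (Metropolis construction: uniform proposal, min(1, pi_j/pi_i) acceptance)
metropolis_chain <- function(pi) {
  K <- length(pi)
  P <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) if (i != j)
    P[i, j] <- pmin(1, pi[j] / pi[i]) / (K - 1)
  diag(P) <- 1 - rowSums(P)
  P
}

test_that("transition counting matches direct enumeration and respects boundaries", {
  # single sequence, lag 1, sliding
  C <- count_transitions(list(c(1L, 1L, 2L, 2L)), lag = 1, spacing = 1)
  expect_equal(C$C, matrix(c(1L, 0L, 1L, 1L), 2, 2))

  # two trajectories: no inter-trajectory pair
  C2 <- count_transitions(list(c(1L, 2L), c(2L, 1L)), lag = 1, spacing = 1)
  expect_equal(C2$C, matrix(c(0L, 1L, 1L, 0L), 2, 2))

  # lag shorter than spacing or a non-multiple is rejected
  expect_error(count_transitions(list(1:4), lag = 0.5, spacing = 1), "multiple")
  expect_error(count_transitions(list(1:4), lag = 2.5, spacing = 1), "multiple")

  # lag of 2 frames, independent (non-sliding) counting
  C3 <- count_transitions(list(c(1L, 2L, 1L, 2L, 1L)), lag = 2, spacing = 1,
                          sliding = FALSE)
  expect_equal(C3$C, matrix(c(2L, 0L, 0L, 0L), 2, 2))

  # long chain from a known matrix: row-normalized counts approach P
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  s <- sample_chain(P, n_steps = 10000L, rng_seed = 2L)
  C4 <- count_transitions(s, lag = 1, spacing = 1)
  Phat <- C4$C / rowSums(C4$C)
  expect_lt(max(abs(Phat - P)), 0.02)
})

test_that("ergodic trimming keeps the largest strongly connected component", {
  cm <- function(M) structure(list(C = M, lag = 1, lag_frames = 1L,
                                   sliding = TRUE, K = nrow(M)),
                              class = "CountMatrix")
  # fully connected -> unchanged with identity map
  M <- matrix(c(5L, 1L, 1L, 1L, 5L, 1L, 1L, 1L, 5L), 3, 3)
  tr <- ergodic_trim(cm(M))
  expect_equal(tr$C, M)
  expect_equal(tr$mapping, 1:3)

  # state 3 never returns -> trimmed to {1, 2}
  M2 <- matrix(c(5L, 1L, 0L, 1L, 5L, 1L, 0L, 0L, 0L), 3, 3, byrow = TRUE)
  tr2 <- ergodic_trim(cm(M2))
  expect_equal(tr2$mapping, 1:2)
  expect_equal(tr2$dropped, 3L)
  expect_equal(tr2$C, M2[1:2, 1:2])

  # diagonal-only counts -> single-state SCC, flagged degenerate
  M3 <- diag(c(3L, 2L, 1L))
  expect_warning(tr3 <- ergodic_trim(cm(M3)), "degenerate")
  expect_equal(tr3$K, 1L)

  # all-zero counts -> error
  expect_error(ergodic_trim(cm(matrix(0L, 2, 2))), "zero")
})

cm_from <- function(M, lag = 1) {
  structure(list(C = M, lag = lag, lag_frames = 1L, sliding = TRUE,
                 K = nrow(M)), class = "CountMatrix")
}

test_that("naive and reversible estimators agree on symmetric counts", {
  sym <- ergodic_trim(cm_from(matrix(c(8L, 2L, 2L, 8L), 2, 2)))
  naive <- estimate_transition_matrix(sym, mode = "naive")
  expect_equal(naive$P, matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2), tolerance = 1e-12)
  expect_equal(naive$pi, c(0.5, 0.5), tolerance = 1e-12)

  rev <- estimate_transition_matrix(sym, mode = "reversible-mle")
  expect_equal(rev$P, naive$P, tolerance = 1e-9)
  expect_equal(rev$pi, naive$pi, tolerance = 1e-9)
})

test_that("reversible MLE maximizes the likelihood over the reversible family", {
  # 2 states: every irreducible 2-state chain is reversible, so the
  # constrained MLE equals plain row normalization; verify additionally
  # against an exhaustive 2-D grid search over (p01, p10)
  C <- matrix(c(90L, 10L, 30L, 70L), 2, 2, byrow = TRUE)
  est <- estimate_transition_matrix(ergodic_trim(cm_from(C)), "reversible-mle")
  loglik <- function(P) sum(C[P > 0] * log(P[P > 0]))
  grid <- seq(0.005, 0.995, by = 0.005)
  best <- -Inf; best_pq <- NULL
  for (p in grid) for (q in grid) {
    ll <- loglik(matrix(c(1 - p, p, q, 1 - q), 2, 2, byrow = TRUE))
    if (ll > best) { best <- ll; best_pq <- c(p, q) }
  }
  expect_equal(est$P[1, 2], best_pq[1], tolerance = 0.005)
  expect_equal(est$P[2, 1], best_pq[2], tolerance = 0.005)
  expect_equal(est$pi, c(0.75, 0.25), tolerance = 1e-6)

  # 3 states: compare with a numerical optimizer over the reversible
  # parametrization (symmetric auxiliary matrix X, P = X / rowSums(X))
  C3 <- matrix(c(50L, 5L, 1L, 2L, 60L, 8L, 3L, 4L, 70L), 3, 3, byrow = TRUE)
  est3 <- estimate_transition_matrix(ergodic_trim(cm_from(C3)), "reversible-mle")
  # detailed balance holds
  expect_lt(max(abs(est3$pi * est3$P - t(est3$pi * est3$P))), 1e-10)
  nll <- function(theta) {
    X <- matrix(0, 3, 3)
    X[upper.tri(X, diag = TRUE)] <- exp(theta)
    X[lower.tri(X)] <- t(X)[lower.tri(X)]
    P <- X / rowSums(X)
    -sum(C3 * log(P))
  }
  opt <- optim(rep(0, 6), nll, method = "BFGS", control = list(maxit = 2000))
  ll_est <- sum(C3 * log(est3$P))
  expect_gte(ll_est, -opt$value - 1e-6)        # at least as good as the optimizer
  expect_lt(abs(ll_est - (-opt$value)), 1e-3)  # and the same maximum

  # reversible log-likelihood never exceeds the unconstrained (naive) one
  naive3 <- estimate_transition_matrix(ergodic_trim(cm_from(C3)), "naive")
  expect_lte(sum(C3 * log(est3$P)), sum(C3 * log(naive3$P)) + 1e-12)
})

test_that("transition-model invariants hold after estimation", {
  set.seed(8)
  pi_true <- c(0.4, 0.3, 0.2, 0.1)
  P <- metropolis_chain(pi_true)
  s <- sample_chain(P, n_steps = 20000L, rng_seed = 5L)
  model <- build_msm(s, lag = 1, spacing = 1, mode = "reversible-mle")
  expect_lt(max(abs(rowSums(model$P) - 1)), 1e-12)
  expect_true(all(model$pi > 0))
  expect_equal(sum(model$pi), 1, tolerance = 1e-12)
  expect_lt(max(abs(model$pi %*% model$P - model$pi)), 1e-10)
  expect_equal(model$eigenvalues[1], 1, tolerance = 1e-10)
  db <- model$pi * model$P
  expect_lt(max(abs(db - t(db))), 1e-10)
})

test_that("stationary distribution is recovered from sampled data", {
  pi_true <- c(0.4, 0.3, 0.2, 0.1)
  P <- metropolis_chain(pi_true)
  s <- sample_chain(P, n_steps = 50001L, rng_seed = 11L)
  model <- build_msm(s, lag = 1, spacing = 1, mode = "reversible-mle")
  tv <- 0.5 * sum(abs(model$pi - pi_true))
  expect_lt(tv, 0.02)
})

test_that("implied timescales match the closed form and are flat for Markov chains", {
  # exact eigenvalue: P with mu2 = 0.8 at tau = 1 ns -> t2 = -1/log(0.8)
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  s <- sample_chain(P, n_steps = 200000L, rng_seed = 3L)
  its <- implied_timescales(s, lags = c(1, 2, 3, 4), spacing = 1,
                            mode = "reversible-mle", n_timescales = 1L)
  t2_true <- -1 / log(0.8)
  expect_equal(nrow(its), 4L)
  expect_true(all(its$flag == "ok"))
  expect_true(all(abs(its$timescale - t2_true) / t2_true < 0.15))

  # convergence with sample size: error shrinks from 20k to 200k steps
  s_small <- sample_chain(P, n_steps = 5000L, rng_seed = 3L)
  its_small <- implied_timescales(s_small, lags = 1, spacing = 1,
                                  n_timescales = 1L)
  err_small <- abs(its_small$timescale[1] - t2_true)
  err_big <- abs(its$timescale[its$lag == 1][1] - t2_true)
  expect_lt(err_big, err_small)

  # non-positive eigenvalue -> undefined marker, no crash
  flip <- matrix(c(0.05, 0.95, 0.95, 0.05), 2, 2)  # mu2 = -0.9
  sf <- sample_chain(flip, n_steps = 5000L, rng_seed = 6L)
  its_f <- implied_timescales(sf, lags = 1, spacing = 1, mode = "naive",
                              n_timescales = 1L)
  expect_equal(its_f$flag[1], "undefined")
  expect_true(is.na(its_f$timescale[1]))

  # strongly cyclic chain in naive mode -> complex pair flagged, modulus used
  cyc <- matrix(c(0.1, 0.9, 0.0,
                  0.0, 0.1, 0.9,
                  0.9, 0.0, 0.1), 3, 3, byrow = TRUE)
  sc <- sample_chain(cyc, n_steps = 30000L, rng_seed = 8L)
  its_c <- implied_timescales(sc, lags = 1, spacing = 1, mode = "naive",
                              n_timescales = 2L)
  expect_true(all(its_c$flag == "complex"))
  expect_true(all(is.finite(its_c$timescale)))
  mu_c <- Mod(eigen(cyc, only.values = TRUE)$values[2])
  expect_equal(its_c$eigenvalue[1], mu_c, tolerance = 0.05)
})

test_that("states are ranked by equilibrium population with index tie-break", {
  m <- function(pi) structure(list(P = diag(length(pi)), pi = pi,
                                   eigenvalues = 1, lag = 1, mode = "naive",
                                   K = length(pi), mapping = seq_along(pi)),
                              class = "TransitionModel")
  expect_equal(rank_states(m(c(0.1, 0.7, 0.2)))$state, c(2L, 3L, 1L))
  expect_equal(rank_states(m(rep(1 / 3, 3)))$state, c(1L, 2L, 3L))
})

test_that("sparse matrix serialization round-trips counts and transition matrices", {
  C <- cm_from(matrix(c(8L, 2L, 2L, 8L), 2, 2))
  f <- withr::local_tempfile(fileext = ".txt")
  write_matrix_sparse(C, f)
  back <- read_matrix_sparse(f)
  expect_equal(back$matrix, C$C + 0)
  expect_equal(back$header$K, 2L)

  model <- estimate_transition_matrix(ergodic_trim(C), "reversible-mle")
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_matrix_sparse(model, f2)
  back2 <- read_matrix_sparse(f2)
  expect_equal(back2$matrix, model$P, tolerance = 1e-15)
  expect_equal(back2$header$mode, "reversible-mle")
})
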