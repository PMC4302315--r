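# birth-death chain with given up/down rates; states 1..K
birth_death <- function(p_up, p_down) {
  K <- length(p_up) + 1L
  P <- matrix(0, K, K)
  for (i in seq_len(K)) {
    if (i < K) P[i, i + 1] <- p_up[i]
    if (i > 1) P[i, i - 1] <- p_down[i - 1]
    P[i, i] <- 1 - sum(P[i, ])
  }
  P
}

test_that("committor solves its linear system with correct boundary values", {
  # symmetric 3-state chain 1<->2<->3: q = (0, 0.5, 1)
  P <- birth_death(c(0.5, 0.5), c(0.5, 0.5))
  m <- model_stub(P)
  macro <- macro_stub(1L, 3L, 3L)
  expect_equal(committor(m, macro), c(0, 0.5, 1), tolerance = 1e-12)

  # 4-state birth-death with asymmetric rates vs an independent dense solve
  P4 <- birth_death(c(0.3, 0.2, 0.4), c(0.1, 0.25, 0.3))
  m4 <- model_stub(P4)
  macro4 <- macro_stub(1L, 4L, 4L)
  q <- committor(m4, macro4)
  # oracle: solve the full (I - P) system restricted by boundary conditions
  A <- diag(4) - P4
  A[1, ] <- 0; A[1, 1] <- 1
  A[4, ] <- 0; A[4, 4] <- 1
  q_oracle <- solve(A, c(0, 0, 0, 1))
  expect_equal(q, as.numeric(q_oracle), tolerance = 1e-12)

  # committor is 1 on sink states exactly, 0 on source states exactly
  expect_identical(q[4], 1)
  expect_identical(q[1], 0)

  # monotone along a 1-D birth-death chain
  P6 <- birth_death(rep(0.3, 5), rep(0.2, 5))
  q6 <- committor(model_stub(P6), macro_stub(1L, 6L, 6L))
  expect_true(all(diff(q6) >= -1e-12))
})

test_that("net flux follows the TPT formula and conserves flux", {
  P <- birth_death(c(0.5, 0.5), c(0.5, 0.5))
  pi <- rep(1 / 3, 3)
  m <- model_stub(P, pi = pi)
  macro <- macro_stub(1L, 3L, 3L)
  q <- committor(m, macro)
  fl <- net_flux(m, q, macro)
  # hand evaluation: f_12 = pi_1 * 1 * 0.5 * 0.5; f_23 = pi_2 * 0.5 * 0.5 * 1
  expect_equal(fl$net[1, 2], 1 / 3 * 0.5 * 0.5, tolerance = 1e-12)
  expect_equal(fl$net[2, 3], 1 / 3 * 0.5 * 0.5, tolerance = 1e-12)
  # reverse directions carry zero net flux; sink rows are zero
  expect_equal(fl$net[2, 1], 0)
  expect_equal(fl$net[3, 2], 0)
  expect_true(all(fl$net[3, ] == 0))
  # conservation at intermediate state 2: inflow equals outflow
  expect_equal(sum(fl$net[, 2]), sum(fl$net[2, ]), tolerance = 1e-12)
  expect_equal(fl$total, fl$net[1, 2], tolerance = 1e-12)
})

test_that("pathway decomposition extracts bottleneck paths with the flux threshold", {
  # single chain: one pathway carrying the total flux
  P <- birth_death(c(0.5, 0.5), c(0.5, 0.5))
  m <- model_stub(P, pi = rep(1 / 3, 3))
  macro <- macro_stub(1L, 3L, 3L)
  res <- tpt_analysis(m, macro)
  expect_equal(nrow(res$pathways), 1L)
  expect_equal(res$pathways$path[1], "1,2,3")
  expect_equal(res$pathways$flux[1], res$total_flux, tolerance = 1e-12)

  # hand-built network with two parallel routes of bottleneck flux 10 and 6
  net <- matrix(0, 4, 4)
  net[1, 2] <- 10; net[2, 4] <- 10   # route A
  net[1, 3] <- 6;  net[3, 4] <- 6    # route B
  macro2 <- macro_stub(1L, 4L, 4L)
  paths_50 <- top_pathways(net, macro2, threshold_fraction = 0.5)
  expect_equal(nrow(paths_50), 2L)
  expect_equal(paths_50$path, c("1,2,4", "1,3,4"))
  expect_equal(paths_50$flux, c(10, 6))

  paths_70 <- top_pathways(net, macro2, threshold_fraction = 0.7)
  expect_equal(nrow(paths_70), 1L)
  expect_equal(paths_70$path, "1,2,4")

  # exhaustive decomposition (threshold 0) recovers the total flux
  paths_all <- top_pathways(net, macro2, threshold_fraction = 0)
  expect_equal(sum(paths_all$flux), 16, tolerance = 1e-8)

  # zero flux -> empty table with a warning
  expect_warning(p0 <- top_pathways(matrix(0, 3, 3), macro_stub(1L, 3L, 3L)),
                 "zero")
  expect_equal(nrow(p0), 0L)
})

test_that("MFPT matches closed forms and an independent series summation", {
  # 2-state geometric case: P_12 = 0.1 -> MFPT = 10 * tau
  P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE)
  m <- model_stub(P, lag = 1)
  expect_equal(mfpt(m, macro_stub(1L, 2L, 2L))$mfpt, 10, tolerance = 1e-12)
  # in physical time: tau = 2 ns doubles the MFPT
  m2 <- model_stub(P, lag = 2)
  expect_equal(mfpt(m2, macro_stub(1L, 2L, 2L))$mfpt, 20, tolerance = 1e-12)

  # source adjacent to sink with P(source -> sink) = 1 -> MFPT = tau
  P1 <- matrix(c(0, 1, 0.5, 0.5), 2, 2, byrow = TRUE)
  expect_equal(mfpt(model_stub(P1, lag = 3), macro_stub(1L, 2L, 2L))$mfpt, 3,
               tolerance = 1e-12)

  # birth-death chain vs the standard first-passage recursion
  p_up <- c(0.3, 0.2, 0.4); p_down <- c(0.1, 0.25, 0.3)
  P4 <- birth_death(p_up, p_down)
  m4 <- model_stub(P4, lag = 1)
  got <- mfpt(m4, macro_stub(1L, 4L, 4L))
  # analytic recursion for birth-death hitting times of state K:
  # h_K = 0; going down from i, h_i = (1 + p_down_i * h_{i-1}) ... solve the
  # tridiagonal system explicitly via the classical sum formula
  K <- 4
  h <- numeric(K)   # h[i] = expected steps from i to K
  # solve by backward substitution on the tridiagonal equations
  A <- diag(K - 1) - P4[1:(K - 1), 1:(K - 1)]
  h[1:(K - 1)] <- solve(A, rep(1, K - 1))
  expect_equal(got$mfpt_states[1:3], h[1:3], tolerance = 1e-10)

  # brute-force expected hitting time by dense series summation on 5 states
  P5 <- birth_death(c(0.2, 0.3, 0.25, 0.4), c(0.15, 0.1, 0.2, 0.35))
  m5 <- model_stub(P5, lag = 1)
  got5 <- mfpt(m5, macro_stub(1L, 5L, 5L))
  Q <- P5[1:4, 1:4]   # transient block when state 5 is absorbing
  series <- diag(4)
  term <- diag(4)
  for (n in 1:20000) {
    term <- term %*% Q
    series <- series + term
  }
  h5 <- as.numeric(series %*% rep(1, 4))   # sum_n (Q^n) 1 = expected steps
  expect_equal(got5$mfpt_states[1:4], h5, tolerance = 1e-8)
  expect_equal(got5$rate, 1 / got5$mfpt, tolerance = 1e-12)

  # unreachable sink is an error
  Pbad <- diag(2)
  expect_error(mfpt(model_stub(Pbad, pi = c(0.5, 0.5)), macro_stub(1L, 2L, 2L)),
               "unreachable")
})

test_that("full TPT analysis satisfies its conservation invariants", {
  set.seed(14)
  # random reversible 6-state model
  X <- matrix(runif(36, 0.01, 1), 6, 6)
  X <- X + t(X)
  P <- X / rowSums(X)
  pi <- rowSums(X) / sum(X)
  m <- model_stub(P, pi = pi)
  macro <- macro_stub(c(1L, 2L), 6L, 6L)
  res <- tpt_analysis(m, macro, threshold_fraction = 0)
  q <- res$committor
  expect_true(all(q >= 0 & q <= 1))
  # pairwise one-directionality
  expect_true(all(res$net_flux * t(res$net_flux) <= 1e-20))
  # conservation at intermediates
  for (i in macro$intermediate)
    expect_equal(sum(res$net_flux[, i]), sum(res$net_flux[i, ]),
                 tolerance = 1e-10)
  # complete decomposition sums to the total reactive flux
  expect_equal(sum(res$pathways$flux), res$total_flux, tolerance = 1e-8)
})

test_that("macrostates are classified by distance and reference RMSD cutoffs", {
  run <- toy_run()
  gt <- run$sim$ground_truth
  ens <- run$sim$ensemble
  ref1 <- msmpose:::get_frame(ens, 1L, 1L)
  macro <- define_macrostates(run$model, ens, run$cm$centers, gt$bound_pose,
                              ref_frame = ref1)
  expect_gt(length(macro$source), 0L)
  expect_gt(length(macro$sink), 0L)
  expect_length(intersect(macro$source, macro$sink), 0L)
  # every source state's medoid is > 20 A from the protein; sinks < 3 A RMSD
  expect_true(all(macro$min_dist[macro$source] > 20))
  expect_true(all(macro$rmsd_ref[macro$sink] < 3))
  # the designed bound well is in the sink: the top-populated state is bound
  top <- rank_states(run$model)$state[1]
  expect_true(top %in% macro$sink)
  # impossible cutoffs raise instructive errors
  expect_error(define_macrostates(run$model, ens, run$cm$centers, gt$bound_pose,
                                  ref_frame = ref1, unbound_cutoff = 1e6),
               "unbound")
  expect_error(define_macrostates(run$model, ens, run$cm$centers, gt$bound_pose,
                                  ref_frame = ref1, bound_cutoff = 1e-6),
               "bound")
})
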