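test_that("init_Q draws reproducible simplex columns", {
  expect_equal(init_Q(1, 5, seed = 1), matrix(1, 1, 5))
  Q <- init_Q(4, 20, seed = 7)
  expect_true(all(Q >= 0))
  expect_equal(colSums(Q), rep(1, 20))
  expect_identical(Q, init_Q(4, 20, seed = 7))
  expect_false(identical(Q, init_Q(4, 20, seed = 8)))
})

test_that("update_P solves the box-constrained locus problems", {
  # individuals each purely from one population
  Q <- diag(2)
  G <- matrix(c(2, 0), 1, 2)
  expect_equal(update_P(Q, G), matrix(c(1, 0), 1, 2))

  # zero-residual recovery
  set.seed(301)
  Ptrue <- matrix(runif(20), 10, 2)
  Qtrue <- rand_admix(2, 6)
  G0 <- 2 * compute_m(Ptrue, Qtrue)  # exact real-valued "genotypes"
  expect_equal(update_P(Qtrue, G0), Ptrue, tolerance = 1e-8)

  # per-locus agreement with the bound-configuration oracle
  G <- matrix(sample(0:2, 4 * 6, TRUE), 4, 6)
  P <- update_P(Qtrue, G)
  for (l in 1:4)
    expect_equal(P[l, ], oracle_bvls(2 * t(Qtrue), G[l, ]),
                 tolerance = 1e-6)
})

test_that("update_Q solves the simplex-constrained penalized problems", {
  set.seed(302)
  P <- matrix(runif(100), 50, 2)
  Qtrue <- rand_admix(2, 5)
  G0 <- 2 * compute_m(P, Qtrue)
  expect_equal(update_Q(P, G0, alpha = 1), Qtrue, tolerance = 1e-6)

  # overwhelming admixture prior pulls every column to the barycenter
  G <- matrix(sample(0:2, 50 * 5, TRUE), 50, 5)
  Qbig <- update_Q(P, G, alpha = 1e6)
  expect_true(max(abs(Qbig - 0.5)) < 1e-3)

  # K = 3 agreement with the support-enumeration oracle
  P3 <- matrix(runif(90), 30, 3)
  G3 <- matrix(sample(0:2, 30 * 6, TRUE), 30, 6)
  ne <- build_normal_equations(P3, G3, 1.4)
  Q3 <- update_Q(P3, G3, 1.4)
  for (j in 1:6)
    expect_equal(Q3[, j], oracle_simplex(ne$gram, ne$rhs[, j]),
                 tolerance = 1e-6)
})

test_that("fit recovers a noiseless pure-population construction", {
  set.seed(303)
  M <- 60; N <- 12; K <- 2
  Ptrue <- matrix(sample(0:1, M * K, TRUE), M, K)
  Qtrue <- matrix(0, K, N)
  Qtrue[cbind(sample(1:K, N, TRUE), 1:N)] <- 1
  G <- 2 * compute_m(Ptrue, Qtrue)
  stopifnot(all(G %in% c(0, 1, 2)))

  success <- 0
  for (s in 1:5) {
    ft <- fit_admixture(G, config = fit_config(K, seed = 4000 + s))
    expect_true(all(diff(ft$objective_trace) <=
                      1e-6 * pmax(1, abs(ft$objective_trace[-ft$n_iter]))))
    if (ft$objective_trace[ft$n_iter] <= 1e-6) {
      perm <- align_populations(ft$Q, Qtrue)
      expect_equal(ft$Q[perm, ], Qtrue, tolerance = 1e-4)
      expect_equal(ft$P[, perm], Ptrue, tolerance = 1e-4)
      success <- success + 1
    }
  }
  expect_gte(success, 1)
})

test_that("fit with K = 1 matches the per-locus closed form", {
  set.seed(304)
  G <- matrix(sample(0:2, 40 * 6, TRUE), 40, 6)
  ft <- fit_admixture(G, config = fit_config(1, seed = 1))
  expect_equal(ft$Q, matrix(1, 1, 6))
  expect_equal(drop(ft$P), pmin(pmax(rowMeans(G) / 2, 0), 1),
               tolerance = 1e-10)
})

test_that("huge epsilon stops at the first comparison, reported converged", {
  set.seed(305)
  G <- matrix(sample(0:2, 30 * 8, TRUE), 30, 8)
  ft <- fit_admixture(G, config = fit_config(2, epsilon = 1e10, seed = 2))
  expect_true(ft$converged)
  expect_gte(ft$n_iter, 1)
  expect_lte(ft$n_iter, 2)
})

test_that("objective trace is non-increasing on noisy data", {
  set.seed(306)
  for (alpha in c(0.5, 1, 2)) {
    sim <- simulate_admixture(sim_scenario(150, 25, 3, alpha = alpha))
    ft <- fit_admixture(sim$G, config = fit_config(3, alpha = alpha,
                                                   seed = 11))
    expect_true(all(diff(ft$objective_trace) <= 1e-6))
    if (ft$converged) {
      tr <- ft$objective_trace
      expect_lt(abs(tr[ft$n_iter] - tr[ft$n_iter - 1]), ft$epsilon)
      # fixed point: one extra sweep moves the criterion by < epsilon
      P1 <- update_P(ft$Q, sim$G)
      Q1 <- update_Q(P1, sim$G, alpha)
      expect_lt(abs(penalized_objective(P1, Q1, sim$G, alpha) -
                      tr[ft$n_iter]), ft$epsilon)
    }
  }
})

test_that("permuting individuals permutes the fit identically", {
  set.seed(307)
  sim <- simulate_admixture(sim_scenario(80, 10, 2))
  perm <- sample(10)
  Q0 <- init_Q(2, 10, seed = 5)
  f1 <- fit_admixture(sim$G, config = fit_config(2), Q_init = Q0)
  f2 <- fit_admixture(sim$G[, perm], config = fit_config(2),
                      Q_init = Q0[, perm])
  expect_equal(f2$Q, f1$Q[, perm], tolerance = 1e-10)
  expect_equal(f2$P, f1$P, tolerance = 1e-10)
  expect_equal(f2$objective_trace, f1$objective_trace, tolerance = 1e-10)
})

test_that("fit errors on inconsistent sizes and reports non-convergence", {
  G <- matrix(sample(0:2, 12, TRUE), 3, 4)
  expect_error(fit_admixture(G, config = fit_config(5)), "at least K")
  set.seed(308)
  sim <- simulate_admixture(sim_scenario(100, 20, 2))
  ft <- fit_admixture(sim$G, config = fit_config(2, max_iter = 3, seed = 1))
  expect_false(ft$converged)
  expect_equal(ft$n_iter, 3)
})

test_that("known-Q least-squares estimator matches its closed form", {
  set.seed(309)
  Ptrue <- matrix(runif(40), 20, 2)
  Q <- rand_admix(2, 15)
  G0 <- 2 * compute_m(Ptrue, Q)
  expect_equal(estimate_p_known_Q(G0, Q), Ptrue, tolerance = 1e-10)

  # K = 1: the estimate is half the locus mean
  Q1 <- matrix(1, 1, 15)
  G <- matrix(sample(0:2, 20 * 15, TRUE), 20, 15)
  expect_equal(drop(estimate_p_known_Q(G, Q1)), rowMeans(G) / 2)

  # generic case: per-locus normal-equations solve
  Phat <- estimate_p_known_Q(G, Q)
  for (l in 1:5)
    expect_equal(Phat[l, ],
                 drop(solve(tcrossprod(Q), Q %*% G[l, ])) / 2,
                 tolerance = 1e-10)

  expect_error(estimate_p_known_Q(G, matrix(0.5, 2, 15)), "singular")
})

test_that("known-P estimator recovers Q and its orthogonal closed form", {
  set.seed(310)
  P <- matrix(runif(160), 80, 2)
  Qtrue <- rand_admix(2, 8)
  G0 <- 2 * compute_m(P, Qtrue)
  expect_equal(estimate_q_known_P(G0, P, alpha = 1), Qtrue,
               tolerance = 1e-6)

  # orthogonal design: rows alternate (1,0) and (0,1), so with
  # q2 = 1 - q1 the criterion is a scalar quadratic in q1 with closed-form
  # minimizer (sum(gA) - sum(gB) + 2 nB) / (2 (nA + nB)), clamped to [0,1]
  Port <- matrix(0, 40, 2)
  Port[seq(1, 39, 2), 1] <- 1
  Port[seq(2, 40, 2), 2] <- 1
  G <- matrix(sample(0:2, 40 * 6, TRUE), 40, 6)
  Qhat <- estimate_q_known_P(G, Port, alpha = 1)
  gA <- colSums(G[seq(1, 39, 2), ])
  gB <- colSums(G[seq(2, 40, 2), ])
  q1 <- pmin(pmax((gA - gB + 2 * 20) / 80, 0), 1)
  expect_equal(Qhat[1, ], q1, tolerance = 1e-8)
  expect_equal(Qhat[2, ], 1 - q1, tolerance = 1e-8)
})

test_that("single-locus ML estimator matches analytic and grid oracles", {
  set.seed(311)
  Q <- rand_admix(2, 12)
  # all genotypes 2: likelihood maximized at p = (1, 1)
  expect_equal(ml_estimate_p_known_Q(matrix(2, 1, 12), Q, 1), c(1, 1),
               tolerance = 1e-4)

  # K = 1: binomial MLE is the half-mean
  g <- sample(0:2, 12, TRUE)
  expect_equal(ml_estimate_p_known_Q(matrix(g, 1), matrix(1, 1, 12), 1),
               mean(g) / 2, tolerance = 1e-5)

  # K = 2 against a dense grid search (step 0.001)
  G <- matrix(sample(0:2, 12, TRUE), 1, 12)
  phat <- ml_estimate_p_known_Q(G, Q, 1)
  gr <- seq(0, 1, by = 0.001)
  best <- c(NA, NA); best_ll <- -Inf
  for (p1 in gr) {
    m <- pmin(pmax(p1 * Q[1, ] + outer(Q[2, ], gr), 1e-10), 1 - 1e-10)
    ll <- drop(G[1, ] %*% log(m) + (2 - G[1, ]) %*% log1p(-m))
    if (max(ll) > best_ll) {
      best_ll <- max(ll)
      best <- c(p1, gr[which.max(ll)])
    }
  }
  expect_equal(phat, best, tolerance = 2e-3)
})
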