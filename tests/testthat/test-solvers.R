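test_that("bvls handles interior and fully-clamped trivial cases", {
  I2 <- diag(2)
  expect_equal(bvls_multirhs(I2, cbind(c(0.3, 0.6))), cbind(c(0.3, 0.6)))
  expect_equal(bvls_multirhs(I2, cbind(c(-0.4, 1.7))), cbind(c(0, 1)))
})

test_that("bvls agrees with the bound-configuration brute force", {
  set.seed(201)
  for (rep in 1:20) {
    K <- sample(2:3, 1)
    A <- matrix(rnorm(6 * K), 6, K)
    B <- matrix(rnorm(6 * 5, sd = 2), 6, 5)
    X <- bvls_multirhs(A, B)
    for (j in 1:5) {
      expect_equal(X[, j], oracle_bvls(A, B[, j]), tolerance = 1e-6)
    }
    # KKT conditions at the returned point
    Gr <- crossprod(A) %*% X - crossprod(A, B)
    interior <- X > 1e-8 & X < 1 - 1e-8
    expect_true(all(abs(Gr[interior]) < 1e-6))
    expect_true(all(Gr[X <= 1e-8] > -1e-6))
    expect_true(all(Gr[X >= 1 - 1e-8] < 1e-6))
  }
})

test_that("bvls with infinite bounds reproduces ordinary least squares", {
  set.seed(202)
  for (rep in 1:10) {
    A <- matrix(rnorm(24), 8, 3)
    B <- matrix(rnorm(16), 8, 2)
    X <- bvls_multirhs(A, B, lower = -Inf, upper = Inf)
    expect_equal(X, solve(crossprod(A), crossprod(A, B)), tolerance = 1e-10)
  }
})

test_that("grouped-column solving is bit-identical to per-column solving", {
  set.seed(203)
  A <- matrix(rnorm(12), 6, 2)
  B <- matrix(rnorm(42, sd = 2), 6, 7)
  AtA <- crossprod(A)
  AtB <- crossprod(A, B)
  X1 <- admixls:::bvls_normal(AtA, AtB, 0, 1)
  X2 <- vapply(1:7, function(j)
    admixls:::bvls_normal(AtA, AtB[, j, drop = FALSE], 0, 1)[, 1],
    numeric(2))
  expect_identical(X1, X2)

  P <- matrix(runif(60), 20, 3)
  G <- matrix(sample(0:2, 20 * 8, TRUE), 20, 8)
  ne <- build_normal_equations(P, G, 1.3)
  Q1 <- simplex_ls_multirhs(ne)
  Q2 <- vapply(1:8, function(j) {
    ne_j <- ne
    ne_j$rhs <- ne$rhs[, j, drop = FALSE]
    simplex_ls_multirhs(ne_j)[, 1]
  }, numeric(3))
  expect_identical(Q1, Q2)
})

test_that("bvls rejects rank-deficient designs", {
  A <- cbind(1:4, 2 * (1:4))
  expect_error(bvls_multirhs(A, cbind(rnorm(4))), "rank deficient")
  expect_error(bvls_multirhs(matrix(1, 2, 3), matrix(1, 2, 1)),
               "rank deficient")
})

test_that("normal equations match their definition", {
  set.seed(204)
  P <- matrix(runif(150), 50, 3)
  G <- matrix(sample(0:2, 50 * 4, TRUE), 50, 4)
  ne <- build_normal_equations(P, G, alpha = 2)
  expect_equal(ne$gram, 4 * t(P) %*% P + 9 * diag(3))
  expect_equal(ne$rhs, 2 * t(P) %*% G + 3)
  expect_equal(ne$U, solve(ne$gram))
  expect_equal(ne$a * sum(ne$U), 1)
  expect_true(isSymmetric(ne$gram, tol = 1e-12))

  ne1 <- build_normal_equations(P, G, alpha = 1)
  expect_equal(ne1$gram, 4 * t(P) %*% P)
  expect_equal(ne1$rhs, 2 * t(P) %*% G)

  # single-locus rank deficiency
  expect_error(build_normal_equations(matrix(c(1, 0), 1, 2),
                                      matrix(2, 1, 1), alpha = 1),
               "rank deficient")
  # strong sparsity prior overwhelming a tiny Gram matrix
  expect_error(build_normal_equations(matrix(c(0.5, 0.5), 1, 2),
                                      matrix(1, 1, 1), alpha = 0.5),
               "too strong")
  expect_error(build_normal_equations(P, G, alpha = -1), "alpha")
})

test_that("simplex-constrained solver agrees with support enumeration", {
  set.seed(205)
  for (rep in 1:20) {
    P <- matrix(runif(60), 20, 3)
    G <- matrix(sample(0:2, 20 * 6, TRUE), 20, 6)
    alpha <- sample(c(0.8, 1, 1.5), 1)
    ne <- build_normal_equations(P, G, alpha)
    Q <- simplex_ls_multirhs(ne)
    expect_true(all(Q >= 0))
    expect_equal(colSums(Q), rep(1, 6), tolerance = 1e-12)
    for (j in 1:6) {
      expect_equal(Q[, j], oracle_simplex(ne$gram, ne$rhs[, j]),
                   tolerance = 1e-6)
    }
  }
})

test_that("simplex solver handles K = 1 and interior closed form", {
  P <- matrix(runif(10), 10, 1)
  G <- matrix(sample(0:2, 30, TRUE), 10, 3)
  expect_equal(simplex_ls_multirhs(build_normal_equations(P, G)),
               matrix(1, 1, 3))

  # interior case: solution equals the Lagrange closed form on all of K
  set.seed(206)
  Ptrue <- matrix(runif(200), 100, 2)
  Qtrue <- rand_admix(2, 4)
  G0 <- round(2 * compute_m(Ptrue, Qtrue))  # low-noise, interior optimum
  ne <- build_normal_equations(Ptrue, G0, 1)
  Q <- simplex_ls_multirhs(ne)
  Uj <- rowSums(ne$U)
  closed <- ne$a * Uj +
    (ne$U - ne$a * (ne$U %*% ne$J %*% ne$U)) %*% ne$rhs
  if (all(closed >= 0)) {
    expect_equal(Q, closed, tolerance = 1e-10)
    expect_equal(colSums(closed), rep(1, 4), tolerance = 1e-10)
  }
})

test_that("constrained solutions beat random feasible points", {
  set.seed(207)
  P <- matrix(runif(90), 30, 3)
  G <- matrix(sample(0:2, 30 * 5, TRUE), 30, 5)
  ne <- build_normal_equations(P, G, 1.2)
  Q <- simplex_ls_multirhs(ne)
  objective <- function(q, j)
    drop(q %*% ne$gram %*% q - 2 * sum(ne$rhs[, j] * q))
  for (j in 1:5) {
    opt <- objective(Q[, j], j)
    rnd <- replicate(100, objective(rand_admix(3, 1)[, 1], j))
    expect_true(all(opt <= rnd + 1e-9))
  }
})
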