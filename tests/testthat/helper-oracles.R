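# Independent brute-force oracles for the constrained least-squares
# kernels.  Both enumerate every bound/support configuration, solve the
# equality-constrained subproblem for each, and return the feasible
# candidate with the smallest objective.  They share no code with the
# package solvers.

# min ||A x - b||^2 over lower <= x <= upper by enumerating all 3^K
# assignments of each variable to {at lower, passive, at upper}.
oracle_bvls <- function(A, b, lower = 0, upper = 1) {
  K <- ncol(A)
  b <- as.numeric(b)
  configs <- expand.grid(rep(list(c(-1L, 0L, 1L)), K))
  best <- NULL
  best_obj <- Inf
  for (r in seq_len(nrow(configs))) {
    s <- as.integer(configs[r, ])
    x <- numeric(K)
    x[s == -1L] <- lower
    x[s == 1L] <- upper
    pas <- which(s == 0L)
    if (length(pas)) {
      resid <- b - A[, s != 0L, drop = FALSE] %*% x[s != 0L]
      Ap <- A[, pas, drop = FALSE]
      x[pas] <- qr.solve(Ap, resid)
    }
    if (any(x < lower - 1e-9) || any(x > upper + 1e-9)) next
    obj <- sum((A %*% x - b)^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- x
    }
  }
  best
}

# min x' gram x - 2 rhs' x over the probability simplex by enumerating all
# nonempty support sets and solving each sum-to-one equality subproblem
# with a textbook bordered (KKT) system.
oracle_simplex <- function(gram, rhs) {
  K <- nrow(gram)
  rhs <- as.numeric(rhs)
  best <- NULL
  best_obj <- Inf
  for (mask in seq_len(2^K - 1L)) {
    S <- which(bitwAnd(mask, 2L^(seq_len(K) - 1L)) > 0L)
    ns <- length(S)
    kkt <- rbind(cbind(2 * gram[S, S, drop = FALSE], rep(1, ns)),
                 c(rep(1, ns), 0))
    sol <- tryCatch(solve(kkt, c(2 * rhs[S], 1)), error = function(e) NULL)
    if (is.null(sol)) next
    x <- numeric(K)
    x[S] <- sol[seq_len(ns)]
    if (any(x < -1e-9)) next
    obj <- drop(x %*% gram %*% x - 2 * sum(rhs * x))
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- x
    }
  }
  best
}

# random valid admixture matrix (columns on the simplex)
rand_admix <- function(K, N) {
  Q <- matrix(stats::runif(K * N), K, N)
  sweep(Q, 2, colSums(Q), "/")
}
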