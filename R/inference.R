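# Two-block coordinate descent for the least-squares admixture criterion,
# plus the one-shot "known P" / "known Q" estimators used in the best-case
# experiments and the theory validation.

#' Random simplex initialization of the admixture matrix
#'
#' Draws each column as K independent uniform deviates normalized to sum to
#' one.
#'
#' @param K number of populations.
#' @param N number of individuals.
#' @param seed optional RNG seed; `NULL` consumes the current stream.
#' @return K x N admixture matrix.
#' @export
init_Q <- function(K, N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- matrix(stats::runif(K * N), K, N)
  sweep(Q, 2, colSums(Q), "/")
}

#' Allele-frequency update (P-step)
#'
#' For fixed Q, every locus row of P solves the independent box-constrained
#' problem `min ||2 Q' p - g_l||^2` over `0 <= p <= 1`.  All M loci are
#' solved in one multi-right-hand-side call.
#'
#' @param Q K x N admixture matrix with full row rank.
#' @param G M x N genotype matrix.
#' @return M x K allele-frequency matrix.
#' @export
update_P <- function(Q, G) {
  if (ncol(Q) != ncol(G))
    stop(sprintf("dimension mismatch: Q is %s but G is %s",
                 dim_string(Q), dim_string(G)), call. = FALSE)
  # design A = 2 Q' shared by every locus: A'A = 4 Q Q', A'G' = 2 Q G'
  t(bvls_normal(4 * tcrossprod(Q), 2 * tcrossprod(Q, G), 0, 1))
}

#' Admixture update (Q-step)
#'
#' For fixed P, every column of Q solves the simplex-constrained penalized
#' problem `min ||2 P q - g_i||^2 + K^2 (alpha - 1) ||q - 1/K||^2` subject
#' to `q >= 0`, `sum(q) = 1`.
#'
#' @param P M x K allele-frequency matrix with full column rank.
#' @param G M x N genotype matrix.
#' @param alpha degree of admixture (> 0); 1 leaves the criterion
#'   unpenalized.
#' @return K x N admixture matrix.
#' @export
update_Q <- function(P, G, alpha = 1) {
  simplex_ls_multirhs(build_normal_equations(P, G, alpha))
}

#' Fit the least-squares admixture model
#'
#' Alternates [update_P()] and [update_Q()] from a random simplex
#' initialization of Q until the absolute change in the penalized criterion
#' between consecutive sweeps falls below `epsilon`, or `max_iter` sweeps
#' are reached.  Each block update solves its convex subproblem to global
#' optimality, so the criterion never increases.
#'
#' @param G M x N genotype matrix (entries 0, 1, 2).
#' @param K number of ancestral populations (used when `config` is not
#'   supplied).
#' @param alpha,epsilon,max_iter,seed see [fit_config()].
#' @param config optionally, a ready-made [fit_config()] object overriding
#'   the individual arguments.
#' @param Q_init optional K x N starting admixture matrix in place of the
#'   random initialization.
#' @param verbose emit one message per sweep (iteration, objective, delta).
#' @return an object of class `admix_fit` with elements `P`, `Q`,
#'   `objective_trace`, `n_iter`, `converged`, `K`, `alpha`, `epsilon`,
#'   `seed`.
#' @export
fit_admixture <- function(G, K, alpha = 1, epsilon = NULL,
                          max_iter = 2000L, seed = NULL, config = NULL,
                          Q_init = NULL, verbose = FALSE) {
  if (is.null(config))
    config <- fit_config(K, alpha, epsilon, max_iter, seed)
  if (!inherits(config, "fit_config"))
    stop("config must come from fit_config()", call. = FALSE)
  G <- genotype_matrix(G)
  M <- nrow(G)
  N <- ncol(G)
  K <- config$K
  if (N < K || M < K)
    stop(sprintf("need at least K individuals and K loci: K = %d but G is %s",
                 K, dim_string(G)), call. = FALSE)
  eps <- if (is.null(config$epsilon)) M * N * 1e-10 else config$epsilon

  Q <- if (is.null(Q_init)) init_Q(K, N, config$seed)
       else admix_matrix(Q_init)
  trace <- numeric(config$max_iter)
  converged <- FALSE
  n_iter <- 0L
  P <- NULL
  for (it in seq_len(config$max_iter)) {
    P <- update_P(Q, G)
    Q <- update_Q(P, G, config$alpha)
    obj <- penalized_objective(P, Q, G, config$alpha)
    trace[it] <- obj
    n_iter <- it
    if (verbose)
      message(sprintf("iter %4d  objective %.6f  delta %s", it, obj,
                      if (it > 1L) sprintf("%.4g", trace[it - 1L] - obj)
                      else "NA"))
    if (it >= 2L && abs(trace[it] - trace[it - 1L]) < eps) {
      converged <- TRUE
      break
    }
  }
  structure(list(P = P, Q = Q, objective_trace = trace[seq_len(n_iter)],
                 n_iter = n_iter, converged = converged, K = K,
                 alpha = config$alpha, epsilon = eps, seed = config$seed),
            class = "admix_fit")
}

#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf("Least-squares admixture fit: M = %d loci, N = %d individuals, K = %d\n",
              nrow(x$P), ncol(x$Q), x$K))
  cat(sprintf("  alpha = %g, epsilon = %g\n", x$alpha, x$epsilon))
  cat(sprintf("  %d iterations, %s (final objective %.6g)\n", x$n_iter,
              if (x$converged) "converged" else "NOT converged",
              x$objective_trace[x$n_iter]))
  invisible(x)
}

#' Unconstrained allele-frequency estimate for known Q
#'
#' The closed-form least-squares estimator `(1/2) G Q' (Q Q')^{-1}` used in
#' the best-case experiments and the variance-bound theory.  Entries may
#' fall outside \[0, 1\]; set `clamp = TRUE` to clip them.
#'
#' @param G M x N genotype matrix.
#' @param Q K x N admixture matrix with full row rank.
#' @param clamp clip the estimate into \[0, 1\]?
#' @return M x K matrix of allele-frequency estimates.
#' @export
estimate_p_known_Q <- function(G, Q, clamp = FALSE) {
  if (ncol(Q) != ncol(G))
    stop(sprintf("dimension mismatch: Q is %s but G is %s",
                 dim_string(Q), dim_string(G)), call. = FALSE)
  QQt <- tcrossprod(Q)
  inv <- tryCatch(solve(QQt), error = function(e)
    stop("Q Q' is singular: Q does not have full row rank", call. = FALSE))
  P <- 0.5 * G %*% crossprod(Q, inv)
  if (clamp) P <- pmin(pmax(P, 0), 1)
  P
}

#' One-shot admixture estimate for known P
#'
#' A single simplex-constrained Q-update against the true allele
#' frequencies.
#'
#' @inheritParams update_Q
#' @return K x N admixture matrix.
#' @export
estimate_q_known_P <- function(G, P, alpha = 1) {
  update_Q(P, G, alpha)
}

#' Binomial maximum-likelihood allele-frequency estimate for one locus
#'
#' Maximizes the binomial log-likelihood of one locus row of G over
#' `p` in `[0, 1]^K` by box-constrained numerical optimization
#' (`optim(method = "L-BFGS-B")`), starting from the clamped least-squares
#' estimate.  Never returns a point with lower likelihood than the start.
#'
#' @param G M x N genotype matrix.
#' @param Q K x N admixture matrix with full row rank.
#' @param row locus index (row of G) to estimate.
#' @param floor probability floor for log evaluation.
#' @return length-K vector of allele-frequency estimates.
#' @export
ml_estimate_p_known_Q <- function(G, Q, row, floor = 1e-10) {
  g <- as.numeric(G[row, ])
  K <- nrow(Q)
  p0 <- drop(estimate_p_known_Q(G[row, , drop = FALSE], Q))
  p0 <- pmin(pmax(p0, 0), 1)
  nll <- function(p) {
    m <- pmin(pmax(drop(crossprod(Q, p)), floor), 1 - floor)
    -sum(g * log(m) + (2 - g) * log1p(-m))
  }
  res <- tryCatch(
    stats::optim(p0, nll, method = "L-BFGS-B", lower = 0, upper = 1),
    error = function(e)
      stop(sprintf("likelihood optimization failed at locus %d: %s",
                   row, conditionMessage(e)), call. = FALSE))
  if (res$value <= nll(p0)) res$par else p0
}
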