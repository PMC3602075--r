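# Closed-form expectations and variance bounds for the partially-solved
# estimators, and the effective degree-of-admixture formula.  These double
# as library features and as oracles for the simulation tests.

#' Dirichlet specification
#'
#' Shape parameters of the Dirichlet prior on admixture columns.  Either a
#' full vector `alphas` or a single symmetric value together with `K`.
#'
#' @param alphas vector of positive shape parameters, or a scalar to be
#'   recycled to length `K`.
#' @param K number of populations when `alphas` is scalar.
#' @return an object of class `dirichlet_spec` with fields `alphas`,
#'   `alpha0` (their sum) and `K`.
#' @export
dirichlet_spec <- function(alphas, K = NULL) {
  if (length(alphas) == 1L && !is.null(K)) alphas <- rep(alphas, K)
  alphas <- as.numeric(alphas)
  if (any(!is.finite(alphas)) || any(alphas <= 0))
    stop("all Dirichlet shape parameters must be positive", call. = FALSE)
  structure(list(alphas = alphas, alpha0 = sum(alphas),
                 K = length(alphas)),
            class = "dirichlet_spec")
}

as_dirichlet_spec <- function(x, K = NULL) {
  if (inherits(x, "dirichlet_spec")) x else dirichlet_spec(x, K)
}

#' Worst-case variance of a single genotype
#'
#' The variance of a Binomial(2, m) genotype is 2 m (1 - m), maximized at
#' m = 1/2 where it equals 1/2.
#'
#' @return 0.5
#' @export
genotype_variance_bound <- function() 0.5

trace_inverse_eighth <- function(S, label) {
  inv <- tryCatch(solve(S), error = function(e)
    stop(sprintf("%s is singular", label), call. = FALSE))
  sum(diag(inv)) / 8
}

#' Empirical bound on the total variance of the known-Q estimator
#'
#' For the unconstrained estimator of one locus row of P given Q, the trace
#' of the estimator covariance is bounded by `(1/8) trace((Q Q')^{-1})`.
#' Supply either the admixture matrix `Q` or the K x K cross-product
#' `QQt = Q %*% t(Q)` directly.
#'
#' @param Q K x N admixture matrix.
#' @param QQt optional precomputed K x K matrix `Q Q'`.
#' @return positive scalar bound.
#' @export
empirical_p_variance_bound <- function(Q = NULL, QQt = NULL) {
  if (is.null(QQt)) {
    if (is.null(Q)) stop("supply Q or QQt", call. = FALSE)
    QQt <- tcrossprod(as.matrix(Q))
  }
  trace_inverse_eighth(as.matrix(QQt), "Q Q'")
}

#' Empirical bound on the total variance of the known-P estimator
#'
#' Bound `(1/8) trace((P'P)^{-1})` on the trace of the covariance of the
#' admixture estimate for one individual given P.  For iid uniform rows of
#' P the bound decreases like 1/M.
#'
#' @param P M x K allele-frequency matrix.
#' @return positive scalar bound.
#' @export
empirical_q_variance_bound <- function(P) {
  trace_inverse_eighth(crossprod(as.matrix(P)), "P'P")
}

#' Second moment matrix of a Dirichlet vector
#'
#' `E[q q']` with diagonal `a_k (a_k + 1) / (a_0 (a_0 + 1))` and
#' off-diagonal `a_k a_j / (a_0 (a_0 + 1))`.
#'
#' @param spec a [dirichlet_spec()] (or a vector of shape parameters).
#' @return K x K second-moment matrix.
#' @export
dirichlet_second_moment <- function(spec) {
  spec <- as_dirichlet_spec(spec)
  a <- spec$alphas
  a0 <- spec$alpha0
  S <- outer(a, a) / (a0 * (a0 + 1))
  diag(S) <- a * (a + 1) / (a0 * (a0 + 1))
  S
}

#' Asymptotic bound on the total variance of the known-Q estimator
#'
#' As N grows with iid symmetric-Dirichlet admixture columns, the empirical
#' bound approaches `(1/(8N)) trace(E[q q']^{-1})`, which in closed form is
#' `K^2 (1 + (K - 1) alpha) / (8 N)`; for K = 2 this is `(alpha + 1)/(2N)`.
#'
#' @param N number of individuals.
#' @param alpha symmetric Dirichlet shape parameter.
#' @param K number of populations.
#' @return positive scalar bound.
#' @export
asymptotic_p_variance_bound <- function(N, alpha, K) {
  if (N < 1 || alpha <= 0 || K < 1)
    stop("need N >= 1, alpha > 0, K >= 1", call. = FALSE)
  K^2 * (1 + (K - 1) * alpha) / (8 * N)
}

#' Bound report for the known-Q estimator
#'
#' Pairs the finite-sample bound computed from a realized Q with the
#' asymptotic Dirichlet bound it approaches as N grows.
#'
#' @param Q K x N admixture matrix.
#' @param alpha symmetric Dirichlet shape parameter of the columns.
#' @return an object of class `bound_report` with fields
#'   `empirical_bound`, `asymptotic_bound`, `n_used`.
#' @export
bound_report <- function(Q, alpha) {
  Q <- as.matrix(Q)
  structure(list(empirical_bound = empirical_p_variance_bound(Q),
                 asymptotic_bound = asymptotic_p_variance_bound(ncol(Q),
                                                                alpha,
                                                                nrow(Q)),
                 n_used = ncol(Q)),
            class = "bound_report")
}

#' Effective symmetric degree of admixture
#'
#' The single symmetric shape parameter whose Dirichlet has the same total
#' variance as a general Dirichlet(alpha_1, ..., alpha_K): with
#' `v = sum_k a_k (a_0 - a_k) / (a_0^2 (a_0 + 1))`, the effective value is
#' `(K - 1) / (K^2 v) - 1/K`.  For symmetric input it returns the common
#' shape exactly.
#'
#' @param spec a [dirichlet_spec()] (or a vector of shape parameters).
#' @return positive scalar effective alpha.
#' @export
effective_alpha <- function(spec) {
  spec <- as_dirichlet_spec(spec)
  K <- spec$K
  if (K < 2L) stop("K must be at least 2", call. = FALSE)
  a <- spec$alphas
  a0 <- spec$alpha0
  v <- sum(a * (a0 - a)) / (a0^2 * (a0 + 1))
  if (v <= 0) stop("degenerate Dirichlet: total variance is zero",
                   call. = FALSE)
  (K - 1) / (K^2 * v) - 1 / K
}
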