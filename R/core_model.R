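# Data model and scalar objective functions shared by every other module.
#
# The model: a diploid individual i carries g_li in {0,1,2} copies of the
# reference allele at locus l.  Each allele copy is an independent Bernoulli
# draw with success probability m_li = sum_k p_lk q_ki, where p_lk is the
# reference-allele frequency in ancestral population k and q_ki is the
# fraction of individual i's genome originating from population k.

dim_string <- function(x) paste(dim(x), collapse = "x")

stop_dims <- function(what, A, B) {
  stop(sprintf("dimension mismatch in %s: %s is %s but %s is %s",
               what, deparse(substitute(A)), dim_string(A),
               deparse(substitute(B)), dim_string(B)), call. = FALSE)
}

#' Validate a genotype matrix
#'
#' Checks that `G` is an M x N numeric matrix of reference-allele counts
#' with every entry in \{0, 1, 2\} and returns it (in double storage).
#' Missing values are not permitted here; see [read_genotypes()] for the
#' imputation policy applied at file-reading time.
#'
#' @param G matrix of genotypes, loci in rows, individuals in columns.
#' @return the validated matrix.
#' @export
genotype_matrix <- function(G) {
  G <- as.matrix(G)
  if (!is.numeric(G) || nrow(G) < 1L || ncol(G) < 1L)
    stop("G must be a non-empty numeric matrix", call. = FALSE)
  if (anyNA(G) || !all(G %in% c(0, 1, 2)))
    stop("genotype entries must all be 0, 1 or 2 (no missing values)",
         call. = FALSE)
  storage.mode(G) <- "double"
  G
}

#' Validate an allele-frequency matrix
#'
#' Checks that `P` is an M x K matrix with entries in \[0, 1\].
#'
#' @param P matrix of population allele frequencies, loci in rows,
#'   populations in columns.
#' @param tol numeric slack permitted beyond the \[0, 1\] box.
#' @return the validated matrix.
#' @export
freq_matrix <- function(P, tol = 1e-9) {
  P <- as.matrix(P)
  if (!is.numeric(P) || nrow(P) < 1L || ncol(P) < 1L)
    stop("P must be a non-empty numeric matrix", call. = FALSE)
  if (anyNA(P) || min(P) < -tol || max(P) > 1 + tol)
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  pmin(pmax(P, 0), 1)
}

#' Validate an admixture matrix
#'
#' Checks that `Q` is a K x N matrix with nonnegative entries whose columns
#' each sum to one (within `tol`).
#'
#' @param Q matrix of admixture proportions, populations in rows,
#'   individuals in columns.
#' @param tol absolute tolerance on nonnegativity and the column sums.
#' @return the validated matrix.
#' @export
admix_matrix <- function(Q, tol = 1e-9) {
  Q <- as.matrix(Q)
  if (!is.numeric(Q) || nrow(Q) < 1L || ncol(Q) < 1L)
    stop("Q must be a non-empty numeric matrix", call. = FALSE)
  if (anyNA(Q) || min(Q) < -tol)
    stop("admixture proportions must be nonnegative", call. = FALSE)
  if (max(abs(colSums(Q) - 1)) > tol)
    stop(sprintf("each column of Q must sum to 1 (max deviation %.3g)",
                 max(abs(colSums(Q) - 1))), call. = FALSE)
  Q
}

#' Fit configuration
#'
#' Bundles the run parameters of [fit_admixture()].
#'
#' @param K number of ancestral populations.
#' @param alpha symmetric Dirichlet degree of admixture (> 0); `alpha = 1`
#'   is the uninformative prior and leaves the criterion unpenalized.
#' @param epsilon absolute convergence tolerance on the penalized
#'   criterion; the default `NULL` resolves to `M * N * 1e-10` once the
#'   genotype matrix is seen.
#' @param max_iter cap on outer (P, Q) sweeps.
#' @param seed optional RNG seed for the random initialization of Q; `NULL`
#'   consumes the current RNG stream.
#' @param clip_likelihood probability floor used when evaluating the
#'   binomial log-likelihood (monitoring only).
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(K, alpha = 1, epsilon = NULL, max_iter = 2000L,
                       seed = NULL, clip_likelihood = 1e-10) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be at least 1", call. = FALSE)
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (!is.null(epsilon) && epsilon <= 0)
    stop("epsilon must be positive", call. = FALSE)
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("max_iter must be at least 1", call. = FALSE)
  structure(list(K = K, alpha = alpha, epsilon = epsilon,
                 max_iter = max_iter, seed = seed,
                 clip_likelihood = clip_likelihood),
            class = "fit_config")
}

#' Binomial success probabilities implied by P and Q
#'
#' Computes the M x N matrix `m = P %*% Q` whose entry (l, i) is the
#' probability that one allele copy of individual i at locus l is the
#' reference allele.
#'
#' @param P M x K allele-frequency matrix.
#' @param Q K x N admixture matrix.
#' @return M x N matrix of success probabilities.
#' @export
compute_m <- function(P, Q) {
  if (ncol(P) != nrow(Q))
    stop(sprintf("dimension mismatch: P is %s but Q is %s",
                 dim_string(P), dim_string(Q)), call. = FALSE)
  P %*% Q
}

check_conformable <- function(P, Q, G) {
  if (ncol(P) != nrow(Q) || nrow(P) != nrow(G) || ncol(Q) != ncol(G))
    stop(sprintf("dimension mismatch: P is %s, Q is %s, G is %s",
                 dim_string(P), dim_string(Q), dim_string(G)), call. = FALSE)
  invisible(NULL)
}

#' Least-squares criterion
#'
#' The squared Frobenius distance `||2 P Q - G||^2` between the expected
#' genotypes 2PQ and the observed genotypes.  This is the first-order
#' approximation (around m = 1/2) of the negative binomial log-likelihood,
#' up to scale.
#'
#' @inheritParams compute_m
#' @param G M x N genotype matrix.
#' @return nonnegative scalar.
#' @export
ls_objective <- function(P, Q, G) {
  check_conformable(P, Q, G)
  R <- 2 * (P %*% Q) - G
  sum(R * R)
}

#' Penalized least-squares criterion
#'
#' Adds the Dirichlet degree-of-admixture penalty
#' `K^2 (alpha - 1) * sum((Q - 1/K)^2)` to [ls_objective()].  For
#' `alpha = 1` the two criteria coincide; for `alpha < 1` the penalty
#' contribution is nonpositive (it rewards sparse columns of Q).
#'
#' @inheritParams ls_objective
#' @param alpha degree of admixture (> 0).
#' @return scalar criterion value.
#' @export
penalized_objective <- function(P, Q, G, alpha = 1) {
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  K <- nrow(Q)
  ls_objective(P, Q, G) + K^2 * (alpha - 1) * sum((Q - 1 / K)^2)
}

#' Binomial log-likelihood (monitoring)
#'
#' The log-likelihood of (P, Q) under the binomial genotype model, up to an
#' additive constant: `sum(g * log(m) + (2 - g) * log(1 - m))` with the
#' success probabilities clamped to `[floor, 1 - floor]` so the value is
#' always finite.
#'
#' @inheritParams ls_objective
#' @param floor probability floor in (0, 0.5).
#' @return finite scalar.
#' @export
binom_loglik <- function(P, Q, G, floor = 1e-10) {
  if (floor <= 0 || floor >= 0.5)
    stop("floor must lie in (0, 0.5)", call. = FALSE)
  check_conformable(P, Q, G)
  m <- pmin(pmax(P %*% Q, floor), 1 - floor)
  sum(G * log(m) + (2 - G) * log1p(-m))
}
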