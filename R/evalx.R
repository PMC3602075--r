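# Evaluation utilities (population-label alignment, RMSE) and the
# simulation-study harnesses: the covariance/bound validation experiment,
# the known-Q best-case protocol, and the factorial study over (K, N,
# alpha).

permutations_lex <- function(K) {
  if (K == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(K)) {
    rest <- permutations_lex(K - 1L)
    for (p in rest) {
      v <- seq_len(K)[-i]
      out[[length(out) + 1L]] <- c(i, v[p])
    }
  }
  out
}

#' Align estimated population labels to the truth
#'
#' Population labels are only identified up to permutation (label
#' switching).  Finds, by exhaustive search over all K! permutations, the
#' row permutation of `Q_est` minimizing the squared error against
#' `Q_true`; ties go to the lexicographically smallest permutation.
#'
#' @param Q_est,Q_true K x N admixture matrices.
#' @return integer permutation `perm` such that `Q_est[perm, ]` best
#'   matches `Q_true`.
#' @export
align_populations <- function(Q_est, Q_true) {
  Q_est <- as.matrix(Q_est)
  Q_true <- as.matrix(Q_true)
  if (!all(dim(Q_est) == dim(Q_true)))
    stop(sprintf("dimension mismatch: Q_est is %s but Q_true is %s",
                 dim_string(Q_est), dim_string(Q_true)), call. = FALSE)
  K <- nrow(Q_true)
  if (K > 8L)
    stop("K > 8: exhaustive permutation search is impractical; ",
         "solve the label assignment problem instead", call. = FALSE)
  best <- seq_len(K)
  best_val <- Inf
  for (p in permutations_lex(K)) {
    val <- sum((Q_est[p, , drop = FALSE] - Q_true)^2)
    if (val < best_val) {
      best_val <- val
      best <- p
    }
  }
  best
}

#' Root mean squared error in percent
#'
#' `100 * sqrt(mean((X_est - X_true)^2))` over all entries.
#'
#' @param X_est,X_true matrices of the same shape.
#' @return nonnegative scalar, in percent.
#' @export
rmse_percent <- function(X_est, X_true) {
  X_est <- as.matrix(X_est)
  X_true <- as.matrix(X_true)
  if (!all(dim(X_est) == dim(X_true)))
    stop(sprintf("dimension mismatch: X_est is %s but X_true is %s",
                 dim_string(X_est), dim_string(X_true)), call. = FALSE)
  100 * sqrt(mean((X_est - X_true)^2))
}

#' Replicate study of the known-Q estimator's mean and covariance
#'
#' Draws one admixture matrix Q (Dirichlet columns), then `n_trials`
#' independent single-locus genotype rows from Binomial(2, p'Q), estimates
#' p in each trial by the unconstrained least-squares formula, and returns
#' the sample mean and covariance of the estimates together with the
#' empirical and asymptotic total-variance bounds for the drawn Q.
#'
#' @param p_true length-K vector of true allele frequencies for the locus.
#' @param N number of individuals.
#' @param alpha symmetric Dirichlet shape of the admixture columns.
#' @param n_trials number of replicate genotype rows (>= 100).
#' @param seed optional RNG seed.
#' @return list with `mean` (length K), `cov` (K x K), `trace`, `bounds`
#'   (a [bound_report()]), `Q` and `n_trials`.
#' @export
run_empirical_cov <- function(p_true, N, alpha = 1, n_trials = 10000L,
                              seed = NULL) {
  if (n_trials < 100L) stop("n_trials must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p_true <- as.numeric(p_true)
  K <- length(p_true)
  Q <- sample_admixture(N, dirichlet_spec(alpha, K))
  m <- drop(crossprod(Q, p_true))
  Gt <- matrix(stats::rbinom(n_trials * N, 2L, rep(m, each = n_trials)),
               n_trials, N)
  QQt <- tcrossprod(Q)
  inv <- tryCatch(solve(QQt), error = function(e)
    stop("Q Q' is singular", call. = FALSE))
  Phat <- 0.5 * Gt %*% crossprod(Q, inv)
  covp <- stats::cov(Phat)
  list(mean = colMeans(Phat), cov = covp, trace = sum(diag(covp)),
       bounds = bound_report(Q, alpha), Q = Q, n_trials = n_trials)
}

#' Best-case RMSE of the allele-frequency estimators for known Q
#'
#' For each point of the 10 x 10 grid `p_i in {0.05, 0.15, ..., 0.95}`
#' (K = 2) and each of `n_trials` replicates: draw Q with Dirichlet(alpha)
#' columns, draw one genotype row from Binomial(2, p'Q), and estimate p
#' either by the unconstrained least-squares formula (`"ls"`) or by
#' box-constrained maximization of the binomial likelihood (`"ml"`).
#' Returns the RMSE in percent pooled over all grid points, trials and
#' components.
#'
#' @param N number of individuals.
#' @param alpha symmetric Dirichlet shape of the admixture columns.
#' @param n_trials replicates per grid point.
#' @param seed optional RNG seed.
#' @param estimator `"ls"` or `"ml"`.
#' @return aggregate RMSE in percent.
#' @export
run_bestcase_P <- function(N, alpha = 1, n_trials = 1000L, seed = NULL,
                           estimator = c("ls", "ml")) {
  estimator <- match.arg(estimator)
  if (!is.null(seed)) set.seed(seed)
  grid <- as.matrix(expand.grid(p1 = seq(0.05, 0.95, by = 0.1),
                                p2 = seq(0.05, 0.95, by = 0.1)))
  ngrid <- nrow(grid)
  spec <- dirichlet_spec(alpha, 2L)
  sqsum <- 0
  count <- 0L
  for (t in seq_len(n_trials)) {
    Q <- sample_admixture(N, spec)
    m <- grid %*% Q
    Gm <- matrix(stats::rbinom(length(m), 2L, m), ngrid, N)
    Phat <- if (estimator == "ls") {
      estimate_p_known_Q(Gm, Q)
    } else {
      t(vapply(seq_len(ngrid),
               function(r) ml_estimate_p_known_Q(Gm, Q, r),
               numeric(2L)))
    }
    sqsum <- sqsum + sum((Phat - grid)^2)
    count <- count + length(grid)
  }
  100 * sqrt(sqsum / count)
}

#' Factorial simulation study of the full fit
#'
#' For every combination of `Ks`, `Ns` and `alphas` and each of `n_trials`
#' replicates: simulate (P, Q, G) under the binomial admixture model, run
#' the alternating least-squares fit (with the uninformative prior, or the
#' true alpha when `use_known_alpha`), align populations to the truth, and
#' record RMSE (percent) for Q and for P.  The alignment permutation is
#' chosen on Q and the same permutation is applied to the columns of P.
#' Individual trial failures are recorded in the result, not raised.
#'
#' @param Ks,Ns,alphas vectors of factor levels.
#' @param M number of loci.
#' @param n_trials replicates per factor combination.
#' @param seed optional RNG seed.
#' @param use_known_alpha fit with the true degree of admixture instead of
#'   the uninformative prior.
#' @param epsilon,max_iter passed to [fit_config()]; `epsilon = NULL`
#'   resolves to `M * N * 1e-10`.
#' @param verbose emit one message per completed trial.
#' @return list of `experiment_result` objects, one per factor
#'   combination, each with fields `factors`, `rmse_Q_percent`,
#'   `rmse_P_percent`, `per_trial` (data frame), `n_trials`, `n_failed`,
#'   `seed`.
#' @export
run_factorial <- function(Ks, Ns, alphas, M = 10000L, n_trials = 50L,
                          seed = NULL, use_known_alpha = FALSE,
                          epsilon = NULL, max_iter = 2000L,
                          verbose = FALSE) {
  if (M < max(Ks)) stop("M must be at least max(Ks)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  combos <- expand.grid(K = Ks, N = Ns, alpha = alphas,
                        KEEP.OUT.ATTRS = FALSE)
  results <- vector("list", nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    K <- combos$K[ci]
    N <- combos$N[ci]
    alpha <- combos$alpha[ci]
    fit_alpha <- if (use_known_alpha) alpha else 1
    sim_seeds <- sample.int(2147483646L, n_trials)
    fit_seeds <- sample.int(2147483646L, n_trials)
    rec <- data.frame(trial = seq_len(n_trials), rmse_Q = NA_real_,
                      rmse_P = NA_real_, n_iter = NA_integer_,
                      converged = NA, failed = FALSE,
                      error = NA_character_)
    for (t in seq_len(n_trials)) {
      res <- tryCatch({
        sim <- simulate_admixture(sim_scenario(M, N, K, alpha,
                                               seed = sim_seeds[t]))
        ft <- fit_admixture(sim$G,
                            config = fit_config(K, alpha = fit_alpha,
                                                epsilon = epsilon,
                                                max_iter = max_iter,
                                                seed = fit_seeds[t]))
        perm <- align_populations(ft$Q, sim$Q)
        list(rmse_Q = rmse_percent(ft$Q[perm, , drop = FALSE], sim$Q),
             rmse_P = rmse_percent(ft$P[, perm, drop = FALSE], sim$P),
             n_iter = ft$n_iter, converged = ft$converged)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rec$failed[t] <- TRUE
        rec$error[t] <- conditionMessage(res)
      } else {
        rec$rmse_Q[t] <- res$rmse_Q
        rec$rmse_P[t] <- res$rmse_P
        rec$n_iter[t] <- res$n_iter
        rec$converged[t] <- res$converged
      }
      if (verbose)
        message(sprintf("K=%d N=%d alpha=%.2f trial %d/%d: %s",
                        K, N, alpha, t, n_trials,
                        if (rec$failed[t]) "FAILED"
                        else sprintf("rmse_Q=%.3f%% rmse_P=%.3f%% (%d iter)",
                                     rec$rmse_Q[t], rec$rmse_P[t],
                                     rec$n_iter[t])))
    }
    ok <- !rec$failed
    results[[ci]] <- structure(
      list(factors = list(K = K, N = N, M = M, alpha = alpha,
                          estimator = if (use_known_alpha) "LSalpha"
                                      else "LS1"),
           rmse_Q_percent = mean(rec$rmse_Q[ok]),
           rmse_P_percent = mean(rec$rmse_P[ok]),
           per_trial = rec, n_trials = n_trials,
           n_failed = sum(rec$failed), seed = seed),
      class = "experiment_result")
  }
  results
}

#' @export
print.experiment_result <- function(x, ...) {
  f <- x$factors
  cat(sprintf("K=%d N=%d M=%d alpha=%.2f [%s]: RMSE(Q) = %.2f%%, RMSE(P) = %.2f%% (%d trials, %d failed)\n",
              f$K, f$N, f$M, f$alpha, f$estimator, x$rmse_Q_percent,
              x$rmse_P_percent, x$n_trials, x$n_failed))
  invisible(x)
}
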