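# Synthetic genotype data under the binomial admixture model:
# P uniform on [0, 1] (or a user-supplied frequency panel), admixture
# columns Dirichlet, genotypes Binomial(2, PQ).

#' Simulation scenario
#'
#' @param M number of loci.
#' @param N number of individuals.
#' @param K number of populations.
#' @param alpha symmetric Dirichlet degree of admixture; ignored when
#'   `alphas` is supplied.
#' @param alphas optional full vector of Dirichlet shape parameters.
#' @param panel optional M x K allele-frequency matrix to use instead of
#'   uniform draws (e.g. frequencies estimated from a reference panel).
#' @param seed optional RNG seed governing the whole scenario.
#' @return an object of class `sim_scenario`.
#' @export
sim_scenario <- function(M, N, K, alpha = 1, alphas = NULL, panel = NULL,
                         seed = NULL) {
  M <- as.integer(M); N <- as.integer(N); K <- as.integer(K)
  if (M < 1L || N < 1L || K < 1L)
    stop("M, N and K must all be at least 1", call. = FALSE)
  spec <- if (is.null(alphas)) dirichlet_spec(alpha, K)
          else dirichlet_spec(alphas)
  if (spec$K != K)
    stop(sprintf("Dirichlet spec has %d populations but K = %d",
                 spec$K, K), call. = FALSE)
  if (!is.null(panel)) {
    panel <- freq_matrix(panel)
    if (nrow(panel) != M || ncol(panel) != K)
      stop(sprintf("panel is %s but scenario expects %dx%d",
                   dim_string(panel), M, K), call. = FALSE)
  }
  structure(list(M = M, N = N, K = K, dirichlet = spec, panel = panel,
                 seed = seed),
            class = "sim_scenario")
}

#' Sample uniform population allele frequencies
#'
#' @param M number of loci.
#' @param K number of populations.
#' @param seed optional RNG seed; `NULL` consumes the current stream.
#' @return M x K matrix with iid Uniform(0, 1) entries.
#' @export
sample_frequencies <- function(M, K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(M * K), M, K)
}

#' Sample Dirichlet admixture columns
#'
#' Columns are iid Dirichlet draws obtained by normalizing independent
#' Gamma deviates.
#'
#' @param N number of individuals.
#' @param spec a [dirichlet_spec()] (or a vector of shape parameters).
#' @param seed optional RNG seed; `NULL` consumes the current stream.
#' @return K x N admixture matrix.
#' @export
sample_admixture <- function(N, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- as_dirichlet_spec(spec)
  K <- spec$K
  Gm <- matrix(stats::rgamma(K * N, shape = spec$alphas), K, N)
  cs <- colSums(Gm)
  # for very small shapes a whole column can underflow to zero; redraw it
  while (any(cs == 0)) {
    bad <- which(cs == 0)
    Gm[, bad] <- stats::rgamma(K * length(bad), shape = spec$alphas)
    cs[bad] <- colSums(Gm[, bad, drop = FALSE])
  }
  sweep(Gm, 2, cs, "/")
}

#' Sample binomial genotypes
#'
#' Draws `g_li ~ Binomial(2, m_li)` independently with `m = P Q`.
#'
#' @param P M x K allele-frequency matrix.
#' @param Q K x N admixture matrix.
#' @param seed optional RNG seed; `NULL` consumes the current stream.
#' @return M x N genotype matrix with entries in \{0, 1, 2\}.
#' @export
sample_genotypes <- function(P, Q, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- compute_m(P, Q)
  if (min(m) < -1e-12 || max(m) > 1 + 1e-12)
    stop("success probabilities fall outside [0, 1]: invalid P or Q",
         call. = FALSE)
  m <- pmin(pmax(m, 0), 1)
  matrix(stats::rbinom(length(m), 2L, m), nrow(m), ncol(m))
}

#' Simulate a full (P, Q, G) triple
#'
#' Composes the three samplers under one seed, consuming the RNG stream in
#' the fixed order P, then Q, then G.  When the scenario carries a
#' frequency panel it is used verbatim in place of the uniform draw.
#'
#' @param scenario a [sim_scenario()].
#' @return list with elements `P` (M x K), `Q` (K x N), `G` (M x N) and
#'   the scenario itself.
#' @export
simulate_admixture <- function(scenario) {
  if (!inherits(scenario, "sim_scenario"))
    stop("scenario must come from sim_scenario()", call. = FALSE)
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  P <- if (is.null(scenario$panel))
    sample_frequencies(scenario$M, scenario$K)
  else scenario$panel
  Q <- sample_admixture(scenario$N, scenario$dirichlet)
  G <- sample_genotypes(P, Q)
  list(P = P, Q = Q, G = G, scenario = scenario)
}
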