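# Constrained least-squares kernels.
#
# Both solvers use a fast combinatorial active/passive-set strategy over
# many right-hand sides at once: columns sharing the same bound pattern are
# solved in one grouped linear solve against the shared Gram matrix.  The
# default pivot rule is full exchange (clamp every bound violator and
# release every clamped variable with an inward-pointing gradient in the
# same sweep); a column whose objective fails to decrease twice falls back
# to single-variable exchange, which guarantees termination.

# Cholesky factor with an explicit near-singularity check: plain chol()
# can succeed numerically on a rank-deficient Gram matrix.
chol_fullrank <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch) ||
      min(diag(ch))^2 < .Machine$double.eps * max(diag(S)) * nrow(S))
    stop("design matrix is rank deficient: increase the number of ",
         "individuals or reduce K", call. = FALSE)
  ch
}

# Solve min ||A x - b||^2 over box [lower, upper] given the normal
# equations AtA = A'A (K x K) and AtB = A'B (K x R).  Shared by
# bvls_multirhs() and update_P(), which can form AtA/AtB cheaply without
# materializing A or B.
bvls_normal <- function(AtA, AtB, lower = 0, upper = 1,
                        max_iter = NULL, tol = 1e-8) {
  K <- nrow(AtA)
  R <- ncol(AtB)
  if (is.null(max_iter)) max_iter <- 30L * K
  chol_fullrank(AtA)

  # state per variable: 0 = passive, -1 = clamped at lower, 1 = at upper
  state <- matrix(0L, K, R)
  X <- matrix(0, K, R)
  done <- logical(R)
  obj_prev <- rep(Inf, R)
  stall <- integer(R)
  single <- logical(R)

  pow3 <- 3L^(seq_len(K) - 1L)
  it <- 0L
  active_cols <- seq_len(R)
  while (length(active_cols)) {
    it <- it + 1L
    if (it > max_iter)
      stop(sprintf(paste0("bounded-variable LS failed to settle within %d ",
                          "active-set iterations (first unconverged column: ",
                          "%d of %d)"), max_iter, active_cols[1L], R),
           call. = FALSE)

    # equality-constrained solve per unique bound pattern
    st <- state[, active_cols, drop = FALSE]
    key <- colSums((st + 1L) * pow3)
    for (grp in split(seq_along(active_cols), key)) {
      cc <- active_cols[grp]
      s <- state[, cc[1L]]
      pas <- which(s == 0L)
      xfix <- numeric(K)
      xfix[s == -1L] <- lower
      xfix[s == 1L] <- upper
      Xc <- matrix(xfix, K, length(cc))
      if (length(pas)) {
        rhs <- AtB[pas, cc, drop = FALSE]
        fx <- which(s != 0L)
        if (length(fx))
          rhs <- rhs - drop(AtA[pas, fx, drop = FALSE] %*% xfix[fx])
        chp <- chol_fullrank(AtA[pas, pas, drop = FALSE])
        Xc[pas, ] <- backsolve(chp, backsolve(chp, rhs, transpose = TRUE))
      }
      X[, cc] <- Xc
    }

    # KKT assessment (gradient of 0.5 ||A x - b||^2 is AtA x - Atb)
    ac <- active_cols
    Xa <- X[, ac, drop = FALSE]
    Gr <- AtA %*% Xa - AtB[, ac, drop = FALSE]
    sta <- state[, ac, drop = FALSE]
    viol_lo <- sta == 0L & Xa < lower - tol
    viol_hi <- sta == 0L & Xa > upper + tol
    rel_lo <- sta == -1L & Gr < -tol
    rel_hi <- sta == 1L & Gr > tol
    moves <- viol_lo | viol_hi | rel_lo | rel_hi
    fin <- colSums(moves) == 0L

    if (any(fin)) {
      cols_fin <- ac[fin]
      X[, cols_fin] <- pmin(pmax(X[, cols_fin, drop = FALSE], lower), upper)
      done[cols_fin] <- TRUE
    }
    if (any(!fin)) {
      idx <- which(!fin)
      cols <- ac[idx]
      # anti-cycling bookkeeping on the projected candidate
      Xc <- pmin(pmax(Xa[, idx, drop = FALSE], lower), upper)
      obj <- colSums(Xc * (AtA %*% Xc)) -
        2 * colSums(Xc * AtB[, cols, drop = FALSE])
      worse <- obj >= obj_prev[cols] - 1e-12
      stall[cols] <- ifelse(worse, stall[cols] + 1L, 0L)
      single[cols] <- single[cols] | stall[cols] >= 2L
      obj_prev[cols] <- pmin(obj_prev[cols], obj)

      full_idx <- idx[!single[cols]]
      if (length(full_idx)) {
        cfull <- ac[full_idx]
        sub <- state[, cfull, drop = FALSE]
        sub[viol_lo[, full_idx, drop = FALSE]] <- -1L
        sub[viol_hi[, full_idx, drop = FALSE]] <- 1L
        sub[rel_lo[, full_idx, drop = FALSE] |
              rel_hi[, full_idx, drop = FALSE]] <- 0L
        state[, cfull] <- sub
      }
      for (j in idx[single[cols]]) {
        col <- ac[j]
        vl <- which(viol_lo[, j])
        vh <- which(viol_hi[, j])
        if (length(vl) || length(vh)) {
          cand <- c(vl, vh)
          dist <- c(lower - Xa[vl, j], Xa[vh, j] - upper)
          kstar <- cand[which.max(dist)]
          state[kstar, col] <- if (kstar %in% vl) -1L else 1L
        } else {
          cand <- c(which(rel_lo[, j]), which(rel_hi[, j]))
          kstar <- cand[which.max(abs(Gr[cand, j]))]
          state[kstar, col] <- 0L
        }
      }
    }
    active_cols <- which(!done)
  }
  X
}

#' Bounded-variable least squares with multiple right-hand sides
#'
#' Minimizes `||A x - b_r||^2` subject to `lower <= x <= upper` for every
#' column `b_r` of `B`, using an active/passive-set scheme in which columns
#' with identical bound patterns share one grouped linear solve.  At the
#' solution the Karush-Kuhn-Tucker conditions hold: the gradient is zero on
#' passive variables, nonnegative on variables clamped at the lower bound
#' and nonpositive on variables clamped at the upper bound.
#'
#' @param A n x K design matrix with full column rank (K <= n).
#' @param B n x R matrix of right-hand sides.
#' @param lower,upper box bounds (scalars, `lower < upper`); infinite
#'   bounds give the ordinary least-squares solution.
#' @param max_iter cap on active-set sweeps (default `30 * K`).
#' @param tol absolute KKT/feasibility tolerance.
#' @return K x R matrix of solutions, one column per right-hand side.
#' @export
bvls_multirhs <- function(A, B, lower = 0, upper = 1,
                          max_iter = NULL, tol = 1e-8) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (nrow(A) != nrow(B))
    stop(sprintf("dimension mismatch: A is %s but B is %s",
                 dim_string(A), dim_string(B)), call. = FALSE)
  if (!(lower < upper)) stop("lower must be strictly below upper",
                             call. = FALSE)
  if (ncol(A) > nrow(A))
    stop("design matrix is rank deficient: increase the number of ",
         "individuals or reduce K", call. = FALSE)
  bvls_normal(crossprod(A), crossprod(A, B), lower, upper, max_iter, tol)
}

#' Normal equations of the penalized admixture subproblem
#'
#' Precomputes the quantities shared by every column of the Q-update: the
#' Gram matrix `4 P'P + K^2 (alpha - 1) I`, the right-hand sides
#' `2 P'G + K (alpha - 1)`, the inverse Gram `U` and the Lagrange scalar
#' `a = 1 / sum(U)` used by the sum-to-one closed form.
#'
#' @param P M x K allele-frequency matrix with full column rank.
#' @param G M x N genotype matrix.
#' @param alpha degree of admixture (> 0).
#' @return an object of class `normal_equations`.
#' @export
build_normal_equations <- function(P, G, alpha = 1) {
  P <- as.matrix(P)
  G <- as.matrix(G)
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (nrow(P) != nrow(G))
    stop(sprintf("dimension mismatch: P is %s but G is %s",
                 dim_string(P), dim_string(G)), call. = FALSE)
  K <- ncol(P)
  gram <- 4 * crossprod(P) + K^2 * (alpha - 1) * diag(K)
  rhs <- 2 * crossprod(P, G) + K * (alpha - 1)
  ch <- tryCatch(chol(gram), error = function(e) NULL)
  if (is.null(ch)) {
    if (alpha < 1)
      stop("penalized normal equations are not positive definite: the ",
           "degree-of-admixture prior is too strong for this data size",
           call. = FALSE)
    stop("normal equations are singular: P is rank deficient", call. = FALSE)
  }
  U <- chol2inv(ch)
  structure(list(gram = gram, rhs = rhs, U = U, a = 1 / sum(U), K = K,
                 j = rep(1, K), J = matrix(1, K, K)),
            class = "normal_equations")
}

#' Simplex-constrained least squares with multiple right-hand sides
#'
#' Minimizes the penalized quadratic criterion encoded in a
#' [build_normal_equations()] object for every column, subject to
#' nonnegativity and the sum-to-one constraint.  The equality constraint is
#' handled by a Lagrange-multiplier closed form
#' `q = a U j + (U - a U J U) rhs` applied to each column's passive set
#' (with `U`, `a` recomputed on the passive submatrix); nonnegativity is
#' enforced by the active-set exchange described in [bvls_multirhs()].
#'
#' @param ne a `normal_equations` object.
#' @param max_iter cap on active-set sweeps (default `30 * K`).
#' @param tol absolute KKT/feasibility tolerance.
#' @return K x N matrix whose columns are nonnegative and sum to one.
#' @export
simplex_ls_multirhs <- function(ne, max_iter = NULL, tol = 1e-8) {
  if (!inherits(ne, "normal_equations"))
    stop("ne must come from build_normal_equations()", call. = FALSE)
  gram <- ne$gram
  rhs <- ne$rhs
  K <- ne$K
  R <- ncol(rhs)
  if (K == 1L) return(matrix(1, 1L, R))
  if (is.null(max_iter)) max_iter <- 30L * K

  # state per variable: 0 = passive, 1 = clamped at zero
  state <- matrix(0L, K, R)
  X <- matrix(0, K, R)
  done <- logical(R)
  obj_prev <- rep(Inf, R)
  stall <- integer(R)
  single <- logical(R)

  pow2 <- 2L^(seq_len(K) - 1L)
  it <- 0L
  active_cols <- seq_len(R)
  while (length(active_cols)) {
    it <- it + 1L
    if (it > max_iter)
      stop(sprintf(paste0("simplex-constrained LS failed to settle within ",
                          "%d active-set iterations (first unconverged ",
                          "column: %d of %d)"),
                   max_iter, active_cols[1L], R), call. = FALSE)

    # sum-to-one solve per unique clamp pattern, restricted to passive set
    st <- state[, active_cols, drop = FALSE]
    key <- colSums(st * pow2)
    for (grp in split(seq_along(active_cols), key)) {
      cc <- active_cols[grp]
      s <- state[, cc[1L]]
      pas <- which(s == 0L)
      U <- chol2inv(chol(gram[pas, pas, drop = FALSE]))
      Uj <- rowSums(U)
      a <- 1 / sum(Uj)
      t1 <- U %*% rhs[pas, cc, drop = FALSE]
      sol <- t1 + outer(a * Uj, 1 - colSums(t1))
      Xc <- matrix(0, K, length(cc))
      Xc[pas, ] <- sol
      X[, cc] <- Xc
    }

    ac <- active_cols
    Xa <- X[, ac, drop = FALSE]
    Gr <- gram %*% Xa - rhs[, ac, drop = FALSE]
    sta <- state[, ac, drop = FALSE]
    pasm <- sta == 0L
    # equality multiplier per column estimated from the passive gradient
    lam <- colSums(Gr * pasm) / colSums(pasm)
    Mu <- Gr - rep(lam, each = K)
    viol <- pasm & Xa < -tol
    rel <- sta == 1L & Mu < -tol
    fin <- colSums(viol | rel) == 0L

    if (any(fin)) {
      cols_fin <- ac[fin]
      Xf <- X[, cols_fin, drop = FALSE]
      Xf[Xf < 0] <- 0
      X[, cols_fin] <- sweep(Xf, 2, colSums(Xf), "/")
      done[cols_fin] <- TRUE
    }
    if (any(!fin)) {
      idx <- which(!fin)
      cols <- ac[idx]
      Xc <- Xa[, idx, drop = FALSE]
      Xc[Xc < 0] <- 0
      Xc <- sweep(Xc, 2, pmax(colSums(Xc), .Machine$double.eps), "/")
      obj <- colSums(Xc * (gram %*% Xc)) -
        2 * colSums(Xc * rhs[, cols, drop = FALSE])
      worse <- obj >= obj_prev[cols] - 1e-12
      stall[cols] <- ifelse(worse, stall[cols] + 1L, 0L)
      single[cols] <- single[cols] | stall[cols] >= 2L
      obj_prev[cols] <- pmin(obj_prev[cols], obj)

      full_idx <- idx[!single[cols]]
      if (length(full_idx)) {
        cfull <- ac[full_idx]
        sub <- state[, cfull, drop = FALSE]
        sub[viol[, full_idx, drop = FALSE]] <- 1L
        sub[rel[, full_idx, drop = FALSE]] <- 0L
        state[, cfull] <- sub
      }
      for (j in idx[single[cols]]) {
        col <- ac[j]
        vl <- which(viol[, j])
        if (length(vl)) {
          state[vl[which.min(Xa[vl, j])], col] <- 1L
        } else {
          rl <- which(rel[, j])
          state[rl[which.min(Mu[rl, j])], col] <- 0L
        }
      }
    }
    active_cols <- which(!done)
  }
  X
}
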