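#' Solve a simplex-constrained quadratic program
#'
#' Minimizes `1/2 w'Hw + c'w` over the probability simplex
#' (`w >= 0`, `sum(w) = 1`) with an exact primal active-set method. This is
#' the inner problem of the synthetic-control fit: `H` and `c` come from the
#' predictor discrepancy between the treated unit and a weighted donor
#' average.
#'
#' `H` is symmetrized and, when rank-deficient (fewer predictors than
#' donors, the usual case), ridge-regularized by a tiny multiple of its
#' trace so the solution is unique and deterministic; ties between equally
#' optimal vertices resolve toward the minimum-norm solution.
#'
#' @param H Symmetric positive semi-definite `J x J` matrix.
#' @param c_vec Numeric length-`J` linear term.
#' @param tol Feasibility/optimality tolerance (relative to problem scale).
#' @param max_iter Iteration cap; the active-set method terminates long
#'   before this on any sane input.
#' @return List with `w` (the solution, non-negative, summing to one within
#'   1e-8), `value` (the objective `1/2 w'Hw + c'w`), and `converged`.
#' @export
solve_simplex_qp <- function(H, c_vec, tol = 1e-10, max_iter = NULL) {
  J <- length(c_vec)
  stopifnot(nrow(H) == J, ncol(H) == J)
  if (any(!is.finite(H)) || any(!is.finite(c_vec))) {
    abort("Non-finite entries in the quadratic program.")
  }
  if (J == 1L) {
    return(list(w = 1, value = 0.5 * H[1, 1] + c_vec[1], converged = TRUE))
  }
  H <- (H + t(H)) / 2
  scale <- max(abs(H), abs(c_vec), 1)
  ridge <- max(1e-11 * mean(abs(diag(H))), 1e-13 * scale)
  Hr <- H + diag(ridge, J)
  max_iter <- max_iter %||% (100L * J)

  w <- rep(1 / J, J)
  active <- rep(FALSE, J)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    free <- which(!active)
    nf <- length(free)
    # Equality-constrained subproblem on the free set: KKT system for
    # min 1/2 w'Hw + c'w  s.t.  sum(w_free) = 1, w_active = 0.
    K <- rbind(cbind(Hr[free, free, drop = FALSE], rep(1, nf)), c(rep(1, nf), 0))
    rhs <- c(-c_vec[free], 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) {
      Hr <- Hr + diag(1e-8 * scale, J)
      next
    }
    w_target <- sol[seq_len(nf)]
    lambda <- sol[nf + 1]

    if (all(w_target >= -tol * max(1, scale))) {
      w[] <- 0
      w[free] <- pmax(w_target, 0)
      w <- w / sum(w)
      # Check multipliers of the active bounds; release the worst violator.
      if (!any(active)) {
        converged <- TRUE
        break
      }
      mu <- (Hr %*% w + c_vec)[active] + lambda
      if (all(mu >= -1e-9 * max(1, scale))) {
        converged <- TRUE
        break
      }
      j_rel <- which(active)[which.min(mu)]
      active[j_rel] <- FALSE
    } else {
      # Partial step toward the subproblem solution until a bound blocks.
      d <- numeric(J)
      d[free] <- w_target - w[free]
      neg <- free[d[free] < 0]
      alphas <- -w[neg] / d[neg]
      alpha <- max(0, min(1, alphas))
      w <- w + alpha * d
      j_block <- neg[which.min(alphas)]
      w[j_block] <- 0
      active[j_block] <- TRUE
      w <- pmax(w, 0)
      w <- w / sum(w)
    }
  }
  value <- drop(0.5 * t(w) %*% H %*% w + sum(c_vec * w))
  list(w = w, value = value, converged = converged)
}

#' Inner synthetic-control weight solve
#'
#' Finds the donor weights `W` minimizing the importance-weighted predictor
#' discrepancy `(X1 - X0 W)' diag(V) (X1 - X0 W)` over the probability
#' simplex. Deterministic: the problem is a convex quadratic program solved
#' exactly (see [solve_simplex_qp()]).
#'
#' @param X1 Numeric length-`k` treated predictor vector.
#' @param X0 Numeric `k x J` donor predictor matrix (donors in columns).
#' @param v Numeric length-`k` non-negative predictor-importance vector;
#'   normalized to sum to one internally.
#' @return Named numeric weight vector (names from `colnames(X0)`), with an
#'   attribute `"objective"` holding the attained discrepancy.
#' @examples
#' X0 <- cbind(a = c(1, 0), b = c(0, 1), c = c(2, 2))
#' solve_inner_weights(c(0.5, 0.5), X0, c(1, 1))
#' @export
solve_inner_weights <- function(X1, X0, v = rep(1, length(X1))) {
  X1 <- as.numeric(X1)
  X0 <- as.matrix(X0)
  k <- length(X1)
  stopifnot(nrow(X0) == k, length(v) == k, all(v >= 0), sum(v) > 0)
  v <- v / sum(v)
  Xv <- v * X0
  H <- 2 * crossprod(X0, Xv)
  c_vec <- drop(-2 * crossprod(Xv, X1))
  fit <- solve_simplex_qp(H, c_vec)
  w <- fit$w
  names(w) <- colnames(X0)
  attr(w, "objective") <- inner_objective(X1, X0, v, w)
  w
}

# Importance-weighted predictor discrepancy at weights w.
inner_objective <- function(X1, X0, v, w) {
  r <- X1 - drop(X0 %*% w)
  sum(v * r^2)
}
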