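# Heterogeneous-matrix completion by truncated Schatten p-norm
# minimisation. The target matrix stacks the fused miRNA similarity, the
# binary association block and the fused disease similarity; observed
# entries are the two similarity blocks plus the known 1-entries of the
# association blocks. The solver alternates (outer) recomputation of the
# truncation factors and singular-value weights with (inner) a
# box-constrained ADMM whose low-rank step is a weighted singular-value
# contraction.

#' Solver configuration
#'
#' @param alpha Equilibrium coefficient weighting the data-fit term.
#' @param beta ADMM penalty parameter.
#' @param p Power of the retained singular values, in (0, 1]; `p = 1` with
#'   `r = 0` reduces to plain nuclear-norm completion.
#' @param r Truncation rank: the number of leading singular values exempt
#'   from shrinkage.
#' @param l_max Outer iterations (truncation-factor refreshes).
#' @param k_max Weight-sequence refreshes per outer iteration.
#' @param eps1 Tolerance on the relative change of X between ADMM steps.
#' @param eps2 Tolerance on the change of that relative change.
#' @param max_inner Safety cap on ADMM iterations per inner solve.
#' @param sigma_floor Floor applied to singular values before raising to
#'   `p - 1`, preventing infinite weights when `p < 1`.
#' @return A `solver_config` list.
#' @export
solver_config <- function(alpha = 20, beta = 5, p = 1, r = 5, l_max = 4,
                          k_max = 1, eps1 = 2e-3, eps2 = 1e-5,
                          max_inner = 200, sigma_floor = 1e-10) {
  stopifnot(alpha > 0, beta > 0, p > 0, p <= 1, r >= 0, l_max >= 1,
            k_max >= 1, eps1 > 0, eps2 > 0, max_inner >= 0,
            sigma_floor >= 0)
  structure(list(alpha = alpha, beta = beta, p = p, r = as.integer(r),
                 l_max = as.integer(l_max), k_max = as.integer(k_max),
                 eps1 = eps1, eps2 = eps2,
                 max_inner = as.integer(max_inner),
                 sigma_floor = sigma_floor),
            class = "solver_config")
}

#' Build the heterogeneous target matrix
#'
#' Stacks the fused similarities and the association matrix as
#' `H = rbind(cbind(MM, A), cbind(t(A), DD))`. The observation mask covers
#' both similarity blocks entirely and, in the association blocks, only the
#' known 1-entries: unverified zeros are treated as missing, which is what
#' the completion fills in.
#'
#' @param MM Fused miRNA similarity (nm x nm).
#' @param A Binary association matrix (nm x nd).
#' @param DD Fused disease similarity (nd x nd).
#' @return A `het_system`: list with `H`, logical observation `mask`, and
#'   `layout = c(nm, nd)`.
#' @export
build_target_matrix <- function(MM, A, DD) {
  nm <- nrow(A)
  nd <- ncol(A)
  if (nrow(MM) != nm || ncol(MM) != nm || nrow(DD) != nd || ncol(DD) != nd) {
    stop("similarity block dimensions do not match the association matrix")
  }
  if (!is.null(rownames(MM)) && !identical(rownames(MM), rownames(A))) {
    stop("MM labels do not match association matrix rows")
  }
  if (!is.null(rownames(DD)) && !identical(rownames(DD), colnames(A))) {
    stop("DD labels do not match association matrix columns")
  }
  H <- rbind(cbind(MM, A), cbind(t(A), DD))
  labels <- c(rownames(A), colnames(A))
  dimnames(H) <- list(labels, labels)
  mask <- matrix(FALSE, nm + nd, nm + nd)
  mask[seq_len(nm), seq_len(nm)] <- TRUE
  mask[nm + seq_len(nd), nm + seq_len(nd)] <- TRUE
  mask[seq_len(nm), nm + seq_len(nd)] <- A == 1
  mask[nm + seq_len(nd), seq_len(nm)] <- t(A) == 1
  structure(list(H = H, mask = mask, layout = c(nm = nm, nd = nd)),
            class = "het_system")
}

#' Project a matrix onto the observed entries
#'
#' Keeps entries where `mask` is TRUE, zeroes the rest. Idempotent and
#' linear.
#'
#' @param M Numeric matrix.
#' @param mask Logical matrix of the same shape.
#' @return The masked matrix.
#' @export
project_observed <- function(M, mask) {
  if (!identical(dim(M), dim(mask))) stop("mask shape does not match matrix")
  M * mask
}

#' Truncation factors from the leading singular vectors
#'
#' `A` holds the first `r` left singular vectors of `X` as rows, `B` the
#' first `r` right singular vectors, so that the top `r` singular values of
#' `t(B) %*% A` equal 1 and the weight sequence spares them from shrinkage.
#'
#' @param X Square numeric matrix.
#' @param r Truncation rank (0 gives empty factors).
#' @param sv Optional precomputed `svd(X)`.
#' @return List with `A` (r x n) and `B` (r x n).
#' @export
truncation_factors <- function(X, r, sv = NULL) {
  n <- nrow(X)
  if (r > n) stop("truncation rank exceeds matrix dimension")
  if (is.null(sv)) sv <- svd(X)
  if (r == 0L) {
    return(list(A = matrix(0, 0, n), B = matrix(0, 0, n)))
  }
  list(A = t(sv$u[, seq_len(r), drop = FALSE]),
       B = t(sv$v[, seq_len(r), drop = FALSE]))
}

#' Singular-value weight sequence
#'
#' Linearised truncated Schatten p-norm weights
#' `w_i = p * (1 - sigma_i(t(B) %*% A)) * max(sigma_i(X), floor)^(p - 1)`,
#' evaluated at the current iterate's singular values (descending).
#' Because `sigma(t(B) %*% A)` is 1 for the first `r` indices and 0 after,
#' the weights vanish on the retained singular values; with `p = 1` the
#' remainder get unit (nuclear-norm) weights. Tiny numerical dips are
#' repaired with a running maximum so the sequence is exactly
#' non-decreasing, as the contraction operator requires.
#'
#' @param sigma_x Singular values of the current iterate, sorted descending.
#' @param A,B Truncation factors from [truncation_factors()].
#' @param p Schatten power in (0, 1].
#' @param sigma_floor Floor on singular values before exponentiation.
#' @return Non-decreasing, non-negative weight vector.
#' @export
compute_weights <- function(sigma_x, A, B, p, sigma_floor = 1e-10) {
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
  n <- length(sigma_x)
  if (is.unsorted(rev(sigma_x))) stop("singular values must be descending")
  sig_ba <- rep(0, n)
  if (nrow(A) > 0L) {
    d <- svd(crossprod(B, A), nu = 0, nv = 0)$d
    sig_ba[seq_along(d)] <- d
  }
  w <- p * (1 - sig_ba) * pmax(sigma_x, sigma_floor)^(p - 1)
  w <- pmax(w, 0)
  if (any(diff(w) < -1e-8)) {
    stop("computed weight sequence is decreasing; singular values may be ",
         "mis-ordered")
  }
  cummax(w)
}

#' Weighted singular-value contraction operator
#'
#' The proximal map of `tau * sum(w_i * sigma_i(X))`: shrink each singular
#' value of `Q` by `tau * w_i` and floor at zero. The closed form is the
#' exact minimiser of `tau * sum(w_i sigma_i(X)) + ||X - Q||_F^2 / 2` only
#' for non-decreasing weights, which is enforced.
#'
#' @param Q Numeric matrix.
#' @param W Non-decreasing, non-negative weight vector (recycled/truncated
#'   to `min(dim(Q))`).
#' @param tau Shrinkage scale (`1 / beta` inside the ADMM).
#' @return The contracted matrix.
#' @export
weighted_svt <- function(Q, W, tau) {
  if (tau < 0) stop("tau must be non-negative")
  k <- min(dim(Q))
  if (length(W) < k) stop("weight vector shorter than the singular spectrum")
  W <- W[seq_len(k)]
  if (any(W < 0)) stop("weights must be non-negative")
  if (any(diff(W) < 0)) {
    stop("weighted_svt requires a non-decreasing weight sequence")
  }
  if (tau == 0) return(Q)
  sv <- svd(Q)
  d <- pmax(sv$d - tau * W, 0)
  sv$u %*% (d * t(sv$v))
}

# Data-fit + box-constraint step: closed-form minimiser over T of
# alpha/2 ||P(T) - P(H)||_F^2 + tr(E'(X - T)) + beta/2 ||X - T||_F^2,
# clipped to [0, 1].
update_T <- function(X, E, H, mask, alpha, beta, clip = TRUE) {
  M <- E / beta + (alpha / beta) * project_observed(H, mask) + X
  Tbar <- M - (alpha / (alpha + beta)) * project_observed(M, mask)
  if (clip) pmin(pmax(Tbar, 0), 1) else Tbar
}

# Low-rank step: weighted singular-value contraction of T - E/beta.
update_X <- function(T_mat, E, W, beta) {
  weighted_svt(T_mat - E / beta, W, 1 / beta)
}

# Dual ascent on the splitting constraint X = T.
update_E <- function(E, X, T_mat, beta) {
  E + beta * (X - T_mat)
}

#' Inner ADMM loop at a fixed weight sequence
#'
#' Iterates the T (data-fit + box), X (weighted contraction) and E (dual)
#' updates until the relative change of X and the change of that relative
#' change fall below `cfg$eps1` and `cfg$eps2`, or `cfg$max_inner` is
#' reached.
#'
#' @param H_sys A `het_system` from [build_target_matrix()].
#' @param W Weight sequence (fixed during the loop).
#' @param cfg A `solver_config`.
#' @param state List with initial `X`, `T`, `E` matrices.
#' @return List with final `X`, `T`, `E`, `converged`, `iterations`, and
#'   the per-iteration `rel_change` trace.
#' @export
admm_inner <- function(H_sys, W, cfg, state) {
  X <- state$X
  T_mat <- state$T
  E <- state$E
  s1_prev <- NA_real_
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_inner) {
    iter <- iter + 1L
    T_mat <- update_T(X, E, H_sys$H, H_sys$mask, cfg$alpha, cfg$beta)
    X_new <- update_X(T_mat, E, W, cfg$beta)
    E <- update_E(E, X_new, T_mat, cfg$beta)
    if (!all(is.finite(X_new))) {
      stop("ADMM diverged (non-finite iterate) at inner iteration ", iter)
    }
    s1 <- norm(X_new - X, "F") / max(norm(X, "F"), .Machine$double.eps)
    s2 <- if (is.na(s1_prev)) Inf else abs(s1 - s1_prev) / max(abs(s1_prev), 1)
    trace <- c(trace, s1)
    X <- X_new
    if (s1 <= cfg$eps1 && s2 <= cfg$eps2) {
      converged <- TRUE
      break
    }
    s1_prev <- s1
  }
  list(X = X, T = T_mat, E = E, converged = converged, iterations = iter,
       rel_change = trace)
}

#' Complete the heterogeneous matrix
#'
#' Outer loop: from the current iterate's SVD, refresh the truncation
#' factors and the singular-value weights, then run the inner ADMM; stop
#' early when the outer relative change of X drops below `cfg$eps1`. The
#' iterate is initialised at the target matrix itself. The final X is
#' clipped to `[0, 1]` and split back into the completed similarity blocks
#' and the association score block.
#'
#' @param H_sys A `het_system` from [build_target_matrix()].
#' @param cfg A `solver_config`.
#' @param verbose Emit a per-outer-iteration message.
#' @return A `completion_result`: list with `H_star`, `A_star` (nm x nd
#'   score block), `MM_star`, `DD_star`, `converged`, `outer_iters`,
#'   `inner_iters`.
#' @export
complete_matrix <- function(H_sys, cfg = solver_config(), verbose = FALSE) {
  n <- nrow(H_sys$H)
  if (cfg$r >= n) stop("truncation rank must be below the matrix dimension")
  X <- H_sys$H
  T_mat <- X
  E <- matrix(0, n, n)
  inner_total <- 0L
  converged <- FALSE
  outer_done <- 0L
  for (l in seq_len(cfg$l_max)) {
    X_prev <- X
    sv <- svd(X)
    fac <- truncation_factors(X, cfg$r, sv = sv)
    for (k in seq_len(cfg$k_max)) {
      sigma_x <- if (k == 1L) sv$d else svd(X, nu = 0, nv = 0)$d
      W <- compute_weights(sigma_x, fac$A, fac$B, cfg$p, cfg$sigma_floor)
      st <- admm_inner(H_sys, W, cfg,
                       state = list(X = X, T = T_mat, E = E))
      X <- st$X
      T_mat <- st$T
      E <- st$E
      inner_total <- inner_total + st$iterations
      converged <- st$converged
    }
    outer_done <- l
    outer_change <- norm(X - X_prev, "F") /
      max(norm(X_prev, "F"), .Machine$double.eps)
    if (verbose) {
      message(sprintf("outer %d: inner iters %d, rel change %.3e",
                      l, st$iterations, outer_change))
    }
    if (outer_change <= cfg$eps1) break
  }
  X <- pmin(pmax(X, 0), 1)
  X <- (X + t(X)) / 2 # symmetric inputs keep this a no-op up to round-off
  dimnames(X) <- dimnames(H_sys$H)
  nm <- H_sys$layout[["nm"]]
  nd <- H_sys$layout[["nd"]]
  structure(list(
    H_star = X,
    A_star = X[seq_len(nm), nm + seq_len(nd), drop = FALSE],
    MM_star = X[seq_len(nm), seq_len(nm), drop = FALSE],
    DD_star = X[nm + seq_len(nd), nm + seq_len(nd), drop = FALSE],
    converged = converged,
    outer_iters = outer_done,
    inner_iters = inner_total
  ), class = "completion_result")
}

#' Extract the association score block
#'
#' Averages the upper-right block with the transpose of the lower-left
#' block (identical for symmetric completions) and returns it as a labelled
#' score matrix in `[0, 1]`.
#'
#' @param result A `completion_result`.
#' @return Labelled score matrix (miRNAs x diseases) with role `scores`.
#' @export
extract_association_scores <- function(result) {
  nm <- nrow(result$A_star)
  nd <- ncol(result$A_star)
  lower <- t(result$H_star[nm + seq_len(nd), seq_len(nm), drop = FALSE])
  scores <- (result$A_star + lower) / 2
  stopifnot(min(scores) >= 0, max(scores) <= 1)
  validate_labeled_matrix(scores, role = "scores")
}
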