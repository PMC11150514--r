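# Independent oracles used to verify the implementation. Each one derives
# the quantity by a different route than the code under test.

# Brute-force minimiser of tau * sum(w_i sigma_i(X)) + ||X - Q||_F^2 / 2.
# By von Neumann's trace inequality the minimiser shares Q's singular
# vectors, so the problem reduces to the singular-value vector; that
# nonsmooth n-dimensional problem is minimised by restarted Nelder-Mead
# (no shrinkage formula involved).
brute_force_prox <- function(Q, W, tau, restarts = 7L) {
  sv <- svd(Q)
  n <- length(sv$d)
  g <- function(d) {
    d <- pmax(d, 0)
    tau * sum(W * sort(d, decreasing = TRUE)) + 0.5 * sum((d - sv$d)^2)
  }
  best <- sv$d
  bestv <- g(best)
  starts <- list(sv$d, pmax(sv$d - tau, 0), rep(0, n))
  for (s in seq_len(restarts)) {
    st <- if (s <= 3) starts[[s]] else pmax(sv$d + stats::rnorm(n, sd = 0.5), 0)
    fit <- stats::optim(st, g, method = "Nelder-Mead",
                        control = list(maxit = 20000, reltol = 1e-16,
                                       abstol = 1e-16))
    if (fit$value < bestv) {
      bestv <- fit$value
      best <- fit$par
    }
  }
  sv$u %*% (pmax(best, 0) * t(sv$v))
}

# Independently coded nuclear-norm ADMM with box constraints: explicit
# index loops over the observed set and a classical (unweighted)
# singular-value thresholding step. Mirrors the update equations but
# shares no code with the package.
plain_svt_admm <- function(H, obs_idx, alpha, beta, eps1 = 2e-3,
                           eps2 = 1e-5, max_iter = 200L) {
  n <- nrow(H)
  PH <- matrix(0, n, n)
  PH[obs_idx] <- H[obs_idx]
  X <- H
  E <- matrix(0, n, n)
  s1_prev <- NA_real_
  for (it in seq_len(max_iter)) {
    M <- E / beta + (alpha / beta) * PH + X
    PM <- matrix(0, n, n)
    PM[obs_idx] <- M[obs_idx]
    Tm <- M - (alpha / (alpha + beta)) * PM
    Tm[Tm < 0] <- 0
    Tm[Tm > 1] <- 1
    sv <- svd(Tm - E / beta)
    Xn <- sv$u %*% diag(pmax(sv$d - 1 / beta, 0)) %*% t(sv$v)
    E <- E + beta * (Xn - Tm)
    s1 <- norm(Xn - X, "F") / max(norm(X, "F"), .Machine$double.eps)
    s2 <- if (is.na(s1_prev)) Inf else abs(s1 - s1_prev) / max(abs(s1_prev), 1)
    X <- Xn
    if (s1 <= eps1 && s2 <= eps2) break
    s1_prev <- s1
  }
  X[X < 0] <- 0
  X[X > 1] <- 1
  X
}

# All-pairs comparison AUC: the fraction of (positive, negative) pairs the
# positive wins, ties counting one half.
brute_force_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) {
    for (q in neg) {
      wins <- wins + (p > q) + 0.5 * (p == q)
    }
  }
  wins / (length(pos) * length(neg))
}

# Naive semantic-similarity evaluator over an edge data frame: ancestor
# sets by repeated edge scanning, first-scheme contributions by direct
# recursion, both similarity schemes straight from their definitions.
naive_ancestors <- function(edges, term) {
  out <- term
  repeat {
    more <- unique(edges$parent[edges$child %in% out])
    more <- setdiff(more, out)
    if (!length(more)) return(out)
    out <- c(out, more)
  }
}

naive_w1 <- function(edges, root, phi) {
  tset <- naive_ancestors(edges, root)
  rec <- function(t) {
    if (t == root) return(1)
    kids <- intersect(edges$child[edges$parent == t], tset)
    phi * max(vapply(kids, rec, numeric(1)))
  }
  stats::setNames(vapply(tset, rec, numeric(1)), tset)
}

naive_ds1 <- function(edges, roots, phi, di, dj) {
  wi <- naive_w1(edges, roots[[di]], phi)
  wj <- naive_w1(edges, roots[[dj]], phi)
  shared <- intersect(names(wi), names(wj))
  sum(wi[shared] + wj[shared]) / (sum(wi) + sum(wj))
}

naive_ds2 <- function(edges, roots, di, dj) {
  tsets <- lapply(roots, function(r) naive_ancestors(edges, r))
  w2 <- function(t) {
    -log(sum(vapply(tsets, function(s) t %in% s, logical(1))) / length(roots))
  }
  ti <- tsets[[di]]
  tj <- tsets[[dj]]
  denom <- sum(vapply(ti, w2, numeric(1))) + sum(vapply(tj, w2, numeric(1)))
  if (denom == 0) return(0)
  shared <- intersect(ti, tj)
  sum(vapply(shared, function(t) 2 * w2(t), numeric(1))) / denom
}

# Random layered DAG over indexed terms (edges always point to a lower
# index, so acyclicity holds by construction) with diseases on random
# terms.
random_dag_fixture <- function(n_terms = 8L, n_diseases = 3L) {
  edges <- do.call(rbind, lapply(2:n_terms, function(i) {
    parents <- sample(seq_len(i - 1), min(sample(1:2, 1), i - 1))
    data.frame(child = paste0("t", i), parent = paste0("t", parents),
               stringsAsFactors = FALSE)
  }))
  roots <- stats::setNames(
    paste0("t", sample(2:n_terms, n_diseases)),
    paste0("dis", seq_len(n_diseases)))
  list(edges = edges, roots = roots)
}
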