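make_system <- function(nm = 6L, nd = 4L, density = 0.4, seed = 1L) {
  spec <- synthetic_spec(nm = nm, nd = nd, latent_rank = 2L,
                         density = density, noise_sd = 0.02, seed = seed)
  b <- generate_planted_dataset(spec)
  list(sys = build_target_matrix(b$MM, b$assoc, b$DD), bundle = b)
}

test_that("target matrix stacks the blocks and observes only known ones", {
  lab_m <- c("m1", "m2")
  lab_d <- "d1"
  MM <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(lab_m, lab_m))
  DD <- matrix(1, 1, 1, dimnames = list(lab_d, lab_d))
  A <- matrix(c(1, 0), 2, 1, dimnames = list(lab_m, lab_d))
  hs <- build_target_matrix(MM, A, DD)
  expect_equal(hs$H[1, 3], 1) # A[1,1] sits in the upper-right block
  expect_equal(hs$H, t(hs$H))
  expect_true(hs$mask[1, 3])
  expect_true(hs$mask[3, 1])
  expect_false(hs$mask[2, 3]) # unverified zero is unobserved
  expect_true(all(hs$mask[1:2, 1:2]))

  A0 <- A * 0
  hs0 <- build_target_matrix(MM, A0, DD)
  expect_equal(sum(hs0$mask), 4 + 1) # similarity blocks only

  expect_error(build_target_matrix(MM, A, MM), "dimensions")
})

test_that("projection is masked identity: idempotent and linear", {
  set.seed(3)
  M <- matrix(rnorm(16), 4, 4)
  none <- matrix(FALSE, 4, 4)
  all_ <- matrix(TRUE, 4, 4)
  expect_equal(project_observed(M, none), matrix(0, 4, 4))
  expect_equal(project_observed(M, all_), M)
  mask <- matrix(sample(c(TRUE, FALSE), 16, replace = TRUE), 4, 4)
  P <- project_observed(M, mask)
  expect_equal(project_observed(P, mask), P)
  N <- matrix(rnorm(16), 4, 4)
  expect_equal(project_observed(M + 2 * N, mask),
               project_observed(M, mask) + 2 * project_observed(N, mask))
})

test_that("truncation factors are orthonormal slices of the SVD", {
  set.seed(4)
  X <- matrix(rnorm(36), 6, 6)
  for (r in c(0L, 2L, 5L)) {
    fac <- truncation_factors(X, r)
    expect_equal(dim(fac$A), c(r, 6L))
    if (r > 0) {
      expect_lt(max(abs(tcrossprod(fac$A) - diag(r))), 1e-10)
      expect_lt(max(abs(tcrossprod(fac$B) - diag(r))), 1e-10)
      # top-r singular values of t(B) %*% A are exactly 1
      d <- svd(crossprod(fac$B, fac$A))$d
      expect_equal(d[seq_len(r)], rep(1, r), tolerance = 1e-10)
    }
  }
  expect_error(truncation_factors(X, 7L), "exceeds")
})

test_that("weight sequence spares retained singular values and is
           non-decreasing", {
  set.seed(8)
  X <- matrix(rnorm(36), 6, 6)
  sv <- svd(X)

  fac0 <- truncation_factors(X, 0L, sv = sv)
  w <- compute_weights(sv$d, fac0$A, fac0$B, p = 1)
  expect_equal(w, rep(1, 6)) # plain nuclear-norm weights

  fac2 <- truncation_factors(X, 2L, sv = sv)
  w2 <- compute_weights(sv$d, fac2$A, fac2$B, p = 1)
  expect_equal(w2, c(0, 0, 1, 1, 1, 1), tolerance = 1e-8)

  w3 <- compute_weights(c(4, 1), matrix(0, 0, 2), matrix(0, 0, 2), p = 0.5)
  expect_equal(w3, c(0.25, 0.5))

  expect_error(compute_weights(c(2, 1), fac0$A, fac0$B, p = 1.5), "p must")
  expect_error(compute_weights(c(1, 2), fac0$A, fac0$B, p = 1),
               "descending")

  # property: non-decreasing for random matrices and any p, r
  for (rep in 1:10) {
    Y <- matrix(rnorm(49), 7, 7)
    svy <- svd(Y)
    r <- sample(0:4, 1)
    p <- runif(1, 0.2, 1)
    fac <- truncation_factors(Y, r, sv = svy)
    wr <- compute_weights(svy$d, fac$A, fac$B, p = p)
    expect_true(all(diff(wr) >= 0))
    expect_true(all(wr >= 0))
  }
})

test_that("weighted contraction has the expected closed-form behaviour", {
  fx <- worked_example_fixture()
  expect_equal(weighted_svt(fx$prox$Q, fx$prox$W, fx$prox$tau),
               fx$expected$prox_result)

  set.seed(9)
  Q <- matrix(rnorm(25), 5, 5)
  expect_equal(weighted_svt(Q, rep(1, 5), 0), Q) # tau = 0 is the identity

  # all-ones weights reduce to classical singular-value thresholding
  sv <- svd(Q)
  classical <- sv$u %*% diag(pmax(sv$d - 0.3, 0)) %*% t(sv$v)
  expect_equal(weighted_svt(Q, rep(1, 5), 0.3), classical,
               tolerance = 1e-12)

  expect_error(weighted_svt(Q, c(1, 0.5, 1, 1, 1), 0.3), "non-decreasing")
})

test_that("ADMM single steps satisfy their optimality conditions", {
  set.seed(10)
  n <- 6
  X <- matrix(runif(n * n), n, n)
  E <- matrix(rnorm(n * n, sd = 0.1), n, n)
  H <- matrix(runif(n * n), n, n)
  mask <- matrix(sample(c(TRUE, FALSE), n * n, replace = TRUE), n, n)
  alpha <- 20
  beta <- 5

  # unclipped stationarity: alpha P(P(T) - P(H)) - E - beta (X - T) = 0
  Tbar <- mdacomp:::update_T(X, E, H, mask, alpha, beta, clip = FALSE)
  resid <- alpha * project_observed(Tbar - H, mask) - E - beta * (X - Tbar)
  expect_lt(max(abs(resid)), 1e-8)

  # empty mask: T = clip(X + E / beta)
  none <- matrix(FALSE, n, n)
  expect_equal(mdacomp:::update_T(X, E, H, none, alpha, beta),
               pmin(pmax(X + E / beta, 0), 1))

  big <- X
  big[1, 1] <- 5
  big[2, 2] <- -3
  Tc <- mdacomp:::update_T(big, E * 0, H, none, alpha, beta)
  expect_equal(Tc[1, 1], 1)
  expect_equal(Tc[2, 2], 0)

  # zero weights: X-step is exactly T - E / beta
  expect_equal(mdacomp:::update_X(X, E, rep(0, n), beta), X - E / beta)
  # dual update is linear in the primal residual
  expect_equal(mdacomp:::update_E(E, X, X, beta), E)
  expect_equal(mdacomp:::update_E(E, X + 1 / beta, X, beta), E + 1)
})

test_that("inner ADMM reproduces a fully observed low-rank target", {
  ms <- make_system(nm = 8L, nd = 5L)
  hs <- ms$sys
  hs$mask[] <- TRUE # fully observed
  cfg <- solver_config(alpha = 1000, beta = 1, r = 13 - 1, max_inner = 300)
  n <- nrow(hs$H)
  W <- rep(0, n) # no shrinkage: pure data fit
  st <- admm_inner(hs, W, cfg,
                   state = list(X = hs$H, T = hs$H,
                                E = matrix(0, n, n)))
  expect_lt(max(abs(st$X - hs$H)), 1e-3)
  expect_true(all(is.finite(st$rel_change)))

  cfg0 <- solver_config(max_inner = 0)
  st0 <- admm_inner(hs, W, cfg0,
                    state = list(X = hs$H, T = hs$H,
                                 E = matrix(0, n, n)))
  expect_false(st0$converged)
  expect_equal(st0$X, hs$H)
})

test_that("solver accepts the default configuration and fills in masked
           structure", {
  cfg <- solver_config()
  expect_equal(cfg$alpha, 20)
  expect_equal(cfg$beta, 5)
  expect_equal(cfg$p, 1)
  expect_equal(cfg$r, 5L)

  spec <- synthetic_spec(nm = 20L, nd = 15L, latent_rank = 3L,
                         density = 0.3, noise_sd = 0, seed = 21)
  b <- generate_planted_dataset(spec)
  ones <- which(b$assoc == 1)
  set.seed(22)
  masked <- sample(ones, round(0.4 * length(ones)))
  train <- b$assoc
  train[masked] <- 0
  hs <- build_target_matrix(b$MM, train, b$DD)
  res <- complete_matrix(hs, solver_config(r = 4))
  scores <- extract_association_scores(res)
  never <- which(b$assoc == 0)
  expect_gt(mean(scores[masked]), mean(scores[never]))
  # known training positives score at or above the matrix median
  expect_true(all(scores[train == 1] >= stats::median(scores)))
})

test_that("completion preserves symmetry and the box constraint", {
  for (seed in 1:5) {
    ms <- make_system(nm = 7L, nd = 5L, seed = seed)
    res <- complete_matrix(ms$sys, solver_config(r = 3))
    expect_true(all(res$H_star >= 0 & res$H_star <= 1))
    expect_lt(max(abs(res$H_star - t(res$H_star))), 1e-8)
    sc <- extract_association_scores(res)
    expect_equal(sc, res$A_star, ignore_attr = TRUE)
  }
})
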