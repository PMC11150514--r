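test_that("rank-based AUC matches the all-pairs comparison oracle", {
  expect_equal(auc_from_scores(c(0.9, 0.4), c(0.6, 0.1)), 0.75)
  expect_equal(auc_from_scores(c(1, 1), c(0.1, 0.2)), 1)
  expect_equal(auc_from_scores(rep(0.5, 3), rep(0.5, 4)), 0.5)
  expect_error(auc_from_scores(numeric(0), 1), "non-empty")

  set.seed(31)
  for (rep in 1:100) {
    pos <- round(runif(sample(1:8, 1)), 2) # rounding forces ties
    neg <- round(runif(sample(1:8, 1)), 2)
    expect_equal(auc_from_scores(pos, neg), brute_force_auc(pos, neg))
  }
})

test_that("precision-recall area follows the stepwise hand construction", {
  expect_equal(aupr_from_scores(c(0.9, 0.8), c(0.2, 0.1)), 1)
  expect_equal(aupr_from_scores(0.99, runif(9, 0, 0.9)), 1)
  # hand PR curve: ranks P N P N -> 0.5 * 1 + 0.5 * (2/3)
  expect_equal(aupr_from_scores(c(0.9, 0.4), c(0.6, 0.1)), 5 / 6)
  # tied block handled as one group: P and N at the same score
  expect_equal(aupr_from_scores(0.5, 0.5), 0.5)
})

test_that("k-fold folds partition the positives and are seed-reproducible", {
  spec <- synthetic_spec(nm = 12L, nd = 8L, latent_rank = 2L,
                         density = 0.25, noise_sd = 0.02, seed = 41)
  b <- generate_planted_dataset(spec)
  cvc <- cv_config(k = 4L, seed = 7L)
  scfg <- solver_config(r = 3L, max_inner = 80)
  r1 <- kfold_cv(b$assoc, list(), cvc, scfg)
  r2 <- kfold_cv(b$assoc, list(), cvc, scfg)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_length(r1$per_fold, 4L)
  expect_true(r1$auc >= 0 && r1$auc <= 1)
  # every positive scored exactly once as a held-out test case
  expect_equal(sum(r1$score_table$is_positive), sum(b$assoc))

  expect_error(kfold_cv(b$assoc, list(),
                        cv_config(k = sum(b$assoc) + 1), scfg),
               "exceeds")
})

test_that("planted-structure k-fold recovers held-out associations well", {
  spec <- synthetic_spec(nm = 30L, nd = 20L, latent_rank = 3L,
                         density = 0.3, noise_sd = 0, seed = 51)
  b <- generate_planted_dataset(spec)
  res <- kfold_cv(b$assoc, list(mf = b$MM, ds = b$DD),
                  cv_config(k = 5L, seed = 3L), solver_config(r = 4L))
  expect_gt(res$auc, 0.8)
  expect_gt(res$aupr, 0.3)
})

test_that("leave-one-out is deterministic and perfect on a structurally
           forced system", {
  # two miRNAs similar only to each other and sharing the one associated
  # disease: the held-out pair is forced to the top of the ranking
  nm <- 10L
  nd <- 6L
  mirnas <- sprintf("m%02d", 1:nm)
  diseases <- sprintf("d%d", 1:nd)
  MM <- matrix(0.05, nm, nm, dimnames = list(mirnas, mirnas))
  diag(MM) <- 1
  MM["m01", "m02"] <- MM["m02", "m01"] <- 0.9
  DD <- matrix(0.05, nd, nd, dimnames = list(diseases, diseases))
  diag(DD) <- 1
  A <- matrix(0, nm, nd, dimnames = list(mirnas, diseases))
  A["m01", "d1"] <- 1
  A["m02", "d1"] <- 1
  cvc <- cv_config(scheme = "global_loocv", seed = 1L)
  scfg <- solver_config(r = 2L)
  r1 <- global_loocv(A, list(mf = MM, ds = DD), cvc, scfg)
  expect_equal(r1$auc, 1)
  # no sampling involved: a different seed cannot change the result
  r2 <- global_loocv(A, list(mf = MM, ds = DD),
                     cv_config(scheme = "global_loocv", seed = 99L), scfg)
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$per_fold, r2$per_fold)

  expect_warning(
    global_loocv(A, list(mf = MM, ds = DD),
                 cv_config(scheme = "global_loocv", loocv_cap = 1L), scfg),
    "cap")
})

test_that("confusion metrics reproduce the hand-worked table and behave at
           the extremes", {
  hand <- data.frame(score = c(0.9, 0.3, 0.7, 0.1),
                     is_positive = c(TRUE, TRUE, FALSE, FALSE))
  out <- threshold_metrics(hand, thresholds = c(tau = 0.5))
  expect_equal(out$accuracy, 0.5)
  expect_equal(out$precision, 0.5)
  expect_equal(out$recall, 0.5)
  expect_equal(out$f1, 0.5)
  expect_equal(out$mcc, 0)

  perfect <- data.frame(score = c(0.9, 0.8, 0.2, 0.1),
                        is_positive = c(TRUE, TRUE, FALSE, FALSE))
  best <- threshold_metrics(perfect)
  expect_equal(rownames(best), c("T1", "T2", "T3"))
  expect_equal(best$accuracy, rep(1, 3))
  expect_equal(best$mcc, rep(1, 3))

  set.seed(71)
  noise <- data.frame(score = runif(2000), is_positive = rep(c(TRUE, FALSE),
                                                             1000))
  bal <- balance_score_table(noise, ratio = 1, seed = 5L)
  m <- threshold_metrics(bal, thresholds = c(0.5))
  expect_lt(abs(m$mcc), 0.1)

  expect_error(threshold_metrics(data.frame(score = 1, is_positive = TRUE)),
               "both classes")
})

test_that("sparsity experiment reuses the full matrix at fraction 1 and
           guards bad fractions", {
  spec <- synthetic_spec(nm = 12L, nd = 8L, latent_rank = 2L,
                         density = 0.25, noise_sd = 0.02, seed = 81)
  b <- generate_planted_dataset(spec)
  cvc <- cv_config(k = 3L, seed = 11L)
  scfg <- solver_config(r = 3L, max_inner = 80)
  plain <- kfold_cv(b$assoc, list(), cvc, scfg)
  sweep <- sparsity_experiment(b$assoc, list(), fractions = c(0.5, 1),
                               cv_cfg = cvc, solver_cfg = scfg)
  expect_identical(sweep$auc[sweep$fraction == 1], plain$auc)
  expect_error(sparsity_experiment(b$assoc, list(), fractions = c(0, 0.5)),
               "fractions")
})

test_that("held-out entries cannot influence training artifacts", {
  spec <- synthetic_spec(nm = 10L, nd = 8L, latent_rank = 2L,
                         density = 0.3, noise_sd = 0.02, seed = 91)
  b <- generate_planted_dataset(spec)
  pos <- which(b$assoc == 1, arr.ind = TRUE)
  test_idx <- pos[1:5, , drop = FALSE]
  poisoned <- b$assoc
  poisoned[test_idx] <- 99 # sentinel held-out values
  clean <- build_training_system(b$assoc, test_idx,
                                 list(mf = b$MM, ds = b$DD))
  dirty <- build_training_system(poisoned, test_idx,
                                 list(mf = b$MM, ds = b$DD))
  expect_identical(clean$train, dirty$train)
  expect_identical(clean$system$H, dirty$system$H)
  expect_identical(clean$system$mask, dirty$system$mask)
})
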