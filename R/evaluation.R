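# Cross-validation protocols and metrics: global leave-one-out and k-fold
# CV over known association entries, rank-based AUC / AUPR, thresholded
# confusion metrics with 1:1 negative sampling, and the sparsity
# sensitivity experiment.

#' Cross-validation configuration
#'
#' @param scheme `"kfold"` or `"global_loocv"`.
#' @param k Number of folds for `"kfold"` (>= 2).
#' @param seed RNG seed; recorded in the result.
#' @param recompute_gipk Recompute the interaction-profile kernels (and the
#'   similarity fusion) from the training matrix of each fold. Keeping this
#'   on prevents held-out associations from leaking into the similarities.
#' @param negative_ratio Negatives sampled per positive for the thresholded
#'   confusion metrics.
#' @param loocv_cap Emit a warning when leave-one-out is asked to re-solve
#'   more than this many folds.
#' @return A `cv_config` list.
#' @export
cv_config <- function(scheme = c("kfold", "global_loocv"), k = 5L,
                      seed = 1L, recompute_gipk = TRUE,
                      negative_ratio = 1, loocv_cap = 500L) {
  scheme <- match.arg(scheme)
  stopifnot(k >= 2, negative_ratio > 0)
  structure(list(scheme = scheme, k = as.integer(k), seed = as.integer(seed),
                 recompute_gipk = isTRUE(recompute_gipk),
                 negative_ratio = negative_ratio,
                 loocv_cap = as.integer(loocv_cap)),
            class = "cv_config")
}

#' Rank-based AUC from two score lists
#'
#' The probability that a random positive outranks a random negative, with
#' ties counting one half: the Mann-Whitney statistic divided by
#' `n_pos * n_neg`.
#'
#' @param positives,negatives Numeric score vectors, both non-empty.
#' @return AUC in `[0, 1]`.
#' @export
auc_from_scores <- function(positives, negatives) {
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("both score lists must be non-empty")
  }
  r <- rank(c(positives, negatives))
  np <- length(positives)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(negatives))
}

#' Area under the precision-recall curve
#'
#' Step interpolation over descending scores; tied scores are processed as
#' one group so the curve is a deterministic function of the score
#' multiset.
#'
#' @inheritParams auc_from_scores
#' @return AUPR in `(0, 1]`.
#' @export
aupr_from_scores <- function(positives, negatives) {
  if (length(positives) == 0L) stop("positives must be non-empty")
  scores <- c(positives, negatives)
  labels <- rep(c(1, 0), c(length(positives), length(negatives)))
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  labels <- labels[ord]
  grp_end <- which(!duplicated(scores, fromLast = TRUE))
  tp <- cumsum(labels)[grp_end]
  n_at <- grp_end
  precision <- tp / n_at
  recall <- tp / length(positives)
  sum(diff(c(0, recall)) * precision)
}

# Training system for one CV fold: zero the held-out entries, recompute
# the interaction-profile kernels from the training matrix (unless told to
# reuse precomputed ones), fuse, and assemble the target matrix. Exposed so
# leakage can be audited directly.

#' Build the training-fold heterogeneous system
#'
#' Zeroes the held-out association entries and assembles the completion
#' target from the training data only. With `recompute_gipk = TRUE`
#' (default) the interaction-profile kernels and fused similarities are
#' derived from the training matrix, so held-out entries cannot influence
#' any training artifact.
#'
#' @param assoc Full binary association matrix.
#' @param test_idx Two-column index matrix (row, col) of held-out
#'   1-entries.
#' @param similarities List with optional `mf` (miRNA functional
#'   similarity) and `ds` (disease semantic similarity) matrices; when
#'   absent the kernels alone are used.
#' @param recompute_gipk Recompute kernels from the training matrix.
#' @param precomputed Optional list with `mgks` and `dgks` used when
#'   `recompute_gipk = FALSE`.
#' @return List with `system` (a `het_system`) and `train` (the training
#'   association matrix).
#' @export
build_training_system <- function(assoc, test_idx,
                                  similarities = list(),
                                  recompute_gipk = TRUE,
                                  precomputed = NULL) {
  train <- assoc
  if (length(test_idx)) train[test_idx] <- 0
  if (recompute_gipk || is.null(precomputed)) {
    mgks <- gipk_similarity(train, "mirna")
    dgks <- gipk_similarity(train, "disease")
  } else {
    mgks <- precomputed$mgks
    dgks <- precomputed$dgks
  }
  mf <- similarities$mf
  ds <- similarities$ds
  zero_like <- function(k) {
    matrix(0, nrow(k), ncol(k), dimnames = dimnames(k))
  }
  MM <- fuse_similarity(if (is.null(mf)) zero_like(mgks) else mf, mgks, "MM")
  DD <- fuse_similarity(if (is.null(ds)) zero_like(dgks) else ds, dgks, "DD")
  list(system = build_target_matrix(MM, train, DD), train = train)
}

fold_scores <- function(assoc, test_idx, similarities, cv_cfg, solver_cfg) {
  ts <- build_training_system(assoc, test_idx, similarities,
                              recompute_gipk = cv_cfg$recompute_gipk)
  res <- complete_matrix(ts$system, solver_cfg)
  extract_association_scores(res)
}

#' Global leave-one-out cross-validation
#'
#' Each known association is held out in turn, the model is re-trained on
#' the remainder (kernels recomputed from the training matrix), and the
#' held-out pair is ranked against every never-known candidate pair. The
#' reported AUC pools all test-versus-candidate comparisons.
#'
#' @param assoc Binary association matrix.
#' @param similarities List with optional `mf` and `ds` matrices (see
#'   [build_training_system()]).
#' @param cv_cfg A `cv_config`.
#' @param solver_cfg A `solver_config`.
#' @return A `cv_result` list with `auc`, `aupr`, `per_fold`,
#'   `score_table`, `seed`, `scheme`.
#' @export
global_loocv <- function(assoc, similarities = list(),
                         cv_cfg = cv_config(scheme = "global_loocv"),
                         solver_cfg = solver_config()) {
  pos <- which(assoc == 1, arr.ind = TRUE)
  if (nrow(pos) < 2L) stop("leave-one-out needs at least 2 associations")
  if (nrow(pos) > cv_cfg$loocv_cap) {
    warning("leave-one-out will re-solve ", nrow(pos),
            " folds (cap ", cv_cfg$loocv_cap, "); this may be slow")
  }
  cand <- which(assoc == 0, arr.ind = TRUE)
  wins <- 0
  total <- 0
  per_fold <- numeric(nrow(pos))
  pos_scores <- numeric(nrow(pos))
  cand_sum <- numeric(nrow(cand))
  for (f in seq_len(nrow(pos))) {
    scores <- tryCatch(
      fold_scores(assoc, pos[f, , drop = FALSE], similarities, cv_cfg,
                  solver_cfg),
      error = function(e) stop("solver failed on fold ", f, ": ",
                               conditionMessage(e))
    )
    s_test <- scores[pos[f, , drop = FALSE]]
    s_cand <- scores[cand]
    wins <- wins + sum(s_test > s_cand) + 0.5 * sum(s_test == s_cand)
    total <- total + length(s_cand)
    per_fold[f] <- auc_from_scores(s_test, s_cand)
    pos_scores[f] <- s_test
    cand_sum <- cand_sum + s_cand
  }
  score_table <- rbind(
    data.frame(mirna = rownames(assoc)[pos[, 1]],
               disease = colnames(assoc)[pos[, 2]],
               score = pos_scores, is_positive = TRUE,
               stringsAsFactors = FALSE),
    data.frame(mirna = rownames(assoc)[cand[, 1]],
               disease = colnames(assoc)[cand[, 2]],
               score = cand_sum / nrow(pos), is_positive = FALSE,
               stringsAsFactors = FALSE)
  )
  structure(list(auc = wins / total,
                 aupr = aupr_from_scores(pos_scores, cand_sum / nrow(pos)),
                 per_fold = per_fold, score_table = score_table,
                 seed = cv_cfg$seed, scheme = "global_loocv"),
            class = "cv_result")
}

#' k-fold cross-validation over known associations
#'
#' The known 1-entries are shuffled by seed and split into `k` near-equal
#' folds. Per fold, test entries are zeroed in the training matrix, the
#' model re-trained, and the test scores ranked against every never-known
#' candidate pair. The headline AUC is the mean of the per-fold AUCs;
#' candidate scores in the pooled score table are averaged over folds.
#'
#' @inheritParams global_loocv
#' @return A `cv_result` list.
#' @export
kfold_cv <- function(assoc, similarities = list(),
                     cv_cfg = cv_config(), solver_cfg = solver_config()) {
  pos <- which(assoc == 1, arr.ind = TRUE)
  n_pos <- nrow(pos)
  k <- cv_cfg$k
  if (k > n_pos) stop("k exceeds the number of known associations")
  set.seed(cv_cfg$seed)
  fold_of <- sample(rep_len(seq_len(k), n_pos))
  cand <- which(assoc == 0, arr.ind = TRUE)
  per_fold <- numeric(k)
  pos_scores <- numeric(n_pos)
  cand_sum <- numeric(nrow(cand))
  for (f in seq_len(k)) {
    test_idx <- pos[fold_of == f, , drop = FALSE]
    if (nrow(test_idx) == 0L) stop("fold ", f, " is empty")
    scores <- fold_scores(assoc, test_idx, similarities, cv_cfg, solver_cfg)
    s_test <- scores[test_idx]
    s_cand <- scores[cand]
    per_fold[f] <- auc_from_scores(s_test, s_cand)
    pos_scores[fold_of == f] <- s_test
    cand_sum <- cand_sum + s_cand
  }
  cand_mean <- cand_sum / k
  score_table <- rbind(
    data.frame(mirna = rownames(assoc)[pos[, 1]],
               disease = colnames(assoc)[pos[, 2]],
               score = pos_scores, is_positive = TRUE,
               stringsAsFactors = FALSE),
    data.frame(mirna = rownames(assoc)[cand[, 1]],
               disease = colnames(assoc)[cand[, 2]],
               score = cand_mean, is_positive = FALSE,
               stringsAsFactors = FALSE)
  )
  structure(list(auc = mean(per_fold),
                 aupr = aupr_from_scores(pos_scores, cand_mean),
                 per_fold = per_fold, score_table = score_table,
                 seed = cv_cfg$seed, scheme = "kfold"),
            class = "cv_result")
}

#' Balance a score table by sampling negatives
#'
#' Uniform sampling without replacement from the negative rows, seeded, at
#' `ratio` negatives per positive.
#'
#' @param score_table Data frame with columns `score` and `is_positive`.
#' @param ratio Negatives per positive.
#' @param seed RNG seed.
#' @return The balanced score table.
#' @export
balance_score_table <- function(score_table, ratio = 1, seed = 1L) {
  pos <- score_table[score_table$is_positive, , drop = FALSE]
  neg <- score_table[!score_table$is_positive, , drop = FALSE]
  n_take <- min(nrow(neg), round(ratio * nrow(pos)))
  set.seed(seed)
  take <- sample(nrow(neg), n_take)
  rbind(pos, neg[take, , drop = FALSE])
}

confusion_metrics <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  tp <- sum(pred & labels)
  fp <- sum(pred & !labels)
  fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  c(threshold = threshold, accuracy = (tp + tn) / length(labels),
    precision = prec, recall = rec, f1 = f1, mcc = mcc)
}

#' Thresholded confusion metrics
#'
#' Reports Accuracy, Precision, Recall, F1 and MCC at three thresholds T1,
#' T2, T3 that respectively maximise Accuracy, F1 and MCC over an
#' exhaustive scan of the achievable decision boundaries (midpoints of the
#' sorted unique scores, plus the all-positive and all-negative
#' extremes). A score is classified positive when it is at or above the
#' threshold. Explicit `thresholds` skip the search.
#'
#' @param score_table Data frame with columns `score` and `is_positive`,
#'   containing both classes (balance it first with
#'   [balance_score_table()] for protocol work).
#' @param thresholds Optional named or unnamed numeric vector of thresholds
#'   to evaluate instead of searching.
#' @return Data frame with one row per threshold (`T1`, `T2`, `T3` when
#'   searched) and the five metrics.
#' @export
threshold_metrics <- function(score_table, thresholds = NULL) {
  labels <- score_table$is_positive
  scores <- score_table$score
  if (all(labels) || !any(labels)) {
    stop("score table must contain both classes")
  }
  if (is.null(thresholds)) {
    u <- sort(unique(scores))
    cand <- c(u[1], if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
              u[length(u)] + 1)
    grid <- t(vapply(cand, function(th) confusion_metrics(scores, labels, th),
                     numeric(6)))
    thresholds <- c(
      T1 = cand[which.max(grid[, "accuracy"])],
      T2 = cand[which.max(grid[, "f1"])],
      T3 = cand[which.max(grid[, "mcc"])]
    )
  }
  out <- t(vapply(thresholds, function(th) confusion_metrics(scores, labels, th),
                  numeric(6)))
  out <- as.data.frame(out)
  if (!is.null(names(thresholds))) rownames(out) <- names(thresholds)
  out
}

#' Masked-positive recovery on a planted dataset
#'
#' Generates a planted low-rank dataset, hides `mask_fraction` of the
#' association 1-entries, optionally subsamples the remaining observed ones
#' to `observed_fraction`, completes the system using the generator's
#' similarity matrices, and reports the AUC of the masked (held-out)
#' positives against the never-associated pairs. All randomness descends
#' from `spec$seed`.
#'
#' @param spec A `synthetic_spec`.
#' @param mask_fraction Fraction of 1-entries hidden for evaluation.
#' @param observed_fraction Fraction of the remaining 1-entries kept as
#'   training observations.
#' @param solver_cfg A `solver_config`.
#' @return List with `auc`, `n_masked`, `n_observed`.
#' @export
planted_recovery_auc <- function(spec, mask_fraction = 0.3,
                                 observed_fraction = 1,
                                 solver_cfg = solver_config()) {
  stopifnot(mask_fraction > 0, mask_fraction < 1,
            observed_fraction > 0, observed_fraction <= 1)
  bundle <- generate_planted_dataset(spec)
  ones <- which(bundle$assoc == 1)
  never <- which(bundle$assoc == 0)
  # RNG state is already seeded (and advanced) by the generator, so the
  # mask and subsample are reproducible from spec$seed alone
  masked <- sample(ones, round(mask_fraction * length(ones)))
  kept <- setdiff(ones, masked)
  if (observed_fraction < 1) {
    kept <- sample(kept, max(1L, round(observed_fraction * length(kept))))
  }
  train <- bundle$assoc
  train[] <- 0
  train[kept] <- 1
  hs <- build_target_matrix(bundle$MM, train, bundle$DD)
  scores <- extract_association_scores(complete_matrix(hs, solver_cfg))
  list(auc = auc_from_scores(scores[masked], scores[never]),
       n_masked = length(masked), n_observed = length(kept))
}

#' Sensitivity of CV performance to association sparsity
#'
#' Subsamples the known associations to each requested fraction (seeded),
#' reruns the configured cross-validation scheme, and reports the AUC per
#' fraction. A fraction of 1 reuses the full matrix, so the result then
#' matches the plain CV run bit for bit at equal seed.
#'
#' @inheritParams global_loocv
#' @param fractions Fractions of known associations to retain, in (0, 1].
#' @return Data frame with columns `fraction`, `n_associations`, `auc`,
#'   `aupr`.
#' @export
sparsity_experiment <- function(assoc, similarities = list(),
                                fractions = c(0.1, 0.5, 1),
                                cv_cfg = cv_config(),
                                solver_cfg = solver_config()) {
  if (any(fractions <= 0) || any(fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  pos <- which(assoc == 1)
  rows <- lapply(fractions, function(fr) {
    sub <- assoc
    if (fr < 1) {
      n_keep <- max(1L, floor(fr * length(pos)))
      set.seed(cv_cfg$seed)
      keep <- sample(pos, n_keep)
      sub[setdiff(pos, keep)] <- 0
    }
    n1 <- sum(sub == 1)
    if (cv_cfg$scheme == "kfold" && n1 < cv_cfg$k) {
      stop("fraction ", fr, " leaves fewer associations than folds")
    }
    res <- if (cv_cfg$scheme == "kfold") {
      kfold_cv(sub, similarities, cv_cfg, solver_cfg)
    } else {
      global_loocv(sub, similarities, cv_cfg, solver_cfg)
    }
    data.frame(fraction = fr, n_associations = n1, auc = res$auc,
               aupr = res$aupr)
  })
  do.call(rbind, rows)
}
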