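# Similarity layer: ontology-DAG semantic similarity (two contribution
# schemes and their average), Gaussian interaction-profile kernels over the
# association matrix, and the fusion of both into the final miRNA (MM) and
# disease (DD) similarity matrices.

#' First-scheme semantic contributions of ontology terms to a disease
#'
#' The disease's own term contributes 1; every ancestor term t contributes
#' `phi * max(W(t'))` over its DAG-children t' restricted to the disease's
#' own sub-DAG, so contributions decay geometrically with distance from the
#' disease.
#'
#' @param dag A `disease_dag`.
#' @param disease_id Disease present in `dag$disease_roots`.
#' @return Named numeric vector over the terms of the disease's sub-DAG.
#' @export
semantic_contribution_w1 <- function(dag, disease_id) {
  if (!disease_id %in% names(dag$disease_roots)) {
    stop("unknown disease id: ", disease_id)
  }
  root <- dag$disease_roots[[disease_id]]
  terms <- dag_ancestors(dag, root)
  w <- stats::setNames(rep(NA_real_, length(terms)), terms)
  w[root] <- 1
  # children within T(d), per ancestor term
  kids <- lapply(terms, function(t) {
    intersect(dag$edges$child[dag$edges$parent == t], terms)
  })
  names(kids) <- terms
  # ancestors become computable once all their in-T(d) children are; a DAG
  # guarantees progress each sweep
  while (anyNA(w)) {
    progressed <- FALSE
    for (t in terms[is.na(w)]) {
      kw <- w[kids[[t]]]
      if (length(kw) && !anyNA(kw)) {
        w[t] <- dag$phi * max(kw)
        progressed <- TRUE
      }
    }
    if (!progressed) stop("sub-DAG of ", disease_id, " is not acyclic")
  }
  w
}

#' First-scheme semantic similarity between two diseases
#'
#' Shared-ancestor similarity: the summed contributions of the terms common
#' to both sub-DAGs, normalised by the two diseases' total semantic scores.
#' Symmetric and in `[0, 1]`; equals 1 for identical sub-DAGs.
#'
#' @inheritParams semantic_contribution_w1
#' @param d_i,d_j Disease ids.
#' @return A single similarity value.
#' @export
semantic_similarity_ds1 <- function(dag, d_i, d_j) {
  wi <- semantic_contribution_w1(dag, d_i)
  wj <- semantic_contribution_w1(dag, d_j)
  shared <- intersect(names(wi), names(wj))
  s_i <- sum(wi)
  s_j <- sum(wj)
  stopifnot(s_i + s_j > 0) # each disease contributes 1 for its own term
  sum(wi[shared] + wj[shared]) / (s_i + s_j)
}

#' Second-scheme (information-content) term contributions
#'
#' Each term scores `-log(n_t / N)` where `n_t` is the number of disease
#' sub-DAGs containing the term and `N` the number of diseases; the natural
#' logarithm is used. A term present in every sub-DAG carries no
#' information and scores 0.
#'
#' @param dag A `disease_dag`.
#' @param disease_universe Disease ids over which DAG membership is counted;
#'   defaults to all diseases in `dag`.
#' @return Named numeric vector over all terms appearing in at least one
#'   sub-DAG.
#' @export
semantic_contribution_w2 <- function(dag, disease_universe = NULL) {
  if (is.null(disease_universe)) disease_universe <- names(dag$disease_roots)
  if (length(disease_universe) == 0L) stop("disease universe is empty")
  tsets <- lapply(disease_universe, function(d) {
    dag_ancestors(dag, dag$disease_roots[[d]])
  })
  counts <- table(unlist(lapply(tsets, unique)))
  stats::setNames(-log(as.numeric(counts) / length(disease_universe)),
                  names(counts))
}

#' Second-scheme semantic similarity between two diseases
#'
#' As [semantic_similarity_ds1()] but with information-content term weights,
#' which are disease-independent. When both diseases' total scores are zero
#' (every term ubiquitous) the similarity is defined as 0.
#'
#' @inheritParams semantic_similarity_ds1
#' @param w2 Optional precomputed term weights from
#'   [semantic_contribution_w2()]; recomputed over all diseases in `dag`
#'   when missing.
#' @return A single similarity value.
#' @export
semantic_similarity_ds2 <- function(dag, d_i, d_j, w2 = NULL) {
  if (is.null(w2)) w2 <- semantic_contribution_w2(dag)
  ti <- dag_ancestors(dag, dag$disease_roots[[d_i]])
  tj <- dag_ancestors(dag, dag$disease_roots[[d_j]])
  shared <- intersect(ti, tj)
  denom <- sum(w2[ti]) + sum(w2[tj])
  if (denom == 0) return(0)
  sum(w2[shared] + w2[shared]) / denom
}

#' Pairwise disease semantic similarity matrices
#'
#' Evaluates one of the two semantic schemes over every disease pair.
#'
#' @param dag A `disease_dag`.
#' @param scheme `"ds1"` (geometric-decay contributions) or `"ds2"`
#'   (information-content contributions).
#' @param diseases Disease ids; defaults to all diseases in `dag`.
#' @return A labelled symmetric similarity matrix.
#' @export
disease_semantic_similarity <- function(dag, scheme = c("ds1", "ds2"),
                                        diseases = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(diseases)) diseases <- names(dag$disease_roots)
  n <- length(diseases)
  m <- matrix(0, n, n, dimnames = list(diseases, diseases))
  w2 <- if (scheme == "ds2") semantic_contribution_w2(dag, diseases)
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- if (scheme == "ds1") {
        semantic_similarity_ds1(dag, diseases[i], diseases[j])
      } else {
        semantic_similarity_ds2(dag, diseases[i], diseases[j], w2 = w2)
      }
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  # a disease whose every term is ubiquitous has DS2(d, d) = 0; force the
  # self-similarity convention before role validation
  diag(m) <- 1
  validate_labeled_matrix(m, role = toupper(scheme))
}

#' Average the two disease semantic similarity matrices
#'
#' @param ds1,ds2 Labelled similarity matrices over identical diseases.
#' @return The elementwise mean, a labelled matrix with role `DS`.
#' @export
integrate_disease_semantic <- function(ds1, ds2) {
  if (!identical(dimnames(ds1), dimnames(ds2))) {
    stop("DS1 and DS2 must share labels")
  }
  validate_labeled_matrix((ds1 + ds2) / 2, role = "DS")
}

#' Gaussian interaction-profile kernel bandwidths
#'
#' The miRNA bandwidth is the reciprocal of the mean squared norm of the
#' association-matrix rows; the disease bandwidth is the analogue over
#' columns. These normalise the kernel to the average profile energy.
#'
#' @param assoc Binary association matrix (miRNAs x diseases).
#' @return List with `lambda_m` and `lambda_d`, both strictly positive.
#' @export
gipk_bandwidths <- function(assoc) {
  msq_rows <- mean(rowSums(assoc^2))
  msq_cols <- mean(colSums(assoc^2))
  if (msq_rows == 0 || msq_cols == 0) {
    stop("association matrix is all zero; GIPK bandwidths are undefined")
  }
  list(lambda_m = 1 / msq_rows, lambda_d = 1 / msq_cols)
}

#' Gaussian interaction-profile kernel similarity
#'
#' RBF kernel over interaction profiles: rows of the association matrix for
#' miRNAs, columns for diseases. `K(i, j) = exp(-lambda * ||x_i - x_j||^2)`.
#'
#' @param assoc Binary association matrix (miRNAs x diseases).
#' @param axis `"mirna"` (row profiles) or `"disease"` (column profiles).
#' @param bw Bandwidths from [gipk_bandwidths()]; recomputed from `assoc`
#'   when missing.
#' @return Labelled similarity matrix with role `MGKS` or `DGKS`.
#' @export
gipk_similarity <- function(assoc, axis = c("mirna", "disease"), bw = NULL) {
  axis <- match.arg(axis)
  if (is.null(bw)) bw <- gipk_bandwidths(assoc)
  profiles <- if (axis == "mirna") assoc else t(assoc)
  lambda <- if (axis == "mirna") bw$lambda_m else bw$lambda_d
  if (!(lambda > 0 && is.finite(lambda))) stop("bandwidth must be positive")
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0 # numerical round-off on identical profiles
  k <- exp(-lambda * d2)
  k <- (k + t(k)) / 2
  diag(k) <- 1
  validate_labeled_matrix(k, role = if (axis == "mirna") "MGKS" else "DGKS")
}

#' Fuse a primary similarity with its interaction-profile kernel
#'
#' Elementwise: the primary (functional or semantic) similarity where it is
#' non-zero, the kernel similarity elsewhere. The diagonal is forced to 1.
#'
#' @param primary Labelled similarity matrix (`MF` or `DS` role).
#' @param gipk Kernel similarity matrix over the same labels.
#' @param role Output role, `"MM"` or `"DD"`.
#' @return Labelled fused similarity matrix.
#' @export
fuse_similarity <- function(primary, gipk, role = c("MM", "DD")) {
  role <- match.arg(role)
  if (!identical(dimnames(primary), dimnames(gipk))) {
    stop("primary and kernel similarity must share labels")
  }
  out <- ifelse(primary != 0, primary, gipk)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  validate_labeled_matrix(out, role = role)
}
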