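# Synthetic fixtures with the structure the completion model assumes:
# a planted low-rank association pattern whose similarity matrices are
# consistent with the same latent factors, plus tiny hand-checkable
# ontology DAGs.

#' Specification of a planted synthetic dataset
#'
#' @param nm,nd Numbers of miRNAs and diseases.
#' @param latent_rank Rank of the planted score matrix (<= min(nm, nd)).
#' @param density Fraction of entries set to 1 in the association matrix,
#'   in (0, 1); `density * nm * nd` must be at least 1.
#' @param noise_sd Standard deviation of the perturbation added to the
#'   similarity kernels.
#' @param seed RNG seed; the whole bundle is reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(nm = 60L, nd = 40L, latent_rank = 3L,
                           density = 0.3, noise_sd = 0.05, seed = 1L) {
  stopifnot(nm >= 2, nd >= 2, latent_rank >= 1,
            latent_rank <= min(nm, nd),
            density > 0, density < 1, density * nm * nd >= 1,
            noise_sd >= 0)
  structure(list(nm = as.integer(nm), nd = as.integer(nd),
                 latent_rank = as.integer(latent_rank), density = density,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a planted low-rank dataset
#'
#' Draws non-negative latent factors G (miRNAs) and F (diseases), forms the
#' ground-truth score matrix as `G %*% t(F)` with each row scaled to
#' `[0, 1]` (rank-preserving), and sets the globally largest
#' `floor(density * nm * nd)` entries to 1 to obtain the binary association
#' matrix. The similarity matrices are RBF kernels over the latent factor
#' rows — so they carry the same structure the completion is meant to
#' exploit — optionally perturbed by symmetric Gaussian noise, clipped to
#' `[0, 1]`, with a unit diagonal.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `assoc` (binary matrix), `MM`, `DD` (similarity
#'   matrices), `truth` (latent score matrix) and `spec`.
#' @export
generate_planted_dataset <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  mirnas <- sprintf("m%03d", seq_len(spec$nm))
  diseases <- sprintf("d%03d", seq_len(spec$nd))
  G <- matrix(stats::rgamma(spec$nm * spec$latent_rank, shape = 2, rate = 2),
              spec$nm, spec$latent_rank)
  F_ <- matrix(stats::rgamma(spec$nd * spec$latent_rank, shape = 2, rate = 2),
               spec$nd, spec$latent_rank)
  truth <- G %*% t(F_)
  truth <- truth / pmax(apply(truth, 1, max), .Machine$double.eps)
  dimnames(truth) <- list(mirnas, diseases)
  n_ones <- floor(spec$density * spec$nm * spec$nd)
  assoc <- matrix(0, spec$nm, spec$nd, dimnames = dimnames(truth))
  assoc[order(truth, decreasing = TRUE)[seq_len(n_ones)]] <- 1
  MM <- latent_kernel(G, mirnas, spec$noise_sd)
  DD <- latent_kernel(F_, diseases, spec$noise_sd)
  list(assoc = assoc, MM = MM, DD = DD, truth = truth, spec = spec)
}

# RBF kernel over latent-factor rows, bandwidth set to the reciprocal mean
# squared pairwise distance; noise is added symmetrically, then the matrix
# is clipped to [0, 1] with unit diagonal.
latent_kernel <- function(factors, labels, noise_sd) {
  sq <- rowSums(factors^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(factors)
  d2[d2 < 0] <- 0
  gamma <- 1 / max(mean(d2), .Machine$double.eps)
  k <- exp(-gamma * d2)
  if (noise_sd > 0) {
    n <- nrow(k)
    noise <- matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
    k <- k + (noise + t(noise)) / 2
  }
  k <- pmin(pmax((k + t(k)) / 2, 0), 1)
  diag(k) <- 1
  dimnames(k) <- list(labels, labels)
  validate_labeled_matrix(k, role = "MM")
}

#' Generate a layered toy ontology DAG
#'
#' Builds a balanced layered DAG: one shared root, `branching` children per
#' node, `levels` layers in total. Each disease is rooted at a distinct
#' leaf (sampled by seed when there are more leaves than diseases). With
#' `levels = 1` the diseases are isolated nodes.
#'
#' @param levels Number of layers (>= 1).
#' @param branching Children per internal node.
#' @param n_diseases Number of diseases to place on distinct leaves.
#' @param seed RNG seed for leaf assignment.
#' @param phi Contribution decay factor.
#' @return A `disease_dag`.
#' @export
generate_toy_dag <- function(levels = 2L, branching = 2L, n_diseases = 2L,
                             seed = 1L, phi = 0.5) {
  stopifnot(levels >= 1, branching >= 1, n_diseases >= 1)
  if (levels == 1L) {
    roots <- stats::setNames(sprintf("t1_%d", seq_len(n_diseases)),
                             sprintf("dis%d", seq_len(n_diseases)))
    return(suppressMessages(disease_dag(
      edges = data.frame(child = character(0), parent = character(0),
                         stringsAsFactors = FALSE),
      disease_roots = roots, phi = phi)))
  }
  edges <- list()
  prev <- "t1_1" # root layer
  for (lv in 2:levels) {
    n_here <- branching^(lv - 1)
    here <- sprintf("t%d_%d", lv, seq_len(n_here))
    parent <- prev[ceiling(seq_len(n_here) / branching)]
    edges[[lv - 1]] <- data.frame(child = here, parent = parent,
                                  stringsAsFactors = FALSE)
    prev <- here
  }
  leaves <- prev
  if (n_diseases > length(leaves)) {
    stop("not enough leaves (", length(leaves), ") for ", n_diseases,
         " diseases")
  }
  set.seed(seed)
  chosen <- if (n_diseases == length(leaves)) leaves else
    sample(leaves, n_diseases)
  roots <- stats::setNames(chosen, sprintf("dis%d", seq_len(n_diseases)))
  # unoccupied leaves are unreachable by construction; not worth reporting
  suppressMessages(
    disease_dag(edges = do.call(rbind, edges), disease_roots = roots,
                phi = phi))
}

#' Fixed tiny worked-example bundle
#'
#' A 3-miRNA x 2-disease system with hand-derived expected values used
#' across the documentation and tests: a two-disease DAG sharing one root
#' (first-scheme similarity 1/3 at phi = 0.5), a chain and a diamond DAG
#' for the contribution recursion, and a diagonal weighted-contraction
#' instance with its known closed-form result.
#'
#' @return List with the association matrix, the DAGs, and an `expected`
#'   list of hand-derived values.
#' @export
worked_example_fixture <- function() {
  pairs <- association_table(c("m1", "m2"), c("d1", "d2"))
  assoc <- build_association_matrix(pairs, mirna_ids = c("m1", "m2", "m3"),
                                    disease_ids = c("d1", "d2"))
  shared_root <- disease_dag(
    edges = data.frame(child = c("d1", "d2"), parent = c("g", "g"),
                       stringsAsFactors = FALSE),
    disease_roots = c(d1 = "d1", d2 = "d2"), phi = 0.5)
  chain <- disease_dag(
    edges = data.frame(child = c("d", "p"), parent = c("p", "g"),
                       stringsAsFactors = FALSE),
    disease_roots = c(d = "d"), phi = 0.5)
  diamond <- disease_dag(
    edges = data.frame(child = c("d", "d", "p1", "p2"),
                       parent = c("p1", "p2", "g", "g"),
                       stringsAsFactors = FALSE),
    disease_roots = c(d = "d"), phi = 0.5)
  list(
    assoc = assoc,
    shared_root_dag = shared_root,
    chain_dag = chain,
    diamond_dag = diamond,
    prox = list(Q = diag(c(3, 1)), W = c(0, 1), tau = 0.5),
    expected = list(
      n_ones = 2,
      ds1_d1_d2 = 1 / 3,
      chain_w1 = c(d = 1, p = 0.5, g = 0.25),
      diamond_w1_g = 0.25,
      prox_result = diag(c(3, 0.5))
    )
  )
}
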