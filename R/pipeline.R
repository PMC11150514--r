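# End-to-end pipeline glue: similarity computation and fusion, completion,
# ranked prediction output, evaluation runs, and fixture simulation. These
# functions back the command-line entry point in exec/.

#' Run the full prediction pipeline
#'
#' From a binary association matrix and optional primary similarities
#' (miRNA functional similarity matrix; disease semantic similarity either
#' precomputed or derived from an ontology DAG), computes the
#' interaction-profile kernels, fuses the similarities, assembles the
#' heterogeneous target matrix, completes it, and ranks candidate pairs.
#'
#' @param assoc Binary association matrix (miRNAs x diseases).
#' @param mf Optional miRNA functional similarity matrix.
#' @param ds Optional disease semantic similarity matrix; ignored when
#'   `dag` is given.
#' @param dag Optional `disease_dag` from which the two semantic schemes
#'   are computed and averaged.
#' @param solver_cfg A `solver_config`.
#' @param top_k Candidates ranked per disease.
#' @return List with `scores` (labelled matrix), `predictions` (ranked
#'   table), and the raw `completion` result.
#' @export
run_prediction <- function(assoc, mf = NULL, ds = NULL, dag = NULL,
                           solver_cfg = solver_config(), top_k = 50L) {
  if (!is.null(dag)) {
    ds1 <- disease_semantic_similarity(dag, "ds1",
                                       diseases = colnames(assoc))
    ds2 <- disease_semantic_similarity(dag, "ds2",
                                       diseases = colnames(assoc))
    ds <- integrate_disease_semantic(ds1, ds2)
  }
  ts <- build_training_system(assoc, test_idx = matrix(0L, 0, 2),
                              similarities = list(mf = mf, ds = ds))
  result <- complete_matrix(ts$system, solver_cfg)
  scores <- extract_association_scores(result)
  list(scores = scores,
       predictions = rank_predictions(scores, assoc, top_k),
       completion = result)
}

write_run_manifest <- function(path, seed, config, inputs = character(0)) {
  digests <- if (length(inputs)) {
    unname(Map(function(f) list(path = f, md5 = unname(tools::md5sum(f))),
               inputs))
  } else {
    list()
  }
  jsonlite::write_json(
    list(package = "mdacomp",
         version = as.character(utils::packageVersion("mdacomp")),
         seed = seed, config = unclass(config), inputs = digests,
         timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Command back-ends for the shell entry point
#'
#' `cmd_predict()` runs [run_prediction()] from files on disk and writes
#' the score matrix, the ranked prediction table and a run manifest;
#' `cmd_evaluate()` runs the configured cross-validation (optionally the
#' sparsity experiment) and writes a TSV summary; `cmd_simulate()` writes a
#' planted synthetic bundle in the package's standard file formats.
#'
#' @param pairs Path to the association pair table.
#' @param mf Optional path to the miRNA functional similarity matrix.
#' @param dag_edges,dag_roots Optional paths to the ontology edge list and
#'   disease-to-term mapping.
#' @param out_dir Output directory (created if needed).
#' @param solver_cfg A `solver_config`.
#' @param top_k Candidates per disease.
#' @param seed RNG seed recorded in the manifest.
#' @return Named character vector of output paths, invisibly.
#' @export
cmd_predict <- function(pairs, mf = NULL, dag_edges = NULL,
                        dag_roots = NULL, out_dir = ".",
                        solver_cfg = solver_config(), top_k = 50L,
                        seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_association_pairs(pairs)
  mf_mat <- if (!is.null(mf)) read_labeled_matrix(mf, role = "MF")
  dag <- if (!is.null(dag_edges)) read_dag_edges(dag_edges, dag_roots)
  # the functional-similarity labels define the miRNA universe when given,
  # so miRNAs without any known association still get scored
  assoc <- build_association_matrix(
    tab, mirna_ids = if (!is.null(mf_mat)) rownames(mf_mat))
  res <- run_prediction(assoc, mf = mf_mat, dag = dag,
                        solver_cfg = solver_cfg, top_k = top_k)
  paths <- c(scores = file.path(out_dir, "scores.tsv"),
             predictions = file.path(out_dir, "predictions.tsv"),
             manifest = file.path(out_dir, "run_manifest.json"))
  write_labeled_matrix(res$scores, paths[["scores"]])
  utils::write.table(res$predictions, paths[["predictions"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_run_manifest(paths[["manifest"]], seed, solver_cfg,
                     inputs = c(pairs, mf, dag_edges, dag_roots))
  invisible(paths)
}

#' @rdname cmd_predict
#' @param scheme Cross-validation scheme, `"kfold"` or `"global_loocv"`.
#' @param k Folds for k-fold CV.
#' @param fractions Optional fractions for the sparsity experiment; when
#'   given the experiment is run instead of a single CV.
#' @export
cmd_evaluate <- function(pairs, mf = NULL, dag_edges = NULL,
                         dag_roots = NULL, out_dir = ".",
                         scheme = "kfold", k = 5L, seed = 1L,
                         fractions = NULL,
                         solver_cfg = solver_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_association_pairs(pairs)
  sims <- list()
  if (!is.null(mf)) sims$mf <- read_labeled_matrix(mf, role = "MF")
  assoc <- build_association_matrix(
    tab, mirna_ids = if (!is.null(sims$mf)) rownames(sims$mf))
  if (!is.null(dag_edges)) {
    dag <- read_dag_edges(dag_edges, dag_roots)
    ds1 <- disease_semantic_similarity(dag, "ds1", diseases = colnames(assoc))
    ds2 <- disease_semantic_similarity(dag, "ds2", diseases = colnames(assoc))
    sims$ds <- integrate_disease_semantic(ds1, ds2)
  }
  cvc <- cv_config(scheme = scheme, k = k, seed = seed)
  paths <- c(summary = file.path(out_dir, "cv_summary.tsv"),
             manifest = file.path(out_dir, "run_manifest.json"))
  if (!is.null(fractions)) {
    out <- sparsity_experiment(assoc, sims, fractions, cvc, solver_cfg)
    utils::write.table(out, paths[["summary"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    res <- if (scheme == "kfold") kfold_cv(assoc, sims, cvc, solver_cfg)
           else global_loocv(assoc, sims, cvc, solver_cfg)
    out <- data.frame(scheme = res$scheme, auc = res$auc, aupr = res$aupr,
                      folds = length(res$per_fold), seed = res$seed)
    utils::write.table(out, paths[["summary"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_run_manifest(paths[["manifest"]], seed, solver_cfg,
                     inputs = c(pairs, mf, dag_edges, dag_roots))
  invisible(paths)
}

#' @rdname cmd_predict
#' @param nm,nd,latent_rank,density,noise_sd Planted-dataset parameters
#'   (see [synthetic_spec()]).
#' @export
cmd_simulate <- function(out_dir = ".", nm = 60L, nd = 40L,
                         latent_rank = 3L, density = 0.3,
                         noise_sd = 0.05, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- synthetic_spec(nm, nd, latent_rank, density, noise_sd, seed)
  bundle <- generate_planted_dataset(spec)
  pairs_idx <- which(bundle$assoc == 1, arr.ind = TRUE)
  pairs <- data.frame(mirna = rownames(bundle$assoc)[pairs_idx[, 1]],
                      disease = colnames(bundle$assoc)[pairs_idx[, 2]])
  pairs <- pairs[order(pairs$mirna, pairs$disease), ]
  paths <- c(pairs = file.path(out_dir, "pairs.tsv"),
             mm = file.path(out_dir, "mirna_similarity.tsv"),
             dd = file.path(out_dir, "disease_similarity.tsv"),
             truth = file.path(out_dir, "truth.tsv"),
             dag_edges = file.path(out_dir, "dag_edges.tsv"),
             dag_roots = file.path(out_dir, "dag_roots.tsv"),
             manifest = file.path(out_dir, "run_manifest.json"))
  utils::write.table(pairs, paths[["pairs"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_labeled_matrix(bundle$MM, paths[["mm"]])
  write_labeled_matrix(bundle$DD, paths[["dd"]])
  write_labeled_matrix(bundle$truth, paths[["truth"]])
  dag <- generate_toy_dag(levels = 3L, branching = 2L,
                          n_diseases = min(nd, 4L), seed = seed)
  utils::write.table(dag$edges, paths[["dag_edges"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(disease = names(dag$disease_roots),
               term = unname(dag$disease_roots)),
    paths[["dag_roots"]], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  write_run_manifest(paths[["manifest"]], seed, spec)
  invisible(paths)
}
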