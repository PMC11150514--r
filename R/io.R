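# On-disk formats: association pair tables, labelled matrices, DAG edge
# lists, ranked prediction tables. All files are plain text (TSV preferred,
# CSV accepted) so fixtures stay diffable.

SIMILARITY_ROLES <- c("MF", "DS1", "DS2", "DS", "MGKS", "DGKS", "MM", "DD")
MATRIX_ROLES <- c(SIMILARITY_ROLES, "H", "scores")

#' Read a miRNA-disease association pair table
#'
#' Reads a two-column text table of (miRNA id, disease id) pairs. Lines
#' starting with `#` are treated as comments. The delimiter is
#' auto-detected: tab if the first data line contains one, otherwise comma,
#' otherwise any whitespace. Duplicate pairs are dropped, keeping first-seen
#' order; the number of duplicates is reported via [message()].
#'
#' @param path Path to the pair file.
#' @return An `association_table`: a data frame with columns `mirna` and
#'   `disease`, one row per unique pair.
#' @export
read_association_pairs <- function(path) {
  if (!file.exists(path)) {
    stop("association pair file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    warning("empty association pair file: ", path)
    return(association_table(character(0), character(0)))
  }
  delim <- detect_delimiter(lines[idx[1]])
  mirna <- character(length(idx))
  disease <- character(length(idx))
  for (k in seq_along(idx)) {
    fields <- strsplit(lines[idx[k]], delim)[[1]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields)]
    if (length(fields) < 2L) {
      stop("malformed association pair at line ", idx[k], " of ", path,
           ": expected at least 2 columns")
    }
    mirna[k] <- fields[1]
    disease[k] <- fields[2]
  }
  dup <- duplicated(paste(mirna, disease, sep = "\r"))
  if (any(dup)) {
    message(sum(dup), " duplicate pair(s) dropped")
  }
  association_table(mirna[!dup], disease[!dup])
}

detect_delimiter <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else "\\s+"
}

association_table <- function(mirna, disease) {
  stopifnot(length(mirna) == length(disease))
  if (any(!nzchar(mirna)) || any(!nzchar(disease))) {
    stop("association ids must be non-empty strings")
  }
  structure(
    data.frame(mirna = as.character(mirna), disease = as.character(disease),
               stringsAsFactors = FALSE),
    class = c("association_table", "data.frame")
  )
}

#' Build the binary association matrix from a pair table
#'
#' Entry (i, j) is 1 when miRNA i and disease j appear as a pair, 0
#' otherwise. When label universes are not supplied they are taken from the
#' table and sorted lexicographically for a reproducible layout.
#'
#' @param table An `association_table` (see [read_association_pairs()]).
#' @param mirna_ids,disease_ids Optional label universes. Every pair id must
#'   be a member when supplied.
#' @return A numeric 0/1 matrix with miRNA row names and disease column
#'   names.
#' @export
build_association_matrix <- function(table, mirna_ids = NULL,
                                     disease_ids = NULL) {
  if (is.null(mirna_ids)) {
    mirna_ids <- sort(unique(table$mirna))
  } else if (anyDuplicated(mirna_ids)) {
    stop("mirna_ids must be unique")
  }
  if (is.null(disease_ids)) {
    disease_ids <- sort(unique(table$disease))
  } else if (anyDuplicated(disease_ids)) {
    stop("disease_ids must be unique")
  }
  bad_m <- setdiff(table$mirna, mirna_ids)
  bad_d <- setdiff(table$disease, disease_ids)
  if (length(bad_m) || length(bad_d)) {
    stop("pair ids outside the supplied label universe: ",
         paste(c(bad_m, bad_d), collapse = ", "))
  }
  A <- matrix(0, length(mirna_ids), length(disease_ids),
              dimnames = list(mirna_ids, disease_ids))
  if (nrow(table) > 0L) {
    A[cbind(match(table$mirna, mirna_ids),
            match(table$disease, disease_ids))] <- 1
  }
  A
}

#' Validate a labelled matrix for a given role
#'
#' Similarity roles (`MF`, `DS1`, `DS2`, `DS`, `MGKS`, `DGKS`, `MM`, `DD`)
#' must be square, symmetric within `tol`, have entries in `[0, 1]` and a
#' unit diagonal. Asymmetry within tolerance is repaired by averaging with
#' the transpose.
#'
#' @param m Numeric matrix with row and column names.
#' @param role One of the matrix roles; `"scores"` and `"H"` are
#'   unconstrained.
#' @param tol Symmetry tolerance.
#' @return The validated (possibly symmetrised) matrix with a `role`
#'   attribute.
#' @export
validate_labeled_matrix <- function(m, role = "scores", tol = 1e-6) {
  role <- match.arg(role, MATRIX_ROLES)
  if (!is.matrix(m) || !is.numeric(m)) stop("expected a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("labelled matrix requires row and column names")
  }
  if (role %in% SIMILARITY_ROLES) {
    if (nrow(m) != ncol(m)) {
      stop("role ", role, " requires a square matrix")
    }
    if (!identical(rownames(m), colnames(m))) {
      stop("role ", role, " requires identical row and column labels")
    }
    asym <- max(abs(m - t(m)))
    if (asym > tol) {
      stop("matrix for role ", role, " is asymmetric beyond tolerance (",
           format(asym), " > ", format(tol), ")")
    }
    m <- (m + t(m)) / 2
    if (min(m) < -tol || max(m) > 1 + tol) {
      stop("role ", role, " requires entries in [0, 1]; range is [",
           format(min(m)), ", ", format(max(m)), "]")
    }
    if (max(abs(diag(m) - 1)) > tol) {
      stop("role ", role, " requires a unit diagonal")
    }
  }
  attr(m, "role") <- role
  m
}

#' Read / write a labelled matrix
#'
#' Plain TSV with a header row of column labels and a first column of row
#' labels. `read_labeled_matrix(write_labeled_matrix(m, f), role)` restores
#' labels exactly and values to within 1e-12.
#'
#' @param path File path.
#' @param role Matrix role used for validation (see
#'   [validate_labeled_matrix()]).
#' @return The labelled matrix (read), or `path` invisibly (write).
#' @export
read_labeled_matrix <- function(path, role = "scores") {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("matrix body must be numeric: ", path)
  validate_labeled_matrix(m, role)
}

#' @rdname read_labeled_matrix
#' @param m Labelled numeric matrix.
#' @export
write_labeled_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("id", colnames(m)))
  invisible(path)
}

#' Read a disease ontology DAG from edge and root files
#'
#' The edge file holds (child, parent) term pairs; the roots file maps each
#' disease id to its own term in the ontology. Acyclicity is verified; terms
#' unreachable from every disease root are permitted but reported.
#'
#' @param path Edge-list file (child, parent).
#' @param roots_path Disease-to-term mapping file.
#' @param phi Semantic contribution decay factor in (0, 1); 0.5 follows the
#'   standard MeSH-DAG similarity convention.
#' @return A `disease_dag` object.
#' @export
read_dag_edges <- function(path, roots_path, phi = 0.5) {
  edges <- read_two_column(path, what = "DAG edge")
  roots <- read_two_column(roots_path, what = "disease root")
  disease_roots <- stats::setNames(roots[[2]], roots[[1]])
  disease_dag(edges = edges, disease_roots = disease_roots, phi = phi)
}

read_two_column <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  }
  delim <- detect_delimiter(lines[keep[1]])
  a <- character(length(keep))
  b <- character(length(keep))
  for (k in seq_along(keep)) {
    fields <- trimws(strsplit(lines[keep[k]], delim)[[1]])
    fields <- fields[nzchar(fields)]
    if (length(fields) < 2L) {
      stop("malformed ", what, " at line ", keep[k], " of ", path)
    }
    a[k] <- fields[1]
    b[k] <- fields[2]
  }
  data.frame(a = a, b = b, stringsAsFactors = FALSE)
}

#' Construct a disease ontology DAG
#'
#' @param edges Data frame of (child, parent) term pairs.
#' @param disease_roots Named character vector mapping disease id to the
#'   term that represents the disease itself.
#' @param phi Contribution decay factor in (0, 1).
#' @return A `disease_dag`: list with `terms`, `edges`, `disease_roots`,
#'   `phi`.
#' @export
disease_dag <- function(edges, disease_roots, phi = 0.5) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  if (!(is.numeric(phi) && length(phi) == 1L && phi > 0 && phi < 1)) {
    stop("phi must be a single number in (0, 1)")
  }
  names(edges)[1:2] <- c("child", "parent")
  terms <- unique(c(edges$child, edges$parent, unname(disease_roots)))
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       directed = TRUE)
    if (!igraph::is_dag(g)) {
      stop("ontology edge list contains a cycle: ",
           paste(find_one_cycle(edges), collapse = " -> "))
    }
  }
  missing_roots <- setdiff(unname(disease_roots), terms)
  if (length(missing_roots)) {
    stop("disease root term(s) absent from the ontology: ",
         paste(missing_roots, collapse = ", "))
  }
  obj <- structure(
    list(terms = terms, edges = edges[, c("child", "parent")],
         disease_roots = disease_roots, phi = phi),
    class = "disease_dag"
  )
  reach <- unique(unlist(lapply(names(disease_roots), function(d) {
    dag_ancestors(obj, disease_roots[[d]])
  })))
  orphan <- setdiff(terms, reach)
  if (length(orphan)) {
    message(length(orphan), " ontology term(s) unreachable from any disease")
  }
  obj
}

# Iterative DFS over child -> parent edges; returns one directed cycle for
# the error message.
find_one_cycle <- function(edges) {
  adj <- split(edges$parent, edges$child)
  state <- new.env(parent = emptyenv())
  path <- character(0)
  visit <- function(v) {
    assign(v, "open", envir = state)
    path <<- c(path, v)
    for (w in adj[[v]] %||% character(0)) {
      st <- if (exists(w, envir = state)) get(w, envir = state) else NA
      if (identical(st, "open")) {
        i <- match(w, path)
        return(c(path[i:length(path)], w))
      }
      if (is.na(st)) {
        res <- visit(w)
        if (!is.null(res)) return(res)
      }
    }
    assign(v, "done", envir = state)
    path <<- path[-length(path)]
    NULL
  }
  for (v in unique(edges$child)) {
    st <- if (exists(v, envir = state)) get(v, envir = state) else NA
    if (is.na(st)) {
      res <- visit(v)
      if (!is.null(res)) return(res)
    }
  }
  character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# T(d): the disease's own term plus all ancestors along child -> parent
# edges.
dag_ancestors <- function(dag, term) {
  seen <- term
  frontier <- term
  while (length(frontier)) {
    parents <- unique(dag$edges$parent[dag$edges$child %in% frontier])
    frontier <- setdiff(parents, seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' Rank and write candidate predictions
#'
#' For each disease, pairs that are not known associations are ranked by
#' predicted score (descending; ties broken by miRNA id ascending) and the
#' top `top_k` are written as a TSV with columns `disease_id`, `rank`,
#' `mirna_id`, `score`.
#'
#' @param scores Labelled score matrix (miRNAs x diseases).
#' @param known Binary association matrix with the same labels; known pairs
#'   are excluded from the ranking.
#' @param path Output file.
#' @param top_k Number of candidates per disease (>= 1).
#' @return The ranked table (invisibly for [write_predictions()]).
#' @export
rank_predictions <- function(scores, known, top_k = 50L) {
  if (top_k < 1L) stop("top_k must be >= 1")
  if (!identical(rownames(scores), rownames(known)) ||
      !identical(colnames(scores), colnames(known))) {
    stop("scores and known association matrix must share labels")
  }
  out <- lapply(colnames(scores), function(d) {
    cand <- rownames(scores)[known[, d] == 0]
    if (length(cand) == 0L) return(NULL)
    s <- scores[cand, d]
    ord <- order(-s, cand)
    take <- seq_len(min(top_k, length(cand)))
    data.frame(disease_id = d, rank = take, mirna_id = cand[ord][take],
               score = unname(s[ord][take]), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @rdname rank_predictions
#' @export
write_predictions <- function(scores, known, path, top_k = 50L) {
  tab <- rank_predictions(scores, known, top_k)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
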