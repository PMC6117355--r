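# Redundancy and specificity metrics for identified term sets: pairwise
# semantic similarity (graph-based Wang measure or annotation Jaccard), the
# averaged similarity score (ASS) with a resampled background, and ontology
# levels (longest is_a path to the root).

# Wang (2007) S-values of a term and all its ancestors: S(t) = 1 at the term
# itself; each step up an is_a edge multiplies by the decay weight and the
# maximum over downward paths is kept. Nodes are processed in decreasing
# level order so every contribution is final before it is propagated.
.wang_svalues <- function(term, dag, w = 0.8) {
  ta <- c(term, .dag_ancestors(term, dag))
  sv <- stats::setNames(numeric(length(ta)), ta)
  sv[term] <- 1
  for (node in ta[order(-dag$levels[ta])]) {
    val <- sv[[node]]
    for (p in dag$parents[[node]]) {
      if (w * val > sv[[p]]) sv[[p]] <- w * val
    }
  }
  sv
}

.wang_pair <- function(sa, sb) {
  shared <- intersect(names(sa), names(sb))
  (sum(sa[shared]) + sum(sb[shared])) / (sum(sa) + sum(sb))
}

#' Semantic similarity between two terms
#'
#' \code{method = "wang"}: the graph-based Wang (2007) measure on the is_a
#' DAG with decay weight 0.8 — the shared ancestors' S-values over the
#' summed S-values of both terms. \code{method = "jaccard"}: the
#' annotation-based Jaccard index \eqn{|S_a \cap S_b| / |S_a \cup S_b|}, a
#' DAG-free fallback.
#'
#' @param a,b term ids.
#' @param dag a \code{cea_dag} (required for \code{"wang"}).
#' @param db a \code{cea_db} (required for \code{"jaccard"}).
#' @param method \code{"wang"} or \code{"jaccard"}.
#' @return a similarity score in [0, 1]; exactly 1 when \code{a == b}.
#' @export
term_similarity <- function(a, b, dag = NULL, db = NULL,
                            method = c("wang", "jaccard")) {
  method <- match.arg(method)
  if (method == "wang") {
    stopifnot(inherits(dag, "cea_dag"))
    for (t in c(a, b)) if (!t %in% dag$nodes)
      stop("term not in ontology DAG: ", t)
    .wang_pair(.wang_svalues(a, dag), .wang_svalues(b, dag))
  } else {
    stopifnot(inherits(db, "cea_db"))
    for (t in c(a, b)) if (is.null(db$terms[[t]]))
      stop("term not in annotation database: ", t)
    ga <- db$terms[[a]]; gb <- db$terms[[b]]
    length(intersect(ga, gb)) / length(union(ga, gb))
  }
}

#' Pairwise similarity matrix of a term set
#'
#' @param terms character vector of term ids (duplicates dropped).
#' @param dag,db,method as in \code{\link{term_similarity}}.
#' @return an object of class \code{cea_simmat}: list with \code{term_ids}
#'   and the symmetric \code{values} matrix (unit diagonal).
#' @export
similarity_matrix <- function(terms, dag = NULL, db = NULL,
                              method = c("wang", "jaccard")) {
  method <- match.arg(method)
  terms <- unique(as.character(terms))
  n <- length(terms)
  if (n < 1L) stop("need at least one term")
  V <- diag(1, n)
  if (method == "wang") {
    stopifnot(inherits(dag, "cea_dag"))
    missing <- setdiff(terms, dag$nodes)
    if (length(missing))
      stop("term(s) not in ontology DAG: ", paste(missing, collapse = ", "))
    sv <- lapply(terms, .wang_svalues, dag = dag)
    if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      V[i, j] <- V[j, i] <- .wang_pair(sv[[i]], sv[[j]])
    }
  } else {
    stopifnot(inherits(db, "cea_db"))
    if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      V[i, j] <- V[j, i] <- term_similarity(terms[i], terms[j], db = db,
                                            method = "jaccard")
    }
  }
  dimnames(V) <- list(terms, terms)
  structure(list(term_ids = terms, values = V, method = method),
            class = "cea_simmat")
}

#' Averaged semantic similarity score (ASS) of a term set
#'
#' The mean of the \eqn{\binom{n}{2}} pairwise similarity scores — the
#' redundancy metric for an identified term set. Lower values indicate less
#' redundant (more complementary) terms.
#'
#' @param terms character vector of at least two term ids, all present in
#'   \code{sim}.
#' @param sim a \code{cea_simmat}.
#' @return the mean pairwise score in [0, 1].
#' @export
average_similarity <- function(terms, sim) {
  stopifnot(inherits(sim, "cea_simmat"))
  terms <- unique(as.character(terms))
  n <- length(terms)
  if (n < 2L) stop("ASS needs at least two distinct terms")
  idx <- match(terms, sim$term_ids)
  if (anyNA(idx))
    stop("term(s) not in similarity matrix: ",
         paste(terms[is.na(idx)], collapse = ", "))
  M <- sim$values[idx, idx]
  mean(M[upper.tri(M)])
}

#' Background distribution of the ASS under random term sets
#'
#' Repeatedly samples \code{n_terms} terms uniformly without replacement
#' from the full candidate pool (all terms of the database, not only
#' identified ones) and records the ASS of each sample. For the Wang method
#' the pool is restricted to terms present in the DAG; the number dropped is
#' recorded.
#'
#' @param n_terms size of each sampled term set (>= 2).
#' @param db a \code{cea_db} defining the candidate pool.
#' @param dag a \code{cea_dag} (Wang method).
#' @param method \code{"wang"} or \code{"jaccard"}.
#' @param reps number of resampling draws (default 100000).
#' @param seed integer seed; draws are deterministic given it.
#' @param sim optional precomputed \code{cea_simmat} over the pool (skips
#'   the pairwise computation).
#' @return an object of class \code{cea_background}: list with \code{draws}
#'   (length \code{reps}), \code{mean}, \code{n_terms}, \code{reps},
#'   \code{seed}, \code{method}, \code{n_dropped}.
#' @export
background_distribution <- function(n_terms, db, dag = NULL,
                                    method = c("wang", "jaccard"),
                                    reps = 100000, seed = 1, sim = NULL) {
  method <- match.arg(method)
  n_terms <- .assert_scalar_count(n_terms, "n_terms", min = 2L)
  reps <- .assert_scalar_count(reps, "reps", min = 1L)
  n_dropped <- 0L
  if (is.null(sim)) {
    stopifnot(inherits(db, "cea_db"))
    pool <- names(db$terms)
    if (method == "wang") {
      stopifnot(inherits(dag, "cea_dag"))
      in_dag <- pool %in% dag$nodes
      n_dropped <- sum(!in_dag)
      if (n_dropped)
        message(n_dropped, " term(s) absent from the DAG dropped from the background pool")
      pool <- pool[in_dag]
    }
    if (n_terms > length(pool))
      stop(sprintf("n_terms (%d) exceeds the candidate pool (%d)",
                   n_terms, length(pool)))
    sim <- similarity_matrix(pool, dag = dag, db = db, method = method)
  }
  np <- length(sim$term_ids)
  if (n_terms > np)
    stop(sprintf("n_terms (%d) exceeds the candidate pool (%d)", n_terms, np))
  V <- sim$values
  denom <- n_terms * (n_terms - 1)
  draws <- .with_seed(seed, vapply(seq_len(reps), function(i) {
    idx <- sample.int(np, n_terms)
    (sum(V[idx, idx]) - n_terms) / denom  # unit diagonal subtracted
  }, numeric(1)))
  structure(list(draws = draws, mean = mean(draws), n_terms = n_terms,
                 reps = reps, seed = seed, method = method,
                 n_dropped = n_dropped),
            class = "cea_background")
}

#' Empirical percentile of an ASS value against a background
#'
#' @param bg a \code{cea_background}.
#' @param ass a query ASS value.
#' @return the fraction of background draws less than or equal to
#'   \code{ass}.
#' @export
ass_percentile <- function(bg, ass) {
  stopifnot(inherits(bg, "cea_background"))
  mean(bg$draws <= ass)
}

#' Ontology level of a term
#'
#' The length (edge count) of the longest is_a path from the term up to the
#' root; the root itself has level 0. Higher levels indicate more specific
#' terms.
#'
#' @param term a term id present in \code{dag}.
#' @param dag a \code{cea_dag}.
#' @return a non-negative integer.
#' @export
term_level <- function(term, dag) {
  stopifnot(inherits(dag, "cea_dag"))
  term <- as.character(term)
  if (!term %in% dag$nodes) stop("term not in ontology DAG: ", term)
  unname(dag$levels[term])
}

#' Specificity summary of a term set
#'
#' Per-term annotated-gene counts and ontology levels, with five-number
#' summaries for boxplot-style comparisons of term specificity.
#'
#' @param terms character vector of term ids (must exist in \code{db};
#'   levels are NA for terms absent from \code{dag}).
#' @param db a \code{cea_db}.
#' @param dag optional \code{cea_dag}.
#' @return a data.frame with columns \code{term_id}, \code{n_genes},
#'   \code{level}, carrying attribute \code{fivenum}: a list with the
#'   five-number summaries of both columns.
#' @export
specificity_summary <- function(terms, db, dag = NULL) {
  stopifnot(inherits(db, "cea_db"))
  terms <- unique(as.character(terms))
  unknown <- setdiff(terms, names(db$terms))
  if (length(unknown))
    stop("unknown term id(s): ", paste(unknown, collapse = ", "))
  n_genes <- lengths(db$terms[terms])
  level <- rep(NA_integer_, length(terms))
  if (!is.null(dag)) {
    in_dag <- terms %in% dag$nodes
    level[in_dag] <- dag$levels[terms[in_dag]]
  }
  out <- data.frame(term_id = terms, n_genes = unname(n_genes),
                    level = level, stringsAsFactors = FALSE)
  out <- out[order(out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fivenum") <- list(
    n_genes = stats::fivenum(out$n_genes),
    level = if (all(is.na(out$level))) rep(NA_real_, 5L)
            else stats::fivenum(out$level[!is.na(out$level)]))
  out
}
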