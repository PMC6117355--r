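#' Bind an active gene list to a universe
#'
#' Splits the universe \eqn{U} into the active set \eqn{U_G} (the genes to be
#' functionally explained, e.g. top differentially expressed genes) and its
#' complement \eqn{U_O}.
#'
#' @param genes character vector of active gene ids.
#' @param db a \code{cea_db}; genes outside its universe are dropped with a
#'   warning.
#' @return an object of class \code{cea_active} with elements \code{active},
#'   \code{inactive} and \code{universe_size}.
#' @export
active_gene_set <- function(genes, db) {
  stopifnot(inherits(db, "cea_db"))
  genes <- unique(as.character(genes))
  outside <- setdiff(genes, db$universe)
  if (length(outside)) {
    warning("dropping ", length(outside), " active gene(s) outside the universe")
    genes <- setdiff(genes, outside)
  }
  if (length(genes) == 0L) stop("no active genes remain inside the universe")
  structure(list(active = sort(genes),
                 inactive = setdiff(db$universe, genes),
                 universe_size = length(db$universe)),
            class = "cea_active")
}

#' @export
print.cea_active <- function(x, ...) {
  cat(sprintf("cea_active: %d active / %d universe genes\n",
              length(x$active), x$universe_size))
  invisible(x)
}

#' Hypergeometric upper-tail probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(\eqn{N, K, n}): the
#' probability of observing an overlap of at least \code{k} between a term of
#' \code{K} genes and an active list of \code{n} genes drawn from a universe
#' of \code{N}. This is the one-sided (over-representation) Fisher exact
#' p-value of the 2x2 overlap table. Computed via the accurate tail routine
#' of \code{stats::phyper}; \code{log_p = TRUE} returns the natural-log
#' p-value, which stays finite where the p-value itself underflows.
#'
#' @param k observed overlap.
#' @param K number of annotated genes (size of the term or composite union).
#' @param n active list size.
#' @param N universe size.
#' @param log_p return log(p) instead of p.
#' @return the tail probability (or its log); exactly 1 when \code{k = 0}.
#' @export
hypergeom_tail_p <- function(k, K, n, N, log_p = FALSE) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(K > N) || any(n > N) ||
      any(k > pmin(K, n)))
    stop("invalid hypergeometric parameters: need 0 <= k <= min(K, n), K <= N, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = log_p)
}

#' Pseudo composite term: the union of a term combination's gene sets
#'
#' @param X character vector of term ids (duplicates are harmless).
#' @param db a \code{cea_db}.
#' @return character vector of member genes of \eqn{\cup_{i \in X} S_i}.
#' @export
composite_gene_set <- function(X, db) {
  stopifnot(inherits(db, "cea_db"))
  X <- unique(as.character(X))
  if (length(X) == 0L) stop("'X' must contain at least one term id")
  unknown <- setdiff(X, names(db$terms))
  if (length(unknown))
    stop("unknown term id(s): ", paste(unknown, collapse = ", "))
  unique(unlist(db$terms[X], use.names = FALSE))
}

#' Enrichment test of a term combination
#'
#' Builds the pseudo composite term (union of the combination's gene sets)
#' and applies the one-sided hypergeometric test to its overlap with the
#' active gene set.
#'
#' @param X character vector of term ids.
#' @param ag a \code{cea_active}.
#' @param db a \code{cea_db}.
#' @return a list with \code{terms}, the 2x2 counts \code{k} (overlap),
#'   \code{K} (union size), \code{n} (active size), \code{N} (universe size),
#'   \code{p_value}, and \code{log10_p} (log-space, robust to underflow).
#' @export
combination_pvalue <- function(X, ag, db) {
  stopifnot(inherits(ag, "cea_active"))
  comp <- composite_gene_set(X, db)
  k <- length(intersect(comp, ag$active))
  K <- length(comp)
  n <- length(ag$active)
  N <- ag$universe_size
  list(terms = sort(unique(as.character(X))), k = k, K = K, n = n, N = N,
       p_value = hypergeom_tail_p(k, K, n, N),
       log10_p = hypergeom_tail_p(k, K, n, N, log_p = TRUE) / log(10))
}

#' Coverage of the active gene set by a term combination
#'
#' \eqn{C(X) = |(\cup_{i \in X} S_i) \cap U_G| / |U_G|}, the proportion of
#' active genes annotated by at least one selected term.
#'
#' @inheritParams combination_pvalue
#' @return fraction in [0, 1]; an empty combination has coverage 0.
#' @export
coverage <- function(X, ag, db) {
  stopifnot(inherits(ag, "cea_active"))
  if (length(ag$active) == 0L) stop("active gene set is empty")
  X <- unique(as.character(X))
  if (length(X) == 0L) return(0)
  length(intersect(composite_gene_set(X, db), ag$active)) / length(ag$active)
}

#' Single-term enrichment scan
#'
#' The classical per-term baseline: every term is tested individually with
#' the one-sided hypergeometric test, ranked by p-value (ties share the
#' minimum rank) and Benjamini-Hochberg adjusted.
#'
#' @param ag a \code{cea_active}.
#' @param db a \code{cea_db}.
#' @return a data.frame sorted by ascending p with columns \code{term_id},
#'   \code{name}, \code{k}, \code{K}, \code{n}, \code{N}, \code{p_value},
#'   \code{p_adj}, \code{rank}.
#' @export
single_term_scan <- function(ag, db) {
  stopifnot(inherits(ag, "cea_active"), inherits(db, "cea_db"))
  ids <- names(db$terms)
  n <- length(ag$active)
  N <- ag$universe_size
  k <- vapply(db$terms, function(g) length(intersect(g, ag$active)), integer(1))
  K <- lengths(db$terms)
  p <- hypergeom_tail_p(k, K, n, N)
  out <- data.frame(term_id = ids, name = unname(db$term_names[ids]),
                    k = unname(k), K = unname(K), n = n, N = N,
                    p_value = unname(p),
                    p_adj = unname(stats::p.adjust(p, method = "BH")),
                    rank = unname(rank(p, ties.method = "min")),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
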