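#' Construct an annotation database
#'
#' An annotation database holds the candidate term family (named gene sets
#' \eqn{S_1,\dots,S_m}), the gene universe \eqn{U}, and the coverage-frequency
#' index \eqn{N_e = \{i : e \in S_i\}} used by the set-cover weights.
#'
#' @param terms named list; each element is a character vector of gene ids
#'   annotated by that term. Names are the term ids and must be unique.
#' @param term_names optional named character vector of free-text term
#'   descriptions, keyed by term id; defaults to the ids themselves.
#' @param universe optional character vector of gene ids defining \eqn{U}.
#'   Defaults to the union of all annotated genes. Every annotated gene must
#'   lie inside the declared universe.
#' @return an object of class \code{cea_db} with elements \code{terms},
#'   \code{term_names}, \code{universe} (sorted) and \code{coverage_index}.
#' @export
annotation_db <- function(terms, term_names = NULL, universe = NULL) {
  if (!is.list(terms) || length(terms) == 0L || is.null(names(terms)) ||
      any(!nzchar(names(terms))))
    stop("'terms' must be a non-empty named list of gene-id vectors")
  ids <- names(terms)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate term id(s): ", paste(dup, collapse = ", "))
  terms <- lapply(terms, function(g) unique(as.character(g)))
  empty <- ids[lengths(terms) == 0L]
  if (length(empty))
    stop("term(s) with no member genes: ", paste(empty, collapse = ", "))
  annotated <- unique(unlist(terms, use.names = FALSE))
  if (is.null(universe)) {
    universe <- sort(annotated)
  } else {
    universe <- sort(unique(as.character(universe)))
    outside <- setdiff(annotated, universe)
    if (length(outside))
      stop("annotated gene(s) outside the declared universe: ",
           paste(utils::head(outside, 5L), collapse = ", "),
           if (length(outside) > 5L) ", ...")
  }
  if (is.null(term_names)) {
    term_names <- stats::setNames(ids, ids)
  } else {
    term_names <- stats::setNames(as.character(term_names[ids]), ids)
    term_names[is.na(term_names)] <- ids[is.na(term_names)]
  }
  coverage_index <- split(rep(ids, lengths(terms)),
                          unlist(terms, use.names = FALSE))
  structure(list(terms = terms, term_names = term_names,
                 universe = universe, coverage_index = coverage_index),
            class = "cea_db")
}

#' @export
print.cea_db <- function(x, ...) {
  cat(sprintf("cea_db: %d terms, %d genes in universe, %d annotated genes\n",
              length(x$terms), length(x$universe), length(x$coverage_index)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Reads the tab-separated GMT dialect (one term per line: id, description,
#' then member genes). Duplicate genes within a line are collapsed; lines
#' whose member list is empty are dropped with a warning.
#'
#' @param path path to a GMT file.
#' @param universe optional character vector of gene ids overriding the
#'   default universe (the union of all annotated genes); see
#'   \code{\link{load_universe}}.
#' @return a \code{cea_db}; see \code{\link{annotation_db}}.
#' @export
load_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields",
                 line_no[bad[1L]]))
  ids <- vapply(fields, `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate term id(s) in GMT: ", paste(dup, collapse = ", "))
  descs <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) unique(f[-c(1L, 2L)][nzchar(f[-c(1L, 2L)])]))
  nonempty <- lengths(genes) > 0L
  if (any(!nonempty)) {
    warning("dropping ", sum(!nonempty), " term(s) with no member genes: ",
            paste(ids[!nonempty], collapse = ", "))
  }
  if (!any(nonempty)) stop("no terms with member genes in ", path)
  annotation_db(stats::setNames(genes[nonempty], ids[nonempty]),
                term_names = stats::setNames(descs[nonempty], ids[nonempty]),
                universe = universe)
}

#' Write an annotation database to a GMT file
#'
#' @param db a \code{cea_db}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "cea_db"))
  lines <- vapply(names(db$terms), function(id) {
    paste(c(id, db$term_names[[id]], db$terms[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene universe file
#'
#' One gene id per line; blank lines and text after '#' are ignored.
#'
#' @param path path to the universe file.
#' @return character vector of gene ids.
#' @export
load_universe <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  unique(lines[nzchar(lines)])
}

#' Restrict an annotation database to a gene universe
#'
#' Intersects every term with \code{universe}, drops terms that become empty,
#' and rebuilds the coverage index. The resulting universe is the
#' intersection of the current one with \code{universe} (so restricting to a
#' superset is the identity).
#'
#' @param db a \code{cea_db}.
#' @param universe non-empty character vector of gene ids.
#' @return a restricted \code{cea_db}.
#' @export
restrict_to_universe <- function(db, universe) {
  stopifnot(inherits(db, "cea_db"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("'universe' must be non-empty")
  new_terms <- lapply(db$terms, intersect, universe)
  keep <- lengths(new_terms) > 0L
  if (!any(keep))
    stop("no terms remain after restricting to the given universe")
  annotation_db(new_terms[keep], term_names = db$term_names[keep],
                universe = intersect(db$universe, universe))
}

#' Construct an ontology DAG from child-to-parent links
#'
#' @param parents named list mapping each node id to the character vector of
#'   its is_a parents (empty vector for the root). All referenced parents
#'   must themselves be nodes.
#' @param term_names optional named character vector of node descriptions.
#' @return an object of class \code{cea_dag} with elements \code{nodes},
#'   \code{parents}, \code{root}, \code{term_names} and \code{levels} (the
#'   longest-path-to-root level of every node; root has level 0).
#' @export
ontology_dag <- function(parents, term_names = NULL) {
  if (!is.list(parents) || is.null(names(parents)))
    stop("'parents' must be a named list")
  nodes <- names(parents)
  parents <- lapply(parents, as.character)
  unknown <- setdiff(unique(unlist(parents, use.names = FALSE)), nodes)
  if (length(unknown))
    stop("parent id(s) not present as nodes: ", paste(unknown, collapse = ", "))
  roots <- nodes[lengths(parents) == 0L]
  if (length(roots) != 1L)
    stop(sprintf("expected exactly one root, found %d: %s", length(roots),
                 paste(roots, collapse = ", ")))
  levels <- .dag_levels(nodes, parents)  # errors on cycles
  if (is.null(term_names)) {
    term_names <- stats::setNames(nodes, nodes)
  } else {
    term_names <- stats::setNames(as.character(term_names[nodes]), nodes)
    term_names[is.na(term_names)] <- nodes[is.na(term_names)]
  }
  structure(list(nodes = nodes, parents = parents, root = roots,
                 term_names = term_names, levels = levels),
            class = "cea_dag")
}

# Longest path (edge count) from every node up to the root, by memoized
# DFS over the child->parent links; detects cycles via an in-stack mark.
.dag_levels <- function(nodes, parents) {
  state <- stats::setNames(integer(length(nodes)), nodes)  # 0 new, 1 open, 2 done
  lev <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  visit <- function(n) {
    if (state[[n]] == 1L) stop("cycle detected in ontology at node ", n)
    if (state[[n]] == 2L) return(lev[[n]])
    state[[n]] <<- 1L
    ps <- parents[[n]]
    l <- if (length(ps) == 0L) 0L else 1L + max(vapply(ps, visit, integer(1)))
    lev[[n]] <<- l
    state[[n]] <<- 2L
    l
  }
  for (n in nodes) visit(n)
  lev
}

#' @export
print.cea_dag <- function(x, ...) {
  cat(sprintf("cea_dag: %d nodes, root %s, max level %d\n",
              length(x$nodes), x$root, max(x$levels)))
  invisible(x)
}

#' Read an ontology from an OBO file
#'
#' Parses OBO 1.2-style [Term] stanzas, keeping non-obsolete terms of the
#' requested namespace and their is_a edges. is_a links pointing outside the
#' kept node set are dropped. The root is the unique kept node with no
#' remaining parent; zero or multiple such nodes is an error.
#'
#' @param path path to the OBO file.
#' @param namespace namespace to keep (e.g. \code{"biological_process"}).
#'   Stanzas without a namespace line are kept only when \code{namespace} is
#'   \code{NULL}.
#' @return a \code{cea_dag}; see \code{\link{ontology_dag}}.
#' @export
load_obo <- function(path, namespace = "biological_process") {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0); pars <- list()
  for (s in seq_along(starts)) {
    block <- lines[(bounds[s] + 1L):(bounds[s + 1L] - 1L)]
    block <- block[!startsWith(block, "[")]
    field <- function(key) {
      v <- block[startsWith(block, paste0(key, ":"))]
      trimws(sub("!.*$", "", sub(paste0("^", key, ":"), "", v)))
    }
    id <- field("id")
    if (length(id) == 0L) next
    if (any(field("is_obsolete") == "true")) next
    ns <- field("namespace")
    if (!is.null(namespace)) {
      if (length(ns) == 0L || ns[1L] != namespace) next
    }
    nm <- field("name")
    ids <- c(ids, id[1L])
    nms <- c(nms, if (length(nm)) nm[1L] else id[1L])
    # "is_a: GO:xxxx ! label" -> target id only
    pars[[id[1L]]] <- vapply(strsplit(field("is_a"), "[ \t]+"),
                             `[[`, character(1), 1L)
  }
  if (length(ids) == 0L) stop("no terms of namespace '", namespace, "' in ", path)
  pars <- lapply(pars, intersect, ids)
  ontology_dag(pars[ids], term_names = stats::setNames(nms, ids))
}

# All (proper) ancestors of `node` via is_a edges, as a character vector.
.dag_ancestors <- function(node, dag) {
  seen <- character(0)
  frontier <- dag$parents[[node]]
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)),
                        seen)
  }
  unique(seen)
}
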