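# Active-list derivation from two-group expression data, and synthetic
# annotation databases / planted benchmark instances so every module is
# testable without external downloads.

#' Read a genes-by-samples expression matrix and its group labels
#'
#' The expression file is TSV with a header row of sample ids and gene ids
#' in the first column. The groups file is two tab-separated columns
#' (sample id, group label) without a header; exactly two distinct labels
#' are required. Rows with missing values are dropped with a message.
#'
#' @param expr_path path to the expression TSV.
#' @param groups_path path to the sample-to-group file.
#' @return a list of class \code{cea_expr} with \code{values} (numeric
#'   matrix, genes x samples) and \code{groups} (named character vector).
#' @export
read_expression <- function(expr_path, groups_path) {
  tab <- utils::read.delim(expr_path, header = TRUE, row.names = 1L,
                           check.names = FALSE)
  values <- as.matrix(tab)
  storage.mode(values) <- "double"
  grp <- utils::read.delim(groups_path, header = FALSE,
                           col.names = c("sample", "group"),
                           colClasses = "character")
  groups <- stats::setNames(grp$group, grp$sample)
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("sample(s) without a group label: ", paste(missing, collapse = ", "))
  groups <- groups[colnames(values)]
  bad <- rowSums(is.na(values)) > 0L
  if (any(bad)) {
    message("dropping ", sum(bad), " gene row(s) with missing values")
    values <- values[!bad, , drop = FALSE]
  }
  if (length(unique(groups)) != 2L)
    stop("expected exactly two group labels, found: ",
         paste(unique(groups), collapse = ", "))
  if (any(table(groups) < 2L))
    stop("each group needs at least two samples")
  structure(list(values = values, groups = groups), class = "cea_expr")
}

#' Derive an active gene set from a two-group expression matrix
#'
#' Per-gene two-sample t-test between the two groups, genes sorted by
#' ascending p-value (ties broken by gene id for a reproducible cut), the
#' top \code{top_n} taken as differentially expressed, then filtered to
#' genes with at least one annotation in \code{db}. Constant-expression
#' genes get p = 1 and are never selected while any varying gene remains.
#'
#' @param expr a \code{cea_expr} (see \code{\link{read_expression}}) or a
#'   list with \code{values} and \code{groups} of that shape.
#' @param db a \code{cea_db} supplying the annotation filter and universe.
#' @param top_n number of top genes to take (default 100); if fewer genes
#'   exist, all are used with a warning.
#' @param test \code{"welch"} (unequal variances, default) or
#'   \code{"student"} (pooled variance); both two-sided.
#' @return a \code{cea_active} bound to \code{db}.
#' @export
derive_active_genes <- function(expr, db, top_n = 100,
                                test = c("welch", "student")) {
  test <- match.arg(test)
  top_n <- .assert_scalar_count(top_n, "top_n", min = 1L)
  stopifnot(inherits(db, "cea_db"))
  values <- expr$values
  groups <- expr$groups
  labs <- unique(groups)
  if (length(labs) != 2L) stop("expected exactly two group labels")
  i1 <- which(groups == labs[1L]); i2 <- which(groups == labs[2L])
  if (length(i1) < 2L || length(i2) < 2L)
    stop("each group needs at least two samples")
  pvals <- apply(values, 1L, function(v) {
    tryCatch(stats::t.test(v[i1], v[i2],
                           var.equal = (test == "student"))$p.value,
             error = function(e) 1)  # zero-variance rows: p = 1
  })
  pvals[is.na(pvals)] <- 1
  ord <- order(pvals, rownames(values))
  if (top_n > length(ord)) {
    warning(sprintf("top_n (%d) exceeds the %d available genes; using all",
                    top_n, length(ord)))
    top_n <- length(ord)
  }
  top <- rownames(values)[ord[seq_len(top_n)]]
  annotated <- top[top %in% names(db$coverage_index)]
  if (length(annotated) == 0L)
    stop("no annotated genes among the top ", top_n)
  active_gene_set(annotated, db)
}

#' Generate a synthetic annotation database
#'
#' Universe of \code{n_genes} synthetic gene ids; term sizes drawn
#' log-uniformly from \code{size_range}; for \code{overlap > 0} that
#' fraction of each term's members is resampled from genes already used by
#' earlier terms (term-to-term redundancy), the rest drawn from the whole
#' universe. With \code{overlap = 0} terms are mutually disjoint (an error
#' if the universe cannot host them).
#'
#' @param n_genes universe size.
#' @param n_terms number of terms.
#' @param size_range two-element range of term sizes (default c(5, 200)).
#' @param overlap fraction in [0, 1) of members resampled from earlier
#'   terms.
#' @param seed integer seed; the database is a pure function of the
#'   arguments.
#' @return a \code{cea_db} whose universe is the full synthetic gene set
#'   (genes in no term included).
#' @export
make_synthetic_db <- function(n_genes = 2000, n_terms = 300,
                              size_range = c(5, 200), overlap = 0.1,
                              seed = 1) {
  n_genes <- .assert_scalar_count(n_genes, "n_genes", min = 2L)
  n_terms <- .assert_scalar_count(n_terms, "n_terms", min = 1L)
  stopifnot(length(size_range) == 2L, size_range[1L] >= 1,
            size_range[2L] >= size_range[1L], overlap >= 0, overlap < 1)
  if (size_range[2L] > n_genes)
    stop("size_range exceeds the universe size")
  universe <- sprintf("g%05d", seq_len(n_genes))
  .with_seed(seed, {
    sizes <- pmax(1L, as.integer(round(exp(stats::runif(
      n_terms, log(size_range[1L]), log(size_range[2L]))))))
    terms <- vector("list", n_terms)
    used <- character(0)
    fresh_pool <- universe  # genes in no term yet, for the disjoint case
    for (i in seq_len(n_terms)) {
      s <- sizes[i]
      if (overlap == 0) {
        if (s > length(fresh_pool))
          stop("infeasible: disjoint terms exceed the universe; ",
               "increase n_genes or reduce term sizes/count")
        g <- sample(fresh_pool, s)
        fresh_pool <- setdiff(fresh_pool, g)
      } else {
        n_ov <- min(round(overlap * s), length(used))
        ov <- if (n_ov > 0L) sample(used, n_ov) else character(0)
        g <- c(ov, sample(setdiff(universe, ov), s - n_ov))
      }
      terms[[i]] <- g
      used <- union(used, g)
    }
    names(terms) <- sprintf("T%04d", seq_len(n_terms))
    annotation_db(terms, universe = universe)
  })
}

#' Generate a planted benchmark instance
#'
#' Builds a synthetic database in which \code{k_planted} mutually disjoint
#' terms are carved from the universe up front (the true combination) and
#' the remaining terms are uniform random decoys. The active gene set is
#' the planted union plus \code{noise_active} genes sampled from outside it
#' — emulating active genes introduced by experimental noise that no small
#' coherent term combination explains. With \code{noise_active = 0} the
#' planted set is a zero-objective exact cover of the active set, hence the
#' unique minimum of \eqn{S(X) - t(X)} at its coverage level (certifiable
#' with the exact oracle on small instances).
#'
#' @param n_genes universe size (default 2000).
#' @param n_terms total number of terms including planted ones (default
#'   300).
#' @param k_planted number of disjoint planted terms (default 10).
#' @param noise_active number of active genes outside the planted union
#'   (default 5).
#' @param size_range log-uniform term-size range (default c(5, 200)).
#' @param seed integer seed.
#' @return a list of class \code{cea_planted}: \code{db}, \code{active}
#'   (a \code{cea_active}), \code{planted} (term ids), \code{noise_genes},
#'   and \code{provenance} (data.frame gene/source).
#' @export
make_planted_instance <- function(n_genes = 2000, n_terms = 300,
                                  k_planted = 10, noise_active = 5,
                                  size_range = c(5, 200), seed = 1) {
  k_planted <- .assert_scalar_count(k_planted, "k_planted", min = 1L)
  noise_active <- .assert_scalar_count(noise_active, "noise_active", min = 0L)
  n_genes <- .assert_scalar_count(n_genes, "n_genes", min = 10L)
  n_terms <- .assert_scalar_count(n_terms, "n_terms", min = k_planted)
  universe <- sprintf("g%05d", seq_len(n_genes))
  .with_seed(seed, {
    sizes <- pmax(1L, as.integer(round(exp(stats::runif(
      n_terms, log(size_range[1L]), log(size_range[2L]))))))
    planted_idx <- seq_len(k_planted)
    if (sum(sizes[planted_idx]) > n_genes / 2)
      stop("cannot plant ", k_planted, " disjoint terms of these sizes; ",
           "increase n_genes or shrink size_range")
    planted_genes <- sample(universe, sum(sizes[planted_idx]))
    terms <- vector("list", n_terms)
    off <- 0L
    for (i in planted_idx) {
      terms[[i]] <- planted_genes[(off + 1L):(off + sizes[i])]
      off <- off + sizes[i]
    }
    for (i in setdiff(seq_len(n_terms), planted_idx)) {
      terms[[i]] <- sample(universe, sizes[i])
    }
    names(terms) <- sprintf("T%04d", seq_len(n_terms))
    db <- annotation_db(terms, universe = universe)
    planted_union <- planted_genes[seq_len(off)]
    outside <- setdiff(universe, planted_union)
    if (noise_active > length(outside))
      stop("noise_active exceeds the genes outside the planted union")
    noise_genes <- if (noise_active > 0L) sample(outside, noise_active)
                   else character(0)
    active <- active_gene_set(c(planted_union, noise_genes), db)
    structure(list(db = db, active = active,
                   planted = names(terms)[planted_idx],
                   noise_genes = sort(noise_genes),
                   provenance = data.frame(
                     gene = c(planted_union, noise_genes),
                     source = rep(c("planted", "noise"),
                                  c(length(planted_union), noise_active)),
                     stringsAsFactors = FALSE)),
              class = "cea_planted")
  })
}

#' @export
print.cea_planted <- function(x, ...) {
  cat(sprintf(paste0("cea_planted: %d planted terms (%d genes) + %d noise ",
                     "active genes; %d terms, %d-gene universe\n"),
              length(x$planted),
              sum(x$provenance$source == "planted"),
              length(x$noise_genes), length(x$db$terms),
              length(x$db$universe)))
  invisible(x)
}
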