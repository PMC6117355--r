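# Randomized greedy search over the enrichment-set-cover model.
#
# Model: over the universe U = U_G (active) + U_O, each gene e gets weight
# w(e) = 1/|N_e| (N_e = terms annotating e); a term's weight w(S) is the sum
# of w(e) over its inactive genes. The greedy step picks, uniformly at
# random, one term whose cost-effectiveness w(S_i)/|(S_i cap U_G) \ C| is
# within (1+d) of the current minimum sigma, where C is the set of already
# covered active genes. Every prefix of every run is recorded as a candidate
# term combination.

#' Per-gene set-cover weight
#'
#' \eqn{w(e) = 1/|N_e|}: genes annotated by many terms are cheap to include,
#' rarely-annotated genes are expensive.
#'
#' @param e a gene id annotated by at least one term.
#' @param db a \code{cea_db}.
#' @return a positive real.
#' @export
element_weight <- function(e, db) {
  stopifnot(inherits(db, "cea_db"))
  ne <- db$coverage_index[[as.character(e)]]
  if (is.null(ne)) stop("gene not annotated by any term: ", e)
  1 / length(ne)
}

#' Term weight: summed element weights of its inactive genes
#'
#' \eqn{w(S) = \sum_{e \in S \cap U_O} w(e)}; a term fully inside the active
#' set has weight 0.
#'
#' @param term a term id.
#' @param ag a \code{cea_active}.
#' @param db a \code{cea_db}.
#' @return a non-negative real.
#' @export
set_weight <- function(term, ag, db) {
  stopifnot(inherits(ag, "cea_active"), inherits(db, "cea_db"))
  genes <- db$terms[[as.character(term)]]
  if (is.null(genes)) stop("unknown term id: ", term)
  out <- setdiff(genes, ag$active)
  if (length(out) == 0L) return(0)
  sum(vapply(out, element_weight, numeric(1), db = db))
}

#' Cost-effectiveness of a term given already-covered active genes
#'
#' \eqn{w(S)/|(S \cap U_G) \setminus C|}: the inactive-gene penalty paid per
#' newly covered active gene. Terms adding no uncovered active gene get
#' \code{Inf} (never selectable).
#'
#' @param term a term id.
#' @param covered character vector of already covered active genes (the set
#'   C of a greedy state).
#' @param ag a \code{cea_active}.
#' @param db a \code{cea_db}.
#' @return a non-negative real or \code{Inf}.
#' @export
cost_effectiveness <- function(term, covered, ag, db) {
  new_active <- setdiff(intersect(db$terms[[as.character(term)]], ag$active),
                        covered)
  if (length(new_active) == 0L) return(Inf)
  set_weight(term, ag, db) / length(new_active)
}

# Precompute integer-indexed views of (db, ag) shared by all greedy repeats.
.cea_context <- function(ag, db) {
  stopifnot(inherits(ag, "cea_active"), inherits(db, "cea_db"))
  uni <- db$universe
  nU <- length(uni)
  act_pos <- match(ag$active, uni)
  nG <- length(act_pos)
  is_active <- logical(nU); is_active[act_pos] <- TRUE
  act_rank <- integer(nU); act_rank[act_pos] <- seq_len(nG)
  term_ids <- names(db$terms)
  m <- length(term_ids)
  term_genes <- lapply(db$terms, match, uni)
  cov_freq <- tabulate(unlist(term_genes, use.names = FALSE), nbins = nU)
  w_elem <- ifelse(cov_freq > 0L, 1 / cov_freq, 0)
  w_term <- vapply(term_genes, function(g) sum(w_elem[g[!is_active[g]]]),
                   numeric(1), USE.NAMES = FALSE)
  term_active <- lapply(term_genes, function(g) act_rank[g[is_active[g]]])
  # reverse index: for each active gene, the terms that annotate it
  ta_flat <- unlist(term_active, use.names = FALSE)
  ta_term <- rep.int(seq_len(m), lengths(term_active))
  gene_terms <- split(ta_term, factor(ta_flat, levels = seq_len(nG)))
  base_new <- lengths(term_active)
  list(term_ids = term_ids, m = m, nU = nU, nG = nG,
       term_genes = term_genes, term_active = term_active,
       gene_terms = gene_terms, w_term = w_term, base_new = base_new,
       active = ag$active,
       uncoverable = ag$active[!(seq_len(nG) %in% unique(ta_flat))])
}

# One randomized greedy run over a precomputed context. Returns the prefix
# path as parallel vectors; p-values are attached later in one vectorized
# call. Consumes the current RNG stream.
.greedy_run_impl <- function(ctx, d, max_coverage = 1) {
  if (all(ctx$base_new == 0L)) stop("nothing to cover: no term overlaps the active gene set")
  new_count <- ctx$base_new
  covered_active <- logical(ctx$nG)
  covered_univ <- logical(ctx$nU)
  sel <- integer(0)
  S_vec <- integer(0); t_vec <- integer(0)
  t_cur <- 0L; S_cur <- 0L
  repeat {
    cand <- which(new_count > 0L)
    if (length(cand) == 0L) break
    ce <- ctx$w_term[cand] / new_count[cand]
    sigma <- min(ce)
    elig <- cand[ce <= (1 + d) * sigma]
    pick <- if (length(elig) == 1L) elig else elig[sample.int(length(elig), 1L)]
    newg <- ctx$term_active[[pick]]
    newg <- newg[!covered_active[newg]]
    covered_active[newg] <- TRUE
    dec <- unlist(ctx$gene_terms[newg], use.names = FALSE)
    new_count <- new_count - tabulate(dec, nbins = ctx$m)
    g <- ctx$term_genes[[pick]]
    add <- g[!covered_univ[g]]
    covered_univ[add] <- TRUE
    S_cur <- S_cur + length(add)
    t_cur <- t_cur + length(newg)
    sel <- c(sel, pick)
    S_vec <- c(S_vec, S_cur); t_vec <- c(t_vec, t_cur)
    if (t_cur / ctx$nG >= max_coverage) break
  }
  list(sel = sel, S = S_vec, t = t_vec)
}

# Turn a greedy path into a data.frame of prefix combinations.
.path_to_df <- function(path, ctx, repeat_idx) {
  ns <- length(path$sel)
  ids <- ctx$term_ids[path$sel]
  members <- vector("list", ns)
  keys <- character(ns)
  acc <- character(0)
  for (j in seq_len(ns)) {
    acc <- sort(c(acc, ids[j]))
    members[[j]] <- acc
    keys[j] <- paste(acc, collapse = ";")
  }
  logp <- hypergeom_tail_p(path$t, path$S, ctx$nG, ctx$nU, log_p = TRUE)
  data.frame(key = keys, size = seq_len(ns), union_size = path$S,
             active_overlap = path$t, coverage = path$t / ctx$nG,
             p_value = hypergeom_tail_p(path$t, path$S, ctx$nG, ctx$nU),
             log10_p = logp / log(10),
             repeat_idx = repeat_idx, step = seq_len(ns),
             stringsAsFactors = FALSE) -> df
  df$members <- members
  df
}

#' One randomized greedy run
#'
#' Runs the greedy search once: at each step the minimum cost-effectiveness
#' \eqn{\sigma} is computed over all terms still adding at least one
#' uncovered active gene, and one term is drawn uniformly from those with
#' cost-effectiveness at most \eqn{(1+d)\sigma} (with \code{d = 0} this is
#' the deterministic greedy). The run stops when no term adds an uncovered
#' active gene, or when \code{max_coverage} is reached. Every prefix of the
#' selection path is returned as a candidate combination.
#'
#' @param ag a \code{cea_active}.
#' @param db a \code{cea_db}.
#' @param d non-negative randomization width; 0 = deterministic greedy.
#' @param seed optional integer seed (NULL uses the current RNG stream).
#' @param max_coverage stop early once this coverage fraction is reached.
#' @return a data.frame of prefix combinations with columns \code{key},
#'   \code{size}, \code{union_size} (\eqn{S(X)}), \code{active_overlap}
#'   (\eqn{t(X)}), \code{coverage}, \code{p_value}, \code{log10_p},
#'   \code{repeat_idx}, \code{step} and list-column \code{members}.
#' @export
greedy_run <- function(ag, db, d = 1, seed = NULL, max_coverage = 1) {
  stopifnot(d >= 0)
  ctx <- .cea_context(ag, db)
  path <- .with_seed(seed, .greedy_run_impl(ctx, d, max_coverage))
  .path_to_df(path, ctx, repeat_idx = 1L)
}

#' Combination-based enrichment analysis
#'
#' Repeats the randomized greedy run \code{repeats} times (repeat \code{r}
#' is seeded with \code{seed + r}, so the pool is independent of execution
#' order), pools every prefix combination of every run, and deduplicates by
#' member set keeping first-seen provenance. The result is the landscape of
#' near-optimal term combinations across sizes, coverages and p-values.
#'
#' @param ag a \code{cea_active}.
#' @param db a \code{cea_db}.
#' @param d randomization width (default 1).
#' @param repeats number of greedy repeats (default 500).
#' @param seed master integer seed (default 1).
#' @param max_coverage optional early-stop coverage target in (0, 1].
#' @return an object of class \code{cea_solutions}: a data.frame as in
#'   \code{\link{greedy_run}}, one row per distinct combination, with
#'   attributes \code{n_active}, \code{universe_size}, \code{d},
#'   \code{repeats}, \code{seed} and \code{uncoverable} (active genes no
#'   term annotates; reported, not an error).
#' @export
run_cea <- function(ag, db, d = 1, repeats = 500, seed = 1,
                    max_coverage = 1) {
  stopifnot(d >= 0)
  repeats <- .assert_scalar_count(repeats, "repeats", min = 1L)
  seed <- .assert_scalar_count(seed, "seed", min = 0L)
  ctx <- .cea_context(ag, db)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  pool <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    path <- .with_seed(seed + r, .greedy_run_impl(ctx, d, max_coverage))
    df <- .path_to_df(path, ctx, repeat_idx = r)
    fresh <- !vapply(df$key, function(k) exists(k, envir = seen), logical(1))
    for (k in df$key[fresh]) assign(k, TRUE, envir = seen)
    pool[[r]] <- df[fresh, , drop = FALSE]
  }
  out <- do.call(rbind, pool)
  rownames(out) <- NULL
  structure(out, class = c("cea_solutions", "data.frame"),
            n_active = ctx$nG, universe_size = ctx$nU, d = d,
            repeats = repeats, seed = seed, uncoverable = ctx$uncoverable)
}

#' @export
print.cea_solutions <- function(x, ...) {
  cat(sprintf(paste0("cea_solutions: %d distinct combinations ",
                     "(sizes %d-%d), best p = %.3g at size %d\n"),
              nrow(x), min(x$size), max(x$size), min(x$p_value),
              x$size[which.min(x$log10_p)]))
  if (length(attr(x, "uncoverable")))
    cat(sprintf("  note: %d active gene(s) not annotated by any term\n",
                length(attr(x, "uncoverable"))))
  invisible(x)
}

#' Pareto front of a solution set
#'
#' Non-dominated combinations under (maximize \eqn{t(X)}, minimize
#' \eqn{S(X) - t(X)}). Among solutions with identical objective pairs the
#' lexicographically smallest member set is kept. Returned sorted by
#' ascending \eqn{t(X)}.
#'
#' @param sols a \code{cea_solutions} (or compatible data.frame).
#' @return a data.frame of the non-dominated rows.
#' @export
pareto_front <- function(sols) {
  if (nrow(sols) == 0L) stop("empty solution set")
  t_val <- sols$active_overlap
  obj <- sols$union_size - sols$active_overlap
  # per (t, obj) keep lexicographically smallest member key
  ord <- order(t_val, obj, sols$key)
  sols <- sols[ord, , drop = FALSE]
  t_val <- t_val[ord]; obj <- obj[ord]
  first <- !duplicated(data.frame(t_val, obj))
  sols <- sols[first, , drop = FALSE]
  t_val <- t_val[first]; obj <- obj[first]
  # dominance sweep from high t: keep strictly improving objective
  o <- order(-t_val, obj)
  keep <- logical(length(o))
  best <- Inf
  for (i in o) {
    if (obj[i] < best) { keep[i] <- TRUE; best <- obj[i] }
  }
  out <- sols[keep, , drop = FALSE]
  out <- out[order(out$active_overlap), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter pooled solutions by size, p-value and coverage
#'
#' @param sols a \code{cea_solutions}.
#' @param size keep only combinations of exactly this many terms.
#' @param p_max keep only combinations with p-value at most this.
#' @param min_coverage keep only combinations with coverage at least this.
#' @return the surviving rows, sorted by size then ascending p-value.
#' @export
filter_solutions <- function(sols, size = NULL, p_max = NULL,
                             min_coverage = NULL) {
  if (is.null(size) && is.null(p_max) && is.null(min_coverage))
    stop("give at least one of 'size', 'p_max', 'min_coverage'")
  keep <- rep(TRUE, nrow(sols))
  if (!is.null(size)) keep <- keep & sols$size == size
  if (!is.null(p_max)) keep <- keep & sols$p_value <= p_max
  if (!is.null(min_coverage)) keep <- keep & sols$coverage >= min_coverage
  out <- sols[keep, , drop = FALSE]
  out <- out[order(out$size, out$log10_p, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Landscape table of a solution set
#'
#' One row per combination with its size, \eqn{-\log_{10} p} (computed in
#' log space, finite even where p underflows) and coverage — the
#' size/enrichment/coverage landscape of the pooled near-optimal solutions.
#'
#' @param sols a non-empty \code{cea_solutions}.
#' @return a data.frame with columns \code{size}, \code{neg_log10_p},
#'   \code{coverage}, \code{terms} (member ids joined by ';').
#' @export
landscape_table <- function(sols) {
  if (nrow(sols) == 0L) stop("empty solution set")
  data.frame(size = sols$size, neg_log10_p = -sols$log10_p,
             coverage = sols$coverage, terms = sols$key,
             stringsAsFactors = FALSE)
}
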