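# Exhaustive reference solvers for small instances. These certify the
# randomized greedy search; they enumerate all term subsets and are only
# meant for instances where that is feasible.

# Enumerate statistics (t, S, size) of every non-empty subset with size <=
# max_size. Returns a list of parallel vectors plus a list of member-index
# vectors. Budget guards against accidental combinatorial blow-up.
.enumerate_subsets <- function(ag, db, max_size = NULL, budget = 2e6) {
  ctx <- .cea_context(ag, db)
  m <- ctx$m
  if (is.null(max_size)) max_size <- m
  max_size <- min(max_size, m)
  total <- sum(choose(m, seq_len(max_size)))
  if (total > budget)
    stop(sprintf("enumeration needs %.0f subsets, over the budget of %.0f",
                 total, budget))
  # term-by-gene incidence, restricted views for t and S
  TG <- matrix(0L, nrow = m, ncol = ctx$nU)
  for (i in seq_len(m)) TG[i, ctx$term_genes[[i]]] <- 1L
  act_cols <- match(ctx$active, db$universe)
  members <- list(); t_all <- integer(0); S_all <- integer(0)
  size_all <- integer(0)
  for (s in seq_len(max_size)) {
    combs <- utils::combn(m, s)
    nc <- ncol(combs)
    acc <- matrix(0L, nrow = nc, ncol = ctx$nU)
    for (j in seq_len(s)) acc <- acc + TG[combs[j, ], , drop = FALSE]
    covered <- acc > 0L
    S_all <- c(S_all, as.integer(rowSums(covered)))
    t_all <- c(t_all, as.integer(rowSums(covered[, act_cols, drop = FALSE])))
    size_all <- c(size_all, rep.int(s, nc))
    members <- c(members, lapply(seq_len(nc), function(j) combs[, j]))
  }
  list(ctx = ctx, t = t_all, S = S_all, size = size_all, members = members)
}

.subset_ids <- function(enum, i) sort(enum$ctx$term_ids[enum$members[[i]]])

# Tie-break: smaller size, then lexicographically smallest sorted member ids.
.pick_best <- function(enum, idx) {
  if (length(idx) == 1L) return(idx)
  sz <- enum$size[idx]
  idx <- idx[sz == min(sz)]
  if (length(idx) == 1L) return(idx)
  keys <- vapply(idx, function(i) paste(.subset_ids(enum, i), collapse = ";"),
                 character(1))
  idx[order(keys)[1L]]
}

.combo_record <- function(enum, i) {
  ctx <- enum$ctx
  ids <- .subset_ids(enum, i)
  logp <- hypergeom_tail_p(enum$t[i], enum$S[i], ctx$nG, ctx$nU, log_p = TRUE)
  list(members = ids, size = enum$size[i], union_size = enum$S[i],
       active_overlap = enum$t[i], coverage = enum$t[i] / ctx$nG,
       p_value = hypergeom_tail_p(enum$t[i], enum$S[i], ctx$nG, ctx$nU),
       log10_p = logp / log(10),
       objective = enum$S[i] - enum$t[i])
}

#' Exhaustive minimum-p term combination
#'
#' Evaluates the composite-term p-value of every non-empty subset of at most
#' \code{max_size} terms and returns the minimum — the enumeration that the
#' greedy search exists to avoid, feasible only on small instances.
#'
#' @param ag a \code{cea_active}.
#' @param db a \code{cea_db}.
#' @param max_size largest subset size to enumerate (default: all terms).
#' @param budget refuse if more than this many subsets would be evaluated.
#' @return a list describing the best combination: \code{members},
#'   \code{size}, \code{union_size}, \code{active_overlap}, \code{coverage},
#'   \code{p_value}, \code{log10_p}, \code{objective}. Ties are broken by
#'   smaller size, then lexicographic member ids.
#' @export
enumerate_best_pvalue <- function(ag, db, max_size = NULL, budget = 2e6) {
  enum <- .enumerate_subsets(ag, db, max_size, budget)
  logp <- hypergeom_tail_p(enum$t, enum$S, enum$ctx$nG, enum$ctx$nU,
                           log_p = TRUE)
  best <- .pick_best(enum, which(logp == min(logp)))
  .combo_record(enum, best)
}

#' Exact enrichment-set-cover solution
#'
#' Exhaustively minimizes \eqn{S(X) - t(X)} subject to the coverage
#' constraint \eqn{t(X) \ge \lceil \alpha |U_G| \rceil} (the constraint is
#' discretized upward since \eqn{t} is integral).
#'
#' @param ag a \code{cea_active}.
#' @param db a \code{cea_db}.
#' @param alpha coverage constraint parameter in [0, 1]; \code{alpha = 0}
#'   returns the empty combination with objective 0.
#' @param max_size,budget as in \code{\link{enumerate_best_pvalue}}.
#' @return a combination record as in \code{\link{enumerate_best_pvalue}};
#'   errors if the constraint is infeasible, reporting the attainable
#'   maximum coverage.
#' @export
solve_escp_exact <- function(ag, db, alpha, max_size = NULL, budget = 2e6) {
  stopifnot(alpha >= 0, alpha <= 1)
  ctx0 <- .cea_context(ag, db)
  req <- ceiling(alpha * ctx0$nG)
  if (req == 0L)
    return(list(members = character(0), size = 0L, union_size = 0L,
                active_overlap = 0L, coverage = 0, p_value = 1, log10_p = 0,
                objective = 0L))
  enum <- .enumerate_subsets(ag, db, max_size, budget)
  feas <- which(enum$t >= req)
  if (length(feas) == 0L)
    stop(sprintf("infeasible coverage constraint: need t >= %d, max attainable is %d",
                 req, max(enum$t)))
  obj <- enum$S[feas] - enum$t[feas]
  best <- .pick_best(enum, feas[obj == min(obj)])
  .combo_record(enum, best)
}

#' Exact Pareto front by enumeration
#'
#' Enumerates all subsets once, takes for every attainable overlap level
#' \eqn{t} the minimum of \eqn{S(X) - t(X)}, and removes dominated points —
#' the exact front of the two-objective model (maximize \eqn{t}, minimize
#' \eqn{S - t}). Its size is at most \eqn{|U_G| + 1} (one point per
#' attainable \eqn{t} value, plus the empty combination at \eqn{t = 0}).
#'
#' @param ag a \code{cea_active}.
#' @param db a \code{cea_db}.
#' @param budget refuse if more than this many subsets would be enumerated.
#' @return a list of combination records sorted by ascending
#'   \code{active_overlap}.
#' @export
exact_pareto <- function(ag, db, budget = 2e6) {
  enum <- .enumerate_subsets(ag, db, NULL, budget)
  # the empty combination is the (t = 0, objective = 0) anchor of the front
  pts <- list(list(members = character(0), size = 0L, union_size = 0L,
                   active_overlap = 0L, coverage = 0, p_value = 1,
                   log10_p = 0, objective = 0L))
  for (tv in setdiff(sort(unique(enum$t)), 0L)) {
    idx <- which(enum$t == tv)
    obj <- enum$S[idx] - enum$t[idx]
    pts[[length(pts) + 1L]] <- .combo_record(enum,
                                             .pick_best(enum, idx[obj == min(obj)]))
  }
  tv <- vapply(pts, `[[`, numeric(1), "active_overlap")
  ov <- vapply(pts, `[[`, numeric(1), "objective")
  keep <- logical(length(pts)); best <- Inf
  for (i in order(-tv, ov)) {
    if (ov[i] < best) { keep[i] <- TRUE; best <- ov[i] }
  }
  pts <- pts[keep]
  pts[order(vapply(pts, `[[`, numeric(1), "active_overlap"))]
}
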