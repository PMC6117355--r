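# Fixtures built in code: tiny databases, toy ontologies, random small
# instances, and an independent hypergeometric tail oracle.

# Exhaustive pmf summation from log-binomials; independent of phyper.
oracle_tail_p <- function(k, K, n, N) {
  j <- k:min(K, n)
  if (k == 0L) return(1)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

tiny_db <- function() {
  annotation_db(list(A = c("g1", "g2"), B = c("g2", "g3")))
}

# 5-term fixture with a strict cost-effectiveness order at every greedy
# step; the deterministic (d = 0) path is T2, T1, T4 with prefix
# (S, t) = (2,2), (5,4), (9,6). Universe: a1..a6 active, o1..o6 inactive.
hand_fixture <- function() {
  db <- annotation_db(list(
    T1 = c("a2", "a3", "a4", "o1"),
    T2 = c("a1", "a2"),
    T3 = c("a4", "a5", "o2", "o3"),
    T4 = c("a5", "a6", "o4", "o5"),
    T5 = c("a6", "o5", "o6")))
  list(db = db, ag = active_gene_set(paste0("a", 1:6), db))
}

# Small random instance in the oracle-checkable regime (m <= 15 terms,
# |U| <= 40, |U_G| <= 8); regenerated until some term overlaps the actives.
random_small_instance <- function(seed, m_range = 5:15) {
  set.seed(seed)
  m <- sample(m_range, 1L)
  nU <- sample(20:40, 1L)
  nG <- sample(4:8, 1L)
  uni <- sprintf("u%02d", seq_len(nU))
  repeat {
    terms <- lapply(seq_len(m), function(i) sample(uni, sample(2:8, 1L)))
    names(terms) <- sprintf("T%02d", seq_len(m))
    act <- sample(uni, nG)
    if (any(vapply(terms, function(g) length(intersect(g, act)) > 0L,
                   logical(1)))) break
  }
  db <- annotation_db(terms, universe = uni)
  list(db = db, ag = active_gene_set(act, db))
}

# Five-node tree: root r with children b, c; d under b, e under c.
toy_dag <- function() {
  ontology_dag(list(r = character(0), b = "r", c = "r", d = "b", e = "c"))
}

# Diamond with a short and a long route: t -> p1 -> r and t -> p2 -> q -> r.
diamond_dag <- function() {
  ontology_dag(list(r = character(0), p1 = "r", q = "r", p2 = "q",
                    t = c("p1", "p2")))
}

write_obo <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  path
}

# Minimal OBO text: chain c3 is_a c2 is_a c1, one obsolete term, one term
# from another namespace.
chain_obo <- function() {
  write_obo(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: rootish",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: mid",
    "namespace: biological_process", "is_a: GO:0000001 ! rootish", "",
    "[Term]", "id: GO:0000003", "name: leaf",
    "namespace: biological_process", "is_a: GO:0000002 ! mid", "",
    "[Term]", "id: GO:0000004", "name: gone",
    "namespace: biological_process", "is_a: GO:0000001", "is_obsolete: true", "",
    "[Term]", "id: GO:0000005", "name: elsewhere",
    "namespace: molecular_function", ""))
}

# 20 genes x 6 samples; genes s1..s5 shifted far beyond the noise, one
# constant row.
make_shift_expr <- function() {
  set.seed(101)
  genes <- c(paste0("s", 1:5), paste0("n", 1:14), "const")
  vals <- matrix(rnorm(20 * 6, sd = 0.1), nrow = 20,
                 dimnames = list(genes, paste0("smp", 1:6)))
  vals[1:5, 4:6] <- vals[1:5, 4:6] + 10
  vals["const", ] <- 3
  groups <- stats::setNames(rep(c("control", "disease"), each = 3),
                            colnames(vals))
  structure(list(values = vals, groups = groups), class = "cea_expr")
}

shift_db <- function() {
  annotation_db(list(ALL = c(paste0("s", 1:5), paste0("n", 1:14), "const")))
}

# cea_simmat with prescribed pairwise values (for ASS arithmetic tests).
manual_simmat <- function(ids, values) {
  dimnames(values) <- list(ids, ids)
  structure(list(term_ids = ids, values = values, method = "manual"),
            class = "cea_simmat")
}
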