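test_that("element and set weights follow the coverage-frequency formula", {
  fx <- hand_fixture()
  expect_identical(element_weight("o1", fx$db), 1)   # only T1
  expect_identical(element_weight("o5", fx$db), 0.5) # T4 and T5
  expect_error(element_weight("nope", fx$db), "not annotated")
  expect_identical(set_weight("T2", fx$ag, fx$db), 0)     # fully active
  expect_identical(set_weight("T4", fx$ag, fx$db), 1.5)   # o4 (1) + o5 (0.5)
  # active members contribute nothing: T1 weight is just o1
  expect_identical(set_weight("T1", fx$ag, fx$db), 1)
})

test_that("cost-effectiveness is penalty per new active gene, Inf when none", {
  fx <- hand_fixture()
  expect_equal(cost_effectiveness("T4", character(0), fx$ag, fx$db), 0.75)
  expect_identical(cost_effectiveness("T2", c("a1", "a2"), fx$ag, fx$db), Inf)
  expect_identical(cost_effectiveness("T2", character(0), fx$ag, fx$db), 0)
})

test_that("d = 0 on a tie-free fixture gives the hand-traced greedy path", {
  fx <- hand_fixture()
  for (s in 1:10) {
    g <- greedy_run(fx$ag, fx$db, d = 0, seed = s)
    expect_identical(vapply(seq_len(nrow(g)), function(i) tail(setdiff(
      g$members[[i]], if (i > 1) g$members[[i - 1]] else character(0)), 1),
      character(1)), c("T2", "T1", "T4"))
    expect_identical(g$union_size, c(2L, 5L, 9L))
    expect_identical(g$active_overlap, c(2L, 4L, 6L))
  }
})

test_that("a zero-weight candidate shrinks the eligible band to zero cost", {
  # T2 and T3 cost nothing; with any d the first pick must be one of them
  db <- annotation_db(list(T1 = c("a1", "a2", "o1"), T2 = c("a1", "a3"),
                           T3 = c("a2", "a4")))
  ag <- active_gene_set(paste0("a", 1:4), db)
  for (s in 1:10) {
    g <- greedy_run(ag, db, d = 100, seed = s)
    expect_true(g$members[[1]] %in% c("T2", "T3"))
  }
})

test_that("a disjoint exact tiling is covered at zero objective", {
  db <- annotation_db(list(A = c("a1", "a2"), B = c("a3", "a4"),
                           C = c("a5", "a6")))
  ag <- active_gene_set(paste0("a", 1:6), db)
  g <- greedy_run(ag, db, d = 1, seed = 1)
  expect_identical(nrow(g), 3L)
  expect_identical(g$coverage[3L], 1)
  expect_identical(g$union_size[3L] - g$active_overlap[3L], 0L)
})

test_that("coverage strictly increases along every greedy path", {
  for (s in 1:5) {
    inst <- random_small_instance(200 + s)
    g <- greedy_run(inst$ag, inst$db, d = 1, seed = s)
    expect_true(all(diff(c(0L, g$active_overlap)) >= 1L))
  }
})

test_that("run_cea is deterministic and pools deduplicated prefixes", {
  inst <- random_small_instance(17)
  a <- run_cea(inst$ag, inst$db, d = 1, repeats = 50, seed = 3)
  b <- run_cea(inst$ag, inst$db, d = 1, repeats = 50, seed = 3)
  expect_identical(a, b)
  expect_false(any(duplicated(a$key)))
  # repeats = 1 is a single greedy run under the substream seed + 1
  solo <- run_cea(inst$ag, inst$db, d = 0, repeats = 1, seed = 3)
  det <- greedy_run(inst$ag, inst$db, d = 0, seed = 4)
  expect_identical(solo$key, det$key)
})

test_that("cached solution statistics match a from-scratch recomputation", {
  inst <- random_small_instance(23)
  sols <- run_cea(inst$ag, inst$db, d = 1, repeats = 30, seed = 5)
  for (i in seq_len(nrow(sols))) {
    X <- sols$members[[i]]
    ref <- combination_pvalue(X, inst$ag, inst$db)
    expect_identical(sols$union_size[i], ref$K)
    expect_identical(sols$active_overlap[i], ref$k)
    expect_identical(sols$p_value[i], ref$p_value)
    expect_identical(sols$coverage[i], coverage(X, inst$ag, inst$db))
  }
})

test_that("run_cea errors when nothing overlaps the active set", {
  db <- annotation_db(list(A = c("o1", "o2")), universe = c("o1", "o2", "a1"))
  ag <- active_gene_set("a1", db)
  expect_error(run_cea(ag, db, repeats = 1), "nothing to cover")
})

test_that("pareto front keeps exactly the non-dominated solutions", {
  inst <- random_small_instance(31)
  sols <- run_cea(inst$ag, inst$db, d = 1, repeats = 40, seed = 2)
  front <- pareto_front(sols)
  t_all <- sols$active_overlap; o_all <- sols$union_size - sols$active_overlap
  # brute-force dominance check of every pooled solution
  dominated <- vapply(seq_len(nrow(sols)), function(i) {
    any(t_all >= t_all[i] & o_all <= o_all[i] &
        (t_all > t_all[i] | o_all < o_all[i]))
  }, logical(1))
  expect_setequal(unique(paste(front$active_overlap,
                               front$union_size - front$active_overlap)),
                  unique(paste(t_all[!dominated], o_all[!dominated])))
  expect_true(!is.unsorted(front$active_overlap))
  # single solution is its own front
  one <- sols[1, , drop = FALSE]
  expect_identical(pareto_front(one)$key, one$key)
})

test_that("filters and the landscape table behave per their contracts", {
  inst <- random_small_instance(37)
  sols <- run_cea(inst$ag, inst$db, d = 1, repeats = 20, seed = 4)
  expect_identical(nrow(filter_solutions(sols, p_max = 0)), 0L)
  expect_identical(nrow(filter_solutions(sols, min_coverage = 0)), nrow(sols))
  sz <- sols$size[1]
  f <- filter_solutions(sols, size = sz)
  expect_true(all(f$size == sz))
  expect_true(!is.unsorted(f$p_value))
  expect_error(filter_solutions(sols), "at least one")
  lt <- landscape_table(sols)
  expect_identical(nrow(lt), nrow(sols))
  expect_true(all(lt$coverage >= 0 & lt$coverage <= 1))
  expect_equal(lt$neg_log10_p[sols$p_value == max(sols$p_value)][1],
               -log10(max(sols$p_value)), tolerance = 1e-9)
})
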