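test_that("hypergeometric tail matches exact enumeration and closed forms", {
  expect_identical(hypergeom_tail_p(0, 5, 4, 20), 1)
  expect_equal(hypergeom_tail_p(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  # sum of C(3,j) C(7,4-j) / C(10,4) over j = 2,3 is 70/210 = 1/3
  expect_equal(hypergeom_tail_p(2, 3, 4, 10), 1 / 3, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:50) {
    N <- sample(5:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_tail_p(k, K, n, N), oracle_tail_p(k, K, n, N),
                 tolerance = 1e-10)
  }
  expect_error(hypergeom_tail_p(6, 5, 5, 10), "invalid")
  expect_error(hypergeom_tail_p(2, 11, 5, 10), "invalid")
})

test_that("log-space tail stays finite where the p-value underflows", {
  lp <- hypergeom_tail_p(500, 500, 505, 2000, log_p = TRUE)
  expect_true(is.finite(lp) && lp < -500)
  expect_identical(hypergeom_tail_p(500, 500, 505, 2000), 0)
})

test_that("composite gene set is the union, idempotent, and validated", {
  db <- tiny_db()
  expect_setequal(composite_gene_set("A", db), c("g1", "g2"))
  expect_setequal(composite_gene_set(c("A", "B"), db), c("g1", "g2", "g3"))
  expect_setequal(composite_gene_set(c("A", "A"), db),
                  composite_gene_set("A", db))
  expect_error(composite_gene_set("Z", db), "Z")
})

test_that("combination p-value reduces to closed forms on extreme overlaps", {
  # composite equals U_G exactly in a universe of size 2n: p = 1/C(2n, n)
  db <- annotation_db(list(A = paste0("a", 1:4)),
                      universe = c(paste0("a", 1:4), paste0("o", 1:4)))
  ag <- active_gene_set(paste0("a", 1:4), db)
  res <- combination_pvalue("A", ag, db)
  expect_equal(res$p_value, 1 / choose(8, 4), tolerance = 1e-12)
  # composite disjoint from U_G: k = 0, p = 1
  db2 <- annotation_db(list(A = c("o1", "o2"), B = c("a1", "a2")))
  ag2 <- active_gene_set(c("a1", "a2"), db2)
  res2 <- combination_pvalue("A", ag2, db2)
  expect_identical(res2$k, 0L)
  expect_identical(res2$p_value, 1)
  # all terms together cover the active set: k = n
  res3 <- combination_pvalue(c("A", "B"), ag2, db2)
  expect_identical(res3$k, length(ag2$active))
})

test_that("combination p-value is permutation-invariant and singleton-consistent", {
  fx <- hand_fixture()
  scan <- single_term_scan(fx$ag, fx$db)
  for (id in names(fx$db$terms)) {
    expect_identical(combination_pvalue(id, fx$ag, fx$db)$p_value,
                     scan$p_value[scan$term_id == id])
  }
  set.seed(9)
  for (i in 1:20) {
    X <- sample(names(fx$db$terms), sample(2:5, 1))
    a <- combination_pvalue(X, fx$ag, fx$db)
    b <- combination_pvalue(rev(X), fx$ag, fx$db)
    expect_identical(a, b)
    # adding a term contributing no new genes changes nothing
    sub <- combination_pvalue(c(X, X[1]), fx$ag, fx$db)
    expect_identical(a, sub)
  }
})

test_that("coverage follows its definition and is monotone under supersets", {
  fx <- hand_fixture()
  expect_identical(coverage(character(0), fx$ag, fx$db), 0)
  expect_equal(coverage(names(fx$db$terms), fx$ag, fx$db), 1)
  # |T1 cap U_G| = 3 of 6 active genes
  expect_equal(coverage("T1", fx$ag, fx$db), 0.5)
  set.seed(3)
  for (i in 1:20) {
    X <- sample(names(fx$db$terms), sample(1:4, 1))
    extra <- sample(setdiff(names(fx$db$terms), X), 1)
    expect_gte(coverage(c(X, extra), fx$ag, fx$db), coverage(X, fx$ag, fx$db))
  }
})

test_that("single-term scan ranks, ties and BH adjustment are correct", {
  # only B overlaps the active genes: rank 1
  db <- annotation_db(list(A = c("o1", "o2"), B = c("a1", "o3"),
                           C = c("o4", "o5")))
  ag <- active_gene_set("a1", db)
  scan <- single_term_scan(ag, db)
  expect_identical(scan$term_id[1L], "B")
  expect_identical(scan$rank[1L], 1L)
  # identical (k, K) implies identical p and shared minimum rank
  db2 <- annotation_db(list(A = c("a1", "o1"), B = c("a1", "o2"),
                            C = c("o3", "o4")))
  ag2 <- active_gene_set("a1", db2)
  scan2 <- single_term_scan(ag2, db2)
  expect_identical(scan2$p_value[1L], scan2$p_value[2L])
  expect_identical(scan2$rank[1L:2L], c(1L, 1L))
  # BH recomputed by the explicit step-up formula on the 5-term fixture
  fx <- hand_fixture()
  scan3 <- single_term_scan(fx$ag, fx$db)
  m <- nrow(scan3)
  p <- scan3$p_value  # already ascending
  expect_true(!is.unsorted(p))
  bh <- rev(cummin(rev(m * p / seq_len(m))))
  expect_equal(scan3$p_adj, pmin(bh, 1), tolerance = 1e-12)
  expect_true(!is.unsorted(scan3$p_adj))
})
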