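test_that("median calling is strict: ties at the median are negative", {
  m <- matrix(c(1, 2, 3, 4, 5,
                0, 0, 0, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("g", "z"), paste0("c", 1:5)))
  calls <- call_positive(expression_matrix(m), "population_median")
  expect_equal(unname(calls$calls["g", ]), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(calls$rule$threshold[["g"]]), 3)
  expect_false(any(calls$calls["z", ]))  # all-zero gene never positive
})

test_that("fixed-threshold calling is strict at the boundary", {
  m <- matrix(c(0, 0.1), 1, dimnames = list("g", c("c1", "c2")))
  calls <- call_positive(expression_matrix(m), "fixed_threshold", threshold = 0)
  expect_equal(unname(calls$calls["g", ]), c(FALSE, TRUE))
  expect_error(call_positive(expression_matrix(m), "fixed_threshold",
                             threshold = c(1, 2)), "length")
})

test_that("strict-median property: all-distinct values over 2m cells give m positives", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 2 * sample(3:10, 1)
    m <- matrix(sample(seq_len(1000), n), 1,
                dimnames = list("g", sprintf("c%02d", seq_len(n))))
    calls <- call_positive(expression_matrix(m), "population_median")
    expect_equal(sum(calls$calls), n / 2)
  }
})

test_that("HPAT phenotype map follows the published call-triple table", {
  # columns are cells with (HPAT21, HPAT2, HPAT15) patterns
  pat <- rbind(HPAT21 = c(1, 1, 1, 1, 0, 0),
               HPAT2  = c(0, 0, 1, 1, 0, 1),
               HPAT15 = c(0, 1, 0, 1, 0, 0))
  colnames(pat) <- sprintf("c%d", 1:6)
  calls <- call_positive(expression_matrix(pat), "fixed_threshold")
  ph <- classify_hpat(calls)
  expect_equal(as.character(ph),
               c("spHPAT21", "dpHPAT15", "HPAT2pos_double",
                 "HPAT2pos_triple", "null_phenotype", "other"))
})

test_that("classify_hpat is total: phenotype counts sum to the cell count", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 50
    pat <- matrix(rbinom(3 * n, 1, 0.5), nrow = 3,
                  dimnames = list(c("HPAT21", "HPAT2", "HPAT15"),
                                  sprintf("c%02d", seq_len(n))))
    calls <- call_positive(expression_matrix(pat), "fixed_threshold")
    ph <- classify_hpat(calls)
    expect_equal(sum(table(ph)), n)
    expect_false(anyNA(ph))
  }
  m <- matrix(1, 1, 1, dimnames = list("HPAT21", "c1"))
  expect_error(classify_hpat(call_positive(expression_matrix(m),
                                           "fixed_threshold")), "HPAT2")
})

test_that("prevalence counts positives with all/any semantics and flags empty groups", {
  m <- rbind(A = c(1, 1, 0, 1), B = c(1, 0, 0, 1), C = c(0, 0, 0, 1))
  colnames(m) <- sprintf("c%d", 1:4)
  calls <- call_positive(expression_matrix(m), "fixed_threshold")
  rows <- prevalence(calls, groups = list(all = colnames(m)),
                     genes = c("A", "B", "C"), semantics = "all")
  expect_equal(rows$n_positive, 1L)  # only c4 is positive for all three
  rows_any <- prevalence(calls, groups = list(all = colnames(m)),
                         genes = c("A", "B", "C"), semantics = "any")
  expect_equal(rows_any$n_positive, 3L)
  empty <- prevalence(calls, groups = list(none = character()), genes = "A")
  expect_equal(empty$n_total, 0L)
  expect_true(is.na(empty$percent))
})

test_that("prevalence percent matches the printed one-decimal convention", {
  # a group of 819 cells with 175 positive prints 21.4
  m <- matrix(c(rep(1, 175), rep(0, 819 - 175)), nrow = 1,
              dimnames = list("MLME", sprintf("c%03d", 1:819)))
  calls <- call_positive(expression_matrix(m), "fixed_threshold")
  row <- prevalence(calls, groups = list("TERT positive (n = 819)" = colnames(m)),
                    genes = "MLME")
  expect_identical(row$percent, 21.4)
})

test_that("two-tailed Fisher matches hand-derivable tables", {
  expect_equal(fisher_two_tailed(5, 5, 5, 5), 1.0)
  # [[3,0],[0,3]]: the two extreme tables each have pmf 1/20
  expect_equal(fisher_two_tailed(3, 0, 0, 3), 0.1, tolerance = 1e-12)
  expect_error(fisher_two_tailed(-1, 1, 1, 1), "non-negative")
})

test_that("Fisher agrees with the exhaustive-enumeration oracle on small tables", {
  set.seed(42)
  # all tables with N <= 12, plus random tables up to N = 30
  small <- expand.grid(a = 0:6, b = 0:6, c = 0:6, d = 0:6)
  small <- small[rowSums(small) > 0 & rowSums(small) <= 12, ]
  idx <- sample(nrow(small), 400)
  for (i in idx) {
    t <- small[i, ]
    expect_equal(fisher_two_tailed(t$a, t$b, t$c, t$d),
                 oracle_fisher_two_tailed(t$a, t$b, t$c, t$d),
                 tolerance = 1e-7)
  }
  for (rep in 1:100) {
    t <- as.integer(stats::rmultinom(1, sample(13:30, 1), rep(0.25, 4)))
    expect_equal(fisher_two_tailed(t[1], t[2], t[3], t[4]),
                 oracle_fisher_two_tailed(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-7)
  }
})

test_that("Kruskal-Wallis reproduces the rank formula and its symmetries", {
  g1 <- list(c(1, 2, 3), c(1, 2, 3))
  res <- kruskal_wallis(g1)
  expect_equal(res$statistic, 0, tolerance = 1e-9)
  expect_equal(res$p_value, 1, tolerance = 1e-9)

  g2 <- list(c(1, 2, 3), c(4, 5, 6))
  res2 <- kruskal_wallis(g2)
  expect_equal(res2$statistic, oracle_kruskal_H(g2), tolerance = 1e-12)
  expect_equal(res2$p_value,
               stats::pchisq(res2$statistic, df = 1, lower.tail = FALSE))

  res2r <- kruskal_wallis(rev(g2))  # permuting groups changes nothing
  expect_equal(res2r$statistic, res2$statistic)
  expect_equal(res2r$p_value, res2$p_value)

  set.seed(1)
  g3 <- list(rnorm(7), rnorm(12, 1), c(rnorm(5), 0.5, 0.5))  # ties included
  expect_equal(kruskal_wallis(g3)$statistic, oracle_kruskal_H(g3),
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})
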