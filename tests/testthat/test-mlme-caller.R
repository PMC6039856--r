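make_call_matrix <- function(pos_genes, all_genes, cell = "c1") {
  m <- matrix(0, length(all_genes), 1,
              dimnames = list(all_genes, cell))
  m[pos_genes, 1] <- 1
  call_positive(expression_matrix(m), "fixed_threshold")
}

test_that("MLME rule needs >= 4 markers per lineage plus every master regulator", {
  panel <- marker_panel(
    lineage_markers = list(EPI = sprintf("E%d", 1:6),
                           PE = sprintf("P%d", 1:6),
                           TE = sprintf("T%d", 1:6)),
    min_markers_per_lineage = 4L)
  genes <- panel_genes(panel)

  ok <- make_call_matrix(c(sprintf("E%d", 1:4), sprintf("P%d", 1:4),
                           sprintf("T%d", 1:4), "NANOG", "POU5F1", "SOX2"),
                         genes)
  expect_true(call_mlme(ok, panel)[["c1"]])

  no_sox2 <- make_call_matrix(c(sprintf("E%d", 1:4), sprintf("P%d", 1:4),
                                sprintf("T%d", 1:4), "NANOG", "POU5F1"),
                              genes)
  expect_false(call_mlme(no_sox2, panel)[["c1"]])

  three_pe <- make_call_matrix(c(sprintf("E%d", 1:4), sprintf("P%d", 1:3),
                                 sprintf("T%d", 1:4), "NANOG", "POU5F1", "SOX2"),
                               genes)
  expect_false(call_mlme(three_pe, panel)[["c1"]])

  expect_error(call_mlme(make_call_matrix("E1", c("E1", "E2")), panel),
               "missing")
})

test_that("masters count toward a lineage tally only when listed in its panel", {
  # EPI panel contains the masters themselves plus one extra marker
  panel <- marker_panel(
    lineage_markers = list(EPI = c("NANOG", "POU5F1", "SOX2", "L1"),
                           PE = sprintf("P%d", 1:4),
                           TE = sprintf("T%d", 1:4)),
    min_markers_per_lineage = 4L)
  genes <- panel_genes(panel)
  calls <- make_call_matrix(c("NANOG", "POU5F1", "SOX2", "L1",
                              sprintf("P%d", 1:4), sprintf("T%d", 1:4)),
                            genes)
  expect_true(call_mlme(calls, panel)[["c1"]])

  # without L1 the EPI tally is only the 3 masters -> below threshold
  calls2 <- make_call_matrix(c("NANOG", "POU5F1", "SOX2",
                               sprintf("P%d", 1:4), sprintf("T%d", 1:4)),
                             genes)
  expect_false(call_mlme(calls2, panel)[["c1"]])
})

test_that("contingency counts enforce the hypergeometric support", {
  expect_s3_class(contingency_counts(10, 4, 5, 2), "contingency_counts")
  expect_error(contingency_counts(10, 11, 5, 2), "K <= N")
  expect_error(contingency_counts(10, 4, 5, 5), "feasible")
  expect_error(contingency_counts(10, 9, 9, 7), "feasible")  # k < n + K - N
  expect_error(contingency_counts(10, 4, 5, -1), "non-negative")
})

test_that("hypergeometric enrichment matches hand-derived values", {
  # 5 labelled of 5 drawn from 10/20: C(10,5)/C(20,5)
  p <- hypergeom_enrichment(contingency_counts(20, 10, 5, 5), "upper")
  expect_equal(p, choose(10, 5) / choose(20, 5), tolerance = 1e-12)
  # whole population drawn: certain event
  expect_equal(hypergeom_enrichment(contingency_counts(20, 10, 20, 10), "upper"), 1)
  expect_equal(hypergeom_enrichment(contingency_counts(20, 10, 20, 10), "lower"), 1)
})

test_that("tail and point probabilities match the exact-rational oracle (N <= 40)", {
  set.seed(7)
  grid <- expand.grid(N = c(2:15, 20, 25, 30, 35, 40))
  for (N in grid$N) {
    Ks <- unique(round(seq(0, N, length.out = 6)))
    for (K in Ks) for (n in unique(c(1, round(N / 3), round(N / 2), N))) {
      if (n < 1) next
      ks <- max(0, n + K - N):min(K, n)
      for (k in ks) {
        cc <- contingency_counts(N, K, n, k)
        expect_equal(hypergeom_enrichment(cc, "upper"),
                     min(1, oracle_hyper_upper(N, K, n, k)), tolerance = 1e-10)
        expect_equal(hypergeom_enrichment(cc, "lower"),
                     min(1, oracle_hyper_lower(N, K, n, k)), tolerance = 1e-10)
        expect_equal(hypergeom_enrichment(cc, "point"),
                     oracle_hyper_pmf(N, K, n, k), tolerance = 1e-10)
      }
    }
  }
})

test_that("upper-tail p is strictly decreasing in k at fixed margins", {
  N <- 100; K <- 30; n <- 40
  ks <- max(0, n + K - N):min(K, n)
  ps <- vapply(ks, function(k)
    hypergeom_enrichment(contingency_counts(N, K, n, k), "upper"), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("subset and complement carry identical enrichment evidence", {
  # the published tables print the same p for the TERT+ and TERT- rows
  N <- 1529; K <- 267; n <- 819; k <- 175
  comp <- contingency_counts(N, K, N - n, K - k)
  expect_equal(hypergeom_enrichment(contingency_counts(N, K, n, k), "upper"),
               hypergeom_enrichment(comp, "lower"), tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(contingency_counts(N, K, n, k), "point"),
               hypergeom_enrichment(comp, "point"), tolerance = 1e-12)
})

test_that("prevalence report rows carry counts, percents and enrichment p", {
  cells <- sprintf("c%04d", 1:100)
  flags <- stats::setNames(rep(c(TRUE, FALSE), c(30, 70)), cells)
  strata <- list(top = cells[1:20],                  # all MLME
                 background = cells)
  rep <- build_prevalence_report(flags, strata, tail = "upper")
  expect_equal(rep$n_positive[rep$label == "top"], 20L)
  expect_equal(rep$percent[rep$label == "top"], 100)
  expect_equal(rep$p_value[rep$label == "background"], 1)  # stratum = background
  empty <- build_prevalence_report(flags, list(none = character()))
  expect_equal(empty$n_total, 0L)
  expect_true(is.na(empty$percent))
})

test_that("rank bands resolve printed band sizes and ceiling fractions", {
  scores <- data.frame(cell_id = sprintf("c%03d", 1:819),
                       score = seq(1, 0, length.out = 819))
  bands <- rank_bands(scores, n = c(25L, 41L, 82L))
  expect_equal(lengths(bands[c("top_25", "top_41", "top_82")]),
               c(top_25 = 25L, top_41 = 41L, top_82 = 82L))
  expect_equal(length(bands$bottom_737), 737L)
  frac <- rank_bands(scores, fractions = 0.03)
  expect_equal(length(frac$top_25), 25L)  # ceiling(819 * 0.03) = 25
})

test_that("planted enrichment is detected and the null is honest (reduced scale)", {
  set.seed(31)
  hits <- 0L
  for (rep in 1:20) {
    ds <- simulate_dataset(enrichment_config(seed = 1000 + rep, rr = 2))
    tr <- ds$truth
    cc <- contingency_counts(nrow(tr), sum(tr$is_mlme),
                             sum(tr$is_tert_positive),
                             sum(tr$is_mlme & tr$is_tert_positive))
    if (hypergeom_enrichment(cc, "upper") < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
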