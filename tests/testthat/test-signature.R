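test_that("ratio-signature weights follow the log2 mean-ratio formula", {
  m <- rbind(eq = c(2, 2, 2, 2),
             up = c(4, 4, 1, 1),
             dn = c(1, 1, 4, 4))
  colnames(m) <- c("n1", "n2", "d1", "d2")
  em <- expression_matrix(m)
  sig <- derive_ratio_signature(em, c("n1", "n2"), c("d1", "d2"),
                                pseudocount = 1)
  expect_equal(sig$weights[sig$genes == "eq"], 0)          # equal means
  expect_equal(sig$weights[sig$genes == "up"], log2(5 / 2))  # 1.3219...
  swapped <- derive_ratio_signature(em, c("d1", "d2"), c("n1", "n2"),
                                    pseudocount = 1)
  expect_equal(swapped$weights, -sig$weights)  # antisymmetry
  expect_error(derive_ratio_signature(em, character(), "d1"), "non-empty")
  expect_error(derive_ratio_signature(em, "n1", "n1"), "disjoint")
  expect_error(derive_ratio_signature(em, "n1", "d1", pseudocount = 0),
               "pseudocount")
})

test_that("correlation scores hit the exact endpoints and the Pearson formula", {
  sig <- structure(list(genes = paste0("g", 1:4),
                        weights = c(-1, 0, 1, 2),
                        numerator_label = "a", denominator_label = "b",
                        pseudocount = 1),
                   class = "signature_profile")
  # profile whose log2(x + 1) equals the weights exactly -> r = 1
  prof <- stats::setNames(2^sig$weights - 1, sig$genes)
  expect_equal(as.numeric(correlation_score(prof, sig)), 1)
  # reversed pattern -> r = -1
  prof_rev <- stats::setNames(2^rev(sig$weights) - 1, sig$genes)
  expect_equal(as.numeric(correlation_score(prof_rev, sig)), -1)

  # arbitrary 4-gene profile against the textbook covariance formula
  prof2 <- stats::setNames(c(0.5, 3, 1, 8), sig$genes)
  y <- log2(prof2 + 1); y <- y - mean(y)
  w <- sig$weights
  r_direct <- sum((y - mean(y)) * (w - mean(w))) /
    sqrt(sum((y - mean(y))^2) * sum((w - mean(w))^2))
  expect_equal(as.numeric(correlation_score(prof2, sig)), r_direct,
               tolerance = 1e-12)

  # zero-variance profile is flagged undefined, not NaN
  flat <- stats::setNames(rep(3, 4), sig$genes)
  s <- correlation_score(flat, sig)
  expect_true(is.na(s) && isTRUE(attr(s, "undefined")))
})

test_that("scores are invariant under positive affine maps of the profile", {
  sig <- structure(list(genes = paste0("g", 1:5),
                        weights = c(-2, -1, 0, 1, 2),
                        numerator_label = "a", denominator_label = "b",
                        pseudocount = 1),
                   class = "signature_profile")
  set.seed(8)
  for (i in 1:5) {
    prof <- stats::setNames(rlnorm(5, 1), sig$genes)
    base <- as.numeric(correlation_score(prof, sig, transform = "none"))
    scaled <- as.numeric(correlation_score(3.7 * prof + 2, sig,
                                           transform = "none"))
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("score classification is strict at the cutoff with named presets", {
  scores <- data.frame(cell_id = c("a", "b", "c"),
                       score = c(0.51, 0.5, NA))
  lab <- classify_by_score(scores, 0.5)
  expect_equal(lab$is_mlme_like, c(TRUE, FALSE, FALSE))
  expect_equal(attr(classify_by_score(scores, "lenient"), "cutoff"), 0.4)
  expect_equal(attr(classify_by_score(scores, "stringent"), "cutoff"), 0.55)
  all_in <- classify_by_score(data.frame(cell_id = "a", score = -0.99), -1)
  expect_true(all_in$is_mlme_like)
  expect_error(classify_by_score(scores, 1.5), "\\[-1, 1\\]")
})

test_that("score_cells ranks descending with lexicographic tie-break", {
  m <- rbind(g1 = c(8, 1, 8, 4), g2 = c(1, 8, 1, 4), g3 = c(4, 2, 4, 4))
  colnames(m) <- c("b", "a", "azz", "c")
  em <- expression_matrix(m)
  sig <- derive_ratio_signature(em, c("b"), c("a"), genes = c("g1", "g2", "g3"))
  sc <- score_cells(em, sig)
  # cells "b" and "azz" have identical profiles hence tied scores
  expect_equal(sc$score[sc$cell_id == "b"], sc$score[sc$cell_id == "azz"])
  expect_lt(sc$rank[sc$cell_id == "azz"], sc$rank[sc$cell_id == "b"])
  expect_setequal(sc$rank, 1:4)
})

test_that("refinement keeps shifted genes, drops null genes, respects alpha", {
  set.seed(13)
  n <- 60
  cells <- sprintf("c%03d", 1:n)
  hi <- cells[1:25]
  shifted <- c(exp(rnorm(25, 5)), exp(rnorm(n - 25, 0)))   # 5 log-unit shift
  null1 <- exp(rnorm(n, 1))
  null2 <- exp(rnorm(n, 1))
  m <- rbind(shifted = shifted, null1 = null1, null2 = null2)
  colnames(m) <- cells
  em <- expression_matrix(m)
  scores <- data.frame(cell_id = cells,
                       score = ifelse(cells %in% hi, 0.8, 0.1))
  sig <- structure(list(genes = rownames(m), weights = c(1, 0.5, -0.5),
                        numerator_label = "a", denominator_label = "b",
                        pseudocount = 1),
                   class = "signature_profile")
  ref <- refine_signature(em, scores, sig, cutoff = 0.5, alpha = 0.05)
  expect_true("shifted" %in% ref$genes)
  expect_true(all(ref$genes %in% sig$genes))  # output subset of input

  ref_all <- refine_signature(em, scores, sig, cutoff = 0.5, alpha = 1)
  expect_setequal(ref_all$genes, sig$genes)   # alpha = 1 keeps everything
  expect_true(all(ref$genes %in% ref_all$genes))  # alpha-monotone

  # a gene identical in both groups is excluded
  m2 <- rbind(m, same = rep(c(1, 2), length.out = n))
  em2 <- expression_matrix(m2)
  sig2 <- structure(list(genes = rownames(m2), weights = c(1, 0.5, -0.5, 0.1),
                         numerator_label = "a", denominator_label = "b",
                         pseudocount = 1),
                    class = "signature_profile")
  ref2 <- refine_signature(em2, scores, sig2, cutoff = 0.5, alpha = 0.05)
  expect_false("same" %in% ref2$genes)

  expect_error(refine_signature(em, scores, sig, cutoff = 0.99), "lower the cutoff")
})

test_that("rank-sum retention agrees with a permutation oracle on a shifted gene", {
  set.seed(99)
  a <- exp(rnorm(50, 5)); b <- exp(rnorm(50, 0))
  # permutation null of the rank-sum statistic
  obs <- sum(rank(c(a, b))[1:50])
  perm <- replicate(500, sum(rank(c(a, b))[sample(100, 50)]))
  p_perm <- mean(abs(perm - mean(perm)) >= abs(obs - mean(perm)))
  expect_lt(p_perm, 0.05)
  expect_lt(suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value),
            0.05)
})

test_that("top-scoring selection finds the minimal stage-covering prefix", {
  scores <- data.frame(cell_id = sprintf("c%d", 1:6),
                       score = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  meta <- data.frame(cell_id = sprintf("c%d", 1:6),
                     stage = c("E4", "E5", "E3", "E4", "E5", "E3"))
  sel <- select_top_scoring(scores, meta, c("E3", "E4", "E5"))
  expect_true(sel$satisfiable)
  expect_equal(sel$k, 3L)  # best cells of the three stages are ranks 1-3
  expect_equal(sel$cells, c("c1", "c2", "c3"))

  miss <- select_top_scoring(scores, meta, c("E3", "E7"))
  expect_false(miss$satisfiable)
  expect_equal(miss$missing_stages, "E7")

  set.seed(17)
  for (i in 1:10) {
    n <- 20
    sc <- data.frame(cell_id = sprintf("c%02d", 1:n), score = runif(n))
    md <- data.frame(cell_id = sc$cell_id,
                     stage = sample(c("E3", "E4", "E5"), n, replace = TRUE))
    req <- unique(md$stage)
    got <- select_top_scoring(sc, md, req)
    want <- oracle_top_scoring_k(sc, stats::setNames(md$stage, md$cell_id), req)
    expect_equal(got$k, want)
  }
})
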