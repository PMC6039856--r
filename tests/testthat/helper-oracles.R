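# Independent oracles used by the test-suite. These deliberately avoid the
# code paths of the package implementations they check.

# Exact hypergeometric pmf by direct binomial-coefficient arithmetic;
# choose() is exact integer arithmetic at these sizes (N <= 40).
oracle_hyper_pmf <- function(N, K, n, k) {
  choose(K, k) * choose(N - K, n - k) / choose(N, n)
}

oracle_hyper_upper <- function(N, K, n, k) {
  ks <- k:min(K, n)
  sum(oracle_hyper_pmf(N, K, n, ks))
}

oracle_hyper_lower <- function(N, K, n, k) {
  ks <- max(0, n + K - N):k
  sum(oracle_hyper_pmf(N, K, n, ks))
}

# Two-sided Fisher p by exhaustive enumeration over all tables with the
# observed margins: sum the probabilities of tables whose point probability
# does not exceed the observed one (within relative tolerance 1e-7).
oracle_fisher_two_tailed <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + b          # first-row margin
  n <- a + c          # first-column margin
  ks <- max(0, n + K - N):min(K, n)
  pmf <- oracle_hyper_pmf(N, K, n, ks)
  obs <- oracle_hyper_pmf(N, K, n, a)
  sum(pmf[pmf <= obs * (1 + 1e-7)])
}

# Kruskal-Wallis H by the rank-sum formula with tie correction, evaluated
# directly on pooled ranks.
oracle_kruskal_H <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  sizes <- vapply(groups, length, 1L)
  idx <- rep(seq_along(groups), sizes)
  R <- tapply(r, idx, sum)
  H <- 12 / (N * (N + 1)) * sum(R^2 / sizes) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Straight-line re-implementation of the spectral filter loop via SVD of
# the centred data matrix (the package uses eigen() on the covariance).
oracle_filter <- function(mat, threshold, var_fraction = 0.95) {
  spectrum <- function(m) {
    xc <- m - rowMeans(m)
    sv <- svd(xc)
    lam <- sv$d^2 / (ncol(m) - 1)
    list(lam = lam, load = sv$u)
  }
  entropy <- function(m) {
    lam <- spectrum(m)$lam
    p <- lam / sum(lam)
    p <- p[p > 1e-300]
    -sum(p * log(p))
  }
  H0 <- entropy(mat)
  current <- rownames(mat)
  order_removed <- character()
  halted_on <- NA_character_
  while (length(current) > 2L) {
    sp <- spectrum(mat[current, , drop = FALSE])
    J <- seq_len(which(cumsum(sp$lam) / sum(sp$lam) >= var_fraction)[1L])
    contrib <- drop((sp$load[, J, drop = FALSE]^2) %*% sp$lam[J])
    names(contrib) <- current
    victim <- current[order(contrib, current)][1L]
    rest <- setdiff(current, victim)
    if (abs(entropy(mat[rest, , drop = FALSE]) - H0) / H0 >= threshold) {
      halted_on <- victim
      break
    }
    order_removed <- c(order_removed, victim)
    current <- rest
  }
  list(removed = order_removed, retained = current, halted_on = halted_on)
}

# Smallest k whose top-k by score covers every required stage, by linear
# scan over k = 1..n.
oracle_top_scoring_k <- function(scores, stage_by_cell, stages_required) {
  ids <- scores$cell_id[order(-scores$score, scores$cell_id)]
  for (k in seq_along(ids)) {
    if (all(stages_required %in% stage_by_cell[ids[seq_len(k)]])) return(k)
  }
  NA_integer_
}

# Rank-based AUROC of score against a boolean truth label.
auroc <- function(score, truth) {
  r <- rank(score)
  (mean(r[truth]) - (sum(truth) + 1) / 2) / sum(!truth)
}
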