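# Fixture builders shared across test files.

tiny_matrix <- function() {
  m <- matrix(c(0, 1, 2,
                3, 4, 5), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  expression_matrix(m)
}

random_matrix <- function(n_genes, n_cells, seed) {
  set.seed(seed)
  m <- matrix(round(stats::rlnorm(n_genes * n_cells), 4),
              n_genes, n_cells,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("c%03d", seq_len(n_cells))))
  expression_matrix(m)
}

toy_panel <- function(min_markers = 2L) {
  marker_panel(
    lineage_markers = list(
      EPI = c("NANOG", "POU5F1", "SOX2", "LIN28A"),
      PE  = c("GATA4", "FGFR2", "GRB2", "SOX17"),
      TE  = c("CDX2", "TROP2", "TEAD4", "GATA3")),
    min_markers_per_lineage = min_markers)
}

# config of ~1000 cells used by the parameter-recovery checks
recovery_config <- function(seed, dropout = 0) {
  simulation_config(
    seed = seed,
    stages = data.frame(
      stage = c("E3", "E4", "E5.early", "E5", "E6", "E7"),
      n_embryos = c(10L, 11L, 8L, 11L, 11L, 9L),
      cells_per_embryo = c(6L, 12L, 16L, 20L, 22L, 24L)),
    dropout_prob = dropout)
}

# single-stage config of exactly 1000 cells with a planted MLME / TERT+
# association of relative risk `rr` (rr = 1 gives the null)
enrichment_config <- function(seed, rr = 2, f = 0.15, t0 = 0.5) {
  if (rr == 1) {
    t1 <- t0
  } else {
    # solve P(MLME | TERT+) = rr * P(MLME | TERT-) for a = P(MLME & TERT+):
    # (rr-1) a^2 + (d + rr b - (rr-1) f) a - rr f b = 0, then t1 = a / f
    b <- (1 - f) * t0
    d <- (1 - f) * (1 - t0)
    roots <- polyroot(c(-rr * f * b, d + rr * b - (rr - 1) * f, rr - 1))
    a <- Re(roots[abs(Im(roots)) < 1e-9 & Re(roots) > 0 & Re(roots) < f])[1]
    t1 <- a / f
  }
  simulation_config(
    seed = seed,
    stages = data.frame(stage = "E5.early", n_embryos = 50L,
                        cells_per_embryo = 20L),
    lineage_mix = list("E5.early" = c(EPI = 0.1, PE = 0.1, TE = 0.1,
                                      "pre-lineage" = 0.7)),
    mlme_fraction = c("E5.early" = f),
    tert_positive_prob = c(MLME = t1, non_MLME = t0),
    n_background_genes = 5L)
}
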