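#' Per-gene differential expression between two cell groups
#'
#' For each gene, the log2 mean-ratio effect (with pseudocount) between a
#' positive group (e.g. MLME-like cells) and a negative group, and a
#' two-sided rank-sum p-value (Welch t-test via flag). No multiple-testing
#' correction is applied by default; pass `adjust = "BH"` for
#' Benjamini-Hochberg.
#'
#' @param x an [expression_matrix()] object.
#' @param group_pos,group_neg disjoint cell-id vectors, each of size >= 2.
#' @param genes genes to test (default: all).
#' @param pseudocount positive real for the effect ratio, default 1.
#' @param test `"wilcox"` (default) or `"t"`.
#' @param adjust p-adjustment method for [stats::p.adjust()], default
#'   `"none"`.
#' @return data.frame with `gene_id`, `effect` (log2 ratio pos/neg), `p`.
#' @export
differential_genes <- function(x, group_pos, group_neg,
                               genes = rownames(x$values),
                               pseudocount = 1,
                               test = c("wilcox", "t"),
                               adjust = "none") {
  stopifnot(inherits(x, "expr_matrix"))
  test <- match.arg(test)
  if (length(group_pos) < 2L || length(group_neg) < 2L)
    stopf("each group needs at least 2 cells")
  if (length(intersect(group_pos, group_neg)))
    stopf("groups must be disjoint")
  absent <- setdiff(c(group_pos, group_neg), colnames(x$values))
  if (length(absent))
    stopf("cell(s) not in matrix: %s", paste(utils::head(absent, 5L), collapse = ", "))
  vp <- x$values[genes, group_pos, drop = FALSE]
  vn <- x$values[genes, group_neg, drop = FALSE]
  effect <- log2((rowMeans(vp) + pseudocount) / (rowMeans(vn) + pseudocount))
  p <- vapply(seq_along(genes), function(i) {
    a <- vp[i, ]; b <- vn[i, ]
    if (stats::sd(c(a, b)) == 0) return(1)
    if (test == "wilcox")
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    else
      stats::t.test(a, b)$p.value
  }, numeric(1))
  p <- stats::p.adjust(p, method = adjust)
  data.frame(gene_id = genes, effect = unname(effect), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Cross-dataset consensus of concordantly regulated genes
#'
#' Given per-gene differential statistics from two independent datasets,
#' returns the genes significant in both (p < alpha each) with effects of
#' the same sign — the consensus-signature construction that yielded the
#' published 863-gene set (241 up, 622 down) across two validation
#' datasets.
#'
#' @param stats_A,stats_B data.frames from [differential_genes()]
#'   (columns `gene_id`, `effect`, `p`).
#' @param alpha significance level applied to both datasets, default 0.05.
#' @param origins optional data.frame with `gene_id` and `origin`
#'   (maternal / embryonic / unknown) attached to the output; genes without
#'   a label get `"unknown"`.
#' @return data.frame of consensus genes: `gene_id`, `direction`
#'   ("up"/"down"), `effect_A`, `effect_B`, `p_A`, `p_B`, `origin`. Zero
#'   overlap between the gene universes yields an empty result with a
#'   warning.
#' @export
concordant_consensus <- function(stats_A, stats_B, alpha = 0.05,
                                 origins = NULL) {
  for (s in list(stats_A, stats_B))
    if (!all(c("gene_id", "effect", "p") %in% names(s)))
      stopf("differential stats need columns gene_id, effect, p")
  if (alpha <= 0 || alpha > 1) stopf("`alpha` must be in (0, 1]")
  shared <- intersect(stats_A$gene_id, stats_B$gene_id)
  if (length(shared) == 0L) {
    warning("gene universes do not overlap; empty consensus")
    return(data.frame(gene_id = character(), direction = character(),
                      effect_A = numeric(), effect_B = numeric(),
                      p_A = numeric(), p_B = numeric(),
                      origin = character(), stringsAsFactors = FALSE))
  }
  a <- stats_A[match(shared, stats_A$gene_id), ]
  b <- stats_B[match(shared, stats_B$gene_id), ]
  keep <- a$p < alpha & b$p < alpha &
    sign(a$effect) == sign(b$effect) & sign(a$effect) != 0
  out <- data.frame(gene_id = shared[keep],
                    direction = ifelse(a$effect[keep] > 0, "up", "down"),
                    effect_A = a$effect[keep], effect_B = b$effect[keep],
                    p_A = a$p[keep], p_B = b$p[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(origins)) {
    if (!all(c("gene_id", "origin") %in% names(origins)))
      stopf("`origins` needs columns gene_id and origin")
    out$origin <- origins$origin[match(out$gene_id, origins$gene_id)]
    out$origin[is.na(out$origin)] <- "unknown"
  } else {
    out$origin <- rep("unknown", nrow(out))
  }
  rownames(out) <- NULL
  out
}

#' Concordance correlation of effects between two datasets
#'
#' Pearson correlation of the per-gene log-ratio effects over the shared
#' gene universe (the "r = ..." of a cross-dataset concordance scatter).
#'
#' @inheritParams concordant_consensus
#' @return the correlation, or `NA` flagged `undefined` when fewer than 3
#'   shared genes with variance are available.
#' @export
concordance_correlation <- function(stats_A, stats_B) {
  shared <- intersect(stats_A$gene_id, stats_B$gene_id)
  ea <- stats_A$effect[match(shared, stats_A$gene_id)]
  eb <- stats_B$effect[match(shared, stats_B$gene_id)]
  if (length(shared) < 3L || stats::sd(ea) == 0 || stats::sd(eb) == 0)
    return(structure(NA_real_, undefined = TRUE))
  stats::cor(ea, eb)
}

#' Maternal/embryonic origin breakdown of a consensus signature
#'
#' Reports, at one-decimal percent precision, the fraction of up-regulated
#' consensus genes of embryonic origin and of down-regulated genes of
#' maternal origin, plus the full direction-by-origin count table.
#' Fractions are computed over origin-labelled genes only; the unknown
#' count is surfaced alongside.
#'
#' @param consensus data.frame from [concordant_consensus()] with an
#'   `origin` column.
#' @return list with `pct_up_embryonic`, `pct_down_maternal` (percents, NA
#'   when the denominator is empty), `counts` (direction x origin table)
#'   and `n_unknown`.
#' @export
origin_summary <- function(consensus) {
  if (!all(c("gene_id", "direction", "origin") %in% names(consensus)))
    stopf("consensus table needs gene_id, direction, origin columns")
  if (nrow(consensus) == 0L) {
    return(list(pct_up_embryonic = NA_real_, pct_down_maternal = NA_real_,
                counts = table(direction = character(), origin = character()),
                n_unknown = 0L))
  }
  dir <- factor(consensus$direction, levels = c("up", "down"))
  ori <- factor(consensus$origin, levels = ORIGIN_LEVELS)
  counts <- table(direction = dir, origin = ori)
  up_lab <- counts["up", "maternal"] + counts["up", "embryonic"]
  dn_lab <- counts["down", "maternal"] + counts["down", "embryonic"]
  list(
    pct_up_embryonic = if (up_lab > 0)
      round_half_up(100 * counts["up", "embryonic"] / up_lab, 1) else NA_real_,
    pct_down_maternal = if (dn_lab > 0)
      round_half_up(100 * counts["down", "maternal"] / dn_lab, 1) else NA_real_,
    counts = counts,
    n_unknown = sum(counts[, "unknown"]))
}
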