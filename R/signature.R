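#' Derive a log-ratio gene signature between two cell populations
#'
#' A signature is an ordered gene list with one weight per gene, the log2
#' ratio of mean expression between a numerator population (e.g. TERT+
#' cells) and a denominator population (e.g. EPI cells), with a pseudocount
#' guarding against zeros:
#' `weight_g = log2((mean_num + pc) / (mean_den + pc))`.
#'
#' @param x an [expression_matrix()] object.
#' @param numerator_cells,denominator_cells disjoint non-empty character
#'   vectors of cell ids.
#' @param genes gene ids to include, in signature order.
#' @param pseudocount positive real added to both means; default 1.
#' @param numerator_label,denominator_label provenance strings stored with
#'   the signature.
#' @return an object of class `signature_profile`: list with `genes`,
#'   `weights`, `numerator_label`, `denominator_label`, `pseudocount`.
#' @export
derive_ratio_signature <- function(x, numerator_cells, denominator_cells,
                                   genes = rownames(x$values),
                                   pseudocount = 1,
                                   numerator_label = "numerator",
                                   denominator_label = "denominator") {
  stopifnot(inherits(x, "expr_matrix"))
  if (length(numerator_cells) == 0L || length(denominator_cells) == 0L)
    stopf("numerator and denominator cell sets must be non-empty")
  if (length(intersect(numerator_cells, denominator_cells)))
    stopf("numerator and denominator cell sets must be disjoint")
  if (pseudocount <= 0) stopf("`pseudocount` must be > 0")
  absent <- setdiff(c(numerator_cells, denominator_cells), colnames(x$values))
  if (length(absent))
    stopf("cell(s) not in matrix: %s", paste(utils::head(absent, 5L), collapse = ", "))
  missing_g <- setdiff(genes, rownames(x$values))
  if (length(missing_g))
    stopf("gene(s) not in matrix: %s", paste(missing_g, collapse = ", "))
  if (anyDuplicated(genes)) stopf("duplicate genes in signature gene list")
  mnum <- rowMeans(x$values[genes, numerator_cells, drop = FALSE])
  mden <- rowMeans(x$values[genes, denominator_cells, drop = FALSE])
  w <- log2((mnum + pseudocount) / (mden + pseudocount))
  structure(list(genes = genes, weights = unname(w),
                 numerator_label = numerator_label,
                 denominator_label = denominator_label,
                 pseudocount = pseudocount),
            class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  cat(sprintf("<signature_profile> %d genes: %s vs %s (pseudocount %g)\n",
              length(x$genes), x$numerator_label, x$denominator_label,
              x$pseudocount))
  invisible(x)
}

#' Write / read a signature as a two-column TSV (gene, weight)
#' @param sig a `signature_profile`.
#' @param path output file.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "signature_profile"))
  utils::write.table(
    data.frame(gene_id = sig$genes, weight = sig$weights),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Correlation score of one expression profile against a signature
#'
#' The MLME-resemblance score of a cell (or of a population mean profile)
#' is the correlation between the cell's transformed expression over the
#' signature genes and the signature's log-ratio weights. The default
#' transform is `log2(value + pseudocount)`; the profile is then centred
#' across the signature genes, which leaves the Pearson correlation
#' unchanged but makes the compared quantities commensurate (both are
#' log-scale deviations). Scores live in [-1, 1].
#'
#' @param profile named numeric vector of non-negative expression values
#'   covering every signature gene, or a vector ordered like
#'   `signature$genes`.
#' @param signature a `signature_profile`.
#' @param transform `"log"` (default: log2(x + pseudocount)) or `"none"`
#'   (score the raw values, for profiles that are already ratios/logs).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return the correlation score, or `NA` with attribute
#'   `undefined = TRUE` when the transformed profile (or the weights) has
#'   zero variance.
#' @export
correlation_score <- function(profile, signature,
                              transform = c("log", "none"),
                              method = c("pearson", "spearman")) {
  stopifnot(inherits(signature, "signature_profile"))
  transform <- match.arg(transform)
  method <- match.arg(method)
  if (!is.null(names(profile))) {
    absent <- setdiff(signature$genes, names(profile))
    if (length(absent))
      stopf("profile lacks signature gene(s): %s",
            paste(utils::head(absent, 5L), collapse = ", "))
    profile <- profile[signature$genes]
  } else if (length(profile) != length(signature$genes)) {
    stopf("unnamed profile length %d does not match %d signature genes",
          length(profile), length(signature$genes))
  }
  y <- if (transform == "log") log2(profile + signature$pseudocount) else profile
  y <- y - mean(y)
  if (length(y) < 3L) stopf("need at least 3 signature genes to score")
  if (stats::sd(y) == 0 || stats::sd(signature$weights) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  stats::cor(y, signature$weights, method = method)
}

#' Score every cell of a matrix against a signature
#'
#' Applies [correlation_score()] per cell and ranks cells by descending
#' score (ties broken by cell id, lexicographically), attaching the
#' MLME-like label at the requested cutoff.
#'
#' @inheritParams correlation_score
#' @param x an [expression_matrix()] object containing all signature genes.
#' @param cutoff score cutoff for the MLME-like label; strict (`score >
#'   cutoff`). Default 0.5; 0.4 and 0.55 are the conventional lenient /
#'   stringent alternatives.
#' @return data.frame with columns `cell_id`, `score`, `rank`,
#'   `is_mlme_like`; cells with undefined scores carry `NA` score,
#'   rank after all defined scores, and `FALSE` label.
#' @export
score_cells <- function(x, signature, cutoff = 0.5,
                        transform = c("log", "none"),
                        method = c("pearson", "spearman")) {
  stopifnot(inherits(x, "expr_matrix"))
  transform <- match.arg(transform)
  method <- match.arg(method)
  absent <- setdiff(signature$genes, rownames(x$values))
  if (length(absent))
    stopf("matrix lacks signature gene(s): %s",
          paste(utils::head(absent, 5L), collapse = ", "))
  v <- x$values[signature$genes, , drop = FALSE]
  scores <- vapply(seq_len(ncol(v)), function(j)
    as.numeric(correlation_score(v[, j], signature,
                                 transform = transform, method = method)),
    numeric(1))
  out <- data.frame(cell_id = colnames(v), score = scores,
                    stringsAsFactors = FALSE)
  ord <- order(-out$score, out$cell_id, na.last = TRUE)
  out$rank[ord] <- seq_len(nrow(out))
  classify_by_score(out, cutoff)
}

#' Label scored cells as MLME-like at a score cutoff
#'
#' Strict rule: `is_mlme_like = score > cutoff`. Undefined (`NA`) scores are
#' never MLME-like.
#'
#' @param scores data.frame with at least `cell_id` and `score`.
#' @param cutoff numeric in [-1, 1], or one of the named presets
#'   `"lenient"` (0.4), `"default"` (0.5), `"stringent"` (0.55).
#' @return the input data.frame with `is_mlme_like` (re)computed.
#' @export
classify_by_score <- function(scores, cutoff = 0.5) {
  if (is.character(cutoff)) {
    cutoff <- switch(cutoff, lenient = 0.4, default = 0.5, stringent = 0.55,
                     stopf("unknown cutoff preset '%s'", cutoff))
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < -1 || cutoff > 1)
    stopf("`cutoff` must be a single number in [-1, 1]")
  scores$is_mlme_like <- !is.na(scores$score) & scores$score > cutoff
  attr(scores, "cutoff") <- cutoff
  scores
}

#' Refine a signature to the genes that differ between high- and low-score cells
#'
#' Splits scored cells at the cutoff (score > cutoff vs the rest), tests
#' each signature gene for a difference in expression between the two
#' groups (two-sided Mann-Whitney rank-sum by default), keeps the genes
#' with p < alpha, and re-derives the log-ratio weights between the two
#' groups. This is the step that reduced a 46-gene signature to its
#' 23-gene refinement in the original analysis.
#'
#' @param x an [expression_matrix()] object.
#' @param scores data.frame from [score_cells()].
#' @param signature the `signature_profile` to refine.
#' @param cutoff score cutoff splitting the groups; default 0.5.
#' @param alpha significance level, default 0.05.
#' @param test `"wilcox"` (default) or `"t"`.
#' @return a `signature_profile` over the retained gene subset, weights
#'   re-derived as high-score vs low-score log2 mean ratios.
#' @export
refine_signature <- function(x, scores, signature, cutoff = 0.5,
                             alpha = 0.05, test = c("wilcox", "t")) {
  stopifnot(inherits(x, "expr_matrix"), inherits(signature, "signature_profile"))
  test <- match.arg(test)
  if (alpha <= 0 || alpha > 1) stopf("`alpha` must be in (0, 1]")
  hi <- scores$cell_id[!is.na(scores$score) & scores$score > cutoff]
  lo <- scores$cell_id[!is.na(scores$score) & scores$score <= cutoff]
  if (length(hi) == 0L)
    stopf("no cells score above %g; lower the cutoff", cutoff)
  if (length(lo) == 0L)
    stopf("no cells score at or below %g; raise the cutoff", cutoff)
  v <- x$values[signature$genes, , drop = FALSE]
  pvals <- vapply(signature$genes, function(g) {
    a <- v[g, hi]; b <- v[g, lo]
    if (stats::sd(c(a, b)) == 0) return(1)  # identical everywhere
    if (test == "wilcox")
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    else
      stats::t.test(a, b)$p.value
  }, numeric(1))
  keep <- signature$genes[pvals < alpha]
  if (length(keep) == 0L)
    stopf("no signature gene differs at alpha = %g between score groups", alpha)
  derive_ratio_signature(
    x, numerator_cells = hi, denominator_cells = lo, genes = keep,
    pseudocount = signature$pseudocount,
    numerator_label = sprintf("score > %g", cutoff),
    denominator_label = sprintf("score <= %g", cutoff))
}

#' Minimal top-scoring cell set covering every required stage
#'
#' Implements the selection rule for top-scoring MLME-like cells: take the
#' smallest k such that the k highest-scoring cells include at least one
#' cell from every required developmental stage — the minimum selection
#' under which at least one MLME-like cell would emerge in embryos of every
#' stage prior to lineage segregation. Ties at the k-th score are broken by
#' cell id (lexicographic).
#'
#' @param scores data.frame with `cell_id` and `score`.
#' @param cell_meta data.frame with `cell_id` and `stage`.
#' @param stages_required character vector of stage labels that must be
#'   covered.
#' @return list with `satisfiable` (logical), `k`, and `cells` (the
#'   selected cell ids in rank order). When a required stage has no scored
#'   cells the result is flagged `satisfiable = FALSE` and `cells` contains
#'   all scored cells.
#' @export
select_top_scoring <- function(scores, cell_meta, stages_required) {
  if (nrow(scores) == 0L) stopf("`scores` is empty")
  if (!all(c("cell_id", "stage") %in% names(cell_meta)))
    stopf("`cell_meta` needs `cell_id` and `stage` columns")
  stage <- stats::setNames(as.character(cell_meta$stage), cell_meta$cell_id)
  ok <- !is.na(scores$score)
  ordered_ids <- scores$cell_id[ok][order(-scores$score[ok], scores$cell_id[ok])]
  st <- stage[ordered_ids]
  missing <- setdiff(stages_required, st)
  if (length(missing)) {
    return(list(satisfiable = FALSE, k = NA_integer_, cells = ordered_ids,
                missing_stages = missing))
  }
  # k is the worst (largest) first-occurrence rank over required stages
  first_rank <- vapply(stages_required, function(s) match(s, st), 1L)
  k <- max(first_rank)
  list(satisfiable = TRUE, k = k, cells = ordered_ids[seq_len(k)])
}
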