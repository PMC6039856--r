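#' Digital positive/negative expression calls
#'
#' Converts an expression matrix to boolean per-gene, per-cell calls. Two
#' rules are supported. `"population_median"` follows the validation-data
#' convention: a marker counts as expressed in a cell when its value
#' strictly exceeds the median of that gene over *all* cells of the supplied
#' matrix (a value tied with the median is negative). `"fixed_threshold"`
#' calls a cell positive when the value strictly exceeds a fixed cutoff
#' (default 0, i.e. any detected signal), the natural rule for
#' discovery-style qPCR-like data.
#'
#' @param x an [expression_matrix()] object.
#' @param rule `"population_median"` or `"fixed_threshold"`.
#' @param threshold for `fixed_threshold`: a single non-negative value, or a
#'   per-gene vector named or ordered like the matrix rows.
#' @return an object of class `binary_calls`: list with `calls` (logical
#'   genes x cells matrix), `rule` (the rule kind plus the realised per-gene
#'   thresholds), `gene_ids`, `cell_ids`.
#' @export
#' @examples
#' m <- matrix(1:10, nrow = 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), paste0("c", 1:5)))
#' calls <- call_positive(expression_matrix(m), "population_median")
#' calls$calls["a", ]   # values 1..5, median 3: only 4 and 5 are positive
call_positive <- function(x,
                          rule = c("population_median", "fixed_threshold"),
                          threshold = 0) {
  stopifnot(inherits(x, "expr_matrix"))
  rule <- match.arg(rule)
  v <- x$values
  if (rule == "population_median") {
    thr <- apply(v, 1L, stats::median)
  } else {
    if (length(threshold) == 1L) {
      thr <- rep(as.numeric(threshold), nrow(v))
      names(thr) <- rownames(v)
    } else {
      if (length(threshold) != nrow(v))
        stopf("per-gene threshold length %d does not match %d genes",
              length(threshold), nrow(v))
      thr <- as.numeric(threshold)
      names(thr) <- if (!is.null(names(threshold))) names(threshold) else rownames(v)
      thr <- thr[rownames(v)]
      if (anyNA(thr)) stopf("per-gene thresholds missing for some genes")
    }
    if (any(thr < 0)) stopf("fixed thresholds must be >= 0")
  }
  calls <- sweep(v, 1L, thr, ">")
  structure(list(calls = calls,
                 rule = list(kind = rule, threshold = thr),
                 gene_ids = rownames(v), cell_ids = colnames(v)),
            class = "binary_calls")
}

#' @export
print.binary_calls <- function(x, ...) {
  cat(sprintf("<binary_calls> %d genes x %d cells (rule: %s)\n",
              nrow(x$calls), ncol(x$calls), x$rule$kind))
  invisible(x)
}

HPAT_PHENOTYPES <- c("spHPAT21", "dpHPAT15", "HPAT2pos_double",
                     "HPAT2pos_triple", "null_phenotype", "other")

#' Segregate cells by HPAT lincRNA expression phenotype
#'
#' Classifies every cell by the positive/negative pattern of the three HPAT
#' lincRNAs (HPAT21, HPAT2, HPAT15) that stratify human blastocyst cells
#' into lineage-resembling populations: single-positive HPAT21 cells
#' (TE-like), double-positive HPAT15 cells (PE-like) and HPAT2-positive
#' double/triple-positive cells (epiblast-like, the MLME-enriched
#' population). The map from call triple (HPAT21, HPAT2, HPAT15) to label:
#' \itemize{
#'   \item (+,-,-) spHPAT21
#'   \item (+,-,+) dpHPAT15
#'   \item (+,+,-) HPAT2pos_double
#'   \item (+,+,+) HPAT2pos_triple
#'   \item (-,-,-) null_phenotype
#'   \item anything else: other
#' }
#'
#' @param calls a `binary_calls` object containing the three HPAT genes.
#' @param hpat_genes the gene ids for (HPAT21, HPAT2, HPAT15), in that
#'   order, as they appear in the call matrix.
#' @return a factor over the cells with levels
#'   `r paste(HPAT_PHENOTYPES, collapse = ", ")`.
#' @export
classify_hpat <- function(calls, hpat_genes = c("HPAT21", "HPAT2", "HPAT15")) {
  stopifnot(inherits(calls, "binary_calls"))
  if (length(hpat_genes) != 3L)
    stopf("`hpat_genes` must name exactly 3 genes (HPAT21, HPAT2, HPAT15)")
  absent <- setdiff(hpat_genes, calls$gene_ids)
  if (length(absent))
    stopf("HPAT gene(s) missing from calls: %s", paste(absent, collapse = ", "))
  h21 <- calls$calls[hpat_genes[1L], ]
  h2  <- calls$calls[hpat_genes[2L], ]
  h15 <- calls$calls[hpat_genes[3L], ]
  lab <- rep("other", length(h21))
  lab[h21 & !h2 & !h15] <- "spHPAT21"
  lab[h21 & !h2 &  h15] <- "dpHPAT15"
  lab[h21 &  h2 & !h15] <- "HPAT2pos_double"
  lab[h21 &  h2 &  h15] <- "HPAT2pos_triple"
  lab[!h21 & !h2 & !h15] <- "null_phenotype"
  factor(stats::setNames(lab, calls$cell_ids), levels = HPAT_PHENOTYPES)
}

#' Prevalence of marker-positive cells across cell groups
#'
#' For each group of cells, counts how many are positive for a target gene
#' or gene set and reports the percent positive (one decimal, half-up).
#' With several target genes, `semantics = "all"` requires positivity for
#' every listed gene (conjunction), `"any"` for at least one.
#'
#' @param calls a `binary_calls` object.
#' @param groups named list of character vectors of cell ids; groups need
#'   not cover all cells. An empty group yields a flagged row
#'   (`n_total = 0`, `percent = NA`), never a dropped one.
#' @param genes character vector of target gene ids.
#' @param semantics `"all"` (default) or `"any"`.
#' @return data.frame with columns `label`, `n_total`, `n_positive`,
#'   `percent`.
#' @export
prevalence <- function(calls, groups, genes, semantics = c("all", "any")) {
  stopifnot(inherits(calls, "binary_calls"))
  semantics <- match.arg(semantics)
  if (!is.list(groups) || is.null(names(groups)) || any(!nzchar(names(groups))))
    stopf("`groups` must be a named list of cell-id vectors")
  absent <- setdiff(genes, calls$gene_ids)
  if (length(absent))
    stopf("target gene(s) missing from calls: %s", paste(absent, collapse = ", "))
  sub <- calls$calls[genes, , drop = FALSE]
  pos <- if (semantics == "all") colSums(sub) == length(genes) else colSums(sub) > 0L
  rows <- lapply(names(groups), function(lab) {
    ids <- groups[[lab]]
    unknown <- setdiff(ids, calls$cell_ids)
    if (length(unknown))
      stopf("group '%s' references unknown cell(s): %s", lab,
            paste(utils::head(unknown, 5L), collapse = ", "))
    n <- length(ids)
    k <- sum(pos[ids])
    data.frame(label = lab, n_total = n, n_positive = k,
               percent = if (n > 0L) round_half_up(100 * k / n, 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the 2x2 table `rbind(c(a, b), c(c, d))`,
#' using the point-probability summation convention: the p-value sums the
#' hypergeometric probabilities of all tables with the observed margins
#' whose point probability does not exceed that of the observed table.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return the two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_two_tailed(3, 0, 0, 3)  # 0.1
fisher_two_tailed <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("Fisher test needs non-negative integer counts")
  if (sum(counts) == 0L) stopf("all-zero table has no defined p-value")
  tab <- matrix(as.integer(counts), nrow = 2L, byrow = TRUE)
  min(1, stats::fisher.test(tab, alternative = "two.sided")$p.value)
}

#' Kruskal-Wallis rank test for two or more independent groups
#'
#' Rank-based H statistic with tie correction and a chi-square reference
#' distribution on k - 1 degrees of freedom, suited to independent samples
#' of unequal size.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return list with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("need at least 2 groups")
  if (any(vapply(groups, length, 1L) == 0L))
    stopf("every group must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3L) stopf("need at least 3 observations in total")
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic),
       p_value = if (is.nan(kt$p.value)) 1 else unname(kt$p.value),
       df = unname(kt$parameter))
}
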