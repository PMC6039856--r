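#' Construct a lineage marker panel
#'
#' A marker panel lists the lineage-specific genes used for digital
#' (positive/negative) cell typing: one gene list per blastocyst lineage
#' (EPI, PE, TE), the pluripotency master regulators that an MLME call
#' additionally requires, and the per-lineage marker-count threshold. The
#' defaults encode the published rule: a cell is multi-lineage
#' markers-expressing when it is positive for at least 4 markers of each of
#' the three lineages and for all of NANOG, POU5F1 and SOX2.
#'
#' Gene ids are opaque, case-sensitive strings; synonyms (e.g. POU5F1 vs
#' OCT4) must be resolved in the panel itself.
#'
#' @param lineage_markers named list with non-empty character vectors `EPI`,
#'   `PE`, `TE`; no duplicates within a lineage.
#' @param master_regulators character vector; default
#'   `c("NANOG", "POU5F1", "SOX2")`.
#' @param min_markers_per_lineage positive integer, default 4.
#' @return an object of class `marker_panel`.
#' @export
#' @examples
#' marker_panel(list(EPI = c("NANOG", "POU5F1", "SOX2", "LIN28A"),
#'                   PE  = c("GATA4", "FGFR2", "GRB2", "SOX17"),
#'                   TE  = c("CDX2", "TROP2", "TEAD4", "GATA3")))
marker_panel <- function(lineage_markers,
                         master_regulators = c("NANOG", "POU5F1", "SOX2"),
                         min_markers_per_lineage = 4L) {
  if (!is.list(lineage_markers))
    stopf("`lineage_markers` must be a named list")
  needed <- c("EPI", "PE", "TE")
  missing <- setdiff(needed, names(lineage_markers))
  if (length(missing))
    stopf("marker panel is missing lineage(s): %s", paste(missing, collapse = ", "))
  lineage_markers <- lineage_markers[needed]
  for (ln in needed) {
    g <- lineage_markers[[ln]]
    if (!is.character(g) || length(g) == 0L)
      stopf("lineage %s must have a non-empty character marker list", ln)
    if (anyDuplicated(g))
      stopf("duplicate marker(s) in lineage %s: %s", ln,
            paste(unique(g[duplicated(g)]), collapse = ", "))
  }
  if (!is.character(master_regulators) || length(master_regulators) == 0L ||
      anyDuplicated(master_regulators))
    stopf("`master_regulators` must be a non-empty set of unique gene ids")
  min_markers_per_lineage <- as.integer(min_markers_per_lineage)
  if (is.na(min_markers_per_lineage) || min_markers_per_lineage < 1L)
    stopf("`min_markers_per_lineage` must be a positive integer")
  structure(list(lineage_markers = lineage_markers,
                 master_regulators = master_regulators,
                 min_markers_per_lineage = min_markers_per_lineage),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel>\n")
  for (ln in names(x$lineage_markers))
    cat(sprintf("  %s: %d markers\n", ln, length(x$lineage_markers[[ln]])))
  cat("  master regulators:", paste(x$master_regulators, collapse = ", "), "\n")
  cat("  min markers per lineage:", x$min_markers_per_lineage, "\n")
  invisible(x)
}

#' All gene ids a panel refers to
#' @param panel a `marker_panel`.
#' @return character vector of unique gene ids (lineage markers plus
#'   master regulators).
#' @export
panel_genes <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  unique(c(unlist(panel$lineage_markers, use.names = FALSE),
           panel$master_regulators))
}

#' Read a marker panel from a YAML or JSON configuration file
#'
#' The file must declare `lineage_markers` with the three lineage keys;
#' `master_regulators` defaults to NANOG/POU5F1/SOX2 and
#' `min_markers_per_lineage` to 4 when omitted.
#'
#' @param path config file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return a validated [marker_panel()].
#' @export
read_marker_panel <- function(path) {
  if (!file.exists(path)) stopf("panel file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stopf("unsupported panel config extension '%s'", ext))
  lm <- cfg$lineage_markers %||% cfg[c("EPI", "PE", "TE")]
  lm <- lapply(lm, function(g) as.character(unlist(g)))
  marker_panel(
    lineage_markers = lm,
    master_regulators = as.character(
      unlist(cfg$master_regulators %||% c("NANOG", "POU5F1", "SOX2"))),
    min_markers_per_lineage = cfg$min_markers_per_lineage %||% 4L)
}

#' Check that every panel gene is present in an expression matrix
#' @param panel a `marker_panel`.
#' @param x an `expr_matrix`.
#' @return invisibly TRUE; errors listing any absent genes.
#' @export
validate_panel <- function(panel, x) {
  stopifnot(inherits(panel, "marker_panel"), inherits(x, "expr_matrix"))
  absent <- setdiff(panel_genes(panel), rownames(x$values))
  if (length(absent))
    stopf("panel gene(s) absent from matrix: %s", paste(absent, collapse = ", "))
  invisible(TRUE)
}

#' Write a prevalence table to a tab-separated file
#'
#' One header line then one line per row; percents printed to 1 decimal
#' (half-up) and p-values in scientific notation below 1e-3.
#'
#' @param rows data.frame of prevalence rows as produced by [prevalence()]
#'   or [build_prevalence_report()]; must contain `label`, `n_total`,
#'   `n_positive`, `percent` and optionally `p_value`, `test`.
#' @param path output file.
#' @export
write_prevalence_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stopf("`rows` must be a non-empty data.frame")
  need <- c("label", "n_total", "n_positive", "percent")
  missing <- setdiff(need, names(rows))
  if (length(missing))
    stopf("prevalence rows lack column(s): %s", paste(missing, collapse = ", "))
  out <- data.frame(label = rows$label,
                    n_total = rows$n_total,
                    n_positive = rows$n_positive,
                    percent = format_percent1(rows$percent),
                    stringsAsFactors = FALSE)
  if ("p_value" %in% names(rows)) out$p_value <- format_pvalue(rows$p_value)
  if ("test" %in% names(rows)) out$test <- rows$test
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
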