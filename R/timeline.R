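#' Probability that at least one MLME cell emerges in one embryo
#'
#' Under an independence model, if a fraction `f` of a stage's cell pool
#' carries the MLME phenotype and an individual embryo at that stage has
#' `n` cells, the chance that at least one of them is MLME is
#' `1 - (1 - f)^n`.
#'
#' @param f MLME fraction in [0, 1].
#' @param n cells per embryo (integer >= 1).
#' @return emergence probability in [0, 1]; monotone non-decreasing in
#'   both arguments.
#' @export
#' @examples
#' emergence_probability(0.1, 10)  # 1 - 0.9^10 = 0.6513...
emergence_probability <- function(f, n) {
  if (any(f < 0) || any(f > 1)) stopf("`f` must be in [0, 1]")
  if (any(n < 1) || any(n != round(n))) stopf("`n` must be a positive integer")
  1 - (1 - f)^n
}

#' Wilson 95% score interval for a binomial proportion
#' @keywords internal
wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  den <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / den
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  # at k = 0 (resp. k = n) the bound is exactly 0 (resp. 1); avoid fp residue
  c(low = if (k == 0) 0 else max(0, centre - half),
    high = if (k == n) 1 else min(1, centre + half))
}

#' Per-stage emergence timeline of MLME cells
#'
#' For each developmental stage, pools the analysed cells across embryos,
#' estimates the MLME fraction `f` with a Wilson 95% interval, and converts
#' it to the probability that at least one MLME cell is present in an
#' individual embryo of that stage given its typical cell count.
#'
#' @param mlme_flags named logical vector over cells (MLME phenotype or
#'   MLME-like call).
#' @param cell_meta data.frame with `cell_id` and `stage`.
#' @param cells_per_embryo named vector/list mapping every stage present in
#'   the data to the cell count of one embryo at that stage.
#' @return data.frame ordered by developmental stage with columns `stage`,
#'   `n_cells` (analysed), `n_mlme`, `f`, `ci_low`, `ci_high`,
#'   `cells_per_embryo`, `p_emerge`. Stages with zero analysed cells are
#'   flagged with `NA` estimates.
#' @export
stage_timeline <- function(mlme_flags, cell_meta, cells_per_embryo) {
  if (is.null(names(mlme_flags))) stopf("`mlme_flags` must be named by cell id")
  if (!all(c("cell_id", "stage") %in% names(cell_meta)))
    stopf("`cell_meta` needs `cell_id` and `stage` columns")
  cells_per_embryo <- unlist(cells_per_embryo)
  stages <- unique(as.character(cell_meta$stage))
  missing <- setdiff(stages, names(cells_per_embryo))
  if (length(missing))
    stopf("no cells_per_embryo entry for stage(s): %s",
          paste(missing, collapse = ", "))
  stages <- intersect(STAGE_LEVELS, stages)  # developmental order
  rows <- lapply(stages, function(s) {
    ids <- cell_meta$cell_id[cell_meta$stage == s]
    ids <- intersect(ids, names(mlme_flags))
    n <- length(ids)
    npe <- as.integer(cells_per_embryo[[s]])
    if (n == 0L) {
      return(data.frame(stage = s, n_cells = 0L, n_mlme = 0L, f = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        cells_per_embryo = npe, p_emerge = NA_real_,
                        stringsAsFactors = FALSE))
    }
    k <- sum(mlme_flags[ids])
    f <- k / n
    ci <- wilson_interval(k, n)
    data.frame(stage = s, n_cells = n, n_mlme = k, f = f,
               ci_low = ci[["low"]], ci_high = ci[["high"]],
               cells_per_embryo = npe,
               p_emerge = emergence_probability(f, npe),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
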