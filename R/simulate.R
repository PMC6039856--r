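#' Configuration for the embryo-structured expression simulator
#'
#' Builds (and validates) the parameter set of [simulate_dataset()]. The
#' defaults emulate the structure of a large single-cell validation study
#' of human preimplantation development: embryos sampled at E3 through E7,
#' pre-lineage cells dominating before blastocyst formation and the three
#' lineages (with trophectoderm expanding) afterwards; a planted MLME
#' subpopulation absent at E3, emerging at E4, peaking in early E5 and
#' sustained through E6-E7; and telomerase-positive probabilities of 0.66
#' for MLME and 0.51 for non-MLME cells, matching the conditional rates
#' implied by the published prevalence tables (175/267 and 644/1262).
#' Expression is two-state log-normal: "on" genes draw from
#' `on_state` (meanlog 4, sdlog 1), "off" genes from `off_state`
#' (meanlog 0, sdlog 1) — a 4-natural-log separation — with technical
#' dropout zeroing "on" draws at `dropout_prob` (default 0.2).
#' Pre-lineage cells express each lineage marker with a bleed-through
#' probability (default 0.2), mimicking the intermediate co-expression
#' state that precedes lineage segregation.
#'
#' @param seed integer master seed; all sampling derives from it.
#' @param stages data.frame with columns `stage`, `n_embryos`,
#'   `cells_per_embryo`.
#' @param lineage_mix named list: per stage, a probability vector over
#'   `EPI`, `PE`, `TE`, `pre-lineage` (must sum to 1 within 1e-9).
#' @param mlme_fraction named numeric: per stage, probability that a cell
#'   is a planted MLME cell.
#' @param tert_positive_prob numeric with names `MLME`, `non_MLME`.
#' @param n_background_genes number of always-off background genes.
#' @param panel_sizes named integer: markers per lineage in the generated
#'   panel (master regulators are part of the EPI panel).
#' @param on_state,off_state numeric `c(meanlog, sdlog)` of the log-normal
#'   expression states.
#' @param dropout_prob probability an "on" value is zeroed.
#' @param bleed_through per-gene "on" probability for pre-lineage cells.
#' @param min_markers_per_lineage threshold stored in the generated panel.
#' @param dataset_id label stored in the cell metadata.
#' @return a validated object of class `sim_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    stages = data.frame(
      stage = c("E3", "E4", "E5.early", "E5", "E6", "E7"),
      n_embryos = c(15L, 16L, 12L, 16L, 16L, 13L),
      cells_per_embryo = c(6L, 12L, 16L, 20L, 22L, 24L)),
    lineage_mix = list(
      "E3"       = c(EPI = 0,    PE = 0,    TE = 0,    "pre-lineage" = 1),
      "E4"       = c(EPI = 0,    PE = 0,    TE = 0,    "pre-lineage" = 1),
      "E5.early" = c(EPI = 0.10, PE = 0.10, TE = 0.10, "pre-lineage" = 0.70),
      "E5"       = c(EPI = 0.20, PE = 0.15, TE = 0.40, "pre-lineage" = 0.25),
      "E6"       = c(EPI = 0.20, PE = 0.15, TE = 0.60, "pre-lineage" = 0.05),
      "E7"       = c(EPI = 0.20, PE = 0.15, TE = 0.65, "pre-lineage" = 0)),
    mlme_fraction = c("E3" = 0, "E4" = 0.05, "E5.early" = 0.15,
                      "E5" = 0.08, "E6" = 0.05, "E7" = 0.03),
    tert_positive_prob = c(MLME = 0.66, non_MLME = 0.51),
    n_background_genes = 200L,
    panel_sizes = c(EPI = 8L, PE = 8L, TE = 10L),
    on_state = c(meanlog = 4, sdlog = 1),
    off_state = c(meanlog = 0, sdlog = 1),
    dropout_prob = 0.2,
    bleed_through = 0.2,
    min_markers_per_lineage = 4L,
    dataset_id = "simulated") {
  cfg <- list(seed = as.integer(seed), stages = stages,
              lineage_mix = lineage_mix, mlme_fraction = mlme_fraction,
              tert_positive_prob = tert_positive_prob,
              n_background_genes = as.integer(n_background_genes),
              panel_sizes = panel_sizes, on_state = on_state,
              off_state = off_state, dropout_prob = dropout_prob,
              bleed_through = bleed_through,
              min_markers_per_lineage = as.integer(min_markers_per_lineage),
              dataset_id = dataset_id)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  st <- cfg$stages
  if (!is.data.frame(st) ||
      !all(c("stage", "n_embryos", "cells_per_embryo") %in% names(st)) ||
      nrow(st) == 0L)
    stopf("`stages` must be a data.frame with stage, n_embryos, cells_per_embryo")
  if (any(st$cells_per_embryo < 1L) || any(st$n_embryos < 1L))
    stopf("`n_embryos` and `cells_per_embryo` must be >= 1")
  bad <- setdiff(st$stage, STAGE_LEVELS)
  if (length(bad)) stopf("unknown stage(s) in config: %s", paste(bad, collapse = ", "))
  for (s in st$stage) {
    mix <- cfg$lineage_mix[[s]]
    if (is.null(mix)) stopf("no lineage_mix entry for stage %s", s)
    if (!setequal(names(mix), c("EPI", "PE", "TE", "pre-lineage")))
      stopf("lineage_mix for %s must cover EPI, PE, TE, pre-lineage", s)
    if (any(mix < 0) || any(mix > 1) || abs(sum(mix) - 1) > 1e-9)
      stopf("lineage_mix for %s must be a probability vector summing to 1", s)
    f <- cfg$mlme_fraction[[s]]
    if (is.null(f) || is.na(f) || f < 0 || f > 1)
      stopf("mlme_fraction for %s must be a probability", s)
  }
  tp <- cfg$tert_positive_prob
  if (!all(c("MLME", "non_MLME") %in% names(tp)) || any(tp < 0) || any(tp > 1))
    stopf("tert_positive_prob needs MLME and non_MLME probabilities in [0, 1]")
  if (cfg$n_background_genes < 1L) stopf("need at least one background gene")
  if (!all(c("EPI", "PE", "TE") %in% names(cfg$panel_sizes)))
    stopf("panel_sizes must name EPI, PE, TE")
  if (any(cfg$panel_sizes < cfg$min_markers_per_lineage))
    stopf("every panel size must be >= min_markers_per_lineage (%d)",
          cfg$min_markers_per_lineage)
  for (nm in c("dropout_prob", "bleed_through"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stopf("`%s` must be in [0, 1]", nm)
  for (nm in c("on_state", "off_state"))
    if (length(cfg[[nm]]) != 2L || cfg[[nm]][2L] <= 0)
      stopf("`%s` must be c(meanlog, sdlog) with sdlog > 0", nm)
  invisible(cfg)
}

#' Read a simulation config from YAML/JSON
#' @param path config file (`.yaml`/`.yml`/`.json`); keys override the
#'   [simulation_config()] defaults.
#' @return a `sim_config`.
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stopf("unsupported config extension '%s'", ext))
  if (!is.null(cfg$stages)) cfg$stages <- as.data.frame(cfg$stages)
  if (!is.null(cfg$lineage_mix))
    cfg$lineage_mix <- lapply(cfg$lineage_mix, function(v) unlist(v))
  if (!is.null(cfg$mlme_fraction)) cfg$mlme_fraction <- unlist(cfg$mlme_fraction)
  if (!is.null(cfg$tert_positive_prob))
    cfg$tert_positive_prob <- unlist(cfg$tert_positive_prob)
  do.call(simulation_config, cfg)
}

#' Marker panel implied by a simulation config
#'
#' The generated panel names its markers `EPI_M4 ...`, `PE_M1 ...`,
#' `TE_M1 ...`; the first three EPI slots are the master regulators NANOG,
#' POU5F1, SOX2, which therefore count toward the EPI tally.
#'
#' @param config a `sim_config`.
#' @return a [marker_panel()].
#' @export
simulated_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  masters <- c("NANOG", "POU5F1", "SOX2")
  ps <- config$panel_sizes
  epi_extra <- if (ps[["EPI"]] > 3L)
    sprintf("EPI_M%d", seq(4L, ps[["EPI"]])) else character()
  marker_panel(
    lineage_markers = list(
      EPI = c(masters, epi_extra)[seq_len(max(ps[["EPI"]], 3L))],
      PE = sprintf("PE_M%d", seq_len(ps[["PE"]])),
      TE = sprintf("TE_M%d", seq_len(ps[["TE"]]))),
    master_regulators = masters,
    min_markers_per_lineage = config$min_markers_per_lineage)
}

#' Simulate an embryo-structured single-cell expression dataset
#'
#' Generates a gene x cell matrix with planted ground truth. Cells are
#' organised as embryos within stages; each cell draws a lineage from the
#' stage's mixture and may be planted as an MLME cell with the stage's
#' MLME fraction. Marker "on/off" states follow the cell identity:
#' \itemize{
#'   \item planted MLME cells: every lineage marker and every master
#'     regulator is on (before dropout);
#'   \item non-MLME cells of lineage L: L's markers on, all other panels
#'     off;
#'   \item pre-lineage non-MLME cells: each marker independently on with
#'     the bleed-through probability;
#'   \item background genes: always off;
#'   \item TERT: expressed (on-state draw) only in telomerase-positive
#'     cells, zero otherwise, so TERT status is derivable from the matrix.
#' }
#' Values draw from the on/off log-normal states; dropout then zeroes
#' "on" draws independently. Sampling is reproducible: the master seed
#' spawns one deterministic sub-stream per stage.
#'
#' @param config a [simulation_config()].
#' @param panel optional [marker_panel()]; defaults to
#'   [simulated_panel()] of the config.
#' @return an object of class `sim_dataset`: list with `matrix` (an
#'   [expression_matrix()]), `truth` (data.frame: `cell_id`, `embryo_id`,
#'   `stage`, `lineage`, `is_mlme`, `is_tert_positive`), `panel`, `config`.
#' @export
simulate_dataset <- function(config, panel = simulated_panel(config)) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  stopifnot(inherits(panel, "marker_panel"))
  if (any(config$panel_sizes < panel$min_markers_per_lineage))
    stopf("panel sizes below the panel's min_markers_per_lineage")
  marker_genes <- panel_genes(panel)
  bg_genes <- sprintf("BG%04d", seq_len(config$n_background_genes))
  genes <- c(marker_genes, "TERT", bg_genes)
  lineages <- c("EPI", "PE", "TE", "pre-lineage")

  per_stage <- lapply(seq_len(nrow(config$stages)), function(i) {
    s <- config$stages$stage[i]
    n_emb <- config$stages$n_embryos[i]
    n_cells <- config$stages$cells_per_embryo[i]
    # deterministic per-stage sub-stream from the master seed
    stage_seed <- (config$seed + i * 99991L) %% 2147483647L
    with_seed(stage_seed, {
      total <- n_emb * n_cells
      embryo <- rep(sprintf("%s_emb%02d", s, seq_len(n_emb)), each = n_cells)
      cell_id <- sprintf("%s_emb%02d_c%03d",
                         s, rep(seq_len(n_emb), each = n_cells),
                         rep(seq_len(n_cells), n_emb))
      lin <- sample(lineages, total, replace = TRUE,
                    prob = config$lineage_mix[[s]][lineages])
      is_mlme <- stats::runif(total) < config$mlme_fraction[[s]]
      tp <- ifelse(is_mlme, config$tert_positive_prob[["MLME"]],
                   config$tert_positive_prob[["non_MLME"]])
      is_tert <- stats::runif(total) < tp

      # on/off indicator matrix, genes x cells
      on <- matrix(FALSE, length(genes), total,
                   dimnames = list(genes, cell_id))
      for (ln in c("EPI", "PE", "TE")) {
        m <- panel$lineage_markers[[ln]]
        on[m, lin == ln & !is_mlme] <- TRUE
      }
      pre <- lin == "pre-lineage" & !is_mlme
      if (any(pre)) {
        bl <- matrix(stats::runif(length(marker_genes) * sum(pre)) <
                       config$bleed_through,
                     length(marker_genes), sum(pre))
        on[marker_genes, pre] <- bl
      }
      on[c(marker_genes), is_mlme] <- TRUE
      on["TERT", ] <- is_tert

      vals <- matrix(stats::rlnorm(length(on),
                                   meanlog = config$off_state[[1L]],
                                   sdlog = config$off_state[[2L]]),
                     length(genes), total, dimnames = dimnames(on))
      n_on <- sum(on)
      if (n_on > 0L)
        vals[on] <- stats::rlnorm(n_on, meanlog = config$on_state[[1L]],
                                  sdlog = config$on_state[[2L]])
      vals["TERT", !is_tert] <- 0  # TERT status readable from the matrix
      if (config$dropout_prob > 0 && n_on > 0L) {
        drop <- stats::runif(n_on) < config$dropout_prob
        idx <- which(on)
        vals[idx[drop]] <- 0
      }
      list(values = vals,
           truth = data.frame(cell_id = cell_id, embryo_id = embryo,
                              stage = s, lineage = lin, is_mlme = is_mlme,
                              is_tert_positive = is_tert,
                              stringsAsFactors = FALSE))
    })
  })
  values <- do.call(cbind, lapply(per_stage, `[[`, "values"))
  truth <- do.call(rbind, lapply(per_stage, `[[`, "truth"))
  cell_meta <- data.frame(cell_id = truth$cell_id, embryo_id = truth$embryo_id,
                          stage = truth$stage, lineage = truth$lineage,
                          dataset_id = config$dataset_id,
                          stringsAsFactors = FALSE)
  mat <- expression_matrix(values, cell_meta = cell_meta)
  structure(list(matrix = mat, truth = truth, panel = panel, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d genes x %d cells, %d planted MLME, %d TERT+\n",
              nrow(x$matrix$values), ncol(x$matrix$values),
              sum(x$truth$is_mlme), sum(x$truth$is_tert_positive)))
  invisible(x)
}

#' Exact planted-truth rates per stage
#'
#' Tabulates the planted MLME and telomerase-positive fractions of a
#' simulated dataset by exact counting over the truth records — the oracle
#' side of parameter-recovery checks.
#'
#' @param dataset a `sim_dataset`.
#' @return data.frame with `stage`, `n_cells`, `n_mlme`, `mlme_fraction`,
#'   `n_tert_pos`, `tert_fraction`, in developmental-stage order.
#' @export
empirical_truth_rates <- function(dataset) {
  stopifnot(inherits(dataset, "sim_dataset"))
  tr <- dataset$truth
  stages <- intersect(STAGE_LEVELS, unique(tr$stage))
  rows <- lapply(stages, function(s) {
    t_s <- tr[tr$stage == s, ]
    n <- nrow(t_s)
    data.frame(stage = s, n_cells = n,
               n_mlme = sum(t_s$is_mlme),
               mlme_fraction = sum(t_s$is_mlme) / n,
               n_tert_pos = sum(t_s$is_tert_positive),
               tert_fraction = sum(t_s$is_tert_positive) / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a pair of datasets with planted concordant differential genes
#'
#' Generates two independent two-group expression datasets sharing a set of
#' planted concordantly regulated genes (the same direction in both
#' datasets, alternating up/down) on top of independent null noise genes —
#' the ground truth for testing cross-dataset consensus construction.
#' Expression is log-normal; planted genes are shifted by `effect_lnfold`
#' natural-log units in the positive group of both datasets.
#'
#' @param n_concordant number of planted concordant genes.
#' @param n_noise number of null genes (independent in both datasets).
#' @param n_pos,n_neg group sizes within each dataset.
#' @param effect_lnfold natural-log shift of planted genes, default 2.
#' @param seed integer seed.
#' @return list of two elements `A` and `B`, each a list with `matrix`
#'   (an [expression_matrix()]), `group_pos`, `group_neg`; plus `planted`
#'   (data.frame `gene_id`, `direction`).
#' @export
simulate_consensus_pair <- function(n_concordant = 100L, n_noise = 400L,
                                    n_pos = 40L, n_neg = 60L,
                                    effect_lnfold = 2, seed = 1L) {
  if (n_concordant < 1L || n_noise < 0L) stopf("invalid gene counts")
  genes <- c(sprintf("CON%04d", seq_len(n_concordant)),
             if (n_noise > 0L) sprintf("NULL%04d", seq_len(n_noise)))
  direction <- rep(c("up", "down"), length.out = n_concordant)
  make_one <- function(sub_seed, tag) {
    with_seed(sub_seed, {
      n <- n_pos + n_neg
      cells <- sprintf("%s_c%03d", tag, seq_len(n))
      pos <- cells[seq_len(n_pos)]
      neg <- setdiff(cells, pos)
      shift <- c(up = effect_lnfold, down = -effect_lnfold)[direction]
      mean_pos <- c(shift + 1, rep(1, n_noise))
      mean_neg <- c(rep(1, n_concordant), rep(1, n_noise))
      vals <- cbind(
        matrix(stats::rlnorm(length(genes) * n_pos, meanlog = mean_pos, sdlog = 1),
               length(genes), n_pos),
        matrix(stats::rlnorm(length(genes) * n_neg, meanlog = mean_neg, sdlog = 1),
               length(genes), n_neg))
      dimnames(vals) <- list(genes, cells)
      list(matrix = expression_matrix(vals), group_pos = pos, group_neg = neg)
    })
  }
  list(A = make_one((seed * 2L + 11L) %% 2147483647L, "A"),
       B = make_one((seed * 2L + 12L) %% 2147483647L, "B"),
       planted = data.frame(gene_id = genes[seq_len(n_concordant)],
                            direction = direction, stringsAsFactors = FALSE))
}
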