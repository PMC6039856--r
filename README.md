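# mlmescreen

Digital screening of single-cell expression data of preimplantation
embryos for telomerase-positive **multi-lineage markers-expressing
(MLME) cells** — candidate multi-lineage precursors that co-express
markers of all three blastocyst lineages (epiblast, primitive endoderm,
trophectoderm) together with the pluripotency master regulators NANOG,
POU5F1 and SOX2.

The package is aimed at analysts of embryonic single-cell RNA-seq (or
qPCR-style) matrices who want a tested, scriptable implementation of the
whole screening pipeline:

* **Binary marker calling** — a marker is expressed in a cell when its
  value strictly exceeds the gene's median over the cell population
  (`call_positive(rule = "population_median")`), or a fixed threshold for
  discovery-style data.
* **The MLME rule** — a cell is MLME iff it is positive for ≥ 4 markers
  of *each* lineage panel and for *every* master regulator
  (`call_mlme()`).
* **Prevalence tables with exact hypergeometric statistics** — for a
  stratum of n cells with k MLME inside a background of N cells with K
  MLME, `hypergeom_enrichment()` computes, for X ~ Hypergeometric(N, K, n),
  the enrichment tail P(X ≥ k), the depletion tail P(X ≤ k), or the point
  probability P(X = k) — the convention under which published prevalence
  tables reproduce to printed precision (`build_prevalence_report()`,
  `rank_bands()`).
* **HPAT lincRNA phenotyping** — segregation of blastocyst cells by the
  (HPAT21, HPAT2, HPAT15) call triple into spHPAT21 / dpHPAT15 /
  HPAT2pos populations (`classify_hpat()`), with Fisher and
  Kruskal–Wallis comparisons (`fisher_two_tailed()`, `kruskal_wallis()`).
* **Signature scoring** — log2 mean-ratio signatures
  w_g = log2((x̄_num + c)/(x̄_den + c)) (`derive_ratio_signature()`),
  per-cell Pearson correlation scores on centred log profiles
  (`score_cells()`, strict cutoffs 0.4/0.5/0.55), rank-sum refinement to
  the differential gene subset (`refine_signature()`), and the minimal
  top-scoring selection covering every pre-segregation stage
  (`select_top_scoring()`).
* **Cross-dataset consensus** — genes concordantly significant in two
  datasets (`differential_genes()`, `concordant_consensus()`,
  `concordance_correlation()`) with maternal/embryonic origin breakdowns
  (`origin_summary()`).
* **Spectral gene filtering** — the heatmap-preparation transform
  (log2 above 2, halve at or below 2, plus tie-breaking jitter) and
  iterative removal of the gene with the smallest eigenvalue-weighted
  contribution to the 95%-variance components, halting at a 10% (or 7%)
  relative change of the eigenvalue-spectrum entropy
  (`transform_fpkm()`, `gene_contributions()`, `iterative_filter()`).
* **Emergence timelines** — per-stage MLME fractions with Wilson
  intervals and the per-embryo emergence probability
  1 − (1 − f)^n (`stage_timeline()`, `emergence_probability()`).
* **A seeded synthetic-data generator** (`simulate_dataset()`) producing
  embryo-structured matrices with planted MLME / TERT+ ground truth, so
  every stage of the pipeline is testable end to end.

See the vignette (`vignettes/mlme-screening.Rmd`) for the model
assumptions, parameter conventions and design decisions.

## Worked example

```r
library(mlmescreen)

cfg <- simulation_config(seed = 42, dropout_prob = 0)
ds  <- simulate_dataset(cfg)
ds
#> <sim_dataset> 227 genes x 1458 cells, 102 planted MLME, 739 TERT+

calls <- call_positive(ds$matrix, rule = "population_median")
mlme  <- call_mlme(calls, ds$panel)
tert  <- ds$matrix$values["TERT", ] > 0

build_prevalence_report(
  mlme,
  strata = list(
    "all cells"     = names(mlme),
    "TERT positive" = list(cells = names(mlme)[tert],  background = names(mlme)),
    "TERT negative" = list(cells = names(mlme)[!tert], background = names(mlme))))
#>           label n_total n_positive percent p_value                   test
#> 1     all cells    1458        106     7.3  1.0000 hypergeometric (point)
#> 2 TERT positive     739         62     8.4  0.0201 hypergeometric (point)
#> 3 TERT negative     719         44     6.1  0.0201 hypergeometric (point)
```

106 of 1,458 cells satisfy the digital MLME rule (7.3%); the MLME
phenotype is more frequent among TERT+ cells (8.4%) than TERT− cells
(6.1%). The point probability is printed-table evidence; note it is the
same number for a subset and its complement. For a calibrated one-sided
test use the upper tail:

```r
hypergeom_enrichment(
  contingency_counts(N = length(mlme), K = sum(mlme),
                     n = sum(tert), k = sum(mlme & tert)), tail = "upper")
#> [1] 0.05815181
```

(borderline here by design: the generator plants the modest MLME/TERT
association implied by the published conditional rates, 0.66 vs 0.51).
Score cells against an MLME signature and estimate the emergence
timeline:

```r
sig <- derive_ratio_signature(ds$matrix,
  numerator_cells   = names(mlme)[mlme],
  denominator_cells = names(mlme)[!mlme],
  numerator_label = "MLME", denominator_label = "non-MLME")
scores <- score_cells(ds$matrix, sig, cutoff = 0.5)
head(scores[order(scores$rank), ], 3)
#>            cell_id     score rank is_mlme_like
#> 710  E5_emb12_c016 0.8563189    1         TRUE
#> 930  E6_emb07_c004 0.8523780    2         TRUE
#> 1091 E6_emb14_c011 0.8491338    3         TRUE

stage_timeline(mlme, ds$matrix$cell_meta,
  c(E3 = 8, E4 = 16, "E5.early" = 30, E5 = 60, E6 = 100, E7 = 150))
#>      stage n_cells n_mlme      f ci_low ci_high cells_per_embryo p_emerge
#> 1       E3      90      0 0.0000 0.0000  0.0409                8    0.000
#> 2       E4     192     11 0.0573 0.0323  0.0997               16    0.611
#> 3 E5.early     192     33 0.1719 0.1251  0.2315               30    0.997
#> 4       E5     320     26 0.0813 0.0560  0.1164               60    0.994
#> 5       E6     352     19 0.0540 0.0348  0.0828               100   0.996
#> 6       E7     312     17 0.0545 0.0343  0.0855               150   1.000
```

No MLME cell is called at E3 (Wilson interval includes 0); the phenotype
emerges at E4, peaks in early E5 (17.2% of cells) and persists through
E7 — at typical embryo sizes, essentially every embryo from early E5
onward is expected to contain at least one MLME cell.

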