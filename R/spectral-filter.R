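#' Piecewise FPKM transform with tie-breaking jitter
#'
#' The heatmap-preparation transform: values above 2 are log2-transformed,
#' values at or below 2 are halved (a continuous piecewise map: both
#' branches give 1 at x = 2), then a negligible uniform random value in
#' (0, 1e-5) is added to every entry to break ties in downstream
#' clustering. The jitter is drawn once per call under `jitter_seed`, so a
#' dataset gets a fixed, reproducible perturbation.
#'
#' @param values non-negative numeric matrix (genes x cells).
#' @param jitter_seed integer seed for the jitter draw.
#' @return transformed matrix of the same shape and dimnames.
#' @export
#' @examples
#' m <- matrix(c(0, 2, 8, 64), 2, dimnames = list(c("a", "b"), c("x", "y")))
#' transform_fpkm(m, jitter_seed = 1) - c(0, 1, 3, 6) < 1e-5  # all TRUE
transform_fpkm <- function(values, jitter_seed = 0L) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (any(values < 0)) stopf("negative values are not allowed")
  out <- ifelse(values > 2, log2(values), values / 2)
  jit <- with_seed(jitter_seed, stats::runif(length(out), 0, 1e-5))
  out <- out + jit
  dim(out) <- dim(values)
  dimnames(out) <- dimnames(values)
  out
}

#' Eigenvalue spectrum of the gene-gene covariance matrix
#' @keywords internal
cov_spectrum <- function(mat) {
  # cells are observations, genes are variables; no scaling
  C <- stats::cov(t(mat))
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)  # clamp numerical negatives
  list(values = lam, vectors = e$vectors)
}

#' Shannon entropy of the normalised eigenvalue spectrum
#'
#' Eigenvalues of the gene-gene covariance matrix are normalised to sum to
#' one and their Shannon entropy (natural log) is returned; it lies in
#' [0, ln(rank)]. This is the "entropy of the dataset" tracked by
#' [iterative_filter()].
#'
#' @param mat transformed genes x cells matrix (>= 2 cells).
#' @return entropy in nats.
#' @export
spectrum_entropy <- function(mat) {
  lam <- cov_spectrum(mat)$values
  tot <- sum(lam)
  if (tot <= 0) stopf("zero total variance; cannot define spectrum entropy")
  p <- lam / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-gene contribution to the leading variance components
#'
#' Eigendecomposes the gene-gene covariance matrix (cells as observations),
#' takes the smallest prefix J of descending eigenvalues whose cumulative
#' variance fraction reaches `var_fraction` (default 95%), and scores each
#' gene by its eigenvalue-weighted squared loadings over J:
#' `contribution_g = sum_{j in J} lambda_j * v_{gj}^2`. By orthonormality
#' the contributions sum to `sum_{j in J} lambda_j`. With
#' `weighted = FALSE` the plain squared loadings are summed instead.
#'
#' @param mat transformed genes x cells matrix with >= 2 genes and
#'   >= 2 cells.
#' @param var_fraction cumulative variance fraction defining the component
#'   prefix, default 0.95.
#' @param weighted weight squared loadings by their eigenvalue (default
#'   TRUE).
#' @return named non-negative vector of per-gene contributions, with
#'   attribute `n_components` (|J|).
#' @export
gene_contributions <- function(mat, var_fraction = 0.95, weighted = TRUE) {
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stopf("need at least 2 genes and 2 cells")
  sp <- cov_spectrum(mat)
  tot <- sum(sp$values)
  if (tot <= 0) stopf("zero total variance; contributions undefined")
  J <- seq_len(which(cumsum(sp$values) / tot >= var_fraction)[1L])
  V2 <- sp$vectors[, J, drop = FALSE]^2
  contrib <- if (weighted) drop(V2 %*% sp$values[J]) else rowSums(V2)
  structure(stats::setNames(contrib, rownames(mat)), n_components = length(J))
}

#' Iterative removal of least-informative genes with an entropy halt
#'
#' Starting from a transformed matrix, repeatedly removes the single gene
#' with the smallest contribution to the variance captured by the
#' components accounting for 95% of variance (ties broken by lexicographic
#' gene id), tracking the Shannon entropy of the covariance eigenvalue
#' spectrum of the remaining genes. Removal halts when the relative
#' entropy change versus the initial spectrum reaches
#' `entropy_change_threshold`; the gene whose removal first crossed the
#' threshold is restored, so the retained set is the last one inside the
#' entropy budget. The published procedure used a 10% change for large
#' datasets and 7% for a small one.
#'
#' @param mat transformed genes x cells matrix (use [transform_fpkm()]
#'   first), >= 3 genes.
#' @param entropy_change_threshold relative entropy change in (0, 1) that
#'   halts removal; default 0.10.
#' @param var_fraction,weighted passed to [gene_contributions()].
#' @return list with `retained` (character vector of surviving gene ids,
#'   in input order) and `trace` (data.frame with one row per attempted
#'   removal: `iteration`, `gene_id`, `contribution`, `entropy_after`,
#'   `rel_entropy_change`, `n_components`, `removed`; the final row with
#'   `removed = FALSE`, if present, is the restored gene).
#' @export
iterative_filter <- function(mat, entropy_change_threshold = 0.10,
                             var_fraction = 0.95, weighted = TRUE) {
  if (!is.matrix(mat) || nrow(mat) < 3L)
    stopf("need a matrix with at least 3 genes")
  if (is.null(rownames(mat))) stopf("matrix must have gene ids as rownames")
  if (entropy_change_threshold <= 0 || entropy_change_threshold >= 1)
    stopf("`entropy_change_threshold` must be in (0, 1)")
  H0 <- spectrum_entropy(mat)
  if (H0 <= 0) stopf("initial spectrum entropy is zero; filtering undefined")
  current <- rownames(mat)
  trace <- list()
  it <- 0L
  while (length(current) > 2L) {
    it <- it + 1L
    contrib <- gene_contributions(mat[current, , drop = FALSE],
                                  var_fraction = var_fraction,
                                  weighted = weighted)
    victim <- current[order(contrib, current)][1L]
    remaining <- setdiff(current, victim)
    Ht <- spectrum_entropy(mat[remaining, , drop = FALSE])
    rel <- abs(Ht - H0) / H0
    crossed <- rel >= entropy_change_threshold
    trace[[it]] <- data.frame(
      iteration = it, gene_id = victim,
      contribution = unname(contrib[victim]),
      entropy_after = Ht, rel_entropy_change = rel,
      n_components = attr(contrib, "n_components"),
      removed = !crossed, stringsAsFactors = FALSE)
    if (crossed) break  # restore: `current` keeps the victim
    current <- remaining
  }
  list(retained = rownames(mat)[rownames(mat) %in% current],
       trace = do.call(rbind, trace) %||%
         data.frame(iteration = integer(), gene_id = character(),
                    contribution = numeric(), entropy_after = numeric(),
                    rel_entropy_change = numeric(), n_components = integer(),
                    removed = logical(), stringsAsFactors = FALSE))
}
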