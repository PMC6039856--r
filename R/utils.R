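# Internal helpers shared across modules.

#' Round half away from zero (for non-negative values)
#'
#' Prevalence tables print percents rounded half-up to one decimal;
#' base [round()] rounds half to even, so 0.25 would print as 0.2.
#'
#' @param x non-negative numeric vector.
#' @param digits decimal places, default 0.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Format a percent to one decimal the way prevalence tables print it
#' @keywords internal
format_percent1 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.1f", round_half_up(x, 1)))
}

#' Format a p-value: scientific notation below 1e-3, plain otherwise
#' @keywords internal
format_pvalue <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("NA")
    if (pi < 1e-3) sprintf("%.4E", pi) else sprintf("%.6g", pi)
  }, character(1))
}

#' Evaluate code under a temporary RNG state
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so library functions do not perturb user simulations.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
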