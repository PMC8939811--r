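# Internal helpers shared across modules.

# Smallest p-value carried through probit transforms; matches the truncation
# applied before plotting extreme set scores.
.P_FLOOR <- 1e-300
# Upper clip so probit(1 - p) stays finite when p == 1.
.P_CEIL_OFFSET <- 1e-16

#' Derive a child seed from a master seed and a stream name
#'
#' Every stochastic operation in the package draws its seed from a named
#' stream, so the panel, the architecture, the summary statistics and each
#' EPVP permutation are independently reproducible from one master seed.
#'
#' @param master Integer master seed.
#' @param name Character stream name, e.g. `"panel"` or `"epvp:3"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(master) %% 2147483629 * 48271 + h) %% 2147483629)
}

clip_p <- function(p) pmin(pmax(p, .P_FLOOR), 1)

# probit(1 - p) with the documented clipping at both ends.
probit_upper <- function(p) {
  stats::qnorm(pmax(pmin(p, 1 - .P_CEIL_OFFSET), .P_FLOOR), lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1. Wrapper around [stats::p.adjust()] so a single definition is
#' used everywhere genes or gene sets are adjusted.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(is.numeric(pvals), all(pvals > 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Probit-scale gene-set score
#'
#' Transforms an FDR-adjusted upper-tail p-value to a Z-statistic via
#' `qnorm(1 - p_fdr)`. Extreme p-values are truncated to 1e-300; p = 1 is
#' offset by 1e-16 so the score stays finite.
#'
#' @param p_fdr Numeric vector of FDR-adjusted upper-tail p-values in (0, 1].
#' @return Numeric vector of probit-scale scores.
#' @export
probit_setscore <- function(p_fdr) {
  stopifnot(all(p_fdr > 0 & p_fdr <= 1))
  probit_upper(p_fdr)
}

# Point-in-interval test under the internal 0-based half-open convention:
# a 1-based position `pos` occupies [pos - 1, pos), so it is inside [s, e)
# iff s < pos <= e.
pos_in_interval <- function(pos, start, end) pos > start & pos <= end

# Per-row union length of a set of 0-based half-open intervals.
union_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  sum(IRanges::width(ir))
}

# Merge overlapping 0-based half-open intervals; returns a tibble(start, end).
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  tibble::tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
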