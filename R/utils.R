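# Internal helpers shared across modules.

#' Fractional ranks on (0, 1]
#'
#' Ranks non-missing values ascending with average ranks for ties, then divides
#' by the number of non-missing values so that the largest value maps to 1 and
#' ranks live on (0, 1]. Missing values stay missing ("unranked").
#'
#' @param x Numeric vector, possibly with `NA`.
#' @return Numeric vector of the same length; `NA` where `x` is `NA`.
#' @examples
#' fractional_rank(c(10, 20, 30))  # 1/3, 2/3, 1
#' fractional_rank(c(5, 5))        # 0.75, 0.75
#' @export
fractional_rank <- function(x) {
  if (length(x) == 0L || all(is.na(x))) {
    stop("fractional_rank() needs at least one non-missing value")
  }
  n <- sum(!is.na(x))
  rank(x, na.last = "keep", ties.method = "average") / n
}

#' Distance between genome positions, wrapping on circular contigs
#'
#' `d(a, b) = min(|a - b|, L - |a - b|)` when circular, `|a - b|` otherwise.
#'
#' @param a,b Positions (vectors recycle).
#' @param length_bp Contig length.
#' @param circular Logical.
#' @return Numeric distances.
#' @export
wrap_distance <- function(a, b, length_bp, circular = TRUE) {
  d <- abs(a - b)
  if (circular) pmin(d, length_bp - d) else d
}

#' Protein identifiers used by the pulldown generator
#'
#' @param n Number of proteins.
#' @return Character vector `P0001 ... P<n>`.
#' @export
protein_ids <- function(n) sprintf("P%04d", seq_len(n))

#' Derive a per-stage seed from one pipeline seed
#'
#' Stage seeds are fanned out from a single user seed with fixed offsets so
#' every stochastic stage is independently reproducible (kept below 2^31).
#'
#' @param seed Integer seed.
#' @param stage One of `"pulldown"`, `"chip"`, `"counts"`, `"analysis"`.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  offsets <- c(pulldown = 101L, chip = 202L, counts = 303L, analysis = 404L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 2000000000L) + offsets[[stage]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
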