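# Combined-rank scoring of crosslink-IP-MS pulldowns. A protein is scored per
# replicate by three fractional ranks over the normalized log2 abundances:
#   abundance   -- its abundance in the target pulldown;
#   specificity -- target minus nonspecific pulldown;
#   enrichment  -- target minus unfractionated lysate;
# summed and rescaled to [0, 1] (the arithmetic mean of the three). Proteins
# consistently high across replicates are called interactors at a top-quantile
# threshold (default top 2%).

#' Normalize raw MS intensities
#'
#' Each sample column is normalized to its overall abundance (column total)
#' and to protein molecular weight, then log2-transformed:
#' `log2(raw / sum(raw) / mw)`. Zero intensities become explicit missing
#' values.
#'
#' @param raw Numeric matrix (proteins x samples) of raw intensities (>= 0);
#'   column names identify samples.
#' @param mw_kda Positive numeric vector of molecular weights (kDa), one per
#'   protein.
#' @return Numeric matrix of normalized log2 abundances with `NA` where the
#'   raw intensity was zero.
#' @export
normalize_intensities <- function(raw, mw_kda) {
  raw <- as.matrix(raw)
  if (any(raw < 0, na.rm = TRUE)) stop("raw intensities must be >= 0")
  if (length(mw_kda) != nrow(raw) || any(mw_kda <= 0)) {
    stop("mw_kda must be positive, one value per protein")
  }
  totals <- colSums(raw, na.rm = TRUE)
  if (any(totals == 0)) {
    stop("sample column(s) with all-zero intensities: ",
         paste(colnames(raw)[totals == 0], collapse = ", "))
  }
  norm <- log2(sweep(raw, 2, totals, "/") / mw_kda)
  norm[!is.finite(norm)] <- NA_real_
  norm
}

# Impute a column floor for missing control values: absence from a control
# sample is evidence of specificity, not missingness at random.
impute_floor <- function(x, fallback, offset = 0.1) {
  floor_val <- if (all(is.na(x))) min(fallback, na.rm = TRUE) - offset
               else min(x, na.rm = TRUE) - offset
  ifelse(is.na(x), floor_val, x)
}

#' Component and combined ranks for one replicate
#'
#' Computes the abundance, specificity and enrichment fractional ranks over
#' the proteins observed in the target pulldown, and their combined 0-1 score.
#' Proteins missing in the target pulldown are excluded from the replicate.
#' Missing nonspecific or lysate values are imputed at that column's observed
#' minimum minus 0.1 log2 units before differencing.
#'
#' @param target,nonspecific,lysate Normalized log2 abundance vectors for one
#'   replicate (equal length, `NA` = missing), as from
#'   [normalize_intensities()].
#' @param protein Optional protein ids (default positional).
#' @return `data.frame` with one row per protein observed in the target:
#'   `protein`, `abundance_rank`, `specificity_rank`, `enrichment_rank`,
#'   `combined_rank`.
#' @export
component_ranks <- function(target, nonspecific, lysate,
                            protein = seq_along(target)) {
  stopifnot(length(nonspecific) == length(target),
            length(lysate) == length(target),
            length(protein) == length(target))
  keep <- !is.na(target)
  if (!any(keep)) {
    return(data.frame(protein = character(), abundance_rank = numeric(),
                      specificity_rank = numeric(), enrichment_rank = numeric(),
                      combined_rank = numeric()))
  }
  spec_diff <- target - impute_floor(nonspecific, fallback = target)
  enr_diff <- target - impute_floor(lysate, fallback = target)
  out <- data.frame(
    protein = as.character(protein[keep]),
    abundance_rank = fractional_rank(target[keep]),
    specificity_rank = fractional_rank(spec_diff[keep]),
    enrichment_rank = fractional_rank(enr_diff[keep]),
    stringsAsFactors = FALSE
  )
  out$combined_rank <- combine_ranks(out$abundance_rank, out$specificity_rank,
                                     out$enrichment_rank)
  out
}

#' Combine three component ranks into a 0-1 score
#'
#' The overall score is the sum of the three fractional ranks rescaled to
#' `[0, 1]`, i.e. their arithmetic mean.
#'
#' @param abundance_rank,specificity_rank,enrichment_rank Fractional ranks in
#'   (0, 1].
#' @return Numeric combined rank in (0, 1].
#' @export
combine_ranks <- function(abundance_rank, specificity_rank, enrichment_rank) {
  (abundance_rank + specificity_rank + enrichment_rank) / 3
}

#' Rank a multi-replicate pulldown table
#'
#' Applies [normalize_intensities()] column-wise and [component_ranks()] per
#' replicate, then aggregates: a protein's aggregate combined rank is the
#' minimum across replicates, and only proteins observed (non-missing target)
#' in every replicate receive one.
#'
#' @param table Wide data.frame with columns `protein`, `mw_kda` and
#'   `<role>_<rep>` raw intensity columns for roles
#'   `target`/`nonspecific`/`lysate`, as produced by [gen_pulldown()].
#' @param n_replicates Number of replicates (column triples) to use.
#' @return A list: `per_replicate` (list of [component_ranks()] tables) and
#'   `aggregate` (data.frame `protein`, `n_present`, `combined_rank` with `NA`
#'   for proteins absent from >= 1 replicate).
#' @export
rank_pulldown <- function(table, n_replicates) {
  roles <- c("target", "nonspecific", "lysate")
  cols <- as.vector(outer(roles, seq_len(n_replicates), paste, sep = "_"))
  if (!all(c("protein", "mw_kda", cols) %in% names(table))) {
    stop("table must have protein, mw_kda and <role>_<rep> columns for ",
         n_replicates, " replicates")
  }
  raw <- as.matrix(table[, cols, drop = FALSE])
  rownames(raw) <- table$protein
  norm <- normalize_intensities(raw, table$mw_kda)

  per_rep <- lapply(seq_len(n_replicates), function(r) {
    component_ranks(norm[, paste0("target_", r)],
                    norm[, paste0("nonspecific_", r)],
                    norm[, paste0("lysate_", r)],
                    protein = table$protein)
  })
  names(per_rep) <- paste0("replicate_", seq_len(n_replicates))

  combined <- sapply(per_rep, function(tab) {
    tab$combined_rank[match(table$protein, tab$protein)]
  })
  combined <- matrix(combined, nrow = nrow(table))
  n_present <- rowSums(!is.na(combined))
  agg <- ifelse(n_present == n_replicates,
                apply(combined, 1, min), NA_real_)
  ranked <- n_present > 0
  list(per_replicate = per_rep,
       aggregate = data.frame(protein = table$protein[ranked],
                              n_present = n_present[ranked],
                              combined_rank = agg[ranked],
                              stringsAsFactors = FALSE))
}

#' Call interactors at a top-quantile combined-rank threshold
#'
#' Proteins present in every replicate whose aggregate combined rank lies in
#' the top `quantile` fraction of ranked proteins are called, sorted by rank
#' descending. The number of calls is `floor(n_ranked * quantile)` (ties
#' broken by rank then protein id).
#'
#' @param aggregate The `aggregate` table from [rank_pulldown()].
#' @param quantile Top fraction to call, in (0, 1); default 0.02 (top 2%).
#' @param n_replicates Number of replicates required for presence.
#' @return `data.frame` `protein`, `combined_rank`, `n_present`, `called`
#'   (calls first, rank-descending).
#' @export
call_interactors <- function(aggregate, quantile = 0.02,
                             n_replicates = max(aggregate$n_present)) {
  if (!is.numeric(quantile) || quantile <= 0 || quantile >= 1) {
    stop("quantile must lie in (0, 1)")
  }
  n_ranked <- nrow(aggregate)
  k <- floor(n_ranked * quantile)
  eligible <- aggregate$n_present >= n_replicates & !is.na(aggregate$combined_rank)
  ord <- order(-ifelse(eligible, aggregate$combined_rank, -Inf),
               aggregate$protein)
  out <- aggregate[ord, , drop = FALSE]
  out$called <- eligible[ord] & seq_len(n_ranked) <= k
  rownames(out) <- NULL
  out
}

#' Venn region counts across replicate call sets
#'
#' Counts the proteins in every exclusive intersection region of the given
#' call sets (as in a replicate-overlap Venn diagram).
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return `data.frame` with one row per non-empty membership pattern:
#'   `region` (e.g. `"rep1&rep3"`) and `count`; counts sum to the union size.
#' @export
venn_overlap <- function(sets) {
  if (length(sets) < 2) stop("venn_overlap() needs >= 2 sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, names(sets)))
  region <- apply(membership, 1, function(m) paste(names(sets)[m], collapse = "&"))
  counts <- table(region)
  data.frame(region = names(counts), count = as.integer(counts),
             stringsAsFactors = FALSE)
}
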