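# Differential expression across a strain x treatment factorial design:
# filtered strand-specific read counting, length normalization with a
# generalized-log variance-stabilizing transform, per-gene two-way ANOVA,
# Benjamini-Hochberg correction, fold-change filtering and promoter
# cross-referencing.

#' Count reads per gene with quality, overlap and strand filters
#'
#' A read is assigned to a gene iff its mapping quality is above 10 (strict),
#' the overlapped fraction of the read length is above 0.5 (strict), and its
#' strand is compatible with the library orientation (`"reverse"`: read
#' strand opposite the gene strand, typical of directional dUTP libraries;
#' `"forward"`: same strand; `"unstranded"`: any). Reads satisfying the rule
#' for two or more genes are discarded as ambiguous.
#'
#' @param reads `data.frame` with columns `start`, `end` (0-based half-open),
#'   `strand` (`"+"`/`"-"`), `mapq`.
#' @param genes `data.frame` with columns `gene`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @param strandedness `"reverse"` (default), `"forward"` or `"unstranded"`.
#' @param min_mapq,min_overlap Strict lower bounds on mapping quality and
#'   overlap fraction.
#' @return Named integer vector of counts, one per gene (in `genes` order).
#' @export
count_reads <- function(reads, genes, strandedness = "reverse",
                        min_mapq = 10, min_overlap = 0.5) {
  strandedness <- match.arg(strandedness,
                            c("reverse", "forward", "unstranded"))
  counts <- stats::setNames(integer(nrow(genes)), genes$gene)
  keep <- reads$mapq > min_mapq
  reads <- reads[keep, , drop = FALSE]
  if (nrow(reads) == 0) return(counts)

  r_rng <- IRanges::IRanges(start = reads$start + 1L, end = reads$end)
  g_rng <- IRanges::IRanges(start = genes$start + 1L, end = genes$end)
  hits <- IRanges::findOverlaps(r_rng, g_rng)
  ov <- IRanges::width(IRanges::pintersect(
    r_rng[S4Vectors::queryHits(hits)], g_rng[S4Vectors::subjectHits(hits)]))
  frac <- ov / IRanges::width(r_rng)[S4Vectors::queryHits(hits)]
  strand_ok <- switch(strandedness,
    unstranded = TRUE,
    forward = reads$strand[S4Vectors::queryHits(hits)] ==
      genes$strand[S4Vectors::subjectHits(hits)],
    reverse = reads$strand[S4Vectors::queryHits(hits)] !=
      genes$strand[S4Vectors::subjectHits(hits)])
  pass <- frac > min_overlap & strand_ok

  q <- S4Vectors::queryHits(hits)[pass]
  s <- S4Vectors::subjectHits(hits)[pass]
  n_genes_hit <- table(q)
  unambiguous <- q %in% as.integer(names(n_genes_hit)[n_genes_hit == 1])
  tab <- table(s[unambiguous])
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts
}

#' Length normalization and generalized-log variance stabilization
#'
#' Counts are scaled to per-kb rates, divided by median-ratio size factors
#' (the median, over genes with no zero, of each sample's ratio to the
#' gene-wise geometric mean), and stabilized with
#' `glog2(x, c) = log2((x + sqrt(x^2 + c^2)) / 2)`, a generalized log that is
#' finite at zero (`log2(c/2)`) and converges to `log2(x)` for `x >> c`. The
#' tuning constant `c` is the 25th percentile of the positive normalized
#' values.
#'
#' @param counts Integer matrix (genes x samples).
#' @param gene_lengths Gene lengths in bp (> 0), one per row.
#' @return A list: `mat` (stabilized matrix), `size_factors`, `glog_c`.
#' @export
normalize_vst <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (length(gene_lengths) != nrow(counts)) {
    stop("gene_lengths must have one entry per gene")
  }
  if (any(gene_lengths <= 0)) stop("gene with zero or negative length")
  x0 <- counts / (gene_lengths / 1000)
  logs <- log(x0)
  finite <- rowSums(is.finite(logs)) == ncol(x0)   # genes with no zero
  if (!any(finite)) stop("no gene observed in all samples; cannot size-normalize")
  loggeo <- rowMeans(logs[finite, , drop = FALSE])
  size_factors <- apply(logs[finite, , drop = FALSE], 2, function(lg) {
    exp(stats::median(lg - loggeo))
  })
  x <- sweep(x0, 2, size_factors, "/")
  c0 <- stats::quantile(x[x > 0], 0.25, names = FALSE)
  list(mat = glog2(x, c0), size_factors = size_factors, glog_c = c0)
}

#' Generalized log2 transform
#'
#' @param x Non-negative values.
#' @param c Tuning constant (> 0).
#' @return `log2((x + sqrt(x^2 + c^2)) / 2)`.
#' @export
glog2 <- function(x, c) log2((x + sqrt(x^2 + c^2)) / 2)

#' Per-gene two-way factorial ANOVA
#'
#' Fits `value ~ strain * treatment` gene by gene and returns F statistics
#' and p-values for the strain, treatment and interaction terms (sequential
#' sums of squares; identical to the classical balanced decomposition when
#' the design is balanced), plus a per-gene overall p: the minimum of the
#' three effect p-values Bonferroni-adjusted by 3. All genes share one design,
#' so the residual projections are computed once via QR and applied to every
#' gene at once.
#'
#' @param mat Numeric matrix (genes x samples) of stabilized expression.
#' @param strain,treatment Factors (or character vectors), one per sample.
#' @return `data.frame` with per-gene `F_strain`, `p_strain`, `F_treatment`,
#'   `p_treatment`, `F_interaction`, `p_interaction`, `p_overall`.
#' @export
factorial_anova <- function(mat, strain, treatment) {
  mat <- as.matrix(mat)
  n <- ncol(mat)
  stopifnot(length(strain) == n, length(treatment) == n)
  strain <- factor(strain)
  treatment <- factor(treatment)
  if (any(table(strain, treatment) < 1)) {
    stop("every strain x treatment cell needs at least one sample")
  }
  with_interaction <- TRUE
  if (all(table(strain, treatment) == 1)) {
    warning("no replication: interaction term dropped")
    with_interaction <- FALSE
  }

  Y <- t(mat)
  rss <- function(X) {
    qrX <- qr(X)
    colSums(qr.resid(qrX, Y)^2)
  }
  X0 <- model.matrix(~1, data.frame(strain))
  X1 <- model.matrix(~strain)
  X2 <- model.matrix(~strain + treatment)
  X3 <- if (with_interaction) model.matrix(~strain * treatment) else X2
  rss0 <- rss(X0); rss1 <- rss(X1); rss2 <- rss(X2); rss3 <- rss(X3)

  df_s <- nlevels(strain) - 1L
  df_t <- nlevels(treatment) - 1L
  df_i <- if (with_interaction) df_s * df_t else 0L
  df_res <- n - (1L + df_s + df_t + df_i)
  if (df_res < 1) stop("no residual degrees of freedom")
  mse <- rss3 / df_res

  f_p <- function(ss, df) {
    f <- (ss / df) / mse
    list(f = f, p = stats::pf(f, df, df_res, lower.tail = FALSE))
  }
  s <- f_p(rss0 - rss1, df_s)
  t_ <- f_p(rss1 - rss2, df_t)
  gene <- rownames(mat) %||% paste0("gene", seq_len(nrow(mat)))
  out <- data.frame(gene = gene, F_strain = s$f, p_strain = s$p,
                    F_treatment = t_$f, p_treatment = t_$p,
                    F_interaction = NA_real_, p_interaction = NA_real_,
                    stringsAsFactors = FALSE)
  if (with_interaction) {
    i <- f_p(rss2 - rss3, df_i)
    out$F_interaction <- i$f
    out$p_interaction <- i$p
  }
  out$p_overall <- pmin(1, 3 * pmin(out$p_strain, out$p_treatment,
                                    if (with_interaction) out$p_interaction
                                    else Inf))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement
#' (wraps `stats::p.adjust(method = "BH")` after validating the inputs).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Log2 fold changes of each strain vs WT within treatment
#'
#' Differences of design-cell means of the stabilized values: for every
#' non-reference strain s and treatment t,
#' `lfc = mean(s, t) - mean(ref, t)`.
#'
#' @param mat Stabilized matrix (genes x samples).
#' @param strain,treatment Design factors per sample.
#' @param ref_strain Reference strain (default `"WT"`).
#' @return Numeric matrix genes x `<strain>_<treatment>` cells.
#' @export
lfc_vs_reference <- function(mat, strain, treatment, ref_strain = "WT") {
  mat <- as.matrix(mat)
  strain <- as.character(strain)
  treatment <- as.character(treatment)
  if (!ref_strain %in% strain) stop("reference strain absent from design")
  cell_mean <- function(s, t) {
    rowMeans(mat[, strain == s & treatment == t, drop = FALSE])
  }
  strains <- setdiff(unique(strain), ref_strain)
  treatments <- unique(treatment)
  cells <- expand.grid(strain = strains, treatment = treatments,
                       stringsAsFactors = FALSE)
  lfc <- vapply(seq_len(nrow(cells)), function(i) {
    cell_mean(cells$strain[i], cells$treatment[i]) -
      cell_mean(ref_strain, cells$treatment[i])
  }, numeric(nrow(mat)))
  lfc <- matrix(lfc, nrow = nrow(mat),
                dimnames = list(rownames(mat),
                                paste(cells$strain, cells$treatment, sep = "_")))
  lfc
}

#' Filter differentially expressed genes
#'
#' A gene is called for a strain x treatment cell iff its q-value is below
#' `q_max` (strict) and the absolute log2 fold change vs WT in the matching
#' treatment is above `lfc_min` (strict); direction is the fold-change sign.
#'
#' @param q Named (by gene) q-value vector.
#' @param lfc Fold-change matrix from [lfc_vs_reference()] (genes x cells).
#' @param q_max,lfc_min Strict thresholds (defaults 0.01 and 0.5).
#' @return Long `data.frame`: `gene`, `strain`, `treatment`, `lfc`, `q`,
#'   `direction` (`"up"`/`"down"`), one row per called gene x cell.
#' @export
de_filter <- function(q, lfc, q_max = 0.01, lfc_min = 0.5) {
  stopifnot(length(q) == nrow(lfc))
  cells <- colnames(lfc)
  parts <- strsplit(cells, "_(?=[^_]+$)", perl = TRUE)
  rows <- lapply(seq_along(cells), function(j) {
    hit <- q < q_max & abs(lfc[, j]) > lfc_min
    if (!any(hit)) return(NULL)
    data.frame(gene = rownames(lfc)[hit],
               strain = parts[[j]][1], treatment = parts[[j]][2],
               lfc = lfc[hit, j], q = q[hit],
               direction = ifelse(lfc[hit, j] > 0, "up", "down"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), strain = character(),
                      treatment = character(), lfc = numeric(), q = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Cross-reference DE calls with peak-assigned promoters
#'
#' Intersects differential-expression calls in a given treatment with the
#' genes downstream of peak-assigned TSS, reporting per-strain fold-change
#' columns relative to WT.
#'
#' @param de_calls Output of [de_filter()].
#' @param assigned_genes Character vector of genes downstream of assigned
#'   peaks (`assign_peaks()$genes`).
#' @param lfc Fold-change matrix from [lfc_vs_reference()].
#' @param treatment Treatment to report (default `"rifampicin"`).
#' @return `data.frame` `gene` plus one `lfc_<strain>` column per
#'   non-reference strain, restricted to assigned genes with at least one DE
#'   call in the treatment.
#' @export
crossref_promoters <- function(de_calls, assigned_genes, lfc,
                               treatment = "rifampicin") {
  hit <- de_calls$treatment == treatment & de_calls$gene %in% assigned_genes
  genes <- sort(unique(de_calls$gene[hit]))
  cols <- grep(paste0("_", treatment, "$"), colnames(lfc), value = TRUE)
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (cl in cols) {
    out[[paste0("lfc_", sub(paste0("_", treatment, "$"), "", cl))]] <-
      lfc[match(genes, rownames(lfc)), cl]
  }
  out
}
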