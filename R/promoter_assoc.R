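# Peak-to-promoter association: nearest-TSS distances, assignment at an
# inclusive 20-bp cutoff, intergenic/genic classification of unassigned peaks,
# and a -10 element position weight matrix from peak-centered sequence windows.

#' Nearest-TSS distance per peak
#'
#' Distance is `min |summit - tss|`, circular if the genome is circular
#' (`d(a, b) = min(|a - b|, L - |a - b|)`). Also returns the step counts of
#' peaks within each distance `0..max_step`.
#'
#' @param summits Integer vector of peak summit positions (0-based).
#' @param tss_positions Integer vector of TSS positions (0-based); must be
#'   non-empty.
#' @param genome_length Contig length (bp).
#' @param circular Logical.
#' @param max_step Largest distance in the step-count output.
#' @return A list: `distances` (data.frame `summit`, `tss`, `distance` with
#'   the nearest TSS per peak) and `steps` (data.frame `distance`,
#'   `n_peaks` = count of peaks with nearest distance <= that value).
#' @export
peak_tss_distances <- function(summits, tss_positions, genome_length,
                               circular = TRUE, max_step = 100) {
  if (length(tss_positions) == 0) stop("TSS list is empty")
  d <- vapply(summits, function(p) {
    dd <- wrap_distance(p, tss_positions, genome_length, circular)
    i <- which.min(dd)
    c(tss_positions[i], dd[i])
  }, numeric(2))
  distances <- data.frame(summit = as.integer(summits),
                          tss = as.integer(d[1, ]), distance = d[2, ])
  steps <- data.frame(distance = 0:max_step,
                      n_peaks = vapply(0:max_step, function(k) {
                        sum(distances$distance <= k)
                      }, integer(1)))
  list(distances = distances, steps = steps)
}

#' Assign peaks to transcription start sites
#'
#' A peak is assigned to its nearest TSS iff the distance is at most
#' `max_dist` (inclusive boundary: a peak exactly `max_dist` away is
#' assigned). If several TSS tie at the minimum distance, all are reported
#' and the downstream gene list is deduplicated.
#'
#' @param summits Integer vector of peak summits (0-based).
#' @param tss `data.frame` with columns `position`, `strand`, `gene`.
#' @param genome_length Contig length (bp).
#' @param max_dist Assignment cutoff (bp), default 20.
#' @param circular Logical.
#' @return A list: `assigned` (data.frame `summit`, `tss`, `strand`, `gene`,
#'   `distance`; possibly several rows per peak on ties), `unassigned`
#'   (data.frame `summit`, `distance`), and `genes` (deduplicated character
#'   vector of assigned downstream genes).
#' @export
assign_peaks <- function(summits, tss, genome_length, max_dist = 20,
                         circular = TRUE) {
  stopifnot(all(c("position", "strand", "gene") %in% names(tss)))
  if (nrow(tss) == 0) stop("TSS list is empty")
  rows <- lapply(summits, function(p) {
    dd <- wrap_distance(p, tss$position, genome_length, circular)
    dmin <- min(dd)
    if (dmin <= max_dist) {
      hit <- which(dd == dmin)
      data.frame(summit = p, tss = tss$position[hit], strand = tss$strand[hit],
                 gene = tss$gene[hit], distance = dmin,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(summit = p, tss = NA_integer_, strand = NA_character_,
                 gene = NA_character_, distance = dmin,
                 stringsAsFactors = FALSE)
    }
  })
  all_rows <- do.call(rbind, rows)
  assigned <- all_rows[!is.na(all_rows$gene), , drop = FALSE]
  unassigned <- unique(all_rows[is.na(all_rows$gene), c("summit", "distance"),
                                drop = FALSE])
  rownames(assigned) <- rownames(unassigned) <- NULL
  list(assigned = assigned, unassigned = unassigned,
       genes = unique(assigned$gene))
}

#' Classify unassigned peaks as intergenic or genic
#'
#' A peak is intergenic iff its summit overlaps no gene interval
#' (strand-agnostic; intervals are 0-based half-open).
#'
#' @param summits Integer vector of summit positions (0-based).
#' @param genes `data.frame` with columns `gene`, `start`, `end` (0-based
#'   half-open).
#' @return `data.frame` `summit`, `class` (`"intergenic"` or `"genic"`).
#' @export
classify_unassigned <- function(summits, genes) {
  stopifnot(all(c("start", "end") %in% names(genes)))
  if (nrow(genes) == 0) {
    return(data.frame(summit = as.integer(summits),
                      class = rep("intergenic", length(summits))))
  }
  gene_ranges <- IRanges::IRanges(start = genes$start + 1L, end = genes$end)
  hits <- IRanges::overlapsAny(
    IRanges::IRanges(start = as.integer(summits) + 1L, width = 1L),
    gene_ranges)
  data.frame(summit = as.integer(summits),
             class = ifelse(hits, "genic", "intergenic"),
             stringsAsFactors = FALSE)
}

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                 ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Build a position weight matrix from peak-centered windows
#'
#' Extracts `width`-bp windows `[summit - width/2, summit + width/2)` on the
#' plus strand (wrapping on circular genomes; off-end windows on linear
#' contigs are skipped with a warning), stacks them ungapped, and tallies base
#' frequencies with a pseudocount. The consensus takes the most frequent base
#' per column, using an IUPAC ambiguity code when runner-up bases lie within
#' 0.1 of the top frequency. Per-column information content is
#' `2 + sum(f * log2 f)` bits.
#'
#' An optional shift search re-aligns each window by the offset in
#' `-shift..shift` maximizing its log-likelihood under the initial matrix,
#' then rebuilds the matrix (one refinement pass); this recovers a motif whose
#' placement jitters by a few bp without gapped alignment.
#'
#' @param summits Integer vector of peak summits (0-based).
#' @param genome Genome sequence: a single character string or
#'   `Biostrings::DNAString`.
#' @param width Window width (bp), default 20.
#' @param pseudocount Added to each base count per column.
#' @param circular Logical.
#' @param shift Maximum per-window re-alignment shift (bp); 0 disables.
#' @return A list of class `pwm`: `freq` (4 x width base-frequency matrix,
#'   columns sum to 1), `counts`, `consensus` (length-`width` string), `ic`
#'   (per-column information content, bits), `n_windows`.
#' @export
build_pwm <- function(summits, genome, width = 20, pseudocount = 0.5,
                      circular = TRUE, shift = 0) {
  genome <- toupper(as.character(genome))
  L <- nchar(genome)
  half <- width %/% 2L
  get_window <- function(p, off = 0L) {
    idx <- (p - half + off) + 0:(width - 1L)
    if (circular) idx <- idx %% L
    else if (any(idx < 0L | idx >= L)) return(NULL)
    paste(substring(genome, idx + 1L, idx + 1L), collapse = "")
  }
  windows <- lapply(as.integer(summits), get_window)
  skipped <- vapply(windows, is.null, logical(1))
  if (any(skipped)) {
    warning(sum(skipped), " window(s) off the end of a linear contig skipped")
  }
  windows <- unlist(windows[!skipped])
  if (length(windows) == 0) stop("no usable sequence windows")

  tally <- function(wins) {
    m <- matrix(unlist(strsplit(wins, "")), nrow = length(wins), byrow = TRUE)
    counts <- vapply(seq_len(width), function(j) {
      tabulate(factor(m[, j], levels = c("A", "C", "G", "T")), nbins = 4)
    }, numeric(4))
    rownames(counts) <- c("A", "C", "G", "T")
    counts
  }
  counts <- tally(windows)

  if (shift > 0) {
    freq0 <- sweep(counts + pseudocount, 2,
                   colSums(counts + pseudocount), "/")
    summits_kept <- as.integer(summits)[!skipped]
    realigned <- vapply(summits_kept, function(p) {
      cand <- vapply(-shift:shift, function(off) {
        w <- get_window(p, off)
        if (is.null(w)) return(-Inf)
        b <- match(strsplit(w, "")[[1]], rownames(freq0))
        ok <- !is.na(b)
        sum(log(freq0[cbind(b[ok], which(ok))]))
      }, numeric(1))
      get_window(p, (-shift:shift)[which.max(cand)])
    }, character(1))
    counts <- tally(realigned)
  }

  total <- counts + pseudocount
  freq <- sweep(total, 2, colSums(total), "/")
  plogp <- ifelse(freq > 0, freq * log2(freq), 0)  # 0 log 0 = 0
  ic <- 2 + colSums(plogp)
  consensus <- vapply(seq_len(width), function(j) {
    f <- freq[, j]
    keep <- names(f)[f >= max(f) - 0.1]
    IUPAC_CODES[[paste(sort(keep), collapse = "")]]
  }, character(1))
  structure(list(freq = freq, counts = counts,
                 consensus = paste(consensus, collapse = ""),
                 ic = ic, n_windows = length(windows)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %d windows, width %d\nconsensus: %s\nIC (bits): %s\n",
              x$n_windows, ncol(x$freq), x$consensus,
              paste(round(x$ic, 2), collapse = " ")))
  invisible(x)
}
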