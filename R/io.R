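# Readers/writers for the external formats. Internal coordinates are
# uniformly 0-based half-open; GFF3 (1-based inclusive) and the 1-based
# GRanges convention are converted at the boundary only. Parsing of
# bedGraph/BED/GFF3 is delegated to rtracklayer and FASTA to Biostrings;
# these wrappers add the coordinate conversions and validation the pipeline
# relies on.

#' Read a bedGraph file into a per-position coverage track
#'
#' Run-length intervals are expanded to one value per position; uncovered
#' positions get 0. Overlapping intervals are an error; unsorted input is
#' sorted with a warning.
#'
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @param genome_length Track length; defaults to the largest interval end.
#' @param circular Logical flag stored on the returned track.
#' @return A [coverage_track()] (stage `"raw"` if all values are
#'   non-negative, otherwise `"bg_subtracted"`).
#' @export
read_bedgraph <- function(path, genome_length = NULL, circular = TRUE) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  if (is.unsorted(start0)) {
    warning("unsorted bedGraph input: sorting")
    o <- order(start0)
    gr <- gr[o]; start0 <- start0[o]; end0 <- end0[o]
  }
  if (any(start0[-1] < end0[-length(end0)])) {
    stop("overlapping intervals in bedGraph: ", path)
  }
  L <- genome_length %||% max(end0)
  if (max(end0) > L) stop("interval end exceeds genome length")
  values <- numeric(L)
  for (i in seq_along(start0)) {
    values[(start0[i] + 1L):end0[i]] <- gr$score[i]
  }
  contig <- as.character(GenomicRanges::seqnames(gr)[1])
  stage <- if (all(values >= 0)) "raw" else "bg_subtracted"
  coverage_track(values, contig = contig, circular = circular, stage = stage)
}

#' Write a coverage track as bedGraph
#'
#' Values are run-length encoded; `read_bedgraph(write_bedgraph(x))`
#' preserves the values exactly.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  r <- rle(track$values)
  end0 <- cumsum(r$lengths)
  start0 <- end0 - r$lengths
  gr <- GenomicRanges::GRanges(track$contig,
                               IRanges::IRanges(start = start0 + 1L,
                                                end = end0),
                               score = r$values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file (wrapping allowed).
#' @return Named character vector of sequences, uppercased, with non-ACGT
#'   letters replaced by `N`.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  gsub("[^ACGT]", "N", out)
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path,
                              width = 70)
  invisible(path)
}

#' Read gene/TSS features from GFF3
#'
#' Converts GFF3 1-based inclusive coordinates to internal 0-based half-open.
#'
#' @param path GFF3 file.
#' @return `data.frame`: `feature`, `gene` (from the `ID` attribute),
#'   `start`, `end` (0-based half-open), `strand`.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(feature = as.character(gr$type),
             gene = as.character(gr$ID),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write gene and TSS annotation as GFF3
#'
#' @param genes `data.frame` `gene`, `start`, `end` (0-based half-open),
#'   `strand`.
#' @param tss Optional `data.frame` `position`, `strand`, `gene` written as
#'   width-1 `TSS` features.
#' @param path Output path.
#' @param contig Contig id.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path, tss = NULL, contig = "genome") {
  gr_list <- list()
  if (nrow(genes) > 0) {
    g <- GenomicRanges::GRanges(contig,
                                IRanges::IRanges(start = genes$start + 1L,
                                                 end = genes$end),
                                strand = genes$strand)
    g$type <- "gene"
    g$ID <- genes$gene
    gr_list$genes <- g
  }
  if (!is.null(tss) && nrow(tss) > 0) {
    t <- GenomicRanges::GRanges(contig,
                                IRanges::IRanges(start = tss$position + 1L,
                                                 width = 1L),
                                strand = tss$strand)
    t$type <- "TSS"
    t$ID <- paste0("tss_", tss$gene)
    gr_list$tss <- t
  }
  gr <- do.call(c, unname(gr_list))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read intervals from BED (0-based half-open)
#'
#' @param path BED file.
#' @return `data.frame` `name`, `start`, `end` (0-based half-open), `strand`,
#'   `score`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (any(GenomicRanges::width(gr) == 0)) {
    stop("zero-length feature in BED: ", path)
  }
  data.frame(name = if (is.null(gr$name)) NA_character_ else gr$name,
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             score = if (is.null(gr$score)) NA_real_ else gr$score,
             stringsAsFactors = FALSE)
}

#' Write peak calls as 6-column BED
#'
#' Each peak becomes a width-1 interval at its summit; the BED score is the
#' sigma score scaled by 100 (capped at 1000).
#'
#' @param peaks Peak table from [call_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (nrow(peaks) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(peaks$contig,
                               IRanges::IRanges(start = peaks$summit + 1L,
                                                width = 1L),
                               strand = "*")
  gr$name <- sprintf("peak_%03d", seq_len(nrow(peaks)))
  gr$score <- pmin(1000, round(peaks$sigma_score * 100))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write a data frame as TSV
#'
#' @param x `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @return `data.frame`.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
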