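# Synthetic-data generators with planted ground truth. These define the study
# conditions under which the downstream stages are exercised: a three-sample
# crosslink-IP proteomics design (target pulldown, nonspecific pulldown,
# lysate), ChIP coverage tracks over a circular bacterial genome with ~150 bp
# sonication fragments, and a 3 strain x 2 treatment RNA-seq count matrix.

#' Describe a synthetic pulldown experiment
#'
#' Ground truth for [gen_pulldown()]: a label-free proteomics design with a
#' target pulldown, a nonspecific (untagged strain) pulldown and an
#' unfractionated lysate per replicate, and a chosen set of planted bait
#' interactors enriched in the target pulldown.
#'
#' @param n_proteins Number of proteins in the table.
#' @param planted_interactors Character vector of planted interactor ids
#'   (must be a subset of the generated ids `P0001`, `P0002`, ...).
#' @param enrichment_log2 Log2 enrichment added to planted proteins in the
#'   target pulldown (>= 0).
#' @param abundance_sdlog2 Spread (sd, log2 units) of baseline protein
#'   abundances. Default 2, i.e. ~3.5 orders of magnitude across 99% of the
#'   proteome, typical of a label-free MS-detected bacterial proteome.
#' @param noise_sdlog2 Replicate-level measurement noise (sd, log2 units).
#' @param missing_rate Marginal probability that an intensity is recorded as
#'   zero (missing); missingness is intensity-dependent (see Details).
#' @param n_replicates Number of experimental replicates.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#'
#' @details Missing values are generated intensity-dependently: the
#'   probability of a zero follows a logistic curve decreasing in the
#'   standardized log2 intensity (slope 3, i.e. a soft detection limit), with
#'   its intercept calibrated so the marginal missing rate equals
#'   `missing_rate`. This mirrors label-free MS missingness, which is tightly
#'   coupled to abundance: proteins well above the detection limit are
#'   essentially never missing.
#' @return An object of class `pulldown_truth`.
#' @export
pulldown_truth <- function(n_proteins, planted_interactors = character(),
                           enrichment_log2 = 3, abundance_sdlog2 = 2,
                           noise_sdlog2 = 0.5, missing_rate = 0.05,
                           n_replicates = 3, seed = 1L) {
  if (!is.numeric(n_proteins) || n_proteins < 1) {
    stop("n_proteins must be a positive count")
  }
  ids <- protein_ids(n_proteins)
  planted_interactors <- as.character(planted_interactors)
  if (!all(planted_interactors %in% ids)) {
    stop("planted_interactors must be a subset of the protein ids ",
         "(P0001 ... P", format(n_proteins), ")")
  }
  if (enrichment_log2 < 0) stop("enrichment_log2 must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(
    n_proteins = as.integer(n_proteins),
    planted_interactors = planted_interactors,
    enrichment_log2 = enrichment_log2,
    abundance_sdlog2 = abundance_sdlog2,
    noise_sdlog2 = noise_sdlog2,
    missing_rate = missing_rate,
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  ), class = "pulldown_truth")
}

# Calibrate the logistic missingness intercept so mean probability == rate.
missing_prob <- function(log2_intensity, rate, slope = 3) {
  if (rate <= 0) return(rep(0, length(log2_intensity)))
  z <- as.numeric(scale(log2_intensity))
  z[is.na(z)] <- 0
  a <- stats::uniroot(function(a) mean(stats::plogis(a - slope * z)) - rate,
                      c(-50, 50))$root
  stats::plogis(a - slope * z)
}

#' Generate raw pulldown intensity tables
#'
#' Draws log-normal baseline abundances, adds the planted target enrichment,
#' replicate noise and intensity-dependent missingness, and returns a wide raw
#' intensity table (one `target`/`nonspecific`/`lysate` column triple per
#' replicate) together with the truth labels.
#'
#' @param truth A [pulldown_truth()] object.
#' @return A list with `table` (data.frame: `protein`, `mw_kda`, then
#'   `<role>_<replicate>` raw intensity columns with zeros marking missing
#'   values) and `truth`.
#' @export
gen_pulldown <- function(truth) {
  stopifnot(inherits(truth, "pulldown_truth"))
  withr::with_seed(truth$seed, {
    n <- truth$n_proteins
    ids <- protein_ids(n)
    mw <- round(exp(stats::rnorm(n, log(40), 0.45)), 1)  # kDa, ~15-110
    base_log2 <- stats::rnorm(n, 20, truth$abundance_sdlog2)
    planted <- ids %in% truth$planted_interactors
    tab <- data.frame(protein = ids, mw_kda = mw, stringsAsFactors = FALSE)
    for (r in seq_len(truth$n_replicates)) {
      for (role in c("target", "nonspecific", "lysate")) {
        lg <- base_log2 + stats::rnorm(n, 0, truth$noise_sdlog2)
        if (role == "target") lg <- lg + ifelse(planted, truth$enrichment_log2, 0)
        raw <- 2^lg
        miss <- stats::runif(n) < missing_prob(lg, truth$missing_rate)
        raw[miss] <- 0
        tab[[paste0(role, "_", r)]] <- raw
      }
    }
    list(table = tab, truth = truth)
  })
}

#' Describe a synthetic ChIP genome
#'
#' Ground truth for [gen_chip_tracks()]: a (circular) genome with planted
#' protein-binding peaks, each carrying a -10 promoter hexamer at its center
#' and a transcription start site at a fixed downstream offset.
#'
#' @param length_bp Genome length (bp).
#' @param circular Logical; wrap coordinates and windows.
#' @param planted_peaks `data.frame` with columns `position` (0-based summit),
#'   `fold_enrichment` (> 1) and `motif` (hexamer placed at the peak center).
#' @param background_mean_depth Mean background sequencing depth (reads/bp).
#' @param fragment_size_bp Mean sonication fragment length (default 150 bp).
#' @param tss_offset_bp Offset from each peak center to its TSS. Default 10:
#'   the -10 element center sits ~10 bp upstream of the start site.
#' @param gene_length_bp Length of the gene placed downstream of each TSS.
#' @param seed Integer seed.
#' @return An object of class `genome_truth`.
#' @export
genome_truth <- function(length_bp = 50000, circular = TRUE,
                         planted_peaks = data.frame(position = integer(),
                                                    fold_enrichment = numeric(),
                                                    motif = character()),
                         background_mean_depth = 20, fragment_size_bp = 150,
                         tss_offset_bp = 10, gene_length_bp = 900, seed = 1L) {
  stopifnot(is.data.frame(planted_peaks))
  need <- c("position", "fold_enrichment", "motif")
  if (!all(need %in% names(planted_peaks))) {
    stop("planted_peaks needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(planted_peaks) > 0) {
    if (any(planted_peaks$position %% 1 != 0)) {
      stop("planted peak positions must be integers")
    }
    planted_peaks$position <- as.integer(planted_peaks$position)
    if (any(planted_peaks$position < 0 | planted_peaks$position >= length_bp)) {
      stop("planted peak positions must lie in [0, length_bp)")
    }
    if (any(planted_peaks$fold_enrichment <= 1)) {
      stop("fold_enrichment must be > 1")
    }
  }
  if (fragment_size_bp <= 0) stop("fragment_size_bp must be > 0")
  structure(list(
    length_bp = as.integer(length_bp), circular = isTRUE(circular),
    planted_peaks = planted_peaks,
    background_mean_depth = background_mean_depth,
    fragment_size_bp = fragment_size_bp,
    tss_offset_bp = as.integer(tss_offset_bp),
    gene_length_bp = as.integer(gene_length_bp),
    seed = as.integer(seed)
  ), class = "genome_truth")
}

# Random fragment lengths: geometric rounded around the mean, >= 1 bp.
fragment_lengths <- function(n, mean_bp) {
  1L + stats::rgeom(n, prob = 1 / mean_bp)
}

background_fragments <- function(length_bp, depth, fragment_size_bp) {
  n <- stats::rpois(1, length_bp * depth / fragment_size_bp)
  start <- sample.int(length_bp, n, replace = TRUE) - 1L
  data.frame(start = start, end = start + fragment_lengths(n, fragment_size_bp))
}

#' Generate ChIP coverage tracks, genome sequence and annotation
#'
#' Background coverage is a pileup of uniformly started, geometric-length
#' fragments; each planted peak adds `(fold_enrichment - 1) * background`
#' extra fragments centered on its position (so the expected summit depth is
#' `fold_enrichment * background`). The genome
#' sequence carries each peak's motif centered at the peak position, and a TSS
#' plus downstream gene are placed at the configured offset.
#'
#' @param truth A [genome_truth()] object.
#' @return A list: `target` and `nonspecific` raw [coverage_track()]s,
#'   `genome` (single character string), `tss` (data.frame `position`,
#'   `strand`, `gene`), `genes` (data.frame `gene`, `start`, `end`, `strand`;
#'   0-based half-open), and `truth`.
#' @export
gen_chip_tracks <- function(truth) {
  stopifnot(inherits(truth, "genome_truth"))
  withr::with_seed(truth$seed, {
    L <- truth$length_bp
    genome <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    pk <- truth$planted_peaks
    for (i in seq_len(nrow(pk))) {
      motif <- strsplit(toupper(pk$motif[i]), "")[[1]]
      at <- (pk$position[i] - floor(length(motif) / 2) + seq_along(motif) - 1L)
      at <- if (truth$circular) at %% L else at[at >= 0 & at < L]
      genome[at + 1L] <- motif[seq_along(at)]
    }

    target_frags <- background_fragments(L, truth$background_mean_depth,
                                         truth$fragment_size_bp)
    for (i in seq_len(nrow(pk))) {
      n_extra <- stats::rpois(1, (pk$fold_enrichment[i] - 1) *
                                 truth$background_mean_depth)
      len <- fragment_lengths(n_extra, truth$fragment_size_bp)
      start <- pk$position[i] - len %/% 2L
      if (truth$circular) start <- start %% L else start <- pmax(start, 0L)
      target_frags <- rbind(target_frags,
                            data.frame(start = start, end = start + len))
    }
    nonspecific_frags <- background_fragments(L, truth$background_mean_depth,
                                              truth$fragment_size_bp)

    tss <- genes <- NULL
    if (nrow(pk) > 0) {
      tss_pos <- pk$position + truth$tss_offset_bp
      if (truth$circular) tss_pos <- tss_pos %% L
      gene_ids <- sprintf("gene%03d", seq_len(nrow(pk)))
      tss <- data.frame(position = tss_pos, strand = "+", gene = gene_ids,
                        stringsAsFactors = FALSE)
      gstart <- tss_pos + 1L
      genes <- data.frame(gene = gene_ids, start = gstart,
                          end = gstart + truth$gene_length_bp, strand = "+",
                          stringsAsFactors = FALSE)
    } else {
      tss <- data.frame(position = integer(), strand = character(),
                        gene = character(), stringsAsFactors = FALSE)
      genes <- data.frame(gene = character(), start = integer(),
                          end = integer(), strand = character(),
                          stringsAsFactors = FALSE)
    }

    list(
      target = depth_from_fragments(target_frags, L, circular = truth$circular,
                                    contig = "genome"),
      nonspecific = depth_from_fragments(nonspecific_frags, L,
                                         circular = truth$circular,
                                         contig = "genome"),
      genome = paste(genome, collapse = ""),
      tss = tss, genes = genes, truth = truth
    )
  })
}

#' Describe a synthetic RNA-seq experiment
#'
#' Ground truth for [gen_counts()]: a 3 strain (WT, dcedA, dcedA_pCedA) x
#' 2 treatment (control, rifampicin) design with negative-binomial counts and
#' planted per-condition log2 effects.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per design cell.
#' @param planted_de `data.frame` with columns `gene`, `strain`, `treatment`,
#'   `effect_log2`: the log2 shift applied to that gene's mean in that cell.
#' @param nb_dispersion Negative-binomial dispersion (> 0); `size = 1/dispersion`.
#' @param planted_expressed If `TRUE` (default), genes carrying planted
#'   effects draw their baseline from the upper half of the expression
#'   distribution: a gene must be expressed for its differential response to
#'   be observable at all, and the planted genes emulate genes under active
#'   promoters.
#' @param gene_lengths Optional vector of gene lengths (bp); drawn 300-3000 bp
#'   if `NULL`.
#' @param base_log2_mean,base_log2_sd Location/spread of per-kb baseline
#'   expression (log2 scale); defaults give typical counts of a few hundred.
#' @param seed Integer seed.
#' @return An object of class `counts_truth`.
#' @export
counts_truth <- function(n_genes = 2000, n_replicates = 3,
                         planted_de = data.frame(gene = character(),
                                                 strain = character(),
                                                 treatment = character(),
                                                 effect_log2 = numeric()),
                         nb_dispersion = 0.05, planted_expressed = TRUE,
                         gene_lengths = NULL,
                         base_log2_mean = 9, base_log2_sd = 2.5, seed = 1L) {
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (n_genes < 1) stop("n_genes must be a positive count")
  need <- c("gene", "strain", "treatment", "effect_log2")
  if (!all(need %in% names(planted_de))) {
    stop("planted_de needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(planted_de$strain %in% de_strains())) stop("unknown strain in planted_de")
  if (!all(planted_de$treatment %in% de_treatments())) {
    stop("unknown treatment in planted_de")
  }
  if (!is.null(gene_lengths) && length(gene_lengths) != n_genes) {
    stop("gene_lengths must have one entry per gene")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    planted_de = planted_de, nb_dispersion = nb_dispersion,
    planted_expressed = isTRUE(planted_expressed),
    gene_lengths = gene_lengths, base_log2_mean = base_log2_mean,
    base_log2_sd = base_log2_sd, seed = as.integer(seed)
  ), class = "counts_truth")
}

de_strains <- function() c("WT", "dcedA", "dcedA_pCedA")
de_treatments <- function() c("control", "rifampicin")

#' Generate a negative-binomial count matrix with planted effects
#'
#' Counts are drawn as `NB(mu, size = 1/dispersion)` with
#' `mu = base_per_kb * length_kb * 2^effect` for each gene x sample, where the
#' effect is the planted log2 shift of that gene in that sample's design cell
#' (zero elsewhere).
#'
#' @param truth A [counts_truth()] object.
#' @return A list: `counts` (integer matrix genes x samples), `design`
#'   (data.frame `sample`, `strain`, `treatment`, `replicate`),
#'   `gene_lengths` (bp, named), and `truth`.
#' @export
gen_counts <- function(truth) {
  stopifnot(inherits(truth, "counts_truth"))
  withr::with_seed(truth$seed, {
    g <- truth$n_genes
    gene_ids <- sprintf("g%05d", seq_len(g))
    lengths <- truth$gene_lengths %||%
      round(exp(stats::runif(g, log(300), log(3000))))
    names(lengths) <- gene_ids
    z <- stats::rnorm(g)
    if (truth$planted_expressed && nrow(truth$planted_de) > 0) {
      planted <- gene_ids %in% truth$planted_de$gene
      z[planted] <- abs(z[planted])
    }
    base_per_kb <- 2^(truth$base_log2_mean + truth$base_log2_sd * z)

    design <- expand.grid(replicate = seq_len(truth$n_replicates),
                          treatment = de_treatments(), strain = de_strains(),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    design$sample <- sprintf("%s_%s_%d", design$strain, design$treatment,
                             design$replicate)
    design <- design[, c("sample", "strain", "treatment", "replicate")]

    effect <- matrix(0, g, nrow(design), dimnames = list(gene_ids, design$sample))
    pd <- truth$planted_de
    if (nrow(pd) > 0 && !all(pd$gene %in% gene_ids)) {
      stop("planted_de genes must be among the generated ids (g00001 ...)")
    }
    for (i in seq_len(nrow(pd))) {
      cols <- design$strain == pd$strain[i] & design$treatment == pd$treatment[i]
      effect[pd$gene[i], cols] <- effect[pd$gene[i], cols] + pd$effect_log2[i]
    }
    mu <- base_per_kb * (lengths / 1000) * 2^effect
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / truth$nb_dispersion),
                     nrow = g, dimnames = dimnames(effect))
    list(counts = counts, design = design, gene_lengths = lengths, truth = truth)
  })
}
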