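#!/usr/bin/env Rscript
# Generate the three synthetic inputs with planted ground truth:
#  (a) a crosslink-IP-MS pulldown intensity table (target / nonspecific /
#      lysate, 3 replicates, 20 planted bait interactors at 8-fold),
#  (b) ChIP coverage tracks over a 50-kb circular genome with 10 planted
#      promoter peaks carrying TATAAT at their centers, plus FASTA/GFF3,
#  (c) a 3 strain x 2 treatment NB count matrix with 10 promoter-proximal
#      rifampicin responders and a 30% background response.
# Downstream drivers (02-06) consume the files written here.

suppressMessages(library(cedseek))
seed <- 1L
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- default_config()

## (a) pulldown ----------------------------------------------------------
pd <- gen_pulldown(pulldown_truth(
  n_proteins = cfg$pulldown$n_proteins,
  planted_interactors = protein_ids(cfg$pulldown$n_proteins)[1:cfg$pulldown$n_planted],
  enrichment_log2 = cfg$pulldown$enrichment_log2,
  n_replicates = cfg$pulldown$n_replicates,
  seed = stage_seed(seed, "pulldown")))
write_tsv(pd$table, file.path(out, "pulldown_intensities.tsv"))
jsonlite::write_json(pd$truth[c("planted_interactors", "enrichment_log2", "seed")],
                     file.path(out, "pulldown_truth.json"), auto_unbox = TRUE)
message("pulldown: ", nrow(pd$table), " proteins x ",
        cfg$pulldown$n_replicates, " replicates, ",
        length(pd$truth$planted_interactors), " planted interactors")

## (b) chip --------------------------------------------------------------
peak_pos <- round(seq(0.08, 0.92, length.out = cfg$chip$n_peaks) *
                    cfg$chip$length_bp)
ch <- gen_chip_tracks(genome_truth(
  length_bp = cfg$chip$length_bp, circular = TRUE,
  planted_peaks = data.frame(position = peak_pos,
                             fold_enrichment = cfg$chip$fold_enrichment,
                             motif = cfg$chip$motif),
  background_mean_depth = cfg$chip$background_mean_depth,
  seed = stage_seed(seed, "chip")))
write_bedgraph(ch$target, file.path(out, "chip_target.bedgraph"))
write_bedgraph(ch$nonspecific, file.path(out, "chip_nonspecific.bedgraph"))
write_genome_fasta(c(genome = ch$genome), file.path(out, "genome.fa"))
write_gff(ch$genes, file.path(out, "annotation.gff3"), tss = ch$tss)
jsonlite::write_json(list(positions = peak_pos, motif = cfg$chip$motif),
                     file.path(out, "chip_truth.json"), auto_unbox = TRUE)
message("chip: ", cfg$chip$length_bp, " bp circular genome, ",
        length(peak_pos), " planted peaks at ",
        cfg$chip$background_mean_depth, "x background")

## (c) counts ------------------------------------------------------------
planted_de <- data.frame(gene = sprintf("g%05d", seq_len(cfg$chip$n_peaks)),
                         strain = "dcedA", treatment = "rifampicin",
                         effect_log2 = cfg$de$effect_log2)
# background response (drug and strain effects over ~30% of genes), as in the
# pipeline's default scenario
planted_de <- rbind(planted_de, withr::with_seed(
  stage_seed(seed, "analysis"), {
    bg <- sample(setdiff(seq_len(cfg$de$n_genes), seq_len(cfg$chip$n_peaks)),
                 cfg$de$n_background_de)
    half <- length(bg) %/% 2
    eff <- function(n) sample(c(-1, 1), n, TRUE) * stats::runif(n, 0.5, 2)
    drug_eff <- eff(half); strain_eff <- eff(length(bg) - half)
    rbind(
      do.call(rbind, lapply(c("WT", "dcedA", "dcedA_pCedA"), function(st) {
        data.frame(gene = sprintf("g%05d", bg[seq_len(half)]), strain = st,
                   treatment = "rifampicin", effect_log2 = drug_eff)
      })),
      do.call(rbind, lapply(c("control", "rifampicin"), function(tr) {
        data.frame(gene = sprintf("g%05d", bg[(half + 1):length(bg)]),
                   strain = "dcedA_pCedA", treatment = tr,
                   effect_log2 = strain_eff)
      }))
    )
  }))
cn <- gen_counts(counts_truth(
  n_genes = cfg$de$n_genes, n_replicates = cfg$de$n_replicates,
  planted_de = planted_de, nb_dispersion = cfg$de$nb_dispersion,
  seed = stage_seed(seed, "counts")))
write_tsv(data.frame(gene = rownames(cn$counts), cn$counts,
                     check.names = FALSE), file.path(out, "counts.tsv"))
write_tsv(cn$design, file.path(out, "design.tsv"))
write_tsv(data.frame(gene = names(cn$gene_lengths),
                     length_bp = cn$gene_lengths),
          file.path(out, "gene_lengths.tsv"))
message("counts: ", nrow(cn$counts), " genes x ", ncol(cn$counts),
        " samples, ", length(unique(planted_de$gene)),
        " genes with planted effects")
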