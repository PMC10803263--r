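#!/usr/bin/env Rscript
# Call ChIP-seq peaks on the simulated coverage: log2 + 50-bp rolling mean on
# both tracks, subtract the nonspecific background, subtract the histogram-
# mode baseline, and report 3-sigma local maxima.

suppressMessages(library(cedseek))
sim <- "results/simulated"
out <- "results/chip"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- read_genome_fasta(file.path(sim, "genome.fa"))
L <- unname(nchar(genome))
target <- read_bedgraph(file.path(sim, "chip_target.bedgraph"),
                        genome_length = L, circular = TRUE)
control <- read_bedgraph(file.path(sim, "chip_nonspecific.bedgraph"),
                         genome_length = L, circular = TRUE)

res <- chip_peak_pipeline(target, control, peak_params())
write_peaks_bed(res$peaks, file.path(out, "peaks.bed"))
write_tsv(res$peaks, file.path(out, "peaks.tsv"))
write_bedgraph(res$track, file.path(out, "processed_track.bedgraph"))

truth <- jsonlite::read_json(file.path(sim, "chip_truth.json"),
                             simplifyVector = TRUE)
err <- vapply(truth$positions, function(p) {
  if (nrow(res$peaks) == 0) Inf
  else min(wrap_distance(p, res$peaks$summit, L))
}, numeric(1))
message(nrow(res$peaks), " peaks called (sigma = ", round(res$sigma, 3),
        ", baseline = ", round(res$baseline, 2), ")")
message(sum(err <= 25), "/", length(err),
        " planted peaks recovered within 25 bp; median summit error ",
        stats::median(err[is.finite(err)]), " bp")
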