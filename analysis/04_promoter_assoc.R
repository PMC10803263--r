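#!/usr/bin/env Rscript
# Associate called peaks with transcription start sites (inclusive 20-bp
# rule), classify unassigned peaks as intergenic or genic, and build the
# -10 element consensus from 20-bp peak-centered sequence windows.

suppressMessages(library(cedseek))
out <- "results/promoters"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

peaks <- read_tsv("results/chip/peaks.tsv")
genome <- read_genome_fasta("results/simulated/genome.fa")
L <- unname(nchar(genome))
ann <- read_gff("results/simulated/annotation.gff3")
genes <- ann[ann$feature == "gene", c("gene", "start", "end", "strand")]
tss <- data.frame(position = ann$start[ann$feature == "TSS"],
                  strand = ann$strand[ann$feature == "TSS"],
                  gene = sub("^tss_", "", ann$gene[ann$feature == "TSS"]))

dist <- peak_tss_distances(peaks$summit, tss$position, L, circular = TRUE)
write_tsv(dist$steps, file.path(out, "tss_distance_steps.tsv"))

asg <- assign_peaks(peaks$summit, tss, L, max_dist = 20, circular = TRUE)
write_tsv(asg$assigned, file.path(out, "peak_tss_assignment.tsv"))
cls <- classify_unassigned(asg$unassigned$summit, genes)
write_tsv(cls, file.path(out, "unassigned_classification.tsv"))

pwm <- build_pwm(peaks$summit, genome, width = 20, circular = TRUE)
write_tsv(data.frame(base = rownames(pwm$freq), round(pwm$freq, 4)),
          file.path(out, "pwm_frequencies.tsv"))
writeLines(c(paste0("# consensus: ", pwm$consensus),
             paste0("# IC (bits): ",
                    paste(round(pwm$ic, 3), collapse = " "))),
           file.path(out, "pwm_consensus.txt"))

message(length(unique(asg$assigned$summit)), "/", nrow(peaks),
        " peaks within 20 bp of a TSS; ",
        sum(cls$class == "intergenic"), " unassigned peaks intergenic, ",
        sum(cls$class == "genic"), " genic")
message("-10 consensus window: ", pwm$consensus,
        if (grepl("TATAAT", pwm$consensus, fixed = TRUE))
          "  (contains TATAAT)" else "")
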