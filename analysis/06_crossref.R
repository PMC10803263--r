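#!/usr/bin/env Rscript
# Intersect the DE calls with genes downstream of peak-assigned TSS: the
# putative direct targets whose promoters carry the factor and respond to
# rifampicin, with per-strain log2 fold changes relative to WT.

suppressMessages(library(cedseek))
out <- "results"

asg <- read_tsv("results/promoters/peak_tss_assignment.tsv")
calls <- read_tsv("results/diffexpr/de_calls.tsv")
de_tab <- read_tsv("results/diffexpr/de_table.tsv")
lfc_cols <- grep("^(dcedA|dcedA_pCedA)_", names(de_tab), value = TRUE)
lfc <- as.matrix(de_tab[, lfc_cols])
rownames(lfc) <- de_tab$gene

# annotation gene ids (gene001...) map onto count-matrix ids (g00001...)
assigned_genes <- sprintf("g%05d", as.integer(sub("gene", "",
                                                  unique(asg$gene))))
direct <- crossref_promoters(calls, assigned_genes, lfc,
                             treatment = "rifampicin")
write_tsv(direct, file.path(out, "promoter_crossref.tsv"))

message(nrow(direct), " factor-associated promoters responded to rifampicin ",
        "(q < 0.01, |lfc| > 0.5):")
for (i in seq_len(nrow(direct))) {
  message(sprintf("  %s  lfc(dcedA) = %+.2f  lfc(dcedA+pCedA) = %+.2f",
                  direct$gene[i], direct$lfc_dcedA[i],
                  direct$lfc_dcedA_pCedA[i]))
}
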