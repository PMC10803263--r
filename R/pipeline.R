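# Top-level orchestration: a single configuration drives the synthetic
# simulate -> rank -> peaks -> annotate -> de -> crossref flow and writes all
# artifacts plus a machine-readable run manifest. Rerunning with the same
# config and seed reproduces every output byte-identically.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every recognized key at its
#' default. Pass overrides to [run_pipeline()] as a (possibly partial) list
#' with the same structure; unknown keys are rejected.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "cedseek_run",
    pulldown = list(n_proteins = 1000L, n_planted = 20L, enrichment_log2 = 3,
                    missing_rate = 0.05, n_replicates = 3L, quantile = 0.02),
    chip = list(length_bp = 50000L, circular = TRUE, n_peaks = 10L,
                fold_enrichment = 8, motif = "TATAAT",
                background_mean_depth = 100, fragment_size_bp = 150,
                tss_offset_bp = 10L, window_bp = 50L, sigma_multiplier = 3,
                max_dist = 20L, pwm_width = 20L),
    de = list(n_genes = 1000L, n_replicates = 3L, nb_dispersion = 0.05,
              effect_log2 = -4, n_background_de = 300L,
              q_max = 0.01, lfc_min = 0.5)
  )
}

merge_config <- function(user, defaults, path = "config") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]])) {
      merge_config(user[[k]], defaults[[k]], paste0(path, "$", k))
    } else user[[k]]
  }
  defaults
}

#' Run the full synthetic pipeline
#'
#' Generates the three synthetic inputs, then runs interactor ranking, peak
#' calling, promoter association and the differential-expression stage with
#' promoter cross-referencing, writing every artifact (TSV, bedGraph, FASTA,
#' GFF3, BED) and a JSON manifest of parameters, seed and output checksums
#' under `config$out_dir`. The simulated peaks are planted at the promoters of
#' the first `chip$n_peaks` count-matrix genes, whose expression responds to
#' rifampicin, so the cross-reference stage has a planted ground truth.
#'
#' @param config Partial configuration list (see [default_config()]); unknown
#'   keys are rejected before any computation. May also be a path to a YAML
#'   file with the same structure.
#' @return Invisibly, a list with the main in-memory results and the manifest.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config, default_config())
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, ...)

  ## --- pulldown: simulate + combined-rank scoring -------------------------
  pc <- cfg$pulldown
  pd_truth <- pulldown_truth(
    n_proteins = pc$n_proteins,
    planted_interactors = protein_ids(pc$n_proteins)[seq_len(pc$n_planted)],
    enrichment_log2 = pc$enrichment_log2, missing_rate = pc$missing_rate,
    n_replicates = pc$n_replicates, seed = stage_seed(cfg$seed, "pulldown"))
  pd <- gen_pulldown(pd_truth)
  write_tsv(pd$table, out("pulldown_intensities.tsv"))
  ranked <- rank_pulldown(pd$table, pc$n_replicates)
  calls <- call_interactors(ranked$aggregate, quantile = pc$quantile,
                            n_replicates = pc$n_replicates)
  write_tsv(calls, out("interactor_calls.tsv"))
  per_rep_calls <- lapply(ranked$per_replicate, function(tab) {
    tab$protein[tab$combined_rank >= stats::quantile(tab$combined_rank,
                                                     1 - pc$quantile)]
  })
  write_tsv(venn_overlap(per_rep_calls), out("replicate_venn.tsv"))

  ## --- chip: simulate + peak calling + promoter association ---------------
  cc <- cfg$chip
  peak_pos <- round(seq(0.08, 0.92, length.out = cc$n_peaks) * cc$length_bp)
  g_truth <- genome_truth(
    length_bp = cc$length_bp, circular = cc$circular,
    planted_peaks = data.frame(position = peak_pos,
                               fold_enrichment = cc$fold_enrichment,
                               motif = cc$motif),
    background_mean_depth = cc$background_mean_depth,
    fragment_size_bp = cc$fragment_size_bp, tss_offset_bp = cc$tss_offset_bp,
    seed = stage_seed(cfg$seed, "chip"))
  chip <- gen_chip_tracks(g_truth)
  write_bedgraph(chip$target, out("chip_target.bedgraph"))
  write_bedgraph(chip$nonspecific, out("chip_nonspecific.bedgraph"))
  write_genome_fasta(c(genome = chip$genome), out("genome.fa"))
  write_gff(chip$genes, out("annotation.gff3"), tss = chip$tss)

  params <- peak_params(window_bp = cc$window_bp,
                        sigma_multiplier = cc$sigma_multiplier)
  pk <- chip_peak_pipeline(chip$target, chip$nonspecific, params)
  write_peaks_bed(pk$peaks, out("peaks.bed"))
  write_tsv(pk$peaks, out("peaks.tsv"))

  assignment <- assign_peaks(pk$peaks$summit, chip$tss, cc$length_bp,
                             max_dist = cc$max_dist, circular = cc$circular)
  write_tsv(assignment$assigned, out("peak_tss_assignment.tsv"))
  classed <- classify_unassigned(assignment$unassigned$summit, chip$genes)
  write_tsv(classed, out("unassigned_classification.tsv"))
  pwm <- build_pwm(pk$peaks$summit, chip$genome, width = cc$pwm_width,
                   circular = cc$circular)
  write_tsv(data.frame(base = rownames(pwm$freq), round(pwm$freq, 4)),
            out("pwm_frequencies.tsv"))
  writeLines(c(pwm$consensus, paste(round(pwm$ic, 3), collapse = "\t")),
             out("pwm_consensus.txt"))

  ## --- de: simulate counts + factorial ANOVA + crossref -------------------
  dc <- cfg$de
  count_gene <- function(i) sprintf("g%05d", i)
  # peak-associated genes respond to rifampicin in the deletion strain
  planted_de <- data.frame(gene = count_gene(seq_len(cc$n_peaks)),
                           strain = "dcedA", treatment = "rifampicin",
                           effect_log2 = dc$effect_log2)
  # background response: rifampicin and the deletion/overexpression perturb a
  # sizeable fraction of the transcriptome, as in real strain x drug designs
  if (dc$n_background_de > 0) {
    planted_de <- rbind(planted_de, withr::with_seed(
      stage_seed(cfg$seed, "analysis"), {
        bg <- sample(setdiff(seq_len(dc$n_genes), seq_len(cc$n_peaks)),
                     dc$n_background_de)
        half <- length(bg) %/% 2
        eff <- function(n) sample(c(-1, 1), n, TRUE) * stats::runif(n, 0.5, 2)
        drug_eff <- eff(half)
        strain_eff <- eff(length(bg) - half)
        rbind(
          # drug response shared by all strains
          do.call(rbind, lapply(c("WT", "dcedA", "dcedA_pCedA"), function(st) {
            data.frame(gene = count_gene(bg[seq_len(half)]), strain = st,
                       treatment = "rifampicin", effect_log2 = drug_eff)
          })),
          # persistent overexpression response in both treatments
          do.call(rbind, lapply(c("control", "rifampicin"), function(tr) {
            data.frame(gene = count_gene(bg[(half + 1):length(bg)]),
                       strain = "dcedA_pCedA", treatment = tr,
                       effect_log2 = strain_eff)
          }))
        )
      }))
  }
  c_truth <- counts_truth(n_genes = dc$n_genes, n_replicates = dc$n_replicates,
                          planted_de = planted_de,
                          nb_dispersion = dc$nb_dispersion,
                          seed = stage_seed(cfg$seed, "counts"))
  cnt <- gen_counts(c_truth)
  write_tsv(data.frame(gene = rownames(cnt$counts), cnt$counts,
                       check.names = FALSE), out("counts.tsv"))
  write_tsv(cnt$design, out("design.tsv"))

  vst <- normalize_vst(cnt$counts, cnt$gene_lengths)
  de <- factorial_anova(vst$mat, cnt$design$strain, cnt$design$treatment)
  de$q <- bh_adjust(de$p_overall)
  lfc <- lfc_vs_reference(vst$mat, cnt$design$strain, cnt$design$treatment)
  write_tsv(cbind(de, round(lfc[match(de$gene, rownames(lfc)), ], 4)),
            out("de_table.tsv"))
  de_calls <- de_filter(stats::setNames(de$q, de$gene), lfc,
                        q_max = dc$q_max, lfc_min = dc$lfc_min)
  write_tsv(de_calls, out("de_calls.tsv"))

  # map chip annotation gene ids (gene001 ...) onto count genes (g00001 ...)
  assigned_count_genes <- count_gene(
    as.integer(sub("gene", "", assignment$genes)))
  crossref <- crossref_promoters(de_calls, assigned_count_genes, lfc,
                                 treatment = "rifampicin")
  write_tsv(crossref, out("promoter_crossref.tsv"))

  ## --- manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  manifest <- list(
    package = "cedseek",
    version = as.character(utils::packageVersion("cedseek")),
    seed = cfg$seed,
    parameters = cfg,
    outputs = as.list(tools::md5sum(file.path(cfg$out_dir, files)))
  )
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(config = cfg, interactor_calls = calls, peaks = pk$peaks,
                 assignment = assignment, pwm = pwm, de = de, lfc = lfc,
                 de_calls = de_calls, crossref = crossref,
                 manifest = manifest))
}
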