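#' Run the full synthetic meDIP analysis pipeline
#'
#' Generates a genome and modification truth from `config`, simulates the
#' six-library immunoprecipitation design, computes RPKM and
#' vegetative-subtracted signal, classifies germline-limited contigs from
#' the IgG copy-number scatter plus telomere calls, extracts them, scans
#' the somatic genome for the motif at the per-occurrence false-discovery
#' threshold, builds the methylation / hydroxymethylation / motif cohorts,
#' and evaluates everything against the generator's truth.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for the whole run (defaults to the config's).
#' @param fdr_per_occurrence motif scan threshold rate.
#' @return a `medip_pipeline` list: genome, track, libraries, signal table,
#'   enrichment fit, classification, cohort table, venn counts, motif scan,
#'   and an `evaluation` list with MIC precision/recall, fitted germline
#'   slope, cohort recovery and overlap fractions.
#' @export
run_medip_pipeline <- function(config = sim_config(),
                               seed = config$rng_seed,
                               fdr_per_occurrence = 1e-7) {
  set.seed(as.integer(seed))
  genome <- generate_genome(config, seed = NULL)
  track <- plant_modifications(genome, config, seed = NULL)
  libs <- simulate_medip_design(genome, track, config, seed = NULL)
  sig <- build_signal_table(libs)

  seqs <- genome_sequences(genome)
  telo <- vapply(seqs, detect_telomere, character(1),
                 telomere_unit = config$telomere_unit)
  fit <- fit_enrichment_populations(
    data.frame(contig = sig$contig, rpkm_veg = sig$rpkm_igg_veg,
               rpkm_46h = sig$rpkm_igg_46h))
  classification <- classify_mic_contigs(fit, telo)

  mac_ids <- classification$contig[classification$label == "MAC"]
  sig_mac <- sig[sig$contig %in% mac_ids, ]

  p <- pwm_from_consensus(config$motif_consensus,
                          match_prob = config$motif_match_prob,
                          background = genome_base_freqs(seqs[mac_ids]))
  thr <- calibrate_threshold(p, fdr_per_occurrence)
  scan <- scan_genome(p, seqs[mac_ids], thr,
                      cluster_gap = config$motif_cluster_gap)

  cohorts <- cohort_table(sig_mac, scan$counts)
  mc <- cohorts$contig[cohorts$in_mc_cohort]
  hmc <- cohorts$contig[cohorts$in_hmc_cohort]
  cc <- cohorts$contig[cohorts$in_cc_cohort]
  venn <- cohort_overlap(mc, hmc, cc)

  truth_mic <- genome$mic$id
  called_mic <- classification$contig[classification$label == "MIC"]
  tp <- length(intersect(called_mic, truth_mic))
  truth_mc <- genome$mac$id[genome$mac$cohort == "mc_hmc"]
  truth_hmc <- genome$mac$id[genome$mac$cohort != "none"]
  evaluation <- list(
    mic_precision = if (length(called_mic)) tp / length(called_mic) else NA_real_,
    mic_recall = tp / length(truth_mic),
    slope_mic = fit$amplification_fold, r2_mic = fit$r2_high,
    slope_mac = fit$slope_low, r2_mac = fit$r2_low,
    mc_cohort_size = length(mc),
    mc_cohort_recovered = length(intersect(mc, truth_mc)),
    mc_cohort_false_pos = length(setdiff(mc, truth_mc)),
    hmc_cohort_size = length(hmc),
    hmc_cohort_recovered = length(intersect(hmc, truth_hmc)),
    mc_hmc_overlap_fraction = if (length(mc))
      length(intersect(mc, hmc)) / length(mc) else NA_real_,
    cc_cohort_size = length(cc),
    motif_threshold_bits = thr$threshold_bits,
    motif_achieved_tail = thr$achieved_tail
  )

  out <- list(config = config, seed = seed, genome = genome, track = track,
              libraries = libs, signal_table = sig,
              telomere_flags = telo, fit = fit,
              classification = classification, pwm = p, threshold = thr,
              motif_scan = scan, cohort_table = cohorts, venn = venn,
              evaluation = evaluation)
  class(out) <- "medip_pipeline"
  out
}

genome_base_freqs <- function(seqs) {
  tab <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(seqs))[, BASES, drop = FALSE])
  tab / sum(tab)
}

#' @export
print.medip_pipeline <- function(x, ...) {
  ev <- x$evaluation
  cat("meDIP pipeline run\n")
  cat(sprintf("  germline fit   : slope %.2f (R2 %.3f) vs somatic slope %.2f (R2 %.3f)\n",
              ev$slope_mic, ev$r2_mic, ev$slope_mac, ev$r2_mac))
  cat(sprintf("  MIC calls      : precision %.2f, recall %.2f\n",
              ev$mic_precision, ev$mic_recall))
  cat(sprintf("  cohorts        : mC %d (recovered %d, FP %d), hmC %d, motif %d\n",
              ev$mc_cohort_size, ev$mc_cohort_recovered,
              ev$mc_cohort_false_pos, ev$hmc_cohort_size, ev$cc_cohort_size))
  cat(sprintf("  mC/hmC overlap : %.2f of the mC cohort\n",
              ev$mc_hmc_overlap_fraction))
  invisible(x)
}

#' Write the pipeline's report bundle
#'
#' Emits the signal table, classification, cohort table and motif hits as
#' headered TSV/BED, the venn counts and evaluation as JSON, scatter plots
#' of the copy-number and signal views, a per-window depth track for the
#' top cohort contig, and a JSON manifest hashing every file.
#'
#' @param result a `medip_pipeline`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "medip_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(result$signal_table, file.path(dir, "signal_table.tsv"))
  write_tsv(result$classification, file.path(dir, "classification.tsv"))
  write_tsv(result$cohort_table, file.path(dir, "cohort_table.tsv"))
  if (nrow(result$motif_scan$hits))
    write_hits_bed(result$motif_scan$hits, result$pwm$width,
                   file.path(dir, "motif_hits.bed"))
  jsonlite::write_json(result$venn, file.path(dir, "venn.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(result$evaluation, file.path(dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  sig <- result$signal_table
  grDevices::pdf(file.path(dir, "report_plots.pdf"), width = 7, height = 7)
  on.exit(grDevices::dev.off())
  is_mic <- result$classification$label == "MIC"
  plot(sig$rpkm_igg_veg, sig$rpkm_igg_46h,
       col = ifelse(is_mic, "blue", "red"),
       pch = ifelse(is_mic, 17, 1),
       xlab = "vegetative IgG (RPKM)", ylab = "46 h IgG (RPKM)",
       main = "Copy number: vegetative vs 46 h")
  abline(0, 1, lty = 2); abline(0, 5, lty = 3, col = "blue")
  plot(sig$signal_igg, sig$signal_mc,
       xlab = "IgG signal (RPKM)", ylab = "mC signal (RPKM)",
       main = "Vegetative-subtracted signal")
  plot(sig$signal_hmc, sig$signal_mc,
       xlab = "hmC signal (RPKM)", ylab = "mC signal (RPKM)",
       main = "mC vs hmC signal")
  write_manifest(dir, config = result$config[setdiff(names(result$config),
                                                     "mic_contigs")],
                 seed = result$seed)
  invisible(dir)
}
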