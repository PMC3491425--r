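#' Simulation configuration for the synthetic study design
#'
#' Bundles every tunable of the synthetic-data generator.  The defaults
#' emulate the structure of the real experiment: ~2 kb telomere-capped
#' macronuclear (MAC) nanochromosomes; germline-limited micronuclear (MIC)
#' satellite and transposon contigs amplified ~5-fold by polytenization at
#' the 46 h conjugation timepoint; regional all-context cytosine
#' modification at 91%/84% forward/reverse density with geometric skip runs
#' truncated at 8; a 20 bp pyrimidine-rich bipartite motif planted five
#' times, clustered, on every methylation-cohort chromosome; antibody
#' immunoprecipitation libraries with weak cross-reactivity to unmodified
#' cytosine plus bead background; and ~99.5% bisulfite conversion.
#'
#' Library size defaults to 1e5 reads (the real libraries had 5-9 million;
#' the default keeps a full six-library run in seconds while leaving
#' per-contig counting error far below the cohort thresholds).
#'
#' @param n_mac_chromosomes number of MAC nanochromosomes.
#' @param mac_length_mean_bp mean nanochromosome length (lengths are drawn
#'   normal with 15% CV, floored at 4x the fragment length).
#' @param n_cohort_mc number of MAC chromosomes carrying co-planted
#'   methylation + hydroxymethylation regions (the methylation cohort truth).
#' @param n_cohort_hmc_only number of MAC chromosomes carrying
#'   hydroxymethylation-only regions (ribosomal-gene analogs).
#' @param mic_contigs data.frame with columns `kind` ("satellite" or
#'   "transposon"), `repeat_unit_bp` (NA for transposons) and `total_len_bp`.
#' @param polyteny_fold germline copy-number amplification at 46 h (>= 1).
#' @param n_reads_per_library reads drawn per immunoprecipitation library.
#' @param fragment_len_bp sonication fragment length (fixed-length model).
#' @param alpha named numeric: per-modified-cytosine antibody affinity for
#'   `IgG`, `mC`, `hmC`.  `IgG` must be 0.
#' @param gamma cross-reactivity weight per (unmodified or modified)
#'   cytosine in a fragment, both strands counted.
#' @param beta bead/background weight per fragment (> 0).
#' @param mod_density_fwd,mod_density_rev target modified fraction of
#'   cytosines per strand inside designated regions.
#' @param skip_run_geometric_p geometric parameter of skip-run lengths
#'   (runs of consecutive unmodified cytosines), truncated to 1..8.
#' @param hmc_fraction fraction of modified sites carrying
#'   hydroxymethylcytosine rather than methylcytosine in co-marked regions.
#' @param conversion_rate bisulfite conversion probability for an
#'   unmodified cytosine.
#' @param motif_consensus 20-mer consensus of the planted CC motif.
#' @param motif_match_prob per-column probability of the consensus base in
#'   the planted-motif position weight matrix.
#' @param motifs_per_cohort_chrom motif instances planted per cohort
#'   chromosome.
#' @param motif_cluster_gap maximum distance (bp) between consecutive
#'   planted instances (clustered planting).
#' @param modified_region_frac fraction of a cohort chromosome covered by
#'   its central modified region.
#' @param telomere_unit telomeric repeat unit capping MAC chromosomes.
#' @param base_freqs named vector of mononucleotide frequencies (the
#'   organism is AT-rich).
#' @param rng_seed integer seed making every generator deterministic.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_mac_chromosomes = 200L,
                       mac_length_mean_bp = 2000L,
                       n_cohort_mc = 11L,
                       n_cohort_hmc_only = 5L,
                       mic_contigs = default_mic_contigs(),
                       polyteny_fold = 5,
                       n_reads_per_library = 1e5,
                       fragment_len_bp = 300L,
                       alpha = c(IgG = 0, mC = 1, hmC = 1),
                       gamma = 0.02,
                       beta = 1,
                       mod_density_fwd = 0.91,
                       mod_density_rev = 0.84,
                       skip_run_geometric_p = 0.5,
                       hmc_fraction = 0.5,
                       conversion_rate = 0.995,
                       motif_consensus = "TCCCTTTCCCTTTTCCCTCC",
                       motif_match_prob = 0.9,
                       motifs_per_cohort_chrom = 5L,
                       motif_cluster_gap = 200L,
                       modified_region_frac = 0.5,
                       telomere_unit = "GGGGTTTT",
                       base_freqs = c(A = 0.35, C = 0.15, G = 0.15, T = 0.35),
                       rng_seed = 1L) {
  cfg <- list(n_mac_chromosomes = as.integer(n_mac_chromosomes),
              mac_length_mean_bp = as.integer(mac_length_mean_bp),
              n_cohort_mc = as.integer(n_cohort_mc),
              n_cohort_hmc_only = as.integer(n_cohort_hmc_only),
              mic_contigs = mic_contigs,
              polyteny_fold = polyteny_fold,
              n_reads_per_library = as.integer(n_reads_per_library),
              fragment_len_bp = as.integer(fragment_len_bp),
              alpha = alpha, gamma = gamma, beta = beta,
              mod_density_fwd = mod_density_fwd,
              mod_density_rev = mod_density_rev,
              skip_run_geometric_p = skip_run_geometric_p,
              hmc_fraction = hmc_fraction,
              conversion_rate = conversion_rate,
              motif_consensus = toupper(motif_consensus),
              motif_match_prob = motif_match_prob,
              motifs_per_cohort_chrom = as.integer(motifs_per_cohort_chrom),
              motif_cluster_gap = as.integer(motif_cluster_gap),
              modified_region_frac = modified_region_frac,
              telomere_unit = toupper(telomere_unit),
              base_freqs = base_freqs,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Default germline-limited contig layout
#'
#' Five satellite contigs (tandem arrays of a fixed repeat unit, including a
#' 170 bp unit) and five transposon-like contigs.
#'
#' @return data.frame with columns `kind`, `repeat_unit_bp`, `total_len_bp`.
#' @export
default_mic_contigs <- function() {
  data.frame(
    kind = c(rep("satellite", 5L), rep("transposon", 5L)),
    repeat_unit_bp = c(170L, 170L, 120L, 80L, 210L, rep(NA_integer_, 5L)),
    total_len_bp = c(3400L, 2550L, 2400L, 2400L, 3150L,
                     3000L, 2500L, 3500L, 2800L, 3200L)
  )
}

validate_sim_config <- function(cfg) {
  chk_frac <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_field(field, "must be a fraction in [0, 1]")
  }
  chk_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop_field(field, "must be a positive number")
  }
  for (f in c("mod_density_fwd", "mod_density_rev", "hmc_fraction",
              "conversion_rate", "modified_region_frac")) chk_frac(f)
  for (f in c("n_mac_chromosomes", "mac_length_mean_bp",
              "n_reads_per_library", "fragment_len_bp", "beta")) chk_pos(f)
  if (cfg$skip_run_geometric_p <= 0 || cfg$skip_run_geometric_p > 1)
    stop_field("skip_run_geometric_p", "must be in (0, 1]")
  if (cfg$polyteny_fold < 1)
    stop_field("polyteny_fold", "must be >= 1")
  if (cfg$gamma < 0) stop_field("gamma", "must be >= 0")
  if (!all(c("IgG", "mC", "hmC") %in% names(cfg$alpha)))
    stop_field("alpha", "must name IgG, mC and hmC affinities")
  if (any(cfg$alpha < 0)) stop_field("alpha", "must be >= 0")
  if (cfg$alpha[["IgG"]] != 0)
    stop_field("alpha", "must have zero IgG affinity (non-specific control)")
  if (cfg$fragment_len_bp >= cfg$mac_length_mean_bp)
    stop_field("fragment_len_bp", "must be smaller than mac_length_mean_bp")
  if (!grepl("^[ACGT]+$", cfg$motif_consensus))
    stop_field("motif_consensus", "must be a DNA string over A, C, G, T")
  if (cfg$motif_match_prob <= 0.25 || cfg$motif_match_prob > 1)
    stop_field("motif_match_prob", "must be in (0.25, 1]")
  if (cfg$n_cohort_mc + cfg$n_cohort_hmc_only > cfg$n_mac_chromosomes)
    stop_field("n_cohort_mc", "cohort chromosomes exceed n_mac_chromosomes")
  mc <- cfg$mic_contigs
  if (!is.data.frame(mc) ||
      !all(c("kind", "repeat_unit_bp", "total_len_bp") %in% names(mc)))
    stop_field("mic_contigs",
               "must be a data.frame with kind, repeat_unit_bp, total_len_bp")
  if (!all(mc$kind %in% c("satellite", "transposon")))
    stop_field("mic_contigs", "kind must be 'satellite' or 'transposon'")
  sat <- mc$kind == "satellite"
  if (any(is.na(mc$repeat_unit_bp[sat])) ||
      any(mc$repeat_unit_bp[sat] <= 0, na.rm = TRUE))
    stop_field("mic_contigs", "satellite rows need a positive repeat_unit_bp")
  if (any(mc$total_len_bp <= 0))
    stop_field("mic_contigs", "total_len_bp must be positive")
  bf <- cfg$base_freqs
  if (!all(BASES %in% names(bf)) || abs(sum(bf) - 1) > 1e-6 || any(bf <= 0))
    stop_field("base_freqs", "must be positive A/C/G/T frequencies summing to 1")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  MAC chromosomes : %d (mean %d bp; %d mC+hmC cohort, %d hmC-only)\n",
              x$n_mac_chromosomes, x$mac_length_mean_bp,
              x$n_cohort_mc, x$n_cohort_hmc_only))
  cat(sprintf("  MIC contigs     : %d (%s), polyteny %gx\n",
              nrow(x$mic_contigs),
              paste(table(x$mic_contigs$kind), collapse = " sat / "),
              x$polyteny_fold))
  cat(sprintf("  Libraries       : %g reads of %d bp fragments\n",
              x$n_reads_per_library, x$fragment_len_bp))
  cat(sprintf("  Modification    : %.2f fwd / %.2f rev density, hmC fraction %.2f\n",
              x$mod_density_fwd, x$mod_density_rev, x$hmc_fraction))
  cat(sprintf("  Seed            : %d\n", x$rng_seed))
  invisible(x)
}
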