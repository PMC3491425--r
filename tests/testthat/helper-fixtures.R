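# Fixture builders: genomes assembled in code, no stored data.

rand_seq <- function(n, freqs = c(A = 0.35, C = 0.15, G = 0.15, T = 0.35)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

# hand-built genome_model with full control over sequences and regions
make_genome <- function(mac_seqs, mic_seqs = character(0),
                        regions = NULL, copy_multiplier = 5,
                        telomere_unit = "GGGGTTTT") {
  mac <- data.frame(id = names(mac_seqs), length = nchar(mac_seqs),
                    cohort = "none", seq = unname(mac_seqs))
  mic <- if (length(mic_seqs)) {
    data.frame(id = names(mic_seqs), kind = "transposon",
               repeat_unit_bp = NA_integer_, length = nchar(mic_seqs),
               copy_multiplier = copy_multiplier, seq = unname(mic_seqs))
  } else {
    data.frame(id = character(0), kind = character(0),
               repeat_unit_bp = integer(0), length = integer(0),
               copy_multiplier = numeric(0), seq = character(0))
  }
  g <- list(mac = mac, mic = mic, modified_regions = regions,
            motif_truth = NULL, locus_maps = list(),
            telomere_unit = telomere_unit)
  class(g) <- "genome_model"
  g
}

# single-contig genome fully covered by one modified region
make_region_genome <- function(len, mark = "mc_hmc", seed = NULL,
                               id = "ctg") {
  if (!is.null(seed)) set.seed(seed)
  seqs <- stats::setNames(rand_seq(len), id)
  make_genome(seqs, regions = data.frame(contig = id, start = 1L,
                                         end = len, mark = mark))
}

# small fast config for pipeline-shaped tests
small_config <- function(...) {
  sim_config(n_mac_chromosomes = 40L, n_cohort_mc = 4L,
             n_cohort_hmc_only = 2L, n_reads_per_library = 20000L,
             mic_contigs = default_mic_contigs()[c(1, 3, 6, 7), ], ...)
}

expect_no_condition <- function(expr) expect_error(expr, NA)
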