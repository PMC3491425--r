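#' Generate a synthetic MAC + MIC genome with planted ground truth
#'
#' Builds telomere-capped macronuclear nanochromosomes and germline-limited
#' micronuclear contigs.  Cohort-flagged MAC chromosomes receive
#' `motifs_per_cohort_chrom` planted motif instances (sampled from the
#' consensus position weight matrix), clustered so that consecutive
#' instances lie within `motif_cluster_gap` bp of each other, inside the
#' chromosome's designated modified region.  Satellite MIC contigs are exact
#' tandem arrays of their repeat unit; transposon-like contigs are random
#' sequence.  MIC contigs carry no terminal telomeres and a copy multiplier
#' of `polyteny_fold`; MAC chromosomes carry the telomere unit at both ends
#' and a multiplier of 1.  A scrambled locus map (for the rearrangement
#' module) is attached as `locus_maps`.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; defaults to `config$rng_seed`.
#' @return an object of class `genome_model`: list with data.frames `mac`
#'   (id, length, cohort, seq), `mic` (id, kind, repeat_unit_bp, length,
#'   copy_multiplier, seq), `modified_regions` (contig, start, end, mark;
#'   1-based closed), `motif_truth` (contig, start, strand), `locus_maps`,
#'   and the telomere unit.
#' @export
generate_genome <- function(config, seed = config$rng_seed) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(seed, {
    telo <- strrep(config$telomere_unit, 2L)
    telo_rc <- revcomp(telo)
    n <- config$n_mac_chromosomes
    w <- config$motif_match_prob
    pwm <- pwm_from_consensus(config$motif_consensus, match_prob = w,
                              background = config$base_freqs,
                              pseudocount = 0)
    mwidth <- nchar(config$motif_consensus)

    cohort <- rep("none", n)
    if (config$n_cohort_mc > 0L) cohort[seq_len(config$n_cohort_mc)] <- "mc_hmc"
    if (config$n_cohort_hmc_only > 0L)
      cohort[config$n_cohort_mc + seq_len(config$n_cohort_hmc_only)] <- "hmc_only"

    min_len <- 4L * config$fragment_len_bp
    lens <- pmax(min_len, as.integer(round(rnorm(
      n, config$mac_length_mean_bp, 0.15 * config$mac_length_mean_bp))))

    seqs <- character(n)
    regions <- vector("list", n)
    motifs <- vector("list", n)
    for (i in seq_len(n)) {
      core_len <- lens[i] - 2L * nchar(telo)
      core <- random_dna(core_len, config$base_freqs)
      ## central modified region on cohort chromosomes (coords incl. telomere)
      if (cohort[i] != "none") {
        rlen <- as.integer(round(lens[i] * config$modified_region_frac))
        rstart <- as.integer(round((lens[i] - rlen) / 2))
        regions[[i]] <- data.frame(contig = sprintf("mac%03d", i),
                                   start = rstart, end = rstart + rlen - 1L,
                                   mark = cohort[i])
      }
      if (cohort[i] == "mc_hmc" && config$motifs_per_cohort_chrom > 0L) {
        ## plant a cluster of motif instances inside the modified region
        k <- config$motifs_per_cohort_chrom
        gaps <- sample(seq(20L, config$motif_cluster_gap - mwidth), k - 1L,
                       replace = TRUE)
        span <- k * mwidth + sum(gaps)
        r <- regions[[i]]
        if (span > r$end - r$start - 1L)
          stop("motif cluster span exceeds the modified region; ",
               "reduce motifs_per_cohort_chrom or motif_cluster_gap")
        first <- r$start + sample.int(r$end - r$start + 1L - span, 1L) - 1L
        starts <- first + cumsum(c(0L, gaps + mwidth))
        strands <- sample(c("+", "-"), k, replace = TRUE)
        chars <- seq_chars(core)
        for (j in seq_len(k)) {
          inst <- sample_pwm_instance(pwm)
          if (strands[j] == "-") inst <- revcomp(inst)
          pos <- starts[j] - nchar(telo)  # region coords include telomere cap
          chars[pos:(pos + mwidth - 1L)] <- seq_chars(inst)
        }
        core <- paste(chars, collapse = "")
        motifs[[i]] <- data.frame(contig = sprintf("mac%03d", i),
                                  start = starts, strand = strands)
      }
      seqs[i] <- paste0(telo, core, telo_rc)
    }
    mac <- data.frame(id = sprintf("mac%03d", seq_len(n)),
                      length = lens, cohort = cohort, seq = seqs)

    mcfg <- config$mic_contigs
    mic_seqs <- character(nrow(mcfg))
    mic_regions <- vector("list", nrow(mcfg))
    for (i in seq_len(nrow(mcfg))) {
      if (mcfg$kind[i] == "satellite") {
        unit <- random_dna(mcfg$repeat_unit_bp[i], config$base_freqs)
        ncopy <- mcfg$total_len_bp[i] %/% mcfg$repeat_unit_bp[i]
        mic_seqs[i] <- strrep(unit, ncopy)
      } else {
        mic_seqs[i] <- random_dna(mcfg$total_len_bp[i], config$base_freqs)
      }
      mic_regions[[i]] <- data.frame(contig = sprintf("mic%02d", i),
                                     start = 1L, end = nchar(mic_seqs[i]),
                                     mark = "mc_hmc")
    }
    mic <- data.frame(id = sprintf("mic%02d", seq_len(nrow(mcfg))),
                      kind = mcfg$kind, repeat_unit_bp = mcfg$repeat_unit_bp,
                      length = nchar(mic_seqs),
                      copy_multiplier = config$polyteny_fold, seq = mic_seqs)

    genome <- list(mac = mac, mic = mic,
                   modified_regions = do.call(rbind, c(regions, mic_regions)),
                   motif_truth = do.call(rbind, motifs),
                   locus_maps = list(simulate_locus_map(config, seed = NULL)),
                   telomere_unit = config$telomere_unit)
    class(genome) <- "genome_model"
    genome
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d MAC nanochromosomes (%d cohort-flagged), %d MIC contigs\n",
              nrow(x$mac), sum(x$mac$cohort != "none"), nrow(x$mic)))
  cat(sprintf("  planted motifs: %d; modified regions: %d; locus maps: %d\n",
              if (is.null(x$motif_truth)) 0L else nrow(x$motif_truth),
              if (is.null(x$modified_regions)) 0L else nrow(x$modified_regions),
              length(x$locus_maps)))
  invisible(x)
}

genome_sequences <- function(genome) {
  out <- c(genome$mac$seq, genome$mic$seq)
  names(out) <- c(genome$mac$id, genome$mic$id)
  out
}

genome_copy_multiplier <- function(genome) {
  out <- c(rep(1, nrow(genome$mac)), genome$mic$copy_multiplier)
  names(out) <- c(genome$mac$id, genome$mic$id)
  out
}

#' Write a genome model to FASTA (plus truth BED files)
#'
#' @param genome a `genome_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mac <- genome$mac$seq; names(mac) <- genome$mac$id
  mic <- genome$mic$seq; names(mic) <- genome$mic$id
  write_fasta(mac, file.path(dir, "mac_genome.fasta"))
  if (length(mic)) write_fasta(mic, file.path(dir, "mic_contigs.fasta"))
  if (!is.null(genome$modified_regions)) {
    df <- genome$modified_regions
    df$name <- df$mark
    write_bed(df, file.path(dir, "modified_regions.bed"))
  }
  if (!is.null(genome$motif_truth)) {
    df <- genome$motif_truth
    df$end <- df$start + nchar(attr(genome, "motif_consensus", exact = TRUE) %||% "") - 1L
    if (all(is.na(df$end)) || any(df$end < df$start))
      df$end <- df$start + 19L
    df$name <- "planted_motif"
    write_bed(df, file.path(dir, "planted_motifs.bed"))
  }
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## state codes used in modification tracks
MOD_U <- 0L; MOD_MC <- 1L; MOD_HMC <- 2L

#' Plant cytosine modifications along the genome's designated regions
#'
#' Inside each modified region, each strand's cytosines are modified at the
#' configured per-strand density; unmodified cytosines occur in skip runs
#' whose lengths follow a geometric law truncated to 1..8 (the modified
#' stretches between runs are geometric with the mean implied by the density
#' target).  In `mc_hmc` regions each modified site is hydroxymethylated
#' with probability `hmc_fraction`, otherwise methylated; `hmc_only` regions
#' carry only hydroxymethylcytosine.  Cytosines outside regions (and the
#' whole vegetative genome, see [null_track()]) are unmodified.
#'
#' @param genome a `genome_model`.
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return a `modification_track`: per contig a list with integer vectors
#'   `fwd` and `rev` of the contig length, holding 0 (unmodified), 1 (mC) or
#'   2 (hmC) at cytosine positions of the respective strand (`rev` entries
#'   sit at forward-frame G positions) and NA elsewhere.
#' @export
plant_modifications <- function(genome, config, seed = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  with_seed(seed, {
    seqs <- genome_sequences(genome)
    track <- null_track(genome)
    regs <- genome$modified_regions
    if (is.null(regs)) return(track)
    for (i in seq_len(nrow(regs))) {
      ctg <- regs$contig[i]
      if (!ctg %in% names(track))
        stop("modified region names unknown contig: ", ctg)
      L <- nchar(seqs[[ctg]])
      if (regs$start[i] < 1L || regs$end[i] > L)
        stop(sprintf("region %d:%d outside contig %s bounds (1..%d)",
                     regs$start[i], regs$end[i], ctg, L))
      span <- regs$start[i]:regs$end[i]
      for (strand in c("fwd", "rev")) {
        dens <- if (strand == "fwd") config$mod_density_fwd else config$mod_density_rev
        vec <- track[[ctg]][[strand]]
        cpos <- span[!is.na(vec[span])]
        if (!length(cpos)) next
        state <- plant_strand_states(length(cpos), dens,
                                     config$skip_run_geometric_p)
        if (regs$mark[i] == "hmc_only") {
          state[state == MOD_MC] <- MOD_HMC
        } else {
          mod <- state == MOD_MC
          hm <- mod & runif(length(state)) < config$hmc_fraction
          state[hm] <- MOD_HMC
        }
        vec[cpos] <- state
        track[[ctg]][[strand]] <- vec
      }
    }
    track
  })
}

## Alternating renewal process over the cytosine sequence: modified
## stretches are geometric with mean chosen so the expected modified
## fraction equals `density`; skip runs are geometric(p) truncated to 1..8.
plant_strand_states <- function(n_cyt, density, skip_p) {
  if (density >= 1) return(rep(MOD_MC, n_cyt))
  if (density <= 0) return(rep(MOD_U, n_cyt))
  mean_skip <- mean_trunc_geom(skip_p, 8L)
  mean_mod <- max(1, density / (1 - density) * mean_skip)
  p_mod <- 1 / mean_mod
  out <- integer(0)
  start_modified <- runif(1) < density
  while (length(out) < n_cyt) {
    g <- 1L + rgeom(1L, p_mod)
    k <- rtrunc_geom(1L, skip_p, 8L)
    if (start_modified) {
      out <- c(out, rep(MOD_MC, g), rep(MOD_U, k))
    } else {
      out <- c(out, rep(MOD_U, k), rep(MOD_MC, g))
      start_modified <- TRUE
    }
  }
  out[seq_len(n_cyt)]
}

mean_trunc_geom <- function(p, kmax) {
  k <- seq_len(kmax)
  pk <- p * (1 - p)^(k - 1L)
  sum(k * pk) / sum(pk)
}

rtrunc_geom <- function(n, p, kmax) {
  k <- seq_len(kmax)
  pk <- p * (1 - p)^(k - 1L)
  sample(k, n, replace = TRUE, prob = pk)
}

#' All-unmodified modification track (vegetative genome)
#'
#' @param genome a `genome_model`.
#' @return a `modification_track` with every cytosine unmodified.
#' @export
null_track <- function(genome) {
  seqs <- genome_sequences(genome)
  track <- lapply(seqs, function(s) {
    ch <- seq_chars(s)
    fwd <- rep(NA_integer_, length(ch)); fwd[ch == "C"] <- MOD_U
    rev <- rep(NA_integer_, length(ch)); rev[ch == "G"] <- MOD_U
    list(fwd = fwd, rev = rev)
  })
  class(track) <- "modification_track"
  track
}

#' Summarise per-strand modified fractions of a track
#'
#' @param track a `modification_track`.
#' @param contig contig id.
#' @param start,end optional 1-based closed bounds.
#' @return data.frame with strand, n_cytosine, n_modified, n_hmc, fraction.
#' @export
track_density <- function(track, contig, start = 1L, end = NULL) {
  tr <- track[[contig]]
  if (is.null(tr)) stop("unknown contig: ", contig)
  if (is.null(end)) end <- length(tr$fwd)
  span <- start:end
  res <- lapply(c("fwd", "rev"), function(st) {
    v <- tr[[st]][span]
    v <- v[!is.na(v)]
    data.frame(strand = if (st == "fwd") "+" else "-",
               n_cytosine = length(v),
               n_modified = sum(v > 0L),
               n_hmc = sum(v == MOD_HMC),
               fraction = if (length(v)) sum(v > 0L) / length(v) else NA_real_)
  })
  do.call(rbind, res)
}
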