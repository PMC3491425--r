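#' Simulate a methyl-DNA immunoprecipitation sequencing library
#'
#' Fragments are modeled as fixed-length sliding windows over every contig,
#' sampled with replacement.  A window's sampling weight is
#' \deqn{w = \beta + \gamma \cdot n_C + \alpha_{ab} \cdot n_{mod},}
#' where \eqn{n_C} counts cytosines on both strands of the fragment
#' (capturing the antibodies' weak cross-reactivity to unmodified cytosine
#' and bead background \eqn{\beta}), and \eqn{n_{mod}} counts the modified
#' cytosines recognized by the antibody (mC antibody sees methylcytosine,
#' hmC antibody sees hydroxymethylcytosine, IgG sees nothing).  Fragment
#' origin is additionally weighted by the contig's copy multiplier, so
#' polytenized germline contigs are over-represented at 46 h.
#'
#' @param genome a `genome_model`.
#' @param track a `modification_track`; use [null_track()] for the
#'   vegetative timepoint.
#' @param antibody one of "IgG", "mC", "hmC".
#' @param timepoint "veg" or "46h" (metadata only; the biology enters
#'   through `track` and the genome's copy multipliers, which are taken at
#'   face value for 46 h and forced to 1 for vegetative libraries).
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @param emit_reads if TRUE, also sample per-read window offsets and return
#'   read sequences (needed for SAM export and depth tracks).
#' @return a `medip_library`: list with `counts` (data.frame contig, count),
#'   `total_mapped`, `contig_lengths`, `antibody`, `timepoint`, and (if
#'   requested) `reads` (data.frame contig, start, seq; 1-based).
#' @export
simulate_medip_library <- function(genome, track, antibody = c("IgG", "mC", "hmC"),
                                   timepoint = c("46h", "veg"), config,
                                   seed = NULL, emit_reads = FALSE) {
  antibody <- match.arg(antibody)
  timepoint <- match.arg(timepoint)
  stopifnot(inherits(genome, "genome_model"))
  with_seed(seed, {
    seqs <- genome_sequences(genome)
    cm <- genome_copy_multiplier(genome)
    if (timepoint == "veg") cm[] <- 1
    frag <- config$fragment_len_bp
    alpha <- config$alpha[[antibody]]
    recog <- c(IgG = NA_integer_, mC = MOD_MC, hmC = MOD_HMC)[[antibody]]

    weights <- vector("list", length(seqs))
    names(weights) <- names(seqs)
    for (ctg in names(seqs)) {
      L <- nchar(seqs[[ctg]])
      if (L < frag) { weights[[ctg]] <- numeric(0); next }
      ch <- seq_chars(seqs[[ctg]])
      is_c <- as.integer(ch == "C" | ch == "G")
      n_c <- window_sums(is_c, frag)
      w <- config$beta + config$gamma * n_c
      if (alpha > 0 && !is.na(recog)) {
        tr <- track[[ctg]]
        mod <- as.integer(!is.na(tr$fwd) & tr$fwd == recog) +
               as.integer(!is.na(tr$rev) & tr$rev == recog)
        w <- w + alpha * window_sums(mod, frag)
      }
      weights[[ctg]] <- w * cm[[ctg]]
    }
    totals <- vapply(weights, sum, numeric(1))
    if (sum(totals) <= 0)
      stop("simulation error: total fragment weight is zero")
    n <- config$n_reads_per_library
    counts <- as.vector(rmultinom(1L, n, prob = totals))
    lib <- list(counts = data.frame(contig = names(seqs), count = counts),
                total_mapped = n,
                contig_lengths = stats::setNames(nchar(seqs), names(seqs)),
                antibody = antibody, timepoint = timepoint,
                fragment_len = frag)
    if (emit_reads) {
      reads <- vector("list", length(seqs))
      for (i in seq_along(seqs)) {
        k <- counts[i]
        if (k == 0L) next
        ctg <- names(seqs)[i]
        off <- sample.int(length(weights[[ctg]]), k, replace = TRUE,
                          prob = weights[[ctg]])
        reads[[i]] <- data.frame(contig = ctg, start = off,
                                 seq = substring(seqs[[ctg]], off,
                                                 off + frag - 1L))
      }
      lib$reads <- do.call(rbind, reads)
    }
    class(lib) <- "medip_library"
    lib
  })
}

## rolling window sums of an integer vector (window w, stride 1)
window_sums <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1L):length(cs)] - cs[seq_len(length(cs) - w)]
}

#' Simulate the full six-library immunoprecipitation design
#'
#' IgG, mC and hmC antibodies at the vegetative and 46 h timepoints.  The
#' vegetative libraries share the all-unmodified track, so their expected
#' per-contig proportions are exchangeable across antibodies.
#'
#' @param genome a `genome_model`.
#' @param track the 46 h `modification_track`.
#' @param config a [sim_config()].
#' @param seed optional integer seed (each library draws from the stream).
#' @return named list of six `medip_library` objects
#'   (`igg_veg`, `igg_46h`, `mc_veg`, `mc_46h`, `hmc_veg`, `hmc_46h`).
#' @export
simulate_medip_design <- function(genome, track, config, seed = NULL) {
  with_seed(seed, {
    veg <- null_track(genome)
    list(
      igg_veg = simulate_medip_library(genome, veg, "IgG", "veg", config),
      igg_46h = simulate_medip_library(genome, track, "IgG", "46h", config),
      mc_veg  = simulate_medip_library(genome, veg, "mC", "veg", config),
      mc_46h  = simulate_medip_library(genome, track, "mC", "46h", config),
      hmc_veg = simulate_medip_library(genome, veg, "hmC", "veg", config),
      hmc_46h = simulate_medip_library(genome, track, "hmC", "46h", config)
    )
  })
}

#' Write a simulated library as SAM (plus its count table)
#'
#' The library must have been simulated with `emit_reads = TRUE`.  Reads
#' are written as primary, forward-strand alignments with full-length
#' match CIGARs against the genome the library was simulated from.
#'
#' @param lib a `medip_library` with a `reads` component.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_library_sam <- function(lib, path) {
  if (is.null(lib$reads))
    stop("library was simulated without emit_reads = TRUE")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (ctg in names(lib$contig_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ctg, lib$contig_lengths[[ctg]]), con)
  r <- lib$reads
  writeLines(sprintf("read%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                     seq_len(nrow(r)), r$contig, r$start,
                     nchar(r$seq), r$seq), con)
  invisible(path)
}

#' Write a library's per-contig count table as TSV
#'
#' Format: a `#total=<n>` header line followed by a headered two-column
#' table `contig`, `count`.
#'
#' @param lib a `medip_library`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(lib, path) {
  con <- file(path, "w")
  writeLines(sprintf("#total=%d", lib$total_mapped), con)
  close(con)
  suppressWarnings(
    write.table(lib$counts, path, sep = "\t", quote = FALSE,
                row.names = FALSE, append = TRUE))
  invisible(path)
}
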