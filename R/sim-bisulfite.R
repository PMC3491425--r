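#' Simulate bisulfite-converted clone sequences from a region
#'
#' Each clone is an independent bisulfite conversion of one template strand
#' of the reference region.  On the forward template, every unmodified
#' cytosine deaminates to thymine with probability `conversion_rate`;
#' methylated and hydroxymethylated cytosines never convert (the two are
#' indistinguishable by bisulfite sequencing).  Clones from the reverse
#' template are reported on the forward coordinate frame, so conversion
#' appears as G-to-A substitutions.
#'
#' @param genome a `genome_model` (or a named character vector of
#'   sequences).
#' @param track a `modification_track` for the sample being cloned.
#' @param contig contig id.
#' @param start,end 1-based closed region bounds.
#' @param n_clones number of clones to draw.
#' @param config a [sim_config()] (supplies `conversion_rate`).
#' @param seed optional integer seed.
#' @param strand "both" (each clone picks a template uniformly), "+" or "-".
#' @param per_molecule if TRUE, each clone is an independent molecule: its
#'   modification states are replanted from the configured densities
#'   rather than read from the shared `track`.  This is the faithful model
#'   for a pool of sequenced clones (each DNA molecule carries its own
#'   pattern; skip runs differ between reads); the default track-based
#'   mode keeps clones identical to the genomic truth, which is what
#'   exact-recovery checks need.
#' @return a data.frame with columns `clone_id`, `template` ("forward" /
#'   "reverse"), `seq` (forward-frame clone sequence).  The reference
#'   subsequence is attached as attribute `reference`.
#' @export
simulate_bisulfite_clones <- function(genome, track, contig, start, end,
                                      n_clones, config, seed = NULL,
                                      strand = c("both", "+", "-"),
                                      per_molecule = FALSE) {
  strand <- match.arg(strand)
  seqs <- if (inherits(genome, "genome_model")) genome_sequences(genome) else genome
  if (!contig %in% names(seqs)) stop("unknown contig: ", contig)
  L <- nchar(seqs[[contig]])
  if (start < 1L || end > L || start > end)
    stop(sprintf("empty or out-of-bounds region %d..%d on %s (length %d)",
                 start, end, contig, L))
  with_seed(seed, {
    ref <- substr(seqs[[contig]], start, end)
    ch <- seq_chars(ref)
    span <- start:end
    fwd_state <- track[[contig]]$fwd[span]
    rev_state <- track[[contig]]$rev[span]
    cr <- config$conversion_rate
    out <- vector("list", n_clones)
    for (i in seq_len(n_clones)) {
      tmpl <- switch(strand, both = sample(c("forward", "reverse"), 1L),
                     "+" = "forward", "-" = "reverse")
      if (tmpl == "forward") {
        st <- fwd_state
        if (per_molecule) {
          st <- rep(NA_integer_, length(ch))
          cpos <- which(ch == "C")
          st[cpos] <- plant_strand_states(length(cpos),
                                          config$mod_density_fwd,
                                          config$skip_run_geometric_p)
        }
      } else {
        st <- rev_state
        if (per_molecule) {
          st <- rep(NA_integer_, length(ch))
          gpos <- which(ch == "G")
          st[gpos] <- plant_strand_states(length(gpos),
                                          config$mod_density_rev,
                                          config$skip_run_geometric_p)
        }
      }
      clone <- ch
      if (tmpl == "forward") {
        conv <- !is.na(st) & st == MOD_U & runif(length(ch)) < cr
        clone[conv] <- "T"
      } else {
        conv <- !is.na(st) & st == MOD_U & runif(length(ch)) < cr
        clone[conv] <- "A"
      }
      out[[i]] <- data.frame(clone_id = sprintf("clone%03d", i),
                             template = tmpl,
                             seq = paste(clone, collapse = ""))
    }
    res <- do.call(rbind, out)
    attr(res, "reference") <- ref
    attr(res, "region") <- list(contig = contig, start = start, end = end)
    res
  })
}
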