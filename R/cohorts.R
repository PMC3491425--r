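#' Methylation cohort: contigs with over `min_excess` excess 46 h reads
#'
#' Membership is strict (`excess_mc > min_excess`): the defining rule is
#' "over 100 excess reads" in the methylcytosine library.
#'
#' @param signal_table output of [build_signal_table()] (somatic contigs
#'   only; extract germline contigs first).
#' @param min_excess threshold, reads.
#' @return character vector of member contigs.
#' @export
build_methylation_cohort <- function(signal_table, min_excess = 100) {
  stopifnot("excess_mc" %in% names(signal_table))
  signal_table$contig[signal_table$excess_mc > min_excess]
}

#' Automatic "natural break" threshold for the methylation cohort
#'
#' Finds the largest gap in the upper tail of the sorted excess-read
#' distribution.  Offered as an alternative to the fixed default threshold;
#' not used unless requested.
#'
#' @param excess numeric vector of excess reads.
#' @param tail_n number of top contigs searched for the break.
#' @return threshold placed in the middle of the widest gap.
#' @export
natural_break_threshold <- function(excess, tail_n = 50L) {
  s <- sort(excess, decreasing = TRUE)
  s <- s[seq_len(min(tail_n, length(s)))]
  gaps <- -diff(s)
  i <- which.max(gaps)
  (s[i] + s[i + 1L]) / 2
}

#' Hydroxymethylation cohort
#'
#' Member iff `excess_hmc >= min_excess` *and* the
#' hydroxymethylation-to-IgG signal ratio is at least `min_ratio`.  A
#' contig whose IgG signal is non-positive passes the ratio test by
#' definition (IgG depletion cannot mask enrichment); otherwise the ratio
#' denominator is floored at `eps_ratio` to guard division.
#'
#' @param signal_table output of [build_signal_table()].
#' @param min_excess excess-read threshold (inclusive).
#' @param min_ratio hmC-signal to IgG-signal ratio threshold (inclusive).
#' @param eps_ratio denominator floor, RPKM.
#' @return character vector of member contigs.
#' @export
build_hmc_cohort <- function(signal_table, min_excess = 40, min_ratio = 1.5,
                             eps_ratio = 1) {
  stopifnot(all(c("excess_hmc", "signal_hmc", "signal_igg") %in%
                names(signal_table)))
  ratio_ok <- signal_table$signal_igg <= 0 |
    signal_table$signal_hmc / pmax(signal_table$signal_igg, eps_ratio) >= min_ratio
  signal_table$contig[signal_table$excess_hmc >= min_excess & ratio_ok]
}

#' CC-motif cohort: contigs carrying at least `min_motifs` significant hits
#'
#' @param motif_counts data.frame `contig`, `n_motifs` (as from
#'   [scan_genome()]).
#' @param min_motifs threshold (inclusive).
#' @return character vector of member contigs.
#' @export
build_cc_cohort <- function(motif_counts, min_motifs = 3L) {
  stopifnot(all(c("contig", "n_motifs") %in% names(motif_counts)))
  motif_counts$contig[motif_counts$n_motifs >= min_motifs]
}

#' Venn decomposition of the three cohorts
#'
#' @param mc,hmc,cc character vectors of cohort members.
#' @return named list of the 7 disjoint region counts (`mc_only`,
#'   `hmc_only`, `cc_only`, `mc_hmc`, `mc_cc`, `hmc_cc`, `mc_hmc_cc`) plus
#'   cohort sizes and the union size.
#' @export
cohort_overlap <- function(mc, hmc, cc) {
  u <- union(union(mc, hmc), cc)
  in_mc <- u %in% mc; in_hmc <- u %in% hmc; in_cc <- u %in% cc
  region <- function(a, b, c) sum(in_mc == a & in_hmc == b & in_cc == c)
  out <- list(mc_only = region(TRUE, FALSE, FALSE),
              hmc_only = region(FALSE, TRUE, FALSE),
              cc_only = region(FALSE, FALSE, TRUE),
              mc_hmc = region(TRUE, TRUE, FALSE),
              mc_cc = region(TRUE, FALSE, TRUE),
              hmc_cc = region(FALSE, TRUE, TRUE),
              mc_hmc_cc = region(TRUE, TRUE, TRUE),
              size_mc = length(mc), size_hmc = length(hmc),
              size_cc = length(cc), union = length(u))
  stopifnot(sum(unlist(out[1:7])) == out$union)
  out
}

#' Assemble the cohort table with supporting values
#'
#' One row per contig with the values every membership decision is
#' recomputable from (excess reads, signals, the hmC/IgG ratio, motif
#' counts) and the three cohort flags.
#'
#' @param signal_table output of [build_signal_table()].
#' @param motif_counts data.frame `contig`, `n_motifs`.
#' @param min_excess_mc,min_excess_hmc,min_ratio,eps_ratio,min_motifs
#'   thresholds as in the cohort builders.
#' @return data.frame with supporting values and logical `in_mc_cohort`,
#'   `in_hmc_cohort`, `in_cc_cohort` columns.
#' @export
cohort_table <- function(signal_table, motif_counts,
                         min_excess_mc = 100, min_excess_hmc = 40,
                         min_ratio = 1.5, eps_ratio = 1, min_motifs = 3L) {
  df <- signal_table
  m <- match(df$contig, motif_counts$contig)
  df$n_motifs <- ifelse(is.na(m), 0L, motif_counts$n_motifs[m])
  df$hmc_to_igg_ratio <- df$signal_hmc / pmax(df$signal_igg, eps_ratio)
  df$in_mc_cohort <- df$contig %in%
    build_methylation_cohort(signal_table, min_excess_mc)
  df$in_hmc_cohort <- df$contig %in%
    build_hmc_cohort(signal_table, min_excess_hmc, min_ratio, eps_ratio)
  df$in_cc_cohort <- df$contig %in% build_cc_cohort(df, min_motifs)
  df
}
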