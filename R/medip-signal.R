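#' Count mapped reads per contig from a SAM file or count table
#'
#' SAM input is converted and filtered through Rsamtools: only mapped,
#' primary alignments are counted (secondary and unmapped records are
#' excluded).  TSV input must carry a `#total=<n>` header line followed by
#' a headered `contig`, `count` table.
#'
#' @param path SAM (`.sam`) or TSV path.
#' @param contig_lengths named numeric vector of contig lengths, or a FASTA
#'   path from which lengths are taken.  Contigs present in the input but
#'   absent here raise a reference mismatch error.
#' @param antibody,timepoint optional metadata attached to the result.
#' @return a `medip_library` (see [simulate_medip_library()]).
#' @export
count_reads <- function(path, contig_lengths, antibody = NA_character_,
                        timepoint = NA_character_) {
  if (is.character(contig_lengths) && length(contig_lengths) == 1L &&
      file.exists(contig_lengths)) {
    fa <- Biostrings::readDNAStringSet(contig_lengths)
    contig_lengths <- stats::setNames(Biostrings::width(fa),
                                      sub("\\s.*$", "", names(fa)))
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    counts <- count_sam_primary(path)
  } else {
    counts <- read_count_table(path)
  }
  unknown <- setdiff(counts$counts$contig, names(contig_lengths))
  if (length(unknown))
    stop("reference mismatch: contigs absent from the FASTA index: ",
         paste(head(unknown, 5L), collapse = ", "))
  ## contigs with zero reads still appear, in index order
  full <- data.frame(contig = names(contig_lengths), count = 0L)
  m <- match(counts$counts$contig, full$contig)
  full$count[m] <- counts$counts$count
  lib <- list(counts = full, total_mapped = counts$total,
              contig_lengths = contig_lengths,
              antibody = antibody, timepoint = timepoint)
  class(lib) <- "medip_library"
  lib
}

count_sam_primary <- function(path) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, what = "rname")
  rn <- Rsamtools::scanBam(bam, param = param)[[1L]]$rname
  tab <- table(rn)
  tab <- tab[tab > 0L]
  list(counts = data.frame(contig = names(tab),
                           count = as.integer(tab)),
       total = length(rn))
}

read_count_table <- function(path) {
  lines <- readLines(path)
  tot_line <- grep("^#total=", lines, value = TRUE)
  if (!length(tot_line))
    stop("parse error: count table lacks a '#total=' header line")
  total <- as.integer(sub("^#total=", "", tot_line[1L]))
  body <- lines[!grepl("^#", lines)]
  df <- read.table(text = body, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  if (!all(c("contig", "count") %in% names(df)))
    stop("parse error: count table needs 'contig' and 'count' columns")
  if (any(df$count < 0)) stop("parse error: negative read count")
  if (sum(df$count) > total)
    stop("parse error: per-contig counts exceed #total")
  list(counts = df[c("contig", "count")], total = total)
}

#' Reads per kilobase of contig per million mapped reads
#'
#' \eqn{\mathrm{RPKM} = c / (L/10^3) / (T/10^6)} for count \eqn{c}, contig
#' length \eqn{L} bp and library depth \eqn{T} mapped reads.
#'
#' @param count read count (vectorised).
#' @param contig_length_bp contig length, bp (> 0).
#' @param total_mapped library total mapped reads (> 0).
#' @return numeric RPKM.
#' @export
compute_rpkm <- function(count, contig_length_bp, total_mapped) {
  if (any(contig_length_bp <= 0))
    stop("contig_length_bp must be positive")
  if (any(total_mapped <= 0))
    stop("total_mapped must be positive")
  count / (contig_length_bp / 1e3) / (total_mapped / 1e6)
}

#' Vegetative-subtracted antibody signal per contig
#'
#' The 46 h RPKM minus the same antibody's vegetative RPKM, per contig -
#' the quantity that removes antibody cross-reactivity to unmodified
#' cytosine and bead background.  Excess reads are the depth-normalized raw
#' count difference, `count_46h - count_veg * (total_46h / total_veg)`,
#' rounded half away from zero (cohort thresholds are quoted in reads).
#' Negative values are retained: depletion is informative.
#'
#' @param lib_46h,lib_veg `medip_library` objects for the same antibody
#'   with identical contig sets.
#' @return data.frame `contig`, `length`, `rpkm_veg`, `rpkm_46h`, `signal`,
#'   `excess`.
#' @export
compute_signal <- function(lib_46h, lib_veg) {
  if (!identical(lib_46h$antibody, lib_veg$antibody))
    stop("pairing error: libraries use different antibodies (",
         lib_46h$antibody, " vs ", lib_veg$antibody, ")")
  if (!setequal(lib_46h$counts$contig, lib_veg$counts$contig))
    stop("pairing error: contig sets differ between libraries")
  a <- lib_46h$counts
  b <- lib_veg$counts[match(a$contig, lib_veg$counts$contig), ]
  len <- lib_46h$contig_lengths[a$contig]
  rpkm46 <- compute_rpkm(a$count, len, lib_46h$total_mapped)
  rpkmv <- compute_rpkm(b$count, len, lib_veg$total_mapped)
  scale <- lib_46h$total_mapped / lib_veg$total_mapped
  data.frame(contig = a$contig, length = as.integer(len),
             rpkm_veg = rpkmv, rpkm_46h = rpkm46,
             signal = rpkm46 - rpkmv,
             excess = round_half_away(a$count - b$count * scale),
             row.names = NULL)
}

#' Build the per-contig signal table across the six-library design
#'
#' @param libs named list with elements `igg_veg`, `igg_46h`, `mc_veg`,
#'   `mc_46h`, `hmc_veg`, `hmc_46h` (as from [simulate_medip_design()] or
#'   six [count_reads()] calls).
#' @return data.frame with per-library RPKM columns, per-antibody `signal_*`
#'   (RPKM difference) and `excess_*` (depth-normalized read difference)
#'   columns.
#' @export
build_signal_table <- function(libs) {
  need <- c("igg_veg", "igg_46h", "mc_veg", "mc_46h", "hmc_veg", "hmc_46h")
  if (!all(need %in% names(libs)))
    stop("libs must contain: ", paste(need, collapse = ", "))
  igg <- compute_signal(libs$igg_46h, libs$igg_veg)
  mc <- compute_signal(libs$mc_46h, libs$mc_veg)
  hmc <- compute_signal(libs$hmc_46h, libs$hmc_veg)
  stopifnot(identical(igg$contig, mc$contig),
            identical(igg$contig, hmc$contig))
  data.frame(contig = igg$contig, length = igg$length,
             rpkm_igg_veg = igg$rpkm_veg, rpkm_igg_46h = igg$rpkm_46h,
             rpkm_mc_veg = mc$rpkm_veg, rpkm_mc_46h = mc$rpkm_46h,
             rpkm_hmc_veg = hmc$rpkm_veg, rpkm_hmc_46h = hmc$rpkm_46h,
             signal_igg = igg$signal, signal_mc = mc$signal,
             signal_hmc = hmc$signal,
             excess_mc = mc$excess, excess_hmc = hmc$excess,
             row.names = NULL)
}

#' Per-window read depth track for one contig
#'
#' Raw fragment pile-up depth in fixed windows, for signal-track plotting;
#' window read starts sum to the contig's read count.
#'
#' @param lib a `medip_library` simulated with `emit_reads = TRUE`.
#' @param contig contig id.
#' @param window window width, bp.
#' @return data.frame `start`, `end` (1-based closed), `n_reads`.
#' @export
depth_track <- function(lib, contig, window = 50L) {
  if (is.null(lib$reads))
    stop("library has no per-read positions; simulate with emit_reads = TRUE")
  L <- lib$contig_lengths[[contig]]
  starts <- seq(1L, L, by = window)
  r <- lib$reads[lib$reads$contig == contig, ]
  bin <- findInterval(r$start, starts)
  n <- tabulate(bin, nbins = length(starts))
  data.frame(start = starts, end = pmin(starts + window - 1L, L), n_reads = n)
}
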