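#' @keywords internal
"_PACKAGE"

#' @importFrom stats rmultinom rnorm rbinom runif rgeom sd var t.test pt
#' @importFrom utils read.table write.table head tail
NULL

BASES <- c("A", "C", "G", "T")

## vectorised reverse complement for plain character sequences
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## sample a random DNA string from mononucleotide frequencies
random_dna <- function(n, base_freqs) {
  paste(sample(names(base_freqs), n, replace = TRUE, prob = base_freqs),
        collapse = "")
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

## write a data.frame as a headered TSV
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}

## intervals are 1-based closed in memory; BED output is 0-based half-open
write_bed <- function(df, path) {
  stopifnot(all(c("contig", "start", "end") %in% names(df)))
  bed <- data.frame(chrom = df$contig,
                    chromStart = df$start - 1L,
                    chromEnd = df$end,
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = if ("score" %in% names(df)) df$score else 0L,
                    strand = if ("strand" %in% names(df)) df$strand else ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the configuration echo, seed, package version and a content hash
#' for every output file, so a run can be audited and reproduced.
#'
#' @param out_dir directory whose files are hashed.
#' @param config configuration object (echoed verbatim).
#' @param seed integer seed used for the run.
#' @param path manifest path; defaults to `manifest.json` in `out_dir`.
#' @return path to the manifest, invisibly.
#' @export
write_manifest <- function(out_dir, config = NULL, seed = NULL,
                           path = file.path(out_dir, "manifest.json")) {
  files <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                   normalizePath(path, mustWork = FALSE))
  hashes <- tools::md5sum(files)
  manifest <- list(
    package = "methelim",
    version = as.character(utils::packageVersion("methelim")),
    seed = seed,
    config = config,
    files = data.frame(path = basename(names(hashes)), md5 = unname(hashes))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
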