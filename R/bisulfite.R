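## Bisulfite-aware substitution matrices.  Indexing is
## m[reference_base, read_base]; a converted base (ref C read as T on the
## forward template, ref G read as A on the reverse template) scores as a
## match.
bisulfite_submat <- function(template = c("forward", "reverse"),
                             match = 1, mismatch = -2) {
  template <- match.arg(template)
  m <- matrix(mismatch, 4L, 4L, dimnames = list(BASES, BASES))
  diag(m) <- match
  if (template == "forward") m["C", "T"] <- match else m["G", "A"] <- match
  m
}

#' Align a bisulfite clone to its reference region
#'
#' Global (Needleman-Wunsch) alignment via Biostrings with
#' bisulfite-aware scoring: on the forward template a reference C read as
#' T scores as a match, on the reverse template a reference G read as A.
#' Four candidates are evaluated - each template against the clone as
#' given and reverse-complemented - and the one with the fewest
#' non-bisulfite mismatches wins; clones are always reported on the
#' forward frame of the reference.
#'
#' @param reference reference region sequence (forward frame).
#' @param clone clone sequence.
#' @param min_identity alignments below this identity in every orientation
#'   raise a "clone does not map" error.
#' @return a `clone_alignment`: list with gapped strings `ref` and `read`,
#'   `template` ("forward"/"reverse"), `n_mismatch` (non-bisulfite),
#'   `identity`.
#' @export
align_clone <- function(reference, clone, min_identity = 0.7) {
  if (!nchar(reference) || !nchar(clone))
    stop("reference and clone must be non-empty")
  cand <- list(
    list(template = "forward", read = clone),
    list(template = "reverse", read = clone),
    list(template = "forward", read = revcomp(clone)),
    list(template = "reverse", read = revcomp(clone))
  )
  best <- NULL
  for (cn in cand) {
    mat <- bisulfite_submat(cn$template)
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(reference),
      subject = Biostrings::DNAString(cn$read),
      substitutionMatrix = mat, type = "global",
      gapOpening = 6, gapExtension = 2)
    ref_s <- as.character(Biostrings::alignedPattern(pa))
    read_s <- as.character(Biostrings::alignedSubject(pa))
    stats <- alignment_stats(ref_s, read_s, cn$template)
    if (is.null(best) || stats$n_mismatch < best$n_mismatch ||
        (stats$n_mismatch == best$n_mismatch && stats$identity > best$identity)) {
      best <- c(list(ref = ref_s, read = read_s, template = cn$template),
                stats)
    }
  }
  if (best$identity < min_identity)
    stop(sprintf("clone does not map: best identity %.2f < %.2f",
                 best$identity, min_identity))
  class(best) <- "clone_alignment"
  best
}

## identity counts bisulfite conversions as matches
alignment_stats <- function(ref_s, read_s, template) {
  r <- seq_chars(ref_s); q <- seq_chars(read_s)
  aligned <- r != "-" & q != "-"
  conv <- if (template == "forward") r == "C" & q == "T" else r == "G" & q == "A"
  match <- aligned & (r == q | conv)
  n_mm <- sum(aligned) - sum(match[aligned])
  list(n_mismatch = n_mm,
       identity = if (length(r)) sum(match) / length(r) else 0)
}

#' Classify the sequence context of a cytosine
#'
#' Contexts are read in the template strand's own sense: for a forward
#' cytosine the next two downstream bases; for a reverse-strand cytosine
#' (a G on the forward frame) the complements of the two upstream bases.
#' CpG if the next base is G; CpHpG if the next base is A/C/T and the one
#' after is G; CpHpH otherwise; NA at contig boundaries.
#'
#' @param reference forward-frame reference sequence.
#' @param position 1-based position of the cytosine (forward frame).
#' @param strand "+" or "-".
#' @return "CpG", "CpHpG", "CpHpH" or NA.
#' @export
classify_context <- function(reference, position, strand = "+") {
  ch <- seq_chars(reference)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  get <- function(i, sense) {
    if (i < 1L || i > length(ch)) return(NA_character_)
    b <- ch[i]
    if (!b %in% BASES) return(NA_character_)
    if (sense) b else comp[[b]]
  }
  if (strand == "+") {
    if (ch[position] != "C") stop("position is not a forward-strand cytosine")
    b1 <- get(position + 1L, TRUE); b2 <- get(position + 2L, TRUE)
  } else {
    if (ch[position] != "G") stop("position is not a reverse-strand cytosine")
    b1 <- get(position - 1L, FALSE); b2 <- get(position - 2L, FALSE)
  }
  if (is.na(b1)) return(NA_character_)
  if (b1 == "G") return("CpG")
  if (is.na(b2)) return(NA_character_)
  if (b2 == "G") "CpHpG" else "CpHpH"
}

#' Call per-cytosine methylation from a clone alignment
#'
#' Forward template: reference C with read C is methylated, with read T
#' unmethylated; any other pairing (or a gap) is ambiguous.  Reverse
#' template symmetric on reference G with read G/A.  Positions inside
#' primer intervals are masked regardless of pairing (primer-site
#' methylation cannot be sequenced from PCR products); when no intervals
#' are supplied the outermost `default_primer_bp` of the region are masked
#' with a warning.
#'
#' @param alignment a `clone_alignment`.
#' @param primer_intervals data.frame `start`, `end` (1-based closed,
#'   region coordinates), or NULL.
#' @param default_primer_bp width of the default terminal masks.
#' @param clone_id identifier copied into the output.
#' @return data.frame `clone_id`, `pos` (1-based region coordinate),
#'   `strand`, `context`, `call` in
#'   {methylated, unmethylated, ambiguous, masked}.
#' @export
call_sites <- function(alignment, primer_intervals = NULL,
                       default_primer_bp = 20L, clone_id = "clone") {
  stopifnot(inherits(alignment, "clone_alignment"))
  r <- seq_chars(alignment$ref)
  q <- seq_chars(alignment$read)
  ref_len <- sum(r != "-")
  if (is.null(primer_intervals)) {
    warning("no primer intervals supplied; masking the outermost ",
            default_primer_bp, " bp of the region")
    primer_intervals <- data.frame(
      start = c(1L, ref_len - default_primer_bp + 1L),
      end = c(default_primer_bp, ref_len))
  }
  if (nrow(primer_intervals) &&
      (any(primer_intervals$start < 1L) || any(primer_intervals$end > ref_len)))
    stop("primer interval outside the aligned region")
  masked_pos <- unlist(mapply(seq, primer_intervals$start,
                              primer_intervals$end, SIMPLIFY = FALSE))
  target <- if (alignment$template == "forward") "C" else "G"
  conv_to <- if (alignment$template == "forward") "T" else "A"
  strand <- if (alignment$template == "forward") "+" else "-"
  refseq <- paste(r[r != "-"], collapse = "")

  pos <- cumsum(r != "-")
  keep <- r == target
  out <- data.frame(clone_id = clone_id, pos = pos[keep],
                    strand = strand,
                    ref = r[keep], read = q[keep],
                    stringsAsFactors = FALSE)
  out$call <- ifelse(out$read == target, "methylated",
                     ifelse(out$read == conv_to, "unmethylated", "ambiguous"))
  out$call[out$pos %in% masked_pos] <- "masked"
  out$context <- vapply(out$pos, function(pp)
    classify_context(refseq, pp, strand), character(1))
  out[c("clone_id", "pos", "strand", "context", "call")]
}

#' Call sites for a set of clones against one reference
#'
#' Convenience wrapper: aligns each clone and concatenates the per-site
#' calls.
#'
#' @param reference forward-frame region sequence.
#' @param clones data.frame with `clone_id` and `seq` columns (as from
#'   [simulate_bisulfite_clones()]) or a named character vector.
#' @param primer_intervals see [call_sites()].
#' @param min_identity see [align_clone()].
#' @return combined per-site call data.frame.
#' @export
call_clones <- function(reference, clones, primer_intervals = NULL,
                        min_identity = 0.7) {
  if (is.character(clones))
    clones <- data.frame(clone_id = names(clones), seq = unname(clones))
  out <- lapply(seq_len(nrow(clones)), function(i) {
    aln <- align_clone(reference, clones$seq[i], min_identity)
    call_sites(aln, primer_intervals, clone_id = clones$clone_id[i])
  })
  do.call(rbind, out)
}

#' Skip runs: lengths of consecutive unmethylated cytosine calls
#'
#' Masked and ambiguous calls are dropped before run-length encoding, so a
#' run is consecutive in cytosine order among scored sites.
#'
#' @param calls per-site call data.frame for one clone and strand, ordered
#'   by position.
#' @return integer vector of run lengths (empty when fully methylated).
#' @export
skip_runs <- function(calls) {
  v <- calls$call[calls$call %in% c("methylated", "unmethylated")]
  if (!length(v)) return(integer(0))
  rl <- rle(v == "unmethylated")
  as.integer(rl$lengths[rl$values])
}

#' Summarise clone calls: per-strand and per-context fractions, skip runs
#'
#' @param calls combined per-site call data.frame (any number of clones).
#' @param per_clone if TRUE, strand percentages average per-clone fractions
#'   instead of pooling counts.
#' @return a `clone_report`: list with `by_strand` (n_meth, n_unmeth,
#'   percent per strand), `by_context`, `skip_runs` (all run lengths across
#'   clones and strands), and counts of ambiguous and masked sites.
#' @export
clone_report <- function(calls, per_clone = FALSE) {
  scored <- calls[calls$call %in% c("methylated", "unmethylated"), ]
  pct <- function(df) {
    if (!nrow(df)) return(NA_real_)
    100 * sum(df$call == "methylated") / nrow(df)
  }
  by_strand <- do.call(rbind, lapply(c("+", "-"), function(s) {
    d <- scored[scored$strand == s, ]
    p <- if (per_clone && nrow(d)) {
      mean(vapply(split(d, d$clone_id), pct, numeric(1)), na.rm = TRUE)
    } else pct(d)
    data.frame(strand = s, n_meth = sum(d$call == "methylated"),
               n_unmeth = sum(d$call == "unmethylated"), percent = p)
  }))
  ctx <- scored[!is.na(scored$context), ]
  by_context <- do.call(rbind, lapply(split(ctx, ctx$context), function(d)
    data.frame(context = d$context[1L],
               n_meth = sum(d$call == "methylated"),
               n_unmeth = sum(d$call == "unmethylated"), percent = pct(d))))
  runs <- unlist(lapply(split(calls, list(calls$clone_id, calls$strand),
                              drop = TRUE),
                        function(d) skip_runs(d[order(d$pos), ])))
  out <- list(by_strand = by_strand,
              by_context = if (is.null(by_context))
                data.frame(context = character(0), n_meth = integer(0),
                           n_unmeth = integer(0), percent = numeric(0))
              else `rownames<-`(by_context, NULL),
              skip_runs = as.integer(runs %||% integer(0)),
              n_ambiguous = sum(calls$call == "ambiguous"),
              n_masked = sum(calls$call == "masked"))
  class(out) <- "clone_report"
  out
}

#' @export
print.clone_report <- function(x, ...) {
  cat("Bisulfite clone report\n")
  for (i in seq_len(nrow(x$by_strand)))
    cat(sprintf("  strand %s: %d methylated / %d unmethylated (%.1f%%)\n",
                x$by_strand$strand[i], x$by_strand$n_meth[i],
                x$by_strand$n_unmeth[i], x$by_strand$percent[i]))
  if (length(x$skip_runs))
    cat(sprintf("  skip runs: %d (lengths %s)\n", length(x$skip_runs),
                paste(range(x$skip_runs), collapse = "-")))
  invisible(x)
}

#' Conversion QC on an unmethylated control
#'
#' The unconverted fraction of a control declared unmethylated estimates
#' the bisulfite failure rate; the run passes when it stays below
#' `max_fraction` (methylation calls on real samples above this floor are
#' trustworthy).
#'
#' @param calls per-site calls from the control.
#' @param max_fraction pass threshold on the unconverted fraction.
#' @return list `fraction`, `n_sites`, `pass` (NA when no informative
#'   sites - QC indeterminate).
#' @export
conversion_qc <- function(calls, max_fraction = 0.005) {
  scored <- calls$call[calls$call %in% c("methylated", "unmethylated")]
  if (!length(scored)) {
    warning("conversion QC indeterminate: no informative sites")
    return(list(fraction = NA_real_, n_sites = 0L, pass = NA))
  }
  frac <- sum(scored == "methylated") / length(scored)
  list(fraction = frac, n_sites = length(scored), pass = frac < max_fraction)
}
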