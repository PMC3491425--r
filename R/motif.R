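#' Construct a position weight matrix
#'
#' @param probs 4 x w numeric matrix of per-column base probabilities,
#'   rows named A, C, G, T; columns must each sum to 1.
#' @param background named A/C/G/T background frequencies (order-0 null).
#' @param pseudocount fraction mixed into every cell before validation
#'   (guarantees strictly positive entries for log-odds scoring).
#' @return an object of class `pwm`.
#' @export
pwm <- function(probs, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                pseudocount = 1e-3) {
  stopifnot(is.matrix(probs), nrow(probs) == 4L)
  probs <- probs[BASES, , drop = FALSE]
  if (pseudocount > 0)
    probs <- sweep(probs + pseudocount, 2L, colSums(probs + pseudocount), "/")
  if (any(abs(colSums(probs) - 1) > 1e-9))
    stop("pwm columns must sum to 1")
  if (any(probs <= 0))
    stop("pwm entries must be positive after pseudocount")
  background <- background[BASES]
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0))
    stop("background must be positive frequencies summing to 1")
  structure(list(probs = probs, background = background,
                 width = ncol(probs), pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: width %d, consensus %s\n", x$width, pwm_consensus(x)))
  invisible(x)
}

pwm_consensus <- function(p) paste(BASES[apply(p$probs, 2L, which.max)],
                                   collapse = "")

#' Build a PWM from a consensus sequence
#'
#' Each column gives `match_prob` to the consensus base and splits the
#' remainder evenly.
#'
#' @param consensus DNA string.
#' @param match_prob probability of the consensus base per column.
#' @param background named background frequencies.
#' @param pseudocount see [pwm()].
#' @return a `pwm`.
#' @export
pwm_from_consensus <- function(consensus, match_prob = 0.9,
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                               pseudocount = 1e-3) {
  ch <- seq_chars(toupper(consensus))
  stopifnot(all(ch %in% BASES))
  m <- matrix((1 - match_prob) / 3, nrow = 4L, ncol = length(ch),
              dimnames = list(BASES, NULL))
  m[cbind(match(ch, BASES), seq_along(ch))] <- match_prob
  pwm(m, background, pseudocount)
}

#' Read a motif from a MEME minimal-format file
#'
#' Parses the first motif's letter-probability matrix and, when present,
#' the background letter frequencies.
#'
#' @param path MEME minimal-format motif file.
#' @param pseudocount see [pwm()].
#' @return a `pwm`.
#' @export
read_meme <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1L] + 1L]), "\\s+")[[1L]]
    vals <- as.numeric(toks[c(FALSE, TRUE)])
    names(vals) <- toks[c(TRUE, FALSE)]
    bg <- vals[BASES]
  }
  mat_i <- grep("^letter-probability matrix", lines)
  if (!length(mat_i)) stop("no letter-probability matrix found in ", path)
  hdr <- lines[mat_i[1L]]
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
  rows <- lines[(mat_i[1L] + 1L):(mat_i[1L] + w)]
  m <- t(vapply(strsplit(trimws(rows), "\\s+"),
                function(x) as.numeric(x[1:4]), numeric(4L)))
  colnames(m) <- BASES
  pwm(t(m), background = bg, pseudocount = pseudocount)
}

#' Write a motif in MEME minimal format
#'
#' @param p a `pwm`.
#' @param path output path.
#' @param name motif name.
#' @return `path`, invisibly.
#' @export
write_meme <- function(p, path, name = "CC_motif") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", BASES, p$background), collapse = " "),
               "", sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       p$width)), con)
  writeLines(apply(p$probs, 2L, function(col)
    paste(sprintf("%.6f", col), collapse = "  ")), con)
  invisible(path)
}

## draw one instance from the PWM's per-column distributions
sample_pwm_instance <- function(p) {
  paste(vapply(seq_len(p$width),
               function(j) sample(BASES, 1L, prob = p$probs[, j]),
               character(1)), collapse = "")
}

## integer-rounded log-odds score matrix (FIMO-style): deploying rounded
## scores makes the DP null distribution exact for the deployed system
score_matrix_int <- function(p, resolution) {
  s <- log2(p$probs / p$background)
  round(s / resolution)
}

#' Log-odds score of a single window, in bits
#'
#' \eqn{\sum_j \log_2(p_j(b_j) / q(b_j))}.  Windows containing ambiguous
#' bases return NA (they are skipped in scans).
#'
#' @param p a `pwm`.
#' @param window DNA string of the PWM's width.
#' @return numeric bits (NA for ambiguous windows).
#' @export
score_window <- function(p, window) {
  ch <- seq_chars(toupper(window))
  if (length(ch) != p$width)
    stop("window length must equal pwm width")
  idx <- match(ch, BASES)
  if (anyNA(idx)) return(NA_real_)
  sum(log2(p$probs[cbind(idx, seq_len(p$width))] /
           p$background[idx]))
}

#' Exact null distribution of PWM scores under the background model
#'
#' Dynamic-programming convolution of the per-column score distributions on
#' an integer grid of `resolution` bits.  Scores are rounded per column
#' before summation, and the same rounded scoring system is deployed in
#' [scan_genome()], so the distribution (and every tail probability taken
#' from it) is exact for the scores actually used.
#'
#' @param p a `pwm`.
#' @param resolution grid resolution, bits.  The maximum per-window
#'   discretization error `width * resolution / 2` must stay below 0.5 bit.
#' @return a `score_null`: list with integer `min_score`, numeric `pmf`
#'   (mass over `min_score`, `min_score`+1, ...), `tail` (upper-tail mass),
#'   and `resolution`.
#' @export
exact_score_distribution <- function(p, resolution = 0.01) {
  if (resolution <= 0) stop("resolution must be positive")
  if (p$width * resolution / 2 > 0.5)
    stop("calibration error: resolution too coarse (max discretization ",
         "error exceeds 0.5 bit); use a finer resolution")
  S <- score_matrix_int(p, resolution)
  q <- p$background
  pmf <- 1
  minsc <- 0L
  for (j in seq_len(p$width)) {
    o <- S[, j]
    newmin <- minsc + min(o)
    newlen <- (minsc + length(pmf) - 1L + max(o)) - newmin + 1L
    new <- numeric(newlen)
    for (b in seq_len(4L)) {
      at <- (minsc + o[b] - newmin + 1L):(minsc + o[b] - newmin + length(pmf))
      new[at] <- new[at] + pmf * q[b]
    }
    pmf <- new
    minsc <- newmin
  }
  if (abs(sum(pmf) - 1) > 1e-6)
    stop("null PMF mass deviates from 1; numerical failure")
  structure(list(min_score = minsc, pmf = pmf,
                 tail = rev(cumsum(rev(pmf))), resolution = resolution),
            class = "score_null")
}

## upper-tail probability P(score >= s_int) for integer score(s)
null_tail <- function(null, s_int) {
  i <- s_int - null$min_score + 1L
  n <- length(null$tail)
  out <- numeric(length(i))
  out[i <= 0L] <- 1
  inb <- i > 0L & i <= n
  out[inb] <- null$tail[i[inb]]
  out
}

#' Calibrate the score threshold for a per-occurrence false-discovery rate
#'
#' Returns the smallest score whose null upper-tail probability is at most
#' `fdr_per_occurrence` - e.g. 1e-7 is one false discovery per 10 million
#' scanned occurrences.
#'
#' @param p a `pwm`.
#' @param fdr_per_occurrence per-window null exceedance probability.
#' @param resolution score grid resolution, bits.
#' @return a `motif_threshold`: list with `threshold_int`, `threshold_bits`,
#'   `achieved_tail`, `resolution` and the `score_null`.
#' @export
calibrate_threshold <- function(p, fdr_per_occurrence = 1e-7,
                                resolution = 0.01) {
  null <- exact_score_distribution(p, resolution)
  ok <- which(null$tail <= fdr_per_occurrence)
  if (!length(ok))
    stop("calibration error: requested rate ", fdr_per_occurrence,
         " is unreachable for this pwm/background (minimum attainable ",
         "tail ", format(min(null$tail), digits = 3),
         "); use a wider motif or a finer resolution")
  t_int <- null$min_score + ok[1L] - 1L
  structure(list(threshold_int = t_int,
                 threshold_bits = t_int * resolution,
                 achieved_tail = null$tail[ok[1L]],
                 resolution = resolution, null = null,
                 fdr_per_occurrence = fdr_per_occurrence),
            class = "motif_threshold")
}

## integer score of every window of a coded sequence; NA where ambiguous
scan_scores_int <- function(S, codes) {
  w <- ncol(S)
  n <- length(codes) - w + 1L
  if (n < 1L) return(integer(0))
  tot <- integer(n)
  na <- logical(n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1L)]
    na <- na | is.na(cj)
    sj <- S[cbind(cj, j)]
    sj[is.na(sj)] <- 0L
    tot <- tot + sj
  }
  tot[na] <- NA_integer_
  tot
}

#' Scan a genome for motif occurrences above a calibrated threshold
#'
#' Both strands are scanned with the integer-rounded scoring system the
#' threshold was calibrated on.  Hits are reported with forward-frame start
#' positions (1-based), exact per-occurrence p-values, per-contig counts,
#' and clusters (maximal runs of hits whose consecutive starts lie within
#' `cluster_gap` bp).
#'
#' @param p a `pwm`.
#' @param seqs named character vector of contig sequences (or a
#'   `genome_model`).
#' @param threshold a `motif_threshold` from [calibrate_threshold()].
#' @param cluster_gap maximum within-cluster gap, bp.
#' @return list with `hits` (contig, start, strand, score_bits, p_value),
#'   `counts` (contig, n_motifs), `clusters` (contig, cluster, n_hits,
#'   start, end).
#' @export
scan_genome <- function(p, seqs, threshold, cluster_gap = 200L) {
  stopifnot(inherits(threshold, "motif_threshold"))
  if (inherits(seqs, "genome_model")) seqs <- genome_sequences(seqs)
  S <- score_matrix_int(p, threshold$resolution)
  w <- p$width
  hits <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    ctg <- names(seqs)[i]
    L <- nchar(seqs[[i]])
    if (L < w) {
      warning("contig ", ctg, " shorter than pwm width; skipped")
      next
    }
    fwd_codes <- match(seq_chars(seqs[[i]]), BASES)
    rev_codes <- match(seq_chars(revcomp(seqs[[i]])), BASES)
    sf <- scan_scores_int(S, fwd_codes)
    sr <- scan_scores_int(S, rev_codes)
    hf <- which(!is.na(sf) & sf >= threshold$threshold_int)
    hr <- which(!is.na(sr) & sr >= threshold$threshold_int)
    df <- data.frame(contig = character(0), start = integer(0),
                     strand = character(0), score_int = integer(0))
    if (length(hf))
      df <- rbind(df, data.frame(contig = ctg, start = hf, strand = "+",
                                 score_int = sf[hf]))
    if (length(hr))
      df <- rbind(df, data.frame(contig = ctg, start = L - hr - w + 2L,
                                 strand = "-", score_int = sr[hr]))
    hits[[i]] <- df
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits)) {
    hits <- data.frame(contig = character(0), start = integer(0),
                       strand = character(0), score_bits = numeric(0),
                       p_value = numeric(0))
  } else {
    hits <- hits[order(hits$contig, hits$start), ]
    hits$score_bits <- hits$score_int * threshold$resolution
    hits$p_value <- null_tail(threshold$null, hits$score_int)
    hits$score_int <- NULL
    rownames(hits) <- NULL
  }
  counts <- data.frame(contig = names(seqs),
                       n_motifs = as.integer(table(factor(hits$contig,
                                                          levels = names(seqs)))))
  clusters <- hit_clusters(hits, cluster_gap)
  list(hits = hits, counts = counts, clusters = clusters,
       expected_false = threshold$achieved_tail *
         2 * sum(pmax(nchar(seqs) - w + 1L, 0L)))
}

hit_clusters <- function(hits, gap) {
  if (!nrow(hits))
    return(data.frame(contig = character(0), cluster = integer(0),
                      n_hits = integer(0), start = integer(0),
                      end = integer(0)))
  out <- lapply(split(hits, hits$contig), function(h) {
    s <- sort(h$start)
    brk <- cumsum(c(1L, as.integer(diff(s) > gap)))
    do.call(rbind, lapply(split(s, brk), function(g)
      data.frame(contig = h$contig[1L], n_hits = length(g),
                 start = min(g), end = max(g))))
  })
  out <- do.call(rbind, out)
  out$cluster <- stats::ave(seq_len(nrow(out)), out$contig, FUN = seq_along)
  rownames(out) <- NULL
  out[c("contig", "cluster", "n_hits", "start", "end")]
}

#' Write motif hits as BED6
#'
#' Score column carries bits x 100 as an integer.
#'
#' @param hits hit table from [scan_genome()].
#' @param width motif width (for interval ends).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, width, path) {
  df <- data.frame(contig = hits$contig, start = hits$start,
                   end = hits$start + width - 1L, name = "motif",
                   score = as.integer(round(hits$score_bits * 100)),
                   strand = hits$strand)
  write_bed(df, path)
}
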