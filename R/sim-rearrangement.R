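#' Simulate a scrambled locus map
#'
#' Builds a somatic (MAC) gene sequence, cuts it into macronuclear-destined
#' segments (MDSs) whose adjacent ends share programmed pointer
#' microhomologies, and places the MDSs in scrambled order (some inverted)
#' into a germline (MIC) locus separated by internal eliminated sequences
#' (IESs).  IES bases flanking each MDS are constrained to differ from the
#' MDS's continuation in the somatic product, so programmed pointers are
#' maximal microhomologies by construction.
#'
#' @param config a [sim_config()] (supplies base frequencies).
#' @param n_mds number of MDSs.
#' @param mac_len length of the somatic product, bp.
#' @param pointer_range integer range programmed pointer lengths are drawn
#'   from.
#' @param ies_range integer range of IES lengths.
#' @param invert_prob probability an MDS is placed inverted in the MIC.
#' @param seed optional integer seed (NULL draws from the current stream).
#' @return a `scrambled_locus_map`: list with `mac_seq`, `mic_seq`, `mds`
#'   (data.frame mds_index, mac_start, mac_end, mic_start, mic_end,
#'   orientation; 1-based closed; mds_index is MAC order), `pointers`
#'   (left_mds, right_mds, seq, length) and `ies` intervals.
#' @export
simulate_locus_map <- function(config, n_mds = 6L, mac_len = 1200L,
                               pointer_range = 4:8, ies_range = 25:60,
                               invert_prob = 0.25, seed = NULL) {
  with_seed(seed, {
    bf <- config$base_freqs
    mac <- random_dna(mac_len, bf)
    ## interior cut points with jitter; MDS i spans the pointer-extended
    ## interval [c_{i-1} - pl_{i-1} + 1, c_i]
    cuts <- round(seq(0, mac_len, length.out = n_mds + 1L))
    if (n_mds > 1L) {
      jit <- sample(-15:15, n_mds - 1L, replace = TRUE)
      cuts[2:n_mds] <- cuts[2:n_mds] + jit
    }
    pl <- pointer_range[sample.int(length(pointer_range),
                                   max(n_mds - 1L, 0L), replace = TRUE)]
    mac_start <- c(1L, cuts[2:n_mds] - pl + 1L)[seq_len(n_mds)]
    mac_end <- cuts[-1L]
    pointers <- if (n_mds > 1L)
      data.frame(left_mds = seq_len(n_mds - 1L),
                 right_mds = 2:n_mds,
                 seq = substring(mac, cuts[2:n_mds] - pl + 1L, cuts[2:n_mds]),
                 length = pl)
    else data.frame(left_mds = integer(), right_mds = integer(),
                    seq = character(), length = integer())

    mds_seq <- substring(mac, mac_start, mac_end)  # MAC sense
    orientation <- ifelse(runif(n_mds) < invert_prob, "-", "+")
    perm <- sample.int(n_mds)                      # MIC placement order

    ies_lens <- ies_range[sample.int(length(ies_range), n_mds + 1L,
                                     replace = TRUE)]
    pieces <- character(2L * n_mds + 1L)
    pieces[1L] <- random_dna(ies_lens[1L], bf)
    for (k in seq_len(n_mds)) {
      m <- perm[k]
      s <- mds_seq[m]
      if (orientation[m] == "-") s <- revcomp(s)
      pieces[2L * k] <- s
      pieces[2L * k + 1L] <- random_dna(ies_lens[k + 1L], bf)
    }
    mic <- paste(pieces, collapse = "")
    lens <- nchar(pieces)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    mic_start <- integer(n_mds); mic_end <- integer(n_mds)
    for (k in seq_len(n_mds)) {
      mic_start[perm[k]] <- starts[2L * k]
      mic_end[perm[k]] <- ends[2L * k]
    }
    ies <- data.frame(start = starts[seq(1L, 2L * n_mds + 1L, by = 2L)],
                      end = ends[seq(1L, 2L * n_mds + 1L, by = 2L)])

    map <- list(mac_seq = mac, mic_seq = mic,
                mds = data.frame(mds_index = seq_len(n_mds),
                                 mac_start = mac_start, mac_end = mac_end,
                                 mic_start = mic_start, mic_end = mic_end,
                                 orientation = orientation),
                pointers = pointers, ies = ies)
    class(map) <- "scrambled_locus_map"
    fix_flank_bases(map, bf)
  })
}

## Resample IES bases that would extend a programmed pointer beyond its
## stated length (MDS continuation base in MAC must mismatch the adjacent
## IES base in MIC, on the MAC-sense frame).
fix_flank_bases <- function(map, base_freqs) {
  mic <- seq_chars(map$mic_seq)
  mac <- seq_chars(map$mac_seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- nrow(map$mds)
  for (m in seq_len(n)) {
    row <- map$mds[m, ]
    ## forward continuation (exists unless m is the last MAC-order MDS)
    if (row$mac_end < length(mac)) {
      nxt <- mac[row$mac_end + 1L]
      if (row$orientation == "+") {
        p <- row$mic_end + 1L
        if (p <= length(mic) && mic[p] == nxt)
          mic[p] <- resample_base(nxt, base_freqs)
      } else {
        p <- row$mic_start - 1L
        if (p >= 1L && mic[p] == comp[[nxt]])
          mic[p] <- resample_base(comp[[nxt]], base_freqs)
      }
    }
    ## backward precedent (exists unless m is the first MAC-order MDS)
    if (row$mac_start > 1L) {
      prv <- mac[row$mac_start - 1L]
      if (row$orientation == "+") {
        p <- row$mic_start - 1L
        if (p >= 1L && mic[p] == prv)
          mic[p] <- resample_base(prv, base_freqs)
      } else {
        p <- row$mic_end + 1L
        if (p <= length(mic) && mic[p] == comp[[prv]])
          mic[p] <- resample_base(comp[[prv]], base_freqs)
      }
    }
  }
  map$mic_seq <- paste(mic, collapse = "")
  map
}

resample_base <- function(avoid, base_freqs) {
  pool <- setdiff(BASES, avoid)
  sample(pool, 1L, prob = base_freqs[pool])
}

#' Simulate correctly and aberrantly rearranged products from a locus map
#'
#' Correct products splice the MDSs in MAC order, joining at the programmed
#' pointers (i.e. they equal the somatic sequence).  With probability
#' `error_rate` a product is instead an aberrant precursor molecule: a copy
#' of the germline locus in which the region between two sampled 3-4 bp
#' microhomologies (cryptic pointers) has been deleted, retaining a single
#' copy of the microhomology and preserving segment order - the "false IES"
#' error mode.  Sampled cryptic pointer copies are required to be maximal
#' (the flanking bases mismatch), so the truth records are exactly
#' recoverable by junction annotation.
#'
#' @param map a `scrambled_locus_map`.
#' @param n_products number of product molecules.
#' @param error_rate probability a product is aberrant.
#' @param sep_range allowed distance range (bp) between the two cryptic
#'   pointer copies (the deleted span).
#' @param seed optional integer seed.
#' @return list with `products` (named character vector), `classes`
#'   (data.frame product_id, class), and `junctions` (truth junction table:
#'   product_id, left_mds, right_mds, pointer, length, class).
#' @export
simulate_rearrangement_products <- function(map, n_products, error_rate = 0.3,
                                            sep_range = c(40L, 400L),
                                            seed = NULL) {
  stopifnot(inherits(map, "scrambled_locus_map"))
  with_seed(seed, {
    aberrant <- runif(n_products) < error_rate
    products <- character(n_products)
    ids <- sprintf("product%03d", seq_len(n_products))
    cls <- ifelse(aberrant, "aberrant", "correct")
    juncs <- vector("list", n_products)
    n_mds <- nrow(map$mds)
    for (i in seq_len(n_products)) {
      if (!aberrant[i]) {
        products[i] <- map$mac_seq
        if (n_mds > 1L)
          juncs[[i]] <- data.frame(product_id = ids[i],
                                   left_mds = map$pointers$left_mds,
                                   right_mds = map$pointers$right_mds,
                                   pointer = map$pointers$seq,
                                   length = map$pointers$length,
                                   class = "programmed")
      } else {
        del <- sample_cryptic_deletion(map$mic_seq, sep_range)
        products[i] <- paste0(substr(map$mic_seq, 1L, del$i + del$k - 1L),
                              substr(map$mic_seq, del$j + del$k,
                                     nchar(map$mic_seq)))
        juncs[[i]] <- data.frame(product_id = ids[i],
                                 left_mds = NA_integer_,
                                 right_mds = NA_integer_,
                                 pointer = del$pattern,
                                 length = del$k,
                                 class = "cryptic")
      }
    }
    names(products) <- ids
    list(products = products,
         classes = data.frame(product_id = ids, class = cls),
         junctions = do.call(rbind, juncs))
  })
}

## Sample a pair of identical, maximal k-mers (k in 3:4) separated by a
## distance in sep_range; maximality = mismatching flanking bases on both
## sides, which pins the annotated microhomology to exactly this k-mer.
## Both retained arms must keep >= min_arm bp so the junction stays
## annotatable (real products carry primer-flanked arms on both sides).
sample_cryptic_deletion <- function(mic, sep_range, max_tries = 500L,
                                    min_arm = 30L) {
  L <- nchar(mic)
  subject <- Biostrings::DNAString(mic)
  for (try in seq_len(max_tries)) {
    k <- sample(3:4, 1L)
    lo <- min_arm + 1L
    hi <- L - k - sep_range[1L] - min_arm
    if (hi < lo) stop("locus too short for a cryptic deletion")
    i <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    pattern <- substr(mic, i, i + k - 1L)
    hits <- Biostrings::start(Biostrings::matchPattern(pattern, subject))
    js <- hits[hits > i & hits - i >= sep_range[1L] & hits - i <= sep_range[2L] &
               hits + k - 1L + min_arm <= L]
    if (!length(js)) next
    for (j in js[sample.int(length(js))]) {
      ok <- substr(mic, i - 1L, i - 1L) != substr(mic, j - 1L, j - 1L) &&
            substr(mic, i + k, i + k) != substr(mic, j + k, j + k)
      if (ok) return(list(i = i, j = j, k = k, pattern = pattern))
    }
  }
  stop("could not place a cryptic deletion; widen sep_range")
}

#' Write a locus map as structured TSV
#'
#' Header blocks (`#mac=`, `#mic=`) carry the sequences; the body is the
#' MDS coordinate table.
#'
#' @param map a `scrambled_locus_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locus_map <- function(map, path) {
  con <- file(path, "w")
  writeLines(c(sprintf("#mac=%s", map$mac_seq),
               sprintf("#mic=%s", map$mic_seq)), con)
  close(con)
  suppressWarnings(write.table(map$mds, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read a locus map written by [write_locus_map()]
#'
#' @param path input path.
#' @return a validated `scrambled_locus_map` (pointers re-derived).
#' @export
read_locus_map <- function(path) {
  lines <- readLines(path)
  mac <- sub("^#mac=", "", grep("^#mac=", lines, value = TRUE)[1L])
  mic <- sub("^#mic=", "", grep("^#mic=", lines, value = TRUE)[1L])
  mds <- read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
  map <- list(mac_seq = mac, mic_seq = mic, mds = mds, pointers = NULL,
              ies = NULL)
  class(map) <- "scrambled_locus_map"
  validate_map(map)
}
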