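#' Validate a scrambled locus map
#'
#' Checks that MDS intervals fit inside the germline sequence, that MAC and
#' MIC interval lengths agree, and that each MAC-order-adjacent MDS pair
#' shares its programmed pointer as a suffix/prefix (in MAC sense,
#' accounting for orientation).  Pointer sequences are derived from the
#' coordinates when absent and verified against stated ones when present.
#'
#' @param map a `scrambled_locus_map`.
#' @return the map with a complete `pointers` table.
#' @export
validate_map <- function(map) {
  stopifnot(inherits(map, "scrambled_locus_map"))
  mds <- map$mds[order(map$mds$mds_index), ]
  L <- nchar(map$mic_seq)
  if (any(mds$mic_start < 1L) || any(mds$mic_end > L) ||
      any(mds$mic_start > mds$mic_end))
    stop("map error: MDS interval outside the MIC sequence")
  if (any((mds$mic_end - mds$mic_start) != (mds$mac_end - mds$mac_start)))
    stop("map error: MAC and MIC interval lengths disagree")
  ## same-strand MIC overlap between different MDSs is not a pointer
  ## overlap (those live at MAC-adjacent ends, each in its own MIC copy)
  o <- order(mds$mic_start)
  if (any(mds$mic_start[o][-1L] <= mds$mic_end[o][-nrow(mds)]))
    stop("map error: overlapping MDS coordinates in the MIC")
  mac_sense <- function(i) {
    s <- substr(map$mic_seq, mds$mic_start[i], mds$mic_end[i])
    if (mds$orientation[i] == "-") revcomp(s) else s
  }
  n <- nrow(mds)
  derived <- vector("list", max(n - 1L, 0L))
  for (i in seq_len(n - 1L)) {
    a <- mac_sense(i); b <- mac_sense(i + 1L)
    ## overlap implied by MAC coordinates
    plen <- mds$mac_end[i] - mds$mac_start[i + 1L] + 1L
    if (plen < 1L)
      stop(sprintf("map error: MDS %d and %d do not overlap in MAC coordinates",
                   mds$mds_index[i], mds$mds_index[i + 1L]))
    suf <- substr(a, nchar(a) - plen + 1L, nchar(a))
    pre <- substr(b, 1L, plen)
    if (suf != pre)
      stop(sprintf(
        "map error: derived pointer mismatch between MDS %d and %d ('%s' vs '%s')",
        mds$mds_index[i], mds$mds_index[i + 1L], suf, pre))
    derived[[i]] <- data.frame(left_mds = mds$mds_index[i],
                               right_mds = mds$mds_index[i + 1L],
                               seq = suf, length = plen)
  }
  derived <- if (n > 1L) do.call(rbind, derived)
  else data.frame(left_mds = integer(), right_mds = integer(),
                  seq = character(), length = integer())
  if (!is.null(map$pointers) && nrow(map$pointers)) {
    m <- merge(map$pointers, derived, by = c("left_mds", "right_mds"),
               suffixes = c("_stated", "_derived"))
    bad <- m$seq_stated != m$seq_derived
    if (any(bad))
      stop("map error: stated pointers disagree with coordinates for pair(s): ",
           paste(sprintf("%d-%d", m$left_mds[bad], m$right_mds[bad]),
                 collapse = ", "))
  }
  map$pointers <- derived
  map
}

## longest exact match of product[p..] against the MIC (both strands),
## extended maximally backward and forward; returns NULL when no 20-mer
## seed matches
longest_match_at <- function(prod_ch, p, mic_ch, micr_ch, mic_f, mic_r,
                             min_seed = 20L) {
  n <- length(prod_ch)
  if (p + min_seed - 1L > n) return(NULL)
  seed <- paste(prod_ch[p:(p + min_seed - 1L)], collapse = "")
  best <- NULL
  for (strand in c("+", "-")) {
    subject <- if (strand == "+") mic_f else mic_r
    mch <- if (strand == "+") mic_ch else micr_ch
    starts <- Biostrings::start(Biostrings::matchPattern(seed, subject))
    for (h in starts) {
      fwd <- min_seed
      while (p + fwd <= n && h + fwd <= length(mch) &&
             prod_ch[p + fwd] == mch[h + fwd]) fwd <- fwd + 1L
      back <- 0L
      while (p - back > 1L && h - back > 1L &&
             prod_ch[p - back - 1L] == mch[h - back - 1L]) back <- back + 1L
      cand <- list(strand = strand, subj_start = h - back,
                   prod_start = p - back, prod_end = p + fwd - 1L)
      if (is.null(best) || cand$prod_end > best$prod_end ||
          (cand$prod_end == best$prod_end && cand$subj_start < best$subj_start))
        best <- cand
    }
  }
  best
}

#' Tile a rearrangement product against its locus map
#'
#' Greedy maximal exact-match tiling of the product over the germline
#' sequence (both orientations).  Consecutive segments may overlap in the
#' product by a retained pointer copy; that overlap is the junction
#' microhomology.  Products leaving more than 5% of their bases uncovered
#' trigger a tiling-incomplete warning; products without a single 20 bp
#' seed match raise an error.
#'
#' @param product product sequence.
#' @param map a validated `scrambled_locus_map`.
#' @param min_seed minimum exact seed length, bp.
#' @return data.frame `segment`, `product_start`, `product_end`,
#'   `mic_start`, `mic_end`, `strand` (all 1-based closed; mic coords on
#'   the forward frame).
#' @export
tile_product <- function(product, map, min_seed = 20L) {
  stopifnot(inherits(map, "scrambled_locus_map"))
  prod_ch <- seq_chars(product)
  n <- length(prod_ch)
  L <- nchar(map$mic_seq)
  mic_ch <- seq_chars(map$mic_seq)
  micr <- revcomp(map$mic_seq)
  micr_ch <- seq_chars(micr)
  mic_f <- Biostrings::DNAString(map$mic_seq)
  mic_r <- Biostrings::DNAString(micr)

  segs <- list()
  p <- 1L
  covered_to <- 0L
  repeat {
    m <- NULL
    while (p + min_seed - 1L <= n) {
      m <- longest_match_at(prod_ch, p, mic_ch, micr_ch, mic_f, mic_r,
                            min_seed)
      if (!is.null(m)) break
      p <- p + 1L
    }
    if (is.null(m)) break
    subj_len <- m$prod_end - m$prod_start + 1L
    if (m$strand == "+") {
      mic_start <- m$subj_start
      mic_end <- m$subj_start + subj_len - 1L
    } else {
      mic_end <- L - m$subj_start + 1L
      mic_start <- L - (m$subj_start + subj_len - 1L) + 1L
    }
    segs[[length(segs) + 1L]] <-
      data.frame(product_start = m$prod_start, product_end = m$prod_end,
                 mic_start = mic_start, mic_end = mic_end,
                 strand = m$strand)
    covered_to <- max(covered_to, m$prod_end)
    if (m$prod_end >= n) break
    p <- m$prod_end + 1L
  }
  if (!length(segs))
    stop("product not from locus: no exact match of at least ",
         min_seed, " bp")
  segs <- do.call(rbind, segs)
  segs$segment <- seq_len(nrow(segs))
  covered <- sum(segs$product_end - segs$product_start + 1L)
  ## overlaps double-counted; bound uncovered from the union instead
  uncov <- n - length(unique(unlist(mapply(seq, segs$product_start,
                                           segs$product_end,
                                           SIMPLIFY = FALSE))))
  if (uncov / n > 0.05)
    warning(sprintf("tiling incomplete: %.1f%% of product bases uncovered",
                    100 * uncov / n))
  segs[c("segment", "product_start", "product_end", "mic_start",
         "mic_end", "strand")]
}

## MDS index whose MIC footprint a segment reproduces exactly, else NA
segment_mds <- function(seg, mds) {
  hit <- which(mds$mic_start == seg$mic_start & mds$mic_end == seg$mic_end &
               mds$orientation == seg$strand)
  if (length(hit) == 1L) mds$mds_index[hit] else NA_integer_
}

#' Locate junctions between tiled segments and classify their pointers
#'
#' For each adjacent segment pair the junction microhomology (pointer) is
#' the product overlap between the maximal backward extension of the right
#' segment and the maximal forward extension of the left segment - by
#' construction the maximal string that is simultaneously a suffix of the
#' left segment's germline context and a prefix of the right segment's,
#' retained once in the product.  A junction is programmed iff both
#' segments reproduce MAC-order-adjacent MDS footprints and the pointer
#' equals the map's programmed pointer; otherwise it is cryptic (a
#' zero-length overlap is a blunt cryptic join).
#'
#' @param segments tiling from [tile_product()].
#' @param product the product sequence the segments tile.
#' @param map a validated `scrambled_locus_map`.
#' @param product_id identifier copied into the output.
#' @return data.frame `product_id`, `left_mds`, `right_mds`, `pointer`,
#'   `length`, `class`, `order_preserved`, plus germline coordinates of
#'   both microhomology copies for cryptic junctions.
#' @export
find_junctions <- function(segments, product, map, product_id = "product") {
  stopifnot(inherits(map, "scrambled_locus_map"))
  if (nrow(segments) < 2L)
    return(data.frame(product_id = character(0), left_mds = integer(0),
                      right_mds = integer(0), pointer = character(0),
                      length = integer(0), class = character(0),
                      order_preserved = logical(0)))
  mono <- all(segments$strand == "+") &&
    !is.unsorted(segments$mic_start, strictly = TRUE)
  out <- vector("list", nrow(segments) - 1L)
  for (i in seq_len(nrow(segments) - 1L)) {
    a <- segments[i, ]; b <- segments[i + 1L, ]
    plen <- max(0L, a$product_end - b$product_start + 1L)
    pseq <- if (plen > 0L) substr(product, b$product_start, a$product_end) else ""
    la <- segment_mds(a, map$mds)
    lb <- segment_mds(b, map$mds)
    programmed <- FALSE
    if (!is.na(la) && !is.na(lb) && lb == la + 1L) {
      pr <- map$pointers[map$pointers$left_mds == la &
                         map$pointers$right_mds == lb, ]
      programmed <- nrow(pr) == 1L && pr$seq == pseq
    }
    ## germline coordinates of the two microhomology copies
    if (plen > 0L) {
      left_copy <- if (a$strand == "+")
        c(a$mic_end - plen + 1L, a$mic_end) else c(a$mic_start, a$mic_start + plen - 1L)
      right_copy <- if (b$strand == "+")
        c(b$mic_start, b$mic_start + plen - 1L) else c(b$mic_end - plen + 1L, b$mic_end)
    } else left_copy <- right_copy <- c(NA_integer_, NA_integer_)
    out[[i]] <- data.frame(product_id = product_id,
                           left_mds = la, right_mds = lb,
                           pointer = pseq, length = plen,
                           class = if (programmed) "programmed" else "cryptic",
                           order_preserved = mono,
                           left_copy_start = left_copy[1L],
                           left_copy_end = left_copy[2L],
                           right_copy_start = right_copy[1L],
                           right_copy_end = right_copy[2L])
  }
  do.call(rbind, out)
}

#' Classify a product as correctly processed or aberrant
#'
#' Aberrant iff any junction is cryptic or any of the map's programmed
#' junctions is missing.
#'
#' @param junctions junction table from [find_junctions()] for one product.
#' @param map a validated `scrambled_locus_map`.
#' @return list `class` ("correct"/"aberrant"), `n_cryptic`,
#'   `cryptic_pointer_lengths`.
#' @export
classify_product <- function(junctions, map) {
  stopifnot(inherits(map, "scrambled_locus_map"))
  cry <- junctions$class == "cryptic"
  prog <- junctions[!cry, c("left_mds", "right_mds")]
  need <- map$pointers[c("left_mds", "right_mds")]
  have_all <- nrow(need) == 0L ||
    all(apply(need, 1L, function(p)
      any(prog$left_mds == p[["left_mds"]] &
          prog$right_mds == p[["right_mds"]])))
  list(class = if (any(cry) || !have_all) "aberrant" else "correct",
       n_cryptic = sum(cry),
       cryptic_pointer_lengths = junctions$length[cry])
}

#' Annotate a set of products end to end
#'
#' Tiles each product, finds junctions and classifies, returning a tidy
#' junction table and per-product classes.
#'
#' @param products named character vector of product sequences.
#' @param map a validated `scrambled_locus_map`.
#' @param min_seed see [tile_product()].
#' @return list `junctions` (all products), `classes` (data.frame
#'   product_id, class, n_cryptic).
#' @export
annotate_products <- function(products, map, min_seed = 20L) {
  map <- validate_map(map)
  juncs <- vector("list", length(products))
  cls <- vector("list", length(products))
  for (i in seq_along(products)) {
    id <- names(products)[i] %||% sprintf("product%03d", i)
    segs <- tile_product(products[[i]], map, min_seed)
    j <- find_junctions(segs, products[[i]], map, product_id = id)
    k <- classify_product(j, map)
    juncs[[i]] <- j
    cls[[i]] <- data.frame(product_id = id, class = k$class,
                           n_cryptic = k$n_cryptic)
  }
  list(junctions = do.call(rbind, juncs), classes = do.call(rbind, cls))
}
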