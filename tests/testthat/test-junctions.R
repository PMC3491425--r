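toy_map <- function() {
  # two MDSs sharing the pointer "TAAG"; MDS1 = mac[1..24], MDS2 = mac[21..44]
  set.seed(140)
  cfg <- sim_config()
  simulate_locus_map(cfg, n_mds = 2L, mac_len = 44L, pointer_range = 4L,
                     ies_range = 30L, invert_prob = 0, seed = 141)
}

test_that("map validation derives pointers and flags broken maps", {
  map <- toy_map()
  v <- validate_map(map)
  expect_equal(nrow(v$pointers), 1L)
  expect_equal(v$pointers$length, 4L)
  # stated pointer must match the derived one
  bad <- v
  bad$pointers$seq <- strrep("A", bad$pointers$length)
  if (bad$pointers$seq != v$pointers$seq)
    expect_error(validate_map(bad), "stated pointers disagree")
  bad2 <- map
  bad2$mds$mic_end[1] <- nchar(map$mic_seq) + 50L
  expect_error(validate_map(bad2), "outside the MIC")
  bad3 <- map
  bad3$mds$mic_start[2] <- bad3$mds$mic_start[1]
  bad3$mds$mic_end[2] <- bad3$mds$mic_end[1]
  expect_error(validate_map(bad3), "map error")
})

test_that("a multi-MDS scrambled map validates with programmed pointers", {
  cfg <- sim_config()
  map <- simulate_locus_map(cfg, n_mds = 8L, mac_len = 1600L, seed = 142)
  v <- validate_map(map)
  expect_equal(nrow(v$pointers), 7L)
  expect_true(all(v$pointers$length >= 4L & v$pointers$length <= 8L))
  # scrambling actually happened at this seed
  expect_false(identical(order(v$mds$mic_start), v$mds$mds_index))
})

test_that("correct products tile into the MDS order with programmed junctions", {
  cfg <- sim_config()
  map <- validate_map(simulate_locus_map(cfg, n_mds = 6L, mac_len = 1200L,
                                         seed = 143))
  segs <- tile_product(map$mac_seq, map)
  expect_equal(nrow(segs), 6L)
  expect_equal(segs$mic_start, map$mds$mic_start)
  expect_equal(segs$mic_end, map$mds$mic_end)
  expect_equal(segs$strand, map$mds$orientation)
  j <- find_junctions(segs, map$mac_seq, map)
  expect_true(all(j$class == "programmed"))
  expect_equal(j$pointer, map$pointers$seq)
  k <- classify_product(j, map)
  expect_equal(k$class, "correct")
})

test_that("single-MDS products give one segment and no junctions", {
  cfg <- sim_config()
  map <- validate_map(simulate_locus_map(cfg, n_mds = 4L, mac_len = 900L,
                                         invert_prob = 0, seed = 144))
  one <- substr(map$mac_seq, map$mds$mac_start[2], map$mds$mac_end[2])
  segs <- tile_product(one, map)
  expect_equal(nrow(segs), 1L)
  expect_equal(nrow(find_junctions(segs, one, map)), 0L)
  expect_error(tile_product(strrep("N", 100), map), "not from locus")
})

test_that("a planted false-IES deletion yields one cryptic junction", {
  cfg <- sim_config()
  map <- validate_map(simulate_locus_map(cfg, n_mds = 5L, mac_len = 1000L,
                                         seed = 145))
  prods <- simulate_rearrangement_products(map, 30L, error_rate = 1,
                                           seed = 146)
  ann <- annotate_products(prods$products, map)
  expect_true(all(ann$classes$class == "aberrant"))
  per <- split(ann$junctions, ann$junctions$product_id)
  for (id in names(per)) {
    cj <- per[[id]][per[[id]]$class == "cryptic", ]
    expect_equal(nrow(cj), 1L)
    truth <- prods$junctions[prods$junctions$product_id == id, ]
    expect_equal(cj$pointer, truth$pointer)
    expect_equal(cj$length, truth$length)
    expect_true(cj$length %in% 3:4)
    expect_true(cj$order_preserved)
  }
})

test_that("mixed product sets are classified with full accuracy", {
  cfg <- sim_config()
  map <- validate_map(simulate_locus_map(cfg, n_mds = 6L, mac_len = 1200L,
                                         seed = 147))
  prods <- simulate_rearrangement_products(map, 100L, error_rate = 0.3,
                                           seed = 148)
  frac <- mean(prods$classes$class == "aberrant")
  se <- sqrt(0.3 * 0.7 / 100)
  expect_lt(abs(frac - 0.3), 3 * se)
  ann <- annotate_products(prods$products, map)
  expect_identical(ann$classes$class[match(prods$classes$product_id,
                                           ann$classes$product_id)],
                   prods$classes$class)
})

test_that("reported pointers are maximal microhomologies", {
  cfg <- sim_config()
  map <- validate_map(simulate_locus_map(cfg, n_mds = 5L, mac_len = 1000L,
                                         seed = 149))
  prods <- simulate_rearrangement_products(map, 20L, error_rate = 0.5,
                                           seed = 150)
  ann <- annotate_products(prods$products, map)
  j <- ann$junctions[ann$junctions$class == "cryptic" & ann$junctions$length > 0, ]
  mic <- map$mic_seq
  for (i in seq_len(nrow(j))) {
    # one-base extension on either side must break the identity
    lb <- substr(mic, j$left_copy_start[i] - 1L, j$left_copy_start[i] - 1L)
    rb <- substr(mic, j$right_copy_start[i] - 1L, j$right_copy_start[i] - 1L)
    la <- substr(mic, j$left_copy_end[i] + 1L, j$left_copy_end[i] + 1L)
    ra <- substr(mic, j$right_copy_end[i] + 1L, j$right_copy_end[i] + 1L)
    expect_false(identical(lb, rb))
    expect_false(identical(la, ra))
  }
})

test_that("annotation is orientation invariant up to mirroring", {
  cfg <- sim_config()
  map <- validate_map(simulate_locus_map(cfg, n_mds = 4L, mac_len = 900L,
                                         seed = 151))
  segs_f <- tile_product(map$mac_seq, map)
  segs_r <- tile_product(revcomp(map$mac_seq), map)
  expect_equal(nrow(segs_r), nrow(segs_f))
  # mirrored product order, same MIC footprints, flipped strands
  expect_setequal(paste(segs_r$mic_start, segs_r$mic_end),
                  paste(segs_f$mic_start, segs_f$mic_end))
  m <- match(paste(segs_r$mic_start, segs_r$mic_end),
             paste(segs_f$mic_start, segs_f$mic_end))
  expect_true(all(segs_r$strand != segs_f$strand[m]))
  j_r <- find_junctions(segs_r, revcomp(map$mac_seq), map)
  expect_equal(sort(vapply(j_r$pointer, function(s) revcomp(s), character(1),
                           USE.NAMES = FALSE)),
               sort(map$pointers$seq))
})

test_that("locus maps survive a TSV round trip", {
  cfg <- sim_config()
  map <- validate_map(simulate_locus_map(cfg, n_mds = 5L, seed = 152))
  f <- tempfile(fileext = ".tsv")
  write_locus_map(map, f)
  back <- read_locus_map(f)
  expect_equal(back$mds[names(map$mds)], map$mds)
  expect_equal(back$pointers, map$pointers)
})
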