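# brute-force oracle: enumerate all 4^w words under the integer-rounded
# scoring system and sum background mass (independent of the DP path)
enumerate_null <- function(p, resolution) {
  S <- round(log2(p$probs / p$background) / resolution)
  w <- p$width
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- rowSums(matrix(S[cbind(as.vector(words),
                                   rep(seq_len(w), each = nrow(words)))],
                           nrow = nrow(words)))
  probs <- apply(words, 1L, function(ix) prod(p$background[ix]))
  list(scores = scores, probs = probs)
}

test_that("window scores reduce to log-odds sums", {
  uni <- pwm(matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL)),
             pseudocount = 0)
  expect_equal(score_window(uni, "ACGT"), 0)
  onec <- pwm(matrix(c(0, 1, 0, 0), 4, 1,
                     dimnames = list(c("A", "C", "G", "T"), NULL)),
              pseudocount = 1e-12)
  expect_equal(score_window(onec, "C"), 2, tolerance = 1e-6)
  expect_true(is.na(score_window(onec, "N")))
  # 4-column toy pwm: all 256 windows match per-position hand computation
  set.seed(90)
  m <- matrix(stats::rgamma(16, 1), 4, 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m <- sweep(m, 2, colSums(m), "/")
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  p <- pwm(m, bg, pseudocount = 0)
  words <- expand.grid(rep(list(c("A", "C", "G", "T")), 4))
  for (i in seq_len(nrow(words))) {
    wrd <- paste(unlist(words[i, ]), collapse = "")
    ix <- match(unlist(words[i, ]), c("A", "C", "G", "T"))
    expect_equal(score_window(p, wrd),
                 sum(log2(p$probs[cbind(ix, 1:4)] / bg[ix])))
  }
})

test_that("the DP null distribution equals brute-force enumeration", {
  set.seed(91)
  bg <- c(A = 0.35, C = 0.15, G = 0.15, T = 0.35)
  for (w in c(1L, 4L, 7L)) {
    p <- pwm_from_consensus(rand_seq(w), match_prob = 0.8, background = bg)
    null <- exact_score_distribution(p, 0.01)
    expect_equal(sum(null$pmf), 1, tolerance = 1e-6)
    oracle <- enumerate_null(p, 0.01)
    for (q in unique(stats::quantile(oracle$scores, c(0, .5, .9, .99, 1)))) {
      expect_equal(methelim:::null_tail(null, as.integer(q)),
                   sum(oracle$probs[oracle$scores >= q]),
                   tolerance = 1e-9)
    }
  }
  # width-1 pwm: PMF equals the per-column distribution exactly
  p1 <- pwm_from_consensus("C", match_prob = 0.7, background = bg)
  null1 <- exact_score_distribution(p1, 0.01)
  nz <- which(null1$pmf > 0) + null1$min_score - 1L
  expect_setequal(nz, round(log2(p1$probs[, 1] / bg) / 0.01))
})

test_that("threshold calibration achieves the requested rate", {
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  p <- pwm_from_consensus("CCTTACCA", match_prob = 0.85, background = bg)
  # fdr = 1 admits everything: threshold is the minimum attainable score
  t1 <- calibrate_threshold(p, 1, resolution = 0.01)
  null <- exact_score_distribution(p, 0.01)
  expect_equal(t1$threshold_int, null$min_score)
  # requested rate is achieved and tight
  t2 <- calibrate_threshold(p, 1e-4, resolution = 0.01)
  expect_lte(t2$achieved_tail, 1e-4)
  expect_gt(methelim:::null_tail(null, t2$threshold_int - 1L), 1e-4)
  # unreachable rates are refused
  expect_error(calibrate_threshold(p, 1e-9), "unreachable")
  # resolution guard
  expect_error(exact_score_distribution(p, 0.2), "resolution too coarse")
})

test_that("DP-calibrated hit sets equal brute-force per-window decisions", {
  set.seed(92)
  bg <- c(A = 0.35, C = 0.15, G = 0.15, T = 0.35)
  for (w in c(5L, 8L)) {
    p <- pwm_from_consensus(rand_seq(w), match_prob = 0.85, background = bg)
    fdr <- 4^-w * 20
    thr <- calibrate_threshold(p, fdr, resolution = 0.01)
    seqs <- c(ctg = rand_seq(4000, bg))
    scan <- scan_genome(p, seqs, thr)
    oracle <- enumerate_null(p, 0.01)
    S <- round(log2(p$probs / p$background) / 0.01)
    codes_of <- function(s) match(seq_chars(s), c("A", "C", "G", "T"))
    brute_hits <- function(s) {
      codes <- codes_of(s)
      n <- length(codes) - w + 1L
      sc <- vapply(seq_len(n), function(i)
        sum(S[cbind(codes[i:(i + w - 1L)], seq_len(w))]), numeric(1))
      which(vapply(sc, function(x)
        sum(oracle$probs[oracle$scores >= x]), numeric(1)) <= fdr)
    }
    fwd <- brute_hits(seqs[["ctg"]])
    rev <- brute_hits(revcomp(seqs[["ctg"]]))
    rev_starts <- sort(nchar(seqs[["ctg"]]) - rev - w + 2L)
    expect_identical(sort(scan$hits$start[scan$hits$strand == "+"]),
                     as.integer(fwd))
    expect_identical(sort(scan$hits$start[scan$hits$strand == "-"]),
                     as.integer(rev_starts))
  }
})

test_that("scanning is strand symmetric and finds planted occurrences", {
  set.seed(93)
  bg <- c(A = 0.35, C = 0.15, G = 0.15, T = 0.35)
  cons <- "TCCCTTTCCCTTTTCCCTCC"
  p <- pwm_from_consensus(cons, match_prob = 0.9, background = bg)
  thr <- calibrate_threshold(p, 1e-7)
  host <- rand_seq(2000, bg)
  planted <- paste0(substr(host, 1, 1000), cons, substr(host, 1001, 2000))
  scan <- scan_genome(p, c(ctg = planted), thr)
  expect_equal(nrow(scan$hits), 1L)
  expect_equal(scan$hits$start, 1001L)
  expect_equal(scan$hits$strand, "+")
  expect_lte(scan$hits$p_value, 1e-7)
  # reverse-complemented genome: same hit, strand flipped, position mirrored
  scan_rc <- scan_genome(p, c(ctg = revcomp(planted)), thr)
  expect_equal(nrow(scan_rc$hits), 1L)
  expect_equal(scan_rc$hits$strand, "-")
  expect_equal(scan_rc$hits$start, nchar(planted) - 1001L - 20L + 2L)
  expect_equal(scan_rc$hits$score_bits, scan$hits$score_bits)
})

test_that("lowering the occurrence rate never increases the hit count", {
  set.seed(94)
  bg <- c(A = 0.35, C = 0.15, G = 0.15, T = 0.35)
  p <- pwm_from_consensus("CCTTCC", match_prob = 0.75, background = bg)
  seqs <- c(ctg = rand_seq(20000, bg))
  hits <- sapply(c(1e-2, 1e-3, 1e-4), function(fdr) {
    thr <- calibrate_threshold(p, fdr, resolution = 0.01)
    nrow(scan_genome(p, seqs, thr)$hits)
  })
  expect_true(all(diff(hits) <= 0))
})

test_that("MEME minimal format round-trips a motif", {
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  p <- pwm_from_consensus("CCTTACGT", match_prob = 0.8, background = bg)
  f <- tempfile(fileext = ".meme")
  write_meme(p, f)
  q <- read_meme(f, pseudocount = 0)
  expect_equal(q$probs, p$probs, tolerance = 1e-4)
  expect_equal(q$background, p$background, tolerance = 1e-6)
})

test_that("contigs shorter than the motif are skipped with a warning", {
  p <- pwm_from_consensus("CCCCCCCC")
  thr <- calibrate_threshold(p, 0.01)
  expect_warning(scan <- scan_genome(p, c(tiny = "ACGT"), thr), "skipped")
  expect_equal(nrow(scan$hits), 0L)
})

test_that("cohort chromosomes carry enough hits for cohort membership", {
  cfg <- small_config()
  res <- run_medip_pipeline(cfg, seed = 95)
  truth <- res$genome$mac$id[res$genome$mac$cohort == "mc_hmc"]
  counts <- res$motif_scan$counts
  expect_true(all(counts$n_motifs[counts$contig %in% truth] >= 3L))
})
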