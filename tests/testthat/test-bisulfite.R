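test_that("clone alignment is bisulfite-aware and picks the right template", {
  a <- align_clone("ACGT", "ACGT")
  expect_equal(a$n_mismatch, 0L)
  expect_equal(a$identity, 1)
  # single C->T treated as conversion on the forward template, not mismatch
  a2 <- align_clone("ACCGT", "ATCGT")
  expect_equal(a2$template, "forward")
  expect_equal(a2$n_mismatch, 0L)
  # G->A marks a reverse-template clone
  a3 <- align_clone("ACGGT", "ACAGT")
  expect_equal(a3$template, "reverse")
  expect_equal(a3$n_mismatch, 0L)
  expect_error(align_clone("ACGTACGTACGTACGT", "TTTTGGGGAAAATTCA"),
               "does not map")
})

test_that("site calls follow the conversion rules on both templates", {
  a <- align_clone("ACCGT", "ATCGT")
  calls <- call_sites(a, primer_intervals = data.frame(start = integer(0),
                                                       end = integer(0)))
  expect_equal(calls$pos, c(2L, 3L))
  expect_equal(calls$call, c("unmethylated", "methylated"))
  expect_equal(calls$strand, c("+", "+"))
  # reverse template: ref G + read G methylated, read A unmethylated
  b <- align_clone("ACGGTG", "ACGATG")
  cb <- call_sites(b, primer_intervals = data.frame(start = integer(0),
                                                    end = integer(0)))
  expect_equal(cb$strand, rep("-", 3L))
  expect_equal(cb$call[cb$pos == 3L], "methylated")
  expect_equal(cb$call[cb$pos == 4L], "unmethylated")
})

test_that("primer intervals mask calls and default masking warns", {
  ref <- paste0(strrep("AC", 20), "GGTT")
  a <- align_clone(ref, ref)
  calls <- call_sites(a, primer_intervals = data.frame(start = 1L, end = 44L))
  expect_true(all(calls$call == "masked"))
  expect_true(is.na(clone_report(calls)$by_strand$percent[1]))
  expect_warning(call_sites(a), "masking the outermost")
  expect_error(call_sites(a, primer_intervals = data.frame(start = 1L,
                                                           end = 99L)),
               "outside")
})

test_that("context classification partitions all 3-mer continuations", {
  # exhaustive enumeration oracle over the 16 downstream 2-mers
  for (b1 in c("A", "C", "G", "T")) for (b2 in c("A", "C", "G", "T")) {
    ref <- paste0("AC", b1, b2)
    got <- classify_context(ref, 2L, "+")
    want <- if (b1 == "G") "CpG" else if (b2 == "G") "CpHpG" else "CpHpH"
    expect_identical(got, want)
  }
  expect_identical(classify_context("ACG", 2L, "+"), "CpG")
  expect_identical(classify_context("ACAG", 2L, "+"), "CpHpG")
  # boundary: no downstream context
  expect_true(is.na(classify_context("AC", 2L, "+")))
  # reverse strand reads the reverse complement sense
  expect_identical(classify_context("CGT", 2L, "-"), "CpG")
  expect_identical(classify_context("CTGA", 3L, "-"), "CpHpG")
})

test_that("skip runs are maximal runs over scored sites only", {
  calls <- data.frame(call = c("methylated", "unmethylated", "unmethylated",
                               "unmethylated", "methylated"))
  expect_equal(skip_runs(calls), 3L)
  expect_length(skip_runs(data.frame(call = rep("methylated", 5))), 0L)
  # masked/ambiguous sites do not break a run
  calls2 <- data.frame(call = c("unmethylated", "masked", "unmethylated",
                                "methylated", "ambiguous", "unmethylated"))
  expect_equal(skip_runs(calls2), c(2L, 1L))
})

test_that("conversion QC applies the sub-percent threshold", {
  mk <- function(n_meth, n_unmeth)
    data.frame(call = rep(c("methylated", "unmethylated"),
                          c(n_meth, n_unmeth)))
  qc <- conversion_qc(mk(2, 998))
  expect_equal(qc$fraction, 0.002)
  expect_true(qc$pass)
  qc2 <- conversion_qc(mk(10, 990))
  expect_equal(qc2$fraction, 0.01)
  expect_false(qc2$pass)
  expect_warning(qc3 <- conversion_qc(data.frame(call = "masked")),
                 "indeterminate")
  expect_true(is.na(qc3$pass))
})

test_that("perfect conversion recovers the modification track exactly", {
  cfg <- sim_config(conversion_rate = 1)
  g <- make_region_genome(1500L, seed = 120)
  tr <- plant_modifications(g, cfg, seed = 121)
  cl <- simulate_bisulfite_clones(g, tr, "ctg", 1L, 1500L, 8L, cfg, seed = 122)
  calls <- call_clones(attr(cl, "reference"), cl,
                       primer_intervals = data.frame(start = integer(0),
                                                     end = integer(0)))
  expect_false(any(calls$call == "ambiguous"))
  for (s in c("+", "-")) {
    vec <- if (s == "+") tr$ctg$fwd else tr$ctg$rev
    cs <- calls[calls$strand == s, ]
    # mC and hmC are both reported methylated (indistinguishable)
    expect_identical(cs$call == "methylated", vec[cs$pos] > 0L)
  }
})

test_that("calling is symmetric under reverse complementation", {
  cfg <- sim_config(conversion_rate = 1)
  g <- make_region_genome(800L, seed = 123)
  tr <- plant_modifications(g, cfg, seed = 124)
  cl <- simulate_bisulfite_clones(g, tr, "ctg", 1L, 800L, 6L, cfg, seed = 125)
  ref <- attr(cl, "reference")
  none <- data.frame(start = integer(0), end = integer(0))
  fwd_calls <- call_clones(ref, cl, primer_intervals = none)
  rc <- revcomp(ref)
  rc_clones <- transform(cl, seq = revcomp(seq))
  rc_calls <- call_clones(rc, rc_clones, primer_intervals = none)
  # map back to forward coordinates and flip strands
  rc_calls$pos <- nchar(ref) - rc_calls$pos + 1L
  rc_calls$strand <- ifelse(rc_calls$strand == "+", "-", "+")
  key <- function(d) d[order(d$clone_id, d$strand, d$pos),
                       c("clone_id", "pos", "strand", "call")]
  a <- key(fwd_calls); b <- key(rc_calls)
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("simulated clones at the study densities recover the strand bias", {
  cfg <- sim_config()  # 0.91 forward / 0.84 reverse
  g <- make_region_genome(2500L, seed = 126)
  cl <- simulate_bisulfite_clones(g, null_track(g), "ctg", 1L, 2500L, 30L,
                                  cfg, seed = 127, per_molecule = TRUE)
  calls <- call_clones(attr(cl, "reference"), cl,
                       primer_intervals = data.frame(start = integer(0),
                                                     end = integer(0)))
  rep <- clone_report(calls)
  fwd <- rep$by_strand$percent[rep$by_strand$strand == "+"]
  rev <- rep$by_strand$percent[rep$by_strand$strand == "-"]
  expect_lt(abs(fwd - 91), 2)
  expect_lt(abs(rev - 84), 2)
  # all-context methylation: every context class is called methylated
  expect_true(all(c("CpG", "CpHpG", "CpHpH") %in% rep$by_context$context))
  expect_true(all(rep$by_context$percent > 50))
  # skip runs observed in the configured 1..8 range
  expect_true(length(rep$skip_runs) > 0 && all(rep$skip_runs <= 8L))
})

test_that("site conservation: every strand cytosine is accounted for", {
  cfg <- sim_config()
  g <- make_region_genome(1000L, seed = 128)
  tr <- plant_modifications(g, cfg, seed = 129)
  cl <- simulate_bisulfite_clones(g, tr, "ctg", 1L, 1000L, 1L, cfg,
                                  seed = 130, strand = "+")
  aln <- align_clone(attr(cl, "reference"), cl$seq[1])
  calls <- call_sites(aln, primer_intervals = data.frame(start = 1L,
                                                         end = 20L))
  n_c <- sum(seq_chars(attr(cl, "reference")) == "C")
  expect_equal(nrow(calls), n_c)
  expect_equal(sum(table(calls$call)), n_c)
})
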