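test_that("simulated Ct values follow the log2 abundance model", {
  ab <- data.frame(target = "t", sample = c("s1", "s2"), treatment = "u",
                   template = "native", abundance = c(1, 2))
  ct <- simulate_qpcr(ab, replicates = 3L, noise_sd = 0)
  m <- tapply(ct$ct, ct$sample, mean)
  expect_equal(unname(m["s1"] - m["s2"]), 1)  # doubling drops Ct by 1
  expect_equal(stats::sd(ct$ct[ct$sample == "s1"]), 0)
  # noise level is recovered
  ab2 <- data.frame(target = "t", sample = "s", treatment = "u",
                    template = "native", abundance = 1)
  ct2 <- simulate_qpcr(ab2, replicates = 1000L, noise_sd = 0.2, seed = 160)
  expect_gt(stats::sd(ct2$ct), 0.17)
  expect_lt(stats::sd(ct2$ct), 0.23)
  expect_error(simulate_qpcr(transform(ab, abundance = c(1, 0))), "positive")
  # water controls sit in the no-template Ct window
  ctw <- simulate_qpcr(ab, noise_sd = 0, include_water = TRUE, seed = 161)
  w <- ctw$ct[ctw$sample == "water"]
  expect_true(all(w >= 35 & w <= 38))
})

test_that("ddct_fold reproduces closed-form folds and reciprocity", {
  r3 <- function(x) rep(x, 3)
  eq <- suppressWarnings(ddct_fold(r3(20), r3(20), r3(20), r3(20)))
  expect_equal(eq$ddct, 0)
  expect_equal(eq$fold_change, 1)
  # target one cycle earlier in the sample: fold 2
  f2 <- suppressWarnings(ddct_fold(r3(19), r3(20), r3(20), r3(20)))
  expect_equal(f2$fold_change, 2)
  # means (24, 20, 27, 20) -> ddct -3, fold 8
  f8 <- suppressWarnings(ddct_fold(r3(24), r3(20), r3(27), r3(20)))
  expect_equal(f8$ddct, -3)
  expect_equal(f8$fold_change, 8)
  # swapping arms inverts the fold
  set.seed(162)
  a <- rnorm(3, 21); b <- rnorm(3, 20); c <- rnorm(3, 23); d <- rnorm(3, 20)
  expect_equal(ddct_fold(a, b, c, d)$fold_change *
                 ddct_fold(c, d, a, b)$fold_change, 1)
  # machine offset invariance
  expect_equal(ddct_fold(a + 5, b + 5, c + 5, d + 5)$ddct,
               ddct_fold(a, b, c, d)$ddct)
  expect_error(ddct_fold(1, r3(1), r3(1), r3(1)), "replicat")
})

test_that("one-tailed Welch test matches the closed form and handles ties", {
  set.seed(163)
  a <- rnorm(5, 1); b <- rnorm(6, 0, 2)
  got <- welch_t_one_tailed(a, b)
  # independent computation from the Welch formulae
  sa <- var(a) / 5; sb <- var(b) / 6
  tstat <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / 4 + sb^2 / 5)
  expect_equal(got$t, tstat, tolerance = 1e-12)
  expect_equal(got$df, df, tolerance = 1e-12)
  expect_equal(got$p, stats::pt(tstat, df, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(welch_t_one_tailed(a, b, "less")$p,
               stats::pt(tstat, df, lower.tail = TRUE), tolerance = 1e-12)
  expect_warning(tie <- welch_t_one_tailed(c(1, 1, 1), c(1, 1, 1)), "0.5")
  expect_equal(tie$p, 0.5)
  expect_lt(welch_t_one_tailed(c(10, 10, 10), c(0, 0, 1e-4))$p, 0.005)
  expect_error(welch_t_one_tailed(1, c(1, 2)), "n >= 2")
})

test_that("bisulfite retention signal quantifies conversion-driven loss", {
  r3 <- function(x) rep(x, 3)
  # bisulfite Ct equal to native: fully protected template, L = 1
  bs <- list(s46 = r3(20), veg = r3(30))
  nat <- list(s46 = r3(20), veg = r3(20))
  out <- bisulfite_methylation_signal(bs, nat, control = "veg")
  expect_equal(out$retained_signal[out$sample == "s46"], 1)
  expect_equal(out$retained_signal[out$sample == "veg"], 2^-10,
               tolerance = 1e-12)
  expect_equal(out$fold_vs_control[out$sample == "s46"], 2^10)
  expect_error(bisulfite_methylation_signal(bs, nat[1], control = "veg"),
               "pairing")
})

test_that("methylated 46 h templates give a 30-1000x bisulfite signal ratio", {
  # proof-of-concept assay at the default densities: a template stays
  # amplifiable after bisulfite iff its primer-critical cytosines (12 for
  # a typical cytosine-retaining primer pair) are all retained; a 45-cycle
  # program caps undetectable templates
  cfg <- sim_config()
  n_gate <- 12L
  dens <- mean(c(cfg$mod_density_fwd, cfg$mod_density_rev))
  p_keep <- dens + (1 - dens) * (1 - cfg$conversion_rate)
  surv_46 <- p_keep^n_gate
  surv_veg <- (1 - cfg$conversion_rate)^n_gate
  ab <- data.frame(target = "cohort_chrom", sample = c("veg", "s46",
                                                       "veg", "s46"),
                   treatment = "none",
                   template = rep(c("native", "bisulfite"), each = 2L),
                   abundance = c(1, 1, surv_veg, surv_46))
  ct <- simulate_qpcr(ab, replicates = 3L, noise_sd = 0.15, c0 = 33,
                      seed = 165)
  ct$ct <- pmin(ct$ct, 45)  # no amplification by the final cycle
  pick <- function(tmpl) {
    d <- ct[ct$template == tmpl, ]
    lapply(split(d$ct, d$sample), identity)
  }
  out <- bisulfite_methylation_signal(pick("bisulfite"), pick("native"),
                                      control = "veg")
  fold <- out$fold_vs_control[out$sample == "s46"]
  expect_gt(fold, 30)
  expect_lt(fold, 1000)
  expect_lt(out$p_value[out$sample == "s46"], 0.05)
})

test_that("fold-change tables recover planted retention and demethylation", {
  # retention experiment: 2x more germline template after drug treatment
  ab <- rbind(
    data.frame(target = "mito_rDNA", sample = c("u", "d"),
               treatment = c("untreated", "drug"), template = "native",
               abundance = 1),
    data.frame(target = "satellite_170bp", sample = c("u", "d"),
               treatment = c("untreated", "drug"), template = "native",
               abundance = c(1, 2)))
  ct <- simulate_qpcr(ab, replicates = 3L, noise_sd = 0.15, seed = 166)
  tab <- fold_change_table(ct, norm_target = "mito_rDNA",
                           reference_treatment = "untreated")
  drug <- tab[tab$treatment == "drug", ]
  expect_gt(drug$fold_change, 1.6)
  expect_lt(drug$fold_change, 2.4)
  expect_lt(drug$p_value, 0.05)
  untr <- tab[tab$treatment == "untreated", ]
  expect_equal(untr$fold_change, 1)
  # noise-free identical treatment: folds exactly 1, no stars
  ct0 <- simulate_qpcr(transform(ab, abundance = 1), replicates = 3L,
                       noise_sd = 0)
  tab0 <- suppressWarnings(fold_change_table(ct0))
  expect_true(all(tab0$fold_change == 1))
  expect_true(all(tab0$stars == ""))
  # demethylation: halved modification density halves the bisulfite signal
  ab2 <- rbind(
    data.frame(target = "mito_rDNA", sample = c("u", "d"),
               treatment = c("untreated", "drug"), template = "native",
               abundance = 1),
    data.frame(target = "cohort_chrom", sample = c("u", "d"),
               treatment = c("untreated", "drug"), template = "bisulfite",
               abundance = c(1, 0.5)))
  ct2 <- simulate_qpcr(ab2, replicates = 3L, noise_sd = 0.15, seed = 167)
  tab2 <- fold_change_table(ct2, direction = "less")
  dm <- tab2[tab2$treatment == "drug", ]
  expect_lt(dm$fold_change, 1)
  expect_lt(dm$p_value, 0.05)
  # undetermined Cts are imputed and flagged
  ct2$ct[1] <- NA
  tab3 <- fold_change_table(ct2, direction = "less")
  expect_equal(unique(tab3$n_imputed), 1L)
  expect_error(fold_change_table(ct2, norm_target = "missing"),
               "normalization error")
})
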