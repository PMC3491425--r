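#' One-tailed Welch t-test
#'
#' Student's t-test for unequal variance (Welch-Satterthwaite degrees of
#' freedom), one-tailed.  The degenerate case of zero variance in both
#' groups with equal means returns p = 0.5 with a warning (the symmetric
#' null).
#'
#' @param group_a,group_b numeric vectors (n >= 2 each).
#' @param direction "greater" tests group_a > group_b, "less" the reverse.
#' @return list `t`, `df`, `p`.
#' @export
welch_t_one_tailed <- function(group_a, group_b,
                               direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("insufficient replication: each group needs n >= 2")
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      warning("zero variance in both groups with equal means; p = 0.5")
      return(list(t = 0, df = NA_real_, p = 0.5))
    }
    a_greater <- mean(group_a) > mean(group_b)
    p <- if ((direction == "greater") == a_greater) 0 else 1
    return(list(t = if (a_greater) Inf else -Inf, df = NA_real_, p = p))
  }
  ht <- t.test(group_a, group_b, alternative = direction, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

stars_for_p <- function(p) {
  ifelse(p < 0.005, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' ddCt relative quantification (2^-ddCt)
#'
#' \deqn{\Delta\Delta Ct = (\bar{Ct}_{t,s} - \bar{Ct}_{n,s}) -
#'       (\bar{Ct}_{t,r} - \bar{Ct}_{n,r})}
#' for target t, normalizer n, sample s and reference r;
#' fold change = \eqn{2^{-\Delta\Delta Ct}}.  The standard error propagates
#' as the root sum of squared standard errors of the four arms; the
#' p-value comes from a one-tailed Welch test on replicate-level
#' \eqn{\Delta Ct} values (sample vs reference).
#'
#' @param ct_target_sample,ct_norm_sample,ct_target_ref,ct_norm_ref numeric
#'   replicate Ct vectors (n >= 2 each).
#' @param direction direction of the one-tailed test on fold change vs 1:
#'   "greater" = sample more abundant than reference.
#' @return a `ddct_result`: list `ddct`, `fold_change`, `se`, `p_value`,
#'   `stars`.
#' @export
ddct_fold <- function(ct_target_sample, ct_norm_sample,
                      ct_target_ref, ct_norm_ref,
                      direction = c("greater", "less")) {
  direction <- match.arg(direction)
  arms <- list(ct_target_sample, ct_norm_sample, ct_target_ref, ct_norm_ref)
  if (any(vapply(arms, length, integer(1)) < 2L))
    stop("insufficient replication: each arm needs n >= 2 replicates")
  sem2 <- vapply(arms, function(x) var(x) / length(x), numeric(1))
  ddct <- (mean(ct_target_sample) - mean(ct_norm_sample)) -
          (mean(ct_target_ref) - mean(ct_norm_ref))
  ## fold > 1 (sample enriched) means dct_sample < dct_ref
  dct_s <- delta_reps(ct_target_sample, ct_norm_sample)
  dct_r <- delta_reps(ct_target_ref, ct_norm_ref)
  ht <- suppressWarnings(welch_t_one_tailed(
    dct_r, dct_s, direction = direction))
  out <- list(ddct = ddct, fold_change = 2^(-ddct),
              se = sqrt(sum(sem2)), p_value = ht$p,
              stars = stars_for_p(ht$p))
  class(out) <- "ddct_result"
  out
}

## replicate-level delta-Ct: paired when replicate counts match, else
## each target replicate against the normalizer mean
delta_reps <- function(ct_target, ct_norm) {
  if (length(ct_target) == length(ct_norm)) ct_target - ct_norm
  else ct_target - mean(ct_norm)
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("ddCt %.3f -> fold change %.3f (se %.3f cycles), p = %.4g %s\n",
              x$ddct, x$fold_change, x$se, x$p_value, x$stars))
  invisible(x)
}

#' Bisulfite-qPCR methylation signal
#'
#' Normalizes each bisulfite-treated Ct to the same template in native
#' (untreated) form: the retained signal \eqn{L = 2^{-(\bar{Ct}_{bis} -
#' \bar{Ct}_{nat})}} measures how much amplifiable template survives
#' bisulfite treatment - near 1 for a fully methylated locus, near zero
#' for an unmethylated one.  The methylation fold of a sample is its
#' retained signal over the control sample's.
#'
#' @param ct_bisulfite,ct_native named lists of replicate Ct vectors, one
#'   element per sample (matching names).
#' @param control name of the control sample (e.g. vegetative DNA or a
#'   conversion control).
#' @return data.frame `sample`, `retained_signal`, `fold_vs_control`,
#'   `p_value`, `stars` (one-tailed Welch on replicate \eqn{\Delta Ct},
#'   sample > control).
#' @export
bisulfite_methylation_signal <- function(ct_bisulfite, ct_native, control) {
  samples <- names(ct_bisulfite)
  if (!setequal(samples, names(ct_native)))
    stop("pairing error: bisulfite and native samples differ")
  if (!control %in% samples)
    stop("pairing error: control sample '", control, "' not measured")
  L <- vapply(samples, function(s)
    2^-(mean(ct_bisulfite[[s]]) - mean(ct_native[[s]])), numeric(1))
  dct <- lapply(samples, function(s)
    delta_reps(ct_bisulfite[[s]], ct_native[[s]]))
  names(dct) <- samples
  pv <- vapply(samples, function(s) {
    if (s == control) return(NA_real_)
    ## higher retained signal = smaller delta-Ct
    suppressWarnings(
      welch_t_one_tailed(dct[[control]], dct[[s]], "greater")$p)
  }, numeric(1))
  data.frame(sample = samples, retained_signal = unname(L),
             fold_vs_control = unname(L / L[[control]]),
             p_value = unname(pv),
             stars = stars_for_p(unname(pv)), row.names = NULL)
}

#' Fold-change table across targets and treatments
#'
#' One row per (target, treatment): ddCt fold change of the target in the
#' treated sample relative to the reference treatment, normalized to the
#' loading-control target within each sample.  Undetermined Cts (NA; no
#' amplification by the final cycle) are imputed at `undetermined_ct` and
#' flagged.  Stars come from one-tailed Welch tests on replicate-level
#' delta-Ct; no multiple-testing correction is applied by default (set
#' `holm = TRUE` for a Holm adjustment).
#'
#' @param records data.frame `target`, `sample`, `treatment`, `ct`
#'   (replicate rows; a `template` column, if present, is filtered to
#'   "native" for the loading normalizer).
#' @param norm_target loading-control target measured in every sample.
#' @param reference_treatment treatment whose fold is fixed at 1.
#' @param direction see [ddct_fold()].
#' @param undetermined_ct imputation value for NA Cts.
#' @param holm apply Holm correction to the p-values.
#' @return data.frame `target`, `treatment`, `fold_change`, `ddct`, `se`,
#'   `p_value`, `stars`, `n_imputed`.
#' @export
fold_change_table <- function(records, norm_target = "mito_rDNA",
                              reference_treatment = "untreated",
                              direction = "greater",
                              undetermined_ct = 45, holm = FALSE) {
  need <- c("target", "treatment", "ct")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  n_imp <- sum(is.na(records$ct))
  records$ct[is.na(records$ct)] <- undetermined_ct
  if (!norm_target %in% records$target)
    stop("normalization error: norm target '", norm_target,
         "' not present in records")
  targets <- setdiff(unique(records$target), norm_target)
  treatments <- unique(records$treatment)
  if (!reference_treatment %in% treatments)
    stop("normalization error: reference treatment '", reference_treatment,
         "' not present")
  get_ct <- function(tg, tr) records$ct[records$target == tg &
                                        records$treatment == tr]
  rows <- list()
  for (tg in targets) {
    for (tr in treatments) {
      if (tr == reference_treatment) {
        rows[[length(rows) + 1L]] <-
          data.frame(target = tg, treatment = tr, fold_change = 1,
                     ddct = 0, se = NA_real_, p_value = NA_real_,
                     stars = "", n_imputed = n_imp)
        next
      }
      norm_ref <- get_ct(norm_target, reference_treatment)
      norm_tr <- get_ct(norm_target, tr)
      if (length(norm_tr) < 2L || length(norm_ref) < 2L)
        stop("normalization error: norm target lacks replicates in '",
             tr, "'")
      dd <- ddct_fold(get_ct(tg, tr), norm_tr,
                      get_ct(tg, reference_treatment), norm_ref,
                      direction = direction)
      rows[[length(rows) + 1L]] <-
        data.frame(target = tg, treatment = tr,
                   fold_change = dd$fold_change, ddct = dd$ddct,
                   se = dd$se, p_value = dd$p_value, stars = dd$stars,
                   n_imputed = n_imp)
    }
  }
  out <- do.call(rbind, rows)
  if (holm) {
    idx <- !is.na(out$p_value)
    out$p_value[idx] <- stats::p.adjust(out$p_value[idx], method = "holm")
    out$stars <- stars_for_p(out$p_value)
    out$stars[is.na(out$p_value)] <- ""
  }
  out
}
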