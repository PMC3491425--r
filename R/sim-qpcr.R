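#' Simulate a qPCR threshold-cycle (Ct) table
#'
#' Each row of `abundances` yields `replicates` technical replicates with
#' \eqn{Ct = c_0 - \log_2(\mathrm{abundance}) + N(0, \mathrm{noise\_sd})}.
#' Optional water controls draw Ct uniformly from 35-38 cycles, the range a
#' clean no-template control reads on a 45-cycle program.
#'
#' @param abundances data.frame with columns `target`, `sample`,
#'   `treatment`, `template` and `abundance` (> 0, arbitrary linear scale).
#' @param replicates technical replicates per row (default triplicate).
#' @param noise_sd Ct noise standard deviation, cycles.
#' @param c0 cycle offset of unit abundance.
#' @param include_water add a water control row per target.
#' @param seed optional integer seed.
#' @return data.frame `target`, `sample`, `treatment`, `template`,
#'   `replicate`, `ct`.
#' @export
simulate_qpcr <- function(abundances, replicates = 3L, noise_sd = 0.15,
                          c0 = 30, include_water = FALSE, seed = NULL) {
  need <- c("target", "sample", "treatment", "template", "abundance")
  if (!all(need %in% names(abundances)))
    stop("abundances must have columns ", paste(need, collapse = ", "))
  if (any(abundances$abundance <= 0))
    stop("input error: abundances must be positive")
  with_seed(seed, {
    n <- nrow(abundances)
    rows <- abundances[rep(seq_len(n), each = replicates),
                       c("target", "sample", "treatment", "template")]
    rows$replicate <- rep(seq_len(replicates), times = n)
    mu <- c0 - log2(abundances$abundance)
    rows$ct <- rep(mu, each = replicates) +
      if (noise_sd > 0) rnorm(n * replicates, 0, noise_sd) else 0
    if (include_water) {
      wt <- data.frame(target = unique(abundances$target), sample = "water",
                       treatment = "control", template = "native")
      wt <- wt[rep(seq_len(nrow(wt)), each = replicates), ]
      wt$replicate <- rep(seq_len(replicates), times = length(unique(abundances$target)))
      wt$ct <- runif(nrow(wt), 35, 38)
      rows <- rbind(rows, wt)
    }
    rownames(rows) <- NULL
    rows
  })
}
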