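## Monte-Carlo power for the rare-variant case-control design: carrier
## counts are sampled binomially per group, each replicate is tested by
## a two-sided Fisher exact test, and power is the fraction of
## replicates significant at the chosen threshold.

#' Case carrier frequency under a relative risk
#'
#' By default the case frequency is `baseline_freq * rr`. When
#' `weights` are supplied, `rr` is a vector of relative risks and the
#' case frequency is the weighted mixture
#' `sum(weights * baseline_freq * rr)` (weights must sum to 1) — e.g.
#' mixing the enrichment observed in cases with one, two or three
#' affected first-degree relatives. Frequencies above 1 are clipped
#' with a warning.
#'
#' @param baseline_freq Baseline (control) carrier frequency.
#' @param rr Relative risk, or a vector of relative risks when
#'   `weights` is given.
#' @param weights Optional mixture weights summing to 1.
#' @return Case carrier frequency.
#' @export
caseFrequency <- function(baseline_freq, rr, weights = NULL) {
  stopifnot(baseline_freq > 0, baseline_freq < 1, all(rr >= 0))
  if (is.null(weights)) {
    stopifnot(length(rr) == 1L)
    f <- baseline_freq * rr
  } else {
    if (length(weights) != length(rr))
      stop("weights and rr must have the same length")
    if (abs(sum(weights) - 1) > 1e-8)
      stop("weights must sum to 1")
    f <- sum(weights * baseline_freq * rr)
  }
  if (f > 1) {
    warning("case frequency ", format(f), " clipped to 1")
    f <- 1
  }
  f
}

#' Monte-Carlo power grid
#'
#' For each (baseline frequency, relative risk) cell, `n_reps`
#' replicates draw case carriers from `Binomial(n_cases, case_freq)`
#' and control carriers from `Binomial(n_controls, baseline_freq)`;
#' a replicate is significant when the two-sided Fisher exact P-value
#' is below `alpha`. Power is the significant fraction and `mc_se` its
#' Monte-Carlo standard error `sqrt(power (1 - power) / n_reps)`.
#' Deterministic under the configured seed.
#'
#' @param config A [powerConfig()] list.
#' @param seed Optional integer seed overriding `config$seed`.
#' @return `data.frame`: `freq`, `rr`, `power`, `mc_se`, one row per
#'   grid cell.
#' @export
powerGrid <- function(config = powerConfig(), seed = NULL) {
  stopifnot(inherits(config, "PowerConfig"))
  if (is.null(seed)) seed <- config$seed
  grid <- expand.grid(freq = config$freq_grid, rr = config$rr_grid,
                      KEEP.OUT.ATTRS = FALSE)
  n1 <- config$n_cases
  n2 <- config$n_controls
  .withSeed(seed, {
    res <- lapply(seq_len(nrow(grid)), function(i) {
      f0 <- grid$freq[i]
      f1 <- caseFrequency(f0, if (is.null(config$enrichment_weights)) grid$rr[i]
                          else rep(grid$rr[i], length(config$enrichment_weights)),
                          config$enrichment_weights)
      a <- stats::rbinom(config$n_reps, n1, f1)
      b <- stats::rbinom(config$n_reps, n2, f0)
      ## Fisher P depends only on (a, b); test each distinct outcome once
      key <- paste(a, b)
      uk <- !duplicated(key)
      pu <- mapply(function(ai, bi)
        fisherExactTwoSided(ai, n1 - ai, bi, n2 - bi), a[uk], b[uk])
      sig <- stats::setNames(pu < config$alpha, key[uk])[key]
      pw <- mean(sig)
      data.frame(freq = f0, rr = grid$rr[i], power = pw,
                 mc_se = sqrt(pw * (1 - pw) / config$n_reps))
    })
    do.call(rbind, res)
  })
}
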