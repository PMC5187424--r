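## Independent oracles: small, slow, self-contained implementations
## used to validate the package's statistics. They deliberately share
## no code with the implementation.

## Exact Hardy-Weinberg P by direct enumeration of genotype tables
## compatible with the observed allele counts.
oracle_hwe <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) return(1)
  n_alt <- 2 * n_hom_alt + n_het
  hs <- integer(0)
  pr <- numeric(0)
  for (h in 0:n) {
    rem <- n_alt - h
    if (rem < 0 || rem %% 2 != 0) next
    hom_alt <- rem %/% 2
    hom_ref <- n - h - hom_alt
    if (hom_ref < 0) next
    lp <- lchoose(n, h) + lchoose(n - h, hom_alt) + h * log(2) -
      lchoose(2 * n, n_alt)
    hs <- c(hs, h)
    pr <- c(pr, exp(lp))
  }
  pr <- pr / sum(pr)
  p_obs <- pr[hs == n_het]
  if (length(p_obs) != 1) stop("oracle: inconsistent table")
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

## Two-sided Fisher P for rbind(c(a, b), c(c, d)) by summing
## hypergeometric probabilities no larger than the observed table's.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  pr <- dhyper(xs, m, n, k)
  sum(pr[pr <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

## Naive running-sum enrichment score (loop form).
oracle_es <- function(scores, hit, weight) {
  N <- length(scores)
  m <- sum(hit)
  sw <- sum(abs(scores[hit])^weight)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + if (sw > 0) abs(scores[i])^weight / sw else 1 / m
    } else {
      run <- run - 1 / (N - m)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

## Exhaustive gene-permutation P: fraction of all same-size subsets
## with an enrichment score at least as extreme, matching sign.
oracle_gsea_p <- function(scores, hit, weight) {
  N <- length(scores)
  m <- sum(hit)
  es_obs <- oracle_es(scores, hit, weight)
  subsets <- combn(N, m)
  cnt <- 0
  for (j in seq_len(ncol(subsets))) {
    h <- rep(FALSE, N)
    h[subsets[, j]] <- TRUE
    e <- oracle_es(scores, h, weight)
    if (abs(e) >= abs(es_obs) && sign(e) == sign(es_obs)) cnt <- cnt + 1
  }
  cnt / ncol(subsets)
}

## Exact power of the two-group binomial design by enumerating every
## (case carriers, control carriers) outcome.
oracle_power <- function(freq, rr, n_cases, n_controls, alpha) {
  f1 <- min(freq * rr, 1)
  pa <- dbinom(0:n_cases, n_cases, f1)
  pb <- dbinom(0:n_controls, n_controls, freq)
  tot <- 0
  for (a in 0:n_cases) {
    for (b in 0:n_controls) {
      if (oracle_fisher(a, n_cases - a, b, n_controls - b) < alpha)
        tot <- tot + pa[a + 1] * pb[b + 1]
    }
  }
  tot
}
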