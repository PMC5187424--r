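## Pre-ranked gene-set enrichment: weighted Kolmogorov-Smirnov running
## sum over a ranked gene list, a gene-label permutation null (random
## same-size sets drawn from the ranked list), and Benjamini-Hochberg
## Q values across the collection.

#' Build the ranked gene list from burden results
#'
#' Genes are ranked by their burden permutation P-values, scored as
#' `-log10(p_perm)` (descending); ties are broken by descending odds
#' ratio, then gene symbol, giving a deterministic order.
#'
#' @param burden Burden result table from [burdenTest()].
#' @return `data.frame` with `gene` and `score`, ordered best first.
#' @export
buildRankedList <- function(burden) {
  if (anyDuplicated(burden$gene)) stop("duplicate genes in burden results")
  score <- -log10(burden$p_perm)
  o <- order(-score, -burden$or_freq_ratio, burden$gene)
  data.frame(gene = burden$gene[o], score = score[o], stringsAsFactors = FALSE)
}

## core running sum on hit positions; scores are in ranked order
.runningSum <- function(scores, hit, weight) {
  n <- length(scores)
  m <- sum(hit)
  if (m == 0L) stop("gene set has no overlap with the ranked list")
  if (m == n) stop("gene set spans the entire ranked list (no misses)")
  w <- abs(scores)^weight
  sw <- sum(w[hit])
  inc <- numeric(n)
  if (sw > 0) {
    inc[hit] <- w[hit] / sw
  } else {
    ## all hit scores are zero: fall back to equal (unweighted) steps
    inc[hit] <- 1 / m
  }
  inc[!hit] <- -1 / (n - m)
  cumsum(inc)
}

.esFromRunning <- function(running) {
  running[which.max(abs(running))]
}

#' Gene-set enrichment score
#'
#' Classical weighted Kolmogorov-Smirnov running sum over the ranked
#' list: at each set member ("hit") the sum increases by
#' `|score|^weight` normalized by the total over set members, at each
#' non-member it decreases by `1/(N - |S|)`. The enrichment score is
#' the signed maximum deviation from zero, in `[-1, 1]`. `weight = 0`
#' gives the unweighted KS statistic; when every hit has score zero the
#' hit steps fall back to equal increments.
#'
#' @param ranked `data.frame` with `gene` and `score` in rank order
#'   (see [buildRankedList()]).
#' @param gene_set Character vector of member genes.
#' @param weight Score weight exponent (default 1).
#' @return List with `es`, the `running_sum` profile and the logical
#'   `hits` vector.
#' @export
enrichmentScore <- function(ranked, gene_set, weight = 1) {
  hit <- ranked$gene %in% gene_set
  running <- .runningSum(ranked$score, hit, weight)
  list(es = .esFromRunning(running), running_sum = running, hits = hit)
}

#' Gene-permutation P-value for one gene set
#'
#' Null enrichment scores are obtained by drawing random gene sets of
#' the same size from the ranked list (the pre-ranked convention). The
#' P-value counts null scores at least as extreme as the observed one
#' with matching sign:
#' `(1 + #\{|ES_null| >= |ES_obs|, sign match\}) / (n_perm + 1)`.
#' With `exhaustive = TRUE` all same-size subsets are enumerated and
#' the plain fraction is returned.
#'
#' @inheritParams enrichmentScore
#' @param n_perm Number of random sets (default 1000).
#' @param seed Optional integer seed.
#' @param exhaustive Enumerate all subsets (small lists only).
#' @return List with `es` and `p`.
#' @export
gseaPermutationP <- function(ranked, gene_set, n_perm = 1000L, seed = NULL,
                             exhaustive = FALSE, weight = 1) {
  hit <- ranked$gene %in% gene_set
  gseaPermutationPCore(ranked$score, hit, weight = weight, n_perm = n_perm,
                       seed = seed, exhaustive = exhaustive)
}

## internal worker shared with runGsea so the weight is configurable
gseaPermutationPCore <- function(scores, hit, weight = 1, n_perm = 1000L,
                                 seed = NULL, exhaustive = FALSE) {
  n <- length(hit)
  m <- sum(hit)
  es_obs <- .esFromRunning(.runningSum(scores, hit, weight))
  nullEs <- function(pos) {
    h <- logical(n)
    h[pos] <- TRUE
    .esFromRunning(.runningSum(scores, h, weight))
  }
  extreme <- function(es_null)
    abs(es_null) >= abs(es_obs) & sign(es_null) == sign(es_obs)
  if (exhaustive) {
    if (choose(n, m) > 1e6)
      stop("exhaustive enumeration infeasible for choose(", n, ",", m, ") subsets")
    sets <- utils::combn(n, m)
    es_null <- apply(sets, 2L, nullEs)
    return(list(es = es_obs, p = mean(extreme(es_null))))
  }
  stopifnot(n_perm >= 1)
  p <- .withSeed(seed, {
    hits <- 0L
    for (j in seq_len(n_perm)) {
      hits <- hits + extreme(nullEs(sample.int(n, m)))
    }
    (1 + hits) / (n_perm + 1)
  })
  list(es = es_obs, p = p)
}

#' Benjamini-Hochberg Q values
#'
#' @param p Vector of P-values in `[0, 1]`.
#' @return Adjusted values, monotone after sorting.
#' @export
qValues <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Pre-ranked GSEA over a gene-set collection
#'
#' Builds the ranked list from burden results, computes the enrichment
#' score and gene-permutation P-value per set, adjusts across testable
#' sets by Benjamini-Hochberg, and ranks by P-value then descending
#' enrichment score. Sets with no gene in the ranked list are flagged
#' not testable (`NA` statistics, no rank).
#'
#' The pipeline default is the unweighted KS statistic (`weight = 0`):
#' burden permutation P-values are heavily tied (every gene without a
#' case carrier has P = 1, hence score 0), and score-weighted
#' increments degenerate on such lists — any random set containing a
#' single nonzero-score gene can reach the maximal score of 1. The
#' unweighted statistic depends only on rank positions and stays well
#' calibrated under the gene-permutation null.
#'
#' @param burden Burden result table from [burdenTest()].
#' @param gene_sets Named list of character vectors (see [readGmt()]).
#' @param n_perm Permutations per set (default 1000).
#' @param seed Optional integer seed.
#' @param weight Running-sum weight exponent (default 0, unweighted).
#' @return `DataFrame`: `set`, `n_genes_in_list`, `es`, `p_perm`,
#'   `q_value`, `rank`, `testable`, ordered by rank.
#' @export
runGsea <- function(burden, gene_sets, n_perm = 1000L, seed = NULL, weight = 0) {
  if (length(gene_sets) == 0L) stop("empty gene-set collection")
  ranked <- buildRankedList(burden)
  overlap <- vapply(gene_sets, function(s) sum(ranked$gene %in% s), integer(1))
  testable <- overlap > 0L & overlap < nrow(ranked)
  if (!any(testable)) stop("no gene set overlaps the ranked gene list")
  es <- rep(NA_real_, length(gene_sets))
  p <- rep(NA_real_, length(gene_sets))
  .withSeed(seed, {
    for (i in which(testable)) {
      hit <- ranked$gene %in% gene_sets[[i]]
      r <- gseaPermutationPCore(ranked$score, hit, weight, n_perm, seed = NULL)
      es[i] <- r$es
      p[i] <- r$p
    }
  })
  q <- rep(NA_real_, length(gene_sets))
  q[testable] <- qValues(p[testable])
  res <- S4Vectors::DataFrame(
    set = names(gene_sets), n_genes_in_list = overlap,
    es = es, p_perm = p, q_value = q, testable = testable
  )
  o <- order(!res$testable, res$p_perm, -res$es, res$set)
  res <- res[o, , drop = FALSE]
  res$rank <- NA_integer_
  res$rank[res$testable] <- seq_len(sum(res$testable))
  res
}
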