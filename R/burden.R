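## T1 collapsing carrier burden test with permutation significance,
## frequency-ratio odds ratios, segregation filtering, and Fisher
## replication against external control counts. Case counts are based
## on one randomly assigned proband per pedigree so that familial
## carriers are counted as independent events; sporadic cases are held
## out for replication.

#' Assign one proband per pedigree
#'
#' Chooses, uniformly at random, exactly one sequenced affected member
#' of each pedigree. Deterministic under a fixed seed.
#'
#' @param pedigrees A [PedigreeSet-class].
#' @param cohort A [VariantCohort-class] (or character vector of
#'   sequenced sample ids) used to identify sequenced members.
#' @param seed Optional integer seed.
#' @return Named character vector: pedigree id -> proband sample id.
#' @export
assignProbands <- function(pedigrees, cohort, seed = NULL) {
  eligible <- sequencedAffected(pedigrees, cohort)
  empty <- lengths(eligible) == 0L
  if (any(empty))
    stop("pedigree(s) without a sequenced affected member: ",
         paste(names(eligible)[empty], collapse = ", "))
  .withSeed(seed, vapply(eligible, function(ids)
    ids[sample.int(length(ids), 1L)], character(1)))
}

#' Per-gene carrier indicator matrix
#'
#' A sample is a carrier of a gene when it has at least one non-missing
#' heterozygous or homozygous-alternate genotype across the gene's
#' qualifying variants; multiple qualifying variants in one carrier
#' count once.
#'
#' @param cohort A [VariantCohort-class] (QC-masked).
#' @param qualifying Qualifying-variant table from
#'   [qualifyingVariants()].
#' @param samples Optional sample ids to restrict the columns to.
#' @return Logical matrix, genes x samples.
#' @export
carrierMatrix <- function(cohort, qualifying, samples = colnames(cohort)) {
  gt <- genotypes(cohort)[qualifying$variant_id, samples, drop = FALSE]
  carrier <- !is.na(gt) & gt >= 1L
  genes <- sort(unique(qualifying$gene))
  out <- rowsum(carrier + 0, group = qualifying$gene, reorder = TRUE) > 0
  rownames(out) <- genes
  out
}

#' T1 carrier counts per gene
#'
#' @param cohort A [VariantCohort-class] (QC-masked).
#' @param qualifying Qualifying-variant table.
#' @param probands Character vector of proband sample ids (the case
#'   group).
#' @param controls Character vector of control sample ids.
#' @return `DataFrame` with `gene`, `n_case_carriers`, `n_cases`,
#'   `n_ctrl_carriers`, `n_ctrls`.
#' @export
t1CarrierCounts <- function(cohort, qualifying, probands, controls) {
  cm <- carrierMatrix(cohort, qualifying, c(probands, controls))
  n1 <- length(probands)
  S4Vectors::DataFrame(
    gene = rownames(cm),
    n_case_carriers = as.integer(rowSums(cm[, seq_len(n1), drop = FALSE])),
    n_cases = n1,
    n_ctrl_carriers = as.integer(rowSums(cm[, -seq_len(n1), drop = FALSE])),
    n_ctrls = length(controls)
  )
}

#' Frequency-ratio odds ratio
#'
#' The ratio of the case carrier frequency to the control carrier
#' frequency, `(a/n1) / (b/n2)`. With carrier controls `b = 0` and
#' `a > 0` the ratio is infinite; `continuity = TRUE` instead returns
#' the continuity-corrected estimate
#' `((a+0.5)/(n1+0.5)) / ((b+0.5)/(n2+0.5))`. `a = 0` gives 0.
#'
#' @param a,n1 Case carriers and case total.
#' @param b,n2 Control carriers and control total.
#' @param continuity Use the continuity-corrected estimate (finite for
#'   `b = 0`).
#' @return Numeric odds ratio(s); vectorized.
#' @export
frequencyRatioOR <- function(a, n1, b, n2, continuity = FALSE) {
  if (any(n1 <= 0) || any(n2 <= 0))
    stop("group sizes n1 and n2 must be positive")
  if (any(a < 0 | b < 0 | a > n1 | b > n2))
    stop("carrier counts must satisfy 0 <= a <= n1 and 0 <= b <= n2")
  if (continuity)
    return(((a + 0.5) / (n1 + 0.5)) / ((b + 0.5) / (n2 + 0.5)))
  ifelse(a == 0, 0, (a / n1) / (b / n2))
}

#' Permutation P-value for the carrier burden of one gene
#'
#' The statistic is the number of case carriers. Case/control labels
#' are permuted preserving the group sizes; the one-sided (enrichment)
#' P-value uses the add-one estimator
#' `(1 + #\{permuted statistic >= observed\}) / (n_perm + 1)`, which is
#' never zero. With `exhaustive = TRUE` every label assignment is
#' enumerated and the plain fraction is returned, which equals the
#' hypergeometric tail exactly.
#'
#' @param carrier_flags Logical vector over probands + controls.
#' @param is_case Logical vector of the same length (TRUE = case).
#' @param n_perm Number of permutations (default 1e5).
#' @param seed Optional integer seed.
#' @param exhaustive Enumerate all label assignments instead of
#'   sampling (only feasible for small inputs).
#' @return P-value in (0, 1].
#' @export
permutationBurdenP <- function(carrier_flags, is_case, n_perm = 100000L,
                               seed = NULL, exhaustive = FALSE) {
  stopifnot(length(carrier_flags) == length(is_case))
  carrier_flags <- as.logical(carrier_flags)
  is_case <- as.logical(is_case)
  n <- length(carrier_flags)
  n1 <- sum(is_case)
  obs <- sum(carrier_flags & is_case)
  if (exhaustive) {
    if (choose(n, n1) > 5e6)
      stop("exhaustive enumeration infeasible for choose(", n, ",", n1, ") assignments")
    sets <- utils::combn(n, n1)
    stats <- colSums(matrix(carrier_flags[sets], nrow = n1))
    return(mean(stats >= obs))
  }
  stopifnot(n_perm >= 1)
  .withSeed(seed, {
    ge <- 0L
    for (j in seq_len(n_perm)) {
      ge <- ge + (sum(carrier_flags[sample.int(n, n1)]) >= obs)
    }
    (1 + ge) / (n_perm + 1)
  })
}

#' Pedigree-aware T1 collapsing burden test
#'
#' Assigns one proband per pedigree, counts per-gene qualifying-variant
#' carriers among probands and controls, and assesses enrichment by
#' permuting the case/control status of the proband + control pool. A
#' single set of label permutations is shared by all genes, as one
#' relabelling of the cohort affects every gene simultaneously.
#' Sporadic cases are excluded (they are reserved for replication).
#'
#' @param cohort A QC-masked [VariantCohort-class].
#' @param pedigrees A [PedigreeSet-class].
#' @param qualifying Qualifying-variant table from [applyQC()] /
#'   [qualifyingVariants()].
#' @param n_perm Number of label permutations (default 1e5).
#' @param seed Integer seed driving proband assignment and the
#'   permutations.
#' @return `DataFrame`, one row per tested gene: carrier counts,
#'   `or_freq_ratio` (with `or_infinite` flag and continuity-corrected
#'   `or_continuity`), `p_perm`, `n_affected_familial_carriers`, and
#'   `rank` (see [rankGenes()]), ordered by rank.
#' @export
burdenTest <- function(cohort, pedigrees, qualifying, n_perm = 100000L,
                       seed = NULL) {
  if (nrow(qualifying) == 0L)
    return(S4Vectors::DataFrame(
      gene = character(), n_case_carriers = integer(), n_cases = integer(),
      n_ctrl_carriers = integer(), n_ctrls = integer(),
      or_freq_ratio = numeric(), or_infinite = logical(),
      or_continuity = numeric(), p_perm = numeric(),
      n_affected_familial_carriers = integer(), rank = integer()
    ))
  .withSeed(seed, {
    probands <- vapply(sequencedAffected(pedigrees, cohort), function(ids) {
      if (length(ids) == 0L) stop("pedigree without a sequenced affected member")
      ids[sample.int(length(ids), 1L)]
    }, character(1))
    controls <- controlSamples(cohort)
    pool <- c(probands, controls)
    n1 <- length(probands)
    n <- length(pool)
    cm <- carrierMatrix(cohort, qualifying, pool)
    a <- unname(rowSums(cm[, seq_len(n1), drop = FALSE]))
    b <- unname(rowSums(cm[, -seq_len(n1), drop = FALSE]))

    ## shared permutations, chunked to bound memory
    cmn <- cm + 0
    ge <- numeric(nrow(cm))
    left <- n_perm
    chunk <- max(1L, min(n_perm, as.integer(2e7 / n)))
    while (left > 0L) {
      m <- min(chunk, left)
      idx <- vapply(seq_len(m), function(j) sample.int(n, n1), integer(n1))
      ind <- matrix(0, n, m)
      ind[cbind(as.vector(idx), rep(seq_len(m), each = n1))] <- 1
      stats <- cmn %*% ind
      ge <- ge + rowSums(stats >= a)
      left <- left - m
    }
    p <- (1 + ge) / (n_perm + 1)

    fam <- familialCases(cohort)
    cm_fam <- carrierMatrix(cohort, qualifying, fam)

    res <- S4Vectors::DataFrame(
      gene = rownames(cm),
      n_case_carriers = as.integer(a), n_cases = n1,
      n_ctrl_carriers = as.integer(b), n_ctrls = n - n1,
      or_freq_ratio = frequencyRatioOR(a, n1, b, n - n1),
      or_infinite = b == 0 & a > 0,
      or_continuity = frequencyRatioOR(a, n1, b, n - n1, continuity = TRUE),
      p_perm = p,
      n_affected_familial_carriers = as.integer(rowSums(cm_fam))
    )
    rankGenes(res)
  })
}

#' Rank burden results
#'
#' Ascending permutation P-value, ties broken by descending odds ratio
#' then gene symbol; rank 1 is the most significant gene.
#'
#' @param results Burden result table with `p_perm`, `or_freq_ratio`,
#'   `gene`.
#' @return The table ordered by rank, with a `rank` column.
#' @export
rankGenes <- function(results) {
  if (nrow(results) == 0L) {
    results$rank <- integer()
    return(results)
  }
  o <- order(results$p_perm, -results$or_freq_ratio, results$gene)
  results <- results[o, , drop = FALSE]
  results$rank <- seq_len(nrow(results))
  results
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums hypergeometric probabilities of all tables (with the observed
#' margins) no more probable than the observed one. Tables with a zero
#' margin return 1.
#'
#' @param a,b,c,d Non-negative integer cell counts, rows = groups,
#'   columns = carrier/non-carrier: `rbind(c(a, b), c(c, d))`.
#' @return Two-sided P-value.
#' @export
fisherExactTwoSided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  tab <- matrix(c(a, c, b, d), 2L)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Segregation scan
#'
#' A qualifying variant segregates in a pedigree when the pedigree has
#' at least two sequenced affected members and all of them carry the
#' variant. A gene segregates in a pedigree when any of its qualifying
#' variants does; a gene passes the filter when it segregates in at
#' least `min_families` pedigrees.
#'
#' @param cohort A QC-masked [VariantCohort-class].
#' @param pedigrees A [PedigreeSet-class].
#' @param qualifying Qualifying-variant table.
#' @return `DataFrame` of segregation records — one row per
#'   (gene, pedigree, variant) with at least one affected carrier:
#'   `gene`, `pedigree_id`, `variant_id`, `n_sequenced_affected`,
#'   `n_affected_carriers`, `segregates`.
#' @seealso [segregatingGenes()]
#' @export
segregationScan <- function(cohort, pedigrees, qualifying) {
  gt <- genotypes(cohort)[qualifying$variant_id, , drop = FALSE]
  aff <- sequencedAffected(pedigrees, cohort)
  recs <- lapply(names(aff), function(pid) {
    ids <- aff[[pid]]
    if (length(ids) == 0L) return(NULL)
    g <- gt[, ids, drop = FALSE]
    carrier <- !is.na(g) & g >= 1L
    n_car <- rowSums(carrier)
    hit <- which(n_car > 0L)
    if (length(hit) == 0L) return(NULL)
    data.frame(
      gene = qualifying$gene[hit],
      pedigree_id = pid,
      variant_id = qualifying$variant_id[hit],
      n_sequenced_affected = length(ids),
      n_affected_carriers = as.integer(n_car[hit]),
      segregates = length(ids) >= 2L & n_car[hit] == length(ids),
      stringsAsFactors = FALSE
    )
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L)
    return(S4Vectors::DataFrame(
      gene = character(), pedigree_id = character(), variant_id = character(),
      n_sequenced_affected = integer(), n_affected_carriers = integer(),
      segregates = logical()
    ))
  S4Vectors::DataFrame(do.call(rbind, recs))
}

#' Summarize segregation per gene
#'
#' @param records Output of [segregationScan()].
#' @param min_families Minimum number of segregating pedigrees for a
#'   gene to pass (default 2).
#' @return `DataFrame`: `gene`, `n_segregating_pedigrees`, `pass`.
#' @export
segregatingGenes <- function(records, min_families = 2L) {
  seg <- records[records$segregates, , drop = FALSE]
  n_ped <- vapply(split(seg$pedigree_id, seg$gene),
                  function(p) length(unique(p)), integer(1))
  genes <- sort(unique(records$gene))
  n <- integer(length(genes))
  n[match(names(n_ped), genes)] <- n_ped
  S4Vectors::DataFrame(
    gene = genes,
    n_segregating_pedigrees = n,
    pass = n >= min_families
  )
}

#' Replication test against external control carrier counts
#'
#' For each gene, compares case carrier counts (for example sporadic
#' cases) with carrier counts from a large external control cohort by
#' a two-sided Fisher exact test, and reports the frequency-ratio odds
#' ratio (with infinite-OR flag and continuity-corrected estimate).
#' Genes absent from the external table are skipped with a warning.
#'
#' @param case_counts `data.frame`/`DataFrame` with `gene`,
#'   `carriers`, `total` for the case group.
#' @param external `data.frame` with `gene`, `carriers`, `total` for
#'   the external controls (see [readExternalCounts()]).
#' @return `DataFrame` with per-gene counts, `or_freq_ratio`,
#'   `or_infinite`, `or_continuity`, `p_fisher`.
#' @export
replicationCountsTest <- function(case_counts, external) {
  case_counts <- as.data.frame(case_counts)
  hit <- case_counts$gene %in% external$gene
  if (any(!hit))
    warning("gene(s) absent from external table skipped: ",
            paste(case_counts$gene[!hit], collapse = ", "))
  cc <- case_counts[hit, , drop = FALSE]
  ext <- external[match(cc$gene, external$gene), , drop = FALSE]
  p <- mapply(function(a, n1, b, n2)
    fisherExactTwoSided(a, n1 - a, b, n2 - b),
    cc$carriers, cc$total, ext$carriers, ext$total)
  S4Vectors::DataFrame(
    gene = cc$gene,
    case_carriers = cc$carriers, n_cases = cc$total,
    ext_carriers = ext$carriers, ext_total = ext$total,
    or_freq_ratio = frequencyRatioOR(cc$carriers, cc$total, ext$carriers, ext$total),
    or_infinite = ext$carriers == 0 & cc$carriers > 0,
    or_continuity = frequencyRatioOR(cc$carriers, cc$total, ext$carriers,
                                     ext$total, continuity = TRUE),
    p_fisher = as.numeric(p)
  )
}
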