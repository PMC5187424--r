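make_trio_peds <- function(n_fam, k_aff = 2L) {
  do.call(rbind, lapply(seq_len(n_fam), function(i) {
    fam <- sprintf("PED%03d", i)
    kids <- paste0(fam, "_A", seq_len(k_aff))
    data.frame(pedigree_id = fam,
               individual_id = c(paste0(fam, "_FA"), paste0(fam, "_MO"), kids),
               father_id = c("0", "0", rep(paste0(fam, "_FA"), k_aff)),
               mother_id = c("0", "0", rep(paste0(fam, "_MO"), k_aff)),
               sex = c(1L, 2L, rep(1L, k_aff)),
               affected = c(FALSE, FALSE, rep(TRUE, k_aff)),
               stringsAsFactors = FALSE)
  }))
}

test_that("proband assignment picks one sequenced affected member per pedigree", {
  peds <- PedigreeSet(make_trio_peds(150))
  sequenced <- members(peds)$individual_id[members(peds)$affected]
  pr <- assignProbands(peds, sequenced, seed = 9)
  expect_length(pr, 150L)
  expect_true(all(grepl("_A[12]$", pr)))
  expect_identical(assignProbands(peds, sequenced, seed = 9), pr)
  ## a pedigree with a single sequenced affected member always yields it
  one <- setdiff(sequenced, "PED001_A2")
  for (s in c(1, 2, 3))
    expect_equal(unname(assignProbands(peds, one, seed = s)["PED001"]), "PED001_A1")
  ## no sequenced affected member is an error naming the pedigree
  expect_error(assignProbands(peds, setdiff(sequenced, c("PED002_A1", "PED002_A2"))),
               "PED002")
})

test_that("carrier counting collapses per gene and ignores variant multiplicity", {
  roles <- c("familial_case", rep("control", 4))
  ## two variants of the same gene; sample 1 carries both
  gt <- rbind(c(1L, 0L, 0L, 0L, 1L),
              c(1L, 0L, 1L, 0L, 0L))
  x <- make_cohort(gt, roles, genes = c("GENEA", "GENEA"))
  th <- qcThresholds(maf_max = 0.5)  # tiny cohort: disable the rarity cap
  q <- qualifyingVariants(x, th)
  cm <- carrierMatrix(x, q)
  expect_equal(unname(rowSums(cm)), 3L)  # samples 1, 3, 5 carry once each
  cc <- t1CarrierCounts(x, q, probands = "S01", controls = sprintf("S%02d", 2:5))
  expect_equal(cc$n_case_carriers, 1L)
  expect_equal(cc$n_ctrl_carriers, 2L)
  ## invariant to variant order and duplicated carrier variants
  x2 <- x[c(2, 1), ]
  cm2 <- carrierMatrix(x2, qualifyingVariants(x2, th))
  expect_equal(cm, cm2)
})

test_that("frequency-ratio OR handles zero cells and continuity correction", {
  expect_equal(frequencyRatioOR(0, 150, 5, 1609), 0)
  expect_true(is.infinite(frequencyRatioOR(2, 150, 0, 1609)))
  expect_equal(frequencyRatioOR(2, 150, 0, 1609, continuity = TRUE),
               ((2.5) / 150.5) / ((0.5) / 1609.5))
  expect_error(frequencyRatioOR(1, 0, 1, 10), "positive")
  expect_error(frequencyRatioOR(5, 4, 0, 10), "carrier counts")
})

test_that("exhaustive permutation equals the hypergeometric tail; sampling is close", {
  ## tiny instance from first principles: 4 cases, 4 controls, both
  ## carriers in cases -> P(X >= 2) = C(4,2)/C(8,2) = 6/28
  flags <- c(TRUE, TRUE, rep(FALSE, 6))
  is_case <- c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 4))
  expect_equal(permutationBurdenP(flags, is_case, exhaustive = TRUE), 6 / 28)
  p_mc <- permutationBurdenP(flags, is_case, n_perm = 20000, seed = 1)
  se <- sqrt((6 / 28) * (1 - 6 / 28) / 20000)
  expect_lt(abs(p_mc - 6 / 28), 4 * se + 1e-4)
  ## observed statistic 0 gives p = 1 under both modes
  none <- rep(FALSE, 8)
  expect_equal(permutationBurdenP(none, is_case, exhaustive = TRUE), 1)
  expect_equal(permutationBurdenP(none, is_case, n_perm = 50, seed = 2), 1)
  ## all-carrier input gives p = 1
  expect_equal(permutationBurdenP(rep(TRUE, 8), is_case, n_perm = 50, seed = 2), 1)
  ## determinism
  expect_identical(permutationBurdenP(flags, is_case, n_perm = 500, seed = 5),
                   permutationBurdenP(flags, is_case, n_perm = 500, seed = 5))
})

test_that("permutation p-values match their exact discrete null distribution", {
  ## under no effect the p-value is NOT uniform (the statistic is a
  ## coarse lattice at rare carrier counts); calibration means the
  ## rejection rate matches the attained size implied by the
  ## hypergeometric null, which we compute exactly per gene
  set.seed(31)
  n <- 120L
  n1 <- 40L
  is_case <- c(rep(TRUE, n1), rep(FALSE, n - n1))
  n_genes <- 150L
  alpha <- 0.05
  rej <- exp_rej <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    flags <- runif(n) < 0.25
    flags <- sample(flags)
    K <- sum(flags)
    p <- permutationBurdenP(flags, is_case, n_perm = 400, seed = g)
    rej[g] <- p < alpha
    ## attained size: P(exact tail < alpha) under the null
    xs <- 0:min(K, n1)
    tails <- 1 - phyper(xs - 1, K, n - K, n1)
    exp_rej[g] <- sum(dhyper(xs, K, n - K, n1)[tails < alpha])
  }
  expected <- mean(exp_rej)
  se <- sqrt(expected * (1 - expected) / n_genes)
  expect_lt(abs(mean(rej) - expected), 3 * se + 0.02)
})

test_that("two-sided Fisher matches hypergeometric enumeration", {
  expect_equal(fisherExactTwoSided(1, 1, 1, 1), 1)
  expect_equal(fisherExactTwoSided(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisherExactTwoSided(10, 90, 10, 90), 1)
  ## sporadic-cases versus large external control cohort
  expect_equal(fisherExactTwoSided(3, 631, 0, 27173),
               oracle_fisher(3, 631, 0, 27173), tolerance = 1e-9)
  set.seed(13)
  for (i in 1:50) {
    tb <- rpois(4, sample(c(2, 8, 30), 1))
    expect_equal(fisherExactTwoSided(tb[1], tb[2], tb[3], tb[4]),
                 oracle_fisher(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-9,
                 label = paste(tb, collapse = ","))
  }
  ## zero-margin tables
  expect_equal(fisherExactTwoSided(0, 0, 3, 5), 1)
  expect_equal(fisherExactTwoSided(0, 4, 0, 6), 1)
})

test_that("segregation requires every sequenced affected member to carry", {
  peds <- PedigreeSet(make_trio_peds(3))
  kids <- sprintf("PED%03d_A%d", rep(1:3, each = 2), rep(1:2, 3))
  roles <- c(rep("familial_case", 6), rep("control", 4))
  ## gene A: full sharing in PED001 and PED002; gene B: 1 of 2 in PED003
  gt <- rbind(c(1L, 1L, 1L, 1L, 0L, 0L, rep(0L, 4)),
              c(0L, 0L, 0L, 0L, 1L, 0L, rep(0L, 4)))
  x <- make_cohort(gt, roles, genes = c("GENEA", "GENEB"),
                   pedigree_id = c(rep(c("PED001", "PED002", "PED003"), each = 2),
                                   rep(NA, 4)),
                   sample_ids = c(kids, sprintf("CT%02d", 1:4)))
  th <- qcThresholds(maf_max = 0.5)
  q <- qualifyingVariants(x, th)
  rec <- segregationScan(x, peds, q)
  sg <- segregatingGenes(rec)
  expect_true(sg$pass[sg$gene == "GENEA"])
  expect_equal(sg$n_segregating_pedigrees[sg$gene == "GENEA"], 2L)
  ## partial sharing does not segregate; one pedigree would not pass anyway
  expect_false(sg$pass[sg$gene == "GENEB"])
  expect_equal(sg$n_segregating_pedigrees[sg$gene == "GENEB"], 0L)
  ## a missing genotype in an affected member breaks segregation
  gt2 <- gt
  gt2[1, 3] <- NA_integer_
  x2 <- make_cohort(gt2, roles, genes = c("GENEA", "GENEB"),
                    pedigree_id = c(rep(c("PED001", "PED002", "PED003"), each = 2),
                                    rep(NA, 4)),
                    sample_ids = c(kids, sprintf("CT%02d", 1:4)))
  sg2 <- segregatingGenes(segregationScan(x2, peds, qualifyingVariants(x2, th)))
  expect_equal(sg2$n_segregating_pedigrees[sg2$gene == "GENEA"], 1L)
  expect_false(sg2$pass[sg2$gene == "GENEA"])
})

test_that("gene ranking orders by p, then descending OR, then symbol", {
  res <- S4Vectors::DataFrame(
    gene = c("B", "A", "D", "C"),
    p_perm = c(0.05, 0.01, 0.05, 0.05),
    or_freq_ratio = c(2, 5, 9, 2)
  )
  r <- rankGenes(res)
  expect_equal(r$gene, c("A", "D", "B", "C"))
  expect_equal(r$rank, 1:4)
  empty <- rankGenes(res[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("burden test end to end: counts, OR, permutation p and ranks", {
  sim <- simulateCohort(simConfig(n_families = 20, n_sporadic = 10, n_controls = 200,
                                  n_genes = 40, n_gene_sets = 5, n_risk_genes = 2,
                                  risk_set_size = 4, seed = 21))
  qc <- applyQC(sim$cohort)
  b <- burdenTest(qc$cohort, sim$pedigrees, qc$qualifying, n_perm = 500, seed = 3)
  expect_equal(b$rank, seq_len(nrow(b)))
  expect_true(all(b$n_case_carriers <= b$n_cases))
  expect_true(all(b$n_ctrl_carriers <= b$n_ctrls))
  expect_equal(unique(b$n_cases), 20L)
  expect_equal(unique(b$n_ctrls), 200L)
  expect_true(all(b$p_perm >= 1 / 501 & b$p_perm <= 1))
  expect_equal(b$or_freq_ratio,
               frequencyRatioOR(b$n_case_carriers, b$n_cases,
                                b$n_ctrl_carriers, b$n_ctrls))
  ## deterministic under the seed
  b2 <- burdenTest(qc$cohort, sim$pedigrees, qc$qualifying, n_perm = 500, seed = 3)
  expect_identical(as.data.frame(b), as.data.frame(b2))
  ## planted genes carry familial carriers
  risk <- sim$truth$genes$gene[sim$truth$genes$is_risk]
  expect_true(all(b$n_affected_familial_carriers[b$gene %in% risk] >= 4L))
})

test_that("replication against external counts flags infinite OR and skips unknowns", {
  ext <- data.frame(gene = c("MAP4", "OTHER"), carriers = c(0L, 10L),
                    total = c(27173L, 27173L))
  cc <- data.frame(gene = c("MAP4", "OTHER", "NOVEL"),
                   carriers = c(3L, 0L, 1L), total = c(634L, 634L, 634L))
  expect_warning(rep <- replicationCountsTest(cc, ext), "NOVEL")
  m <- as.data.frame(rep[rep$gene == "MAP4", ])
  expect_true(m$or_infinite)
  expect_true(is.infinite(m$or_freq_ratio))
  expect_gt(m$or_continuity, 0)
  expect_lt(m$p_fisher, 1e-3)
  expect_equal(rep$p_fisher[rep$gene == "OTHER"],
               fisherExactTwoSided(0, 634, 10, 27163))
  ## identical carrier frequencies are not significant
  same <- replicationCountsTest(data.frame(gene = "X", carriers = 10L, total = 100L),
                                data.frame(gene = "X", carriers = 10L, total = 100L))
  expect_equal(same$p_fisher, 1)
  ## no carriers anywhere -> p = 1
  none <- replicationCountsTest(data.frame(gene = "X", carriers = 0L, total = 634L),
                                data.frame(gene = "X", carriers = 0L, total = 27173L))
  expect_equal(none$p_fisher, 1)
})
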