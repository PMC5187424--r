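test_that("consequence classification separates disruptive classes from the rest", {
  expect_equal(classifyConsequence("stop_gained"), "nonsense")
  expect_equal(classifyConsequence("splice_acceptor_variant"), "splice_acceptor_donor")
  expect_equal(classifyConsequence("splice_donor_variant"), "splice_acceptor_donor")
  expect_equal(classifyConsequence("frameshift_variant"), "frameshift")
  expect_equal(classifyConsequence("missense_variant"), "missense")
  expect_equal(classifyConsequence("synonymous_variant"), "other")
  expect_true(all(isDisruptive(c("nonsense", "splice_acceptor_donor", "frameshift"))))
  expect_false(any(isDisruptive(c("missense", "other"))))
  expect_warning(cls <- classifyConsequence("flux_capacitor_variant"), "unrecognized")
  expect_equal(cls, "other")
  ## synonym mapping rescues annotator dialects
  expect_equal(classifyConsequence("stopgain", synonyms = c(stopgain = "stop_gained")),
               "nonsense")
})

test_that("allele-balance chi-square matches its closed form", {
  expect_equal(hetAlleleBalanceChi2(10, 10), 0)
  expect_equal(hetAlleleBalanceChi2(24, 6), (24 - 6)^2 / 30)  # 10.8, passes
  expect_lt(hetAlleleBalanceChi2(24, 6), 10.83)
  expect_equal(hetAlleleBalanceChi2(25, 5), (25 - 5)^2 / 30)  # 13.33, fails
  expect_gte(hetAlleleBalanceChi2(25, 5), 10.83)
  expect_true(is.na(hetAlleleBalanceChi2(0, 0)))
})

test_that("Hardy-Weinberg exact test agrees with brute-force enumeration", {
  expect_equal(hweExactP(100, 0, 0), 1)
  expect_equal(hweExactP(0, 0, 100), 1)
  ## 5 minor alleles in 50 diploids: enumeration over het counts {1,3,5}
  expect_equal(hweExactP(46, 3, 1), oracle_hwe(46, 3, 1), tolerance = 1e-12)
  set.seed(71)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    n_minor <- sample(0:min(50, n), 1)
    het <- if (n_minor == 0) 0 else {
      h <- sample(seq(n_minor %% 2, n_minor, by = 2), 1)
    }
    hom_alt <- (n_minor - het) / 2
    hom_ref <- n - het - hom_alt
    expect_equal(hweExactP(hom_ref, het, hom_alt),
                 oracle_hwe(hom_ref, het, hom_alt), tolerance = 1e-9,
                 label = sprintf("(%d,%d,%d)", hom_ref, het, hom_alt))
  }
})

test_that("genotype filter masks low-quality and unbalanced het calls only", {
  th <- qcThresholds()
  ## het at GQ 29 with perfect balance fails the GQ rule
  r <- genotypeFilter(1L, 10L, 10L, 29L, th)
  expect_true(is.na(r$gt))
  expect_equal(r$reason, "low_gq")
  ## het at GQ 99 with alt depth 2 fails the depth rule
  r <- genotypeFilter(1L, 30L, 2L, 99L, th)
  expect_true(is.na(r$gt))
  expect_equal(r$reason, "het_low_alt_depth")
  ## het with alt depth 5 but chi2 13.3 fails the balance rule
  r <- genotypeFilter(1L, 25L, 5L, 99L, th)
  expect_equal(r$reason, "het_allele_imbalance")
  ## homozygous reference at GQ 35 is retained unchanged
  r <- genotypeFilter(0L, 30L, 0L, 35L, th)
  expect_equal(r$gt, 0L)
  expect_true(is.na(r$reason))
  ## hom-alt calls are exempt from the het depth/balance rules
  r <- genotypeFilter(2L, 0L, 2L, 80L, th)
  expect_equal(r$gt, 2L)
  ## boundary: GQ exactly 30 and alt depth exactly 3 pass
  r <- genotypeFilter(1L, 10L, 3L, 30L, th)
  expect_equal(r$gt, 1L)
})

test_that("site filter drops on call rate, alignability, repeats, tranche and HWE", {
  ## 10 cases + 40 controls, 5 variants
  roles <- c(rep("sporadic_case", 10), rep("control", 40))
  gt <- matrix(0L, 5, 50)
  gt[1, 11:24] <- NA_integer_   # 14/40 controls missing -> call rate 0.65
  gt[5, 11:22] <- 2L            # 12 homozygotes, 0 hets in controls
  x <- make_cohort(gt, roles,
                   alignability = c(1, 0.5, 1, 1, 1),
                   in_simple_repeat = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  tab <- siteFilter(x)
  expect_equal(tab$keep, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(tab$reasons[1], "low_call_rate_controls")
  expect_equal(tab$reasons[2], "low_alignability")
  expect_equal(tab$reasons[3], "simple_repeat")
  expect_equal(tab$reasons[4], "")
  expect_equal(tab$reasons[5], "hwe_fail_controls")
  expect_lt(tab$hwe_p_controls[5], 1e-8)

  ## tranche failure is consumed as an upstream flag
  y <- make_cohort(matrix(0L, 1, 50), roles, tranche_pass = FALSE)
  expect_equal(siteFilter(y)$reasons, "tranche_fail")

  fs <- filterSites(x)
  expect_equal(nrow(fs$cohort), 1L)
  expect_equal(nrow(fs$drops), 4L)
})

test_that("call rate at exactly the threshold is kept, below it dropped", {
  roles <- c(rep("sporadic_case", 4), rep("control", 4))
  gt <- matrix(0L, 2, 8)
  gt[1, 5] <- NA_integer_       # control call rate 0.75 -> kept
  gt[2, 5:6] <- NA_integer_    # control call rate 0.50 -> dropped
  tab <- siteFilter(make_cohort(gt, roles))
  expect_equal(tab$keep, c(TRUE, FALSE))
})

test_that("qualifying variants respect class and both MAF sources", {
  roles <- c(rep("sporadic_case", 20), rep("control", 80))
  gt <- matrix(0L, 4, 100)
  gt[1, 1:5] <- 1L    # MAF 5/200 = 0.025: disruptive but common -> excluded
  gt[2, 1] <- 1L      # MAF 0.005: rare nonsense -> qualifies
  gt[3, 1] <- 1L      # rare missense -> excluded by class
  gt[4, 1] <- 1L      # rare nonsense but annotation MAF 2% -> excluded
  x <- make_cohort(gt, roles,
                   consequence = c("stop_gained", "stop_gained",
                                   "missense_variant", "stop_gained"),
                   annotation_maf = c(NA, NA, NA, 0.02))
  q <- qualifyingVariants(x)
  expect_equal(q$variant_id, rownames(x)[2])
  expect_equal(q$cohort_maf, 1 / 200)
  expect_equal(q$variant_class, "nonsense")
})

test_that("a single het among 1,000 diploids has MAF 0.0005 and qualifies", {
  roles <- c(rep("sporadic_case", 100), rep("control", 900))
  gt <- matrix(0L, 1, 1000)
  gt[1, 7] <- 1L
  x <- make_cohort(gt, roles)
  expect_equal(cohortMaf(x), 0.0005)
  expect_equal(nrow(qualifyingVariants(x)), 1L)
})

test_that("cohort MAF is folded and ignores missing calls", {
  roles <- c(rep("sporadic_case", 2), rep("control", 2))
  gt <- matrix(c(2L, 2L, 2L, 1L), 1)   # alt freq 7/8 -> folded 1/8
  expect_equal(cohortMaf(make_cohort(gt, roles)), 1 / 8)
  gt2 <- matrix(c(1L, NA, NA, NA), 1)  # one called het of one call
  expect_equal(cohortMaf(make_cohort(gt2, roles)), 0.5)
})

test_that("genes with only indel qualifying variants are removed", {
  q <- S4Vectors::DataFrame(
    variant_id = sprintf("v%d", 1:5),
    gene = c("A", "A", "B", "B", "C"),
    variant_class = c("frameshift", "frameshift", "frameshift", "nonsense",
                      "nonsense"),
    cohort_maf = 0.001,
    is_indel = c(TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  out <- excludeIndelOnlyGenes(q)
  ## A: indel-only -> gone; B: mixed -> kept whole; C: SNV-only -> kept
  expect_setequal(unique(out$gene), c("B", "C"))
  expect_equal(sum(out$gene == "B"), 2L)
})

test_that("the QC cascade is idempotent", {
  sim <- simulateCohort(simConfig(n_families = 10, n_sporadic = 20, n_controls = 120,
                                  n_genes = 60, n_gene_sets = 5, n_risk_genes = 2,
                                  risk_set_size = 4, seed = 5))
  qc1 <- applyQC(sim$cohort)
  qc2 <- applyQC(qc1$cohort)
  expect_identical(rownames(qc2$cohort), rownames(qc1$cohort))
  expect_identical(genotypes(qc2$cohort), genotypes(qc1$cohort))
  expect_equal(as.data.frame(qc2$qualifying), as.data.frame(qc1$qualifying))
  expect_equal(sum(qc2$genotype_drops$n), 0L)
  expect_equal(nrow(qc2$site_drops), 0L)
})
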