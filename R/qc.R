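## Variant QC cascade. Order is fixed: genotype-level masking first
## (GQ, het alternate depth, het allele balance), then site-level
## filtering computed on the post-mask data (tranche flag,
## alignability, simple repeats, call rate and Hardy-Weinberg exact
## test in cases and controls separately), then selection of rare
## disruptive qualifying variants per gene, then removal of genes whose
## qualifying variants are all indels.

.DISRUPTIVE_CLASSES <- c("nonsense", "splice_acceptor_donor", "frameshift")

.CONSEQUENCE_MAP <- c(
  stop_gained = "nonsense",
  nonsense = "nonsense",
  splice_acceptor_variant = "splice_acceptor_donor",
  splice_donor_variant = "splice_acceptor_donor",
  splice_acceptor = "splice_acceptor_donor",
  splice_donor = "splice_acceptor_donor",
  frameshift_variant = "frameshift",
  frameshift = "frameshift",
  missense_variant = "missense",
  missense = "missense"
)

## recognized Sequence Ontology terms that are deliberately "other"
.KNOWN_OTHER <- c(
  "synonymous_variant", "stop_lost", "start_lost", "stop_retained_variant",
  "splice_region_variant", "intron_variant", "inframe_insertion",
  "inframe_deletion", "5_prime_UTR_variant", "3_prime_UTR_variant",
  "upstream_gene_variant", "downstream_gene_variant", "intergenic_variant",
  "non_coding_transcript_variant"
)

#' Classify a consequence term
#'
#' Maps annotation terms (Sequence Ontology, as emitted by common
#' annotators) to the classes used by the burden test. Only nonsense,
#' splice acceptor/donor and frameshift changes are disruptive;
#' missense is explicitly not, and every other recognized term is
#' `other`. Unrecognized terms map to `other` with a warning.
#'
#' @param consequence Character vector of annotation terms.
#' @param synonyms Optional named character vector mapping additional
#'   input terms to canonical terms (applied before classification).
#' @return Character vector over `nonsense`, `splice_acceptor_donor`,
#'   `frameshift`, `missense`, `other`.
#' @seealso [isDisruptive()]
#' @export
classifyConsequence <- function(consequence, synonyms = NULL) {
  term <- as.character(consequence)
  if (!is.null(synonyms)) {
    hit <- term %in% names(synonyms)
    term[hit] <- unname(synonyms[term[hit]])
  }
  cls <- unname(.CONSEQUENCE_MAP[term])
  unknown <- is.na(cls) & !term %in% .KNOWN_OTHER & !is.na(term)
  if (any(unknown))
    warning("unrecognized consequence term(s) treated as 'other': ",
            paste(unique(term[unknown]), collapse = ", "))
  cls[is.na(cls)] <- "other"
  cls
}

#' @rdname classifyConsequence
#' @param variant_class Character vector of classes from
#'   `classifyConsequence`.
#' @export
isDisruptive <- function(variant_class) {
  variant_class %in% .DISRUPTIVE_CLASSES
}

#' Heterozygous allele-balance chi-square
#'
#' One-degree-of-freedom goodness-of-fit statistic of the observed
#' reference/alternate read depths of a heterozygous call against the
#' expected 50:50 split: `(ad_ref - ad_alt)^2 / (ad_ref + ad_alt)`.
#' Undefined (`NA`) at zero total depth, in which case the genotype is
#' treated as missing by the filter.
#'
#' @param ad_ref,ad_alt Non-negative read depths (vectorized).
#' @return Numeric chi-square statistic(s).
#' @export
hetAlleleBalanceChi2 <- function(ad_ref, ad_alt) {
  tot <- ad_ref + ad_alt
  out <- (ad_ref - ad_alt)^2 / tot
  out[!is.na(tot) & tot == 0] <- NA_real_
  out
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: conditioning on the observed allele counts,
#' the P-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Monomorphic (or empty) tables return 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return Exact P-value in (0, 1].
#' @export
hweExactP <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0L) return(1)
  n_a <- 2L * n_hom_alt + n_het          # alt allele count
  n_rare <- min(n_a, 2L * n - n_a)
  if (n_rare == 0L) return(1)
  h <- seq(n_rare %% 2L, n_rare, by = 2L)  # possible het counts
  hom_rare <- (n_rare - h) %/% 2L
  hom_common <- n - h - hom_rare
  logp <- lfactorial(n) - lfactorial(hom_rare) - lfactorial(h) -
    lfactorial(hom_common) + h * log(2) +
    lfactorial(n_rare) + lfactorial(2L * n - n_rare) - lfactorial(2L * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  h_obs <- n_het
  p_obs <- p[match(h_obs, h)]
  if (is.na(p_obs)) stop("inconsistent genotype counts")
  sum(p[p <= p_obs * (1 + 1e-12)])
}

#' Genotype-level filter for one call
#'
#' A call is set missing when its genotype quality is below `gq_min`,
#' or — for heterozygous calls — when the alternate depth is below
#' `het_alt_depth_min` or the allele-balance chi-square is at or above
#' `het_chi2_max` (including undefined balance at zero depth).
#' Homozygous calls are not subject to the depth/balance rules.
#'
#' @param gt Integer dosage(s): 0/1/2 or `NA`.
#' @param ad_ref,ad_alt,gq Depths and genotype quality (vectorized).
#' @param thresholds A [qcThresholds()] list.
#' @return List with `gt` (masked dosages) and `reason` (character,
#'   `NA` where the call survives; one of `low_gq`,
#'   `het_low_alt_depth`, `het_allele_imbalance`, `incomplete_format`).
#' @export
genotypeFilter <- function(gt, ad_ref, ad_alt, gq, thresholds = qcThresholds()) {
  gt <- as.integer(gt)
  reason <- rep(NA_character_, length(gt))
  present <- !is.na(gt)
  chi2 <- hetAlleleBalanceChi2(ad_ref, ad_alt)
  incomplete <- present & (is.na(gq) | (gt == .GT_HET & (is.na(ad_ref) | is.na(ad_alt))))
  low_gq <- present & !incomplete & gq < thresholds$gq_min
  het <- present & !incomplete & gt == .GT_HET
  low_ad <- het & !low_gq & ad_alt < thresholds$het_alt_depth_min
  imbal <- het & !low_gq & !low_ad &
    (is.na(chi2) | chi2 >= thresholds$het_chi2_max)
  reason[incomplete] <- "incomplete_format"
  reason[low_gq] <- "low_gq"
  reason[low_ad] <- "het_low_alt_depth"
  reason[imbal] <- "het_allele_imbalance"
  gt[!is.na(reason)] <- NA_integer_
  list(gt = gt, reason = reason)
}

#' Apply the genotype filter across a cohort
#'
#' @param x A [VariantCohort-class].
#' @param thresholds A [qcThresholds()] list.
#' @return The cohort with failing calls set missing; per-reason masked
#'   call counts are stored in `metadata(x)$genotype_drops`.
#' @export
maskGenotypes <- function(x, thresholds = qcThresholds()) {
  res <- genotypeFilter(genotypes(x), refDepth(x), altDepth(x),
                        genotypeQuality(x), thresholds)
  gt <- matrix(res$gt, nrow(x), ncol(x), dimnames = dimnames(genotypes(x)))
  SummarizedExperiment::assay(x, "GT") <- gt
  reasons <- c("low_gq", "het_low_alt_depth", "het_allele_imbalance",
               "incomplete_format")
  drops <- data.frame(
    reason = reasons,
    n = as.integer(table(factor(res$reason, levels = reasons))),
    stringsAsFactors = FALSE
  )
  S4Vectors::metadata(x)$genotype_drops <- drops
  x
}

.groupIdx <- function(x) {
  role <- SummarizedExperiment::colData(x)$role
  list(cases = which(!is.na(role) & role %in% .CASE_ROLES),
       controls = which(!is.na(role) & role == "control"))
}

.gtCounts <- function(gt_rows, idx) {
  ## genotype count matrix for a set of samples: hom_ref, het, hom_alt
  g <- gt_rows[, idx, drop = FALSE]
  cbind(
    hom_ref = rowSums(g == 0L, na.rm = TRUE),
    het = rowSums(g == 1L, na.rm = TRUE),
    hom_alt = rowSums(g == 2L, na.rm = TRUE)
  )
}

#' Site-level filter
#'
#' A variant is kept only if it passed upstream tranche filtering, has
#' alignability equal to the required value, does not overlap a simple
#' repeat, has a post-mask call rate of at least `call_rate_min` in
#' cases and in controls separately, and has a Hardy-Weinberg exact
#' P-value above `hwe_p_min` in cases and in controls separately. The
#' returned table lists every failed rule per variant. Groups with no
#' samples pass their call-rate/HWE rules trivially.
#'
#' @param x A [VariantCohort-class], genotype mask already applied.
#' @param thresholds A [qcThresholds()] list.
#' @return `DataFrame` with one row per variant: `variant_id`, `keep`,
#'   `reasons` (comma-separated, empty when kept), call rates and HWE
#'   P-values per group.
#' @export
siteFilter <- function(x, thresholds = qcThresholds()) {
  rd <- SummarizedExperiment::rowData(x)
  gt <- genotypes(x)
  grp <- .groupIdx(x)
  nv <- nrow(x)

  callRate <- function(idx) {
    if (length(idx) == 0L) return(rep(1, nv))
    rowMeans(!is.na(gt[, idx, drop = FALSE]))
  }
  hweP <- function(idx) {
    if (length(idx) == 0L) return(rep(1, nv))
    cnt <- .gtCounts(gt, idx)
    vapply(seq_len(nv), function(i)
      hweExactP(cnt[i, 1L], cnt[i, 2L], cnt[i, 3L]), numeric(1))
  }
  cr_cases <- callRate(grp$cases)
  cr_ctrls <- callRate(grp$controls)
  hwe_cases <- hweP(grp$cases)
  hwe_ctrls <- hweP(grp$controls)

  fails <- cbind(
    tranche_fail = !rd$tranche_pass,
    low_alignability = rd$alignability != thresholds$alignability_required,
    simple_repeat = rd$in_simple_repeat,
    low_call_rate_cases = cr_cases < thresholds$call_rate_min,
    low_call_rate_controls = cr_ctrls < thresholds$call_rate_min,
    hwe_fail_cases = hwe_cases <= thresholds$hwe_p_min,
    hwe_fail_controls = hwe_ctrls <= thresholds$hwe_p_min
  )
  reasons <- apply(fails, 1L, function(f) paste(colnames(fails)[f], collapse = ","))
  S4Vectors::DataFrame(
    variant_id = rownames(x),
    keep = unname(!apply(fails, 1L, any)),
    reasons = unname(reasons),
    call_rate_cases = unname(cr_cases), call_rate_controls = unname(cr_ctrls),
    hwe_p_cases = hwe_cases, hwe_p_controls = hwe_ctrls
  )
}

#' Apply the site filter, keeping passing variants
#'
#' @inheritParams siteFilter
#' @return List with `cohort` (kept variants) and `drops` (the
#'   [siteFilter()] rows of dropped variants).
#' @export
filterSites <- function(x, thresholds = qcThresholds()) {
  tab <- siteFilter(x, thresholds)
  list(cohort = x[tab$keep, ], drops = tab[!tab$keep, , drop = FALSE])
}

#' Observed cohort minor allele frequency
#'
#' Alternate-allele frequency over non-missing calls across the full
#' cohort, folded to the minor allele.
#'
#' @param x A [VariantCohort-class].
#' @return Numeric vector, one value per variant (`NA` when a variant
#'   has no non-missing calls).
#' @export
cohortMaf <- function(x) {
  gt <- genotypes(x)
  n_called <- rowSums(!is.na(gt))
  af <- rowSums(gt, na.rm = TRUE) / (2 * n_called)
  af[n_called == 0L] <- NA_real_
  unname(pmin(af, 1 - af))
}

#' Select rare disruptive qualifying variants per gene
#'
#' Keeps variants whose consequence class is disruptive (nonsense,
#' splice acceptor/donor, frameshift) and whose minor allele frequency
#' is below `maf_max` — both the observed cohort MAF and, when present,
#' the annotation MAF must pass. Variants without a gene symbol are
#' skipped with a warning.
#'
#' @param x A [VariantCohort-class] after genotype masking and site
#'   filtering.
#' @param thresholds A [qcThresholds()] list.
#' @param synonyms Optional consequence synonym map, see
#'   [classifyConsequence()].
#' @return `DataFrame` with `variant_id`, `gene`, `variant_class`,
#'   `cohort_maf`, `is_indel`, ordered as in `x`.
#' @export
qualifyingVariants <- function(x, thresholds = qcThresholds(), synonyms = NULL) {
  rd <- SummarizedExperiment::rowData(x)
  cls <- classifyConsequence(rd$consequence, synonyms)
  maf <- cohortMaf(x)
  no_gene <- is.na(rd$gene) | rd$gene == ""
  if (any(no_gene & isDisruptive(cls)))
    warning(sum(no_gene & isDisruptive(cls)),
            " disruptive variant(s) without a gene symbol skipped")
  ann <- rd$annotation_maf
  rare <- !is.na(maf) & maf < thresholds$maf_max &
    (is.na(ann) | ann < thresholds$maf_max)
  keep <- isDisruptive(cls) & rare & !no_gene
  S4Vectors::DataFrame(
    variant_id = rownames(x)[keep],
    gene = rd$gene[keep],
    variant_class = cls[keep],
    cohort_maf = maf[keep],
    is_indel = rd$is_indel[keep]
  )
}

#' Drop genes whose qualifying variants are all indels
#'
#' Indel calls are enriched for alignment artefacts; genes supported
#' only by indel qualifying variants are removed from the burden
#' analysis. A gene with at least one non-indel qualifying variant
#' keeps all its variants.
#'
#' @param qualifying Output of [qualifyingVariants()].
#' @return The table restricted to genes with at least one non-indel
#'   qualifying variant.
#' @export
excludeIndelOnlyGenes <- function(qualifying) {
  all_indel <- vapply(split(qualifying$is_indel, qualifying$gene), all, logical(1))
  drop_genes <- names(all_indel)[all_indel]
  qualifying[!qualifying$gene %in% drop_genes, , drop = FALSE]
}

#' Run the full QC cascade
#'
#' Genotype masking, site filtering, qualifying-variant selection and
#' indel-only gene exclusion, in that fixed order. The cascade is
#' idempotent: applying it to its own output changes nothing.
#'
#' @param x A [VariantCohort-class].
#' @param thresholds A [qcThresholds()] list.
#' @param synonyms Optional consequence synonym map.
#' @return List of class `fbQC` with elements `cohort` (masked,
#'   site-filtered), `qualifying` (qualifying-variant table),
#'   `genotype_drops` and `site_drops`.
#' @export
applyQC <- function(x, thresholds = qcThresholds(), synonyms = NULL) {
  masked <- maskGenotypes(x, thresholds)
  sites <- filterSites(masked, thresholds)
  qual <- qualifyingVariants(sites$cohort, thresholds, synonyms)
  qual <- excludeIndelOnlyGenes(qual)
  structure(list(
    cohort = sites$cohort,
    qualifying = qual,
    genotype_drops = S4Vectors::metadata(masked)$genotype_drops,
    site_drops = sites$drops
  ), class = "fbQC")
}

#' @export
print.fbQC <- function(x, ...) {
  cat("famburden QC result\n")
  cat("  variants kept:", nrow(x$cohort), "(", nrow(x$site_drops), "sites dropped )\n")
  cat("  masked calls:", sum(x$genotype_drops$n), "\n")
  cat("  qualifying variants:", nrow(x$qualifying), "in",
      length(unique(x$qualifying$gene)), "genes\n")
  invisible(x)
}
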