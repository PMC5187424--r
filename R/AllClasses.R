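## Genotypes are stored as integer alt-allele dosages: 0 = hom ref,
## 1 = het, 2 = hom alt, NA = missing. Multi-allelic sites must be split
## into one record per alternate allele before construction.

.GT_HOM_REF <- 0L
.GT_HET <- 1L
.GT_HOM_ALT <- 2L

.ROLES <- c("familial_case", "sporadic_case", "control")
.CASE_ROLES <- c("familial_case", "sporadic_case")

.VARIANT_COLS <- c(
  "chrom", "pos", "ref", "alt", "gene", "consequence", "is_indel",
  "annotation_maf", "tranche_pass", "alignability", "in_simple_repeat"
)

#' VariantCohort: annotated variant calls for a case-control cohort
#'
#' A `SummarizedExperiment` subclass holding one row per (site,
#' alternate allele) and one column per sequenced sample. Assays are
#' `GT` (integer alt-allele dosage, `NA` = missing), `AD_REF`/`AD_ALT`
#' (read depths supporting the reference and the alternate allele) and
#' `GQ` (Phred-scaled genotype quality). Row data carries the variant
#' annotations consumed by the QC cascade (`chrom`, `pos`, `ref`,
#' `alt`, `gene`, `consequence`, `is_indel`, `annotation_maf`,
#' `tranche_pass`, `alignability`, `in_simple_repeat`); column data
#' carries `sample_id`, `role` (one of `familial_case`,
#' `sporadic_case`, `control`), `pedigree_id` and `affected`.
#'
#' @aliases VariantCohort-class
#' @exportClass VariantCohort
setClass("VariantCohort", contains = "SummarizedExperiment")

setValidity("VariantCohort", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  need <- c("GT", "AD_REF", "AD_ALT", "GQ")
  if (!all(need %in% an)) {
    msg <- c(msg, paste("missing assays:", paste(setdiff(need, an), collapse = ", ")))
  } else {
    gt <- SummarizedExperiment::assay(object, "GT")
    bad <- gt[!is.na(gt)]
    if (length(bad) && !all(bad %in% 0:2))
      msg <- c(msg, "GT dosages must be 0, 1, 2 or NA")
  }
  rd <- SummarizedExperiment::rowData(object)
  miss <- setdiff(.VARIANT_COLS, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste("missing rowData columns:", paste(miss, collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample_id", "role", "pedigree_id", "affected") %in% colnames(cd))) {
    msg <- c(msg, "colData must have sample_id, role, pedigree_id, affected")
  } else {
    role <- cd$role
    if (any(!is.na(role) & !role %in% .ROLES))
      msg <- c(msg, paste("role must be one of", paste(.ROLES, collapse = ", ")))
    fam <- !is.na(role) & role == "familial_case"
    if (any(fam & is.na(cd$pedigree_id)))
      msg <- c(msg, "every familial_case sample needs a pedigree_id")
    if (anyDuplicated(cd$sample_id))
      msg <- c(msg, "sample_ids must be unique")
  }
  if (is.null(rownames(object)) && nrow(object) > 0)
    msg <- c(msg, "variants must have rownames (variant ids)")
  if (length(msg)) msg else TRUE
})

#' Construct a VariantCohort
#'
#' @param gt Integer matrix of alt-allele dosages (variants x samples);
#'   0 hom ref, 1 het, 2 hom alt, `NA` missing.
#' @param ad_ref,ad_alt Integer matrices of reference/alternate read
#'   depths, same shape as `gt`.
#' @param gq Integer matrix of Phred genotype qualities.
#' @param variants `data.frame` or `DataFrame` with one row per variant
#'   and columns `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`;
#'   optional `annotation_maf` (default `NA`), `tranche_pass` (default
#'   `TRUE`), `alignability` (default 1), `in_simple_repeat` (default
#'   `FALSE`). `is_indel` is derived from the allele lengths.
#' @param samples `data.frame` or `DataFrame` with `sample_id`, `role`,
#'   `pedigree_id`, `affected`, in the column order of `gt`.
#'
#' @return A [VariantCohort-class] object with rownames
#'   `chrom:pos:ref:alt`.
#' @export
VariantCohort <- function(gt, ad_ref, ad_alt, gq, variants, samples) {
  variants <- S4Vectors::DataFrame(variants)
  if (!"annotation_maf" %in% colnames(variants)) variants$annotation_maf <- NA_real_
  if (!"tranche_pass" %in% colnames(variants)) variants$tranche_pass <- TRUE
  if (!"alignability" %in% colnames(variants)) variants$alignability <- 1
  if (!"in_simple_repeat" %in% colnames(variants)) variants$in_simple_repeat <- FALSE
  variants$is_indel <- nchar(variants$ref) != nchar(variants$alt)
  variants <- variants[, .VARIANT_COLS]
  samples <- S4Vectors::DataFrame(samples)
  if (!"pedigree_id" %in% colnames(samples)) samples$pedigree_id <- NA_character_
  vid <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
  if (anyDuplicated(vid))
    stop("duplicate variant records: ", paste(unique(vid[duplicated(vid)]), collapse = ", "))
  storage.mode(gt) <- "integer"
  storage.mode(ad_ref) <- "integer"
  storage.mode(ad_alt) <- "integer"
  storage.mode(gq) <- "integer"
  dimnames(gt) <- dimnames(ad_ref) <- dimnames(ad_alt) <- dimnames(gq) <-
    list(vid, samples$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(GT = gt, AD_REF = ad_ref, AD_ALT = ad_alt, GQ = gq),
    rowData = variants, colData = samples
  )
  new("VariantCohort", se)
}

#' @describeIn VariantCohort Integer genotype dosage matrix.
#' @param x,object A `VariantCohort`.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @export
setMethod("genotypes", "VariantCohort", function(x)
  SummarizedExperiment::assay(x, "GT"))

#' @describeIn VariantCohort Reference-allele read depths.
#' @export
setGeneric("refDepth", function(x) standardGeneric("refDepth"))

#' @export
setMethod("refDepth", "VariantCohort", function(x)
  SummarizedExperiment::assay(x, "AD_REF"))

#' @describeIn VariantCohort Alternate-allele read depths.
#' @export
setGeneric("altDepth", function(x) standardGeneric("altDepth"))

#' @export
setMethod("altDepth", "VariantCohort", function(x)
  SummarizedExperiment::assay(x, "AD_ALT"))

#' @describeIn VariantCohort Phred-scaled genotype qualities.
#' @export
setGeneric("genotypeQuality", function(x) standardGeneric("genotypeQuality"))

#' @export
setMethod("genotypeQuality", "VariantCohort", function(x)
  SummarizedExperiment::assay(x, "GQ"))

#' @describeIn VariantCohort Variant annotation table (rowData).
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @export
setMethod("variantInfo", "VariantCohort", function(x)
  SummarizedExperiment::rowData(x))

#' @describeIn VariantCohort Sample table (colData).
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @export
setMethod("sampleInfo", "VariantCohort", function(x)
  SummarizedExperiment::colData(x))

#' @describeIn VariantCohort Sample ids of cases (familial + sporadic).
#' @export
caseSamples <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  cd$sample_id[!is.na(cd$role) & cd$role %in% .CASE_ROLES]
}

#' @describeIn VariantCohort Sample ids of controls.
#' @export
controlSamples <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  cd$sample_id[!is.na(cd$role) & cd$role == "control"]
}

#' @describeIn VariantCohort Sample ids of familial cases.
#' @export
familialCases <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  cd$sample_id[!is.na(cd$role) & cd$role == "familial_case"]
}

setMethod("show", "VariantCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  tab <- table(factor(cd$role, levels = .ROLES))
  cat("VariantCohort:", nrow(object), "variant records x", ncol(object), "samples\n")
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  genes:", length(unique(SummarizedExperiment::rowData(object)$gene)), "\n")
  invisible(NULL)
})

#' PedigreeSet: family structure for a sequencing study
#'
#' Holds pedigree members as one table with columns `pedigree_id`,
#' `individual_id`, `father_id`, `mother_id` (`"0"` marks a founder),
#' `sex` (1 male, 2 female, 0 unknown), `affected` (logical) and
#' `founder` (logical). Individual ids of sequenced members are matched
#' against `VariantCohort` sample ids; unsequenced members (typically
#' founders) are retained for structure.
#'
#' @aliases PedigreeSet-class
#' @exportClass PedigreeSet
setClass("PedigreeSet", representation(members = "data.frame"))

setValidity("PedigreeSet", function(object) {
  m <- object@members
  need <- c("pedigree_id", "individual_id", "father_id", "mother_id",
            "sex", "affected", "founder")
  miss <- setdiff(need, colnames(m))
  if (length(miss))
    return(paste("missing member columns:", paste(miss, collapse = ", ")))
  key <- paste(m$pedigree_id, m$individual_id)
  if (anyDuplicated(key))
    return("duplicate individual within a pedigree")
  ## non-founder parent references must resolve within the pedigree
  for (pid in unique(m$pedigree_id)) {
    sub <- m[m$pedigree_id == pid, ]
    parents <- setdiff(unique(c(sub$father_id, sub$mother_id)), "0")
    if (!all(parents %in% sub$individual_id))
      return(paste0("pedigree ", pid, ": unresolved parent reference"))
  }
  TRUE
})

#' Construct a PedigreeSet
#'
#' @param members `data.frame` with columns `pedigree_id`,
#'   `individual_id`, `father_id`, `mother_id`, `sex`, `affected`;
#'   `founder` is derived (`father_id == "0" & mother_id == "0"`) when
#'   absent.
#' @return A [PedigreeSet-class].
#' @export
PedigreeSet <- function(members) {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  for (col in c("pedigree_id", "individual_id", "father_id", "mother_id"))
    members[[col]] <- as.character(members[[col]])
  if (!"founder" %in% colnames(members))
    members$founder <- members$father_id == "0" & members$mother_id == "0"
  new("PedigreeSet", members = members)
}

#' @describeIn PedigreeSet Pedigree identifiers.
#' @param x,object A `PedigreeSet`.
#' @export
setGeneric("pedigreeIds", function(x) standardGeneric("pedigreeIds"))

#' @export
setMethod("pedigreeIds", "PedigreeSet", function(x) unique(x@members$pedigree_id))

#' @describeIn PedigreeSet Member table, optionally for one pedigree.
#' @param pedigree Optional pedigree id to subset to.
#' @export
setGeneric("members", function(x, pedigree = NULL) standardGeneric("members"))

#' @export
setMethod("members", "PedigreeSet", function(x, pedigree = NULL) {
  if (is.null(pedigree)) return(x@members)
  x@members[x@members$pedigree_id %in% pedigree, , drop = FALSE]
})

setMethod("length", "PedigreeSet", function(x) length(unique(x@members$pedigree_id)))

setMethod("show", "PedigreeSet", function(object) {
  m <- object@members
  cat("PedigreeSet:", length(unique(m$pedigree_id)), "pedigrees,",
      nrow(m), "members (", sum(m$affected), "affected )\n")
  invisible(NULL)
})

#' Sequenced affected members per pedigree
#'
#' Intersects pedigree membership with the sample ids actually present
#' in a cohort, keeping affected individuals only. These are the
#' members eligible for proband assignment and segregation scanning.
#'
#' @param pedigrees A [PedigreeSet-class].
#' @param cohort A [VariantCohort-class] or a character vector of
#'   sequenced sample ids.
#' @return Named list: pedigree id -> character vector of sequenced
#'   affected sample ids.
#' @export
sequencedAffected <- function(pedigrees, cohort) {
  ids <- if (is(cohort, "VariantCohort")) colnames(cohort) else as.character(cohort)
  m <- members(pedigrees)
  m <- m[m$affected & m$individual_id %in% ids, , drop = FALSE]
  split(m$individual_id, factor(m$pedigree_id, levels = pedigreeIds(pedigrees)))
}
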