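## VCF, PED, GMT, cohort-table and external-count readers/writers.
## Parsing of VCF proper is delegated to VariantAnnotation::readVcf;
## only the per-alternate-allele recode (multi-allelic split) is done
## here, because the T1 burden test counts each alternate allele as an
## independent variant record.

.GT_RE <- "^(\\.|[0-9]+)[/|](\\.|[0-9]+)$"

#' Read an annotated multi-sample VCF into a VariantCohort
#'
#' Reads a VCF v4.2 file whose FORMAT carries `GT`, `AD`, `GQ` and
#' whose INFO carries `GENE`, `CSQ` (one consequence term per variant),
#' `TRANCHE_PASS` (flag), `ALIGNABILITY`, `SIMPLEREP` (flag) and
#' optionally `ANN_MAF`. Multi-allelic rows are split into one record
#' per alternate allele: the genotype dosage counts copies of that
#' allele, `AD_REF` is the reference depth and `AD_ALT` the depth of
#' that allele. Calls with missing FORMAT fields (no GT, or a non-ref
#' call with no usable AD/GQ) become missing genotypes.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param cohort Optional sample table (`data.frame`/`DataFrame` with
#'   `sample_id`, `role`, `pedigree_id`, `affected`) or path to a
#'   tab-separated file with those columns; joined to the VCF sample
#'   order. When omitted, roles are `NA` and must be supplied before
#'   QC/burden steps.
#' @return A [VariantCohort-class] with records in file order (split
#'   alleles adjacent, same `pos`).
#' @export
readCohortVcf <- function(path, cohort = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  smp <- colnames(vcf)
  g <- VariantAnnotation::geno(vcf)
  if (!"GT" %in% names(g)) stop("VCF FORMAT must include GT")
  gts <- g$GT
  ok <- gts == "." | grepl(.GT_RE, gts)
  if (!all(ok)) {
    bad <- gts[!ok][1L]
    stop("unsupported genotype string (unknown separator or ploidy): '", bad, "'")
  }
  a1 <- suppressWarnings(array(as.integer(sub("[/|].*$", "", gts)), dim(gts)))
  a2 <- suppressWarnings(array(as.integer(sub("^.*[/|]", "", gts)), dim(gts)))

  alts <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alts)
  alt_chr <- as.character(unlist(alts))
  rec_site <- rep(seq_len(nrow(vcf)), nalt)
  rec_alt <- sequence(nalt)
  n_rec <- length(rec_site)

  rr <- SummarizedExperiment::rowRanges(vcf)
  inf <- VariantAnnotation::info(vcf)
  getInfo <- function(name, default) {
    if (name %in% colnames(inf)) inf[[name]] else rep(default, nrow(vcf))
  }
  gene <- as.character(getInfo("GENE", NA_character_))
  csq <- as.character(getInfo("CSQ", NA_character_))
  tranche <- as.logical(getInfo("TRANCHE_PASS", TRUE))
  align <- as.numeric(getInfo("ALIGNABILITY", 1))
  simp <- as.logical(getInfo("SIMPLEREP", FALSE))
  ann <- as.numeric(getInfo("ANN_MAF", NA_real_))
  align[is.na(align)] <- 1

  ad <- if ("AD" %in% names(g)) g$AD else NULL
  gq <- if ("GQ" %in% names(g)) g$GQ else NULL
  ad_is_array <- !is.null(ad) && is.array(ad) && length(dim(ad)) == 3L

  gt_m <- matrix(NA_integer_, n_rec, length(smp))
  adr_m <- matrix(NA_integer_, n_rec, length(smp))
  ada_m <- matrix(NA_integer_, n_rec, length(smp))
  gq_m <- matrix(NA_integer_, n_rec, length(smp))

  for (r in seq_len(n_rec)) {
    i <- rec_site[r]
    a <- rec_alt[r]
    dose <- (a1[i, ] == a) + (a2[i, ] == a)
    if (!is.null(ad)) {
      if (ad_is_array) {
        adr <- as.integer(ad[i, , 1L])
        ada <- as.integer(ad[i, , 1L + a])
      } else {
        row <- ad[i, ]
        adr <- vapply(row, function(v)
          if (length(v) >= 1L) as.integer(v[1L]) else NA_integer_, integer(1))
        ada <- vapply(row, function(v)
          if (length(v) >= 1L + a) as.integer(v[1L + a]) else NA_integer_, integer(1))
      }
    } else {
      adr <- ada <- rep(NA_integer_, length(smp))
    }
    gqr <- if (!is.null(gq)) as.integer(gq[i, ]) else rep(NA_integer_, length(smp))
    ## incomplete FORMAT on a call we would need to trust -> missing
    incomplete <- !is.na(dose) & (is.na(gqr) | (dose > 0L & (is.na(adr) | is.na(ada))))
    dose[incomplete] <- NA_integer_
    gt_m[r, ] <- as.integer(dose)
    adr_m[r, ] <- adr
    ada_m[r, ] <- ada
    gq_m[r, ] <- gqr
  }

  variants <- S4Vectors::DataFrame(
    chrom = as.character(GenomicRanges::seqnames(rr))[rec_site],
    pos = GenomicRanges::start(rr)[rec_site],
    ref = as.character(VariantAnnotation::ref(vcf))[rec_site],
    alt = alt_chr,
    gene = gene[rec_site],
    consequence = csq[rec_site],
    annotation_maf = ann[rec_site],
    tranche_pass = tranche[rec_site],
    alignability = align[rec_site],
    in_simple_repeat = simp[rec_site]
  )

  samples <- .resolveCohortTable(cohort, smp)
  VariantCohort(gt_m, adr_m, ada_m, gq_m, variants, samples)
}

.resolveCohortTable <- function(cohort, sample_ids) {
  if (is.null(cohort)) {
    return(S4Vectors::DataFrame(
      sample_id = sample_ids, role = NA_character_,
      pedigree_id = NA_character_, affected = NA
    ))
  }
  if (is.character(cohort) && length(cohort) == 1L)
    cohort <- readCohortTable(cohort)
  cohort <- S4Vectors::DataFrame(cohort)
  missing <- setdiff(sample_ids, cohort$sample_id)
  if (length(missing))
    stop("samples in VCF but not in cohort table: ",
         paste(head(missing, 5), collapse = ", "))
  cohort[match(sample_ids, cohort$sample_id), , drop = FALSE]
}

#' Write a VariantCohort to VCF
#'
#' Emits a VCF v4.2 file with FORMAT `GT:AD:GQ` and the INFO keys
#' consumed by [readCohortVcf()] (`GENE`, `CSQ`, `TRANCHE_PASS`,
#' `ALIGNABILITY`, `SIMPLEREP`, `ANN_MAF`). All records are biallelic,
#' so `readCohortVcf(writeCohortVcf(x))` reproduces the GT/AD/GQ assays
#' and INFO annotations exactly.
#'
#' @param x A [VariantCohort-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeCohortVcf <- function(x, path) {
  rd <- SummarizedExperiment::rowData(x)
  gt <- genotypes(x)
  adr <- refDepth(x)
  ada <- altDepth(x)
  gq <- genotypeQuality(x)
  num <- function(v) format(v, scientific = FALSE, trim = TRUE, digits = 12)
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(rd$chrom), ">"),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence term\">",
    "##INFO=<ID=TRANCHE_PASS,Number=0,Type=Flag,Description=\"Passed upstream tranche filtering\">",
    "##INFO=<ID=ALIGNABILITY,Number=1,Type=Float,Description=\"Alignability (100bp window)\">",
    "##INFO=<ID=SIMPLEREP,Number=0,Type=Flag,Description=\"Overlaps a simple repeat\">",
    "##INFO=<ID=ANN_MAF,Number=1,Type=Float,Description=\"Annotation minor allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(x)), collapse = "\t")
  )
  gt_str <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(x)), function(i) {
    info <- paste0("GENE=", rd$gene[i], ";CSQ=", rd$consequence[i])
    if (isTRUE(rd$tranche_pass[i])) info <- paste0(info, ";TRANCHE_PASS")
    info <- paste0(info, ";ALIGNABILITY=", num(rd$alignability[i]))
    if (isTRUE(rd$in_simple_repeat[i])) info <- paste0(info, ";SIMPLEREP")
    if (!is.na(rd$annotation_maf[i]))
      info <- paste0(info, ";ANN_MAF=", num(rd$annotation_maf[i]))
    dose <- gt[i, ]
    calls <- ifelse(
      is.na(dose), "./.:.:.",
      paste0(gt_str[dose + 1L], ":", adr[i, ], ",", ada[i, ], ":", gq[i, ])
    )
    paste(c(rd$chrom[i], num(rd$pos[i]), ".", rd$ref[i], rd$alt[i], ".",
            "PASS", info, "GT:AD:GQ", calls), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a 6-column PED file
#'
#' Whitespace-separated columns: family id, individual id, father id,
#' mother id, sex (1 male / 2 female / 0 unknown) and phenotype
#' (2 = affected, 1 = unaffected, 0/-9 = unknown). Unsequenced members
#' are retained; founders are rows with both parent ids `0`. Families
#' without any affected member are accepted with a message.
#'
#' @param path Path to the PED file.
#' @return A [PedigreeSet-class].
#' @export
readPed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("PED line ", which(nf < 6L)[1L], ": expected 6 whitespace-separated columns")
  m <- do.call(rbind, lapply(fields, function(f) f[1:6]))
  pheno <- m[, 6L]
  if (any(!grepl("^-?[0-9]+$", pheno)))
    stop("PED line ", which(!grepl("^-?[0-9]+$", pheno))[1L],
         ": non-numeric phenotype '", pheno[!grepl("^-?[0-9]+$", pheno)][1L], "'")
  df <- data.frame(
    pedigree_id = m[, 1L], individual_id = m[, 2L],
    father_id = m[, 3L], mother_id = m[, 4L],
    sex = as.integer(m[, 5L]), affected = as.integer(pheno) == 2L,
    stringsAsFactors = FALSE
  )
  key <- paste(df$pedigree_id, df$individual_id)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate individual within a family: ", dup)
  }
  no_aff <- vapply(split(df$affected, df$pedigree_id), function(a) !any(a), logical(1))
  if (any(no_aff))
    message("pedigrees with no affected member: ",
            paste(names(no_aff)[no_aff], collapse = ", "))
  PedigreeSet(df)
}

#' Write a PedigreeSet as a 6-column PED file
#'
#' @param pedigrees A [PedigreeSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePed <- function(pedigrees, path) {
  m <- members(pedigrees)
  lines <- paste(m$pedigree_id, m$individual_id, m$father_id, m$mother_id,
                 m$sex, ifelse(m$affected, 2L, 1L), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then one gene per field.
#' Duplicate genes within a set are de-duplicated; lines with fewer
#' than three fields, empty gene lists or duplicate set names are
#' rejected.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (one per set) with a
#'   `descriptions` attribute.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1L], ": expected at least 3 tab-separated fields")
  nms <- vapply(fields, `[`, character(1), 1L)
  desc <- vapply(fields, `[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- lengths(sets) == 0L
  if (any(empty))
    stop("GMT line ", which(empty)[1L], ": gene set '", nms[empty][1L], "' is empty")
  if (anyDuplicated(nms))
    stop("duplicate gene-set name: ", nms[duplicated(nms)][1L])
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(desc, nms)
  sets
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors; an optional
#'   `descriptions` attribute supplies the second column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write the cohort sample table
#'
#' Tab-separated with header columns `sample_id`, `role`
#' (`familial_case` / `sporadic_case` / `control`), `pedigree_id`
#' (empty for non-familial samples) and `affected` (0/1).
#'
#' @param path File path.
#' @return `readCohortTable`: a `DataFrame`.
#' @export
readCohortTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "role", "pedigree_id", "affected")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("cohort table missing columns: ", paste(miss, collapse = ", "))
  bad <- !is.na(df$role) & !df$role %in% .ROLES
  if (any(bad)) stop("unknown role: ", df$role[bad][1L])
  df$affected <- as.logical(df$affected)
  S4Vectors::DataFrame(df)
}

#' @rdname readCohortTable
#' @param x Sample table (`DataFrame`/`data.frame`).
#' @export
writeCohortTable <- function(x, path) {
  df <- as.data.frame(x)
  df$affected <- as.integer(df$affected)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an external control carrier-count table
#'
#' Tab-separated with header `gene`, `carriers`, `total` — per-gene
#' qualifying-variant carrier counts in an external control cohort
#' (for example ExAC-style reference controls) used by
#' [replicationCountsTest()].
#'
#' @param path File path.
#' @return `data.frame` with columns `gene`, `carriers`, `total`.
#' @export
readExternalCounts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene", "carriers", "total")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("external count table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$carriers < 0 | df$total <= 0 | df$carriers > df$total))
    stop("invalid external counts (need 0 <= carriers <= total, total > 0)")
  df
}
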