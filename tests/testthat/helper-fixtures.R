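## In-code fixtures: tiny cohorts and files built at test time.

## minimal VariantCohort: gt is a variants x samples dosage matrix;
## clean depths/qualities are filled in so only the fields under test
## matter.
make_cohort <- function(gt, roles, genes = NULL, consequence = "stop_gained",
                        pedigree_id = NULL, sample_ids = NULL, ...) {
  gt <- as.matrix(gt)
  nv <- nrow(gt)
  ns <- ncol(gt)
  if (is.null(genes)) genes <- sprintf("GENE%02d", seq_len(nv))
  dp <- matrix(30L, nv, ns)
  ada <- matrix(0L, nv, ns)
  ada[which(gt == 1L)] <- 15L
  ada[which(gt == 2L)] <- 30L
  adr <- dp - ada
  gq <- matrix(99L, nv, ns)
  adr[which(is.na(gt))] <- NA_integer_
  ada[which(is.na(gt))] <- NA_integer_
  gq[which(is.na(gt))] <- NA_integer_
  extra <- list(...)
  variants <- data.frame(
    chrom = "chr1", pos = seq_len(nv) * 100L,
    ref = "A", alt = "T", gene = genes,
    consequence = rep_len(consequence, nv),
    stringsAsFactors = FALSE
  )
  for (nm in names(extra)) variants[[nm]] <- extra[[nm]]
  if (is.null(pedigree_id))
    pedigree_id <- ifelse(roles == "familial_case",
                          paste0("PED", seq_along(roles)), NA_character_)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(ns))
  samples <- data.frame(
    sample_id = sample_ids,
    role = roles,
    pedigree_id = pedigree_id,
    affected = roles %in% c("familial_case", "sporadic_case"),
    stringsAsFactors = FALSE
  )
  VariantCohort(gt, adr, ada, gq, variants, samples)
}

toy_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=TRANCHE_PASS,Number=0,Type=Flag,Description=\"Tranche\">",
    "##INFO=<ID=ALIGNABILITY,Number=1,Type=Float,Description=\"Alignability\">",
    "##INFO=<ID=SIMPLEREP,Number=0,Type=Flag,Description=\"Simple repeat\">",
    "##INFO=<ID=ANN_MAF,Number=1,Type=Float,Description=\"Annotation MAF\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("chr1", "100", ".", "A", "T", ".", "PASS",
          "GENE=G1;CSQ=stop_gained;TRANCHE_PASS;ALIGNABILITY=1;ANN_MAF=0.001",
          "GT:AD:GQ", "0/1:10,5:99", "0/0:20,0:80", "./.:.:.", sep = "\t"),
    paste("chr1", "200", ".", "A", "C,T", ".", "PASS",
          "GENE=G2;CSQ=missense_variant;TRANCHE_PASS;ALIGNABILITY=0.5;SIMPLEREP",
          "GT:AD:GQ", "1/2:3,4,5:50", "0/1:8,2,0:30", "0/2:7,0,6:40", sep = "\t"))
}

toy_vcf_file <- function(lines = toy_vcf_lines()) {
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  f
}

toy_ped_file <- function(lines) {
  f <- tempfile(fileext = ".ped")
  writeLines(lines, f)
  f
}
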