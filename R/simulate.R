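## Synthetic cohort generator. Emulates the statistical structure the
## pipeline assumes: pedigrees with >= 2 sequenced affected members,
## sporadic cases, controls, per-gene rare variants of mixed
## consequence classes, planted risk genes concentrated in one gene set
## with elevated case carrier frequency and full within-family sharing
## in designated pedigrees, and genotype- and site-level QC noise whose
## injections are recorded in a truth table so every filter can be
## audited.
##
## Rare variants are modelled at the carrier level: unrelated
## individuals are heterozygous carriers with probability equal to the
## variant's carrier frequency; in families, founders carry and
## transmit with Mendelian probability 0.5, and designated risk
## families are conditioned so that all affected members carry the
## planted variant. At carrier frequencies below 1% this is
## indistinguishable from diploid allele sampling and keeps clean sites
## in Hardy-Weinberg proportions.

#' Simulation configuration
#'
#' Defaults mirror the study cohort shape: 150 pedigrees with 2-3
#' sequenced affected members each, 600 sporadic cases, 1,600 controls,
#' 2,000 genes with per-gene carrier frequencies of 0.0005-0.005, and
#' five planted risk genes (relative risk 10, two fully segregating
#' families each) inside one 8-gene set among 50.
#'
#' @param n_families Number of pedigrees.
#' @param affected_per_family Possible counts of sequenced affected
#'   members per pedigree (sampled uniformly).
#' @param n_sporadic,n_controls Unrelated case/control counts.
#' @param n_genes Size of the gene universe.
#' @param variants_per_gene_mean Mean variants per gene (1 + Poisson).
#' @param class_mix Named probabilities over consequence classes
#'   `nonsense`, `splice_acceptor_donor`, `frameshift`, `missense`,
#'   `synonymous`.
#' @param baseline_freq_range Per-gene carrier frequency range for null
#'   genes (split evenly over the gene's variants).
#' @param risk_baseline_freq_range Carrier frequency range for risk
#'   genes (kept low so that case enrichment cannot push a qualifying
#'   variant past the MAF threshold).
#' @param n_risk_genes,risk_rr,risk_families_per_gene Planted signal:
#'   number of risk genes, their case relative risk, and how many
#'   designated pedigrees fully share a private variant per gene.
#' @param planted_variant_freq Baseline carrier frequency of each
#'   family-private planted variant.
#' @param risk_set_name,risk_set_size Name and size of the gene set
#'   containing all risk genes.
#' @param n_gene_sets,gene_set_size_range Collection size and size
#'   range of the null sets (drawn from non-risk genes).
#' @param qc_noise Injection rates: `low_gq_rate` and `missing_rate`
#'   are per genotype call; `low_alt_depth_rate` and `skewed_ad_rate`
#'   are per heterozygous call; `low_alignability_rate`,
#'   `simple_repeat_rate`, `tranche_fail_rate`, `hwe_violation_rate`,
#'   `low_call_rate_rate`, `common_variant_rate` and
#'   `high_annotation_maf_rate` are per site. Injections are mutually
#'   disjoint and never touch risk-gene or planted variants.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(n_families = 150L, affected_per_family = c(2L, 3L),
                      n_sporadic = 600L, n_controls = 1600L,
                      n_genes = 2000L, variants_per_gene_mean = 2,
                      class_mix = c(nonsense = 0.15, splice_acceptor_donor = 0.10,
                                    frameshift = 0.15, missense = 0.35,
                                    synonymous = 0.25),
                      baseline_freq_range = c(5e-4, 5e-3),
                      risk_baseline_freq_range = c(5e-4, 1e-3),
                      n_risk_genes = 5L, risk_rr = 10,
                      risk_families_per_gene = 2L,
                      planted_variant_freq = 5e-4,
                      risk_set_name = "CILIA_MICROTUBULE_FUNCTION",
                      risk_set_size = 8L, n_gene_sets = 50L,
                      gene_set_size_range = c(5L, 40L),
                      qc_noise = list(), seed = 1L) {
  noise_defaults <- list(
    low_gq_rate = 0.001, low_alt_depth_rate = 0.03, skewed_ad_rate = 0.03,
    missing_rate = 0.002, low_alignability_rate = 0.01,
    simple_repeat_rate = 0.01, tranche_fail_rate = 0.01,
    hwe_violation_rate = 0.005, low_call_rate_rate = 0.005,
    common_variant_rate = 0.005, high_annotation_maf_rate = 0.002
  )
  qc_noise <- utils::modifyList(noise_defaults, qc_noise)
  if (!all(unlist(qc_noise) >= 0 & unlist(qc_noise) <= 1))
    stop("all qc_noise rates must be in [0, 1]")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (n_risk_genes * risk_families_per_gene > n_families)
    stop("not enough families for the requested planted risk genes")
  if (risk_rr * max(risk_baseline_freq_range) > 1)
    stop("infeasible: risk carrier frequency exceeds 1")
  if (n_risk_genes > 0 && risk_set_size < n_risk_genes)
    stop("risk_set_size must be >= n_risk_genes")
  structure(list(
    n_families = as.integer(n_families),
    affected_per_family = as.integer(affected_per_family),
    n_sporadic = as.integer(n_sporadic), n_controls = as.integer(n_controls),
    n_genes = as.integer(n_genes),
    variants_per_gene_mean = variants_per_gene_mean, class_mix = class_mix,
    baseline_freq_range = baseline_freq_range,
    risk_baseline_freq_range = risk_baseline_freq_range,
    n_risk_genes = as.integer(n_risk_genes), risk_rr = risk_rr,
    risk_families_per_gene = as.integer(risk_families_per_gene),
    planted_variant_freq = planted_variant_freq,
    risk_set_name = risk_set_name, risk_set_size = as.integer(risk_set_size),
    n_gene_sets = as.integer(n_gene_sets),
    gene_set_size_range = as.integer(gene_set_size_range),
    qc_noise = qc_noise, seed = as.integer(seed)
  ), class = "SimConfig")
}

.sampleFrom <- function(x, n, replace = TRUE) {
  if (length(x) == 1L) rep(x, n) else sample(x, n, replace = replace)
}

## alternate depth of a clean heterozygous call: binomial around 50:50,
## clamped so the call passes both the depth and the balance rule
.cleanHetAlt <- function(dp, chi2max = 10.83, ad_min = 3L) {
  a <- stats::rbinom(length(dp), dp, 0.5)
  dmax <- ceiling(sqrt(chi2max * dp)) - 1
  lo <- pmax(ad_min, ceiling((dp - dmax) / 2))
  hi <- pmax(lo, floor((dp + dmax) / 2))
  pmin(pmax(a, lo), hi)
}

#' Simulate a synthetic cohort
#'
#' Generates genotypes, pedigrees, gene sets and a truth table under a
#' [simConfig()]. Designated risk families carry a family-private
#' nonsense variant shared by all their affected members; risk-gene
#' disruptive variants are enriched in cases (familial founders and
#' sporadic cases) by the configured relative risk; QC violations are
#' injected at the configured rates on disjoint sets of sites and
#' calls, and recorded.
#'
#' @param config A [simConfig()] list.
#' @return List of class `fbSimulation`: `cohort`
#'   ([VariantCohort-class]), `pedigrees` ([PedigreeSet-class]),
#'   `gene_sets` (named list, risk set first), `truth` (list of
#'   `genes`, `variants`, `genotype_noise` tables) and `config`.
#' @export
simulateCohort <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  .withSeed(config$seed, .simulateCohortImpl(config))
}

.simulateCohortImpl <- function(config) {
  nz <- config$qc_noise

  ## --- samples and pedigrees -------------------------------------------
  nf <- config$n_families
  k_aff <- .sampleFrom(config$affected_per_family, nf)
  fam_ids <- sprintf("PED%04d", seq_len(nf))
  child_fam <- rep(seq_len(nf), k_aff)
  child_ids <- unlist(lapply(seq_len(nf), function(i)
    paste0(fam_ids[i], "_A", seq_len(k_aff[i]))), use.names = FALSE)
  spor_ids <- if (config$n_sporadic > 0) sprintf("SP%04d", seq_len(config$n_sporadic)) else character()
  ctrl_ids <- sprintf("CT%04d", seq_len(config$n_controls))
  sample_ids <- c(child_ids, spor_ids, ctrl_ids)
  n_child <- length(child_ids)
  n_spor <- length(spor_ids)
  n_ctrl <- length(ctrl_ids)
  n_samp <- length(sample_ids)
  i_child <- seq_len(n_child)
  i_spor <- n_child + seq_len(n_spor)
  i_ctrl <- n_child + n_spor + seq_len(n_ctrl)

  ped <- do.call(rbind, lapply(seq_len(nf), function(i) {
    kids <- paste0(fam_ids[i], "_A", seq_len(k_aff[i]))
    data.frame(
      pedigree_id = fam_ids[i],
      individual_id = c(paste0(fam_ids[i], "_FA"), paste0(fam_ids[i], "_MO"), kids),
      father_id = c("0", "0", rep(paste0(fam_ids[i], "_FA"), k_aff[i])),
      mother_id = c("0", "0", rep(paste0(fam_ids[i], "_MO"), k_aff[i])),
      sex = c(1L, 2L, rep(1L, k_aff[i])),
      affected = c(FALSE, FALSE, rep(TRUE, k_aff[i])),
      stringsAsFactors = FALSE
    )
  }))
  pedigrees <- PedigreeSet(ped)

  samples <- S4Vectors::DataFrame(
    sample_id = sample_ids,
    role = c(rep("familial_case", n_child), rep("sporadic_case", n_spor),
             rep("control", n_ctrl)),
    pedigree_id = c(fam_ids[child_fam], rep(NA_character_, n_spor + n_ctrl)),
    affected = c(rep(TRUE, n_child + n_spor), rep(FALSE, n_ctrl))
  )

  ## --- gene universe and variant plan ----------------------------------
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  n_risk <- config$n_risk_genes
  risk_genes <- if (n_risk > 0) sort(sample(genes, n_risk)) else character()
  is_risk_gene <- genes %in% risk_genes
  fam_pool <- sample(nf)
  planted_fams <- if (n_risk > 0)
    matrix(fam_pool[seq_len(n_risk * config$risk_families_per_gene)],
           nrow = n_risk, byrow = TRUE)
  else matrix(integer(), 0L, 0L)

  f_gene <- ifelse(is_risk_gene,
                   runif(config$n_genes, config$risk_baseline_freq_range[1],
                         config$risk_baseline_freq_range[2]),
                   runif(config$n_genes, config$baseline_freq_range[1],
                         config$baseline_freq_range[2]))
  n_var_gene <- 1L + stats::rpois(config$n_genes,
                                  max(0, config$variants_per_gene_mean - 1))
  v_gene <- rep(seq_len(config$n_genes), n_var_gene)
  v_class <- sample(names(config$class_mix), sum(n_var_gene), replace = TRUE,
                    prob = config$class_mix)
  v_freq <- f_gene[v_gene] / n_var_gene[v_gene]
  v_within <- sequence(n_var_gene)
  v_planted <- rep(NA_integer_, length(v_gene))

  ## family-private planted variants (nonsense, appended per risk gene)
  if (n_risk > 0) {
    ri <- match(risk_genes, genes)
    for (k in seq_len(n_risk)) {
      for (d in seq_len(config$risk_families_per_gene)) {
        v_gene <- c(v_gene, ri[k])
        v_class <- c(v_class, "nonsense")
        v_freq <- c(v_freq, config$planted_variant_freq)
        v_within <- c(v_within, 500L + d)
        v_planted <- c(v_planted, planted_fams[k, d])
      }
    }
  }
  n_var <- length(v_gene)
  v_flag <- rep("none", n_var)

  ## common and annotation-frequency violations exercise the MAF rules
  eligible0 <- which(!is_risk_gene[v_gene])
  m_common <- round(nz$common_variant_rate * n_var)
  m_ann <- round(nz$high_annotation_maf_rate * n_var)
  pick <- sample(eligible0, min(length(eligible0), m_common + m_ann))
  common_idx <- head(pick, m_common)
  ann_idx <- setdiff(pick, common_idx)
  v_freq[common_idx] <- runif(length(common_idx), 0.04, 0.08)
  v_class[common_idx] <- "nonsense"
  v_class[ann_idx] <- "nonsense"
  v_flag[common_idx] <- "common"
  v_flag[ann_idx] <- "high_annotation_maf"

  v_ann_maf <- rep(NA_real_, n_var)
  with_ann <- runif(n_var) < 0.3 & v_flag == "none"
  v_ann_maf[with_ann] <- v_freq[with_ann] / 2
  v_ann_maf[ann_idx] <- 0.02

  alleles <- list(nonsense = c("C", "T"), splice_acceptor_donor = c("G", "A"),
                  frameshift = c("AT", "A"), missense = c("A", "G"),
                  synonymous = c("T", "C"))
  ref <- vapply(v_class, function(cl) alleles[[cl]][1], character(1))
  alt <- vapply(v_class, function(cl) alleles[[cl]][2], character(1))
  pos <- v_gene * 10000L + v_within * 10L
  csq_term <- c(nonsense = "stop_gained",
                splice_acceptor_donor = "splice_acceptor_variant",
                frameshift = "frameshift_variant",
                missense = "missense_variant",
                synonymous = "synonymous_variant")[v_class]

  ## --- genotypes --------------------------------------------------------
  gt <- matrix(0L, n_var, n_samp)
  disrupt <- v_class %in% .DISRUPTIVE_CLASSES
  for (v in seq_len(n_var)) {
    f <- v_freq[v]
    enriched <- is_risk_gene[v_gene[v]] && disrupt[v]
    f_case <- if (enriched) min(f * config$risk_rr, 0.9) else f
    fa <- stats::rbinom(nf, 1L, f_case)
    mo <- stats::rbinom(nf, 1L, f_case)
    kid <- stats::rbinom(n_child, 1L, 0.5 * fa[child_fam]) +
      stats::rbinom(n_child, 1L, 0.5 * mo[child_fam])
    if (!is.na(v_planted[v]))
      kid[child_fam == v_planted[v]] <- 1L
    gt[v, i_child] <- kid
    if (n_spor > 0) gt[v, i_spor] <- stats::rbinom(n_spor, 1L, f_case)
    gt[v, i_ctrl] <- stats::rbinom(n_ctrl, 1L, f)
  }

  ## --- site-level QC injections (disjoint, never on risk genes) --------
  eligible <- which(!is_risk_gene[v_gene] & v_flag == "none")
  eligible <- eligible[sample.int(length(eligible))]
  takeSites <- function(rate) {
    m <- min(round(rate * n_var), length(eligible))
    out <- head(eligible, m)
    eligible <<- eligible[-seq_len(m)]
    out
  }
  site_align <- takeSites(nz$low_alignability_rate)
  site_rep <- takeSites(nz$simple_repeat_rate)
  site_tranche <- takeSites(nz$tranche_fail_rate)
  site_hwe <- takeSites(nz$hwe_violation_rate)
  site_cr <- takeSites(nz$low_call_rate_rate)

  v_align <- rep(1, n_var)
  v_align[site_align] <- 0.5
  v_simplerep <- rep(FALSE, n_var)
  v_simplerep[site_rep] <- TRUE
  v_tranche <- rep(TRUE, n_var)
  v_tranche[site_tranche] <- FALSE

  ## extreme homozygote excess in controls only
  n_hom_inject <- min(n_ctrl, max(8L, n_ctrl %/% 6L))
  for (v in site_hwe) {
    g <- gt[v, i_ctrl]
    g[g == 1L] <- 0L
    g[sample(n_ctrl, n_hom_inject)] <- 2L
    gt[v, i_ctrl] <- g
  }

  v_site_noise <- rep("none", n_var)
  v_site_noise[site_align] <- "low_alignability"
  v_site_noise[site_rep] <- "simple_repeat"
  v_site_noise[site_tranche] <- "tranche_fail"
  v_site_noise[site_hwe] <- "hwe_fail_controls"
  v_site_noise[site_cr] <- "low_call_rate_controls"

  ## --- read depths and qualities (clean calls pass every rule) ---------
  dp <- matrix(sample(20:40, n_var * n_samp, replace = TRUE), n_var)
  adr <- matrix(0L, n_var, n_samp)
  ada <- matrix(0L, n_var, n_samp)
  hom_ref <- gt == 0L
  adr[hom_ref] <- dp[hom_ref]
  hom_alt <- gt == 2L
  ada[hom_alt] <- dp[hom_alt]
  het <- which(gt == 1L)
  if (length(het)) {
    a <- .cleanHetAlt(dp[het])
    ada[het] <- a
    adr[het] <- dp[het] - a
  }
  gq <- matrix(sample(60:99, n_var * n_samp, replace = TRUE), n_var)

  ## drop >25% of control calls at the designated low-call-rate sites
  n_cr_miss <- ceiling(0.3 * n_ctrl)
  for (v in site_cr) {
    miss <- i_ctrl[sample(n_ctrl, n_cr_miss)]
    gt[v, miss] <- NA_integer_
    adr[v, miss] <- NA_integer_
    ada[v, miss] <- NA_integer_
    gq[v, miss] <- NA_integer_
  }

  ## --- genotype-level QC injections on clean sites ----------------------
  clean_sites <- eligible  # remaining: no site-level injection
  clean_mask <- matrix(FALSE, n_var, n_samp)
  clean_mask[clean_sites, ] <- TRUE
  het_pool <- which(gt == 1L & clean_mask)
  het_pool <- het_pool[sample.int(length(het_pool))]
  n_het_pool <- length(het_pool)
  m_lad <- min(round(nz$low_alt_depth_rate * n_het_pool), n_het_pool)
  lad_cells <- head(het_pool, m_lad)
  if (m_lad > 0L) het_pool <- het_pool[-seq_len(m_lad)]
  m_skew <- min(round(nz$skewed_ad_rate * n_het_pool), length(het_pool))
  skew_cells <- head(het_pool, m_skew)

  cell_pool <- which(clean_mask & !is.na(gt))
  cell_pool <- setdiff(cell_pool, c(lad_cells, skew_cells))
  cell_pool <- cell_pool[sample.int(length(cell_pool))]
  n_clean_calls <- length(cell_pool)
  m_lgq <- min(round(nz$low_gq_rate * n_clean_calls), n_clean_calls)
  lgq_cells <- head(cell_pool, m_lgq)
  if (m_lgq > 0L) cell_pool <- cell_pool[-seq_len(m_lgq)]
  m_miss <- min(round(nz$missing_rate * n_clean_calls), length(cell_pool))
  miss_cells <- head(cell_pool, m_miss)

  ## low alt depth: passes balance (chi2 = 9/7), fails depth (2 < 3)
  adr[lad_cells] <- 5L
  ada[lad_cells] <- 2L
  ## skewed AD: passes depth (6 >= 3), fails balance (chi2 = 16)
  adr[skew_cells] <- 30L
  ada[skew_cells] <- 6L
  gq[lgq_cells] <- sample(5:29, length(lgq_cells), replace = TRUE)
  gt[miss_cells] <- NA_integer_
  adr[miss_cells] <- NA_integer_
  ada[miss_cells] <- NA_integer_
  gq[miss_cells] <- NA_integer_

  cellTruth <- function(cells, type) {
    if (length(cells) == 0L)
      return(data.frame(variant_idx = integer(), sample_id = character(),
                        type = character(), stringsAsFactors = FALSE))
    r <- (cells - 1L) %% n_var + 1L
    s <- (cells - 1L) %/% n_var + 1L
    data.frame(variant_idx = r, sample_id = sample_ids[s], type = type,
               stringsAsFactors = FALSE)
  }
  genotype_noise <- rbind(
    cellTruth(lgq_cells, "low_gq"),
    cellTruth(lad_cells, "het_low_alt_depth"),
    cellTruth(skew_cells, "het_allele_imbalance"),
    cellTruth(miss_cells, "missing")
  )

  gq[is.na(gt)] <- NA_integer_
  adr[is.na(gt)] <- NA_integer_
  ada[is.na(gt)] <- NA_integer_

  ## --- assemble ---------------------------------------------------------
  variants <- S4Vectors::DataFrame(
    chrom = "chr1", pos = pos, ref = ref, alt = alt,
    gene = genes[v_gene], consequence = unname(csq_term),
    annotation_maf = v_ann_maf, tranche_pass = v_tranche,
    alignability = v_align, in_simple_repeat = v_simplerep
  )
  cohort <- VariantCohort(gt, adr, ada, gq, variants, samples)
  genotype_noise$variant_id <- rownames(cohort)[genotype_noise$variant_idx]
  genotype_noise$variant_idx <- NULL

  gene_sets <- .buildGeneSets(genes, risk_genes, config)

  truth_genes <- data.frame(
    gene = genes, is_risk = is_risk_gene,
    rr = ifelse(is_risk_gene, config$risk_rr, 1),
    n_planted_families = ifelse(is_risk_gene,
                                if (n_risk > 0) config$risk_families_per_gene else 0L, 0L),
    stringsAsFactors = FALSE
  )
  truth_variants <- data.frame(
    variant_id = rownames(cohort), gene = genes[v_gene], class = v_class,
    carrier_freq = v_freq,
    planted_family = ifelse(is.na(v_planted), NA_character_, fam_ids[v_planted]),
    flag = v_flag, site_noise = v_site_noise,
    stringsAsFactors = FALSE
  )

  structure(list(
    cohort = cohort, pedigrees = pedigrees, gene_sets = gene_sets,
    truth = list(genes = truth_genes, variants = truth_variants,
                 genotype_noise = genotype_noise),
    config = config
  ), class = "fbSimulation")
}

.buildGeneSets <- function(genes, risk_genes, config) {
  nonrisk <- setdiff(genes, risk_genes)
  filler <- sample(nonrisk, min(config$risk_set_size - length(risk_genes),
                                length(nonrisk)))
  sets <- vector("list", config$n_gene_sets)
  sets[[1L]] <- c(risk_genes, filler)
  sizes <- .sampleFrom(seq(config$gene_set_size_range[1],
                           config$gene_set_size_range[2]),
                       config$n_gene_sets - 1L)
  for (i in seq_len(config$n_gene_sets - 1L))
    sets[[i + 1L]] <- sample(nonrisk, min(sizes[i], length(nonrisk)))
  names(sets) <- c(config$risk_set_name,
                   sprintf("NULL_SET_%03d", seq_len(config$n_gene_sets - 1L)))
  attr(sets, "descriptions") <- stats::setNames(
    c("planted risk gene set", rep("random null set", config$n_gene_sets - 1L)),
    names(sets))
  sets
}

#' Simulate a cohort with no planted effects
#'
#' Same generator with zero risk genes: every gene is null. Used for
#' type-I-error and gene-set false-discovery calibration.
#'
#' @param config A [simConfig()] list (its risk-gene settings are
#'   ignored).
#' @return An `fbSimulation` list, see [simulateCohort()].
#' @export
nullCohort <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  config$n_risk_genes <- 0L
  simulateCohort(config)
}

#' Write a simulated cohort to disk
#'
#' Emits `cohort.vcf`, `cohort.ped`, `sets.gmt`, `cohort.tsv` (sample
#' table) and the truth tables `truth_genes.tsv`, `truth_variants.tsv`,
#' `truth_genotype_noise.tsv` into a directory.
#'
#' @param sim An `fbSimulation` list from [simulateCohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulatedCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCohortVcf(sim$cohort, file.path(dir, "cohort.vcf"))
  writePed(sim$pedigrees, file.path(dir, "cohort.ped"))
  writeGmt(sim$gene_sets, file.path(dir, "sets.gmt"))
  writeCohortTable(sampleInfo(sim$cohort), file.path(dir, "cohort.tsv"))
  wt <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wt(sim$truth$genes, "truth_genes.tsv")
  wt(sim$truth$variants, "truth_variants.tsv")
  wt(sim$truth$genotype_noise, "truth_genotype_noise.tsv")
  invisible(dir)
}
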