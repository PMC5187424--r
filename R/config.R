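## Run configuration: QC thresholds, permutation counts and the power
## grid, with defaults matching the published study design. A YAML file
## with the same field names can override any subset.

#' QC thresholds for the genotype- and site-filter cascade
#'
#' Defaults are the study thresholds: genotype quality >= 30,
#' heterozygous alternate depth >= 3, heterozygous allele-balance
#' chi-square < 10.83, alignability exactly 1, no simple-repeat
#' overlap, Hardy-Weinberg exact P > 1e-8 and call rate >= 75% in
#' cases and controls separately, and a 1% maximal minor allele
#' frequency for qualifying variants.
#'
#' @param gq_min Minimum genotype quality retained.
#' @param het_alt_depth_min Minimum alternate-allele depth for a het call.
#' @param het_chi2_max Exclusive upper bound on the 1-df allele-balance
#'   chi-square of a het call.
#' @param alignability_required Required alignability value (sites with
#'   any other value are dropped).
#' @param hwe_p_min Exclusive lower bound on the Hardy-Weinberg exact P,
#'   applied separately in cases and controls.
#' @param call_rate_min Minimum post-mask call rate in cases and in
#'   controls.
#' @param maf_max Exclusive upper bound on minor allele frequency for a
#'   qualifying variant (cohort and annotation MAF must both pass).
#' @return A list of class `QCThresholds`.
#' @export
qcThresholds <- function(gq_min = 30, het_alt_depth_min = 3,
                         het_chi2_max = 10.83, alignability_required = 1,
                         hwe_p_min = 1e-8, call_rate_min = 0.75,
                         maf_max = 0.01) {
  th <- list(
    gq_min = gq_min, het_alt_depth_min = het_alt_depth_min,
    het_chi2_max = het_chi2_max,
    alignability_required = alignability_required,
    hwe_p_min = hwe_p_min, call_rate_min = call_rate_min, maf_max = maf_max
  )
  if (!all(vapply(th, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                  logical(1))))
    stop("all QC thresholds must be single finite numbers")
  if (maf_max <= 0 || maf_max > 0.5)
    stop("maf_max must be in (0, 0.5]")
  structure(th, class = "QCThresholds")
}

#' Full run configuration
#'
#' Bundles the QC thresholds with the permutation counts of the burden
#' and gene-set-enrichment stages, the power grid, and the random seed.
#'
#' @param thresholds A [qcThresholds()] list.
#' @param n_perm_burden Permutations for the burden test (default 1e5).
#' @param n_perm_gsea Permutations per gene set (default 1000).
#' @param power A [powerConfig()] list.
#' @param seed Integer seed driving proband assignment and permutations.
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(thresholds = qcThresholds(), n_perm_burden = 100000L,
                      n_perm_gsea = 1000L, power = powerConfig(), seed = 1L) {
  stopifnot(n_perm_burden >= 1, n_perm_gsea >= 1)
  structure(list(thresholds = thresholds, n_perm_burden = as.integer(n_perm_burden),
                 n_perm_gsea = as.integer(n_perm_gsea), power = power,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Power-simulation configuration
#'
#' Defaults follow the study design: baseline carrier frequencies
#' spanning 1e-5 to 0.01, relative risks spanning 1.75 to 10, 10,000
#' replicates per grid cell, and an exome-wide significance threshold
#' of 8e-7.
#'
#' @param freq_grid Baseline carrier frequencies.
#' @param rr_grid Relative risks.
#' @param n_cases,n_controls Group sizes.
#' @param n_reps Monte-Carlo replicates per cell.
#' @param alpha Significance threshold for the per-replicate Fisher test.
#' @param enrichment_weights Optional weights (summing to 1) mixing the
#'   case frequency over several relative risks; see [caseFrequency()].
#' @param seed Optional integer seed.
#' @return A list of class `PowerConfig`.
#' @export
powerConfig <- function(freq_grid = c(1e-5, 1e-4, 1e-3, 1e-2),
                        rr_grid = c(1.75, 2.5, 5, 7.5, 10),
                        n_cases = 150L, n_controls = 1609L,
                        n_reps = 10000L, alpha = 8e-7,
                        enrichment_weights = NULL, seed = NULL) {
  stopifnot(all(freq_grid > 0 & freq_grid < 1), all(rr_grid >= 1),
            alpha > 0 && alpha < 1, n_reps >= 1, n_cases >= 1, n_controls >= 1)
  if (!is.null(enrichment_weights) &&
      abs(sum(enrichment_weights) - 1) > 1e-8)
    stop("enrichment_weights must sum to 1")
  structure(list(freq_grid = freq_grid, rr_grid = rr_grid,
                 n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 n_reps = as.integer(n_reps), alpha = alpha,
                 enrichment_weights = enrichment_weights, seed = seed),
            class = "PowerConfig")
}

#' Read a run configuration from YAML
#'
#' Any subset of the fields of [qcThresholds()], [runConfig()] and
#' [powerConfig()] may be given; the remainder keep their defaults.
#' Thresholds are read from a top-level `thresholds:` mapping and the
#' power grid from a `power:` mapping.
#'
#' @param path Path to a YAML file.
#' @return A `RunConfig` list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  th <- do.call(qcThresholds, if (is.null(y$thresholds)) list() else y$thresholds)
  pw <- do.call(powerConfig, if (is.null(y$power)) list() else y$power)
  args <- y[setdiff(names(y), c("thresholds", "power"))]
  do.call(runConfig, c(list(thresholds = th, power = pw), args))
}

## evaluate `expr` under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
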