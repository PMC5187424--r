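---
title: "Methods: familial rare-variant burden discovery with famburden"
author: "famburden authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: familial rare-variant burden discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famburden)
```

# The problem

Families with several affected members are a classical route to
discovering disease genes: a rare, high-impact variant shared by
affected relatives and enriched in cases over controls is strong
evidence even when each individual gene harbours only a handful of
carriers. `famburden` implements this design end to end for
whole-exome-style data: variant and genotype quality control, selection
of rare disruptive variants, a pedigree-aware collapsing burden test
with permutation significance, a within-family segregation filter, a
pre-ranked gene-set enrichment stage, Fisher-exact replication against
external control carrier counts, and a Monte-Carlo power calculation.
A synthetic cohort generator produces data with the same statistical
structure, so the full pipeline is exercised and audited without access
to protected germline data.

The central container is `VariantCohort`, a `SummarizedExperiment`
whose assays are genotype dosage (`GT`: 0/1/2/`NA`), allele depths
(`AD_REF`, `AD_ALT`) and genotype quality (`GQ`), with variant
annotations as row data and sample roles (familial case, sporadic case,
control) as column data. Family structure lives in a `PedigreeSet`.

# QC model and thresholds

Quality control is a fixed cascade: genotype-level masking first, then
site-level filtering computed on the post-mask data, then selection of
qualifying variants. The order matters — call rates and
Hardy–Weinberg statistics are meaningful only after unreliable
individual calls have been removed — and the cascade is idempotent by
construction.

Genotype-level rules (defaults in `qcThresholds()`):

* genotype quality: calls with `GQ < 30` are set missing;
* heterozygous alternate depth: het calls with fewer than 3 alternate
  reads are set missing;
* heterozygous allele balance: het calls with
  $(d_\mathrm{ref} - d_\mathrm{alt})^2 / (d_\mathrm{ref} + d_\mathrm{alt}) \ge 10.83$
  are set missing. This is the 1-df goodness-of-fit statistic of the
  observed read split against the expected 50:50; 10.83 is taken as the
  authoritative numeric cutoff (it is the 1-df critical value at
  $P = 0.001$).

Site-level rules, applied per variant:

* an upstream variant-recalibration tranche flag must be set (consumed
  as a boolean; tranches are not recomputed);
* alignability must equal 1 and the site must not overlap a simple
  repeat;
* call rate must be at least 75% in cases and in controls separately;
* the Hardy–Weinberg *exact* conditional test must give $P > 10^{-8}$
  in cases and in controls separately. The exact test (summing the
  probabilities of heterozygote counts no more likely than the observed
  one, conditional on the allele counts) is used instead of the
  asymptotic chi-square because qualifying variants are rare and the
  asymptotic test is unstable there.

A *qualifying* variant is then a nonsense, splice acceptor/donor or
frameshift change — missense variants are deliberately excluded, since
in-silico damage predictions are unreliable — whose minor allele
frequency is below 1%. Both the observed cohort MAF (computed over
non-missing calls across the full cohort) and, when present, an
annotation (reference-panel) MAF must pass; taking the maximum of the
two is a package decision, as the provenance of the original frequency
filter is ambiguous. Finally, genes whose qualifying variants are all
indels are removed, as indel-only signals are enriched for alignment
artefacts.

Every masked call and dropped site carries a machine-readable reason,
and the simulator records every injected violation, so the audit
"drops by reason equal injections by type" is testable exactly.

# The T1 collapsing burden test

For each gene, a sample is a *carrier* if it has at least one
non-missing het or hom-alt genotype across the gene's qualifying
variants (multiple variants in one carrier count once — the T1
collapsing rule). To keep familial observations independent, exactly
one sequenced affected member per pedigree is chosen uniformly at
random as the *proband*; the case group is the probands, the
comparison group the controls, and sporadic cases are held out for
replication.

The test statistic is the number of case carriers $a$. Significance is
assessed by permuting case/control labels (preserving group sizes)
with the one-sided, add-one estimator

$$ p = \frac{1 + \#\{a^{(perm)} \ge a\}}{n_{perm} + 1}, $$

which is never zero and targets enrichment, the direction of interest
for risk variants. `burdenTest()` shares one set of label permutations
across genes, exactly as a phenotype permutation affects all genes at
once; `permutationBurdenP()` additionally offers exhaustive label
enumeration, under which the p-value equals the hypergeometric tail
identically (a property the test suite checks on every small design).

Effect size is reported as the frequency-ratio odds ratio
$(a/n_1)/(b/n_2)$ of proband versus control carrier frequencies; a
zero control count is flagged infinite, with a continuity-corrected
estimate alongside. Genes are ranked by permutation p, ties broken by
descending OR then symbol.

A gene *segregates* in a pedigree when the pedigree has at least two
sequenced affected members and all of them carry one of the gene's
qualifying variants; the discovery filter keeps genes segregating in
at least two pedigrees. Requiring *all* sequenced affected members
(not just two of many) is the stricter reading and matches the
pedigree evidence the design is built on.

## Calibration and discreteness

With carrier counts of order 2–10, the permutation p-value lives on a
coarse lattice: it is *superuniform* under the null, not uniform. The
attained size at $\alpha = 0.05$ — the hypergeometric tail of the
smallest achievable rejection region — is typically 0.01–0.03 for the
carrier frequencies this design targets, so naive "fraction of genes
with $p < 0.05$" summaries under-shoot the nominal level. This is a
property of any exact discrete test, not an artefact; the test suite
therefore checks calibration against the exact hypergeometric null
distribution on its discrete support rather than against a uniform.

# Pre-ranked gene-set enrichment

Genes are ranked by their burden permutation p-values with score
$-\log_{10} p$, ties broken by OR then symbol. For a set $S$ in a
ranked list of $N$ genes, the running sum increases at members and
decreases by $1/(N - |S|)$ at non-members; the enrichment score (ES)
is the signed maximum deviation, in $[-1, 1]$. With weight $w$, member
increments are $|s_i|^w$ normalized by their sum over $S$
(`enrichmentScore(weight = 1)` is the classical weighted statistic,
`weight = 0` the unweighted Kolmogorov–Smirnov form).

The null is gene-label permutation — random same-size sets drawn from
the ranked list, the standard choice when ranks are the only input —
with the sign-matched add-one estimator
$p = (1 + \#\{|ES_{null}| \ge |ES_{obs}|,\ \mathrm{sign\ match}\})/(n_{perm}+1)$.
Q values are Benjamini–Hochberg across testable sets (sets with no
gene in the ranked list are flagged untestable), and sets are ranked
by p then descending ES.

**Why the pipeline default is `weight = 0`.** Burden p-values are
heavily tied: every gene with no case carrier has $p = 1$ and hence
score exactly 0. On such lists the weighted statistic degenerates —
any random set containing a single nonzero-score gene attains the
maximal ES of 1, so true signal sets cannot be distinguished from
lucky draws, and sets composed entirely of zero-score genes acquire
spuriously extreme negative scores through the weighted/unweighted
asymmetry of the null. The unweighted statistic depends only on rank
positions, remains well calibrated under the gene-permutation null,
and recovers planted signal reliably; `runGsea()` therefore defaults
to `weight = 0` while the `enrichmentScore()` operation keeps the
classical default of 1. Note that published enrichment scores from the
GSEA desktop tool are normalized (NES, magnitudes above 1); the ES
here is the raw running-sum deviation in $[-1, 1]$ and the two are not
numerically comparable.

# Replication and power

`replicationCountsTest()` compares case carrier counts (for example
sporadic cases) against per-gene carrier counts from a large external
control cohort with a two-sided Fisher exact test plus the
frequency-ratio OR. The power module treats "allele frequency" as a
carrier frequency sampled binomially per individual — at MAF below 1%
the distinction from diploid allele sampling is negligible and the
model is exactly enumerable. Each grid cell draws case carriers from
$\mathrm{Bin}(n_1, f \cdot RR)$ and control carriers from
$\mathrm{Bin}(n_2, f)$, tests each replicate with the two-sided Fisher
exact test, and reports the significant fraction with its Monte-Carlo
standard error. Defaults follow the study design: frequencies spanning
$10^{-5}$–$10^{-2}$, relative risks 1.75–10, 10,000 replicates per
cell, exome-wide $\alpha = 8\times10^{-7}$, 150 cases and 1,609
controls. The weighted-enrichment option of `caseFrequency()` mixes
several relative risks (for example the enrichment seen with one, two
or three affected first-degree relatives); since no canonical weights
exist, the default collapses to baseline × RR and weights are
exposed in the configuration.

# The synthetic cohort generator

`simulateCohort()` emulates the cohort shape the analysis assumes:
150 pedigrees with 2–3 sequenced affected members, 600 sporadic cases,
1,600 controls, 2,000 genes, per-gene carrier frequencies drawn from
0.0005–0.005 and split over a gene's variants, and a consequence-class
mix in which roughly 40% of variants are disruptive.

Rare variants are modelled at the carrier level: unrelated individuals
are heterozygous carriers with probability equal to the carrier
frequency, while in families founders carry and transmit with
Mendelian probability 0.5 — so siblings share variants at the rate the
segregation scan relies on, and clean sites stay in Hardy–Weinberg
proportions. Designated risk families are *conditioned*: all affected
members carry the family's planted nonsense variant (the generator
plants the variant in a founder and forces transmission), which makes
within-family sharing explicit and controllable. Risk genes — by
default five, with relative risk 10 and two fully segregating families
each, placed inside one 8-gene set among 50 — keep their baseline
frequency at the low end (0.0005–0.001) so that case enrichment cannot
push a qualifying variant past the 1% MAF cap. Variant positions and
alleles are synthetic toy loci; biological realism of coordinates is
irrelevant to the statistics under test.

QC noise is injected on *disjoint* sets of sites and calls, never
touching risk-gene variants, and every injection is recorded in the
truth tables: low-GQ calls, het calls with too few alternate reads
(AD 5,2), imbalanced het calls (AD 30,6), missing calls, low
alignability, simple-repeat overlap, tranche failures, a homozygote
excess planted in controls (guaranteed past the $10^{-8}$ exact-test
threshold for control arms of 100+), sites with >25% of control calls
missing, common disruptive variants (carrier frequency 4–8%) and
rare variants with a 2% annotation MAF. Disjointness is what makes the
bookkeeping audit exact — each injected violation is caught by exactly
one filter reason.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure, population stratification, sequencing-depth
correlation between samples, relatedness beyond nuclear families, and
genes with recurrent (shared across families) risk variants. Passing
tests on synthetic cohorts therefore demonstrate the correctness and
calibration of the statistical machinery, not robustness to the
confounders of real cohorts.

# Problem sizes used in the checks

The test suite runs the pipeline at reduced but structurally faithful
sizes, chosen so the whole suite completes in a few minutes while
preserving the cohort proportions: null-calibration at 500 genes with
150 probands and 1,600 controls and 2,000 permutations;
parameter recovery over 20 seeds at 300 genes, 150 pedigrees, 100
sporadic cases, 1,600 controls, 50 gene sets, 1,000 burden and 500
set permutations; exhaustive permutation checks on every design of up
to 12 samples; gene-set oracle checks on every set of size up to 3
over lists of length up to 8; power-oracle checks on a 20-vs-20 design
where the full Binomial × Binomial outcome grid is enumerable.

# Numerical choices and degenerate inputs

* Exact HWE probabilities are computed in log space with a
  stabilizing maximum subtraction; observed-probability comparisons
  use a $1 + 10^{-12}$ relative tolerance to absorb rounding.
* Zero-depth heterozygous calls have an undefined balance statistic
  and are set missing (they also always fail the depth rule).
* `frequencyRatioOR` returns 0 for zero case carriers, `Inf` (with a
  flag and a continuity-corrected alternative) for zero control
  carriers, and errors on empty groups.
* Fisher tests on zero-margin tables return 1.
* In the running sum, a set whose members all have score zero falls
  back to equal hit increments (the weighted normalizer would be 0/0).
* Monomorphic sites have HWE $P = 1$; groups with no samples pass
  their call-rate and HWE rules trivially.
* All randomized operations (proband draw, permutations, simulation)
  take explicit seeds and restore the caller's RNG state.

# Known limitations

* The permutation test's discreteness at very rare carrier counts
  (see above) makes p-values conservative; power at exome-wide
  thresholds is correspondingly modest for singleton-carrier genes.
* The segregation rule requires complete sharing among sequenced
  affected members; a single missing genotype in an affected carrier
  breaks segregation rather than being imputed.
* The GSEA stage inherits the tie structure of the burden p-values;
  with very shallow permutation depth the ranked list collapses into
  few score levels and set p-values become coarse.
* Replication uses external *carrier counts* as given; no attempt is
  made to harmonize variant calling or coverage between cohorts.
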