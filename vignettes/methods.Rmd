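---
title: "Methods: coverage-weighted EWAS of lipid traits in regulatory elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-weighted EWAS of lipid traits in regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lipidews` implements a sequencing-based epigenome-wide association
analysis of plasma lipid traits in regulatory-element methylomes, plus a
synthetic study generator that makes the whole stack testable against a
planted truth. This vignette is the package's account of the statistical
choices: the models, their assumptions, the tunable parameters, and the
places where the design was genuinely open.

## Data model and quality control

The primary observable is a per-CpG, per-sample, per-strand pair of read
counts (methylated, total). Strand merging produces the methylation value
as the pooled-count ratio — `(meth_fwd + meth_rev) / (total_fwd +
total_rev)` — never the mean of per-strand ratios, which would weight a
thinly covered strand equally with a deep one. Three entry/site filters
follow:

* **Strand concordance** (`max_strand_diff = 0.20`, a proportion): when
  both strands are covered and their methylation ratios disagree by more
  than 0.20, the entry is set missing. The test is skipped when either
  strand is silent. The filter is applied per (CpG, sample) entry; applying
  it to cohort-aggregated counts instead was considered and rejected
  because a single discordant sample should not erase a site.
* **Depth floor** (`min_reads = 5`, reads, inclusive): entries with fewer
  than 5 total reads are missing.
* **Site filters**: a CpG is kept when covered in at least
  `min_individuals` samples (default 100, the discovery-cohort scale; 50
  is the intended value for cohorts of ~140) *and* strictly more than
  `min_variable_frac = 0.10` of its covered samples show an intermediate
  proportion (0 < m < 1). Both inequalities are deliberate: the
  variability criterion is "more than 10%", so a tie fails.

These filters are idempotent, and the entry-level rules commute, so filter
order does not change the kept set.

## The association model

Each kept CpG is tested against each trait with a binomial GLM on the
logit scale, the proportion weighted by its read coverage — i.e. the
likelihood a binomial with `T_ij` trials would give. Fitting is by
iteratively reweighted least squares (deviance tolerance `1e-8`, at most
50 sweeps); the reported statistic is the Wald z of the trait coefficient.
A Wald test (rather than a per-CpG LRT) matches standard GLM output and
costs one fit per CpG instead of two.

Traits are prepared once: log transform where the distribution is
right-skewed (TG in adipose; TG/HDL or TG/HDL/LDL in the blood-cohort
configurations), a single mean ± 3 SD trim computed on the full
transformed vector (not re-applied to the trimmed set — iterated trimming
has no fixed sample space and keeps eating the tails), then
standardization to SD 1 so effect sizes are per SD of trait. Covariates
are age, sex, BMI, batch and optionally cell proportions with one simplex
column dropped; constant covariate columns are dropped automatically.

Degenerate inputs (constant methylation, constant trait in the covered
subset, too few samples, separation — detected as `|beta| > 15` logits or
`|beta|/se > 1000` — or non-convergence) yield flagged records with
missing statistics, never errors, and flagged records are excluded from
the multiplicity denominator.

The model's key mis-specification is deliberate: real bisulfite counts are
over-dispersed relative to the binomial, and the package does **not** fit
a beta-binomial or quasi-likelihood dispersion per CpG. Calibration is
restored globally, post hoc, by the empirical-null step — the same
division of labor used in large sequencing EWAS.

## Empirical-null recalibration

The z-scores of one trait are modeled as a three-component Gaussian
mixture: a dominant central null `N(mu0, sigma0²)` and two flanking signal
components. `mu0` is the bias, `sigma0` the inflation; corrected
statistics are `z' = (z − mu0)/sigma0` with two-sided normal p-values.
The fit is a constrained EM rather than a Gibbs sampler: deterministic,
fast, and testable. Numerical choices that matter:

* Initialization is deterministic — null at the median with MAD scale and
  weight 0.9, flanks at median ± 3 MAD.
* The flank means are bounded outside median ± 3 MAD and flank SDs floored
  at half the MAD, with the bounds **fixed in advance** (not tracking the
  current `sigma0`). An unconstrained three-component mixture on
  effectively pure-null data is not identifiable: a flank drifts onto the
  null and the likelihood develops a flat ridge along which EM crawls
  indefinitely. Fixing the constraint set restores ordinary EM
  convergence (typically 40–110 sweeps) at the cost of absorbing weak
  signal (< 3 robust SD) into the null — the usual, and intended,
  conservatism of empirical-null methods.
* Convergence is declared at `1e-8` change in mean log-likelihood or
  `1e-7` in the parameter vector; after 500 sweeps the estimator falls
  back to the median/MAD of the input with a warning flag.

The inflation factor λ = median(z²)/qchisq(0.5, 1) is reported before and
after correction; on the default synthetic design the raw λ is ≈ 1.7–1.8
and the corrected λ is within 0.05 of 1.

## Multiplicity

Per trait (traits are corrected individually, not jointly): Storey
q-values with π₀ estimated on the λ-grid 0.05–0.95 and a cubic smoothing
spline evaluated at 0.95, falling back to π₀ = 1 below 100 p-values (then
q-values equal Benjamini–Hochberg exactly — a frozen test case). For
cross-tissue dissection the package uses per-trait Bonferroni cutoffs
`alpha / n_tests`; the denominator is, by default, all replication tests
for that trait across candidate regions, with a per-region variant behind
a flag (the region-level contract does not pin this down, so both are
implemented and the global default documented here).

## Regions, positions, enrichment

CpG-to-element assignment uses 0-based half-open intervals (`start <= pos
< end`) throughout. The positional statistic is the signed percent
distance from the element midpoint, `(pos − (start+end)/2)/length × 100`,
with the midpoint kept real-valued so antisymmetry is exact, and the sign
flipped on minus-strand promoters so that positive always points into the
gene body. UMR profiles are restricted to promoters whose annotated TSS
lies inside the element and within ±1.5 kb of the element midpoint and
that are not flagged bivalent. The ±1.5 kb anchor is an interpretation —
window-from-midpoint rather than from the element boundary or an external
TSS list — chosen because it is the only variant computable from the
element table alone; it is configurable (`umr_tss_window`).

Enrichment contrasts use a two-sided Fisher exact test computed by full
hypergeometric enumeration (sum of all table probabilities not exceeding
the observed one, with a `1e-7` relative tie tolerance, the same
convention `fisher.test` uses). Fold changes are `(a/b)/(c/d)` rounded
**half-up** to one decimal — the printed precision of such tables; R's
default half-even rounding would print 2.25 as 2.2. Backgrounds include
the foreground (count pairs like 362/567 against 22101/50759 are
overlapping sets); this is how the published contrasts are constructed
and is kept configurable by simply passing disjoint counts.

## Replication and fine-mapping

A region–trait pair replicates when at least one replication CpG inside
the region clears the per-trait Bonferroni cutoff; the direction class
compares the replication CpG's sign with the discovery region's top CpG
(smallest p, ties to the leftmost coordinate; a majority-vote direction is
available behind a flag). Regions with no testable replication CpG are
`untestable`, so the three decided classes partition the testable set, and
tightening alpha can only move regions out of the replicated classes.

Fine-mapping contrasts ask, for regions with ≥ 2 discovery CpGs one of
which coincides with the replication platform's top CpG, whether some
non-overlapping sequencing CpG beats it; positional bands (LMR midpoint
band |pct| ≤ 20, UMR bimodal band 20 ≤ |pct| ≤ 45) classify where the
refined signal sits.

## Genetic and expression integration

All integration fits are fixed-effects linear models: the synthetic cohort
is unrelated individuals, so the twin-structure random effects of the
original array analyses would be meaningless here. Methylation enters on
the proportion scale (slopes are methylation per allele / per expression
unit). cis windows are ±250 kb (metQTL) and ±1 Mb (expression), boundary
inclusive, with gene distances measured to the nearest edge of the
transcribed region. Expression effects are tested by a likelihood-ratio
statistic `n log(RSS0/RSS1)` on 1 df — identical to twice the ML
log-likelihood difference, and checked against an explicit two-fit oracle.
metQTL FDR is computed scan-wide per cohort (the per-CpG alternative is a
flag), and an element is "under genetic regulation" when any resident CpG
has a q < 0.10 metQTL.

## The synthetic cohort

The generator emulates the study structure end to end, with defaults
chosen once as the study conditions:

* 200 donors; 60% female; BMI in the severely obese range; two capture
  batches (55/45); Dirichlet(5,3,2,1,1) cell proportions.
* One 10-Mb toy chromosome; 600 LMRs (~1 kb, ~7 CpGs each) and 400 UMRs
  (~2.7 kb, ~37 CpGs each — promoters longer and denser), ~5% background
  CpGs: ~20k CpGs total. 40% of elements are tissue-specific.
* Coverage negative-binomial with mean 33 reads; beta-binomial
  overdispersion ρ = 0.02. ρ is a free parameter (no published value for
  MCC-Seq counts exists to calibrate against); 0.02 was fixed a priori as
  "mild but consequential" — it inflates λ to ~1.8, giving the
  empirical-null step real work. ρ = 0 recovers exact binomial counts for
  calibration tests.
* Four correlated traits (TG log-normal; LDL–TC correlation 0.9, TG–HDL
  −0.4); 1% of element CpGs carry a lipid effect of 0.3 logits per SD
  (moderate for a top EWAS hit); 5% carry a cis-SNP effect of 0.5 logits
  per allele; 30% of elements drive a gene, 40% of those at long range
  (200–900 kb), echoing the observation that the most-correlated gene is
  often not the nearest. An array-like mask captures 6% of LMR and 19% of
  UMR CpGs.
* In the two-tissue design, effects at shared elements are planted in both
  tissues, effects at tissue-specific elements only in the discovery
  tissue.

What the generator does **not** emulate: read-level artefacts (mapping,
conversion error), linkage disequilibrium between SNPs, per-CpG dispersion
heterogeneity beyond the SNP-driven kind, relatedness, and population
structure. Passing tests therefore demonstrate the correctness and
calibration of the estimator stack under the stated generative model, not
robustness to everything real data can do.

One consequence of the correlated traits deserves emphasis: a CpG planted
for TC is genuinely associated with LDL (r = 0.9), so recovery and
false-discovery metrics are defined at the **CpG level** (a discovery is
true when the CpG carries a planted effect for any trait). Pair-level
accounting would misclassify correlated-trait detections — which are real
associations under the generative model — as errors.

## Test and acceptance problem sizes

The test suite exercises: unit fixtures of a few CpGs; ~1.3k–2k-CpG
cohorts for calibration (2,000 null CpGs at n = 200 for the p-value
calibration band); 10,000-statistic vectors for empirical-null recovery;
all 2×2 tables with N ≤ 60 (≈ 600k tables) for Fisher enumeration against
a log-binomial-coefficient oracle; and ten full-design cohorts (~20k CpGs,
n = 200, 1% planted) for end-to-end recovery, where pooled precision at
q < 0.10 must exceed ten times the planted base rate and the realized
false-discovery proportion must stay ≤ 0.15. `scripts/acceptance.R`
re-measures the headline quantities on three full-design cohorts plus the
calibration cohorts, seeded from the command line.

## Known limitations

* The empirical null is global per trait; CpG-specific dispersion (e.g. at
  strong metQTLs) is not absorbed and contributes most of the residual
  false discoveries in the recovery experiments.
* π₀ smoothing uses a fixed λ-grid; very small scans fall back to BH.
* The region replication logic assumes each CpG maps to at most one
  element per class (guaranteed for the synthetic element sets; enforced
  with an explicit error otherwise).
* Bivalency of promoters is an input flag, not computed from gene models.
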