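---
title: "Auditing ancestry-related bias in variant prioritization"
author: "AncestryBias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing ancestry-related bias in variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AncestryBias)
```

## The problem

Clinical variant prioritization filters a patient's genome down to a short
list of candidate disease-causing variants using three kinds of evidence:
pathogenic assertions in clinical databases (OMIM-, HGMD- and ClinVar-style
resources), population allele frequencies, and in-silico deleteriousness
predictors. All three carry an ancestry footprint: the databases are
dominated by European-ancestry submissions, reference frequency panels
under-sample African variation, and several predictors are trained on the
databases themselves. For patients of predominantly African ancestry this
inflates the number of variants that survive prioritization — a larger
haystack around the causal needle — with direct consequences for diagnostic
turnaround and confirmation cost.

`AncestryBias` implements the full audit of this phenomenon as a tested,
seeded pipeline: classification of variants into clinical-priority classes,
population-structure-aware correlation of per-individual class counts with
African-ancestry proportion, tracking of that correlation across versioned
database releases (with attribution of correlation flips to driver
variants), and translation of class counts into per-patient confirmation
costs. Because the motivating cohort data are access-restricted, the package
ships a synthetic-data generator that reproduces the statistical structure
of the problem; every claim the package makes is demonstrated on that
generator by the test suite and `scripts/acceptance.R`.

## Variant classes

Each biallelic SNV is assigned exactly one label:

* **PAV** (pathogenic-annotated variant): asserted pathogenic, for this exact
  variant, in at least one configured clinical database, and located in a
  protein-coding gene.
* **NAV** (non-annotated variant): everything else that is protein-altering
  (missense, nonsense or splice in the synthetic schema).
* Each branch is split into **deleterious** / **non-deleterious** by the
  predictor consensus: at least 2 of 11 in-silico predictors vote
  deleterious, with nonsense and splice variants deleterious irrespective of
  predictors (a configurable exception).
* A MAF gate removes common variants: a PAV is dropped when its minor-allele
  frequency exceeds 5% in *any* population panel, a NAV when it exceeds 2%.
  Pathogenic-annotated variants failing the gate are treated as misidentified
  common database entries and excluded outright rather than demoted to NAVs.
* Everything else lands in `EXCLUDED` with a reason
  (`common_maf`, `non_coding`, `non_protein_altering`).

Two reading choices deserve flagging. First, gene-centric assertions are
treated variant-level for all three databases; real OMIM is gene-centric and
an adapter may wish to coarsen the match. Second, a missing predictor score
counts as a non-deleterious vote, the conservative reading of a
count-of-positive-calls threshold; the per-predictor score cutoffs
themselves are upstream of this package (predictor calls arrive
pre-thresholded in the annotation table).

Per-individual counting defaults to *carrier* mode (a variant counts once
when carried on at least one allele), with allele-dosage counting available;
the audited quantity is "variants per individual", not allele burden.

## The pooled correlation

Cohorts of African-descent populations are sampled as population blocks, so
a plain Pearson correlation across individuals would conflate
between-population differences with the within-population association. The
package therefore estimates the Pearson correlation `r_p` between
African-ancestry proportion and a per-individual count *within* each
population, transforms to Fisher z, and combines the strata as a
fixed-effect meta-analysis with the standard inverse-variance weights
`n_p - 3`:

    z_pool = sum((n_p - 3) * atanh(r_p)) / sum(n_p - 3)
    r_pool = tanh(z_pool),  two-sided p from z_pool * sqrt(sum(n_p - 3))

Design decisions:

* The weighting and the normal reference are the textbook fixed-effect
  combination; a t reference and random-effects pooling were considered and
  rejected as out of scope for a fixed, known set of sampling strata.
* Populations with `n < 4` (Fisher-z variance undefined at `n <= 3`) or zero
  variance in either variable are excluded from pooling and reported in the
  result object rather than silently dropped.
* One usable stratum is allowed (the estimate then collapses to that
  stratum's plain Pearson r); zero usable strata is an error, never a
  fabricated value.

Multiple testing across genes uses Benjamini–Hochberg adjustment (`bhFDR`,
delegating to `stats::p.adjust`); the gene scan's testing universe is the
set of genes actually tested (those with at least one cohort-polymorphic
PAV), with untested genes listed separately rather than assigned `q = 1`.

The African-ancestry proportion itself comes from an ADMIXTURE-style
Q-matrix: the African cluster is the unique cluster in which reference-panel
African individuals average more than 99% membership, and that column is
extracted per individual (`readQMatrix`).

## Database-version drift and driver attribution

`correlationTrajectory` re-runs the audit against every release of a
versioned assertion database: each release's assertions override the ClinVar
slot, per-individual pathogenic counts are recomputed, and the pooled
correlation is evaluated. Two counting modes mirror the two trend lines of
the drift analysis: *unfiltered* counts any carried variant the release
asserts pathogenic (no MAF, consequence or deleteriousness gates);
*filtered* re-runs the full classification and counts surviving deleterious
PAVs. `detectFlips` flags consecutive releases whose correlations are both
significant and opposite in sign.

`attributeDrivers` explains a flip: candidates are the variants whose
assertion state differs between the two releases; each candidate's marginal
effect is the correlation change when that single difference is reverted on
the later-release side; candidates are ranked by absolute marginal effect
and selected greedily until reverting the selected set moves the correlation
at least a configurable fraction (default 0.9) of the way back. Marginal
effects are computed exactly — a reverted variant shifts the count vector by
its carrier indicator — so reverting *all* differences reproduces the earlier
correlation to machine precision. Leave-one-out-plus-greedy is this
package's own attribution rule; the selection is reported with per-candidate
marginal effects so other rules can be layered on top.

## The synthetic study conditions

The generator (`SimConfig`, `simulateCohort`, `simulateAnnotations`,
`simulateReleaseSeries`, `simulateBundle`) defines the conditions under
which the audit is demonstrated. Defaults, and why:

* **Cohort**: 16 populations of 40 individuals (640 total), per-population
  African-ancestry proportions Beta-distributed with means spanning
  0.15–0.90 and concentration 8 — a diverse admixed African-descent cohort
  with substantial within-population ancestry spread.
* **Genome**: 20,000 biallelic SNVs over 300 genes; consequence mix 50%
  missense, 22% synonymous, 5% nonsense, 5% splice, 18% non-coding.
* **Frequencies**: truly deleterious variants (consequence-dependent truth
  probabilities) are rare with ancestry-independent frequencies
  (Beta(0.5, 150)), reflecting that deleterious allele counts per individual
  are not elevated by African ancestry. Rare neutral variants follow a
  sharing-pattern mixture — 55% African-private, 30% shared, 15%
  private to the non-African background, frequencies Beta(0.6, 60) — because
  a site list ascertained in an African-descent cohort is dominated by
  African-enriched rare variation; this, not per-variant frequency shifts,
  is what survives the MAF gates and carries the ancestry signal. A 15%
  common component (AFR Beta(2, 10) vs other Beta(2, 25)) supplies the
  misidentified common database entries that the MAF filter removes.
* **Database bias**: neutral variants that are more common outside Africa
  are asserted pathogenic 1.5x more often (the Euro-centric skew);
  truly deleterious variants are asserted at realistic per-database rates
  (HGMD highest). About 1% of unasserted neutrals carry a benign-style
  (non-pathogenic) ClinVar entry.
* **Predictors**: 11 predictors in two categories (5 database-trained, 6
  agnostic), sensitivity 0.5 on truly deleterious variants, false-positive
  rate 0.07 on neutral ones, a +0.06 call-probability boost for
  database-trained predictors on asserted variants, 5% missing scores.
* **Releases**: 30 snapshots at 34-day intervals from mid-2012; the asserted
  pool grows linearly from 45% to 100% in seeded random order. At release 20
  (which falls in March 2014 under the defaults) a bulk deposit enters: 50
  coding variants strongly skewed against the African background (non-African
  frequency 0.30–0.50) plus 500 ancestry-balanced entries that fail the
  coding filters — so the unfiltered trajectory flips sign while the
  filtered trajectory barely moves, and the deposit is recorded in a
  ground-truth sidecar for recovery tests.

With these conditions the audit reproduces the qualitative phenomenon it was
built to study: per-individual counts of non-deleterious PAVs and of both
NAV classes correlate positively and significantly with African ancestry,
while the deleterious-PAV correlation is attenuated toward zero (that class
is dominated by truly deleterious, ancestry-independent variants); the
unfiltered release trajectory shows exactly one significant sign flip, at
the deposit.

What the generator deliberately does **not** model: linkage disequilibrium
and local-ancestry tracts (genotypes are Binomial given the
individual-level admixed frequency; the analysis consumes only marginal
counts), sequencing error, indels and multi-allelic sites, transcript-level
consequence ambiguity, and real archival database content. Passing tests
therefore demonstrate the correctness and calibration of the statistical
machinery under a faithful sampling structure, not agreement with any
specific real cohort's numbers.

All randomness derives from one seed through fixed per-module stream
offsets, so the cohort, annotations and release series can be regenerated
independently yet reproducibly, and a full bundle is byte-identical across
runs with the same seed.

## Cost model

Prioritized variants (both PAV classes plus deleterious NAVs — the classes
flagged for follow-up review) are restricted to a candidate panel of about
200 genes (roughly 1% of a genome; a uniformly sampled panel under the run
seed when none is supplied). `strataCostComparison` turns mean per-patient
prioritized counts in two ancestry strata (default thresholds: African
ancestry >= 0.5 versus <= 0.1, configurable because the source strata are
not formally defined) into a fold increase and a cost difference at a unit
confirmation cost (default $500 per variant for Sanger confirmation). The
cost difference is linear in the unit cost and the fold is invariant to it.
Clinician review time is deliberately not modelled. Note that on the
synthetic bundle a 200-gene panel covers two-thirds of the 300-gene toy
genome, so synthetic panel counts (and cost differences) run higher than the
real-genome arithmetic; the headline 4.5 vs 2.8 comparison enters as stated
per-patient means.

## Numerical choices and problem sizes

* Correlations at `|r| = 1` are clamped before `atanh` only against values
  outside [-1, 1] from floating-point noise; genuinely perfect strata
  propagate an infinite z and are visible in the result rather than masked.
* The chi-square independence test (predictor category x variant class) uses
  no continuity correction; when any expected cell drops below 1 the
  implementation warns and reports Fisher's exact p-value with an
  `exact = TRUE` flag.
* Gene-set enrichment uses the two-sided Fisher exact test with the
  convention that an empty hit set returns odds ratio 0 and p = 1.
* The test suite exercises the full default bundle (20,000 variants, 640
  individuals) for the end-to-end pattern, flip detection and a 50-seed
  driver-recovery study, scaled-down bundles (400–4,000 variants) for I/O
  round-trips and unit behaviour, 200 replicates per planted correlation for
  parameter recovery and 1,000 replicates for type-I calibration; the whole
  suite runs in a few minutes on one CPU.
* `analyticWithinPopCorrelation` computes the generator's model-implied
  within-population correlation by 512-point quadrature over the ancestry
  distribution; the empirical generator matches it within Monte-Carlo error,
  which the suite asserts at |mean difference| < 0.07.

## Known limitations

* The attribution rule behind a real release flip's driver set is not
  uniquely defined; this package's leave-one-out ranking with greedy
  coverage is one defensible choice, validated against planted ground truth
  rather than against any published driver list.
* OMIM assertions are treated variant-level (see above).
* The pooled estimator assumes within-population bivariate normality only
  through the Fisher-z variance approximation; counts are discrete, and at
  n = 40 per stratum the calibration checks show the normal approximation is
  adequate (type-I error within [0.03, 0.07]).
* VCF support covers diploid GT fields and biallelic SNVs (multi-allelic
  records can be split or rejected); BCF, indels and phasing-aware analyses
  are out of scope.
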