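# AncestryBias

Quantify ancestry-related bias in clinical variant prioritization.

When a genome is filtered down to candidate disease-causing variants, three
standard evidence sources — pathogenic assertions in clinical databases
(OMIM/HGMD/ClinVar-style), population allele frequencies, and in-silico
deleteriousness predictors — all carry a European-ancestry footprint. For
patients of predominantly African ancestry this inflates the number of
variants that survive prioritization, and with it the cost and turnaround of
clinical follow-up. `AncestryBias` is an R package for auditing that
phenomenon end to end, aimed at statistical geneticists and clinical
bioinformaticians who want the bias machinery as tested, reusable functions
rather than one-off scripts.

## What it computes

**Classification.** Every biallelic SNV is assigned one class: deleterious or
non-deleterious **PAV** (pathogenic-annotated: exact assertion in a
configured database, protein-coding gene, minor-allele frequency ≤ 5% in all
population panels) or deleterious / non-deleterious **NAV** (non-annotated:
protein-altering, MAF ≤ 2%), with "deleterious" meaning ≥ 2 of 11 predictor
votes (nonsense/splice auto-qualify). Excluded variants keep their exclusion
reason.

**Pooled ancestry correlation.** Per-individual class counts are correlated
with African-ancestry proportion θ (extracted from an ADMIXTURE-style
Q-matrix via the >99% reference-membership rule) while respecting the
cohort's population blocks: Pearson r within each population, Fisher
z = atanh(r), fixed-effect pooling with weights (n<sub>p</sub> − 3),

&nbsp;&nbsp;&nbsp;&nbsp;r<sub>pool</sub> = tanh( Σ (n<sub>p</sub> − 3) z<sub>p</sub> / Σ (n<sub>p</sub> − 3) ),

with a two-sided p-value from z<sub>pool</sub>·√Σ(n<sub>p</sub> − 3). On top
of this sit a BH-adjusted gene-level scan, a χ² test of whether
database-trained and database-agnostic predictors behave differently on PAVs
versus NAVs, and Fisher-exact gene-set enrichment.

**Database drift.** `correlationTrajectory` recomputes the correlation under
every dated release of a pathogenicity database (filtered and unfiltered
counting), `detectFlips` finds significant sign flips between consecutive
releases, and `attributeDrivers` ranks the variants whose assertion changes
drive a flip (exact leave-one-out marginal effects + greedy selection to a
coverage target).

**Cost.** Prioritized variants (PAVs plus deleterious NAVs) restricted to a
~200-gene candidate panel are converted into per-patient confirmation costs
and compared between ancestry strata.

**Synthetic cohorts.** A seeded generator (`SimConfig`, `simulateBundle`)
produces a complete input bundle — VCF, annotation TSV, Q-matrix, population
labels, dated release tables, gene lists, ground-truth sidecars — with
planted ancestry biases and one bulk database deposit that flips the
correlation sign, so the whole audit is reproducible without restricted
data.

## Worked example

```r
library(AncestryBias)

cfg <- SimConfig(seed = 42)          # 16 populations x 40, 20,000 variants
sim <- simulateCohort(cfg)
ann <- simulateAnnotations(sim, cfg)

cl <- classifyVariants(ann, FilterConfig())
table(cl$class)
#>    DEL_NAV    DEL_PAV   EXCLUDED NONDEL_NAV NONDEL_PAV
#>       2561       1870      10166       4470        933

counts <- perIndividualCounts(sim$cohort, cl)
pooledAncestryCorrelation(sim$cohort, counts[, "DEL_NAV"])
#> BiasResult: pooled r = 0.1882 (p = 3.59e-06), 16 usable strata, n_eff = 592

rs   <- simulateReleaseSeries(sim, ann, cfg)
traj <- correlationTrajectory(rs$series, sim$cohort, ann)
detectFlips(traj)
#>       date_A     date_B       r_A        r_B
#> 1 2014-02-18 2014-03-24 0.3919847 -0.2661568

rel <- releases(rs$series)
attributeDrivers(rel[[19]], rel[[20]], sim$cohort, ann)
#> DriverReport 2014-02-18 -> 2014-03-24: r 0.392 -> -0.266
#>   550 candidates, selected set of 49 covers 90.4% of the change (target 90%)

cmp <- strataCostComparison(4.5, 2.8, CostConfig(costPerConfirmation = 500))
sprintf("fold = %.2f, cost difference = $%.0f", cmp$fold, cmp$costDifference)
#> [1] "fold = 1.61, cost difference = $850"
```

Reading the output: deleterious NAV burden rises significantly with African
ancestry (pooled r = 0.19 across the 16 population strata); the release
series flips from a significantly positive to a significantly negative
correlation exactly at the planted bulk deposit, and the driver report
isolates a 49-variant set explaining 90% of that change; at mean prioritized
counts of 4.5 vs 2.8 per patient and $500 per Sanger confirmation, the
higher-burden stratum costs 1.6× more to confirm — a difference of $850 per
patient.

A whole run (simulate → classify → correlate → timeseries → genescan →
cost) can also be driven from one YAML config with caching and a manifest:
`runPipeline("config.yaml", "out/")`.

## Package layout

- `R/` — S4 classes (`AdmixedCohort`, `VariantAnnotations`,
  `DatabaseRelease`/`ReleaseSeries`, `BiasResult`, `DriverReport`, configs)
  and the module functions (io, classify, stats, temporal, cost, simulate,
  pipeline).
- `tests/testthat/` — unit, property and acceptance suites (fixtures are
  generated in code; oracles are independently coded).
- `vignettes/ancestry-bias-audit.Rmd` — the methods vignette: model,
  assumptions, generator design, numerical choices, limitations.
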