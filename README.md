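# sigbench

Benchmarking directional gene signatures against random gene-set nulls.

## The problem

A fixed gene signature — say 150 genes, each expected to go up or down with
the condition of interest — gets reported with an ROC AUC on some expression
cohort. Is that number good? The only honest reference is empirical: how do
thousands of equally sized gene-sets *sampled at random* perform under the
same evaluation? And that comparison is itself easy to get wrong, in ways
that all flatter the random sets:

- **Within-cohort evaluation** (repeated train/test splits inside one
  cohort) is optimistic whenever processing batches correlate with class:
  both halves of every split share the cohort's batch structure, so even
  probes expressed *below detection* can "classify". Cross-cohort external
  validation — directions fitted on one cohort, AUC measured on fully
  independent cohorts — is the gold standard.
- **The sampling pool matters.** Random sets drawn from a whole array
  inherit published disease- and age-associated genes by chance; a pool
  filtered against known biology, or restricted to background probes, asks
  a different question.
- **Design choices matter.** Merging a heterogeneous clinical group (MCI)
  into the cases, or skipping age/sex matching, moves AUCs without touching
  biology.
- **Multiplicity matters.** One prespecified signature needs one p-value
  per cohort; ten thousand random sets need correction for ten thousand
  tests.

sigbench implements the whole benchmark, plus a synthetic multi-cohort
generator reproducing each confounding structure, so every mechanism above
is demonstrable and testable without any data download.

## The statistics

**Score.** For a signature with up-set *U* and down-set *D*, genes are
ranked ascending within each sample (average ranks for ties, all *G*
platform genes ranked) and

&nbsp;&nbsp;&nbsp;&nbsp;score(s) = ( mean<sub>g∈U</sub> r<sub>gs</sub> − mean<sub>g∈D</sub> r<sub>gs</sub> ) / G.

Being per-sample and rank-based, the score is invariant to monotone
per-sample transforms, hence portable across platforms without
normalisation.

**AUC.** Mann–Whitney form: P(random case scores above random control),
ties credited ½ — so AUC(s) + AUC(−s) = 1 exactly.

**Directions.** For plain gene-sets (the random ones, and candidates put on
an equal footing), each gene's direction is the sign of the case-minus-
control mean difference on training data only.

**Significance.** Empirical p against a null of n random sets uses the
add-one convention p = (1 + #{null ≥ candidate})/(1 + n); score-vs-label
significance is an exact Mann–Whitney permutation test (dynamic programming
over midrank sums, exact under ties) up to n₁·n₀ ≤ 400, normal
approximation with tie and continuity correction beyond;
Benjamini–Hochberg for families of candidates.

## Worked example

The numbered scripts under `analysis/` walk through the full argument on
synthetic cohorts. The batch-confounding experiment
(`analysis/03_batch_confounding.R`) concentrates 80% of cases in batch 1 of
the training cohort (batch sd = noise sd, batch shifts applied to all
probes), samples 500 gene-sets of 150 genes **only from below-detection
background probes**, and evaluates each set both ways:

```
background pool: 283 below-detection probes
        scheme  mean_auc       p95       max
 within_cohort 0.7374613 0.7818444 0.8102222
  cross_cohort 0.4477075 0.5155972 0.5686111
within-cohort optimism on background-only sets: +0.290 AUC
```

Gene-sets with no possible biology average AUC 0.74 within the confounded
cohort — and collapse to chance the moment they must travel to an
independent cohort. The design-choice experiment
(`analysis/05_design_choices.R`) shows the other two mechanisms:

```
planted signature, AD vs CTL:      AUC 1.000 (60 vs 60)
planted signature, AD+MCI vs CTL:  AUC 0.835 (120 vs 60)

age-only signature, unmatched: AUC 0.664 (cases 8.8 y older on average)
age-only signature, matched:   AUC 0.484 (41 pairs, mean |dAge| 2.0 y, 19 cases unmatched)
```

Merging the mixed MCI group into the cases dilutes a perfect signature to
0.835; a signature carrying *only* age biology looks useful (0.66) until
cases and controls are age/sex matched, at which point it is chance.

Orchestrated runs come from a single config (see
`analysis/06_benchmark_report.R` or `?run_benchmark`): candidate and null
evaluation per (scheme × case definition × matching arm × pool) cell,
empirical p and rank, BH across cells, per-test-cohort replication, and a
design-criteria checklist — all reproducible bit-for-bit from one master
seed.

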