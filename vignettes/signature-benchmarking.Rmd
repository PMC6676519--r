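---
title: "Benchmarking gene signatures against random gene-set nulls: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking gene signatures against random gene-set nulls: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigbench)
```

## What question the package answers

Given a directional gene signature (each gene tagged +1/up or −1/down) and
one or more expression cohorts, sigbench asks: *does this signature perform
better than equally sized gene-sets drawn at random from a stated pool,
under a stated validation scheme, with a defensible p-value?* The package's
design premise is that each clause of that sentence — the pool, the scheme,
the clinical group definition, the demographic matching, the multiplicity
handling — changes the answer, and therefore must be an explicit, recorded
parameter rather than an implementation accident.

## The scoring model

For cohort expression matrix $y$ (log2 intensities, $G$ genes × samples),
genes are ranked ascending *within each sample*, ties receiving average
ranks. For a signature with up-set $U$ and down-set $D$ present on the
platform:

$$\mathrm{score}(s) = \frac{1}{G}\left(\frac{1}{|U|}\sum_{g \in U} r_{gs}
  - \frac{1}{|D|}\sum_{g \in D} r_{gs}\right)$$

A one-sided signature is centred instead ($\bar r_{U,s}/G - 0.5$, and
symmetrically for a down-only set), so that the no-information score is 0
in all cases.

Two properties motivated this choice over fitted classifiers:

- Per-sample ranking makes the score invariant under any strictly
  increasing per-sample transform, so scores are comparable across
  platforms and cohorts with no cross-cohort normalisation — a requirement
  for external validation, where the test cohort must not inform the model
  in any way.
- Using the same score for candidate and random sets keeps the benchmark
  like-for-like; a candidate evaluated by one statistic and a null by
  another is not a comparison.

Ranks are computed over **all** platform genes by default, so the rest of
the transcriptome acts as the reference distribution; an alternative mode
ranks within the signature's own genes only (`rank_within_signature`),
provided because both conventions exist in practice, non-default because
the full-array reference is what lets below-detection probes matter only
through their own positions.

Signature genes absent from a platform are dropped with a warning (error
only at zero overlap): two array generations rarely share full gene
content, and a benchmark that refuses to score a signature across
platforms cannot perform external validation at all. The warning threshold
(default: warn below 50% overlap) is configurable.

**Direction fitting.** Plain gene-sets (all random ones, and candidates
re-fitted for parity) get per-gene directions from the sign of the
case-minus-control mean difference on *training data only*. An exact zero
difference maps to +1 — an arbitrary but deterministic tie-break, reported
via a message; with continuous intensities it essentially never fires
outside constructed tests.

## Validation schemes

**Within-cohort** (`within_cohort_cv`): repeated stratified splits,
training share `split_fraction` (0.5 and 0.75 are the two conventional
presets; any value in (0,1) is accepted), directions fitted on the training
share, scored and AUC'd on the held-out share, aggregated over `n_repeats`.
Splits preserve the class ratio; whether the original within-cohort
analyses this mode reproduces were stratified is not documented anywhere we
know of, so stratification is our stated choice and is recorded in the
scheme object. A split leaving either class empty on either side is
redrawn, at most 100 times, then errors.

**Cross-cohort** (`cross_cohort_validate`): directions fitted once on the
*entire* training cohort; each test cohort is ranked within itself and
scored with the travelling signature. Re-fitting per test cohort would
reintroduce exactly the information leakage external validation exists to
rule out, so it is not offered.

Within-cohort optimism is not a bug to be fixed here but a quantity to be
measured: the package deliberately performs no batch correction. Note that
even with batch assignment *independent* of class, a finite cohort has some
realised batch–class imbalance, so the within-cohort null mean conditional
on one cohort draw wobbles around 0.5 (we observe roughly ±0.05 at 120
samples with batch sd half the noise sd). Calibration statements in the
tests are therefore made under the stated seeds, and the mechanism
experiments always compare within against cross on the *same* sets rather
than against an absolute 0.5.

## Sampling pools and the null

`sample_gene_sets` draws sets of `set_size` distinct genes (default 150,
the size of the signature this benchmark design grew around) uniformly
from a pool; sets are mutually independent, so a gene may recur across
sets. Pools carry provenance:

- `all` — the platform universe (the cohort file's own gene ids; no
  probe/symbol mapping layer is provided, identifiers are opaque strings);
- `background` — probes below detection: intensity under the
  `floor_quantile` of the cohort's pooled intensity distribution in at
  least `sample_fraction` of samples (defaults 0.25 and 0.8). "Not
  expressed" has no universal numeric definition, so this quantile/fraction
  rule is this package's operationalisation — both knobs exposed, and the
  pool is monotone in each, which the tests verify;
- `filtered` — a universe minus an explicit exclusion list (e.g. published
  age/disease genes), exclusions recorded in the object;
- per-platform pools, with `intersect_pools` for paired designs where one
  set must be scorable on two platforms with different gene content.

`evaluate_null` records per-set failures (`n_failed`) rather than silently
dropping them, and uses a vectorised path (ranks, splits and per-split
mean-difference vectors computed once per scheme) that the test suite
proves bit-identical to evaluating each set through the public per-set
functions.

## Significance

- Empirical: $p = (1 + \#\{\mathrm{null} \ge \mathrm{cand}\})/(1+n)$, rank
  $= 1 + \#\{\mathrm{null} > \mathrm{cand}\}$. The add-one convention never
  reports $p = 0$ from finite resampling; ties count against the candidate.
- Score-vs-label: two-sided Mann–Whitney. Exact mode (up to
  $n_1 n_0 \le 400$) computes the full permutation distribution of the
  rank-sum by dynamic programming over doubled midranks — identical to
  enumerating all $\binom{n}{n_1}$ labelings, exact in the presence of
  ties; larger samples use the normal approximation with tie and
  continuity correction. The two agree within 0.01 at the crossover
  (tested). The exact route exists because the benchmark's own argument
  includes small-sample cases where a "good-looking" AUC (>0.6) is
  nowhere near significant.
- Families of candidates get Benjamini–Hochberg (`bh_adjust`, a validating
  wrapper over the standard step-up); a *single prespecified* signature is
  judged by unadjusted per-cohort p-values, and "replication" means
  p < α in **every** independent cohort (`replication_verdict`,
  α default 0.05). This asymmetry — BH for the ten-thousand-set family,
  per-cohort replication for the one fixed signature — is the package's
  position on the fair comparison.

## The synthetic generator

`generate_cohorts` draws
$$y_{gs} = \mu_g + d\,\mathrm{dir}_g\,\mathrm{signal}_s\,\mathbb{1}[g \in S]
 + \beta_g \tfrac{\mathrm{age}_s - \overline{\mathrm{age}}}{10}
 + \gamma_g\,\mathbb{1}[s\ \mathrm{male}] + b_{k(s),g} + \varepsilon_{gs}$$

Gaussian on the log2 scale (bead-array-like intensities, not counts).
Defaults, chosen once as a plausible desk-scale rendition of two blood
cohorts and kept fixed: 2 cohorts × (60 cases, 60 controls), 2000 genes of
which 150 planted signal genes at $d = 0.8$ log2 units with random signs,
300 background probes at floor $\mu_{bg} = 4$ versus expressed means
$\mathcal{N}(8, 1)$, noise $\sigma = 1$, 2 batches with $\tau = 0.5$,
control ages uniform 55–85 with cases 4 years older, 50 age genes at 0.3
log2/decade, 20 sex genes at 0.5, MCI mixing $\pi = 0.3$, platform core
overlap 0.8 (non-core genes kept per platform with probability 0.5; all
structured genes live in the core so ground truth exists on every
platform). The background fraction (15%) sits safely below the default
background-pool quantile (25%), so the pooled-intensity threshold lands
*above* the background cluster and the pool recovers essentially all
planted background probes (≈99% purity at the defaults).

Three structural choices carry the argument:

- **batch effects hit every gene, background included** — otherwise
  below-detection probes could never "classify" under confounding;
- **confounding is parameterised as case concentration**: a fraction ρ of
  cases is forced into batch 1 (interpretable and directly testable,
  unlike an abstract correlation coefficient);
- **cases are drawn older than controls**, so skipping the matching stage
  measurably inflates an age-driven signature.

`signal_s` is 1 for cases, Bernoulli(π) per MCI sample, 0 for controls —
MCI is modelled as a mixture, which is precisely why merging it into the
case group dilutes a true signature and why π is a visible parameter.

What the generator does **not** emulate: probe-level bead summarisation,
normalisation artefacts, correlated gene modules (genes are conditionally
independent given batch), missing values, RNA-seq counts. Consequently,
passing tests show the *mechanisms* (optimism, pool contamination,
dilution, demographic leakage) are real and the pipeline detects them; they
do not certify effect sizes on any real cohort, where correlated biology
makes random sets stronger than independence suggests.

## Matching

`match_cases_controls` is greedy 1:1 within sex strata: cases in descending
age, each takes the nearest-age unused same-sex control, accepted within
`age_tolerance` (default 5 years); unmatched cases are dropped and counted.
Greedy rather than optimal matching: deterministic, $O(n \log n)$, and at
benchmark scale the realised mean age gap after matching (≈2 years in the
worked example) is already far below the induced 8-year confound. The seed
only shuffles control order to break exact-distance ties reproducibly.

## Orchestration and determinism

`run_benchmark` fans one master seed out to every randomised stage via
`derive_seed(master, stage_label)` (a two-step Lehmer map modulo
$2^{31}-1$), so a single integer reproduces simulation, splits, pool draws
and matching tie-breaks; report directories contain no timestamps and two
runs from the same config are byte-identical (tested). Cells are the cross
product (scheme × case definition × matching arm × pool); the checklist
booleans (external validation done, significant in all test cohorts,
matched design used, MCI excluded, multiple testing corrected) are pure
functions of the cells, which the tests re-derive independently.

## Numerical conventions and degenerate inputs

- Missing expression values are a hard error at load time — rank scores
  are undefined on missing data and imputation would silently change the
  question. Duplicate gene or sample ids, non-numeric cells: hard errors
  naming the offender.
- Expression TSVs are written with 17 significant digits so write/read
  round-trips are bit-exact.
- AUC ties get 0.5 credit via midranks, making
  $\mathrm{AUC}(s) + \mathrm{AUC}(-s) = 1$ an identity, which the tests
  exploit against a brute-force all-pairs oracle.
- All-identical scores: Mann–Whitney p = 1 with a warning.
- Empty pools (background thresholds too strict, exclusion covering the
  universe) error or warn with actionable messages rather than returning
  silently unusable objects.

## Problem sizes

The shipped experiments use 2 cohorts × 120–180 samples, 2000-gene
platforms, nulls of 500–1,000 sets of 150 genes with 10-repeat
within-cohort schemes, and 200-draw calibration checks — sizes at which
every mechanism is unambiguous yet the whole suite plus the acceptance
script completes in well under a minute on a laptop core. Nulls of 10,000+
sets are a matter of `n_sets` only; runtime is linear in sets × repeats.

## Known limitations

- Gene identifiers are opaque; mapping between probe and symbol spaces is
  out of scope, so cross-platform work assumes a shared identifier scheme.
- Only binary contrasts; no survival or longitudinal endpoints.
- No expression-matched random sampling (matching random genes to the
  candidate's expression distribution) — a worthwhile extension the
  current pools do not cover.
- The generator's independence between genes means synthetic nulls are, if
  anything, better behaved than real ones; conclusions about specific real
  cohorts still require the real data.
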