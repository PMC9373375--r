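---
title: "Inferring driver-gene clonality: model, thresholds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring driver-gene clonality: model, thresholds, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonarch)
```

## The observation model

A somatic mutation observed with `t` alt-supporting reads out of depth `N`
carries information about the fraction of cancer cells that harbor it — its
cancer cell fraction (CCF). In a sample of tumor purity $\rho$, with local
absolute tumor copy number $C_T$ at the site, normal copy number $C_N = 2$
(autosomes), and $m$ mutant copies per carrying cancer cell, the expected
variant allele frequency at CCF $c$ is

$$\mathrm{VAF}(c) \;=\; \frac{\rho \, c \, m}{C_N (1-\rho) + \rho \, C_T}.$$

`expected_vaf()` implements this; the default $m = 1$ is a deliberate
conservative choice — assuming a single mutant copy biases CCF estimates
upward, which avoids overcalling subclonality. The multiplicity is exposed as
a parameter but never estimated from data.

Given the expected VAF, the read count is binomial, so the likelihood of
each candidate CCF on a uniform grid of 100 values $(0.01, 0.02, \dots,
1.00)$ is $\mathrm{Bin}(t \mid N, \mathrm{VAF}(c))$. Normalizing over the
grid yields a discrete posterior (`ccf_posterior()`), from which we take:

* the MAP CCF (ties broken toward the larger grid value — again a
  clonal-favoring tie-break),
* an equal-tailed 95% credible interval: the first grid values whose
  cumulative mass reaches 0.025 and 0.975,
* $P(\mathrm{subclonal}) = P(\mathrm{CCF} < 0.9)$, the mass at grid values
  strictly below 0.9.

A mutation is called **subclonal** only when both conditions hold: the upper
credible bound stays below the top grid value (the interval "cannot reach
1"), *and* $P(\mathrm{subclonal}) > 0.5$. Everything else is **clonal**. The
conjunction is intentionally conservative; the two rules disagree rarely but
not never, and the joint rule is the stricter of the two.

### Numerical choices

Likelihoods are computed in log space with max-subtraction before
exponentiation: at depths in the thousands the direct product underflows
double precision (in fact, even partially — intermediate subnormal products
silently lose precision well before reaching zero, which is why the test
suite's direct-probability oracle refuses any case whose intermediates leave
the normal double range). Degenerate posteriors (all likelihoods zero even
in log space) are a hard error naming the mutation. The grid includes 1.00
as its last point; "the CI overlaps 1" is operationalized as the 97.5%
quantile landing on that last point.

Sites are scored only when they can be: mutations on non-autosomal
chromosomes (the $C_N = 2$ assumption fails there), in samples without a
purity estimate, with no covering copy-number segment, or inside a
homozygous deletion ($C_T = 0$ — a point mutation cannot reside on zero
copies) are excluded and itemized by reason rather than silently dropped.
A flag (`autosomes_only = FALSE`) admits sex chromosomes for callers who
supply an appropriate normal copy number.

## Downstream analyses

**Enrichment** (`enrichment_test()`): for a gene with $n = c_1 + s_1$
classified mutations, each permutation draws $n$ mutations without
replacement from the cohort-wide label pool and counts clonal draws. Because
the clonal count determines the ratio $c_1/s_1$ monotonically at fixed $n$,
comparing counts is equivalent to comparing ratios. P-values use the
at-least-as-extreme convention with the $(k+1)/(B+1)$ correction: a strict
"greater than" estimator can return exactly zero for maximal observed
ratios, which is anti-conservative and breaks FDR control downstream. The
gene's own mutations stay in the background pool (no exclusion rule is
obviously right; exclusion is a flag), and FDR adjustment is
Benjamini–Hochberg. Permutations draw mutation indices, not labels, so
swapping the two labels exactly swaps the two p-values under the same seed —
a property the tests exploit.

**Clinical association** (`association_scan()`): patients are assigned one
category per gene (clonal / subclonal / WT; carriers of both collapse to
clonal by default, a flag flips this). Each binary clinical variable — age
split at the cohort median, AJCC 1/2 vs 3/4, T1/2 vs T3/4, N0 vs N1/2, M0 vs
M1, MSI vs MSS, right vs left, female vs male — forms a 2×3 table including
the wild-type column, tested by a two-sided exact test: full enumeration of
tables with fixed margins, summing probabilities no larger than the observed
table's (the Freeman–Halton extension of Fisher's test). Enumeration is
exact for every table size that arises in cohorts of this scale; a seeded
Monte-Carlo estimator (≥ 10⁵ margin-preserving draws) takes over beyond a
configurable size bound and is flagged as such. Patients missing a clinical
variable drop out of that one test only (pairwise deletion). Genes enter the
scan only with ≥ 5 clonal and ≥ 5 subclonal carriers; ineligible genes are
flagged, not dropped.

**Survival** (`gene_survival_scan()`, `cox_fit()`, `stepwise_backward()`,
`bootstrap_stability()`): Kaplan–Meier, log-rank and Cox machinery is
delegated to the `survival` package (Efron tie handling — the accepted
default for moderately tied data). Gene clonality enters Cox models as two
dummies against wild type; backward stepwise elimination drops, at each
round, the least significant removal unit by likelihood-ratio test until all
remaining units reach the 0.05 stay threshold — a gene's two dummies form
one unit and leave jointly, since the procedure removes genes, not
half-genes. Monotone-likelihood levels (e.g. zero events in a covariate
level) are flagged with an infinite-CI marker rather than failing.
Proportional hazards is reported as a global Schoenfeld-residual p-value,
not enforced. Bootstrap stability resamples patients with replacement,
reruns the stepwise selection, and reports per-unit inclusion frequencies;
failed replicates are counted and excluded from the denominator.

## The synthetic cohort generator

`simulate_cohort()` inverts the observation model to produce cohorts with
known truth, so every downstream stage is testable without external data.
Defaults describe a TCGA-style colorectal exome cohort and were fixed once,
up front:

| parameter | default | rationale |
|---|---|---|
| patients | 536 | the cohort scale the pipeline is aimed at |
| gene panel | 12 genes, rates 0.05–0.70 | mimics the CRC driver frequency spectrum |
| clonal bias | 0.45–0.93 per gene | cohort-wide clonal fraction ≈ 0.8 |
| purity | Uniform(0.3, 0.95) | ABSOLUTE-style purity spread |
| depth | Poisson(100), truncated ≥ 30 | exome coverage; floor avoids degenerate posteriors |
| subclonal CCF | Uniform(0.1, 0.8) | strictly below 0.9 so truth labels agree with the classification threshold |
| copy states | 1–4, mode at 2 | diploid-dominated genomes |
| MSI | 15% prevalence, 3× mutation rate | hypermutator phenotype |
| MSI↔clonality | odds ×3 on subclonality of one gene | a known clinical association to recover |
| survival | exponential, median 60 months; log-HR log(3) on one gene's subclonal carriers; age effect log(2) | known prognostic effects to recover |
| censoring | 55%, independent exponential | see below |

Censoring deserves a note: drawing a censoring time uniformly on $(0, T)$
with the desired frequency would make censoring depend on the latent event
time — informative censoring, which biases partial-likelihood estimates. The
generator instead draws independent exponential censoring times whose rate
is calibrated so the *expected* censored fraction matches the configured
rate.

What the generator does **not** emulate: genome geography (each gene gets a
stub segment at a fixed locus), mutational signatures, multi-region
sampling, subclone phylogenies (each subclonal mutation draws its CCF
independently), and purity estimation error (the purity table is truth up to
rounding at 4 decimals). Passing recovery tests therefore demonstrates that
the inference machinery is correct under its own assumptions — not that
those assumptions hold in any real tumor.

## What recovery looks like, honestly

The classifier's accuracy is depth- and purity-limited, and the package does
not pretend otherwise. At depth $N$ the standard error of the CCF estimate
is roughly $\sqrt{p(1-p)/N} / (\partial \mathrm{VAF}/\partial c)$; at purity
0.7, copy number 2 and depth 500 that is ≈ 0.05 per mutation, so requiring
the MAP to land within ±0.05 of truth succeeds for roughly 70% of mid-range
CCFs — a direct consequence of binomial noise, reproduced (not asserted
away) by `scripts/acceptance.R`. Similarly, for a truly clonal mutation at
depth 200 and purity 0.7, the binding rule is $P(\mathrm{CCF} < 0.9) > 0.5$,
which fires whenever the observed VAF falls below 90% of its clonal
expectation — about one standard deviation at that depth — so ~13% of clonal
mutations are miscalled subclonal there. These operating characteristics
are measured by the acceptance script at fixed problem sizes (2,000
simulated mutations per condition) and by the test suite; deeper sequencing
tightens both rapidly.

The end-to-end properties the test suite verifies on top: posterior
equivalence with a direct-probability oracle (total variation ≤ 10⁻⁹ on all
non-underflowing cases), permutation p-values within Monte-Carlo error of
exact hypergeometric tails and a calibrated type-I error over 400 null genes,
recovery of a configured subclonal hazard ratio of 3 through the full
generate → call → categorize → stepwise-Cox chain in ≥ 80% of 50 seeds at
1,000 patients, and byte-identical pipeline outputs under a fixed config and
seed. Problem sizes in the suite (hundreds of patients, ≤ 1,000
permutations, 50-seed power loops) were chosen so the whole suite runs in
about a minute while keeping every Monte-Carlo tolerance at 3 standard
errors or better.

## Known limitations

* One CCF per mutation; no multi-cluster subclone reconstruction, no
  phasing, no multiplicity estimation, no copy-number timing.
* The multiplicity-1 assumption biases CCFs of amplified early mutations
  upward (by design — the conservative direction for subclonality claims).
* Exact tests enumerate 2×k tables only; larger factors fall back to seeded
  Monte Carlo.
* The stepwise procedure is backward-only with a fixed 0.05 stay threshold;
  entry/stay tuning and information-criterion variants are out of scope.
* The per-gene eligibility filter (≥ 5 carriers of each class) is a
  pragmatic floor for contingency and survival tests, not a power
  calculation.
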