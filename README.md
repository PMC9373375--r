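# clonarch

Tumors are mosaics: some driver mutations arose in the founding clone and
are carried by essentially every cancer cell (*clonal*), others arose later
and mark subpopulations (*subclonal*). Whether a driver gene's mutations are
clonal or subclonal in a patient turns out to matter — for association with
clinicopathological features and for prognosis. `clonarch` is an R package
for making that determination from standard somatic variant data and
carrying it through the downstream statistics, aimed at anyone analyzing
MAF-style mutation tables with matched purity and absolute copy-number
calls (TCGA-style exome cohorts in particular).

## The model

For a mutation with `t` alt reads at depth `N`, in a sample of purity ρ with
local tumor copy number C_T (normal copy number C_N = 2 on autosomes) and
m = 1 mutant copies per cancer cell, the expected VAF at cancer cell
fraction c is

    VAF(c) = ρ c m / ( C_N (1 − ρ) + ρ C_T )

The likelihood Bin(t | N, VAF(c)) is evaluated on a uniform grid of 100 CCF
values (0.01 … 1.00) and normalized into a discrete posterior. A mutation is
called **subclonal** when its equal-tailed 95% credible interval stays below
the top grid value *and* P(CCF < 0.9) > 0.5; otherwise **clonal**. On top of
the per-mutation calls the package provides:

* per-gene clonal/subclonal **enrichment** by permutation of the cohort-wide
  label pool (`(k+1)/(B+1)` p-values, Benjamini–Hochberg FDR),
* **clinical association** of per-patient gene categories
  (clonal / subclonal / WT) with binarized clinicopathological variables by
  an exact 2×3 (Freeman–Halton) test, with a ≥ 5-carrier eligibility filter,
* three-group Kaplan–Meier / log-rank **survival** comparisons per gene and
  multivariable Cox modelling with joint-dummy backward stepwise selection
  and bootstrap stability,
* a **synthetic cohort generator** with known ground truth (mutations,
  segments, purity, clinical tables) so the whole chain is testable without
  any external data.

## Worked example

```r
library(clonarch)

# a 300-patient synthetic cohort with known clonal architecture
sim   <- simulate_cohort(sim_config(n_patients = 300), seed = 42)
calls <- call_clonality(sim$bundle)
print(calls)
#> Clonality calls: 843 classified non-silent mutations ( 534 clonal / 309 subclonal ) in 287 samples, 12 genes
#>   excluded: silent-class=78
```

843 non-silent mutations could be scored (silent variants are excluded and
counted); about two thirds are called clonal. A single mutation's posterior:

```r
ccf_posterior(18, 120, purity = 0.6, local_cn = 2)
#> CCF posterior (18/120 reads, purity 0.6, local CN 2)
#>   MAP CCF: 0.5   95% CI: [0.32, 0.75]
#>   P(CCF < 0.9) = 0.9988
```

18/120 reads at purity 0.6 imply half the cancer cells carry the mutation;
the interval excludes 1 and the subclonal mass is ~1, so this call is
subclonal. Downstream, per-gene enrichment and survival:

```r
enr <- gene_enrichment(calls, n_perm = 1000, seed = 42)
head(as.data.frame(enr)[order(enr$p_clonal),
     c("gene","n","c1","s1","clonal_ratio","p_clonal","q_clonal")], 4)
#>      gene   n  c1 s1 clonal_ratio p_clonal q_clonal
#> 9  PIK3CA  84  62 22         2.82    0.026    0.312
#> 12   TP53 169 112 57         1.96    0.213    0.964
#> 8    KRAS 137  90 47         1.91    0.301    0.964
#> 5    BRAF  45  30 15         2.00    0.395    0.964

categories <- patient_gene_category(calls, samples = sim$bundle$clinical$sample_id)
km <- gene_survival_scan(categories, sim$bundle$clinical)
km[km$eligible, c("gene", "p_overall", "p_subclonal_vs_wt")][1:4, ]
#>     gene p_overall p_subclonal_vs_wt
#> 1   ANK1  1.14e-05          2.06e-06
#> 2    APC  9.94e-01          9.38e-01
#> 3 ARID1A  5.00e-01          2.07e-01
#> 4  BCL9L  7.71e-01          6.75e-01
```

The generator plants a hazard ratio of 3 on subclonal carriers of one gene
(ANK1 by default); the three-group log-rank scan finds exactly that gene
(p ≈ 1e-05) and no other. `run_pipeline(list(sim = list(n_patients = 300),
seed = 42), "out/")` runs all stages at once and writes every table, a run
log, and an md5 manifest; reruns with the same config and seed are
byte-identical.

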