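# emtquad

Isoform-level prognostic analysis for non-small-cell lung cancer (NSCLC)
expression cohorts, built around the observation that a KRAB-domain splice
isoform can be prognostic where overall gene expression is not.  The package
is aimed at computational biologists who have a sample × feature TPM matrix,
a clinical table, and optionally cell-line drug-response / gene-effect /
qPCR data, and want the full analysis chain reproducibly scripted.

## What it computes

**EMT quadrant classifier.** For each sample, aggregate scores over 3
mesenchymal markers (ZEB1, VIM, FN1) and 11 epithelial markers (CDH1,
EPCAM, ESRP1, ESRP2, DDR1, CTNNB1, CD24, CLDN7, KRT8, KRT19, RAB25):

    mes_i = mean over mesenchymal markers of log2(TPM + 1)
    epi_i = mean over epithelial markers of log2(TPM + 1)

Median splits of the two scores assign one of four phenotypes — strictly
above both medians → *HighOverlap*, mesenchymal only → *Mesenchymal*,
epithelial only → *Epithelial*, neither → *LowOverlap*.

**Cutoff survival stratification.** Samples with feature TPM ≥ cutoff
(default 1.5) form the high group; Kaplan–Meier curves, the unweighted
log-rank test, and a univariate Cox hazard ratio (Breslow ties, Wald 95%
CI) compare high vs low — cohort-wide and within each EMT quadrant.

**Drug response.** Per drug and metric (IC50/EC50), cell lines are
*resistant* above mean + 0.5·SD, *sensitive* below mean − 0.5·SD, otherwise
*partial*; resistant-vs-sensitive differential expression uses two-sided
Student's t-tests on log2(TPM + 1).

**Gene-effect normalization.** Raw dependency scores are anchored per cell
line by f(x) = (x − m_ne)/(m_ne − m_e) so control medians land exactly at 0
(non-essential) and −1 (essential); normalized scores ≤ −0.5 are called
*dependent*.

**qPCR.** Relative expression by the comparative-threshold method:
fold = 2^−ΔΔCt with triplicate averaging and a designated reference sample.

**Synthetic cohorts.** `simulate_cohort()`, `simulate_cell_lines()` and
`simulate_qpcr()` generate data with planted isoform correlation, latent
EMT axes, hazard ratios, drug-response shifts and control-anchored gene
effects, plus a ground-truth sidecar — so every estimator above can be
validated by parameter recovery without external data.

## Worked example

```r
library(emtquad)

cfg    <- sim_config(seed = 42)          # 197 tumors, planted HR 1.686
cohort <- simulate_cohort(cfg)

calls <- classify_emt_quadrants(cohort$expression)
table(calls$phenotype)
#>  Epithelial Mesenchymal HighOverlap  LowOverlap
#>          54          54          44          45

strat <- stratify_by_cutoff(cohort$expression[, "ZNF71_KRAB"], 1.5)
attr(strat, "high_fraction")
#> [1] 0.1522843

lr <- logrank_test(cohort$clinical$time, cohort$clinical$event, strat)
hr <- hazard_ratio(cohort$clinical$time, cohort$clinical$event, strat,
                   reference = "low")
sprintf("log-rank p = %.4f; HR = %.3f [%.3f, %.3f]", lr$p, hr$hr, hr$ci_lo, hr$ci_hi)
#> [1] "log-rank p = 0.0110; HR = 1.794 [1.136, 2.832]"
```

About 15% of this simulated cohort expresses the KRAB isoform at TPM ≥ 1.5,
and those tumors have ~1.8-fold the event hazard — the interval covers the
planted 1.686.  Within quadrants:

```r
per_phenotype_survival(cohort$expression, cohort$clinical, calls,
                       "ZNF71_KRAB", 1.5)[, c("phenotype", "n", "n_high",
                                              "logrank_p", "hr", "estimable")]
#>     phenotype  n n_high logrank_p   hr estimable
#> 1  Epithelial 54      6    0.0344 2.54      TRUE
#> 2 Mesenchymal 54     12    0.7591 1.13      TRUE
#> 3 HighOverlap 44      7    0.2033 1.82      TRUE
#> 4  LowOverlap 45      5    0.0162 4.44      TRUE
```

Cell-line side — docetaxel response and the planted KRAB overexpression in
resistant lines:

```r
cl   <- simulate_cell_lines(cfg)
doc  <- subset(cl$drug_response, drug == "docetaxel")
cats <- categorize_response(setNames(doc$ic50, doc$cell_line))
table(cats)
#>   partial resistant sensitive
#>        40        39        38

diff_expr_by_response(cl$expression, cats,
                      features = c("ZNF71_overall", "ZNF71_KRAB",
                                   "ZNF71_KRABless"))[, c("feature", "diff", "t", "p")]
#>          feature    diff      t        p
#> 1  ZNF71_overall  1.0516  6.264 2.15e-08
#> 2     ZNF71_KRAB  1.1626  7.117 5.59e-10
#> 3 ZNF71_KRABless -0.0202 -0.192 8.48e-01
```

The KRAB isoform (and hence overall expression) is ~1.1 log2 units higher
in resistant lines, while the KRAB-less isoform — which carries no planted
shift for this drug — stays null.

`run_pipeline("cfg.yaml", "out/")` executes the whole flow from a config
file and writes `emt_calls.tsv`, `survival_report.json`,
`drug_response.tsv`, `drug_diffexpr.tsv`, `dependency_calls.tsv`,
`qpcr_foldchanges.tsv` and `run.log`; reruns are byte-identical under the
same seed.  A thin CLI wrapper with the same entry points
(`simulate`, `classify`, `survive`, `chemo`, `depend`, `run`) installs to
`exec/emtquad`.

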