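# psgrs

Weighted genetic risk scores (GRS) for case-control studies of psoriasis.

Individual psoriasis risk SNPs carry modest effects (allelic odds ratios
mostly between 1.1 and 1.7, with *HLA-C* the outlier near 4). A weighted
GRS aggregates them into one per-individual quantity,

    GRS_i = sum over panel SNPs j of  d_ij * ln(OR_j)

with `d_ij` the risk-allele dosage (0/1/2) and `OR_j` the SNP's allelic
odds ratio. `psgrs` implements the complete analysis around that score
for biostatisticians and genetic epidemiologists working with candidate
SNP panels:

- **Association & QC** — per-SNP allelic chi-square tests on 2×2 allele
  tables, Woolf confidence intervals, Hardy–Weinberg equilibrium checks,
  strict Bonferroni gating (`associationTable`, `allelicTest`, `hweTest`).
- **Panels & scores** — the nested panel hierarchy (ALL / p<0.1 /
  nominal / Bonferroni / HLA-only / substitutions) with in-sample ln(OR)
  weights and listwise handling of missing genotypes (`buildPanel`,
  `scoreCohort`).
- **Dose-response** — control-referenced score quartiles and per-quartile
  odds ratios vs the bottom quartile (`quartileCutpoints`,
  `quartileOrTable`).
- **Discrimination** — ROC curves, tie-aware AUC, DeLong
  variance/covariance, paired and unpaired AUC comparison, confusion
  metrics, Youden thresholds (`rocCurve`, `compareAucSets`).
- **Model evaluation** — logistic regression, Nagelkerke/McFadden
  pseudo-R², sub-phenotype associations, seeded 75/25 internal
  validation, and allelic-test power (`internalValidation`,
  `powerAllelic`).
- **Simulation** — a case-control cohort generator drawing genotypes
  under retrospective allelic sampling (controls HWE-binomial at the
  control allele frequency, cases at the frequency implied by the target
  odds ratio), with an LD pair, random missingness and score-linked
  sub-phenotypes (`simulateCohort`, `defaultCohortSpec`).

Cohorts are held in a `GrsCohort`, an S4 class extending
`SummarizedExperiment` (dosage assay, SNP metadata in `rowData`,
phenotypes in `colData`). The package ships a 38-SNP published
association summary (`referenceSnpSummary()`) that anchors the worked
examples and parameterises the default simulation.

## Worked example

Simulate a cohort under the published study conditions (38 SNPs, 480
cases / 490 controls), run the pipeline, and compare panels:

```r
library(psgrs)

cohort <- simulateCohort(defaultCohortSpec(seed = 42))
cohort
#> GrsCohort: 38 SNPs x 970 samples (480 cases / 490 controls)
#>   overall missing dosage fraction: 0.0019

res <- associationTable(cohort, bonferroniM = 38)
panelN <- buildPanel(res, "N")      # nominally associated SNPs, p < 0.05
ss <- scoreCohort(cohort, panelN)
ss
#> ScoreSet (panel 'N'): 970 samples, 941 complete
#>   score range (complete): [5.616, 14.231]

quartileOrTable(ss)
#>   quartile n_case pct_case n_ctrl    or ci_lo ci_hi        p
#> 1       Q1     20     4.27    118  1.00    NA    NA       NA
#> 2       Q2     28     5.98    118  1.40 0.747  2.62 2.92e-01
#> 3       Q3     87    18.59    118  4.35 2.512  7.53 4.30e-08
#> 4       Q4    333    71.15    119 16.51 9.834 27.72 2.25e-35

ssH <- scoreCohort(cohort, buildPanel(res, "HLA"))
compareAucSets(ss, ssH)             # paired DeLong test
#> AUC 0.8111 vs 0.6786 (paired DeLong): delta = +0.1325, z = 9.873, p = 5.44e-23

internalValidation(cohort, "N", seed = 7)
#> Internal validation (75/25 split, seed 7, panel 'N', 18 SNPs)
#>   AUC train 0.8047 vs test 0.8181, unpaired p = 0.671
#>   accuracy train 0.733 vs test 0.742 (threshold 9.700)
```

Reading the output: the score separates cases from controls (AUC ≈ 0.81
here), risk rises monotonically across score quartiles (OR 1 → 1.4 →
4.4 → 16.5 relative to the bottom quartile, with 71% of cases in the
top quartile), the multi-SNP panel discriminates significantly better
than the *HLA-C* tag SNP alone, and a 75/25 train/test split shows no
evidence of overfitting (AUCs statistically indistinguishable). On-disk
exchange uses plain TSV or PLINK-style ped/map text files
(`writeCohort` / `readCohort`).

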