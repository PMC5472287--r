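---
title: "Genetic risk scores for psoriasis: models, simulation and evaluation"
author: "psgrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic risk scores for psoriasis: models, simulation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psgrs)
```

## The problem

Psoriasis is a complex disease: its best-established genetic risk factor,
*HLA-C* (tagged here by rs4406273, a close proxy for *HLA-Cw\*0602*), explains
only part of the heritable risk, and several dozen further SNPs each confer a
modest allelic odds ratio. A weighted genetic risk score (GRS) aggregates
these small effects into a single per-individual quantity,

$$\mathrm{GRS}_i \;=\; \sum_{j \in \text{panel}} d_{ij}\,\ln \widehat{OR}_j ,$$

where $d_{ij} \in \{0,1,2\}$ is the count of risk alleles individual $i$
carries at SNP $j$ and $\widehat{OR}_j$ is that SNP's allelic odds ratio.
This package implements the full analysis path around that score for a
case-control cohort: per-SNP association and quality control, nested panel
construction, dose-response analysis by score quartile, ROC/AUC comparison of
competing panels, logistic evaluation, internal validation, and power — plus
a cohort simulator so every stage can be exercised and tested end to end.

## Per-SNP association and quality control

Alleles, not genotypes, are the sampling units: each SNP contributes a 2×2
table of risk/other allele counts in cases and controls (a sample of $n$
genotypes contributes $2n$ alleles, missing genotypes excluded). The test is
the uncorrected 1-df Pearson chi-square on this table — the basic allelic
test of standard GWAS tooling; a continuity-corrected variant is deliberately
not used, and Fisher-style small-sample handling is limited to the
Haldane–Anscombe +0.5 correction of the odds ratio when a cell is empty
(flagged in the output). The odds ratio estimate is the cross-product ratio
$ad/bc$ with a Woolf confidence interval,
$\exp\!\big(\ln \widehat{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d}\,\big)$, which
reproduces the published intervals of our reference panel to rounding.

Hardy–Weinberg equilibrium (HWE) is checked per SNP by a 1-df
goodness-of-fit chi-square against $np^2, 2npq, nq^2$ at the sample allele
frequency; $p < 0.05$ flags a deviation. The default evaluates HWE in the
combined sample, with a controls-only option; monomorphic SNPs are reported
as $p = 1$ with a flag rather than an error. Multiple testing across the
panel uses a strict Bonferroni gate, $p < 0.05/m$ with $m$ the number of
SNPs analysed (38 for the packaged reference panel).

## Panels, weights and the LD drop

`buildPanel()` encodes the panel hierarchy of the study the package
re-implements: **ALL** (every analysed SNP), **0.1** ($p<0.1$), **N**
(nominal, $p<0.05$), **B** (Bonferroni survivors), **HLA** (rs4406273
alone), **N(+)HLA(−)** (N without rs4406273), and **N(subst.)** (N with
rs4406273 replaced by its linked partner rs10484554, carrying rs10484554's
own weight). Two design choices deserve comment:

* **Weights are in-sample $\ln \widehat{OR}$**, re-estimated from the
  analysed cohort rather than taken from the literature. The published
  quartile cut-point range (3.10–3.76) is consistent with in-sample weights
  over the 16-SNP nominal panel; literature weights remain available by
  passing any results table with an `or` column.
* **rs10484554 is dropped from every panel that does not explicitly
  substitute it.** The two *HLA-C* tags are in strong LD, and only one may
  carry the *HLA-C* signal; consequently "ALL" scores 37 of the 38 SNPs.

Scoring is strict about missing data: a sample missing any panel dosage is
flagged incomplete, scored `NA`, and excluded listwise from every downstream
statistic — the behaviour that produced the reference study's exclusion of
11 of 480 cases. Mean imputation is intentionally not performed.

## Quartile dose-response

`quartileCutpoints()` takes empirical quartiles of the complete scores of
the **controls** by default (the reference study's control column, 490
controls, splits 123/122/122/123 — an even control split, which only a
control-referenced cut achieves); binning is half-open $[Q_k, Q_{k+1})$.
For each quartile above the bottom, the odds ratio relative to the bottom
quartile is the 2×2 count ratio with a Woolf interval and chi-square
p-value. A logistic estimator (status on quartile factor) is provided as an
alternative; its point estimates coincide with the count ratio (saturated
model), differing only in interval construction. The published top-vs-bottom
value for the reference table (12.29) does not equal the count ratio of the
printed counts (12.19), and the generating estimator is not stated there, so
this package reports both of its estimators and forces neither to the
printed value.

## ROC, AUC and DeLong comparison

The AUC is computed as the tie-aware Mann–Whitney statistic,
$\widehat{A} = (mn)^{-1}\sum_i\sum_j [\,I(X_i > Y_j) + \tfrac12 I(X_i =
Y_j)\,]$, via sorted placement values in $O(n\log n)$. DeLong's estimator
gives the variance, $\widehat{V} = S_X/m + S_Y/n$ with $S_X, S_Y$ the
empirical variances of the case and control placements, and, for two scores
on the *same* samples, the covariance of the two AUCs from the shared
placements; the paired z-test follows. Pairing requires identical subjects,
so samples incomplete on either panel are removed from both before a paired
comparison (`compareAucSets()`), and disjoint cohorts (e.g. training vs
test sets) are compared with the covariance forced to zero. The in-package
DeLong implementation is cross-checked against an independent library
implementation and against a permutation oracle in the test suite.

Classification metrics (sensitivity, specificity, PPV, NPV, accuracy) are
computed at a threshold; since the reference study states no cut-off rule,
the internal-validation workflow selects the Youden-optimal threshold
($\max(\mathrm{tpr}-\mathrm{fpr})$, ties to the lowest cut-off, midpoints
between observed scores as candidates) on the training data only.

## Logistic evaluation and internal validation

Logistic fits go through iteratively reweighted least squares
(`stats::glm`, binomial family, tolerance $10^{-8}$, 100 iterations);
perfect separation is detected by a vanishing residual deviance and flagged
as non-convergence rather than silently reported. "Phenotypic variation
covered" by a score is reported as Nagelkerke $R^2$ by default — the usual
choice in the GRS literature — with McFadden's ratio alongside; the
reference study does not name its statistic, so neither value is forced to
its printed 19.63%. Sub-phenotype associations (nail psoriasis, psoriatic
arthritis, late onset, family history) are logistic fits of the trait on
the **raw** score within cases, reporting the per-unit odds ratio with Wald
inference; a per-SD option exists because the published effect scale is
unstated.

`internalValidation()` draws a seeded 75/25 split stratified by case
status, then rebuilds everything on the training set alone — association,
panel membership, weights and threshold — and evaluates both sets,
comparing AUCs with the unpaired z-test. The split is bit-reproducible
given its seed.

Power for a future allelic test uses the two-proportion normal
approximation on allele counts ($2n$ per stratum): the alternative case
frequency comes from the exact odds map
$p_1 = OR \cdot o_0/(1 + OR \cdot o_0)$, the critical value uses the pooled
standard error under the null and the power the unpooled one, so that
$OR = 1$ returns exactly $\alpha$. The tests hold this formula to within
±0.03 of Monte-Carlo power over a grid of frequencies and odds ratios.

## The cohort simulator

`simulateCohort()` draws the data-generating model under which the allelic
odds ratio is the estimand — retrospective allelic sampling: control
genotypes are $\mathrm{Binomial}(2, p_0)$ (HWE at the control risk-allele
frequency) and case genotypes $\mathrm{Binomial}(2, p_1)$ with $p_1$ from
the exact odds map above. A liability-threshold model was deliberately not
used: it would make the realised allelic odds ratio only approximately equal
to the target. SNPs are independent except one declared LD pair, drawn from
a two-locus haplotype distribution with $D = +\sqrt{r^2 p_A q_A p_B q_B}$
(same positive linkage sign in both strata). Infeasible $r^2$ targets —
those exceeding the Lewontin bound $D \le \min(p_A q_B, q_A p_B)$ — raise
an error that reports the attainable bound (`maxAttainableR2()`).

The packaged default spec (`defaultCohortSpec()`) encodes the study
conditions end to end: the 38 SNPs of `referenceSnpSummary()` with their
published control frequencies and odds ratios as targets, 480 cases and 490
controls, and the published sub-phenotype links. Three defaults required a
judgement call, made once and documented here:

* **LD pair r².** The published $r^2 = 0.79$ between the two *HLA-C* tags
  is algebraically unattainable at their published allele frequencies
  (bound ≈ 0.44 in controls, ≈ 0.63 in cases); the default spec links the
  pair at the largest value attainable in both strata (≈ 0.44). Any user
  value within the bound is honoured; values beyond it error.
* **Missingness.** Completely-at-random per-cell missingness at rate
  0.0015, chosen so that listwise exclusion on a 16-SNP panel loses about
  11 of 480 cases — the attrition the reference cohort actually showed —
  while respecting its ">98% success per SNP" genotyping figure.
* **Late-onset prevalence.** The reference study does not print its
  T1Ps/T2Ps split; the simulator uses 25% late onset, the proportion
  conventionally cited for psoriasis (about three quarters of patients
  present before age 40).

Sub-phenotypes are assigned by inverting the logistic link the analysis
later fits: case $i$ is positive for a trait with probability
$\mathrm{logit}^{-1}(\alpha + \beta\,\mathrm{GRS}_i)$, with $\beta$ the
configured log-odds per raw score unit (defaults: ln 0.92 nail, ln 0.73
PsA, ln 0.56 late onset, ln 1.83 family history) and $\alpha$ solved by
root-finding so the marginal prevalence among cases hits its target
(52.29%, 33.75%, 25%, 43.33% respectively). The generating score uses the
target $\ln OR$ weights over all spec SNPs minus the LD partner.

What the simulator does **not** emulate: population structure and
relatedness, genotyping error beyond random missingness, LD beyond the one
declared pair, covariates (age, sex), and selection of cases by clinic.
Passing tests therefore demonstrate that the *methods* behave correctly
under the stated model, not that real cohorts satisfy that model.

## Numerical choices and degenerate inputs

* Dosages are 0/1/2/`NA`, always oriented to the declared risk allele;
  flipping orientation maps $d \mapsto 2-d$ exactly (`flipRiskAllele()`).
* Ties: ½-weight in the U statistic and midpoint placements for DeLong;
  half-open quartile bins; Youden ties resolved to the lowest threshold.
* Zero cells: Haldane–Anscombe +0.5 for OR/CI (flagged); empty strata and
  empty reference quartiles are errors, not silent corrections.
* Monomorphic SNPs: HWE $p = 1$ with a flag; the allelic test on a
  monomorphic table returns $\chi^2 = 0$, $p = 1$.
* All simulation, sub-phenotype assignment and the validation split are
  driven by explicit integer seeds and are bit-reproducible.

## Problem sizes used in the tests

The test suite exercises distributional claims at sizes chosen to make
binomial standard errors informative while keeping the default run fast:
single-SNP HWE and frequency checks at $10^5$ controls, LD calibration at
$10^4$ controls, a 20-replicate pipeline run at the study's 480/490 for
discrimination, 500 × 10 null tests for type-I calibration, $10^4$
bootstrap/permutation draws for the DeLong oracles, and $10^4$ Monte-Carlo
cohorts per point of the 3×3 power grid.

## Known limitations

Covariate-adjusted association, genotypic (dominant/recessive) models,
haplotype tests, imputation, genome-scale panels and LD-aware PRS
construction (clumping/thresholding, shrinkage) are out of scope. The
quartile logistic estimator cannot reproduce a published top-quartile value
whose estimator is unstated, and no pseudo-$R^2$ flavour is claimed to
match the published variance-explained figure; both are reported as
computed.
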