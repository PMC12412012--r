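---
title: "Methods: the Glyco-MSI screen, score, and downstream models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Glyco-MSI screen, score, and downstream models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoMSI)
```

This vignette documents the statistical procedures in `glycoMSI`, the
assumptions behind them, the defaults and why they were chosen, and what
the synthetic-data generators do and do not emulate.

## The screening model

The screen looks for glycosyltransferase genes whose expression separates
MSI from MSS colorectal cancer *concordantly* across three very different
measurement modalities: bulk tumor RNA-seq (tumor plus stroma and immune
cells), cancer cell lines (pure tumor, no microenvironment), and single
tumor-epithelial cells (pure tumor, in vivo). Requiring agreement across
all three guards against two classic artifacts: bulk fold changes driven
by immune infiltration differences (MSI tumors are heavily infiltrated),
and cell-line effects that do not transfer to tissue.

A gene is selected when all of the following hold:

1. **Prevalence.** It is expressed (non-zero count) in at least 5% of
   tumor-epithelial cells, computed over all tumor-epithelial cells pooled
   across patients. Single-cell data are dominated by zeros; the 5% rule
   keeps genes that are genuinely expressed in the cell type rather than
   detected in a handful of cells.
2. **Effect size.** |log2 fold change| strictly greater than 0.4 in the
   bulk, cell-line, *and* single-cell comparisons. Fold change is the
   difference of MSI and MSS group means of log2-scale values — the
   convention for matrices distributed already log-transformed — not the
   log2 of a ratio of linear means.
3. **Sign concordance.** The three fold changes share one sign
   ("consistently up- or down-regulated"). This is an explicit requirement
   in the implementation (`require_sign_concordance = TRUE`); a gene at
   |fc| > 0.4 with mixed signs is not selected.

The threshold comparisons are deliberately asymmetric: prevalence uses
`>= 0.05` ("at least 5%"), fold change uses the strict `> 0.4`. The
single-cell fold change is the difference in mean `log2(count + 1)` over
pooled tumor-epithelial cells of MSI versus MSS patients; pseudocount 1 is
the standard bounded-at-zero choice. Patient-level pseudobulk would be a
defensible alternative; pooling was chosen because the prevalence rule is
also defined over pooled cells, keeping the two single-cell statistics on
the same footing. Genes absent from any modality cannot satisfy "all
three" and are reported as unevaluable rather than silently dropped.

Selection is monotone in both thresholds (raising either can only remove
genes) and invariant to gene and sample ordering; both properties are
asserted in the test suite.

## The Glyco-MSI score and AUC

For a signature with up-arm $U$ and down-arm $D$, sample $j$ scores

$$ s_j = \frac{1}{|U|}\sum_{g \in U} x_{gj} \;-\;
         \frac{1}{|D|}\sum_{g \in D} x_{gj}, $$

on the log2-scale values as provided. No z-scoring or re-normalization is
applied: the score definition is a plain average difference, and the score
is used either within one cohort (where a monotone per-cohort transform
would not change the AUC) or after per-cohort median dichotomization
(likewise rank-based). Missing signature genes are dropped from their arm
and counted in `n_up_used` / `n_down_used`; an entirely missing arm is an
error.

Discrimination is summarized by the area under the ROC curve, computed as
the tie-corrected Mann–Whitney concordance probability

$$ \mathrm{AUC} = \frac{U}{n_{\mathrm{MSI}}\, n_{\mathrm{MSS}}}, \qquad
   U = \sum_{i \in \mathrm{MSI}} r_i - \frac{n_{\mathrm{MSI}}(n_{\mathrm{MSI}}+1)}{2}, $$

with midranks for ties. This is exact and deterministic, and makes the
identity with the Mann–Whitney test (`mann_whitney()`) hold to machine
precision. For equal-variance Gaussian score distributions separated by
$\delta$ with common SD $\sigma$, the theoretical AUC is
$\Phi(\delta/(\sigma\sqrt2))$; the test suite checks the empirical AUC
against this closed form at $\delta/\sigma \in \{1, 2\}$.

The immune-infiltration score (`signature_average()`) is the plain mean of
an immune gene set's log-scale values. It is *not* ESTIMATE's rank-based
ssGSEA: the score is used only for correlation direction, the function
accepts any gene list (including the full 141-gene immune signature), and
a plain average keeps the operation transparent and dependency-free.

## Survival analysis

Markers are dichotomized at the sample median; values strictly above the
median are "high", ties with the median go to "low". The tie rule is a
package decision (the convention of the original analysis is not
documented); it is deterministic and keeps the high group at no more than
half the cohort.

Kaplan–Meier estimation, the two-group log-rank test and Cox
proportional-hazards fits are delegated to the `survival` package, with
two conventions fixed here: **Breslow** handling of tied event times
(simple, and with a tractable independent oracle — the test suite
maximizes the Breslow partial likelihood by golden-section search and
checks `coxph`'s estimate against it, and verifies the log-rank statistic
equals the Cox score test at $\beta = 0$ when no times are tied), and
**Wald** 95% intervals $\exp(\hat\beta \pm 1.96\,\widehat{se})$ with the
z-value fixed at 1.96. Censored subjects at time $t$ remain at risk for
events at $t$. P-values are two-sided with 0.05 as the significance
convention. Different software (e.g. Efron ties, likelihood-ratio
intervals) can differ in the third decimal on real data.

## The IHC H-score model

The H-score multiplies staining intensity (0 negative, 1 weak, 2 moderate,
3 strong) by the positivity category (1: 0–25%, 2: 26–50%, 3: 51–75%,
4: 76–100%), giving 16 possible pairs but only nine achievable values
{0, 1, 2, 3, 4, 6, 8, 9, 12}. Tumors with H-score 8–12 are GALNT7-High,
0–7 GALNT7-Low. Note 7 is not an achievable product; the classifier still
cuts at ≥ 8 over the full 0–12 range so that averaged or externally
supplied H-scores remain classifiable. Non-integer positivity percentages
are floored before binning (scores are whole-percent estimates).

Association statistics follow common software conventions where the
original convention is not documented: Fisher's exact two-sided p-value is
the minimum-likelihood rule (the total hypergeometric probability of all
tables with the observed margins that are no more probable than the
observed table, with a small relative tolerance for floating-point ties);
the chi-square test is Pearson's without continuity correction (a
`correct` flag is exposed); the Mann–Whitney p-value uses the
tie-corrected normal approximation.

## The synthetic generators

The generators reproduce the *statistical structure* the analysis assumes,
not the full complexity of real data.

- **Bulk / cell line** (`generate_bulk_cohort()`): log2-scale expression
  is Gaussian around group means; MSI samples get `+effect_log2fc` on
  planted up genes and `-effect_log2fc` on planted down genes. The screen
  consumes log-scale values, so count-level realism adds nothing here.
  Defaults: 76 MSI / 450 MSS samples (the shape of a large public tumor
  cohort), 188-gene universe, effect 0.8, noise SD 0.5 — the noise level
  is the package's canonical worked-example condition and is realistic
  for within-class log2 expression SD of a moderately expressed gene.
- **Single cell** (`generate_single_cell()`): counts are Poisson with
  per-gene rates, then zeroed by independent Bernoulli dropout
  (default 0.3) — the minimal mechanism producing the zero inflation that
  motivates the 5% prevalence rule. Rates are calibrated by root finding
  so that the *observed* (post-dropout) mean `log2(count + 1)` of a
  planted gene differs between MSI and MSS tumor-epithelial cells by
  exactly `effect_log2fc` in expectation; naive rate scaling by
  `2^effect` would shrink badly on the log2(count+1) scale at realistic
  detection rates. Down-regulation is planted by raising the MSS group,
  since a mean of non-negative values cannot drop below zero. The default
  pre-dropout detection rate (5/7) pairs with the default dropout to give
  an observed prevalence of 0.5 for baseline genes. Requested effects
  whose calibrated pre-dropout mean exceeds 25 log2 units (possible only
  at extreme dropout) are truncated with a warning. Cells are assigned to
  10 patients at random; four cell types are generated, with planted
  effects confined to tumor-epithelial cells.
- **Survival** (`generate_survival()`): event times are exponential with
  hazard `baseline_hazard * exp(log_hr * group)`; independent exponential
  censoring is calibrated by root finding on the exact censored-fraction
  formula so the expected censored proportion matches the target, with an
  optional administrative horizon.
- **IHC** (`generate_ihc_cohort()`): MMR status, GALNT7 class, the
  (intensity, positivity) pair (uniform within the class's H-score bin)
  and PD-L1 status are drawn hierarchically from the spec'd conditionals.
  Defaults follow the observed cohort: 8.4% dMMR, GALNT7-High in 65.4% of
  dMMR and 21.3% of pMMR tumors, PD-L1 positivity 23.8% / 58.8% in
  High / Low dMMR tumors; PD-L1 in pMMR/MSS tumors is set to 10%, a
  typical rate chosen once since no reference value is printed. Tn-antigen
  H-scores are drawn with a class-linked shift and TIL counts with an
  MMR-linked shift so the stratified comparisons have real signal.

Every generator is a pure function of its spec: the caller's RNG state is
saved and restored, and the single seed is split into named substreams so
one stage's consumption cannot shift another's.

**What the generators do not emulate** — and hence what passing tests do
not establish about real data: library-size and batch effects, platform
differences among the public cohorts (each is distributed with its own
preprocessing), gene–gene correlation, patient-level clustering of
single-cell expression beyond random assignment, non-proportional hazards,
and inter-observer variation in IHC scoring. Recovery results on synthetic
data validate the *implementation*, not the biological claim.

## Problem sizes and numerical choices

The test suite and the acceptance script run the study at the sizes the
analysis design names: bulk 80/400 (screen) or 76/450 (scoring), cell
lines 20/34, 2,000 tumor-epithelial cells, 20 screen replicates, 50
survival replicates at n = 300, IHC cohorts up to 20,000 records for
stable conditional proportions. These sizes give Monte-Carlo standard
errors comfortably inside the asserted tolerances while keeping a full
run in well under a minute.

Numerical conventions: rate and censoring calibrations use `uniroot` at
tolerance 1e-10; Cox fits use the Breslow partial likelihood with a
gradient tolerance of 1e-9 and at most 50 Newton iterations,
non-convergence (e.g. monotone likelihood) being flagged, not raised;
probe collapse breaks exact mean ties toward the lexicographically
smallest probe id; Fisher enumeration compares probabilities with relative
tolerance 1e-7, matching common software; MSI label harmonization is
case-insensitive and maps MSI-high/dMMR to MSI and MSI-low/MSS/pMMR to
MSS, with unrecognized labels treated as data (`"unknown"`, excluded with
a logged count), not as errors.

## Known limitations

- The screen is purely threshold-based by design; it attaches no p-values
  or multiplicity control to gene selection.
- The proteomic use case treats a protein-abundance matrix as just another
  log-scale matrix; no proteomic-specific normalization is provided.
- Multivariable Cox modeling is supported mechanically
  (`cox_fit(..., covariates)`), but no covariate-set curation, model
  selection, stratified or time-varying extensions are included.
- The immune score is a plain signature average, not ssGSEA; absolute
  values are not comparable to ESTIMATE scores, only directions of
  association.
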