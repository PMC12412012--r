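# glycoMSI

Tools for finding and evaluating glycosyltransferase gene signatures that
separate microsatellite-instable (MSI) from microsatellite-stable (MSS)
colorectal cancers, and for carrying the resulting markers through to
survival stratification and immunohistochemistry (IHC).

Defective DNA mismatch repair produces the hypermutable MSI phenotype, which
responds differently to therapy (notably immune checkpoint blockade) than
MSS disease. Glycosyltransferases — the enzymes that build the tumor
glycocalyx — are differentially expressed between the two classes, and a
small, concordant set of them can classify MSI status from bulk expression
data alone. `glycoMSI` implements that analysis end to end:

- **Concordant tri-modal screen.** For a gene universe of 188
  glycosyltransferases, a gene is selected when it is expressed by at least
  5% of tumor epithelial cells in a single-cell dataset and shows
  |log2 fold change| > 0.4 between MSI and MSS in *all three* of: bulk
  tumors, cell lines, and single tumor-epithelial cells, with a consistent
  sign. Fold change is the difference of group means of log2-scale values.
- **Glyco-MSI score.** For a signature with up-arm *U* and down-arm *D*,
  each sample's score is
  `mean(expr[U]) − mean(expr[D])`. The packaged default
  (`glyco_msi_signature()`) is GALNT7, GALNT1, HPSE up; GALNT6, ST6GAL1
  down. Discrimination is measured by the rank-based AUC,
  `AUC = U-statistic / (n_MSI · n_MSS)` with midrank ties — the probability
  that an MSI sample outscores an MSS sample.
- **Survival stratification.** Markers are dichotomized at the sample
  median (ties to "low"), then compared by Kaplan–Meier curves, the
  two-group log-rank test, and Cox proportional-hazards fits (Breslow
  ties) with 95% Wald intervals `exp(β ± 1.96·se)`.
- **IHC H-score model.** Staining intensity (0–3) times positivity
  category (1: 0–25%, …, 4: 76–100%) gives the H-score (0–12);
  tumors with H-score ≥ 8 are GALNT7-High. Association statistics:
  Fisher exact (minimum-likelihood two-sided p), Pearson chi-square,
  Mann–Whitney U.
- **Synthetic cohorts.** Seeded generators for every data modality —
  bulk/cell-line matrices with planted fold changes, zero-inflated
  single-cell counts, exponential survival with calibrated censoring,
  MMR-stratified IHC records — so the entire pipeline is testable with no
  external downloads.

## Worked example

```r
library(glycoMSI)

study <- simulate_study(seed = 3)          # bulk 76/450, cell lines 20/34,
                                           # 2,500 cells, survival, IHC
res <- run_pipeline(study, "glycomsi_out", seed = 3)
res$signature
#> gene_signature 'screened': up = {GALNT7, GALNT1, HPSE}; down = {GALNT6, ST6GAL1}
res$auc_table
#>        cohort       auc n_msi n_mss n_up_used n_down_used status
#> 1        bulk 0.9975731    76   450         3           2     ok
#> 2 validation1 0.9929687    40   160         3           2     ok
#> 3 validation2 0.9954545    30   220         3           2     ok
```

The screen recovered exactly the five planted signature genes with their
directions, and the resulting Glyco-MSI score separates MSI from MSS with
AUC ≈ 0.99 in each synthetic cohort (the planted effect is 0.8 log2 units
against noise SD 0.5). `res$survival` holds the median-split GALNT7
stratification (log-rank p, hazard ratio with 95% CI); `res$ihc_summary`
the MMR-stratified GALNT7-High proportions and PD-L1 contingency tests.
All stage outputs plus a run manifest land in `glycomsi_out/`.

The same run is available from a shell:

```sh
Rscript inst/scripts/glycomsi.R run --seed 3 --out glycomsi_out
```

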