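# folliclass

Distinguishing follicular thyroid carcinoma (FTC) from follicular thyroid
adenoma (FTA) is one of the hardest calls in thyroid pathology: the two
lesions differ only by capsular or vascular invasion, and their expression
profiles lie on a continuum. `folliclass` implements, as a tested and
reusable R pipeline, the analysis strategy used to search for mRNA markers
of that distinction and to ask how well a small gene panel can classify
follicular tumours from formalin-fixed (FFPE) material:

- **qPCR relative quantification** — efficiency-corrected Pfaffl ratios
  `Q(g,s) = E_g^(Ct_cal(g) − Ct(g,s))`, divided by a per-sample
  normalization factor `NF(s)` (geometric mean of the reference-gene
  quantities), with **geNorm** stability diagnostics (`M`, pairwise
  variation `V`) for the reference panel.
- **Outlier screening** — per-gene `Q3 + 6·IQR` rule for gross FFPE
  artefacts, reported as an advisory exclusion list.
- **Differential expression** — per-gene Student's *t*-test on log2 values
  with Benjamini–Hochberg FDR, and an additive two-way ANOVA
  (`expression ~ oncocytic + malignancy`, Type II sums of squares) that
  adjusts the malignancy contrast for the oncocytic (Hürthle-cell)
  subtype; plus the two-set microarray marker filter (mean > 4.5,
  variance above the 20th percentile, p < 0.001, |FC| ≥ 1.5, secondary
  p < 0.05) and PCA projection.
- **Vote-counting meta-analysis** — identifier harmonization to Entrez,
  within-study deduplication, cross-study tallies and direction-concordance
  classification of published FTC-vs-FTA gene lists (a reconstruction of
  the 14-study corpus ships with the package).
- **DLDA classification** — diagonal linear discriminant analysis with
  *t*-test gene selection, the selection threshold tuned inside a **doubly
  nested leave-one-out cross-validation** (outer loop for unbiased error,
  inner loop for tuning), confusion metrics with exact Clopper–Pearson 95%
  intervals, and a ROC curve whose trapezoidal AUC equals the Mann–Whitney
  statistic.
- **Synthetic data** — generators for qPCR cohorts (programmed fold
  changes, reference genes, oncocytic flags, Ct-scale Gaussian noise,
  planted outliers), microarray-style matrices and multi-study gene lists,
  so every stage has a ground-truth recovery test without any download.

## Worked example

Simulate an FFPE-like validation cohort (31 FTC vs 40 FTA, 15 target genes
with fold changes between 0.48 and 1.49, 3 reference genes, 0.25 cycles of
Ct noise) and run the full validation analysis:

```r
library(folliclass)
sim <- simulate_qpcr_dataset(qpcr_sim_params(seed = 7))
res <- run_qpcr_validation(sim$data, sim$annotation)
head(res$table, 4)
#>      gene fold_change      t_p      t_q  anova_p  anova_q
#> 1  ACVRL1       0.559 4.26e-21 2.13e-20 1.04e-17 3.89e-17
#> 2 ZFYVE21       0.697 1.51e-09 3.23e-09 2.99e-08 6.41e-08
#> 3  CLEC3B       0.800 1.18e-05 2.21e-05 1.01e-04 1.68e-04
#> 4 ZMYND11       0.813 8.60e-05 1.29e-04 1.64e-03 2.46e-03
```

The estimated linear FTC/FTA fold changes (0.559, 0.697, ...) recover the
programmed values (0.58, 0.69, ...) within simulation noise; `t_q` and
`anova_q` are the FDR-adjusted p-values of the *t*-test family and of the
oncocytic-adjusted ANOVA family.

Tally the packaged multi-study corpus:

```r
vt <- tally_votes(meta_study_reports())
vt[vt$count == 3, c("symbol", "count", "consensus_direction")]
#>     symbol count consensus_direction
#>        CA4     3                down
#>       EGR2     3                down
#>    SLC26A4     3                down
#>       TFF3     3                down
#>     KCNAB1     3                down
#>   FAM189A2     3                down
#>        CPQ     3                down
nrow(select_candidates(vt, min_count = 2, concordant_only = TRUE))
#> [1] 50
```

Seven genes are reported by three independent studies, all down-regulated
in carcinoma; fifty genes are reported at least twice with a concordant
direction.

Classifier metrics with exact binomial intervals, here from the confusion
counts of a 29-vs-40 validation cohort:

```r
confusion_metrics(list(tp = 22, fn = 7, tn = 32, fp = 8))
#>        metric  x  n estimate lower upper pct pct_lower pct_upper
#> 1    accuracy 54 69    0.783 0.667 0.873  78        67        87
#> 2 sensitivity 22 29    0.759 0.565 0.897  76        56        90
#> 3 specificity 32 40    0.800 0.644 0.909  80        64        91
```

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "folliclass-cli.R", package = "folliclass")`, with
subcommands `simulate`, `normalize`, `detest`, `metavote`, `classify` and
`roc`.

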