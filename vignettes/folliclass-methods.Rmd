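---
title: "Methods and design of the folliclass pipeline"
author: "folliclass maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the folliclass pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(folliclass)
```

# The problem

Follicular thyroid carcinoma (FTC) and follicular thyroid adenoma (FTA)
are distinguished histologically only by capsular or vascular invasion,
and their transcriptomes are nearly overlapping. `folliclass` packages the
statistical machinery for marker discovery and classification in this
setting: relative quantification of qPCR panels measured on degraded FFPE
RNA, differential-expression testing that accounts for the oncocytic
(Hürthle-cell) subtype, aggregation of published gene lists across
studies, and honest (nested) cross-validation of a small-panel classifier.

# qPCR normalization

## Pfaffl relative quantification

For gene $g$ and sample $s$ with amplification efficiency $E_g \in (1,2]$
(fold amplification per cycle; 2 = perfect doubling), the relative
quantity against a calibrator is

$$Q(g,s) = E_g^{\,Ct_{cal}(g) - Ct(g,s)}.$$

Target quantities are divided by the per-sample normalization factor
$NF(s)$, the geometric mean of the reference-gene quantities of that
sample. With a single reference this reduces to the classical
efficiency-corrected ratio $E_t^{\Delta Ct_t}/E_r^{\Delta Ct_r}$; with
several references it is the multi-reference convention of the geNorm
framework. Design choices:

* **Calibrator.** Defaults to the per-gene arithmetic mean Ct over all
  samples (equivalently, the geometric-mean sample on the quantity
  scale). No single sample is privileged; changing the calibrator only
  rescales each gene's row by a constant, so group fold changes are
  invariant (tested).
* **Missing efficiencies** default to 2.0 with a warning, since qPCR
  assays are designed to amplify near-perfectly; a measured $E$ should be
  supplied whenever available.
* **Technical replicates** collapse by the arithmetic mean of Ct before
  any ratio is formed.

## geNorm diagnostics

The stability measure of candidate reference $g$ is
$M(g) = \operatorname{mean}_{h \neq g}
\operatorname{sd}_s \log_2 \{Q(g,s)/Q(h,s)\}$; candidates are excluded
stepwise (largest $M$ first) until two remain. Because the validation
design fixes an explicit three-gene reference panel (EIF3A, EIF5, HADHA
analogues), `genorm_rank()` is a diagnostic, not an automatic selector:
the pipeline normalizes with the user-declared reference set, and the
geNorm trace (including the advisory pairwise variation $V_{n/n+1}$,
conventional cutoff 0.15) is there to justify or challenge that panel.

# Outlier rule and differential expression

Expression in FFPE material occasionally shows gross, assay-level spikes.
Per gene, cells above $Q_3 + k \cdot IQR$ (linear-interpolation quantiles,
default $k = 6$) are flagged, and a sample flagged in at least one gene is
listed for exclusion. The multiplier 6 is far beyond the 1.5 of
conventional box-plot whiskers, so ordinary biological spread never
triggers it: on clean simulated data the per-cell false-flag rate is
below 0.1%, while a planted spike of a few cycles is always caught
(tested). The report is advisory; `run_qpcr_validation()` applies it by
default but callers can keep all samples.

Testing is classical: per-gene equal-variance Student *t*-test on log2
values (a Welch switch is provided), linear fold change
$2^{\bar{x}_{FTC} - \bar{x}_{FTA}}$, and Benjamini–Hochberg adjustment.
The oncocytic adjustment is an additive two-factor linear model
`log2 expr ~ oncocytic + diagnosis` with the malignancy p-value from Type
II sums of squares — for an additive model, the partial F-test of
dropping `diagnosis` — which is the convention robust to the strong
imbalance of oncocytic frequency between classes (about 61% of FTC vs 15%
of FTA in the validation material). No interaction term is fitted: the
scientific question is the malignancy contrast adjusted for subtype, and
the per-gene sample sizes would not support stable interaction estimates.
BH is applied separately within the *t*-test family and the ANOVA family,
mirroring how the two analyses are reported side by side. Genes with
missing values (assays that failed to amplify) are dropped and reported,
never imputed.

The microarray two-set filter retains genes that pass, in the primary
(concordantly diagnosed) dataset, all of: normalized mean expression
above 4.5, variance above the 20th percentile of gene variances, raw
$p < 0.001$, and fold change at least 1.5 in either direction — and that
also reach $p < 0.05$ in the secondary (less certain) dataset. The filter
is a conjunction; relaxing any criterion is a caller decision.

# Vote-counting meta-analysis

Published FTC-vs-FTA gene lists use heterogeneous identifiers. The
pipeline maps them through a user-supplied static identifier table
(many-to-one onto Entrez-style ids) — never a live lookup, trading
freshness for reproducibility. Within a study, aliases collapse to one
record; a study reporting the same gene in both directions is treated as
unusable for that gene and dropped with a log line (the literature corpus
this machinery was built for contains no such case, so any convention is
defensible; dropping is the conservative one). Tallies count supporting
studies per gene; direction concordance is required before a consensus
direction is assigned, and discordant genes are excluded from candidate
selection while remaining visible in the table. The packaged
reconstruction of the 14-study corpus (107 study-gene records covering
the 50 multiply-reported genes) feeds the acceptance checks: seven genes
reach three supporting studies, all down-regulated in carcinoma.

# DLDA and nested cross-validation

Diagonal linear discriminant analysis models each class as a Gaussian
with class-specific per-gene means and a shared diagonal covariance (the
pooled within-class variance, denominator $n - 2$, floored at $10^{-8}$
times the median pooled variance against degenerate constant genes). The
posterior

$$P(FTC \mid x) = \frac{\pi_{FTC} \prod_g N(x_g;\, \mu_{FTC,g},
\sigma^2_g)}{\sum_c \pi_c \prod_g N(x_g;\, \mu_{c,g}, \sigma^2_g)}$$

is evaluated in log space. Priors default to the empirical class
proportions (the designs this targets are unbalanced); an equal-prior
option exists.

Performance is estimated by a doubly nested leave-one-out
cross-validation: the outer loop holds out one sample for testing; the
inner loop, a second LOOCV over the remaining $n-1$, tunes the gene
selection threshold $\alpha$ over a grid (default
$\{10^{-4}, 5\times10^{-4}, 10^{-3}, 5\times10^{-3}, 10^{-2},
5\times10^{-2}\}$, which brackets the $5\times10^{-4}$ threshold a
four-gene FFPE panel emerges at), with the *t*-test recomputed inside
every inner training fold. Ties in inner accuracy resolve to the smallest
$\alpha$ — the most parsimonious panel. If no gene passes a threshold the
single smallest-p gene is used, so a model always exists. Class calls use
a 0.5 posterior cutoff; the ROC curve exposes the full threshold sweep,
and its trapezoidal AUC equals the Mann–Whitney statistic exactly
(tested to $10^{-12}$).

The implementation computes inner folds from downdated sufficient
statistics (class sums and sums of squares with one sample removed,
clamped at zero against cancellation), which is algebraically identical
to refitting and is verified against a naive loop-based implementation in
the test suite.

Confidence intervals for accuracy, sensitivity and specificity are exact
Clopper–Pearson intervals from beta quantiles. This choice is an
inference from the reported interval arithmetic of the study this
pipeline reconstructs — Wilson or normal-approximation intervals do not
reproduce those printed bounds, Clopper–Pearson does. Reported
percentages round half-away-from-zero to whole percent (base R's
round-half-even would disagree at exact halves); unrounded proportions
are always retained. Accuracy can be stratified (e.g. oncocytic vs
non-oncocytic) via the `strata` argument.

## A note on null behavior of nested LOOCV

On label-permuted (null) data the mean LOOCV accuracy of this procedure
falls systematically *below* the majority-class rate. This is not a bug:
removing the held-out sample shifts its own class mean away from it, so a
mean-based classifier anti-learns on null data, and smallest-$\alpha$
tie-breaking concentrates the model on the single most spuriously
correlated gene, which maximizes the effect. The acceptance suite
measures this calibration directly; the package reports the measured
value rather than forcing it toward the chance rate.

# The synthetic-data module

The generators are first-class, tested code, and their defaults *are* the
validation-study conditions:

* `qpcr_sim_params()`: 31 FTC vs 40 FTA; 15 target genes whose FTC/FTA
  fold changes (0.48–1.49) reproduce the observed validation panel; three
  reference genes with fold change 1; oncocytic flags drawn per class at
  61.3% / 15%; Gaussian Ct noise, default sd 0.25 cycles (log-normal on
  quantities, matching qPCR error structure); per-gene baseline Ct
  uniform in [20, 30] (arbitrary — it cancels in Pfaffl ratios);
  efficiencies default to 2.0 unless specified. The study does not report
  per-gene Ct variance for its FFPE material, so the noise default is a
  choice, not a fit. The default oncocytic effect is zero so that the
  marginal FTC/FTA contrast equals the programmed fold change exactly;
  a per-gene log2 shift can be switched on to exercise the ANOVA
  adjustment.
* One master seed; sub-streams (baselines, oncocytic flags, noise) derive
  child seeds by fixed offsets, so adding a stream never perturbs earlier
  ones and all outputs are byte-reproducible.
* `simulate_expression_matrix()` and `simulate_study_collection()`
  provide microarray-style matrices with planted effects and per-study
  gene lists realizing exact planted vote counts.

**What the simulations do not show.** The qPCR generator models
*technical* noise only. Real follicular tumours add biological
heterogeneity that dwarfs 0.25 cycles, so simulated cohorts separate far
more cleanly than real FFPE cohorts, where small-panel classifiers
plateau near 80% accuracy. Passing recovery tests demonstrates correctness
of the arithmetic (normalization, testing, cross-validation bookkeeping),
not expected field performance. Likewise the generator draws genes
independently, whereas real expression is correlated; and no
fluorescence-curve, melt-curve or probe-level artefacts are simulated.

# Numerical conventions and problem sizes

* Quantiles use linear interpolation between order statistics
  (`type = 7`), documented because Q3/IQR feed a hard exclusion rule.
* Monte-Carlo suites in the tests use 100–200 replicate seeds and cohorts
  of 30 + 40 samples over 10–15 genes (panel-sized), and 1000 genes for
  type-I calibration — sizes at which the binomial/Monte-Carlo error of
  each checked proportion is well below the asserted tolerance.
* `log_transform()` refuses non-positive values by listing the offending
  cells; nothing is floored silently.
* TSV (tab, UTF-8, '.' decimal) is the only I/O dialect; floats are
  written at 6 significant digits, and writers are byte-stable across
  reruns.

# Known limitations

* The microarray branch consumes already-normalized matrices; probe-level
  preprocessing and array QC are out of scope.
* The identifier map is a static snapshot supplied by the user; stale
  maps silently reflect their vintage (by design).
* The optional check against the deposited microarray accession
  (GSE82208) requires a download and is not part of the default suite;
  preprocessing-version drift is expected if it is attempted.
* Classifier machinery is binary (FTC vs FTA) and Gaussian-diagonal;
  multi-class extensions or correlated-feature discriminants are not
  provided.
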