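# microMetab

Desk-scale analysis stack for **low-input LC–MS metabolomics, untargeted
lipidomics and ¹³C stable-isotope tracing of rare sorted cell populations**
(for example haematopoietic stem and progenitor cells sorted by FACS in the
thousands), plus metabolome–transcriptome integration. It is aimed at
analysts who receive feature-by-sample peak-area tables from upstream peak
picking and need a reproducible, tested path from raw AUC tables to
differential-abundance calls, lipid class statistics, tracer incorporation
fractions and pathway-level multi-omics summaries.

## What it computes

**Detection above process blanks.** Sorted-cell extracts carry background
from sheath fluid and plasticware, monitored by process-blank (NC) samples.
Per experiment, missing values of a feature seen in at least one sample are
set to 0 (a feature entirely missing in an experiment keeps its `NA`s); a
feature is screened in when some condition mean exceeds the blank mean.
After technical replicates are averaged into one value per biological
replicate, pooled condition values are tested against pooled blanks — a
Shapiro–Wilk gate chooses Student's *t* or the Wilcoxon rank-sum test — and
a feature is detected when the one-sided *P* < 0.1, its mean abundance
exceeds 100 in some condition, and it is non-zero in ≥ 3 biological
replicates of every condition.

**Differential abundance.** Normality-adaptive two-sided tests (paired for
same-donor designs), log₂ fold changes with infinities clamped to the
dataset's finite extrema, and covariate-adaptive FDR: weighted
Benjamini–Hochberg with bin weights learned from average feature intensity,
reducing exactly to BH for a constant covariate. Significance is called at
adjusted *P* < 0.05.

**Lipid nomenclature and class statistics.** A parser for shorthand names
(`PC O-34:2`, `SM 38:1;O2`, `PE 16:0_18:1`), isomer merging on (normalized
name, formula) with per-sample summation, the m/z ≥ 300 & RT ≥ 2 min
feature filter, class/subclass sums (SM split short/long at 36 carbons;
other classes saturated / monounsaturated / polyunsaturated at 0/1/≥2
double bonds), and "Lipheat" ranking of the top species by fold change.

**¹³C tracing.** Theoretical mass-isotopologue distributions
M+k with binomial natural abundance on unlabelled carbons
(fraction at M+(k+j) = C(n−k, j) p^j (1−p)^(n−k−j), p = 0.0107), natural-
abundance correction by **non-negative least squares** against those
theoretical columns, labelled/unlabelled ratios x_k/x₀, shared
chromatographic integration windows across isotopologues, MS2 confirmation
filtering (15 s / 1 mDa), and internal-standard absolute quantification
with type-1 (monoisotopic-fraction) isotope correction.

**Integration.** Per-pathway enzyme–metabolite Pearson correlations;
metabolograms (pathways need ≥ 5 detected enzymes and ≥ 1 measured
metabolite; centres are mean log₂FCs with one-sample Wilcoxon signed-rank
*P*-values); and univariate-linear-model TF activity, the slope
*t*-statistic of gene statistics regressed on regulon weights.

**Synthetic data.** Seeded generators emulate every input with recorded
ground truth (paired designs with batches, blanks, technical replicates and
missingness; lipid grids with isomer duplicates; isotopologue tables from
known labelled fractions; regulon/pathway inputs), so every pipeline stage
has parameter-recovery tests.

## Worked example

```r
library(microMetab)

g   <- genMetabolomics(1, nPairs = 14)      # paired HSPC vs progenitor design
g$table
#> FeatureTable: 80 features x 65 samples
#>   roles: blank=9, technical=56
#>   conditions: HSPC, Prog
#>   experiments: exp1, exp2, exp3
#>   missing values: 274

det <- detectFeatures(g$table)              # blank screen + test + thresholds
#> [INFO] detectFeatures: 80 features in, 73 finally detected
res <- differentialAbundance(det$table, "HSPC", "Prog", paired = TRUE)
head(as.data.frame(res[order(res$padj), c("feature_id","log2fc","padj")]), 3)
#>   feature_id    log2fc         padj
#> 1     met015 -2.234469 1.333403e-05
#> 2     met012 -1.882262 2.103742e-05
#> 3     met009 -2.141898 7.760577e-05
sum(res$significant)
#> [1] 8
```

73 of 80 simulated features pass the detection gauntlet (the blank-level
background features fail the blank test), and the 8 features carrying an
injected |log₂FC| = 2 effect are the significant calls, with the correct
sign. Tracer correction works the same way on real or simulated MDVs:

```r
cm  <- buildCorrectionMatrix(5, 0.0107)        # 5-carbon compound, e.g. choline
obs <- c(53000, 2900, 120, 22500, 700, 10)     # raw isotopologue areas
corr <- correctNaturalAbundance(obs, cm, compoundId = "choline",
                                labelIndex = 3L)
corr
#> MDV 'choline' (5 carbons, label M+3, corrected fractions):
#>       M+0       M+1       M+2       M+3       M+4       M+5
#> 7.059e-01 4.458e-04 7.370e-04 2.901e-01 2.722e-03 6.388e-05
labelledFraction(corr)                         # M+3 / M+0
#> [1] 0.411

extractionCalculator(5000, 1, 15, c("2-propanol" = 2, acetonitrile = 1))
#> ExtractionSummary: final volume 20 ul (sheath 5 ul)
#>   composition: 2-propanol 50.0%, acetonitrile 25.0%, water 25.0%
```

The corrected M+1/M+2 fractions are near zero because natural ¹³C
satellites of the M+0 species have been attributed back to it; the 0.29 at
M+3 is tracer incorporation. The volume calculator reproduces the FACS
bookkeeping: 5,000 cells × 1 nl droplets add 5 µl of sheath water to 15 µl
of 2:1 buffer, giving a 20 µl extract at 50/25/25%.

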