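---
title: "Statistical methods for low-input sorted-cell metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for low-input sorted-cell metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microMetab)
```

# Scope and data model

microMetab covers the analysis that begins *after* peak picking: feature ×
sample peak-area tables (AUC, linear scale) from targeted MRM metabolomics
or annotated untargeted lipidomics of FACS-sorted cell populations, plus
isotopologue intensity tables for ¹³C tracing and gene-level statistics for
integration. The central container, `FeatureTable`, extends
`SummarizedExperiment`: the `areas` assay holds peak areas with `NA` as the
explicit missing-value code (missing is *not* zero — zero is assigned only
by the imputation rule below), `colData` carries the design (role, condition,
subject, technical-replicate group, experiment batch, freezing condition,
age) and `rowData` the feature annotation (name, formula, m/z, RT).

Because equal cell numbers are sorted per sample, no global scaling or
normalization is applied anywhere in the pipeline; the only normalization is
the explicit per-batch mean division used for fresh-vs-frozen processing
differences.

# Detection above process blanks

Sheath fluid and plasticware contribute real chemical background, so
"detected" is defined against process blanks (NC), in four stages:

1. **Imputation, per experiment.** A feature observed in ≥ 1 sample of an
   experiment has its missing values in that experiment set to 0; a feature
   entirely missing in an experiment keeps its `NA`s. Rationale: within an
   experiment a missing scan for an otherwise-present compound is
   non-detection, while an all-missing feature may simply not have been
   monitored there.
2. **Blank-mean screen, per experiment.** A feature passes when at least one
   condition mean strictly exceeds the blank mean. The screen is a cheap
   one-sided filter; a feature passing in **any** experiment proceeds. The
   per-experiment wording could also be read as "must pass in every
   experiment"; we chose *any* because the screen only nominates candidates
   — the significance test below is the real gate — and requiring unanimity
   would silently discard compounds absent from a single batch.
3. **Technical-replicate averaging.** Arithmetic mean over non-missing
   technical values per biological replicate; an all-missing group stays
   missing.
4. **Blank significance test, pooled across experiments.** Condition values
   (technically averaged) are pooled and compared with pooled blanks,
   one-sided (condition > blank), at level `alpha = 0.1`. A Shapiro–Wilk
   test at level 0.05 on each group gates Student's *t* (both normal) vs the
   Wilcoxon rank-sum test; when normality is undefined (constant values or
   n < 3) the rank test is used. The direction is one-sided because only
   *excess over background* is evidence of detection.
5. **Thresholds.** Mean abundance strictly `> 100` (intensity units) in at
   least one condition, and value `> 0` in `>= 3` biological replicates of
   *every* condition. "Detected in a replicate" means non-zero after
   imputation, since imputation makes 0 the explicit non-detection code.

The tunable parameters are `alpha` (0.1), `minMean` (100, same units as the
areas) and `minReps` (3). All were chosen as the field-standard operating
point for this assay class and are arguments, not constants.

**Degenerate inputs.** An experiment without blanks is a configuration
error; an all-`NA` feature fails every gate but flows through without
special-casing; all-constant groups fall to the rank test (logged).

# Lipid nomenclature, merging and the feature filter

Shorthand names follow `<CLASS>[ O-]<C>:<DB>[;O<k>]`, optionally
chain-resolved with `/` (sn-order known) or `_` (unknown). Normalization
fixes one space after the class token and no whitespace around `:`/`;`,
because identity matching across experiments is *string* matching and
export dialects vary. The `;O<k>` suffix is part of the normalized identity:
hydroxylation distinguishes species, so dropping it would merge distinct
lipids. Chain-resolved names are **not** collapsed to species totals —
`PC 16:0_18:1` and `PC 34:1` carry different information and stay distinct.
Unknown class tokens parse as `other` with totals intact, keeping the
pipeline open to new classes.

Isomer merging sums areas per sample over rows sharing (normalized name,
formula); `NA + x = x` and all-`NA` stays `NA`, so column sums (ignoring
missing) are invariant. Rows sharing a name but conflicting in formula are
flagged and left unmerged rather than guessed at.

Features with m/z < 300 **or** RT < 2 min are removed. The rule's prose
("below 300 and below 2 min") could be read conjunctively; we remove on
either criterion because both regions are individually dominated by
non-lipid signal in reversed-phase positive mode, and we state the choice
here rather than change it silently. Features lacking m/z or RT are removed
with a warning.

Subclasses: SM by total chain length (short < 36, long ≥ 36 carbons; the
boundary belongs to "long"), all other classes by saturation (0 / 1 / ≥ 2
double bonds). Class and subclass statistics use **per-sample sums**
(missing as 0 post-imputation) — a replicate-based test needs per-sample
values, and the mean of per-sample sums equals the sum of per-condition
average AUC, the quantity displayed. Ether-linked PC/PE count as their own
classes throughout.

# Differential statistics

Tests are two-sided and normality-adaptive: for paired designs the
Shapiro–Wilk gate (0.05) runs on paired differences and selects paired *t*
vs signed-rank (zeros dropped, the standard convention); unpaired designs
gate on each group. Features with fewer than 3 values per group are
excluded from testing and FDR.

Log₂ fold changes are `log2(mean_A / mean_B)`; per-replicate matrices use
paired ratios or replicate-vs-reference-mean ratios. A zero denominator or
numerator yields ±Inf, which is clamped to the dataset's maximum/minimum
finite log₂FC so every reported value is finite and bounded by the observed
dynamic range; 0/0 is missing.

**Covariate-adaptive FDR.** `adaptiveFdr()` is weighted Benjamini–Hochberg
with weights learned from a covariate (average feature intensity):
features are cut into `nbins = 4` covariate quantile bins, each bin's
non-null fraction is estimated as `1 − π₀` with Storey's estimator at
`λ = 0.5`, weights proportional to it (floored at 0.01 so no bin is
permanently silenced) are normalized to mean 1, and BH runs on `p/w`.
Guard rails: a constant covariate (or no bin showing signal, max non-null
fraction ≤ 0.02) reduces *exactly* to `p.adjust(..., "BH")`, bit for bit;
adjusted values are monotone in p within a bin. This design was chosen
because intensity-dependent power is the motivation for covariate-adaptive
correction, while exact BH equivalence under an uninformative covariate
makes the procedure auditable. It does not attempt to reproduce any
specific published adaptive-FDR package's numbers.

Lipheat ranking orders features by mean log₂FC descending with lexicographic
`feature_id` tie-breaks and takes the top `k = 30` per direction. Age
correlation is the Pearson test (*t* distribution on n − 2 df) plus the
least-squares line. Sample PCA is a thin wrapper over centred
`stats::prcomp` — no bespoke mathematics.

# ¹³C tracing

For a compound with `n` carbons and tracer label M+k, the theoretical
isotopologue distribution places binomial natural abundance
(`p13c = 0.0107`, configurable) on the `n − k` unlabelled carbons. The
correction matrix has these distributions as columns; an observed intensity
vector is decomposed by **non-negative least squares**
(`pracma::lsqnonneg`) and the solution normalized to sum 1. NNLS rather
than the unconstrained solve because negative isotopologue fractions are
unphysical and the constraint materially stabilizes low-intensity channels.
Only ¹³C is corrected in the MDV: the tracer is ¹³C and, at QTOF
resolution, fine-structure isotopes of other elements are treated as
unresolved contributors that cancel in the fraction normalization.
Other-element abundances enter only through the monoisotopic-fraction
("type 1") correction for absolute quantification, computed by convolving
CHNOPS per-element isotope distributions and taking the zero-shift term.

The labelled fraction reported is `x_k / x₀` (ratio of labelled to
non-labelled); `x₀ = 0` is flagged rather than returning infinity.

Shared integration windows are found on the *summed* trace of all
isotopologues: from the apex, descend each side until the signal reaches 1%
of the apex or the first local minimum, whichever comes first — a boundary
definition this package fixes explicitly, since "identical borders for all
isotopologues" leaves the stopping rule open. Every isotopologue is then
trapezoid-integrated over that identical window, which is what guarantees
unbiased isotopologue *ratios* even when individual traces are noisy. MS2
confirmation keeps features with a confirmed event within 15 s and 1 mDa.

# Integration

Enzyme–metabolite Pearson correlations run over all pathway co-member
pairs across shared (subject-paired) samples; pairs with < 3 shared
samples or zero variance are skipped. Metabolograms require ≥ 5 detected
enzymes and ≥ 1 measured metabolite; centres are the arithmetic means of
slice log₂FCs with a two-sided one-sample Wilcoxon signed-rank *P* against
0 — the one-sample variant is the only Wilcoxon defined on a single set of
fold changes, and genes and metabolites get *separate* centres because the
two halves answer different questions (the plot shows them separately).
"Detected" for eligibility means present in the supplied gene-statistics
table, i.e. the upstream expression filter is accepted as input metadata.

TF activity is the univariate linear model: the gene statistic regressed on
the TF's target weights embedded in the full gene vector with zeros for
non-targets; the score is the slope *t*-statistic (equivalently
`t = r·sqrt((n−2)/(1−r²))`), positive for activation, negative for
repression. Activities are ranked by |score| after a *P* < 0.05 filter,
top 7 per direction, lexicographic ties.

# Synthetic data: what it emulates, and what passing tests show

The generators are pure functions of (seed, parameters) — regeneration is
bit-identical — and each records its ground truth.

* `genMetabolomics()`: log-normal areas with subject random effects
  (sd 0.3 on the log scale), experiment batch effects (sd 0.2), biological
  noise (sd 0.35), technical noise (sd 0.1), feature-specific blank
  background around `blankLevel = 200`, missing-at-random (5%) plus
  censoring below a tenth of the blank level, and one feature forced
  all-missing in one experiment. Defaults mirror the paired design of the
  assay this stack targets: 17 subject pairs, 3 experiments, 2 technical
  replicates, 10% of features carrying |log₂FC| = 2, 10% blank-level
  background. Recovery tests run at 14 pairs, the lipidomics-scale cohort.
* `genLipidomics()`: a class × carbons × double-bond grid (PC, PC O-, PE,
  PE O-, SM;O2, TG, LPC, CAR) with internally consistent synthetic
  formulas and [M+H]⁺ m/z, RT increasing in chain length; carnitines
  deliberately violate the m/z ≥ 300 / RT ≥ 2 min filter; isomer
  duplicates, one chain-resolved/species-level name pair sharing a formula,
  and one same-name formula conflict exercise every merge branch.
  Injected truths: long-chain SM up (+1.5) and polyunsaturated PC down
  (−1) in the first condition.
* `genTracing()`: observed MDVs `M·((1−L)e₀ + L e_k)` scaled and
  multiplied by log-normal noise (CV 1%), for an M+3 choline-pathway panel
  plus an unlabelled control; optional Gaussian chromatograms on a shared
  RT axis.
* `genRegulonExpression()`: gene statistics as active-TF weight sums plus
  noise; pathways with exactly 4 and exactly 5 enzymes probe the
  metabologram eligibility boundary, and one pathway has no metabolites.

What passing recovery tests **do** show: the implementations invert their
own generative models at realistic effect sizes, noise levels and cohort
sizes, and agree with independent brute-force/closed-form oracles. What
they **do not** show: robustness to chromatographic drift, co-eluting
interferences, heavy-tailed contamination, informative missingness beyond
simple censoring, or annotation errors — real LC–MS data contain all of
these, and the detection thresholds here are necessary but not sufficient
safeguards.

# Numerical choices and problem sizes

Isotope-correction recovery is asserted to 1e-9 over the full grid
n ≤ 20, k ≤ n, p ∈ {0, 0.0107, 0.05}; corrected fractions must sum to 1
within 1e-9. Results tables round-trip through text at ≥ 12 significant
digits (written with 15). Monte-Carlo checks use fixed seeds with
3-standard-error acceptance bands: 200–500 replicates for calibration
checks, 500 replicates per labelled fraction for tracing recovery, 50
seeded tables for the detection-oracle equivalence, and 10 pooled
replicates of the default recovery scenario for sensitivity/FDP — sizes
chosen so each estimate's MC error is small against the property being
asserted while the whole suite stays interactive. Ties everywhere break
lexicographically; weighted-BH arithmetic follows `p.adjust`'s operation
order so the constant-covariate case is exactly, not approximately, BH.

# Known limitations

* The blank screen's any-experiment rule and the OR-form feature filter are
  documented interpretations of ambiguous prose; both are stated above and
  in the relevant function documentation.
* The covariate-adaptive FDR is a transparent binned weighted BH, not a
  reimplementation of any specific adaptive-FDR package; with strongly
  informative covariates its power gain is modest compared with dedicated
  methods.
* MDV correction is carbon-only by design; resolution-aware correction for
  non-carbon fine structure is out of scope.
* The sample-preparation calculator reports NaCl mass carried by sheath
  fluid but makes no claim about final w/v percentages, whose published
  values are not internally consistent with the stated sheath composition.
* sn-position and double-bond-position isomers are not resolved; lipid
  ontology mapping is out of scope.
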