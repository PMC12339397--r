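## Normality-adaptive differential abundance, Inf-clamped log2 fold changes,
## covariate-adaptive FDR, lipid class sums, Lipheat ranking, age correlation.

#' Normality-adaptive two-sample test
#'
#' A Shapiro-Wilk gate (level `shapiroAlpha`) chooses between the Student
#' t-test and the Wilcoxon test: for paired designs the gate runs on the
#' paired differences and selects the paired t-test vs the signed-rank test
#' (zero differences dropped, signed-rank convention); for unpaired designs
#' it runs on each group and both must look normal to use the t-test.
#' Normality undefined (constant values or n < 3) falls through to the rank
#' test. Two-sided p-values.
#'
#' @param x condition values
#' @param y reference values (aligned with `x` when `paired`)
#' @param paired logical
#' @param shapiroAlpha normality-gate level (default 0.05)
#' @return list with `p` (NA when fewer than 3 values per group) and
#'   `test_used` ("t" or "wilcoxon")
#' @export
normalityAdaptiveTest <- function(x, y, paired = FALSE,
                                  shapiroAlpha = 0.05) {
    if (paired) {
        stopifnot(length(x) == length(y))
        keep <- !is.na(x) & !is.na(y)
        x <- x[keep]; y <- y[keep]
        if (length(x) < 3L)
            return(list(p = NA_real_, test_used = NA_character_))
        d <- x - y
        if (all(d == 0))
            return(list(p = 1, test_used = "wilcoxon"))
        useT <- isTRUE(.shapiroNormal(d, shapiroAlpha))
        p <- if (useT) stats::t.test(x, y, paired = TRUE)$p.value
             else suppressWarnings(
                 stats::wilcox.test(x, y, paired = TRUE))$p.value
    } else {
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) < 3L || length(y) < 3L)
            return(list(p = NA_real_, test_used = NA_character_))
        useT <- isTRUE(.shapiroNormal(x, shapiroAlpha)) &&
                isTRUE(.shapiroNormal(y, shapiroAlpha))
        p <- if (useT) stats::t.test(x, y)$p.value
             else suppressWarnings(stats::wilcox.test(x, y))$p.value
    }
    if (is.na(p)) p <- 1
    list(p = p, test_used = if (useT) "t" else "wilcoxon")
}

#' Log2 fold changes with Inf clamping
#'
#' `computeLog2fc` returns elementwise `log2(a / b)` (mode
#' `"paired_per_replicate"`) or `log2(a / mean(b))` (mode
#' `"vs_reference_mean"`). Ratios of 0/0 become missing. `clampLog2fc`
#' replaces +Inf by the maximum finite log2FC in the dataset and -Inf by the
#' minimum, so every reported fold change is finite and bounded by the
#' dataset's finite extrema.
#'
#' @param a abundances of the condition of interest (>= 0)
#' @param b reference abundances (>= 0)
#' @param mode fold-change mode, see above
#' @return numeric vector of log2 fold changes (possibly infinite; apply
#'   [clampLog2fc()] across the dataset)
#' @export
computeLog2fc <- function(a, b,
                          mode = c("paired_per_replicate",
                                   "vs_reference_mean")) {
    mode <- match.arg(mode)
    if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
        stop("abundances must be >= 0")
    denom <- if (mode == "vs_reference_mean") mean(b, na.rm = TRUE) else b
    out <- log2(a / denom)
    out[is.nan(out)] <- NA_real_   # 0/0
    out
}

#' @rdname computeLog2fc
#' @param x numeric vector (or matrix) of log2 fold changes
#' @export
clampLog2fc <- function(x) {
    fin <- x[is.finite(x)]
    if (!length(fin)) {
        x[is.infinite(x)] <- NA_real_
        return(x)
    }
    x[x == Inf] <- max(fin)
    x[x == -Inf] <- min(fin)
    x
}

#' Covariate-adaptive false discovery rate control
#'
#' Weighted Benjamini-Hochberg with weights learned from a covariate
#' (typically the feature's average intensity): features are split into
#' `nbins` covariate quantile bins, the non-null fraction of each bin is
#' estimated as `1 - pi0` (Storey, `lambda = 0.5`), and bin weights
#' proportional to it (floored, then normalized to mean 1 over features)
#' rescale the p-values before BH. With a constant covariate (or when no
#' bin shows signal) the procedure reduces exactly to Benjamini-Hochberg.
#' Missing p-values propagate as missing and do not count toward the number
#' of tests.
#'
#' @param pvalues numeric vector of raw p-values (NA allowed)
#' @param covariate numeric covariate, same length (ignored for NA p)
#' @param nbins number of quantile bins (default 4)
#' @param lambda Storey pi0 tuning parameter (default 0.5)
#' @return numeric vector of adjusted p-values (same length as input)
#' @export
adaptiveFdr <- function(pvalues, covariate = NULL, nbins = 4,
                        lambda = 0.5) {
    padj <- rep(NA_real_, length(pvalues))
    valid <- which(!is.na(pvalues))
    m <- length(valid)
    if (m < 2L) {
        if (m == 1L) {
            warning("fewer than 2 valid p-values; passthrough")
            padj[valid] <- pvalues[valid]
        }
        return(padj)
    }
    p <- pvalues[valid]
    w <- rep(1, m)
    if (!is.null(covariate) && m >= 2L) {
        cv <- covariate[valid]
        if (anyNA(cv) || any(!is.finite(cv)))
            stop("covariate must be finite for all tested features")
        br <- unique(stats::quantile(cv, probs = seq(0, 1,
                                                     length.out = nbins + 1)))
        if (length(br) >= 3L) {
            bins <- cut(cv, br, include.lowest = TRUE)
            nonnull <- tapply(p, bins, function(pb) {
                max(0, 1 - min(1, mean(pb > lambda) / (1 - lambda)))
            })
            if (max(nonnull, na.rm = TRUE) > 0.02) {
                wb <- pmax(nonnull, 0.01)
                w <- wb[as.integer(bins)]
                w <- w / mean(w)
            }
        }
    }
    q <- pmin(p / w, 1)
    # BH step-up, same arithmetic order as stats::p.adjust
    o <- order(q, decreasing = TRUE)
    adj <- pmin(1, cummin(m / seq(m, 1) * q[o]))
    padj[valid][o] <- adj
    padj
}

#' Differential abundance between two conditions
#'
#' Per detected feature: the normality-adaptive test (paired when the
#' samples originate from the same biological individuals, matched by
#' `subject_id`), the log2 fold change of condition means (clamped across
#' the dataset so 0-driven infinities map to the dataset extrema), and
#' covariate-adaptive FDR with the feature's average intensity as
#' covariate. Features with fewer than 3 values per group are excluded from
#' FDR (p and padj missing, logged).
#'
#' @param table a [FeatureTable-class] of biological samples (detection
#'   pipeline applied, technical replicates collapsed)
#' @param conditionA condition of interest
#' @param conditionB reference condition
#' @param paired logical; match samples by `subject_id`
#' @param alpha significance level on adjusted p (default 0.05)
#' @return a [DifferentialResult-class]
#' @export
differentialAbundance <- function(table, conditionA, conditionB,
                                  paired = FALSE, alpha = 0.05) {
    cd <- colData(table)
    bio <- cd$role == "biological"
    jA <- which(bio & cd$condition == conditionA)
    jB <- which(bio & cd$condition == conditionB)
    if (!length(jA) || !length(jB))
        stop("conditions not found: ", conditionA, " / ", conditionB)
    if (paired) {
        subj <- intersect(cd$subject_id[jA], cd$subject_id[jB])
        jA <- jA[match(subj, cd$subject_id[jA])]
        jB <- jB[match(subj, cd$subject_id[jB])]
    }
    v <- areas(table)
    rd <- rowData(table)
    n <- nrow(table)
    res <- data.frame(
        feature_id = rd$feature_id,
        name = rd$name,
        class = if ("lipid_class" %in% colnames(rd)) rd$lipid_class else "",
        log2fc = NA_real_, pvalue = NA_real_, padj = NA_real_,
        test_used = NA_character_, paired = paired,
        mean_A = NA_real_, mean_B = NA_real_, detected_flag = TRUE,
        covariate = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
        x <- v[i, jA]; y <- v[i, jB]
        tt <- normalityAdaptiveTest(x, y, paired = paired)
        res$pvalue[i] <- tt$p
        res$test_used[i] <- tt$test_used
        res$mean_A[i] <- mean(x, na.rm = TRUE)
        res$mean_B[i] <- mean(y, na.rm = TRUE)
        res$covariate[i] <- mean(c(x, y), na.rm = TRUE)
    }
    nNoTest <- sum(is.na(res$pvalue))
    if (nNoTest)
        mmLog("INFO", "%d features excluded from FDR (n < 3)", nNoTest)
    res$log2fc <- clampLog2fc(log2(res$mean_A / res$mean_B))
    res$log2fc[is.nan(res$log2fc)] <- NA_real_
    tested <- !is.na(res$pvalue)
    res$padj[tested] <- adaptiveFdr(res$pvalue[tested],
                                    res$covariate[tested])
    res$significant <- !is.na(res$padj) & res$padj < alpha
    res$covariate <- NULL
    new("DifferentialResult", DataFrame(res))
}

#' Per-replicate log2 fold-change matrix
#'
#' For paired designs: the log2FC between each paired biological sample of
#' the two conditions. Otherwise: the log2FC between each biological
#' replicate of the condition of interest and the mean abundance of the
#' other condition. Infinities are clamped to the finite extrema of the
#' whole matrix.
#'
#' @inheritParams differentialAbundance
#' @return numeric matrix, features x replicates
#' @export
perReplicateLog2fc <- function(table, conditionA, conditionB,
                               paired = FALSE) {
    cd <- colData(table)
    bio <- cd$role == "biological"
    jA <- which(bio & cd$condition == conditionA)
    jB <- which(bio & cd$condition == conditionB)
    v <- areas(table)
    if (paired) {
        subj <- intersect(cd$subject_id[jA], cd$subject_id[jB])
        jA <- jA[match(subj, cd$subject_id[jA])]
        jB <- jB[match(subj, cd$subject_id[jB])]
        out <- log2(v[, jA, drop = FALSE] / v[, jB, drop = FALSE])
        colnames(out) <- subj
    } else {
        refMean <- rowMeans(v[, jB, drop = FALSE], na.rm = TRUE)
        out <- log2(v[, jA, drop = FALSE] / refMean)
        colnames(out) <- cd$sample_id[jA]
    }
    out[is.nan(out)] <- NA_real_
    clampLog2fc(out)
}

#' Lipid class and subclass sum statistics
#'
#' Summed peak areas per lipid class and per canonical subclass (SM split
#' by chain length, all other classes by saturation; ether-linked PC/PE are
#' their own classes). Sums are per biological sample with missing values
#' treated as zero (post-imputation convention); significance uses the
#' normality-adaptive test on the per-sample sums with the design's
#' pairing, and the adaptive FDR runs across all classes and subclasses
#' jointly.
#'
#' @inheritParams differentialAbundance
#' @return list with `sums` (numeric matrix, groups x biological samples)
#'   and `stats` (a [S4Vectors::DataFrame] with label, level, per-condition
#'   totals of average AUC, pvalue, padj)
#' @export
classSubclassSums <- function(table, conditionA, conditionB,
                              paired = FALSE) {
    rd <- rowData(table)
    ann <- lapply(rd$name, parseLipidName)
    className <- vapply(ann, function(a)
        paste0(a@classToken, if (a@ether) " O-" else ""), character(1L))
    subName <- vapply(ann, canonicalSubclass, character(1L))
    cd <- colData(table)
    bio <- which(cd$role == "biological")
    v <- areas(table)[, bio, drop = FALSE]
    v[is.na(v)] <- 0
    groups <- c(split(seq_len(nrow(table)), className),
                split(seq_len(nrow(table)), subName))
    level <- rep(c("class", "subclass"),
                 c(length(unique(className)), length(unique(subName))))
    sums <- do.call(rbind, lapply(groups, function(i)
        colSums(v[i, , drop = FALSE])))
    colnames(sums) <- cd$sample_id[bio]
    condOf <- cd$condition[bio]
    subjOf <- cd$subject_id[bio]
    stats <- data.frame(label = names(groups), level = level,
                        n_features = lengths(groups),
                        total_A = NA_real_, total_B = NA_real_,
                        log2fc = NA_real_, pvalue = NA_real_,
                        stringsAsFactors = FALSE)
    for (g in seq_along(groups)) {
        sA <- sums[g, condOf == conditionA]
        sB <- sums[g, condOf == conditionB]
        if (paired) {
            subj <- intersect(subjOf[condOf == conditionA],
                              subjOf[condOf == conditionB])
            sA <- sums[g, condOf == conditionA][
                match(subj, subjOf[condOf == conditionA])]
            sB <- sums[g, condOf == conditionB][
                match(subj, subjOf[condOf == conditionB])]
        }
        # sum over lipids of the per-condition average AUC
        # (= mean over samples of the per-sample class sum)
        stats$total_A[g] <- mean(sA)
        stats$total_B[g] <- mean(sB)
        stats$log2fc[g] <- log2(mean(sA) / mean(sB))
        stats$pvalue[g] <- normalityAdaptiveTest(sA, sB, paired = paired)$p
    }
    stats$log2fc <- clampLog2fc(stats$log2fc)
    stats$padj <- adaptiveFdr(stats$pvalue,
                              rowMeans(sums)[seq_along(groups)])
    list(sums = sums, stats = DataFrame(stats))
}

#' Rank lipids for the Lipheat display
#'
#' Orders features by mean per-replicate log2FC (descending, ties broken by
#' `feature_id` lexicographically) and selects the `topK` most enriched in
#' each direction (or only the positive direction).
#'
#' @param results a [DifferentialResult-class] (supplies feature_id and
#'   log2fc ordering)
#' @param log2fcMatrix per-replicate log2FC matrix from
#'   [perReplicateLog2fc()] (rows follow `results`)
#' @param topK features per direction (default 30)
#' @param bothDirections select from both extremes (default TRUE)
#' @return list with `features` (ordered ids) and `matrix` (the
#'   corresponding rows of `log2fcMatrix`)
#' @export
rankLipheat <- function(results, log2fcMatrix, topK = 30,
                        bothDirections = TRUE) {
    fc <- results$log2fc
    ids <- results$feature_id
    o <- order(-fc, ids)
    n <- length(o)
    sel <- if (topK >= n) o
           else if (bothDirections) unique(c(o[seq_len(topK)],
                                             o[seq(n - topK + 1L, n)]))
           else o[seq_len(topK)]
    list(features = ids[sel],
         matrix = log2fcMatrix[sel, , drop = FALSE])
}

#' Pearson correlation of abundance with age
#'
#' Pearson r with two-sided p from the t distribution on n - 2 degrees of
#' freedom, plus the least-squares regression line (the `lm` smoother +
#' Pearson test convention).
#'
#' @param values per-subject abundances
#' @param ages subject ages in years
#' @return list with `r`, `p`, `slope`, `intercept`, `n`; `r` is NA with a
#'   warning when either variable has zero variance
#' @export
ageCorrelation <- function(values, ages) {
    keep <- !is.na(values) & !is.na(ages)
    values <- values[keep]; ages <- ages[keep]
    if (length(values) < 3L)
        stop("need at least 3 subjects with both abundance and age")
    if (stats::sd(values) == 0 || stats::sd(ages) == 0) {
        warning("zero variance; correlation undefined")
        return(list(r = NA_real_, p = NA_real_, slope = NA_real_,
                    intercept = NA_real_, n = length(values)))
    }
    ct <- stats::cor.test(ages, values, method = "pearson")
    fit <- stats::lm(values ~ ages)
    list(r = unname(ct$estimate), p = ct$p.value,
         slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]), n = length(values))
}

#' PCA of samples on selected features
#'
#' Convenience wrapper over centred singular value decomposition
#' ([stats::prcomp]) of the samples-by-features matrix, typically run on
#' the significantly variable features.
#'
#' @param table a [FeatureTable-class]
#' @param features optional feature_id subset
#' @param scale. scale features to unit variance (default FALSE)
#' @return a `prcomp` object (samples in rows of `$x`)
#' @export
pcaSamples <- function(table, features = NULL, scale. = FALSE) {
    v <- areas(table)
    if (!is.null(features))
        v <- v[rowData(table)$feature_id %in% features, , drop = FALSE]
    keep <- rowSums(is.na(v)) == 0L & apply(v, 1L, stats::sd) > 0
    stats::prcomp(t(v[keep, , drop = FALSE]), center = TRUE, scale. = scale.)
}
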