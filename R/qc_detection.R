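## Multi-stage detection pipeline: per-experiment missing-value handling,
## blank-based screening and testing, technical-replicate collapsing,
## abundance/replicate thresholds, lipid feature filters, batch normalization.

#' Per-experiment missing-value handling
#'
#' Within each experiment, a feature detected in at least one sample has its
#' missing values set to zero (zero is the explicit non-detection code); a
#' feature entirely missing across all samples of an experiment keeps its
#' missing values.
#'
#' @param table a [FeatureTable-class]
#' @return the table with imputed areas
#' @export
imputeMissingWithinExperiment <- function(table) {
    v <- areas(table)
    exp <- colData(table)$experiment_id
    for (e in unique(exp)) {
        j <- which(exp == e)
        sub <- v[, j, drop = FALSE]
        seen <- rowSums(!is.na(sub)) > 0L
        sub[is.na(sub) & matrix(seen, nrow(sub), ncol(sub))] <- 0
        v[, j] <- sub
    }
    areas(table) <- v
    table
}

#' Screen features against the blank mean per experiment
#'
#' A feature passes the screen in an experiment when the mean abundance of at
#' least one condition strictly exceeds the mean of the blank (NC) samples of
#' that experiment.
#'
#' @param table a [FeatureTable-class]; every experiment must contain at
#'   least one blank sample
#' @return logical matrix, features x experiments
#' @export
screenVsBlankMean <- function(table) {
    cd <- colData(table)
    exps <- unique(cd$experiment_id)
    v <- areas(table)
    out <- matrix(FALSE, nrow(table), length(exps),
                  dimnames = list(rownames(table), exps))
    for (e in exps) {
        j <- which(cd$experiment_id == e)
        blanks <- j[cd$role[j] == "blank"]
        if (!length(blanks))
            stop("configuration error: experiment '", e, "' has no blanks")
        nonblank <- j[cd$role[j] != "blank"]
        conds <- unique(cd$condition[nonblank])
        blankMean <- rowMeans(v[, blanks, drop = FALSE], na.rm = TRUE)
        for (cc in conds) {
            jc <- nonblank[cd$condition[nonblank] == cc]
            cm <- rowMeans(v[, jc, drop = FALSE], na.rm = TRUE)
            hit <- !is.na(cm) & !is.na(blankMean) & cm > blankMean
            hit[is.na(hit)] <- FALSE
            out[, e] <- out[, e] | hit
        }
    }
    out
}

.shapiroNormal <- function(x, alpha = 0.05) {
    x <- x[!is.na(x)]
    if (length(x) < 3L || length(unique(x)) == 1L) return(NA)
    stats::shapiro.test(x)$p.value > alpha
}

#' Blank detection test for one feature
#'
#' Tests whether pooled condition intensities exceed pooled process-blank
#' (NC) intensities. A Shapiro-Wilk test (level `shapiroAlpha`) on each
#' group gates the choice: both groups normal leads to an unpaired Student
#' t-test, otherwise an unpaired Wilcoxon rank-sum test; a group on which
#' normality is undefined (constant values or n < 3) falls through to the
#' rank-sum test. The feature is detected above background when the
#' one-sided p-value (condition greater than blank) is below `alpha`.
#'
#' @param x pooled condition intensities (technically averaged biological
#'   values, merged across experiments)
#' @param blank pooled blank intensities
#' @param alpha detection level (default 0.1)
#' @param shapiroAlpha normality-gate level (default 0.05)
#' @return list with `p`, `test_used` ("t" or "wilcoxon") and `passed`
#' @export
blankDetectionTest <- function(x, blank, alpha = 0.1, shapiroAlpha = 0.05) {
    x <- x[!is.na(x)]; blank <- blank[!is.na(blank)]
    if (!length(x) || !length(blank))
        return(list(p = NA_real_, test_used = NA_character_, passed = FALSE))
    nx <- .shapiroNormal(x, shapiroAlpha)
    nb <- .shapiroNormal(blank, shapiroAlpha)
    if (is.na(nx) || is.na(nb))
        mmLog("DEBUG", "normality undefined; falling through to rank-sum")
    useT <- isTRUE(nx) && isTRUE(nb)
    p <- if (useT) {
        stats::t.test(x, blank, alternative = "greater")$p.value
    } else {
        suppressWarnings(
            stats::wilcox.test(x, blank, alternative = "greater"))$p.value
    }
    list(p = p, test_used = if (useT) "t" else "wilcoxon",
         passed = is.finite(p) && p < alpha)
}

#' Average technical replicates into one value per biological replicate
#'
#' Columns sharing a `replicate_group` are collapsed to their arithmetic
#' mean over non-missing technical values; an all-missing group stays
#' missing. Collapsed blank groups keep the blank role; all other collapsed
#' samples become biological.
#'
#' @param table a [FeatureTable-class]
#' @return a [FeatureTable-class] with one column per replicate group
#' @export
collapseTechnicalReplicates <- function(table) {
    cd <- as.data.frame(colData(table))
    v <- areas(table)
    groups <- split(seq_len(ncol(table)), cd$replicate_group)
    groups <- groups[order(vapply(groups, min, integer(1L)))]
    nv <- do.call(cbind, lapply(groups, function(j) {
        sub <- v[, j, drop = FALSE]
        out <- rowMeans(sub, na.rm = TRUE)
        out[rowSums(!is.na(sub)) == 0L] <- NA_real_
        out
    }))
    first <- vapply(groups, `[`, integer(1L), 1L)
    sm <- cd[first, , drop = FALSE]
    sm$sample_id <- names(groups)
    sm$role <- ifelse(sm$role == "blank", "blank", "biological")
    sm$replicate_group <- sm$sample_id
    rownames(sm) <- NULL
    colnames(nv) <- sm$sample_id
    FeatureTable(nv, sm, as.data.frame(rowData(table)))
}

#' Apply abundance and replicate detection thresholds
#'
#' A feature is detected per dataset when its average abundance is strictly
#' higher than `minMean` in at least one condition AND it is detected
#' (value > 0 after imputation) in at least `minReps` biological replicates
#' in every condition. Technical replicates must already be collapsed.
#'
#' @param table a [FeatureTable-class] of biological samples
#' @param minMean abundance threshold (intensity units, default 100;
#'   strictly greater)
#' @param minReps minimum detected biological replicates per condition
#'   (default 3)
#' @return [S4Vectors::DataFrame] with per-feature condition means, detected
#'   replicate counts and `passed_thresholds`
#' @export
applyDetectionThresholds <- function(table, minMean = 100, minReps = 3) {
    cd <- colData(table)
    bio <- which(cd$role == "biological")
    conds <- unique(cd$condition[bio])
    v <- areas(table)
    means <- sapply(conds, function(cc) {
        rowMeans(v[, bio[cd$condition[bio] == cc], drop = FALSE], na.rm = TRUE)
    })
    nreps <- sapply(conds, function(cc) {
        sub <- v[, bio[cd$condition[bio] == cc], drop = FALSE]
        rowSums(!is.na(sub) & sub > 0)
    })
    if (nrow(table) == 1L) {
        means <- matrix(means, 1L, dimnames = list(NULL, conds))
        nreps <- matrix(nreps, 1L, dimnames = list(NULL, conds))
    }
    maxMean <- apply(means, 1L, function(m) {
        m <- m[is.finite(m)]
        if (!length(m)) -Inf else max(m)
    })
    passed <- maxMean > minMean & apply(nreps >= minReps, 1L, all)
    out <- DataFrame(feature_id = rowData(table)$feature_id,
                     passed_thresholds = unname(passed))
    for (cc in conds) {
        out[[paste0("mean_", cc)]] <- unname(means[, cc])
        out[[paste0("n_detected_", cc)]] <- unname(nreps[, cc])
    }
    out
}

#' Remove low-mass / early-eluting lipid features
#'
#' Features with m/z below `minMz` or retention time below `minRt` minutes
#' are excluded (a feature failing either criterion is removed). Features
#' lacking m/z or RT annotation are removed with a warning.
#'
#' @param table a lipid [FeatureTable-class] with `mz` and `rt` in rowData
#' @param minMz m/z cutoff in Da (default 300)
#' @param minRt retention-time cutoff in minutes (default 2)
#' @return the filtered [FeatureTable-class]
#' @export
lipidFeatureFilter <- function(table, minMz = 300, minRt = 2) {
    rd <- rowData(table)
    noAnn <- is.na(rd$mz) | is.na(rd$rt)
    if (any(noAnn))
        mmLog("WARN", "%d lipid features lack m/z or RT and are removed",
              sum(noAnn))
    keep <- !noAnn & rd$mz >= minMz & rd$rt >= minRt
    mmLog("INFO", "lipidFeatureFilter: %d features -> %d (removed %d)",
          nrow(table), sum(keep), sum(!keep))
    table[keep, ]
}

#' Normalize feature values to their batch average
#'
#' Each feature's values are divided by that feature's mean abundance within
#' its batch (default batch key: `freezing_condition`), so batch means of
#' normalized values equal 1 where defined. Used to remove fresh-vs-frozen
#' processing offsets before significance testing. Idempotent.
#'
#' @param table a [FeatureTable-class]
#' @param batchKey colData column naming the batch (default
#'   `"freezing_condition"`)
#' @return the normalized [FeatureTable-class]
#' @export
normalizeByBatch <- function(table, batchKey = "freezing_condition") {
    cd <- colData(table)
    if (!batchKey %in% colnames(cd))
        stop("batch key '", batchKey, "' not in sample metadata")
    v <- areas(table)
    batches <- as.character(cd[[batchKey]])
    for (b in unique(batches)) {
        j <- which(batches == b)
        m <- rowMeans(v[, j, drop = FALSE], na.rm = TRUE)
        bad <- !is.na(m) & m == 0
        if (any(bad)) {
            mmLog("WARN",
                  "batch '%s': %d features have zero mean; values set missing",
                  b, sum(bad))
            v[bad, j] <- NA_real_
        }
        ok <- which(!is.na(m) & m != 0)
        v[ok, j] <- v[ok, j, drop = FALSE] / m[ok]
    }
    areas(table) <- v
    table
}

#' Run the full detection pipeline
#'
#' Orchestrates, in order: per-experiment missing-value handling; the
#' per-experiment blank-mean screen; technical-replicate averaging; the
#' pooled blank significance test per feature (conditions pooled across
#' merged experiments vs pooled blanks, P < `alpha`); and the abundance /
#' replicate thresholds. A feature is finally detected when it passes the
#' screen in at least one experiment, the blank test, and the thresholds.
#'
#' @param table a [FeatureTable-class] with blanks in every experiment
#' @param alpha blank-test level (default 0.1)
#' @param minMean,minReps see [applyDetectionThresholds()]
#' @return list with `report` (a [S4Vectors::DataFrame], one row per input
#'   feature) and `table` (the collapsed [FeatureTable-class] restricted to
#'   finally detected features)
#' @export
detectFeatures <- function(table, alpha = 0.1, minMean = 100, minReps = 3) {
    imp <- imputeMissingWithinExperiment(table)
    screen <- screenVsBlankMean(imp)
    screened <- apply(screen, 1L, any)
    collapsed <- collapseTechnicalReplicates(imp)
    cd <- colData(collapsed)
    v <- areas(collapsed)
    bio <- which(cd$role == "biological")
    blanks <- which(cd$role == "blank")
    bt <- lapply(seq_len(nrow(collapsed)), function(i)
        blankDetectionTest(v[i, bio], v[i, blanks], alpha = alpha))
    report <- DataFrame(
        feature_id = rowData(collapsed)$feature_id,
        screened_vs_blank = unname(screened),
        blank_test_p = vapply(bt, `[[`, numeric(1L), "p"),
        blank_test_used = vapply(bt, `[[`, character(1L), "test_used"),
        passed_blank = vapply(bt, `[[`, logical(1L), "passed"))
    thr <- applyDetectionThresholds(collapsed, minMean, minReps)
    for (col in setdiff(colnames(thr), "feature_id"))
        report[[col]] <- thr[[col]]
    report$final_detected <- report$screened_vs_blank &
        report$passed_blank & report$passed_thresholds
    mmLog("INFO", "detectFeatures: %d features in, %d finally detected",
          nrow(table), sum(report$final_detected))
    list(report = report, table = collapsed[report$final_detected, ])
}
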