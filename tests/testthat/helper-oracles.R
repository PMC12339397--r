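# Independent brute-force evaluation of the detection rules, written with
# plain loops against the rule statements; used to cross-check the pipeline.

bruteForceDetect <- function(ft, alpha = 0.1, minMean = 100, minReps = 3) {
    v <- areas(ft)
    cd <- as.data.frame(SummarizedExperiment::colData(ft))
    nf <- nrow(v)
    # 1. per-experiment missing-value handling
    for (e in unique(cd$experiment_id)) {
        j <- which(cd$experiment_id == e)
        for (i in seq_len(nf)) {
            row <- v[i, j]
            if (any(!is.na(row))) row[is.na(row)] <- 0
            v[i, j] <- row
        }
    }
    # 2. screen: any condition mean strictly above the blank mean, per exp
    screened <- rep(FALSE, nf)
    for (e in unique(cd$experiment_id)) {
        j <- which(cd$experiment_id == e)
        bl <- j[cd$role[j] == "blank"]
        nb <- j[cd$role[j] != "blank"]
        for (i in seq_len(nf)) {
            bm <- mean(v[i, bl], na.rm = TRUE)
            for (cc in unique(cd$condition[nb])) {
                cm <- mean(v[i, nb[cd$condition[nb] == cc]], na.rm = TRUE)
                if (!is.na(cm) && !is.na(bm) && cm > bm)
                    screened[i] <- TRUE
            }
        }
    }
    # 3. technical-replicate averaging
    grp <- unique(cd$replicate_group)
    cv <- matrix(NA_real_, nf, length(grp))
    role2 <- character(length(grp)); cond2 <- character(length(grp))
    for (k in seq_along(grp)) {
        j <- which(cd$replicate_group == grp[k])
        for (i in seq_len(nf)) {
            x <- v[i, j]
            cv[i, k] <- if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
        }
        role2[k] <- if (cd$role[j[1L]] == "blank") "blank" else "biological"
        cond2[k] <- cd$condition[j[1L]]
    }
    # 4. pooled blank significance test (Shapiro gate at 0.05, one-sided)
    normalOk <- function(x) {
        x <- x[!is.na(x)]
        if (length(x) < 3L || length(unique(x)) == 1L) return(FALSE)
        stats::shapiro.test(x)$p.value > 0.05
    }
    passedBlank <- rep(FALSE, nf)
    for (i in seq_len(nf)) {
        x <- cv[i, role2 == "biological"]; x <- x[!is.na(x)]
        b <- cv[i, role2 == "blank"]; b <- b[!is.na(b)]
        if (!length(x) || !length(b)) next
        p <- if (normalOk(x) && normalOk(b))
                 stats::t.test(x, b, alternative = "greater")$p.value
             else suppressWarnings(stats::wilcox.test(
                 x, b, alternative = "greater"))$p.value
        passedBlank[i] <- is.finite(p) && p < alpha
    }
    # 5. abundance > minMean in any condition; detected (>0) in >= minReps
    #    biological replicates in every condition
    conds <- unique(cond2[role2 == "biological"])
    passedThr <- rep(FALSE, nf)
    for (i in seq_len(nf)) {
        anyHigh <- FALSE; allReps <- TRUE
        for (cc in conds) {
            x <- cv[i, role2 == "biological" & cond2 == cc]
            m <- mean(x, na.rm = TRUE)
            if (is.finite(m) && m > minMean) anyHigh <- TRUE
            if (sum(!is.na(x) & x > 0) < minReps) allReps <- FALSE
        }
        passedThr[i] <- anyHigh && allReps
    }
    data.frame(feature_id = rownames(v), screened = screened,
               passed_blank = passedBlank, passed_thresholds = passedThr,
               final = screened & passedBlank & passedThr,
               stringsAsFactors = FALSE)
}

# exact rank-sum p by enumeration of all group assignments (no ties)
exactRankSumP <- function(x, y) {
    pooled <- c(x, y)
    n1 <- length(x)
    r <- rank(pooled)
    obs <- sum(r[seq_len(n1)])
    combs <- utils::combn(length(pooled), n1)
    stat <- apply(combs, 2L, function(idx) sum(rank(pooled)[idx]))
    ex <- n1 * (length(pooled) + 1) / 2
    mean(abs(stat - ex) >= abs(obs - ex) - 1e-9)
}

# exact signed-rank p by enumeration of all 2^n sign assignments (no ties)
exactSignedRankP <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    obs <- sum(r[d > 0])
    ex <- n * (n + 1) / 4
    signs <- expand.grid(rep(list(c(0, 1)), n))
    stat <- as.matrix(signs) %*% r
    mean(abs(stat - ex) >= abs(obs - ex) - 1e-9)
}

tinyFeatureTable <- function() {
    FeatureTable(
        matrix(c(500, 550, 480, 520, 30, 20,
                 10, NA, 12, 9, 25, 30,
                 NA, NA, NA, NA, NA, NA), 3, 6, byrow = TRUE,
               dimnames = list(c("f1", "f2", "f3"),
                               c("a1", "a2", "b1", "b2", "nc1", "nc2"))),
        sampleMeta = data.frame(
            sample_id = c("a1", "a2", "b1", "b2", "nc1", "nc2"),
            role = c(rep("biological", 4L), "blank", "blank"),
            condition = c("A", "A", "B", "B", NA, NA),
            subject_id = c("s1", "s2", "s1", "s2", "", ""),
            stringsAsFactors = FALSE),
        featureMeta = data.frame(feature_id = c("f1", "f2", "f3")))
}
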