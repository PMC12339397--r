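test_that("normality-adaptive test chooses branches and finds shifts", {
    set.seed(1)
    y <- rnorm(17, 100, 5)
    r <- normalityAdaptiveTest(y + 20 + rnorm(17, 0, 2), y, paired = TRUE)
    expect_equal(r$test_used, "t")
    expect_lt(r$p, 0.05)
    # identical samples: no evidence
    expect_equal(normalityAdaptiveTest(y, y, paired = TRUE)$p, 1)
    # tiny groups are excluded
    expect_true(is.na(normalityAdaptiveTest(c(1, 2), c(3, 4))$p))
})

test_that("paired test type-I error is calibrated under a normal null", {
    set.seed(202)
    nrep <- 400
    hits <- replicate(nrep, {
        x <- rnorm(17); y <- rnorm(17)
        normalityAdaptiveTest(x, y, paired = TRUE)$p < 0.05
    })
    se <- sqrt(0.05 * 0.95 / nrep)
    expect_lte(mean(hits), 0.05 + 3 * se)
    expect_gte(mean(hits), 0.05 - 3 * se)
})

test_that("wilcoxon branches agree with exact permutation enumeration", {
    set.seed(7)
    checked <- 0L
    for (i in 1:20) {
        n1 <- sample(4:8, 1); n2 <- sample(4:8, 1)
        x <- rcauchy(n1, 0, 3); y <- rcauchy(n2, 2, 3)
        r <- normalityAdaptiveTest(x, y)
        if (r$test_used != "wilcoxon") next
        expect_equal(r$p, exactRankSumP(x, y), tolerance = 1e-9)
        checked <- checked + 1L
    }
    expect_gte(checked, 5L)
    # paired branch: signed-rank against full sign enumeration
    checkedP <- 0L
    for (i in 1:20) {
        y <- rcauchy(8, 0, 2); x <- y + rcauchy(8, 1, 2)
        r <- normalityAdaptiveTest(x, y, paired = TRUE)
        if (r$test_used != "wilcoxon") next
        expect_equal(r$p, exactSignedRankP(x - y), tolerance = 1e-9)
        checkedP <- checkedP + 1L
    }
    expect_gte(checkedP, 5L)
})

test_that("log2 fold changes clamp infinities to the dataset extrema", {
    expect_equal(computeLog2fc(200, 100), 1)
    expect_equal(computeLog2fc(100, 100), 0)
    fc <- computeLog2fc(c(200, 0, 800, 100, 50), rep(100, 5))
    clamped <- clampLog2fc(fc)
    expect_equal(clamped[2], -1)                  # dataset min finite log2fc
    expect_true(all(is.finite(clamped)))
    expect_true(all(clamped <= max(fc[is.finite(fc)]) &
                    clamped >= min(fc[is.finite(fc)])))
    expect_true(is.na(computeLog2fc(0, 0)))       # 0/0 is missing
    up <- clampLog2fc(computeLog2fc(c(2, Inf, 8), c(1, 0, 1)))
    expect_equal(up[2], 3)                        # +Inf -> dataset max
})

test_that("adaptive FDR equals Benjamini-Hochberg for constant covariates", {
    p <- c(0.01, 0.02, 0.03, 0.04)
    expect_equal(adaptiveFdr(p, rep(5, 4)), rep(0.04, 4))
    expect_equal(adaptiveFdr(rep(1, 6), rep(1, 6)), rep(1, 6))
    set.seed(33)
    for (i in 1:20) {
        pv <- runif(sample(10:500, 1))^sample(1:3, 1)
        expect_identical(adaptiveFdr(pv, rep(1, length(pv))),
                         p.adjust(pv, "BH"))
    }
    # missing p-values propagate and do not count as tests
    pv <- c(0.01, NA, 0.5)
    out <- adaptiveFdr(pv, rep(1, 3))
    expect_true(is.na(out[2]))
    expect_identical(out[c(1, 3)], p.adjust(pv[c(1, 3)], "BH"))
})

test_that("adaptive FDR is monotone in p within a covariate bin", {
    set.seed(44)
    pv <- runif(400)^2
    cv <- rexp(400)
    out <- adaptiveFdr(pv, cv)
    bins <- cut(cv, unique(quantile(cv, seq(0, 1, 0.25))),
                include.lowest = TRUE)
    for (b in levels(bins)) {
        i <- which(bins == b)
        o <- order(pv[i])
        expect_true(all(diff(out[i][o]) >= -1e-12))
    }
})

test_that("adaptive FDR controls the false discovery proportion", {
    set.seed(55)
    fdp <- replicate(60, {
        pv <- runif(2000)
        cv <- rlnorm(2000)
        any(adaptiveFdr(pv, cv) < 0.05)
    })
    se <- sqrt(0.05 * 0.95 / 60)
    expect_lte(mean(fdp), 0.05 + 3 * se)
})

test_that("differential abundance recovers injected paired effects", {
    perf <- sapply(1:10, function(seed) {
        g <- genMetabolomics(seed, nPairs = 14)
        det <- suppressMessages(detectFeatures(g$table))
        res <- suppressMessages(
            differentialAbundance(det$table, "HSPC", "Prog", paired = TRUE))
        tr <- g$truth[match(res$feature_id, g$truth$feature_id), ]
        expect_true(all(is.finite(res$log2fc)))
        hit <- which(res$significant & tr$true_log2fc != 0)
        expect_true(all(sign(res$log2fc[hit]) == sign(tr$true_log2fc[hit])))
        c(tp = sum(res$significant & tr$true_log2fc != 0),
          fp = sum(res$significant & tr$true_log2fc == 0),
          nEffect = sum(tr$true_log2fc != 0))
    })
    sens <- sum(perf["tp", ]) / sum(perf["nEffect", ])
    fdp <- sum(perf["fp", ]) / max(1, sum(perf["tp", ] + perf["fp", ]))
    expect_gte(sens, 0.8)
    expect_lte(fdp, 0.10)
})

test_that("permuting condition labels kills the signal", {
    g <- genMetabolomics(13, nPairs = 14)
    det <- suppressMessages(detectFeatures(g$table))
    tab <- det$table
    cd <- SummarizedExperiment::colData(tab)
    set.seed(99)
    bio <- which(cd$role == "biological")
    perm <- cd$condition
    for (s in unique(cd$subject_id[bio])) {
        i <- bio[cd$subject_id[bio] == s]
        perm[i] <- sample(perm[i])
    }
    cd$condition <- perm
    SummarizedExperiment::colData(tab) <- cd
    res <- suppressMessages(
        differentialAbundance(tab, "HSPC", "Prog", paired = TRUE))
    expect_lte(sum(res$significant), 2L)
})

test_that("single-feature tables fall back to padj = p", {
    ft <- FeatureTable(matrix(c(10, 11, 12, 30, 31, 29), 1),
        data.frame(sample_id = paste0("s", 1:6), role = "biological",
                   condition = rep(c("A", "B"), each = 3)),
        data.frame(feature_id = "f"))
    res <- suppressWarnings(suppressMessages(
        differentialAbundance(ft, "A", "B")))
    expect_equal(res$padj, res$pvalue)
})

test_that("class and subclass sums partition the class totals", {
    g <- genLipidomics(21)
    merged <- suppressMessages(mergeIsomers(g$table))
    cs <- classSubclassSums(merged, "HSPC", "Prog", paired = TRUE)
    sums <- cs$sums
    # SM short + SM long = SM class total per sample
    expect_equal(sums["SM short", ] + sums["SM long", ], sums["SM", ],
                 tolerance = 1e-9)
    # two PC features sum per sample (additivity is construction, check one)
    expect_true(all(sums >= 0))
    st <- as.data.frame(cs$stats)
    # injected effects: long-chain SM flagged, saturated PC not
    expect_lt(st$pvalue[st$label == "SM long"], 0.05)
    expect_gt(st$log2fc[st$label == "SM long"], 0)
    expect_lt(st$log2fc[st$label == "PC polyunsaturated"], 0)
    expect_gt(st$pvalue[st$label == "PC saturated"], 0.05)
})

test_that("lipheat ranking orders by fold change with lexicographic ties", {
    res <- DataFrame(feature_id = c("f1", "f2", "f3"),
                     log2fc = c(2, -1, 0.5))
    m <- matrix(0, 3, 2, dimnames = list(c("f1", "f2", "f3"), NULL))
    r <- rankLipheat(res, m, topK = 3)
    expect_equal(r$features, c("f1", "f3", "f2"))
    r1 <- rankLipheat(res, m, topK = 1)
    expect_equal(r1$features, c("f1", "f2"))
    tied <- DataFrame(feature_id = c("fb", "fa"), log2fc = c(1, 1))
    mt <- matrix(0, 2, 1, dimnames = list(c("fb", "fa"), NULL))
    expect_equal(rankLipheat(tied, mt, topK = 2)$features, c("fa", "fb"))
})

test_that("age correlation returns Pearson r with the regression line", {
    x <- 1:5
    r <- ageCorrelation(2 * x, x)
    expect_equal(r$r, 1)
    expect_equal(r$slope, 2)
    expect_equal(r$intercept, 0, tolerance = 1e-12)
    dec <- ageCorrelation(10 - x, x)
    expect_equal(dec$r, -1)
    expect_warning(ageCorrelation(rep(1, 4), 1:4), "zero variance")
    # null p-values are uniform
    set.seed(77)
    ps <- replicate(300, ageCorrelation(rnorm(10), sample(40:70, 10))$p)
    expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("sample PCA wrapper separates conditions with strong effects", {
    g <- genMetabolomics(31, nPairs = 8, effectFrac = 0.3,
                         effectLog2fc = 3)
    det <- suppressMessages(detectFeatures(g$table))
    pc <- pcaSamples(det$table)
    expect_s3_class(pc, "prcomp")
    expect_equal(nrow(pc$x), ncol(det$table))
})
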