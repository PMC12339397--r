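test_that("missing values are zeroed only in experiments with a detection", {
    v <- matrix(c(5, NA, NA, NA, NA, 7,
                  NA, NA, NA, NA, NA, NA,
                  1, 2, 3, 4, 5, 6), 3, 6, byrow = TRUE)
    sm <- data.frame(sample_id = paste0("s", 1:6), role = "biological",
                     condition = "A",
                     experiment_id = rep(c("e1", "e2"), each = 3))
    ft <- FeatureTable(v, sm, data.frame(feature_id = c("f1", "f2", "f3")))
    out <- areas(imputeMissingWithinExperiment(ft))
    expect_equal(unname(out[1, 1:3]), c(5, 0, 0))    # detected in e1
    expect_equal(unname(out[1, 4:6]), c(0, 0, 7))    # detected in e2
    expect_true(all(is.na(out[2, ])))                # fully missing retained
    expect_equal(unname(out[3, ]), 1:6 + 0)          # untouched
})

test_that("the blank-mean screen flags any condition above blanks", {
    mk <- function(a, b, nc) {
        FeatureTable(matrix(c(a, b, nc), 1, 6),
            data.frame(sample_id = paste0("s", 1:6),
                       role = c(rep("biological", 4), "blank", "blank"),
                       condition = c("A", "A", "B", "B", NA, NA)),
            data.frame(feature_id = "f"))
    }
    expect_true(screenVsBlankMean(mk(c(120, 120), c(40, 40),
                                     c(50, 50)))[1, 1])
    expect_false(screenVsBlankMean(mk(c(10, 10), c(20, 20),
                                      c(50, 50)))[1, 1])
    expect_true(screenVsBlankMean(mk(c(1, 1), c(0, 0), c(0, 0)))[1, 1])
    ftNoBlank <- FeatureTable(matrix(1, 1, 2),
        data.frame(sample_id = c("s1", "s2"), role = "biological",
                   condition = "A"),
        data.frame(feature_id = "f"))
    expect_error(screenVsBlankMean(ftNoBlank), "configuration error")
})

test_that("blank detection test picks tests by normality and detects shifts", {
    set.seed(42)
    # overwhelming shift: 10 SDs
    x <- rnorm(5, 100, 1); b <- rnorm(5, 90, 1)
    r <- blankDetectionTest(x, b)
    expect_true(r$passed)
    # heavy-tailed values push the gate to the rank-sum branch
    used <- replicate(60, {
        blankDetectionTest(rcauchy(8, 10, 5) + 1e3, rcauchy(8, 0, 5))$test_used
    })
    expect_gt(mean(used == "wilcoxon"), 0.5)
    # constant group: normality undefined, falls through to rank-sum
    r2 <- blankDetectionTest(rep(5, 4), rep(1, 4))
    expect_equal(r2$test_used, "wilcoxon")
})

test_that("blank detection test is calibrated under the null", {
    set.seed(101)
    nrep <- 300
    hits <- replicate(nrep, {
        blankDetectionTest(rnorm(6, 50, 5), rnorm(6, 50, 5),
                           alpha = 0.1)$passed
    })
    se <- sqrt(0.1 * 0.9 / nrep)
    expect_lte(mean(hits), 0.1 + 3 * se)
    expect_gte(mean(hits), 0.1 - 3 * se)
})

test_that("technical replicates collapse to per-biological means", {
    v <- matrix(c(100, 120, 100, NA, 7, 7), 3, 2, byrow = TRUE)
    ft <- FeatureTable(v,
        data.frame(sample_id = c("t1", "t2"), role = "technical",
                   condition = "A", subject_id = "s1",
                   replicate_group = "bio1"),
        data.frame(feature_id = c("f1", "f2", "f3")))
    out <- collapseTechnicalReplicates(ft)
    expect_equal(ncol(out), 1L)
    expect_equal(unname(areas(out)[, 1]), c(110, 100, 7))
    expect_equal(SummarizedExperiment::colData(out)$role, "biological")
    # single technical replicate: values unchanged
    single <- FeatureTable(matrix(3, 1, 1),
        data.frame(sample_id = "t1", role = "biological", condition = "A"),
        data.frame(feature_id = "f"))
    expect_equal(unname(areas(collapseTechnicalReplicates(single))[1, 1]), 3)
})

test_that("abundance and replicate thresholds follow the strict rules", {
    mk <- function(a, b) {
        FeatureTable(matrix(c(a, b), 1),
            data.frame(sample_id = paste0("s", seq_along(c(a, b))),
                       role = "biological",
                       condition = rep(c("A", "B"), c(length(a), length(b)))),
            data.frame(feature_id = "f"))
    }
    # high mean in one condition + enough detected reps in both: pass
    r <- applyDetectionThresholds(mk(c(150, 160, 140, 150, 155),
                                     c(20, 25, 15, 22)))
    expect_true(r$passed_thresholds)
    # too few detected replicates in one condition: fail
    r2 <- applyDetectionThresholds(mk(c(150, 160, 140, 150, 155),
                                      c(20, 25, 0, 0)))
    expect_false(r2$passed_thresholds)
    # mean exactly 100 is not "higher than 100": fail
    r3 <- applyDetectionThresholds(mk(rep(100, 4), rep(100, 4)))
    expect_false(r3$passed_thresholds)
})

test_that("lipid feature filter removes sub-300 m/z or early RT features", {
    ft <- FeatureTable(matrix(1, 4, 2),
        data.frame(sample_id = c("s1", "s2"), role = "biological",
                   condition = "A"),
        data.frame(feature_id = paste0("f", 1:4),
                   mz = c(280, 760.58, 310, NA),
                   rt = c(5, 8, 1.5, 3)))
    out <- suppressMessages(lipidFeatureFilter(ft))
    expect_equal(rowData(out)$feature_id, "f2")   # only m/z>=300 & RT>=2
})

test_that("batch normalization centres batch means at 1 and is idempotent", {
    v <- matrix(c(2, 4, 20, 40, 0, 0), 1)
    ft <- FeatureTable(v,
        data.frame(sample_id = paste0("s", 1:6), role = "biological",
                   condition = "A",
                   freezing_condition = rep(c("fresh", "frozen", "dead"),
                                            each = 2)),
        data.frame(feature_id = "f"))
    out <- suppressMessages(normalizeByBatch(ft))
    expect_equal(unname(areas(out)[1, 1:2]), c(2/3, 4/3))
    # identical relative profiles normalize identically across batches
    expect_equal(unname(areas(out)[1, 3:4]), c(2/3, 4/3))
    # zero-mean batch becomes missing
    expect_true(all(is.na(areas(out)[1, 5:6])))
    again <- suppressMessages(normalizeByBatch(out))
    expect_equal(areas(again), areas(out), tolerance = 1e-12)
})

test_that("the pipeline agrees flag-by-flag with the brute-force rules", {
    for (seed in 1:10) {
        g <- genMetabolomics(seed, nFeatures = 15, nPairs = 4,
                             nExperiments = 2, techReps = 2)
        mine <- suppressMessages(detectFeatures(g$table))$report
        oracle <- bruteForceDetect(g$table)
        expect_identical(mine$screened_vs_blank, oracle$screened)
        expect_identical(mine$passed_blank, oracle$passed_blank)
        expect_identical(mine$passed_thresholds, oracle$passed_thresholds)
        expect_identical(mine$final_detected, oracle$final)
    }
})

test_that("signal at 10x blank is detected, blank-level noise mostly is not", {
    det <- sapply(1:6, function(seed) {
        g <- genMetabolomics(seed, nFeatures = 40, nPairs = 6,
                             nExperiments = 2)
        rep <- suppressMessages(detectFeatures(g$table))$report
        tr <- g$truth
        c(bg = mean(rep$final_detected[tr$is_background]),
          sig = mean(rep$final_detected[!tr$is_background]))
    })
    nBg <- 6 * 4    # background features across seeds
    expect_lte(mean(det["bg", ]), 0.1 + 3 * sqrt(0.1 * 0.9 / nBg))
    expect_gte(mean(det["sig", ]), 0.95)
})
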