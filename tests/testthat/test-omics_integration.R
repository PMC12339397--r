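test_that("enzyme-metabolite correlation pairs pathway co-members", {
    samples <- paste0("s", 1:6)
    prof <- c(1, 3, 2, 5, 4, 6)
    expr <- rbind(geneA = prof, geneB = c(2, -1, 4, 0, 3, 1))
    colnames(expr) <- samples
    # orthogonalize geneB against prof (and the intercept)
    expr["geneB", ] <- residuals(lm(expr["geneB", ] ~ prof))
    metab <- rbind(metX = prof)
    colnames(metab) <- samples
    sets <- list(p1 = c("geneA", "geneB"))
    msets <- list(p1 = "metX")
    out <- enzymeMetaboliteCorrelation(metab, expr, sets, msets)
    expect_equal(out$r[out$gene == "geneA"], 1, tolerance = 1e-12)
    expect_equal(out$r[out$gene == "geneB"], 0, tolerance = 1e-12)
    # pathway without metabolite members yields no pairs
    empty <- enzymeMetaboliteCorrelation(metab, expr,
                                         list(p2 = "geneA"),
                                         list(p2 = character()))
    expect_equal(nrow(empty), 0L)
})

test_that("Pearson p agrees with a permutation oracle at small n", {
    set.seed(88)
    x <- rnorm(7); y <- 0.8 * x + rnorm(7, 0, 0.5)
    pObs <- cor.test(x, y)$p.value
    rObs <- abs(cor(x, y))
    perm <- replicate(4000, abs(cor(x, sample(y))))
    pPerm <- mean(perm >= rObs - 1e-12)
    expect_lt(abs(pObs - pPerm), 3 * sqrt(pPerm * (1 - pPerm) / 4000) + 0.01)
})

test_that("metabolograms enforce eligibility and centre statistics", {
    gs <- data.frame(id = paste0("g", 1:6),
                     log2fc = c(0.5, 0.8, 1.1, 0.3, 0.9, 0.6),
                     padj = c(0.04, 0.2, 0.005, 0.5, 0.0005, 0.03))
    ms <- data.frame(id = "metX", log2fc = -1, padj = 0.01)
    m <- buildMetabologram("TCA", genes = gs$id, metabolites = ms$id,
                           geneStats = gs, metabStats = ms)
    expect_true(m@eligible)
    expect_equal(m@centerGeneAvg, mean(gs$log2fc))
    expect_equal(m@centerMetabAvg, -1)
    # six same-sign values: exact signed-rank two-sided tail 2/2^6
    expect_equal(m@centerGeneP, 2 * (1 / 2^6))
    expect_equal(as.character(m@geneSlices$stars[3]), "**")
    expect_equal(as.character(m@geneSlices$stars[5]), "***")

    # four detected enzymes: skipped
    m4 <- buildMetabologram("small", genes = gs$id[1:4],
                            metabolites = ms$id, geneStats = gs,
                            metabStats = ms)
    expect_false(m4@eligible)
    expect_match(m4@reason, "4 detected enzymes")
    # balanced slices have a zero centre
    gs0 <- data.frame(id = paste0("g", 1:5),
                      log2fc = c(1, 1, -1, -1, 0), padj = 1)
    m0 <- buildMetabologram("bal", gs0$id, ms$id, gs0, ms)
    expect_equal(m0@centerGeneAvg, 0)
})

test_that("ulm activity equals the closed-form correlation t-statistic", {
    set.seed(21)
    for (i in 1:25) {
        n <- sample(50:500, 1)
        stat <- setNames(rnorm(n), sprintf("g%04d", 1:n))
        nt <- sample(5:30, 1)
        reg <- data.frame(target = sample(names(stat), nt),
                          weight = rnorm(nt))
        a <- ulmActivity(stat, reg)
        w <- setNames(rep(0, n), names(stat))
        w[reg$target] <- reg$weight
        r <- cor(stat, w)
        tClosed <- r * sqrt((n - 2) / (1 - r^2))
        expect_equal(a$score, tClosed, tolerance = 1e-9)
    }
})

test_that("ulm activity sign tracks activation and repression", {
    genes <- sprintf("g%03d", 1:200)
    w <- rnorm(200)
    names(w) <- genes
    reg <- data.frame(target = genes[1:30], weight = w[1:30])
    stat <- setNames(rep(0, 200), genes)
    stat[1:30] <- 2 * w[1:30]               # targets follow the weights
    # exact proportionality makes lm warn about a perfect fit; expected here
    a <- suppressWarnings(ulmActivity(stat, reg))
    expect_gt(a$score, 10)
    # repressive regulon with targets down: positive activity
    regNeg <- data.frame(target = genes[1:30], weight = -abs(w[1:30]))
    statDn <- setNames(rep(0, 200), genes)
    statDn[1:30] <- -2 * abs(w[1:30])
    expect_gt(suppressWarnings(ulmActivity(statDn, regNeg))$score, 10)
    # permuted weights: null scores centred at zero
    set.seed(3)
    null <- replicate(200, {
        regP <- data.frame(target = genes[1:30], weight = sample(w, 30))
        ulmActivity(stat, regP)$score
    })
    expect_lt(abs(mean(null)), 3 * sd(null) / sqrt(200))
    expect_warning(
        ulmActivity(stat, data.frame(target = genes[1:5], weight = 0)),
        "zero-variance")
    expect_error(ulmActivity(stat, data.frame(target = "zz", weight = 1)),
                 ">= 2")
})

test_that("activity ranking filters and orders with ties broken by id", {
    sc <- data.frame(id = c("tfA", "tfB", "tfC", "tfD"),
                     score = c(3, -5, 3, 1),
                     p = c(0.01, 0.001, 0.01, 0.5))
    out <- rankActivities(sc, topK = 7)
    expect_equal(out$id, c("tfA", "tfC", "tfB"))   # tfD filtered at p
    expect_equal(nrow(rankActivities(sc[sc$p > 0.4, , drop = FALSE])), 0L)
})

test_that("GMT, metabolite-set and regulon readers round-trip", {
    gmt <- withr::local_tempfile(fileext = ".gmt")
    writeLines(c("TCA\tdesc\tCS\tIDH3B\tMDH2",
                 "Purine\tdesc\tPPAT\tATIC"), gmt)
    sets <- readGmt(gmt)
    expect_equal(sets$TCA, c("CS", "IDH3B", "MDH2"))
    mtsv <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("pathway_id\tfeature_id", "TCA\tcitrate", "TCA\tmalate"),
               mtsv)
    expect_equal(readMetaboliteSets(mtsv)$TCA, c("citrate", "malate"))
    rtsv <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("tf\ttarget\tweight", "FOXO3\tSOD2\t1.5",
                 "FOXO3\tCCND1\t-0.7"), rtsv)
    reg <- readRegulon(rtsv)
    expect_equal(reg$FOXO3$weight, c(1.5, -0.7))
})
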