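## Seeded synthetic-data generators emulating every input the pipeline
## consumes, with recorded ground truth for recovery tests. Each generator is
## a pure function of (seed, parameters): regeneration is bit-identical.

#' Synthetic paired targeted-metabolomics dataset
#'
#' Emulates a paired two-condition design (HSPC vs progenitor) with
#' technical replicates, multi-experiment batches, log-normal peak areas,
#' feature-specific blank background, missing values and known log2 effect
#' sizes. A fixed fraction of features is pure blank-level background; one
#' feature is entirely missing within the first experiment to exercise the
#' retained-missing rule.
#'
#' @param seed integer RNG seed
#' @param nFeatures number of features (default 80)
#' @param nPairs biological subject pairs (default 17, the healthy-donor
#'   cohort size)
#' @param nExperiments experiment batches (default 3)
#' @param blankLevel blank background intensity scale (default 200)
#' @param effectFrac fraction of features with a true effect (default 0.1)
#' @param effectLog2fc absolute true log2 effect (default 2)
#' @param missingRate missing-at-random rate (default 0.05)
#' @param techReps technical replicates per biological sample (default 2)
#' @param backgroundFrac fraction of blank-level background features
#'   (default 0.1)
#' @return list with `table` (a [FeatureTable-class]) and `truth`
#'   (data.frame: feature_id, is_background, true_log2fc)
#' @export
genMetabolomics <- function(seed, nFeatures = 80, nPairs = 17,
                            nExperiments = 3, blankLevel = 200,
                            effectFrac = 0.1, effectLog2fc = 2,
                            missingRate = 0.05, techReps = 2,
                            backgroundFrac = 0.1) {
    set.seed(seed)
    nBg <- round(backgroundFrac * nFeatures)
    nEff <- round(effectFrac * nFeatures)
    ids <- sprintf("met%03d", seq_len(nFeatures))
    isBg <- c(rep(TRUE, nBg), rep(FALSE, nFeatures - nBg))
    effSign <- sample(c(-1, 1), nEff, replace = TRUE)
    trueFc <- numeric(nFeatures)
    trueFc[nBg + seq_len(nEff)] <- effSign * effectLog2fc
    baseLog <- stats::runif(nFeatures, log(2000), log(50000))
    blankLog <- log(blankLevel) + stats::rnorm(nFeatures, 0, 0.3)
    subjEff <- stats::rnorm(nPairs, 0, 0.3)
    expOf <- rep(seq_len(nExperiments), length.out = nPairs)
    batchEff <- stats::rnorm(nExperiments, 0, 0.2)

    samples <- list(); cols <- list()
    for (j in seq_len(nPairs)) {
        for (cond in c("HSPC", "Prog")) {
            bioLog <- batchEff[expOf[j]] +
                      ifelse(isBg, blankLog + stats::rnorm(nFeatures, 0, 0.3),
                             baseLog + subjEff[j] +
                             (cond == "HSPC") * trueFc * log(2) +
                             stats::rnorm(nFeatures, 0, 0.35))
            for (tr in seq_len(techReps)) {
                cols[[length(cols) + 1L]] <-
                    exp(bioLog + stats::rnorm(nFeatures, 0, 0.1))
                samples[[length(samples) + 1L]] <- data.frame(
                    sample_id = sprintf("s%02d_%s_t%d", j, cond, tr),
                    role = if (techReps > 1L) "technical" else "biological",
                    condition = cond,
                    subject_id = sprintf("subj%02d", j),
                    replicate_group = sprintf("s%02d_%s", j, cond),
                    experiment_id = sprintf("exp%d", expOf[j]),
                    freezing_condition = "fresh", age = NA_real_,
                    stringsAsFactors = FALSE)
            }
        }
    }
    for (e in seq_len(nExperiments)) {
        for (b in 1:3) {
            cols[[length(cols) + 1L]] <-
                exp(blankLog + batchEff[e] + stats::rnorm(nFeatures, 0, 0.3))
            samples[[length(samples) + 1L]] <- data.frame(
                sample_id = sprintf("blank_e%d_%d", e, b), role = "blank",
                condition = NA_character_, subject_id = "",
                replicate_group = sprintf("blank_e%d_%d", e, b),
                experiment_id = sprintf("exp%d", e),
                freezing_condition = "fresh", age = NA_real_,
                stringsAsFactors = FALSE)
        }
    }
    v <- do.call(cbind, cols)
    sm <- do.call(rbind, samples)
    # missing at random plus censoring of weak signals
    v[matrix(stats::runif(length(v)) < missingRate, nrow(v))] <- NA_real_
    v[!is.na(v) & v < blankLevel / 10] <- NA_real_
    # one feature entirely missing within experiment 1
    v[nFeatures, sm$experiment_id == "exp1"] <- NA_real_
    fm <- data.frame(feature_id = ids, name = ids, formula = "",
                     mz = NA_real_, rt = NA_real_, pathway = "",
                     stringsAsFactors = FALSE)
    list(table = FeatureTable(v, sm, fm),
         truth = data.frame(feature_id = ids, is_background = isBg,
                            true_log2fc = trueFc,
                            stringsAsFactors = FALSE))
}

.LIPID_GRID <- local({
    g <- rbind(
        expand.grid(class = "PC", ether = FALSE, C = c(32, 34, 36, 38),
                    DB = 0:4, stringsAsFactors = FALSE),
        expand.grid(class = "PC", ether = TRUE, C = c(34, 36),
                    DB = 1:3, stringsAsFactors = FALSE),
        expand.grid(class = "PE", ether = FALSE, C = c(34, 36, 38),
                    DB = 1:4, stringsAsFactors = FALSE),
        expand.grid(class = "PE", ether = TRUE, C = c(36, 38),
                    DB = 2:3, stringsAsFactors = FALSE),
        expand.grid(class = "SM", ether = FALSE, C = c(34, 36, 38, 40, 42),
                    DB = 1:2, stringsAsFactors = FALSE),
        expand.grid(class = "TG", ether = FALSE, C = c(48, 50, 52, 54),
                    DB = 1:3, stringsAsFactors = FALSE),
        expand.grid(class = "LPC", ether = FALSE, C = c(16, 18),
                    DB = 0:1, stringsAsFactors = FALSE),
        expand.grid(class = "CAR", ether = FALSE, C = c(8, 10),
                    DB = 0, stringsAsFactors = FALSE))
    g
})

.lipidFormula <- function(class, ether, C, DB, oxy) {
    ## synthetic but internally consistent per-class formula rules
    counts <- switch(class,
        PC = c(C = C + 8, H = 2 * C - 2 * DB + 16 + if (ether) 2 else 0,
               N = 1, O = if (ether) 7 else 8, P = 1),
        PE = c(C = C + 5, H = 2 * C - 2 * DB + 10 + if (ether) 2 else 0,
               N = 1, O = if (ether) 7 else 8, P = 1),
        SM = c(C = C + 6, H = 2 * C - 2 * DB + 13, N = 2, O = 6, P = 1),
        TG = c(C = C + 3, H = 2 * C - 2 * DB + 2, O = 6),
        LPC = c(C = C + 8, H = 2 * C - 2 * DB + 18, N = 1, O = 7, P = 1),
        CAR = c(C = C + 7, H = 2 * C - 2 * DB + 13, N = 1, O = 4))
    paste0(names(counts), ifelse(counts > 1, counts, ""), collapse = "")
}

.formulaMass <- function(formula) {
    masses <- c(C = 12, H = 1.007825, N = 14.003074, O = 15.994915,
                P = 30.973762, S = 31.972071)
    counts <- parseFormula(formula)
    sum(masses[names(counts)] * counts) + 1.007276   # [M+H]+
}

#' Synthetic annotated lipidomics dataset
#'
#' Emulates an annotated untargeted-lipidomics export: shorthand-named
#' species across PC, PC O-, PE, PE O-, SM (;O2), TG, LPC and CAR with
#' synthetic but internally consistent formulas, m/z and RT (carnitines
#' fall below the m/z 300 / RT 2 min filter on purpose); isomer duplicate
#' rows sharing name and formula (to be merged); one chain-resolved vs
#' species-level name pair sharing a formula (not mergeable) and one
#' same-name formula conflict (flagged). Class-level effects are injected:
#' long-chain SM up and polyunsaturated PC down in the first condition.
#'
#' @param seed integer RNG seed
#' @param nPairs biological subject pairs (default 14)
#' @param isomerDupRate fraction of species split into two isomer rows
#'   (default 0.2)
#' @param smLongEffect log2 effect for long-chain SM in condition A
#'   (default 1.5)
#' @param pcPolyEffect log2 effect for polyunsaturated PC in condition A
#'   (default -1)
#' @return list with `table` (a lipid [FeatureTable-class], unmerged) and
#'   `truth` (per-species class identity and true log2 effect)
#' @export
genLipidomics <- function(seed, nPairs = 14, isomerDupRate = 0.2,
                          smLongEffect = 1.5, pcPolyEffect = -1) {
    set.seed(seed)
    g <- .LIPID_GRID
    oxy <- ifelse(g$class == "SM", 2L, 0L)
    names <- paste0(g$class, " ", ifelse(g$ether, "O-", ""), g$C, ":", g$DB,
                    ifelse(oxy > 0L, paste0(";O", oxy), ""))
    formulas <- mapply(.lipidFormula, g$class, g$ether, g$C, g$DB, oxy)
    mz <- vapply(formulas, .formulaMass, numeric(1L))
    rt <- ifelse(g$class == "CAR", 1.2,
                 pmax(2.2, 1 + 0.15 * g$C - 0.2 * g$DB +
                          stats::rnorm(nrow(g), 0, 0.2)))
    trueFc <- numeric(nrow(g))
    trueFc[g$class == "SM" & g$C >= 36] <- smLongEffect
    trueFc[g$class == "PC" & !g$ether & g$DB >= 2] <- pcPolyEffect
    baseLog <- stats::runif(nrow(g), log(5000), log(100000))
    subjEff <- stats::rnorm(nPairs, 0, 0.25)
    expOf <- rep(1:2, length.out = nPairs)
    batchEff <- stats::rnorm(2, 0, 0.15)

    cols <- list(); samples <- list()
    for (j in seq_len(nPairs)) {
        for (cond in c("HSPC", "Prog")) {
            lv <- baseLog + subjEff[j] + batchEff[expOf[j]] +
                (cond == "HSPC") * trueFc * log(2) +
                stats::rnorm(nrow(g), 0, 0.3)
            cols[[length(cols) + 1L]] <- exp(lv)
            samples[[length(samples) + 1L]] <- data.frame(
                sample_id = sprintf("L%02d_%s", j, cond), role = "biological",
                condition = cond, subject_id = sprintf("lsub%02d", j),
                replicate_group = sprintf("L%02d_%s", j, cond),
                experiment_id = sprintf("exp%d", expOf[j]),
                freezing_condition = "fresh", age = NA_real_,
                stringsAsFactors = FALSE)
        }
    }
    for (e in 1:2) for (b in 1:3) {
        cols[[length(cols) + 1L]] <-
            exp(log(100) + stats::rnorm(nrow(g), 0, 0.3))
        samples[[length(samples) + 1L]] <- data.frame(
            sample_id = sprintf("Lblank_e%d_%d", e, b), role = "blank",
            condition = NA_character_, subject_id = "",
            replicate_group = sprintf("Lblank_e%d_%d", e, b),
            experiment_id = sprintf("exp%d", e),
            freezing_condition = "fresh", age = NA_real_,
            stringsAsFactors = FALSE)
    }
    v <- do.call(cbind, cols)
    sm <- do.call(rbind, samples)
    fm <- data.frame(feature_id = sprintf("lip%03d", seq_len(nrow(g))),
                     name = names, formula = unname(formulas), mz = unname(mz),
                     rt = rt, pathway = "", stringsAsFactors = FALSE)
    # split some species into two isomer rows with the same name + formula
    dup <- which(stats::runif(nrow(g)) < isomerDupRate)
    if (length(dup)) {
        frac <- stats::runif(length(dup), 0.3, 0.7)
        vDup <- v[dup, , drop = FALSE] * (1 - frac)
        v[dup, ] <- v[dup, , drop = FALSE] * frac
        fmDup <- fm[dup, , drop = FALSE]
        fmDup$feature_id <- paste0(fm$feature_id[dup], "b")
        v <- rbind(v, vDup)
        fm <- rbind(fm, fmDup)
    }
    # same formula, different annotated names: never merged
    pc341 <- which(fm$name == "PC 34:1")[1L]
    extra <- fm[pc341, , drop = FALSE]
    extra$feature_id <- "lipchain1"
    extra$name <- "PC 16:0_18:1"
    v <- rbind(v, v[pc341, , drop = FALSE] * 0.5)
    fm <- rbind(fm, extra)
    # same name, conflicting formula: flagged, not merged
    conf <- fm[pc341, , drop = FALSE]
    conf$feature_id <- "lipconflict1"
    conf$formula <- paste0(conf$formula, "S")
    v <- rbind(v, v[pc341, , drop = FALSE] * 0.1)
    fm <- rbind(fm, conf)
    idx <- match(fm$name, names)
    truth <- data.frame(feature_id = fm$feature_id, name = fm$name,
                        lipid_class = g$class[idx], ether = g$ether[idx],
                        carbons = g$C[idx], db = g$DB[idx],
                        true_log2fc = trueFc[idx], stringsAsFactors = FALSE)
    chain <- is.na(idx)   # the chain-resolved "PC 16:0_18:1" row
    truth$lipid_class[chain] <- "PC"
    truth$ether[chain] <- FALSE
    truth$carbons[chain] <- 34L
    truth$db[chain] <- 1L
    truth$true_log2fc[chain] <- 0
    list(table = FeatureTable(v, sm, fm), truth = truth)
}

.DEFAULT_TRACING <- data.frame(
    compound_id = c("choline", "phosphocholine", "betaine", "methionine",
                    "control_choline"),
    n_carbons = c(5, 5, 5, 5, 5),
    k = c(3, 3, 3, 1, 3),
    L = c(0.3, 0.2, 0.1, 0.05, 0),
    stringsAsFactors = FALSE)

#' Synthetic isotopologue tracing dataset
#'
#' For each compound with `n_carbons` carbons, label index `k` and true
#' labelled fraction `L`, observed per-sample MDVs are generated as
#' `M ((1-L) e0 + L ek)` (M the natural-abundance correction matrix) times
#' an intensity scale with per-isotopologue multiplicative log-normal
#' noise. Optionally also emits Gaussian chromatogram traces on a shared
#' RT axis whose areas follow the first sample's MDV.
#'
#' @param seed integer RNG seed
#' @param compounds data.frame with `compound_id`, `n_carbons`, `k`, `L`
#'   (defaults to an M+3 choline-pathway panel plus an unlabelled control)
#' @param noiseCv multiplicative noise CV (default 0.01)
#' @param p13c natural 13C abundance (default 0.0107)
#' @param nSamples samples per compound (default 6)
#' @param intensityScale total-intensity scale (default 1e5)
#' @param chromatograms also generate Gaussian traces (default FALSE)
#' @return list with `mdvTable` (long data.frame: compound_id, n_carbons,
#'   k, isotopologue_index, sample, intensity), optional `chromatograms`
#'   (data.frame: compound_id, isotopologue_index, rt_s, intensity) and
#'   `truth` (the compounds table)
#' @export
genTracing <- function(seed, compounds = .DEFAULT_TRACING, noiseCv = 0.01,
                       p13c = 0.0107, nSamples = 6, intensityScale = 1e5,
                       chromatograms = FALSE) {
    stopifnot(all(compounds$L >= 0 & compounds$L <= 1))
    set.seed(seed)
    sdlog <- sqrt(log(1 + noiseCv^2))
    rows <- list()
    for (i in seq_len(nrow(compounds))) {
        n <- compounds$n_carbons[i]; k <- compounds$k[i]
        L <- compounds$L[i]
        cm <- buildCorrectionMatrix(n, p13c)
        mix <- (1 - L) * mdvValues(theoreticalMdv(n, 0, p13c)) +
               L * mdvValues(theoreticalMdv(n, k, p13c))
        for (s in seq_len(nSamples)) {
            noise <- stats::rlnorm(n + 1L, -sdlog^2 / 2, sdlog)
            rows[[length(rows) + 1L]] <- data.frame(
                compound_id = compounds$compound_id[i], n_carbons = n, k = k,
                isotopologue_index = 0:n,
                sample = sprintf("t%02d", s),
                intensity = intensityScale * mix * noise,
                stringsAsFactors = FALSE)
        }
    }
    out <- list(mdvTable = do.call(rbind, rows), truth = compounds)
    if (chromatograms) {
        n <- compounds$n_carbons[1L]
        first <- out$mdvTable[out$mdvTable$compound_id ==
                                  compounds$compound_id[1L] &
                              out$mdvTable$sample == "t01", ]
        rt <- seq(0, 60, by = 0.5)
        out$chromatograms <- do.call(rbind, lapply(0:n, function(kk) {
            amp <- first$intensity[first$isotopologue_index == kk]
            data.frame(compound_id = compounds$compound_id[1L],
                       isotopologue_index = kk, rt_s = rt,
                       intensity = amp * exp(-(rt - 30)^2 / (2 * 5^2)),
                       stringsAsFactors = FALSE)
        }))
    }
    out
}

#' Synthetic regulon, expression-statistic and pathway inputs
#'
#' Gene-level differential statistics are a sum of active-TF weight
#' contributions plus Gaussian noise; regulons carry signed weights;
#' pathways are built with controlled enzyme counts (including exactly 4
#' and exactly 5 detected enzymes to probe the metabologram eligibility
#' boundary) and metabolite members (including one pathway with none).
#'
#' @param seed integer RNG seed
#' @param nGenes genes (default 2000)
#' @param nTfs transcription factors (default 20)
#' @param targetsPerTf targets per TF (default 30)
#' @param nActive number of truly active TFs (default 5; alternating sign
#'   activity of magnitude `activityScale`)
#' @param activityScale magnitude of true TF activity (default 2)
#' @param noiseSd residual noise of the gene statistic (default 0.5)
#' @return list with `geneStat` (named vector), `regulons` (list of
#'   data.frames), `geneSets`, `metabSets`, `metabStats` (toy metabolite
#'   log2fc table) and `truth` (per-TF true activity sign)
#' @export
genRegulonExpression <- function(seed, nGenes = 2000, nTfs = 20,
                                 targetsPerTf = 30, nActive = 5,
                                 activityScale = 2, noiseSd = 0.5) {
    set.seed(seed)
    genes <- sprintf("g%04d", seq_len(nGenes))
    tfs <- sprintf("tf%02d", seq_len(nTfs))
    activity <- numeric(nTfs)
    if (nActive > 0)
        activity[seq_len(nActive)] <- activityScale *
            rep_len(c(1, -1), nActive)
    regulons <- list()
    geneStat <- stats::setNames(rep(0, nGenes), genes)
    for (t in seq_len(nTfs)) {
        targets <- sample(genes, targetsPerTf)
        weights <- stats::rnorm(targetsPerTf)
        regulons[[tfs[t]]] <- data.frame(target = targets, weight = weights,
                                         stringsAsFactors = FALSE)
        geneStat[targets] <- geneStat[targets] + activity[t] * weights
    }
    geneStat <- geneStat + stats::rnorm(nGenes, 0, noiseSd)
    enzCounts <- c(4, 5, 8, 12, 20, 30)
    metCounts <- c(1, 1, 0, 2, 3, 2)
    geneSets <- list(); metabSets <- list()
    metabIds <- sprintf("m%03d", 1:20)
    for (i in seq_along(enzCounts)) {
        pw <- sprintf("pathway%02d", i)
        geneSets[[pw]] <- sample(genes, enzCounts[i])
        metabSets[[pw]] <- if (metCounts[i] > 0) sample(metabIds,
                                                        metCounts[i])
                           else character()
    }
    metabStats <- data.frame(id = metabIds,
                             log2fc = stats::rnorm(20, 0, 1),
                             padj = stats::runif(20),
                             stringsAsFactors = FALSE)
    list(geneStat = geneStat, regulons = regulons, geneSets = geneSets,
         metabSets = metabSets, metabStats = metabStats,
         truth = data.frame(tf = tfs, true_activity = activity,
                            stringsAsFactors = FALSE))
}
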