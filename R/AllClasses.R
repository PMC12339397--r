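#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData
#'   rowData colData<- rowData<-
NULL

.FT_SAMPLE_COLS <- c("sample_id", "role", "condition", "subject_id",
                     "replicate_group", "experiment_id", "freezing_condition",
                     "age")
.FT_FEATURE_COLS <- c("feature_id", "name", "formula", "mz", "rt", "pathway")
.FT_ROLES <- c("biological", "technical", "blank")

#' FeatureTable: features-by-samples peak-area container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay
#' (`"areas"`: chromatographic peak areas, AUC, linear scale, `NA` = missing)
#' plus the sample and feature annotations the low-input LC-MS pipeline needs.
#'
#' `colData` carries `sample_id`, `role` (`"biological"`, `"technical"` or
#' `"blank"`), `condition`, `subject_id`, `replicate_group` (technical
#' replicates of one biological sample share a group), `experiment_id`,
#' `freezing_condition` and `age` (years). `rowData` carries `feature_id`,
#' `name`, `formula`, `mz` (Da), `rt` (minutes) and `pathway`.
#'
#' Validity enforces: peak areas non-negative where present; blank samples
#' carry no condition label; every technical replicate maps to exactly one
#' biological sample (its `replicate_group` is condition/subject/experiment
#' homogeneous); `feature_id` unique.
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
    msg <- character()
    cd <- colData(object)
    rd <- rowData(object)
    miss <- setdiff(.FT_SAMPLE_COLS, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste("missing colData columns:",
                            paste(miss, collapse = ", ")))
    missf <- setdiff(.FT_FEATURE_COLS, colnames(rd))
    if (length(missf))
        msg <- c(msg, paste("missing rowData columns:",
                            paste(missf, collapse = ", ")))
    if (!"areas" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'areas' is required")
    if (length(msg)) return(msg)
    v <- assay(object, "areas")
    if (any(v < 0, na.rm = TRUE))
        msg <- c(msg, "peak areas must be >= 0 where present")
    if (!all(cd$role %in% .FT_ROLES))
        msg <- c(msg, paste("role must be one of:",
                            paste(.FT_ROLES, collapse = ", ")))
    blank <- cd$role == "blank"
    if (any(!is.na(cd$condition[blank]) & nzchar(cd$condition[blank])))
        msg <- c(msg, "blank samples must carry no condition label")
    if (anyDuplicated(rd$feature_id))
        msg <- c(msg, "feature_id values must be unique")
    tech <- cd$role == "technical"
    if (any(tech)) {
        grp <- cd$replicate_group
        if (any(is.na(grp[tech]) | !nzchar(grp[tech]))) {
            msg <- c(msg, "technical replicates need a replicate_group")
        } else {
            for (g in unique(grp[tech])) {
                i <- which(!blank & grp == g)
                if (length(unique(cd$condition[i])) > 1L ||
                    length(unique(cd$subject_id[i])) > 1L ||
                    length(unique(cd$experiment_id[i])) > 1L)
                    msg <- c(msg, paste0("replicate_group '", g,
                        "' mixes conditions, subjects or experiments"))
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix of peak areas (features x samples); `NA`
#'   encodes a missing (undetected) value, which is distinct from 0.
#' @param sampleMeta data.frame/DataFrame with one row per sample. Required:
#'   `sample_id`, `role`. Optional (filled with defaults): `condition`,
#'   `subject_id`, `replicate_group` (defaults to `sample_id`),
#'   `experiment_id` (defaults to `"exp1"`), `freezing_condition`, `age`.
#' @param featureMeta data.frame/DataFrame with one row per feature. Required:
#'   `feature_id`. Optional: `name` (defaults to `feature_id`), `formula`,
#'   `mz`, `rt`, `pathway`.
#'
#' @return a validated [FeatureTable-class] object.
#' @examples
#' ft <- FeatureTable(
#'   matrix(c(100, 200, NA, 50), 2, 2,
#'          dimnames = list(c("cit", "mal"), c("s1", "s2"))),
#'   sampleMeta = data.frame(sample_id = c("s1", "s2"),
#'                           role = "biological",
#'                           condition = c("HSPC", "Prog")),
#'   featureMeta = data.frame(feature_id = c("cit", "mal")))
#' ft
#' @export
FeatureTable <- function(values, sampleMeta, featureMeta) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    sampleMeta <- as.data.frame(sampleMeta)
    featureMeta <- as.data.frame(featureMeta)
    stopifnot("sample_id" %in% colnames(sampleMeta),
              "feature_id" %in% colnames(featureMeta))
    if (is.null(sampleMeta$role)) sampleMeta$role <- "biological"
    if (is.null(sampleMeta$condition)) sampleMeta$condition <- NA_character_
    if (is.null(sampleMeta$subject_id)) sampleMeta$subject_id <- ""
    if (is.null(sampleMeta$replicate_group))
        sampleMeta$replicate_group <- sampleMeta$sample_id
    if (is.null(sampleMeta$experiment_id)) sampleMeta$experiment_id <- "exp1"
    if (is.null(sampleMeta$freezing_condition))
        sampleMeta$freezing_condition <- ""
    if (is.null(sampleMeta$age)) sampleMeta$age <- NA_real_
    sampleMeta$condition[sampleMeta$role == "blank"] <- NA_character_
    if (is.null(featureMeta$name)) featureMeta$name <- featureMeta$feature_id
    if (is.null(featureMeta$formula)) featureMeta$formula <- ""
    if (is.null(featureMeta$mz)) featureMeta$mz <- NA_real_
    if (is.null(featureMeta$rt)) featureMeta$rt <- NA_real_
    if (is.null(featureMeta$pathway)) featureMeta$pathway <- ""
    rownames(values) <- featureMeta$feature_id
    colnames(values) <- sampleMeta$sample_id
    se <- SummarizedExperiment(
        assays = list(areas = values),
        colData = DataFrame(sampleMeta, row.names = sampleMeta$sample_id),
        rowData = DataFrame(featureMeta, row.names = featureMeta$feature_id))
    new("FeatureTable", se)
}

#' @describeIn FeatureTable compact display
#' @param object a FeatureTable
#' @export
setMethod("show", "FeatureTable", function(object) {
    cd <- colData(object)
    cat("FeatureTable:", nrow(object), "features x", ncol(object), "samples\n")
    cat("  roles:", paste(sprintf("%s=%d", names(table(cd$role)),
                                  table(cd$role)), collapse = ", "), "\n")
    cond <- unique(stats::na.omit(cd$condition))
    if (length(cond))
        cat("  conditions:", paste(cond, collapse = ", "), "\n")
    cat("  experiments:", paste(unique(cd$experiment_id), collapse = ", "),
        "\n")
    nmiss <- sum(is.na(assay(object, "areas")))
    cat("  missing values:", nmiss, "\n")
    invisible(NULL)
})

#' Re-exported metadata accessors
#'
#' [SummarizedExperiment::rowData()] and
#' [SummarizedExperiment::colData()] re-exported so FeatureTable metadata
#' is reachable without attaching SummarizedExperiment.
#' @param x a FeatureTable (or any SummarizedExperiment)
#' @param ... passed through
#' @name accessors
NULL

#' @rdname accessors
#' @export
rowData <- SummarizedExperiment::rowData

#' @rdname accessors
#' @export
colData <- SummarizedExperiment::colData

#' Peak-area matrix of a FeatureTable
#' @param x a FeatureTable
#' @return numeric matrix (features x samples), `NA` = missing
#' @export
areas <- function(x) assay(x, "areas")

#' @rdname areas
#' @param value replacement matrix with identical dimensions
#' @export
`areas<-` <- function(x, value) {
    assay(x, "areas") <- value
    x
}

#' ExtractionSummary: sample-preparation volume bookkeeping
#'
#' Captures the volume arithmetic of sorting cells into extraction buffer:
#' the sheath-fluid volume delivered with the cells, the final extract
#' volume, the solvent composition of that final volume, and the NaCl mass
#' carried in by the sheath fluid.
#'
#' @slot finalVolume final extract volume, microlitres
#' @slot sheathVolume sheath-fluid volume delivered by the sorter, microlitres
#' @slot componentFractions named numeric, fraction of final volume per
#'   solvent (sums to 1)
#' @slot naclMass_mg milligrams of NaCl contributed by the sheath fluid
#' @export
setClass("ExtractionSummary",
    representation(finalVolume = "numeric", sheathVolume = "numeric",
                   componentFractions = "numeric", naclMass_mg = "numeric"))

setValidity("ExtractionSummary", function(object) {
    if (abs(sum(object@componentFractions) - 1) > 1e-9)
        return("component fractions must sum to 1")
    if (object@finalVolume < 0 || object@sheathVolume < 0 ||
        object@sheathVolume > object@finalVolume + 1e-12)
        return("volumes inconsistent")
    TRUE
})

#' @describeIn ExtractionSummary display volumes and composition
#' @param object an ExtractionSummary
#' @export
setMethod("show", "ExtractionSummary", function(object) {
    cat(sprintf("ExtractionSummary: final volume %.3g ul (sheath %.3g ul)\n",
                object@finalVolume, object@sheathVolume))
    f <- object@componentFractions
    cat("  composition:", paste(sprintf("%s %.1f%%", names(f), 100 * f),
                                collapse = ", "), "\n")
    cat(sprintf("  NaCl from sheath: %.4g mg\n", object@naclMass_mg))
    invisible(NULL)
})

#' Accessors for ExtractionSummary
#' @param x an ExtractionSummary
#' @return `finalVolume`/`sheathVolume`: microlitres;
#'   `componentFractions`: named fractions summing to 1.
#' @export
finalVolume <- function(x) x@finalVolume
#' @rdname finalVolume
#' @export
sheathVolume <- function(x) x@sheathVolume
#' @rdname finalVolume
#' @export
componentFractions <- function(x) x@componentFractions

#' LipidAnnotation: parsed shorthand lipid name
#'
#' Result of parsing a shorthand lipid species name such as `"SM 38:1;O2"`,
#' `"PC O-34:2"` or chain-resolved `"PE 16:0_18:1"`.
#'
#' @slot lipidClass class code: PC, PE, SM, TG, LPC, PI, CAR or other
#' @slot classToken the literal class token as parsed (kept for "other")
#' @slot ether TRUE for ether-linked species (`O-` prefix)
#' @slot totalCarbons total acyl-chain carbons
#' @slot totalDoubleBonds total acyl-chain double bonds (unsaturations)
#' @slot oxygenSuffix the `;O<k>` hydroxylation count (0 if absent)
#' @slot chains integer matrix with columns carbons, double_bonds; zero rows
#'   when only species-level totals are annotated
#' @slot chainOrderKnown TRUE when chains were separated by "/" (sn-position
#'   known), FALSE for "_"
#' @export
setClass("LipidAnnotation",
    representation(lipidClass = "character", classToken = "character",
                   ether = "logical", totalCarbons = "integer",
                   totalDoubleBonds = "integer", oxygenSuffix = "integer",
                   chains = "matrix", chainOrderKnown = "logical"))

setValidity("LipidAnnotation", function(object) {
    msg <- character()
    if (object@totalCarbons < 0L || object@totalDoubleBonds < 0L ||
        object@oxygenSuffix < 0L)
        msg <- c(msg, "carbon, double-bond and oxygen counts must be >= 0")
    if (nrow(object@chains)) {
        if (sum(object@chains[, 1L]) != object@totalCarbons)
            msg <- c(msg, "chain carbons must sum to total carbons")
        if (sum(object@chains[, 2L]) != object@totalDoubleBonds)
            msg <- c(msg, "chain double bonds must sum to total")
    }
    if (object@ether && !object@lipidClass %in% c("PC", "PE"))
        msg <- c(msg, "ether linkage only supported for PC and PE")
    if (length(msg)) msg else TRUE
})

#' @describeIn LipidAnnotation display the normalized name and classification
#' @param object a LipidAnnotation
#' @export
setMethod("show", "LipidAnnotation", function(object) {
    cat("LipidAnnotation:", formatLipidName(object), "\n")
    cat(sprintf("  class %s%s, C%d:%d%s\n", object@lipidClass,
                if (object@ether) " (ether)" else "", object@totalCarbons,
                object@totalDoubleBonds,
                if (object@oxygenSuffix) sprintf(", ;O%d", object@oxygenSuffix)
                else ""))
    if (nrow(object@chains))
        cat("  chains:", paste(sprintf("%d:%d", object@chains[, 1L],
                                       object@chains[, 2L]),
                               collapse = if (object@chainOrderKnown) "/"
                                          else "_"), "\n")
    invisible(NULL)
})

#' MDV: mass-isotopologue distribution vector
#'
#' Relative intensities (or fractions) of the M+0 ... M+n isotopologues of a
#' compound with `nCarbons` carbon atoms; `labelIndex` records which M+k the
#' tracer produces (e.g. 3 for 13C3-choline).
#'
#' @slot compoundId compound identifier
#' @slot nCarbons number of carbon atoms
#' @slot values numeric vector of length `nCarbons + 1` (M+0 first)
#' @slot labelIndex tracer label index k (M+k), `NA` if not applicable
#' @slot isCorrected TRUE once natural-abundance corrected (then `values`
#'   are fractions summing to 1)
#' @export
setClass("MDV",
    representation(compoundId = "character", nCarbons = "integer",
                   values = "numeric", labelIndex = "integer",
                   isCorrected = "logical"))

setValidity("MDV", function(object) {
    msg <- character()
    if (length(object@values) != object@nCarbons + 1L)
        msg <- c(msg, "values must have length nCarbons + 1")
    if (any(object@values < -1e-12, na.rm = TRUE))
        msg <- c(msg, "MDV entries must be >= 0")
    if (isTRUE(object@isCorrected) && !anyNA(object@values) &&
        abs(sum(object@values) - 1) > 1e-9)
        msg <- c(msg, "corrected fractions must sum to 1")
    if (length(msg)) msg else TRUE
})

#' @describeIn MDV display isotopologue fractions
#' @param object an MDV
#' @export
setMethod("show", "MDV", function(object) {
    cat(sprintf("MDV '%s' (%d carbons%s, %s):\n", object@compoundId,
                object@nCarbons,
                if (!is.na(object@labelIndex))
                    sprintf(", label M+%d", object@labelIndex) else "",
                if (object@isCorrected) "corrected fractions"
                else "raw intensities"))
    v <- object@values
    names(v) <- paste0("M+", seq_along(v) - 1L)
    print(signif(v, 4))
    invisible(NULL)
})

#' @rdname MDV-class
#' @param x an MDV
#' @return `mdvValues`: the numeric vector M+0..M+n.
#' @export
mdvValues <- function(x) x@values

#' CorrectionMatrix: theoretical isotopologue basis for NA correction
#'
#' Column k+1 holds the theoretical isotopologue distribution of a species
#' with exactly k tracer-labelled carbons, with binomial 13C natural
#' abundance on the remaining `n - k` carbons. Every column sums to 1.
#'
#' @slot matrix (n+1) x (n+1) matrix of column distributions
#' @slot nCarbons number of carbons n
#' @slot p13c natural 13C abundance used (default 0.0107)
#' @export
setClass("CorrectionMatrix",
    representation(matrix = "matrix", nCarbons = "integer", p13c = "numeric"))

setValidity("CorrectionMatrix", function(object) {
    m <- object@matrix
    if (nrow(m) != object@nCarbons + 1L || ncol(m) != object@nCarbons + 1L)
        return("matrix must be (n+1) x (n+1)")
    if (any(abs(colSums(m) - 1) > 1e-9))
        return("every column must sum to 1")
    TRUE
})

#' @describeIn CorrectionMatrix display dimensions and abundance
#' @param object a CorrectionMatrix
#' @export
setMethod("show", "CorrectionMatrix", function(object) {
    cat(sprintf("CorrectionMatrix: %d carbons, p13C = %.4f\n",
                object@nCarbons, object@p13c))
    invisible(NULL)
})

#' DifferentialResult: per-feature differential-abundance statistics
#'
#' A [S4Vectors::DataFrame] subclass with one row per tested feature and
#' columns `feature_id`, `name`, `class`, `log2fc` (clamped, always finite),
#' `pvalue`, `padj`, `test_used` ("t" or "wilcoxon"), `paired`, `mean_A`,
#' `mean_B`, `detected_flag` and `significant` (`padj < 0.05`).
#' @export
setClass("DifferentialResult", contains = "DFrame")

#' Metabologram: pathway-scoped metabolome-transcriptome summary
#'
#' Peripheral slices are the pathway's enzymes (gene log2FC + adjusted p) and
#' measured metabolites (feature log2FC + adjusted p); the centre holds the
#' mean log2FC of each half with a one-sample Wilcoxon signed-rank p-value.
#' A pathway is eligible only with >= 5 detected enzymes and >= 1 measured
#' metabolite.
#'
#' @slot pathwayId pathway identifier
#' @slot geneSlices DataFrame: id, log2fc, padj, stars
#' @slot metabSlices DataFrame: id, log2fc, padj, stars
#' @slot centerGeneAvg mean enzyme log2FC
#' @slot centerMetabAvg mean metabolite log2FC
#' @slot centerGeneP signed-rank p for the enzyme log2FCs vs 0
#' @slot centerMetabP signed-rank p for the metabolite log2FCs vs 0
#' @slot eligible TRUE when the >=5-enzyme / >=1-metabolite rule is met
#' @slot reason skip reason when ineligible ("" otherwise)
#' @export
setClass("Metabologram",
    representation(pathwayId = "character", geneSlices = "DFrame",
                   metabSlices = "DFrame", centerGeneAvg = "numeric",
                   centerMetabAvg = "numeric", centerGeneP = "numeric",
                   centerMetabP = "numeric", eligible = "logical",
                   reason = "character"))

#' @describeIn Metabologram display centre summaries
#' @param object a Metabologram
#' @export
setMethod("show", "Metabologram", function(object) {
    cat(sprintf("Metabologram '%s': %s\n", object@pathwayId,
                if (object@eligible) "eligible"
                else paste("skipped -", object@reason)))
    if (object@eligible) {
        cat(sprintf("  %d enzyme slices, centre log2FC %.3f (P = %.3g)\n",
                    nrow(object@geneSlices), object@centerGeneAvg,
                    object@centerGeneP))
        cat(sprintf("  %d metabolite slices, centre log2FC %.3f (P = %.3g)\n",
                    nrow(object@metabSlices), object@centerMetabAvg,
                    object@centerMetabP))
    }
    invisible(NULL)
})
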