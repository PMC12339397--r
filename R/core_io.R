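## Tabular I/O, configuration, logging and the sample-preparation arithmetic.

.LOG_LEVELS <- c(DEBUG = 10L, INFO = 20L, WARN = 30L, ERROR = 40L)

#' Set the package logging threshold
#'
#' Filtering operations report feature counts before/after at INFO level.
#'
#' @param level one of "DEBUG", "INFO", "WARN", "ERROR"
#' @return the previous level, invisibly
#' @export
setLogLevel <- function(level = c("INFO", "DEBUG", "WARN", "ERROR")) {
    level <- match.arg(level)
    old <- getOption("microMetab.logLevel", "INFO")
    options(microMetab.logLevel = level)
    invisible(old)
}

mmLog <- function(level, fmt, ...) {
    threshold <- .LOG_LEVELS[[getOption("microMetab.logLevel", "INFO")]]
    if (.LOG_LEVELS[[level]] >= threshold)
        message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
    invisible(NULL)
}

#' Read a pipeline configuration file
#'
#' YAML key-value configuration with nested sections (e.g. `schema:`,
#' `thresholds:`, `seed:`). Unknown keys are kept as-is.
#'
#' @param path path to a YAML file
#' @return a named list
#' @export
readConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
}

.detectDelim <- function(path) {
    first <- readLines(path, n = 1L)
    counts <- c("," = lengths(regmatches(first, gregexpr(",", first))),
                "\t" = lengths(regmatches(first, gregexpr("\t", first))),
                ";" = lengths(regmatches(first, gregexpr(";", first))))
    names(counts)[which.max(counts)]
}

#' Read a delimited feature table
#'
#' Reads a features-in-rows, samples-in-columns peak-area export (CSV/TSV,
#' delimiter auto-detected) and assembles a validated [FeatureTable-class].
#' Unparseable numeric cells (including empty cells and the `"NA"` token)
#' become missing values, never zero; zeros must be explicit in the file.
#'
#' @param path delimited text file with a header row
#' @param schema list mapping file columns to roles:
#'   `feature_id` (mandatory), optional `name`, `formula`, `mz`, `rt`,
#'   `pathway` naming feature-annotation columns; `samples` either a
#'   character vector of sample column names or `NULL` (all remaining
#'   columns).
#' @param sampleMeta optional data.frame of per-sample annotations
#'   (`sample_id`, `role`, `condition`, ...); defaults make every sample a
#'   biological singleton in one experiment.
#' @return a [FeatureTable-class]
#' @export
readFeatureTable <- function(path, schema = list(feature_id = "feature_id"),
                             sampleMeta = NULL) {
    if (is.null(schema$feature_id))
        stop("schema error: 'feature_id' column mapping is mandatory")
    delim <- .detectDelim(path)
    raw <- utils::read.table(path, header = TRUE, sep = delim,
                             check.names = FALSE, colClasses = "character",
                             quote = "\"", comment.char = "")
    for (col in c("feature_id")) {
        if (!schema[[col]] %in% colnames(raw))
            stop("schema error: column '", schema[[col]], "' not in file")
    }
    annCols <- c(feature_id = schema$feature_id, name = schema$name,
                 formula = schema$formula, mz = schema$mz, rt = schema$rt,
                 pathway = schema$pathway)
    annCols <- annCols[!vapply(annCols, is.null, logical(1))]
    sampleCols <- schema$samples
    if (is.null(sampleCols))
        sampleCols <- setdiff(colnames(raw), unname(annCols))
    missingSamp <- setdiff(sampleCols, colnames(raw))
    if (length(missingSamp))
        stop("schema error: sample columns not in file: ",
             paste(missingSamp, collapse = ", "))
    if (anyDuplicated(raw[[annCols[["feature_id"]]]]))
        stop("validation error: duplicate feature_id values in ", path)
    vals <- suppressWarnings(
        vapply(sampleCols, function(cn) as.numeric(raw[[cn]]),
               numeric(nrow(raw))))
    if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L,
                                        dimnames = list(NULL, sampleCols))
    fm <- data.frame(feature_id = raw[[annCols[["feature_id"]]]],
                     stringsAsFactors = FALSE)
    fm$name <- if ("name" %in% names(annCols)) raw[[annCols[["name"]]]]
               else fm$feature_id
    fm$formula <- if ("formula" %in% names(annCols))
                      raw[[annCols[["formula"]]]] else ""
    fm$mz <- if ("mz" %in% names(annCols))
                 suppressWarnings(as.numeric(raw[[annCols[["mz"]]]]))
             else NA_real_
    fm$rt <- if ("rt" %in% names(annCols))
                 suppressWarnings(as.numeric(raw[[annCols[["rt"]]]]))
             else NA_real_
    fm$pathway <- if ("pathway" %in% names(annCols))
                      raw[[annCols[["pathway"]]]] else ""
    if (is.null(sampleMeta))
        sampleMeta <- data.frame(sample_id = sampleCols, role = "biological",
                                 stringsAsFactors = FALSE)
    sampleMeta <- sampleMeta[match(sampleCols, sampleMeta$sample_id), ,
                             drop = FALSE]
    if (anyNA(sampleMeta$sample_id))
        stop("validation error: sampleMeta does not cover all sample columns")
    ft <- FeatureTable(vals, sampleMeta, fm)
    mmLog("INFO", "read %d features x %d samples from %s",
          nrow(ft), ncol(ft), path)
    ft
}

#' Write (and read back) a differential-result table
#'
#' Writes tab-separated text with the fixed column order `feature_id, name,
#' class, log2fc, pvalue, padj, test_used, mean_A, mean_B, detected_flag`
#' (plus any extra columns after these). Missing values are written as the
#' literal `NA`; numbers carry 15 significant digits so a round-trip
#' reproduces them to at least 12.
#'
#' @param results a [DifferentialResult-class] or data.frame
#' @param path output file path
#' @return `writeResults`: the path, invisibly. `readResults`: the table as
#'   a [DifferentialResult-class].
#' @export
writeResults <- function(results, path) {
    results <- as.data.frame(results)
    if (!nrow(results)) stop("results table is empty")
    lead <- c("feature_id", "name", "class", "log2fc", "pvalue", "padj",
              "test_used", "mean_A", "mean_B", "detected_flag")
    for (col in setdiff(lead, colnames(results)))
        results[[col]] <- NA
    results <- results[, c(lead, setdiff(colnames(results), lead)),
                       drop = FALSE]
    num <- vapply(results, is.numeric, logical(1))
    out <- results
    out[num] <- lapply(results[num], function(x) {
        s <- formatC(x, digits = 15, format = "g")
        s[is.na(x)] <- NA
        s
    })
    con <- tryCatch(file(path, "w"), error = function(e)
        stop("I/O error: cannot open ", path, " for writing"))
    on.exit(close(con))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, na.strings = "NA",
                            quote = "\"", comment.char = "")
    new("DifferentialResult", DataFrame(df))
}

#' Write a FeatureTable to delimited text
#'
#' Writes the feature annotations (`feature_id, name, formula, mz, rt,
#' pathway`) followed by one column per sample to `path` (CSV), and the
#' sample metadata to `paste0(path, ".samples.tsv")`. Missing peak areas
#' become the literal `NA`. The pair round-trips through
#' [readFeatureTable()] with `sampleMeta` pointed at the sidecar file.
#'
#' @param table a [FeatureTable-class]
#' @param path output CSV path
#' @return the path, invisibly
#' @export
writeFeatureTable <- function(table, path) {
    rd <- as.data.frame(rowData(table))[, .FT_FEATURE_COLS]
    v <- areas(table)
    num <- as.data.frame(v)
    num[] <- lapply(as.data.frame(v), function(x) {
        s <- formatC(x, digits = 15, format = "g")
        s[is.na(x)] <- NA
        s
    })
    out <- cbind(rd, num)
    utils::write.table(out, path, sep = ",", quote = FALSE,
                       row.names = FALSE, na = "NA")
    utils::write.table(as.data.frame(colData(table))[, .FT_SAMPLE_COLS],
                       paste0(path, ".samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    invisible(path)
}

#' @rdname writeFeatureTable
#' @param path CSV written by `writeFeatureTable`
#' @export
loadFeatureTable <- function(path) {
    sm <- utils::read.table(paste0(path, ".samples.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE,
                            na.strings = "NA",
                            colClasses = c(age = "numeric"))
    readFeatureTable(path,
                     schema = list(feature_id = "feature_id", name = "name",
                                   formula = "formula", mz = "mz", rt = "rt",
                                   pathway = "pathway"),
                     sampleMeta = sm)
}

#' Sample-preparation volume calculator
#'
#' FACS sorting delivers each cell in a droplet of sheath fluid (water with
#' 2 g/l NaCl), so the sorted cells contribute `cellCount x dropletVolume`
#' of water to the extraction buffer. With a 1 nl droplet, 5,000 cells come
#' with 5 ul of sheath fluid; sorting into 15 ul of 2:1
#' 2-propanol:acetonitrile yields a 20 ul extract at 2:1:1
#' 2-propanol:acetonitrile:water, i.e. 50% / 25% / 25%.
#'
#' @param cellCount number of sorted cells (>= 0)
#' @param dropletVolume_nl droplet volume in nanolitres (> 0; 1 nl for a
#'   70 um nozzle)
#' @param bufferVolume_ul extraction-buffer volume in microlitres
#' @param bufferParts named numeric, relative parts of each solvent in the
#'   buffer (e.g. `c("2-propanol" = 2, acetonitrile = 1)`)
#' @param naclConc_g_l NaCl concentration of the sheath fluid, g/l
#' @return an [ExtractionSummary-class]; sheath fluid counts as water in the
#'   final composition.
#' @examples
#' extractionCalculator(5000, 1, 15,
#'                      c("2-propanol" = 2, acetonitrile = 1))
#' @export
extractionCalculator <- function(cellCount, dropletVolume_nl,
                                 bufferVolume_ul,
                                 bufferParts = c(acetonitrile = 1),
                                 naclConc_g_l = 2) {
    if (cellCount < 0) stop("domain error: cellCount must be >= 0")
    if (dropletVolume_nl <= 0) stop("domain error: dropletVolume_nl must be > 0")
    if (bufferVolume_ul < 0) stop("domain error: bufferVolume_ul must be >= 0")
    if (any(bufferParts <= 0)) stop("domain error: buffer parts must be > 0")
    sheath_ul <- cellCount * dropletVolume_nl * 1e-3   # nl -> ul
    final_ul <- bufferVolume_ul + sheath_ul
    comp_ul <- bufferVolume_ul * bufferParts / sum(bufferParts)
    water <- sheath_ul + if ("water" %in% names(comp_ul))
        comp_ul[["water"]] else 0
    comp_ul <- comp_ul[setdiff(names(comp_ul), "water")]
    comp_ul <- c(comp_ul, water = water)
    fractions <- comp_ul / final_ul
    # NaCl mass from sheath volume; no claim is made about w/v percentages
    nacl_mg <- sheath_ul * 1e-6 * naclConc_g_l * 1e3
    new("ExtractionSummary", finalVolume = final_ul,
        sheathVolume = sheath_ul, componentFractions = fractions,
        naclMass_mg = nacl_mg)
}
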