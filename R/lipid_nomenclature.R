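## Shorthand lipid nomenclature: parsing, normalization, classification and
## isomer merging.

.LIPID_CLASSES <- c("PC", "PE", "SM", "TG", "LPC", "PI", "CAR")

#' Parse a shorthand lipid name
#'
#' Accepts species-level names (`"SM 38:1;O2"`, `"PC O-34:2"`) and
#' chain-resolved names (`"PE 16:0_18:1"`, `"PC 16:0/18:1"`). `/` separates
#' chains of known sn-position order, `_` chains of unknown order. Unknown
#' class tokens are retained and classified as `"other"`; the `;O<k>`
#' hydroxylation suffix is parsed for any class.
#'
#' @param name shorthand lipid name
#' @return a [LipidAnnotation-class]
#' @examples
#' parseLipidName("SM 38:1;O2")
#' parseLipidName("PE 16:0_18:1")
#' parseLipidName("PC O-34:2")
#' @export
parseLipidName <- function(name) {
    stopifnot(is.character(name), length(name) == 1L)
    s <- trimws(name)
    m <- regexec("^([A-Za-z][A-Za-z0-9-]*?)[ ]+(O-)?([0-9:/_]+)(;O([0-9]+))?$",
                 s)
    parts <- regmatches(s, m)[[1L]]
    if (!length(parts))
        stop("parse error: malformed lipid name '", name, "'")
    token <- parts[2L]
    ether <- parts[3L] == "O-"
    body <- parts[4L]
    oxy <- if (nzchar(parts[6L])) as.integer(parts[6L]) else 0L
    cls <- if (token %in% .LIPID_CLASSES) token else "other"
    sep <- if (grepl("/", body, fixed = TRUE)) "/"
           else if (grepl("_", body, fixed = TRUE)) "_" else NA_character_
    chainStrs <- if (is.na(sep)) body else strsplit(body, sep, fixed = TRUE)[[1L]]
    ok <- grepl("^[0-9]+:[0-9]+$", chainStrs)
    if (!all(ok))
        stop("parse error: malformed chain token '", chainStrs[!ok][1L],
             "' in '", name, "'")
    cd <- vapply(strsplit(chainStrs, ":", fixed = TRUE),
                 function(x) as.integer(x), integer(2L))
    if (is.na(sep)) {
        chains <- matrix(integer(), 0L, 2L,
                         dimnames = list(NULL, c("carbons", "double_bonds")))
        totC <- cd[1L, 1L]; totD <- cd[2L, 1L]
    } else {
        chains <- t(cd)
        colnames(chains) <- c("carbons", "double_bonds")
        totC <- sum(chains[, 1L]); totD <- sum(chains[, 2L])
    }
    if (ether && !cls %in% c("PC", "PE"))
        stop("parse error: ether prefix 'O-' not supported for class token '",
             token, "'")
    new("LipidAnnotation", lipidClass = cls, classToken = token,
        ether = ether, totalCarbons = totC, totalDoubleBonds = totD,
        oxygenSuffix = oxy, chains = chains,
        chainOrderKnown = identical(sep, "/"))
}

#' Canonical shorthand name of a LipidAnnotation
#'
#' Normalization: single space after the class token, no whitespace around
#' `:` and `;`, chains joined by `/` or `_` according to
#' `chainOrderKnown`. Cross-experiment identity matching relies on this
#' normalized form (including any `;O<k>` suffix).
#'
#' @param a a [LipidAnnotation-class]
#' @return normalized name string
#' @export
formatLipidName <- function(a) {
    body <- if (nrow(a@chains)) {
        paste(sprintf("%d:%d", a@chains[, 1L], a@chains[, 2L]),
              collapse = if (a@chainOrderKnown) "/" else "_")
    } else sprintf("%d:%d", a@totalCarbons, a@totalDoubleBonds)
    paste0(a@classToken, " ", if (a@ether) "O-" else "", body,
           if (a@oxygenSuffix > 0L) sprintf(";O%d", a@oxygenSuffix) else "")
}

#' Normalize a vector of shorthand lipid names
#' @param names character vector of shorthand names
#' @return character vector of normalized names
#' @export
normalizeLipidNames <- function(names) {
    vapply(names, function(n) formatLipidName(parseLipidName(n)),
           character(1L), USE.NAMES = FALSE)
}

#' Parse many lipid names into an annotation table
#' @param names character vector of shorthand names
#' @return [S4Vectors::DataFrame] with columns `name`, `normalized`,
#'   `lipid_class`, `ether`, `total_carbons`, `total_double_bonds`,
#'   `oxygen_suffix`, `n_chains`, `chain_order_known`, `saturation_class`,
#'   `length_class`
#' @export
parseLipidNames <- function(names) {
    anns <- lapply(names, parseLipidName)
    cls <- lapply(anns, classifyLipid)
    DataFrame(
        name = names,
        normalized = vapply(anns, formatLipidName, character(1L)),
        lipid_class = vapply(anns, function(a) a@lipidClass, character(1L)),
        ether = vapply(anns, function(a) a@ether, logical(1L)),
        total_carbons = vapply(anns, function(a) a@totalCarbons, integer(1L)),
        total_double_bonds = vapply(anns, function(a) a@totalDoubleBonds,
                                    integer(1L)),
        oxygen_suffix = vapply(anns, function(a) a@oxygenSuffix, integer(1L)),
        n_chains = vapply(anns, function(a) nrow(a@chains), integer(1L)),
        chain_order_known = vapply(anns, function(a) a@chainOrderKnown,
                                   logical(1L)),
        saturation_class = vapply(cls, `[[`, character(1L),
                                  "saturation_class"),
        length_class = vapply(cls, `[[`, character(1L), "length_class"))
}

#' Classify a lipid into its statistical subclass
#'
#' Sphingomyelins are subdivided by total acyl-chain length: short-chain
#' (< 36 carbons) vs long-chain (>= 36 carbons; the boundary 36 is "long").
#' All other classes are subdivided by saturation: saturated (0 double
#' bonds), monounsaturated (1) and polyunsaturated (>= 2). Both groupings
#' are returned; the canonical one for class-sum statistics is length for SM
#' and saturation otherwise (see [canonicalSubclass()]).
#'
#' @param a a [LipidAnnotation-class]
#' @return list with `saturation_class` (`"saturated"`, `"monounsaturated"`,
#'   `"polyunsaturated"` or `"n/a"`) and `length_class` (`"short"`, `"long"`
#'   or `"n/a"`)
#' @export
classifyLipid <- function(a) {
    sat <- if (a@totalDoubleBonds == 0L) "saturated"
           else if (a@totalDoubleBonds == 1L) "monounsaturated"
           else "polyunsaturated"
    len <- if (a@totalCarbons >= 36L) "long" else "short"
    if (a@lipidClass == "SM")
        list(saturation_class = "n/a", length_class = len)
    else
        list(saturation_class = sat, length_class = "n/a")
}

#' @rdname classifyLipid
#' @return `canonicalSubclass`: a single label, e.g. `"SM long"` or
#'   `"PC polyunsaturated"`
#' @export
canonicalSubclass <- function(a) {
    cl <- classifyLipid(a)
    sub <- if (a@lipidClass == "SM") cl$length_class else cl$saturation_class
    paste(if (a@ether) paste0(a@lipidClass, " O-") else a@lipidClass, sub)
}

#' Merge isomeric lipid features
#'
#' Lipid isomers sharing the same molecular formula and the same annotated
#' (normalized) name are merged by summing their peak areas per sample;
#' features sharing both name and formula across experiments are thereby the
#' same detected lipid. A missing value plus a number sums to the number; an
#' all-missing set of isomers stays missing. Rows with identical names but
#' conflicting formulas are flagged (rowData column `isomer_conflict`) and
#' left unmerged. Chain-resolved names are not collapsed to species totals:
#' `"PC 16:0_18:1"` and `"PC 34:1"` stay distinct.
#'
#' @param table a lipid [FeatureTable-class] whose `rowData` carries `name`
#'   and `formula`
#' @return a [FeatureTable-class] with one row per unique
#'   (normalized name, formula)
#' @export
mergeIsomers <- function(table) {
    rd <- as.data.frame(rowData(table))
    norm <- normalizeLipidNames(rd$name)
    conflict <- vapply(seq_along(norm), function(i) {
        length(unique(rd$formula[norm == norm[i]])) > 1L
    }, logical(1L))
    if (any(conflict))
        mmLog("WARN", "%d features share a name but conflict in formula; %s",
              sum(conflict), "left unmerged")
    key <- ifelse(conflict, paste0(norm, "\r", rd$formula, "\r", rd$feature_id),
                  paste0(norm, "\r", rd$formula))
    groups <- split(seq_len(nrow(table)), key)
    groups <- groups[order(vapply(groups, min, integer(1L)))]
    v <- areas(table)
    mergedVals <- do.call(rbind, lapply(groups, function(i) {
        sub <- v[i, , drop = FALSE]
        out <- colSums(sub, na.rm = TRUE)
        out[colSums(!is.na(sub)) == 0L] <- NA_real_
        out
    }))
    first <- vapply(groups, `[`, integer(1L), 1L)
    fm <- rd[first, , drop = FALSE]
    fm$name <- norm[first]
    fm$isomer_conflict <- conflict[first]
    fm$n_merged <- lengths(groups)
    rownames(fm) <- NULL
    mmLog("INFO", "mergeIsomers: %d features -> %d after merging",
          nrow(table), nrow(fm))
    FeatureTable(mergedVals, as.data.frame(colData(table)), fm)
}
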