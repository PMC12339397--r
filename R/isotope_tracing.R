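## 13C stable-isotope tracing: theoretical isotopologue distributions,
## natural-abundance correction by non-negative least squares, labelled
## fractions, shared integration windows, MS2 confirmation filtering and
## internal-standard absolute quantification.

#' Theoretical isotopologue distribution
#'
#' Distribution of M+0 ... M+n for a species with `kLabelled` tracer
#' carbons fixed heavy and binomial natural 13C abundance `p13c` on the
#' remaining `n - k` carbons: the fraction at M+(k+j) is
#' `choose(n-k, j) p^j (1-p)^(n-k-j)`; entries below M+k are zero.
#'
#' @param nCarbons number of carbon atoms n
#' @param kLabelled number of tracer-labelled carbons k (0 <= k <= n)
#' @param p13c natural 13C abundance (default 0.0107)
#' @param compoundId optional identifier
#' @return an [MDV-class] of fractions (sums to 1)
#' @examples
#' mdvValues(theoreticalMdv(2, 0, 0.5))   # 0.25 0.50 0.25
#' @export
theoreticalMdv <- function(nCarbons, kLabelled, p13c = 0.0107,
                           compoundId = "theoretical") {
    if (kLabelled > nCarbons || kLabelled < 0)
        stop("domain error: need 0 <= kLabelled <= nCarbons")
    if (p13c < 0 || p13c > 1)
        stop("domain error: p13c must be in [0, 1]")
    v <- numeric(nCarbons + 1L)
    j <- 0:(nCarbons - kLabelled)
    v[kLabelled + j + 1L] <- stats::dbinom(j, nCarbons - kLabelled, p13c)
    new("MDV", compoundId = compoundId, nCarbons = as.integer(nCarbons),
        values = v, labelIndex = as.integer(kLabelled), isCorrected = TRUE)
}

#' Build the natural-abundance correction matrix
#'
#' Column k+1 is [theoreticalMdv()] for exactly k labelled carbons; an
#' observed intensity MDV is modelled as a non-negative linear combination
#' of these columns. At `p13c = 0` the matrix is the identity.
#'
#' @param nCarbons number of carbon atoms (>= 1)
#' @param p13c natural 13C abundance (default 0.0107)
#' @return a [CorrectionMatrix-class]
#' @export
buildCorrectionMatrix <- function(nCarbons, p13c = 0.0107) {
    stopifnot(nCarbons >= 1)
    m <- vapply(0:nCarbons, function(k)
        mdvValues(theoreticalMdv(nCarbons, k, p13c)),
        numeric(nCarbons + 1L))
    new("CorrectionMatrix", matrix = m, nCarbons = as.integer(nCarbons),
        p13c = p13c)
}

#' Correct an observed MDV for natural isotope abundance
#'
#' Solves `min || M x - observed ||_2` subject to `x >= 0` (non-negative
#' least squares; negative isotopologue fractions are unphysical) and
#' normalizes the solution to sum 1, yielding the corrected mass
#' distribution vector.
#'
#' @param observed numeric vector of observed isotopologue intensities
#'   (M+0 first) or an uncorrected [MDV-class]
#' @param cm a [CorrectionMatrix-class] of matching size
#' @param compoundId optional identifier for the result
#' @param labelIndex optional tracer label index carried into the result
#' @return an [MDV-class] of corrected fractions; all-zero input yields
#'   all-missing values with a warning
#' @export
correctNaturalAbundance <- function(observed, cm,
                                    compoundId = "corrected",
                                    labelIndex = NA_integer_) {
    if (is(observed, "MDV")) {
        if (is.na(labelIndex)) labelIndex <- observed@labelIndex
        compoundId <- observed@compoundId
        observed <- mdvValues(observed)
    }
    n <- cm@nCarbons
    if (length(observed) != n + 1L)
        stop("observed MDV length must match the correction matrix")
    if (any(observed < 0, na.rm = TRUE))
        stop("observed intensities must be >= 0")
    if (all(is.na(observed)) || sum(observed, na.rm = TRUE) == 0) {
        warning("all-zero observed MDV; corrected fractions undefined")
        return(new("MDV", compoundId = compoundId, nCarbons = n,
                   values = rep(NA_real_, n + 1L),
                   labelIndex = as.integer(labelIndex), isCorrected = TRUE))
    }
    observed[is.na(observed)] <- 0
    x <- pracma::lsqnonneg(cm@matrix, observed)$x
    x <- x / sum(x)
    new("MDV", compoundId = compoundId, nCarbons = n, values = x,
        labelIndex = as.integer(labelIndex), isCorrected = TRUE)
}

#' Labelled-to-unlabelled fraction ratio
#'
#' The ratio of the labelled fraction M+k (M+3 for choline, phosphocholine,
#' CDP-choline, betaine and lipids; M+1 for methionine and SAM) to the
#' non-labelled fraction M+0 of a corrected MDV.
#'
#' @param corrected a corrected [MDV-class]
#' @param k label index (defaults to the MDV's `labelIndex`)
#' @return `x_k / x_0`; `NA` with a warning when M+0 is zero
#' @export
labelledFraction <- function(corrected, k = NA_integer_) {
    stopifnot(is(corrected, "MDV"), isTRUE(corrected@isCorrected))
    if (is.na(k)) k <- corrected@labelIndex
    if (is.na(k)) stop("no label index available")
    x <- mdvValues(corrected)
    if (is.na(x[1L]) || x[1L] == 0) {
        warning("M+0 fraction is zero; labelled/unlabelled ratio undefined")
        return(NA_real_)
    }
    x[k + 1L] / x[1L]
}

.trapz <- function(x, y) {
    # trapezoid rule on an irregular grid
    sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Shared integration window across isotopologues
#'
#' The chromatographic traces of all isotopologues of a compound are summed
#' on their shared RT axis; the integration window is found on the summed
#' trace (apex, then descent on each side until the signal falls to 1% of
#' the apex or the first local minimum, whichever comes first) and every
#' isotopologue is integrated by the trapezoid rule over the identical
#' window.
#'
#' @param rt shared retention-time axis, seconds, strictly increasing
#' @param traces numeric matrix, one column per isotopologue, intensities
#'   on `rt`
#' @param apexFraction descent stop as a fraction of apex (default 0.01)
#' @return list with `rt_start`, `rt_end` and `areas` (one per
#'   isotopologue); a flat summed trace gives an error
#' @export
sharedIntegrationBounds <- function(rt, traces, apexFraction = 0.01) {
    traces <- as.matrix(traces)
    stopifnot(length(rt) == nrow(traces), all(diff(rt) > 0))
    total <- rowSums(traces)
    if (max(total) <= 0 || stats::sd(total) == 0)
        stop("flat summed trace: no detectable peak")
    apex <- which.max(total)
    floorLevel <- apexFraction * total[apex]
    i0 <- apex
    while (i0 > 1L && total[i0 - 1L] > floorLevel &&
           total[i0 - 1L] <= total[i0]) i0 <- i0 - 1L
    i1 <- apex
    while (i1 < length(total) && total[i1 + 1L] > floorLevel &&
           total[i1 + 1L] <= total[i1]) i1 <- i1 + 1L
    idx <- i0:i1
    areas <- apply(traces[idx, , drop = FALSE], 2L,
                   function(y) .trapz(rt[idx], y))
    list(rt_start = rt[i0], rt_end = rt[i1], areas = areas)
}

#' Keep only MS2-confirmed lipid features
#'
#' A feature is retained for label tracing only when an MS2-confirmed peak
#' exists within `rtTol` seconds and `mzTol` Da of the feature.
#'
#' @param features data.frame with columns `rt_s` (seconds) and `mass` (Da)
#' @param ms2Events data.frame of confirmed events, same columns
#' @param rtTol retention-time tolerance, seconds (default 15)
#' @param mzTol mass tolerance, Da (default 0.001, i.e. 1 mDa)
#' @return the confirmed subset of `features`
#' @export
ms2ConfirmationFilter <- function(features, ms2Events, rtTol = 15,
                                  mzTol = 0.001) {
    keep <- vapply(seq_len(nrow(features)), function(i) {
        any(abs(ms2Events$rt_s - features$rt_s[i]) <= rtTol &
            abs(ms2Events$mass - features$mass[i]) <= mzTol)
    }, logical(1L))
    mmLog("INFO", "ms2ConfirmationFilter: %d features -> %d confirmed",
          nrow(features), sum(keep))
    features[keep, , drop = FALSE]
}

.ELEMENT_ISOTOPES <- list(
    # (mass shift 0, 1, 2, ...) relative isotope abundances
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    P = 1,
    S = c(0.9499, 0.0075, 0.0425, 0, 0.0001))

#' Parse a molecular formula into element counts
#' @param formula formula string such as `"C42H82NO8P"`
#' @return named integer vector of element counts
#' @export
parseFormula <- function(formula) {
    s <- gsub("\\s", "", formula)
    m <- gregexpr("[A-Z][a-z]?[0-9]*", s)
    toks <- regmatches(s, m)[[1L]]
    if (!length(toks) || sum(attr(m[[1L]], "match.length")) != nchar(s))
        stop("unparseable formula: '", formula, "'")
    el <- sub("[0-9]*$", "", toks)
    cnt <- as.integer(ifelse(grepl("[0-9]", toks),
                             sub("^[A-Za-z]+", "", toks), "1"))
    tapply(cnt, el, sum)
}

#' Monoisotopic fraction of a molecular formula
#'
#' Fraction of molecules in the monoisotopic isotopologue, obtained by
#' convolving the per-element isotope-abundance distributions (CHNOPS) and
#' taking the zero-mass-shift term; equals the product of the monoisotopic
#' abundances raised to the element counts.
#'
#' @param formula formula string (elements C, H, N, O, P, S)
#' @return monoisotopic fraction in (0, 1]
#' @export
monoisotopicFraction <- function(formula) {
    counts <- parseFormula(formula)
    unknown <- setdiff(names(counts), names(.ELEMENT_ISOTOPES))
    if (length(unknown))
        stop("no isotope data for element(s): ",
             paste(unknown, collapse = ", "))
    polyMul <- function(a, b) {
        out <- numeric(length(a) + length(b) - 1L)
        for (i in seq_along(a))
            out[i + seq_along(b) - 1L] <- out[i + seq_along(b) - 1L] +
                a[i] * b
        out[seq_len(min(length(out), 8L))]   # high-shift tail negligible
    }
    dist <- 1
    for (el in names(counts)) {
        d <- .ELEMENT_ISOTOPES[[el]]
        for (i in seq_len(counts[[el]])) dist <- polyMul(dist, d)
    }
    dist[1L]
}

#' Absolute quantification against a class internal standard
#'
#' Converts an analyte peak area into a concentration using the
#' co-measured internal standard of its lipid class (e.g. a Splash
#' deuterated standard), with type-1 isotope correction: each monoisotopic
#' peak area is first rescaled by the monoisotopic fraction of its
#' molecular formula so species of different elemental composition become
#' comparable.
#'
#' @param analyteAuc analyte monoisotopic peak area
#' @param standardAuc internal-standard monoisotopic peak area (> 0)
#' @param standardConc internal-standard concentration
#' @param analyteFormula,standardFormula molecular formulas
#' @return analyte concentration in the units of `standardConc`
#' @export
absoluteQuantify <- function(analyteAuc, standardAuc, standardConc,
                             analyteFormula, standardFormula) {
    if (standardAuc <= 0) stop("standardAuc must be > 0")
    fa <- monoisotopicFraction(analyteFormula)
    fs <- monoisotopicFraction(standardFormula)
    standardConc * (analyteAuc / fa) / (standardAuc / fs)
}
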