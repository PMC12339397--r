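## Metabolome-transcriptome integration: per-pathway enzyme-metabolite
## correlation, metabolograms, and univariate-linear-model regulon activity.

#' Read a GMT pathway file
#'
#' Standard GMT: one pathway per line, tab-separated
#' `id<TAB>description<TAB>member...`.
#'
#' @param path GMT file
#' @return named list of character vectors (gene members per pathway)
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    out <- lapply(lines, function(ln) {
        f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
        unique(f[-(1:2)])
    })
    names(out) <- vapply(lines, function(ln)
        strsplit(ln, "\t", fixed = TRUE)[[1L]][1L], character(1L))
    out
}

#' Read pathway metabolite membership
#' @param path TSV with columns `pathway_id`, `feature_id`
#' @return named list of character vectors (metabolite members per pathway)
#' @export
readMetaboliteSets <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    lapply(split(df$feature_id, df$pathway_id), unique)
}

#' Read a TF regulon table
#' @param path TSV with columns `tf`, `target`, `weight`
#' @return named list of regulons; each is a data.frame `target`, `weight`
#' @export
readRegulon <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    lapply(split(df[c("target", "weight")], df$tf), function(d) {
        rownames(d) <- NULL
        d
    })
}

#' Per-pathway enzyme-metabolite Pearson correlation
#'
#' For every (enzyme, metabolite) pair that are co-members of a pathway,
#' the Pearson correlation between per-sample enzyme expression and
#' metabolite abundance across the shared samples (paired transcriptome and
#' metabolome per subject), with the two-sided p-value.
#'
#' @param metab numeric matrix, metabolite features x samples
#' @param expr numeric matrix, genes x samples (column names shared with
#'   `metab` identify the paired samples)
#' @param geneSets named list: pathway -> gene members
#' @param metabSets named list: pathway -> metabolite members
#' @return [S4Vectors::DataFrame] with pathway_id, gene, metabolite, n, r, p
#'   (pairs with fewer than 3 shared samples are skipped)
#' @export
enzymeMetaboliteCorrelation <- function(metab, expr, geneSets, metabSets) {
    shared <- intersect(colnames(metab), colnames(expr))
    rows <- list()
    for (pw in intersect(names(geneSets), names(metabSets))) {
        genes <- intersect(geneSets[[pw]], rownames(expr))
        mets <- intersect(metabSets[[pw]], rownames(metab))
        for (g in genes) for (mm in mets) {
            x <- expr[g, shared]; y <- metab[mm, shared]
            ok <- !is.na(x) & !is.na(y)
            if (sum(ok) < 3L) next
            if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
            ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
            rows[[length(rows) + 1L]] <- data.frame(
                pathway_id = pw, gene = g, metabolite = mm, n = sum(ok),
                r = unname(ct$estimate), p = ct$p.value,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(DataFrame(pathway_id = character(), gene = character(),
                         metabolite = character(), n = integer(),
                         r = numeric(), p = numeric()))
    DataFrame(do.call(rbind, rows))
}

.stars <- function(padj) {
    ifelse(is.na(padj), "",
           ifelse(padj < 0.001, "***",
                  ifelse(padj < 0.01, "**", ifelse(padj < 0.05, "*", ""))))
}

.signedRankCenterP <- function(fc) {
    fc <- fc[!is.na(fc) & fc != 0]
    if (length(fc) < 1L) return(NA_real_)
    suppressWarnings(stats::wilcox.test(fc, mu = 0)$p.value)
}

#' Build a metabologram for one pathway
#'
#' Peripheral slices are the pathway's detected enzymes (gene log2FC and
#' adjusted p) and measured metabolites; the centre shows the mean log2FC
#' of each half, with significance from a two-sided one-sample Wilcoxon
#' signed-rank test of the slice log2FCs against zero. Pathways with fewer
#' than 5 detected enzymes or no measured metabolite are returned as
#' skipped.
#'
#' @param pathwayId pathway identifier
#' @param genes gene members of the pathway
#' @param metabolites metabolite members of the pathway
#' @param geneStats data.frame indexed by `id` with `log2fc`, `padj` for
#'   detected genes
#' @param metabStats data.frame indexed by `id` with `log2fc`, `padj` for
#'   measured metabolites
#' @param minEnzymes minimum detected enzymes (default 5)
#' @param minMetabolites minimum measured metabolites (default 1)
#' @return a [Metabologram-class]
#' @export
buildMetabologram <- function(pathwayId, genes, metabolites, geneStats,
                              metabStats, minEnzymes = 5,
                              minMetabolites = 1) {
    gs <- geneStats[geneStats$id %in% genes, , drop = FALSE]
    ms <- metabStats[metabStats$id %in% metabolites, , drop = FALSE]
    gSlices <- DataFrame(id = gs$id, log2fc = gs$log2fc, padj = gs$padj,
                         stars = .stars(gs$padj))
    mSlices <- DataFrame(id = ms$id, log2fc = ms$log2fc, padj = ms$padj,
                         stars = .stars(ms$padj))
    eligible <- nrow(gs) >= minEnzymes && nrow(ms) >= minMetabolites
    reason <- if (eligible) "" else
        sprintf("%d detected enzymes (need >= %d), %d metabolites (need >= %d)",
                nrow(gs), minEnzymes, nrow(ms), minMetabolites)
    new("Metabologram", pathwayId = pathwayId, geneSlices = gSlices,
        metabSlices = mSlices,
        centerGeneAvg = if (eligible) mean(gs$log2fc) else NA_real_,
        centerMetabAvg = if (eligible) mean(ms$log2fc) else NA_real_,
        centerGeneP = if (eligible) .signedRankCenterP(gs$log2fc)
                      else NA_real_,
        centerMetabP = if (eligible) .signedRankCenterP(ms$log2fc)
                       else NA_real_,
        eligible = eligible, reason = reason)
}

#' Univariate-linear-model regulon activity
#'
#' Regresses the per-gene differential statistic on a TF's target weights
#' embedded in the full gene vector (non-targets get weight 0); the
#' activity score is the t-statistic of the slope, whose sign conveys
#' activation (positive) vs repression. Equivalent to
#' `t = r * sqrt((n - 2) / (1 - r^2))` for the Pearson correlation r
#' between statistic and weight vector.
#'
#' @param geneStat named numeric vector of per-gene differential statistics
#' @param regulon data.frame with `target`, `weight` (>= 2 targets present
#'   in `geneStat`)
#' @return list with `score` (slope t-statistic), `p` (two-sided),
#'   `nTargets`
#' @export
ulmActivity <- function(geneStat, regulon) {
    present <- regulon$target %in% names(geneStat)
    if (sum(present) < 2L)
        stop("need >= 2 regulon targets present in the gene statistics")
    w <- stats::setNames(rep(0, length(geneStat)), names(geneStat))
    w[regulon$target[present]] <- regulon$weight[present]
    if (stats::sd(w) == 0) {
        warning("zero-variance weights; activity undefined")
        return(list(score = NA_real_, p = NA_real_,
                    nTargets = sum(present)))
    }
    fit <- summary(stats::lm(geneStat ~ w))
    list(score = fit$coefficients["w", "t value"],
         p = fit$coefficients["w", "Pr(>|t|)"],
         nTargets = sum(present))
}

#' Rank differential activities
#'
#' Filters activity scores at `pCutoff` and returns the `topK` per
#' direction ordered by absolute score (ties broken lexicographically by
#' identifier).
#'
#' @param scores data.frame with columns `id`, `score`, `p`
#' @param pCutoff significance filter (default 0.05)
#' @param topK entries per direction (default 7)
#' @return the filtered, ordered data.frame
#' @export
rankActivities <- function(scores, pCutoff = 0.05, topK = 7) {
    keep <- scores[!is.na(scores$p) & scores$p < pCutoff, , drop = FALSE]
    if (!nrow(keep)) return(keep)
    keep <- keep[order(-abs(keep$score), keep$id), , drop = FALSE]
    up <- keep[keep$score > 0, , drop = FALSE]
    dn <- keep[keep$score <= 0, , drop = FALSE]
    out <- rbind(utils::head(up, topK), utils::head(dn, topK))
    out[order(-out$score, out$id), , drop = FALSE]
}
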