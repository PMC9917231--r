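#' Intersect stable candidate sets across patterns
#'
#' The weighted candidate set is the intersection over all per-pattern
#' stable candidate sets; the initial predicted drugs are its intersection
#' with the unweighted stable candidates.
#'
#' @param unweighted character vector: stable candidates, unweighted
#'   pattern.
#' @param perPattern non-empty list of character vectors, one stable
#'   candidate set per weighting pattern.
#' @return list with \code{dWeighted} and \code{dP} (both sorted).
#' @export
intersectCandidates <- function(unweighted, perPattern) {
    if (length(perPattern) == 0L)
        stop("perPattern must contain at least one candidate set")
    dWeighted <- sort(Reduce(intersect, perPattern))
    if (length(dWeighted) == 0L)
        warning("weighted candidate intersection is empty")
    dP <- sort(intersect(unweighted, dWeighted))
    if (length(dP) == 0L && length(dWeighted) > 0L)
        warning("no overlap between unweighted and weighted candidates")
    list(dWeighted = dWeighted, dP = dP)
}

#' Survival-essential druggable targets for a cancer
#'
#' A gene is a druggable target for cancer I when its gene-effect score is
#' at or below the cutoff in at least \code{minLines} cell line(s) of that
#' cancer (knockout depletes the line). Missing measurements are excluded
#' from the comparison, never treated as zero.
#'
#' @param effects a \code{GeneEffectMatrix}.
#' @param cancer cancer label to select cell lines by.
#' @param cutoff gene-effect cutoff; default -0.5.
#' @param minLines minimum number of depleting cell lines; default 1.
#' @param strict use a strict inequality (score < cutoff) instead of the
#'   default permissive one (score <= cutoff).
#' @return list with \code{genes} (sorted character vector G(I)) and
#'   \code{support} (named integer: depleting cell-line count per gene,
#'   all tested genes).
#' @export
druggableTargets <- function(effects, cancer, cutoff = -0.5,
                             minLines = 1L, strict = FALSE) {
    stopifnot(is(effects, "GeneEffectMatrix"))
    sel <- lineage(effects) == cancer
    if (!any(sel))
        stop("no cell line carries cancer label '", cancer, "'")
    m <- effectScores(effects)[, sel, drop = FALSE]
    dep <- if (strict) m < cutoff else m <= cutoff
    support <- rowSums(dep, na.rm = TRUE)
    genes <- sort(names(support)[support >= minLines])
    list(genes = genes, support = stats::setNames(as.integer(support),
                                                  names(support)))
}

#' Final repositionable drugs
#'
#' Keeps the initial predicted drugs with at least one target in the
#' druggable target set, annotating each with its qualifying targets.
#' Drugs with an empty target set are excluded with a warning. Targets
#' absent from the gene-effect matrix simply never qualify.
#'
#' @param dP character vector of initial predicted drug ids.
#' @param drugs the \code{DrugSet} providing target sets.
#' @param genes druggable target genes (the \code{genes} element of
#'   \code{\link{druggableTargets}}).
#' @return list with \code{dR} (sorted drug ids) and
#'   \code{qualifyingTargets} (named list over dR).
#' @export
finalDrugs <- function(dP, drugs, genes) {
    tg <- as.list(targets(drugs))
    missing <- setdiff(dP, names(tg))
    if (length(missing))
        stop("drug(s) absent from the collection: ",
             paste(missing, collapse = ", "))
    qual <- lapply(tg[dP], intersect, y = genes)
    empty <- lengths(tg[dP]) == 0L
    if (any(empty)) {
        warning("drug(s) with empty target set excluded: ",
                paste(dP[empty], collapse = ", "))
        qual <- qual[!empty]
    }
    keep <- lengths(qual) > 0L
    dR <- sort(names(qual)[keep])
    list(dR = dR, qualifyingTargets = qual[dR])
}

#' Average rank of final drugs across all scored conditions
#'
#' Aggregates the full non-seed rankings accumulated by every stability
#' run (every pattern and every seed subset): for each drug the mean rank
#' over all conditions in which it was scored. Conditions where a drug was
#' not scored (e.g. it acted as a seed) are skipped for that drug.
#'
#' @param runs list of \code{StabilityRun} objects (all patterns).
#' @param drugIds drugs to report (e.g. the final repositionable drugs);
#'   defaults to every drug seen.
#' @return data.frame with \code{drug_id}, \code{average_rank},
#'   \code{n_conditions}, sorted by average rank.
#' @export
rankReport <- function(runs, drugIds = NULL) {
    stopifnot(length(runs) > 0L)
    sums <- list()
    counts <- list()
    for (r in runs) {
        sums[[length(sums) + 1L]] <- r@rankSums
        counts[[length(counts) + 1L]] <- r@rankCounts
    }
    allIds <- unique(unlist(lapply(sums, names)))
    sumv <- stats::setNames(numeric(length(allIds)), allIds)
    cntv <- stats::setNames(numeric(length(allIds)), allIds)
    for (i in seq_along(sums)) {
        sumv[names(sums[[i]])] <- sumv[names(sums[[i]])] + sums[[i]]
        cntv[names(counts[[i]])] <- cntv[names(counts[[i]])] + counts[[i]]
    }
    if (is.null(drugIds)) drugIds <- allIds
    absent <- setdiff(drugIds, allIds)
    if (length(absent))
        message("drug(s) never scored in any condition: ",
                paste(absent, collapse = ", "))
    drugIds <- intersect(drugIds, allIds)
    df <- data.frame(drug_id = drugIds,
                     average_rank = unname(sumv[drugIds] / cntv[drugIds]),
                     n_conditions = as.integer(unname(cntv[drugIds])),
                     stringsAsFactors = FALSE)
    df[order(df$average_rank, df$drug_id), , drop = FALSE]
}

#' @export
setMethod("candidates", "RepositioningResult", function(x) x@dP)

#' Final repositionable drug ids
#' @param x a \code{RepositioningResult}.
#' @export
repositionedDrugs <- function(x) {
    stopifnot(is(x, "RepositioningResult"))
    x@dR
}

setMethod("show", "RepositioningResult", function(object) {
    cat("RepositioningResult\n")
    cat(sprintf("  stable candidates: %d unweighted, %d weighted (intersection)\n",
                length(object@dUnweighted), length(object@dWeighted)))
    cat(sprintf("  initial predicted drugs: %d\n", length(object@dP)))
    cat(sprintf("  druggable targets: %d\n", length(object@druggableGenes)))
    cat(sprintf("  final repositionable drugs: %d\n", length(object@dR)))
    if (length(object@dR))
        cat("   ", paste(object@dR, collapse = ", "), "\n")
})
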