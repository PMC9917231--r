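#' Hypergeometric enrichment of drug targets in gene sets
#'
#' For each drug and each gene set h the upper-tail hypergeometric
#' probability of drawing at least the observed overlap is computed:
#' population Q (universe size), M successes (set size), q draws (the
#' drug's targets inside the universe), observed overlap F. The survival
#' form \code{phyper(F - 1, M, Q - M, q, lower.tail = FALSE)} avoids the
#' catastrophic cancellation of literally subtracting the lower sum from 1.
#' A drug is enriched in h when the raw p-value is at most \code{alpha}
#' (ties at the boundary count as enriched). No multiple-testing correction
#' is applied by default; set \code{correction} to a \code{p.adjust} method
#' to adjust within each drug.
#'
#' @param drugs a \code{DrugSet}. Drugs with no target inside the universe
#'   cannot be tested and are dropped with a message.
#' @param collection a \code{GeneSetCollection}.
#' @param alpha significance level in (0, 1); default 0.05.
#' @param correction \code{"none"} (default) or a method name understood by
#'   \code{stats::p.adjust}, applied per drug across sets.
#' @return an \code{EnrichmentResult} over the testable drugs.
#' @examples
#' gsc <- GeneSetCollection(list(s1 = c("A", "B", "C"), s2 = c("C", "D")))
#' ds <- DrugSet("D1", targets = list(c("A", "B")))
#' hallmarkEnrichment(ds, gsc)
#' @export
hallmarkEnrichment <- function(drugs, collection, alpha = 0.05,
                               correction = "none") {
    .assertScalarNumeric(alpha, "alpha")
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    uni <- universe(collection)
    Q <- length(uni)
    tg <- as.list(targets(drugs))
    tgIn <- lapply(tg, function(v) intersect(v, uni))
    q <- lengths(tgIn)
    if (any(q == 0L)) {
        message(sum(q == 0L), " drug(s) without in-universe targets dropped ",
                "from enrichment")
        tgIn <- tgIn[q > 0L]
        q <- q[q > 0L]
    }
    if (length(tgIn) == 0L)
        stop("no drug has a target inside the gene-set universe")
    sets <- as.list(geneSets(collection))
    M <- lengths(sets)
    ## overlap counts F: drugs x sets
    Fm <- vapply(sets, function(s) {
        vapply(tgIn, function(t) length(intersect(t, s)), integer(1L))
    }, integer(length(tgIn)))
    Fm <- matrix(Fm, nrow = length(tgIn), ncol = length(sets),
                 dimnames = list(names(tgIn), names(sets)))
    P <- stats::phyper(Fm - 1L,
                       m = matrix(M, nrow(Fm), ncol(Fm), byrow = TRUE),
                       n = matrix(Q - M, nrow(Fm), ncol(Fm), byrow = TRUE),
                       k = matrix(q, nrow(Fm), ncol(Fm)),
                       lower.tail = FALSE)
    dimnames(P) <- dimnames(Fm)
    if (!identical(correction, "none"))
        P <- t(apply(P, 1L, stats::p.adjust, method = correction))
    new("EnrichmentResult", pvalues = P, overlap = Fm,
        indicator = P <= alpha, q = stats::setNames(as.integer(q),
                                                    names(tgIn)),
        alpha = alpha)
}

#' Enrichment profile of a single target set
#'
#' Convenience wrapper around \code{\link{hallmarkEnrichment}} for one
#' drug's target genes.
#'
#' @param targetGenes character vector of target gene symbols.
#' @param collection a \code{GeneSetCollection}.
#' @param alpha significance level in (0, 1).
#' @return a one-drug \code{EnrichmentResult}.
#' @export
enrichDrug <- function(targetGenes, collection, alpha = 0.05) {
    if (length(intersect(targetGenes, universe(collection))) == 0L)
        stop("no target inside the gene-set universe (q = 0)")
    ds <- DrugSet("query", targets = list(targetGenes))
    hallmarkEnrichment(ds, collection, alpha = alpha)
}

#' @export
setMethod("drugIds", "EnrichmentResult", function(x) rownames(x@pvalues))

#' Enrichment p-values
#' @param x an \code{EnrichmentResult}.
#' @return numeric matrix, drugs x gene sets.
#' @export
enrichmentPvalues <- function(x) x@pvalues

#' Binary enrichment profiles H
#' @param x an \code{EnrichmentResult}.
#' @return logical matrix, drugs x gene sets.
#' @export
enrichmentIndicator <- function(x) x@indicator

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf(
        "EnrichmentResult: %d drug(s) x %d gene set(s), alpha = %g\n",
        nrow(object@pvalues), ncol(object@pvalues), object@alpha))
    cat(sprintf("  drugs with >= 1 enriched set: %d\n",
                sum(rowSums(object@indicator) > 0L)))
})

#' Functional similarity of drugs from enrichment profiles
#'
#' Two drugs are functionally similar (value 1) when the Jaccard index of
#' their binary enrichment profiles is non-zero, i.e. they share at least
#' one enriched gene set. Drugs enriched in no set are similar to nobody.
#'
#' Called with one \code{EnrichmentResult}, returns the full symmetric 0/1
#' matrix over its drugs; called with two single-drug results (over the
#' same collection), returns a single 0/1 value.
#'
#' @param x an \code{EnrichmentResult}.
#' @param y optional second \code{EnrichmentResult}.
#' @return integer matrix or single integer in \{0, 1\}.
#' @export
functionalSimilarity <- function(x, y = NULL) {
    stopifnot(is(x, "EnrichmentResult"))
    if (is.null(y)) {
        H <- x@indicator * 1L
        S <- (tcrossprod(H) > 0) * 1L
        dimnames(S) <- list(rownames(H), rownames(H))
        return(S)
    }
    stopifnot(is(y, "EnrichmentResult"))
    if (!identical(colnames(x@indicator), colnames(y@indicator)))
        stop("profiles computed over different gene-set collections")
    hi <- x@indicator[1L, ]
    hj <- y@indicator[1L, ]
    as.integer(any(hi & hj))
}
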