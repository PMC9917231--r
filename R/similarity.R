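#' ATC codes truncated to a classification level
#'
#' Level-5 ATC codes are 7 characters; levels 2, 3 and 4 are their leading
#' 3, 4 and 5 characters (therapeutic subgroup, pharmacological subgroup,
#' chemical subgroup). Duplicated prefixes collapse.
#'
#' @param codes character vector of level-5 ATC codes (non-empty).
#' @param k level, one of 2, 3, 4.
#' @return character vector of distinct level-k prefixes.
#' @examples
#' atcLevelCodes(c("L01XE03", "L01XE07"), 4)  # "L01XE"
#' @export
atcLevelCodes <- function(codes, k) {
    if (length(codes) == 0L) stop("empty ATC code set")
    if (!k %in% 2:4) stop("k must be 2, 3 or 4")
    unique(substr(codes, 1L, k + 1L))
}

#' Clinical therapeutic similarity of two ATC code sets
#'
#' Per-level Jaccard similarity of the level-2/3/4 prefix sets, averaged
#' into the overall clinical similarity
#' \deqn{S_{ATC} = (S_2 + S_3 + S_4) / 3.}
#' Symmetric, in [0, 1], and 1 for identical code sets.
#'
#' @param codesI,codesJ character vectors of level-5 ATC codes (both
#'   non-empty; pairs lacking codes must be skipped upstream, not
#'   zero-scored).
#' @return named list with \code{S2}, \code{S3}, \code{S4}, \code{SATC}.
#' @examples
#' clinicalSimilarity(c("L01XE03", "N02BA01"), "L01XE03")$SATC  # 0.5
#' @export
clinicalSimilarity <- function(codesI, codesJ) {
    if (length(codesI) == 0L || length(codesJ) == 0L)
        stop("both drugs need at least one ATC code")
    jac <- function(a, b) {
        length(intersect(a, b)) / length(union(a, b))
    }
    s <- vapply(2:4, function(k) {
        jac(atcLevelCodes(codesI, k), atcLevelCodes(codesJ, k))
    }, numeric(1L))
    list(S2 = s[[1L]], S3 = s[[2L]], S4 = s[[3L]],
         SATC = mean(s))
}

#' Empirical significance threshold for clinical similarity
#'
#' Nearest-rank percentile (default 95th) of the supplied pairwise
#' similarity values. Zero-valued pairs are part of the empirical
#' distribution by default; \code{excludeZeros} restricts it to pairs with
#' positive similarity.
#'
#' @param values numeric vector of pairwise SATC values (non-empty).
#' @param percentile percentile in (0, 100]; default 95.
#' @param excludeZeros drop zero similarities before taking the percentile.
#' @return a \code{SimilarityThreshold}.
#' @export
estimateThreshold <- function(values, percentile = 95,
                              excludeZeros = FALSE) {
    if (excludeZeros) values <- values[values > 0]
    if (length(values) == 0L) stop("no similarity values supplied")
    new("SimilarityThreshold",
        value = nearestRankPercentile(values, percentile),
        percentile = percentile, nPairs = length(values))
}

#' @export
setMethod("thresholdValue", "SimilarityThreshold", function(x) x@value)

setMethod("show", "SimilarityThreshold", function(object) {
    cat(sprintf(
        "SimilarityThreshold: %gth nearest-rank percentile of %d pairs = %g\n",
        object@percentile, object@nPairs, object@value))
})

## Sparse incidence of drugs x level-k prefixes, for vectorised pairwise
## Jaccard over all ATC-annotated drugs.
.levelIncidence <- function(codeList, k) {
    prefixes <- lapply(codeList, atcLevelCodes, k = k)
    uniq <- unique(unlist(prefixes, use.names = FALSE))
    i <- rep(seq_along(prefixes), lengths(prefixes))
    j <- match(unlist(prefixes, use.names = FALSE), uniq)
    Matrix::sparseMatrix(i = i, j = j, x = 1,
                         dims = c(length(prefixes), length(uniq)),
                         dimnames = list(names(codeList), uniq))
}

#' All pairwise drug similarities and the significance threshold
#'
#' Computes, over the drugs of a collection that have at least one target:
#' the binary functional similarity from hallmark-style enrichment
#' profiles, the per-level and overall ATC clinical similarity for every
#' pair of ATC-annotated drugs, and the empirical significance threshold
#' over all such pairs. The returned pair table keeps every pair with
#' functional similarity 1 or positive clinical similarity.
#'
#' @param drugs a \code{DrugSet}.
#' @param collection a \code{GeneSetCollection}.
#' @param alpha enrichment significance level (default 0.05).
#' @param percentile percentile for the clinical threshold (default 95).
#' @param excludeZeros passed to \code{\link{estimateThreshold}}.
#' @return list with \code{pairs} (data.frame: drug_i, drug_j, functional,
#'   S2, S3, S4, SATC, clinical_significant), \code{threshold}
#'   (\code{SimilarityThreshold}) and \code{enrichment}
#'   (\code{EnrichmentResult}).
#' @export
drugPairSimilarities <- function(drugs, collection, alpha = 0.05,
                                 percentile = 95, excludeZeros = FALSE) {
    keep <- lengths(targets(drugs)) > 0L
    if (!any(keep)) stop("no drug has any target")
    drugs <- drugs[which(keep)]
    ids <- drugIds(drugs)

    enr <- hallmarkEnrichment(drugs, collection, alpha = alpha)
    H <- Matrix::Matrix(enr@indicator * 1, sparse = TRUE)
    shared <- Matrix::tcrossprod(H)
    sharedIdx <- Matrix::which(shared > 0, arr.ind = TRUE)
    sharedIdx <- sharedIdx[sharedIdx[, 1L] < sharedIdx[, 2L], , drop = FALSE]
    eids <- rownames(enr@pvalues)
    funPairs <- data.frame(
        drug_i = eids[sharedIdx[, 1L]],
        drug_j = eids[sharedIdx[, 2L]],
        stringsAsFactors = FALSE)

    codes <- as.list(atcCodes(drugs))
    hasAtc <- lengths(codes) > 0L
    satcMat <- NULL
    thr <- NULL
    if (sum(hasAtc) >= 2L) {
        codeList <- codes[hasAtc]
        aids <- ids[hasAtc]
        n <- length(aids)
        Slev <- vector("list", 3L)
        for (k in 2:4) {
            L <- .levelIncidence(codeList, k)
            inter <- as.matrix(Matrix::tcrossprod(L))
            sizes <- Matrix::rowSums(L)
            uni <- outer(sizes, sizes, "+") - inter
            Slev[[k - 1L]] <- inter / uni
        }
        satcMat <- (Slev[[1L]] + Slev[[2L]] + Slev[[3L]]) / 3
        dimnames(satcMat) <- list(aids, aids)
        vals <- satcMat[upper.tri(satcMat)]
        thr <- estimateThreshold(vals, percentile, excludeZeros)
        S2m <- Slev[[1L]]; S3m <- Slev[[2L]]; S4m <- Slev[[3L]]
        dimnames(S2m) <- dimnames(S3m) <- dimnames(S4m) <- dimnames(satcMat)
    } else {
        message("fewer than two ATC-annotated drugs: no clinical channel")
    }

    ## assemble the union pair table
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    pk <- character(0)
    rows <- list()
    if (nrow(funPairs)) {
        pk <- key(funPairs$drug_i, funPairs$drug_j)
        rows <- funPairs
    }
    if (!is.null(satcMat)) {
        posIdx <- which(satcMat > 0 & upper.tri(satcMat), arr.ind = TRUE)
        if (nrow(posIdx)) {
            cp <- data.frame(
                drug_i = rownames(satcMat)[posIdx[, 1L]],
                drug_j = rownames(satcMat)[posIdx[, 2L]],
                stringsAsFactors = FALSE)
            ck <- key(cp$drug_i, cp$drug_j)
            addn <- !ck %in% pk
            rows <- rbind(as.data.frame(rows), cp[addn, , drop = FALSE])
        }
    }
    rows <- as.data.frame(rows)
    if (nrow(rows) == 0L) {
        pairs <- data.frame(drug_i = character(0), drug_j = character(0),
                            functional = integer(0), S2 = numeric(0),
                            S3 = numeric(0), S4 = numeric(0),
                            SATC = numeric(0),
                            clinical_significant = logical(0))
        return(list(pairs = pairs, threshold = thr, enrichment = enr))
    }
    ## canonical unordered orientation and deterministic order
    swap <- rows$drug_i > rows$drug_j
    tmp <- rows$drug_i[swap]
    rows$drug_i[swap] <- rows$drug_j[swap]
    rows$drug_j[swap] <- tmp
    rows <- rows[order(rows$drug_i, rows$drug_j), , drop = FALSE]

    fk <- if (nrow(funPairs)) key(funPairs$drug_i, funPairs$drug_j)
          else character(0)
    rows$functional <- as.integer(key(rows$drug_i, rows$drug_j) %in% fk)
    pick <- function(m, i, j) {
        out <- rep(NA_real_, length(i))
        ok <- i %in% rownames(m) & j %in% rownames(m)
        out[ok] <- m[cbind(i[ok], j[ok])]
        out
    }
    if (!is.null(satcMat)) {
        rows$S2 <- pick(S2m, rows$drug_i, rows$drug_j)
        rows$S3 <- pick(S3m, rows$drug_i, rows$drug_j)
        rows$S4 <- pick(S4m, rows$drug_i, rows$drug_j)
        rows$SATC <- pick(satcMat, rows$drug_i, rows$drug_j)
        rows$clinical_significant <- !is.na(rows$SATC) &
            rows$SATC >= thresholdValue(thr)
    } else {
        rows$S2 <- rows$S3 <- rows$S4 <- rows$SATC <- NA_real_
        rows$clinical_significant <- FALSE
    }
    rownames(rows) <- NULL
    list(pairs = rows, threshold = thr, enrichment = enr)
}

#' Write / read a drug-pair similarity table
#'
#' @param pairs the pair data.frame from
#'   \code{\link{drugPairSimilarities}}.
#' @param path TSV path.
#' @export
writePairTable <- function(pairs, path) {
    utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writePairTable
#' @export
readPairTable <- function(path) {
    utils::read.delim(path, check.names = FALSE,
                      colClasses = c(drug_i = "character",
                                     drug_j = "character"))
}
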