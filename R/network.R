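#' Build the union drug similarity network
#'
#' An edge joins two drugs when they are functionally similar (share an
#' enriched gene set, \code{A} = 1) and/or clinically similar at
#' significance (SATC at or above the empirical threshold and positive;
#' \code{B} carries the raw SATC then, 0 otherwise). Only drugs with at
#' least one target are eligible as nodes, and isolated drugs are omitted:
#' the node set is exactly the set of edge endpoints.
#'
#' @param pairs pair table from \code{\link{drugPairSimilarities}}.
#' @param threshold a \code{SimilarityThreshold} or a plain numeric value.
#' @param drugs the \code{DrugSet} the pairs were computed over (used to
#'   enforce the at-least-one-target node rule).
#' @return a \code{DrugSimilarityNetwork}.
#' @export
buildNetwork <- function(pairs, threshold, drugs = NULL) {
    thr <- if (is(threshold, "SimilarityThreshold"))
        thresholdValue(threshold) else threshold
    .assertScalarNumeric(thr, "threshold", 0, 1)
    if (!is.null(drugs)) {
        withTargets <- drugIds(drugs)[lengths(targets(drugs)) > 0L]
        pairs <- pairs[pairs$drug_i %in% withTargets &
                       pairs$drug_j %in% withTargets, , drop = FALSE]
    }
    sig <- !is.na(pairs$SATC) & pairs$SATC >= thr & pairs$SATC > 0
    keep <- pairs$functional == 1L | sig
    pairs <- pairs[keep, , drop = FALSE]
    sig <- sig[keep]
    if (nrow(pairs) == 0L)
        stop("no edge survives the similarity thresholds")
    if (any(pairs$drug_i == pairs$drug_j))
        stop("self-pairs are not allowed")
    A <- as.integer(pairs$functional == 1L)
    B <- ifelse(sig, pairs$SATC, 0)
    src <- ifelse(A == 1L & B > 0, "both",
                  ifelse(A == 1L, "functional", "clinical"))
    el <- data.frame(from = pairs$drug_i, to = pairs$drug_j,
                     A = A, B = B, source = src,
                     stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(el, directed = FALSE)
    new("DrugSimilarityNetwork", graph = g, threshold = thr)
}

#' @export
setMethod("nodeIds", "DrugSimilarityNetwork", function(x) {
    igraph::V(x@graph)$name
})

#' @export
setMethod("edgeTable", "DrugSimilarityNetwork", function(x) {
    df <- igraph::as_data_frame(x@graph, what = "edges")
    names(df)[1:2] <- c("drug_i", "drug_j")
    df
})

#' @describeIn DrugSimilarityNetwork number of drugs in the network
#' @param x a \code{DrugSimilarityNetwork}.
#' @export
setMethod("length", "DrugSimilarityNetwork", function(x) {
    igraph::vcount(x@graph)
})

#' Per-node degree and summary statistics
#'
#' @param x a \code{DrugSimilarityNetwork}.
#' @return list with \code{degrees} (named integer), \code{mean},
#'   \code{min} and \code{max}.
#' @export
setMethod("degreeSummary", "DrugSimilarityNetwork", function(x) {
    d <- igraph::degree(x@graph)
    list(degrees = d, mean = mean(d), min = min(d), max = max(d))
})

setMethod("show", "DrugSimilarityNetwork", function(object) {
    src <- table(igraph::E(object@graph)$source)
    cat(sprintf(
        "DrugSimilarityNetwork: %d drugs, %d edges (threshold %.4g)\n",
        igraph::vcount(object@graph), igraph::ecount(object@graph),
        object@threshold))
    cat("  edge sources:",
        paste(sprintf("%s=%d", names(src), as.integer(src)),
              collapse = ", "), "\n")
})

#' Write / read a network edge list
#'
#' TSV columns: drug_i, drug_j, A, B, source. Reading reconstructs the
#' network exactly (the threshold used at build time travels as a header
#' comment).
#'
#' @param network a \code{DrugSimilarityNetwork}.
#' @param path TSV path.
#' @export
writeEdgeList <- function(network, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# threshold=%.17g", network@threshold), con)
    df <- edgeTable(network)
    df$B <- sprintf("%.17g", df$B)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
    first <- readLines(path, n = 1L)
    thr <- if (startsWith(first, "# threshold="))
        as.numeric(sub("# threshold=", "", first, fixed = TRUE)) else 0
    df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                            colClasses = c(drug_i = "character",
                                           drug_j = "character"))
    el <- data.frame(from = df$drug_i, to = df$drug_j, A = df$A, B = df$B,
                     source = df$source, stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(el, directed = FALSE)
    new("DrugSimilarityNetwork", graph = g, threshold = thr)
}
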