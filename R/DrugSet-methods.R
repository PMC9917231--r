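#' Construct a DrugSet
#'
#' @param drugId character vector of unique drug accessions.
#' @param drugName character vector of names (defaults to the ids).
#' @param targets list (or \code{CharacterList}) of target gene symbols.
#' @param atcCodes list (or \code{CharacterList}) of level-5 ATC codes.
#' @return a \code{DrugSet}.
#' @examples
#' ds <- DrugSet("DB01269", "Panitumumab",
#'               targets = list("EGFR"), atcCodes = list("L01XC08"))
#' targets(ds)
#' @export
DrugSet <- function(drugId, drugName = drugId,
                    targets = vector("list", length(drugId)),
                    atcCodes = vector("list", length(drugId))) {
    norm <- function(lst) {
        lst <- lapply(lst, function(v) {
            v <- as.character(v)
            unique(v[!is.na(v) & nzchar(v)])
        })
        IRanges::CharacterList(lst)
    }
    new("DrugSet",
        drugId = as.character(drugId),
        drugName = as.character(drugName),
        targets = norm(as.list(targets)),
        atcCodes = norm(as.list(atcCodes)))
}

#' @describeIn DrugSet number of drugs
#' @param x a \code{DrugSet}.
#' @export
setMethod("length", "DrugSet", function(x) length(x@drugId))

#' @export
setMethod("drugIds", "DrugSet", function(x) x@drugId)

#' @export
setMethod("drugNames", "DrugSet", function(x) {
    stats::setNames(x@drugName, x@drugId)
})

#' @export
setMethod("targets", "DrugSet", function(x, ...) {
    stats::setNames(x@targets, x@drugId)
})

#' @export
setMethod("atcCodes", "DrugSet", function(x) {
    stats::setNames(x@atcCodes, x@drugId)
})

#' @describeIn DrugSet subset by index, logical, or drug identifier
#' @param i index/identifier vector.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "DrugSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) {
        miss <- setdiff(i, x@drugId)
        if (length(miss))
            stop("unknown drug_id: ", paste(miss, collapse = ", "))
        i <- match(i, x@drugId)
    }
    initialize(x,
        drugId = x@drugId[i],
        drugName = x@drugName[i],
        targets = x@targets[i],
        atcCodes = x@atcCodes[i])
})

setMethod("show", "DrugSet", function(object) {
    cat(sprintf("DrugSet with %d drugs\n", length(object)))
    cat(sprintf("  with targets: %d | with ATC codes: %d\n",
                sum(lengths(object@targets) > 0L),
                sum(lengths(object@atcCodes) > 0L)))
    if (length(object)) {
        k <- min(3L, length(object))
        cat("  head:", paste(object@drugId[seq_len(k)], collapse = ", "),
            if (length(object) > k) "..." else "", "\n")
    }
})

#' Construct a GeneSetCollection
#'
#' The universe is computed as the union of the supplied sets.
#'
#' @param sets named list (or \code{CharacterList}) of gene symbol vectors.
#' @return a \code{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets) {
    sets <- lapply(as.list(sets), function(v) unique(as.character(v)))
    cl <- IRanges::CharacterList(sets)
    new("GeneSetCollection", sets = cl,
        universe = unique(unlist(sets, use.names = FALSE)))
}

#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @export
setMethod("universe", "GeneSetCollection", function(x) x@universe)

#' @describeIn GeneSetCollection number of gene sets
#' @param x a \code{GeneSetCollection}.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection gene set names
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection: %d sets over %d genes (universe)\n",
                length(object@sets), length(object@universe)))
})

#' Construct a GeneEffectMatrix
#'
#' @param scores numeric matrix in screen orientation: rows are cell lines,
#'   columns are gene symbols. \code{NA} marks missing measurements.
#' @param lineage named character vector mapping every cell line to its
#'   cancer label.
#' @return a \code{GeneEffectMatrix} (genes x cell lines internally).
#' @export
GeneEffectMatrix <- function(scores, lineage) {
    if (is.null(rownames(scores)) || is.null(colnames(scores)))
        stop("scores must carry cell-line rownames and gene colnames")
    missing <- setdiff(rownames(scores), names(lineage))
    if (length(missing))
        stop("no lineage label for cell line(s): ",
             paste(missing, collapse = ", "))
    cd <- S4Vectors::DataFrame(
        cancer = as.character(lineage[rownames(scores)]),
        row.names = rownames(scores))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(effect = t(scores)), colData = cd)
    new("GeneEffectMatrix", se)
}

#' @export
setMethod("effectScores", "GeneEffectMatrix", function(x) {
    SummarizedExperiment::assay(x, "effect")
})

#' @export
setMethod("cellLines", "GeneEffectMatrix", function(x) colnames(x))

#' @export
setMethod("lineage", "GeneEffectMatrix", function(x) {
    stats::setNames(SummarizedExperiment::colData(x)$cancer, colnames(x))
})

#' Construct a SeedSet
#'
#' @param cancer single cancer label.
#' @param drugs character vector of known therapeutic drug identifiers.
#' @param drugSet optional \code{DrugSet} to resolve members against;
#'   unresolvable members are reported and dropped.
#' @return a \code{SeedSet}.
#' @export
SeedSet <- function(cancer, drugs, drugSet = NULL) {
    drugs <- unique(as.character(drugs))
    if (!is.null(drugSet)) {
        bad <- setdiff(drugs, drugIds(drugSet))
        if (length(bad)) {
            warning("dropping unresolvable seed drug(s): ",
                    paste(bad, collapse = ", "))
            drugs <- setdiff(drugs, bad)
        }
        if (length(drugs) == 0L)
            stop("no seed drug resolves against the drug collection")
    }
    new("SeedSet", cancer = cancer, drugs = drugs)
}

#' @export
setMethod("drugIds", "SeedSet", function(x) x@drugs)

#' @describeIn SeedSet number of seed drugs
#' @param x a \code{SeedSet}.
#' @export
setMethod("length", "SeedSet", function(x) length(x@drugs))

setMethod("show", "SeedSet", function(object) {
    cat(sprintf("SeedSet '%s': %d known therapeutic drug(s)\n",
                object@cancer, length(object@drugs)))
})
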