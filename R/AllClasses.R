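#' @importClassesFrom IRanges CharacterList
#' @importFrom IRanges CharacterList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
NULL

setOldClass("igraph")

## ATC level-5 codes: letter, two digits, letter, letter, two digits.
.ATC_REGEX <- "^[A-Z][0-9]{2}[A-Z][A-Z][0-9]{2}$"

#' Drug collection with target genes and ATC codes
#'
#' A \code{DrugSet} holds one record per drug: an accession identifier, a
#' display name, the set of target gene symbols, and the set of 7-character
#' level-5 ATC codes. Either set may be empty for a given drug. Gene identity
#' is by case-sensitive symbol string; identifier mapping is the caller's
#' responsibility.
#'
#' @slot drugId character vector of unique drug accessions.
#' @slot drugName character vector of display names.
#' @slot targets \code{CharacterList} of target gene symbols per drug.
#' @slot atcCodes \code{CharacterList} of level-5 ATC codes per drug.
#' @export
setClass("DrugSet",
    representation(
        drugId = "character",
        drugName = "character",
        targets = "CharacterList",
        atcCodes = "CharacterList"
    )
)

setValidity("DrugSet", function(object) {
    n <- length(object@drugId)
    if (length(object@drugName) != n || length(object@targets) != n ||
        length(object@atcCodes) != n)
        return("drugId, drugName, targets and atcCodes must have equal length")
    if (anyDuplicated(object@drugId))
        return(sprintf("duplicate drug_id: %s",
            paste(unique(object@drugId[duplicated(object@drugId)]),
                  collapse = ", ")))
    codes <- unlist(object@atcCodes, use.names = FALSE)
    bad <- codes[!grepl(.ATC_REGEX, codes)]
    if (length(bad))
        return(sprintf("malformed ATC code(s): %s",
                       paste(unique(bad), collapse = ", ")))
    TRUE
})

#' Named collection of gene sets with a gene universe
#'
#' The universe is the union of all member sets (e.g. the 4383 genes of the
#' 50 MSigDB hallmark sets) and is the population for hypergeometric
#' enrichment.
#'
#' @slot sets named \code{CharacterList}, one element per gene set.
#' @slot universe character vector, the union of all sets.
#' @export
setClass("GeneSetCollection",
    representation(sets = "CharacterList", universe = "character")
)

setValidity("GeneSetCollection", function(object) {
    if (length(object@sets) == 0L)
        return("collection must contain at least one gene set")
    nm <- names(object@sets)
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
        return("gene set names must be present and unique")
    memb <- unique(unlist(object@sets, use.names = FALSE))
    if (!setequal(memb, object@universe))
        return("universe must equal the union of all gene sets")
    TRUE
})

#' Cell-line by gene CRISPR gene-effect matrix
#'
#' Wraps a \code{SummarizedExperiment} with one assay, \code{"effect"}, laid
#' out genes (rows) by cell lines (columns), and a \code{cancer} column in
#' \code{colData} mapping each cell line to its cancer label. Missing
#' measurements are \code{NA} and are excluded from every threshold
#' comparison, never imputed.
#'
#' @export
setClass("GeneEffectMatrix", contains = "SummarizedExperiment")

setValidity("GeneEffectMatrix", function(object) {
    if (!"effect" %in% SummarizedExperiment::assayNames(object))
        return("assay 'effect' is required")
    m <- SummarizedExperiment::assay(object, "effect")
    if (!is.numeric(m))
        return("assay 'effect' must be numeric")
    if (!"cancer" %in% colnames(SummarizedExperiment::colData(object)))
        return("colData must contain a 'cancer' lineage column")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        return("gene symbols (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        return("cell-line identifiers (colnames) must be present and unique")
    TRUE
})

#' Seed set of known therapeutic drugs for one cancer
#'
#' @slot cancer single cancer label.
#' @slot drugs character vector of drug identifiers, the known therapeutics
#'   used to initialise the restart vector.
#' @export
setClass("SeedSet", representation(cancer = "character", drugs = "character"))

setValidity("SeedSet", function(object) {
    if (length(object@cancer) != 1L || !nzchar(object@cancer))
        return("cancer must be a single non-empty label")
    if (length(object@drugs) == 0L)
        return("seed set must contain at least one drug")
    if (anyDuplicated(object@drugs))
        return("seed drugs must be unique")
    TRUE
})

#' Hypergeometric enrichment of drug targets in gene sets
#'
#' One row per drug, one column per gene set. \code{pvalues} holds the
#' upper-tail hypergeometric probability of observing at least the overlap
#' seen between the drug's in-universe targets and the set; \code{indicator}
#' is the binarised enrichment profile (p <= alpha, ties enriched).
#'
#' @slot pvalues numeric matrix, drugs x sets.
#' @slot overlap integer matrix of target/set overlap counts.
#' @slot indicator logical matrix, the enrichment profile H.
#' @slot q named integer, per drug: number of targets inside the universe.
#' @slot alpha significance level applied to the raw p-values.
#' @export
setClass("EnrichmentResult",
    representation(
        pvalues = "matrix",
        overlap = "matrix",
        indicator = "matrix",
        q = "integer",
        alpha = "numeric"
    )
)

setValidity("EnrichmentResult", function(object) {
    d <- dim(object@pvalues)
    if (!identical(dim(object@overlap), d) ||
        !identical(dim(object@indicator), d))
        return("pvalues, overlap and indicator must share dimensions")
    if (length(object@q) != d[1L])
        return("q must have one entry per drug")
    if (object@alpha <= 0 || object@alpha >= 1)
        return("alpha must lie in (0, 1)")
    TRUE
})

#' Empirical significance threshold for clinical similarity
#'
#' Nearest-rank percentile of the empirical distribution of pairwise ATC
#' similarity values; pairs at or above it are clinically significant.
#'
#' @export
setClass("SimilarityThreshold",
    representation(value = "numeric", percentile = "numeric",
                   nPairs = "integer")
)

setValidity("SimilarityThreshold", function(object) {
    if (object@value < 0 || object@value > 1)
        return("threshold value must lie in [0, 1]")
    if (object@percentile <= 0 || object@percentile > 100)
        return("percentile must lie in (0, 100]")
    TRUE
})

#' Union drug similarity network
#'
#' Undirected graph whose nodes are drugs and whose edges join pairs that are
#' functionally similar (share an enriched hallmark set, edge attribute
#' \code{A} = 1) and/or clinically similar at significance (edge attribute
#' \code{B} = the raw ATC similarity when significant, else 0). The edge
#' attribute \code{source} records which channel(s) produced the edge.
#'
#' @slot graph an \code{igraph} object.
#' @slot threshold the clinical significance threshold used at build time.
#' @export
setClass("DrugSimilarityNetwork",
    representation(graph = "igraph", threshold = "numeric")
)

#' Edge-weighting pattern for the transition matrix
#'
#' A weighted pattern assigns each edge the weight alpha*A + beta*B with
#' positive integer coefficients; ratios are always stored in simplest form
#' (column normalisation makes (c*alpha, c*beta) identical to (alpha, beta)).
#' The unweighted pattern (every edge weight 1) is a distinct sentinel, not
#' the 1:1 ratio.
#'
#' @slot alpha,beta positive integer coefficients (NA when unweighted).
#' @slot weighted logical sentinel.
#' @export
setClass("WeightPattern",
    representation(alpha = "integer", beta = "integer", weighted = "logical")
)

setValidity("WeightPattern", function(object) {
    if (length(object@weighted) != 1L)
        return("weighted must be a single logical")
    if (object@weighted) {
        if (is.na(object@alpha) || is.na(object@beta) ||
            object@alpha < 1L || object@beta < 1L)
            return("weighted pattern needs positive integer alpha, beta")
        if (.gcd(object@alpha, object@beta) != 1L)
            return("alpha:beta must be in simplest form")
    }
    TRUE
})

#' Column-stochastic transition matrix over network drugs
#'
#' @slot W sparse column-normalised matrix; \code{W[i, j]} is the probability
#'   of stepping from drug j to drug i.
#' @slot pattern the \code{WeightPattern} used to weight edges.
#' @export
setClass("TransitionMatrix",
    representation(W = "Matrix", pattern = "WeightPattern")
)

setValidity("TransitionMatrix", function(object) {
    cs <- Matrix::colSums(object@W)
    if (any(abs(cs - 1) > 1e-12))
        return("every column must sum to 1")
    if (any(object@W@x < 0))
        return("entries must be non-negative")
    if (is.null(colnames(object@W)))
        return("node identifiers (dimnames) are required")
    TRUE
})

#' Random Walk with Restart configuration
#'
#' @slot restart restart probability r (paper-standard default 0.7).
#' @slot tol L1 convergence bound (default 1e-10).
#' @slot maxIter iteration cap (default 10000).
#' @export
setClass("RWRConfig",
    representation(restart = "numeric", tol = "numeric", maxIter = "integer"),
    prototype(restart = 0.7, tol = 1e-10, maxIter = 10000L)
)

setValidity("RWRConfig", function(object) {
    if (object@restart <= 0 || object@restart > 1)
        return("restart must lie in (0, 1]")
    if (object@tol <= 0) return("tol must be positive")
    if (object@maxIter < 1L) return("maxIter must be >= 1")
    TRUE
})

#' Converged RWR score vector
#'
#' Per-drug stationary probabilities (summing to 1) of a random walker
#' restarting at the seed set, plus the provenance needed to interpret them.
#'
#' @export
setClass("ScoreVector",
    representation(
        scores = "numeric",
        seeds = "character",
        pattern = "WeightPattern",
        iterations = "integer",
        residual = "numeric"
    )
)

#' One delete-n-out stability run
#'
#' Results of re-scoring under every (or up to \code{subsetCap} sampled)
#' seed subset with \code{nRemoved} seeds deleted: the per-subset top lists,
#' the appearance frequency of each listed drug, the 95th nearest-rank
#' percentile frequency threshold, and the candidate drugs at or above it.
#' Rank sums/counts accumulate the rank of every non-seed drug in every
#' subset run, for downstream average-rank reporting.
#'
#' @export
setClass("StabilityRun",
    representation(
        nRemoved = "integer",
        nSubsets = "integer",
        sampled = "logical",
        rngSeed = "integer",
        topLists = "list",
        frequency = "numeric",
        threshold = "numeric",
        candidates = "character",
        rankSums = "numeric",
        rankCounts = "numeric"
    )
)

#' Full delete-n-out stability screen
#'
#' Runs n = 1, 2, ... while the candidate set at n+1 stays contained in the
#' candidate set at n; \code{stopN} is the first n where containment fails
#' (or the largest feasible n, with a warning, if it never fails), and
#' \code{stableCandidates} is the candidate set there.
#'
#' @export
setClass("StabilityResult",
    representation(
        runs = "list",
        baseline = "character",
        stopN = "integer",
        stableCandidates = "character",
        containmentFailed = "logical",
        stableAt = "character"
    )
)

#' Final repositioning output
#'
#' Set algebra over stable candidates (unweighted vs intersection of all
#' weighted patterns), the survival-essential druggable target set, the
#' final repositionable drugs, and per-drug rank summaries.
#'
#' @export
setClass("RepositioningResult",
    representation(
        dUnweighted = "character",
        dWeighted = "character",
        dP = "character",
        dR = "character",
        druggableGenes = "character",
        geneSupport = "integer",
        qualifyingTargets = "list",
        rankTable = "data.frame"
    )
)

#' Synthetic scenario specification
#'
#' Parameters of the planted-structure generator that emulates the drug
#' table, hallmark-style gene sets, gene-effect matrix, lineage map and seed
#' list. A seed cluster of mutually similar drugs (shared enriched set,
#' shared level-4 ATC branch) is planted together with positive drugs that
#' share both channels with the cluster and whose targets include planted
#' essential genes.
#'
#' @export
setClass("SyntheticScenario",
    representation(
        nDrugs = "integer",
        nGenes = "integer",
        nGeneSets = "integer",
        atcBranching = "integer",
        seedClusterSize = "integer",
        nPlantedPositives = "integer",
        nPlantedEssentialGenes = "integer",
        nCellLines = "integer",
        cancerLineFraction = "numeric",
        essentialFraction = "numeric",
        noiseTargetRate = "numeric",
        noiseCodeProb = "numeric",
        missingRate = "numeric",
        rngSeed = "integer",
        cancer = "character"
    ),
    prototype(
        nDrugs = 150L,
        nGenes = 400L,
        nGeneSets = 20L,
        atcBranching = c(3L, 2L, 2L, 3L, 4L),
        seedClusterSize = 10L,
        nPlantedPositives = 4L,
        nPlantedEssentialGenes = 6L,
        nCellLines = 15L,
        cancerLineFraction = 2 / 3,
        essentialFraction = 0.6,
        noiseTargetRate = 1,
        noiseCodeProb = 0.3,
        missingRate = 0.01,
        rngSeed = 1234L,
        cancer = "LUNG"
    )
)

setValidity("SyntheticScenario", function(object) {
    counts <- c(object@nDrugs, object@nGenes, object@nGeneSets,
                object@seedClusterSize, object@nCellLines)
    if (any(counts < 1L)) return("all counts must be positive")
    if (object@nPlantedPositives < 0L || object@nPlantedEssentialGenes < 0L)
        return("planted counts must be non-negative")
    if (length(object@atcBranching) != 5L || any(object@atcBranching < 1L))
        return("atcBranching must give 5 positive branching factors")
    if (object@seedClusterSize + object@nPlantedPositives > object@nDrugs)
        return("seed cluster plus planted positives exceed nDrugs")
    if (object@nGeneSets > object@nGenes)
        return("more gene sets than genes")
    if (object@cancerLineFraction <= 0 || object@cancerLineFraction > 1)
        return("cancerLineFraction must lie in (0, 1]")
    if (object@essentialFraction <= 0 || object@essentialFraction > 1)
        return("essentialFraction must lie in (0, 1]")
    if (object@atcBranching[1L] > 26L || object@atcBranching[3L] > 26L ||
        object@atcBranching[4L] > 26L)
        return("letter-valued ATC levels allow at most 26 branches")
    if (object@atcBranching[2L] > 99L || object@atcBranching[5L] > 99L)
        return("digit-valued ATC levels allow at most 99 branches")
    TRUE
})
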