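## Coerce a network or prebuilt transition matrix to a TransitionMatrix.
.asTransition <- function(x, pattern) {
    if (is(x, "TransitionMatrix")) return(x)
    if (is(x, "DrugSimilarityNetwork")) return(transitionMatrix(x, pattern))
    stop("expected a DrugSimilarityNetwork or TransitionMatrix")
}

.seedIds <- function(seeds) {
    if (is(seeds, "SeedSet")) drugIds(seeds) else as.character(seeds)
}

#' Leave-one-out recall of the seed set
#'
#' Each seed in turn is removed from the seed set; drugs are re-scored
#' with the remaining seeds and the left-out seed counts as recalled when
#' it lies in the top fraction of the non-seed ranking (the left-out seed
#' is a non-seed drug in that run). Seeds absent from the network count as
#' misses.
#'
#' @param network a \code{DrugSimilarityNetwork} or
#'   \code{TransitionMatrix}.
#' @param seeds a \code{SeedSet} (at least 2 members).
#' @param pattern a \code{WeightPattern}; default unweighted.
#' @param config an \code{RWRConfig}.
#' @param topFraction top fraction of non-seed drugs; default 0.05.
#' @return list with \code{recall} in [0, 1] and \code{hits}, a named
#'   logical vector over the seeds.
#' @export
loocvRecall <- function(network, seeds, pattern = unweightedPattern(),
                        config = RWRConfig(), topFraction = 0.05) {
    W <- .asTransition(network, pattern)
    ids <- .seedIds(seeds)
    if (length(ids) < 2L) stop("leave-one-out needs at least 2 seeds")
    nodes <- nodeIds(W)
    hits <- stats::setNames(logical(length(ids)), ids)
    for (s in ids) {
        if (!s %in% nodes) next  # counted as miss
        rest <- setdiff(ids, s)
        sv <- suppressWarnings(rwrScore(W, rest, config))
        r <- .rankNonSeeds(scores(sv), intersect(rest, nodes), topFraction)
        hits[[s]] <- s %in% r$top
    }
    list(recall = mean(hits), hits = hits)
}

## Retained-seed subsets with n seeds removed: exhaustive when feasible,
## otherwise subsetCap distinct subsets sampled uniformly.
.seedSubsets <- function(ids, n, subsetCap, rngSeed) {
    k <- length(ids)
    total <- choose(k, n)
    if (total <= subsetCap) {
        rem <- utils::combn(ids, n, simplify = FALSE)
        return(list(subsets = lapply(rem, function(r) setdiff(ids, r)),
                    sampled = FALSE))
    }
    if (is.null(rngSeed)) stop("sampled subsets require an rngSeed")
    set.seed(as.integer(rngSeed))
    seen <- character(0)
    out <- list()
    while (length(out) < subsetCap) {
        draw <- min(subsetCap, 2L * (subsetCap - length(out)))
        cand <- replicate(draw, sort(sample(ids, n)), simplify = FALSE)
        keys <- vapply(cand, paste, character(1L), collapse = "\r")
        new <- !duplicated(keys) & !keys %in% seen
        seen <- c(seen, keys[new])
        out <- c(out, cand[new])
    }
    out <- out[seq_len(subsetCap)]
    list(subsets = lapply(out, function(r) setdiff(ids, r)),
         sampled = TRUE)
}

#' One delete-n-out stability run
#'
#' Removes every (or up to \code{subsetCap} sampled) combination of
#' \code{n} seeds, re-scores the network with each retained seed subset,
#' takes the top fraction of non-seed drugs per subset, counts how often
#' each drug appears across subsets, and keeps drugs whose frequency
#' reaches the 95th nearest-rank percentile of the frequency distribution
#' (inclusive; only drugs appearing in at least one top list enter the
#' distribution).
#'
#' @param network a \code{DrugSimilarityNetwork} or
#'   \code{TransitionMatrix}.
#' @param seeds a \code{SeedSet}.
#' @param pattern a \code{WeightPattern}; default unweighted.
#' @param n number of seeds removed, \code{1 <= n < length(seeds)}.
#' @param config an \code{RWRConfig}.
#' @param rngSeed integer seed for subset sampling (unused and irrelevant
#'   when the subset space is enumerated exhaustively).
#' @param subsetCap maximum number of subsets before switching to uniform
#'   sampling without replacement; default 10000.
#' @param topFraction top fraction of non-seed drugs; default 0.05.
#' @param percentile frequency percentile; default 95.
#' @return a \code{StabilityRun}.
#' @export
deleteNOut <- function(network, seeds, pattern = unweightedPattern(),
                       n, config = RWRConfig(), rngSeed = NULL,
                       subsetCap = 10000L, topFraction = 0.05,
                       percentile = 95) {
    W <- .asTransition(network, pattern)
    ids <- .seedIds(seeds)
    n <- as.integer(n)
    if (n < 1L || n >= length(ids))
        stop("n must satisfy 1 <= n < number of seeds")
    sub <- .seedSubsets(ids, n, subsetCap, rngSeed)
    runs <- lapply(sub$subsets, function(retained) {
        sv <- suppressWarnings(rwrScore(W, retained, config))
        .rankNonSeeds(scores(sv), intersect(retained, nodeIds(W)),
                      topFraction)
    })
    topLists <- lapply(runs, `[[`, "top")
    freqTab <- table(unlist(topLists, use.names = FALSE))
    freq <- stats::setNames(as.numeric(freqTab), names(freqTab))
    thr <- nearestRankPercentile(freq, percentile)
    cand <- sort(names(freq)[freq >= thr])
    allRanks <- unlist(lapply(runs, `[[`, "ranks"))
    rankSums <- tapply(allRanks, names(allRanks), sum)
    rankCounts <- tapply(allRanks, names(allRanks), length)
    new("StabilityRun",
        nRemoved = n,
        nSubsets = length(sub$subsets),
        sampled = sub$sampled,
        rngSeed = if (sub$sampled) as.integer(rngSeed) else NA_integer_,
        topLists = topLists,
        frequency = freq,
        threshold = thr,
        candidates = cand,
        rankSums = stats::setNames(as.numeric(rankSums), names(rankSums)),
        rankCounts = stats::setNames(as.numeric(rankCounts),
                                     names(rankCounts)))
}

#' Delete-n-out at a single fixed n
#'
#' Identical to \code{\link{deleteNOut}}; used for the weighted patterns,
#' which all reuse the stopping depth determined once on the unweighted
#' network rather than re-running the full stopping rule.
#'
#' @inheritParams deleteNOut
#' @param nFixed the (externally determined) number of seeds to remove.
#' @return a \code{StabilityRun}.
#' @export
fixedNStability <- function(network, seeds, pattern = unweightedPattern(),
                            nFixed, config = RWRConfig(), rngSeed = NULL,
                            subsetCap = 10000L, topFraction = 0.05,
                            percentile = 95) {
    deleteNOut(network, seeds, pattern, n = nFixed, config = config,
               rngSeed = rngSeed, subsetCap = subsetCap,
               topFraction = topFraction, percentile = percentile)
}

#' Full delete-n-out stability screen with stopping rule
#'
#' Runs delete-n-out for n = 1, 2, ... and continues while the candidate
#' set at n+1 is fully contained in the candidate set at n. The first n
#' where containment fails is \code{stopN} and the stable candidates are
#' the candidate set there (configurable to the previous depth via
#' \code{stableAt}). If containment never fails the screen stops at
#' n = seeds - 1 with a warning. The all-seed (n = 0) top list is recorded
#' as a baseline.
#'
#' @inheritParams deleteNOut
#' @param rngSeed base integer seed; run n uses \code{rngSeed + n} so each
#'   depth samples independently yet reproducibly.
#' @param stableAt \code{"stop"} (default) takes the candidate set at the
#'   first failing depth, \code{"stop-1"} the one before it.
#' @param maxN optional cap on the deletion depth (default
#'   \code{length(seeds) - 1}).
#' @return a \code{StabilityResult}.
#' @export
runStability <- function(network, seeds, pattern = unweightedPattern(),
                         config = RWRConfig(), rngSeed = 1L,
                         subsetCap = 10000L, topFraction = 0.05,
                         percentile = 95, stableAt = c("stop", "stop-1"),
                         maxN = NULL) {
    stableAt <- match.arg(stableAt)
    W <- .asTransition(network, pattern)
    ids <- .seedIds(seeds)
    if (length(ids) < 3L) stop("stability screen needs at least 3 seeds")
    nMax <- length(ids) - 1L
    if (!is.null(maxN)) nMax <- min(nMax, as.integer(maxN))

    sv <- suppressWarnings(rwrScore(W, ids, config))
    baseline <- .rankNonSeeds(scores(sv), intersect(ids, nodeIds(W)),
                              topFraction)$top

    runs <- list()
    stopN <- NA_integer_
    failed <- FALSE
    for (n in seq_len(nMax)) {
        run <- deleteNOut(W, ids, pattern, n = n, config = config,
                          rngSeed = as.integer(rngSeed) + n,
                          subsetCap = subsetCap,
                          topFraction = topFraction,
                          percentile = percentile)
        runs[[n]] <- run
        if (n >= 2L &&
            !all(run@candidates %in% runs[[n - 1L]]@candidates)) {
            stopN <- n
            failed <- TRUE
            break
        }
    }
    if (!failed) {
        stopN <- nMax
        warning("candidate-set containment never failed; stopping at n = ",
                stopN)
    }
    pick <- if (stableAt == "stop" || stopN == 1L) stopN else stopN - 1L
    new("StabilityResult",
        runs = runs,
        baseline = baseline,
        stopN = stopN,
        stableCandidates = runs[[pick]]@candidates,
        containmentFailed = failed,
        stableAt = stableAt)
}

#' @export
setMethod("candidates", "StabilityRun", function(x) x@candidates)

#' @export
setMethod("frequencies", "StabilityRun", function(x) x@frequency)

#' @export
setMethod("frequencyThreshold", "StabilityRun", function(x) x@threshold)

setMethod("show", "StabilityRun", function(object) {
    cat(sprintf(
        "StabilityRun: delete-%d-out, %d subset(s)%s, threshold %g, %d candidate(s)\n",
        object@nRemoved, object@nSubsets,
        if (object@sampled) " (sampled)" else "", object@threshold,
        length(object@candidates)))
})

#' @export
setMethod("stopN", "StabilityResult", function(x) x@stopN)

#' @export
setMethod("stableCandidates", "StabilityResult", function(x) {
    x@stableCandidates
})

#' @export
setMethod("candidates", "StabilityResult", function(x) {
    lapply(x@runs, candidates)
})

setMethod("show", "StabilityResult", function(object) {
    cat(sprintf(
        "StabilityResult: stop at n = %d (%s), %d stable candidate(s)\n",
        object@stopN,
        if (object@containmentFailed) "containment failed"
        else "containment never failed", length(object@stableCandidates)))
})

#' Export a stability run summary table
#'
#' @param run a \code{StabilityRun}.
#' @param path TSV path: drug_id, frequency, threshold, candidate flag.
#' @export
writeStabilitySummary <- function(run, path) {
    df <- data.frame(drug_id = names(run@frequency),
                     frequency = as.integer(run@frequency),
                     threshold = run@threshold,
                     candidate = names(run@frequency) %in% run@candidates,
                     stringsAsFactors = FALSE)
    df <- df[order(-df$frequency, df$drug_id), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
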