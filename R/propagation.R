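#' Construct a weight pattern
#'
#' Ratios are stored in simplest form: \code{WeightPattern(2, 6)} is the
#' same object as \code{WeightPattern(1, 3)} (column normalisation of the
#' transition matrix makes scaled coefficient pairs act identically, which
#' is exactly why only simplest ratios are enumerated).
#'
#' @param alpha,beta positive integer weighting coefficients for the
#'   functional (A) and clinical (B) edge similarity.
#' @return a weighted \code{WeightPattern}.
#' @seealso \code{\link{unweightedPattern}}
#' @export
WeightPattern <- function(alpha, beta) {
    alpha <- as.integer(alpha)
    beta <- as.integer(beta)
    if (is.na(alpha) || is.na(beta) || alpha < 1L || beta < 1L)
        stop("alpha and beta must be positive integers")
    g <- .gcd(alpha, beta)
    new("WeightPattern", alpha = alpha %/% g, beta = beta %/% g,
        weighted = TRUE)
}

#' The unweighted pattern sentinel
#'
#' Every edge gets transition weight 1 regardless of its similarity
#' values. Distinct from the 1:1 weighted ratio, which weights edges by
#' \code{A + B}.
#'
#' @return an unweighted \code{WeightPattern}.
#' @export
unweightedPattern <- function() {
    new("WeightPattern", alpha = NA_integer_, beta = NA_integer_,
        weighted = FALSE)
}

#' @export
setMethod("patternLabel", "WeightPattern", function(x) {
    if (x@weighted) sprintf("%d:%d", x@alpha, x@beta) else "unweighted"
})

setMethod("show", "WeightPattern", function(object) {
    cat("WeightPattern:", patternLabel(object), "\n")
})

#' Enumerate all distinct weighting patterns
#'
#' All ordered coefficient pairs with \code{1 <= alpha, beta <=
#' maxCoefficient} collapse to their simplest ratios; each distinct ratio
#' is emitted once, ordered by alpha then beta. The equal-weight 1:1 ratio
#' is excluded by default, which yields the canonical 54 patterns at the
#' default maximum of 9 (naive coprime enumeration gives 55).
#'
#' @param maxCoefficient largest coefficient value (default 9).
#' @param includeEqual keep the 1:1 ratio (default FALSE).
#' @return list of \code{WeightPattern} objects.
#' @examples
#' length(enumerateWeightPatterns())      # 54
#' length(enumerateWeightPatterns(includeEqual = TRUE))  # 55
#' @export
enumerateWeightPatterns <- function(maxCoefficient = 9,
                                    includeEqual = FALSE) {
    maxCoefficient <- as.integer(maxCoefficient)
    if (is.na(maxCoefficient) || maxCoefficient < 1L)
        stop("maxCoefficient must be a positive integer")
    grid <- expand.grid(alpha = seq_len(maxCoefficient),
                        beta = seq_len(maxCoefficient))
    coprime <- mapply(.gcd, grid$alpha, grid$beta) == 1L
    grid <- grid[coprime, , drop = FALSE]
    if (!includeEqual)
        grid <- grid[!(grid$alpha == 1L & grid$beta == 1L), , drop = FALSE]
    grid <- grid[order(grid$alpha, grid$beta), , drop = FALSE]
    unname(mapply(function(a, b) WeightPattern(a, b),
                  grid$alpha, grid$beta))
}

#' Column-stochastic transition matrix of a network
#'
#' Edge weights are 1 under the unweighted pattern and
#' \code{alpha * A + beta * B} under a weighted pattern; columns are then
#' normalised to sum to 1. A node whose incident weights are all zero
#' would produce a dangling column and is a hard error (the network
#' construction rule makes this impossible: every edge has A = 1 or
#' B > 0).
#'
#' @param network a \code{DrugSimilarityNetwork}.
#' @param pattern a \code{WeightPattern}; default unweighted.
#' @return a \code{TransitionMatrix}.
#' @export
transitionMatrix <- function(network, pattern = unweightedPattern()) {
    stopifnot(is(network, "DrugSimilarityNetwork"),
              is(pattern, "WeightPattern"))
    g <- network@graph
    if (igraph::vcount(g) == 0L) stop("empty network")
    if (pattern@weighted) {
        w <- pattern@alpha * igraph::E(g)$A + pattern@beta * igraph::E(g)$B
    } else {
        w <- rep(1, igraph::ecount(g))
    }
    igraph::E(g)$w <- w
    adj <- igraph::as_adjacency_matrix(g, attr = "w", sparse = TRUE)
    cs <- Matrix::colSums(adj)
    if (any(cs == 0))
        stop("all-zero column(s) for node(s): ",
             paste(colnames(adj)[cs == 0], collapse = ", "))
    W <- adj %*% Matrix::Diagonal(x = 1 / cs)
    dimnames(W) <- dimnames(adj)
    new("TransitionMatrix", W = methods::as(W, "CsparseMatrix"),
        pattern = pattern)
}

#' @export
setMethod("nodeIds", "TransitionMatrix", function(x) colnames(x@W))

#' @export
setMethod("patternLabel", "TransitionMatrix", function(x) {
    patternLabel(x@pattern)
})

setMethod("show", "TransitionMatrix", function(object) {
    cat(sprintf("TransitionMatrix: %d nodes, pattern %s\n",
                ncol(object@W), patternLabel(object@pattern)))
})

#' Random Walk with Restart configuration
#'
#' @param restart restart probability r in (0, 1]; default 0.7.
#' @param tol L1 convergence bound; default 1e-10.
#' @param maxIter iteration cap; default 10000.
#' @return an \code{RWRConfig}.
#' @export
RWRConfig <- function(restart = 0.7, tol = 1e-10, maxIter = 10000L) {
    new("RWRConfig", restart = restart, tol = tol,
        maxIter = as.integer(maxIter))
}

## bare iteration core shared by all scoring entry points
.rwrIterate <- function(W, s0, restart, tol, maxIter) {
    s <- s0
    for (it in seq_len(maxIter)) {
        s1 <- (1 - restart) * as.vector(W %*% s) + restart * s0
        res <- sum(abs(s1 - s))
        s <- s1
        if (res < tol) return(list(s = s, iterations = it, residual = res))
    }
    stop(sprintf(
        "RWR did not converge in %d iterations (last L1 residual %.3e)",
        maxIter, res))
}

#' Score drugs against a seed set by Random Walk with Restart
#'
#' Iterates \eqn{S_{t+1} = (1 - r) W S_t + r S_0} from the restart vector
#' \eqn{S_0} (equal probability on the seeds, summing to 1) until the L1
#' difference between successive iterates falls below the tolerance. The
#' converged probabilities measure each drug's proximity to the seed set.
#'
#' @param W a \code{TransitionMatrix}.
#' @param seeds a \code{SeedSet} or character vector of seed drug ids.
#'   Seeds absent from the node set are dropped with a warning; zero
#'   resolvable seeds is an error.
#' @param config an \code{RWRConfig}.
#' @return a \code{ScoreVector}.
#' @export
rwrScore <- function(W, seeds, config = RWRConfig()) {
    stopifnot(is(W, "TransitionMatrix"), is(config, "RWRConfig"))
    methods::validObject(config)
    seedIds <- if (is(seeds, "SeedSet")) drugIds(seeds) else
        as.character(seeds)
    nodes <- nodeIds(W)
    present <- intersect(seedIds, nodes)
    absent <- setdiff(seedIds, nodes)
    if (length(absent))
        warning("seed(s) absent from the network dropped: ",
                paste(absent, collapse = ", "))
    if (length(present) == 0L)
        stop("no seed resolves to a network node")
    s0 <- stats::setNames(numeric(length(nodes)), nodes)
    s0[present] <- 1 / length(present)
    out <- .rwrIterate(W@W, s0, config@restart, config@tol, config@maxIter)
    new("ScoreVector", scores = stats::setNames(out$s, nodes),
        seeds = present, pattern = W@pattern,
        iterations = out$iterations, residual = out$residual)
}

#' @export
setMethod("scores", "ScoreVector", function(x) x@scores)

#' @export
setMethod("patternLabel", "ScoreVector", function(x) {
    patternLabel(x@pattern)
})

setMethod("show", "ScoreVector", function(object) {
    cat(sprintf(
        "ScoreVector: %d drugs, %d seed(s), pattern %s (%d iterations)\n",
        length(object@scores), length(object@seeds),
        patternLabel(object@pattern), object@iterations))
})

## Fast ranking core: full descending ranking of non-seed drugs with
## deterministic id tie-break, plus the top-fraction cut.
.rankNonSeeds <- function(scoreVec, seedIds, topFraction) {
    nonseed <- setdiff(names(scoreVec), seedIds)
    s <- scoreVec[nonseed]
    o <- order(-s, nonseed)
    ranked <- nonseed[o]
    k <- as.integer(ceiling(topFraction * length(ranked)))
    list(ranked = ranked,
         ranks = stats::setNames(seq_along(ranked), ranked),
         scores = s[o],
         top = ranked[seq_len(min(k, length(ranked)))])
}

#' Rank non-seed drugs and take the top fraction
#'
#' Seeds are retained in the propagation but excluded from the candidate
#' ranking (a seed rediscovered by itself is not a repositioning
#' candidate). Remaining drugs are sorted by score descending with ties
#' broken by drug id ascending; the top
#' \code{ceiling(topFraction * n_nonseed)} drugs are returned.
#'
#' @param scoreVector a \code{ScoreVector}.
#' @param seeds seeds to exclude; defaults to the seeds the scores were
#'   computed with.
#' @param topFraction fraction in (0, 1); default 0.05.
#' @return data.frame with \code{drug_id}, \code{score}, \code{rank}.
#' @export
rankDrugs <- function(scoreVector, seeds = NULL, topFraction = 0.05) {
    stopifnot(is(scoreVector, "ScoreVector"))
    .assertScalarNumeric(topFraction, "topFraction")
    if (topFraction <= 0 || topFraction >= 1)
        stop("topFraction must lie in (0, 1)")
    seedIds <- if (is.null(seeds)) scoreVector@seeds
               else if (is(seeds, "SeedSet")) drugIds(seeds)
               else as.character(seeds)
    r <- .rankNonSeeds(scores(scoreVector), seedIds, topFraction)
    data.frame(drug_id = r$top,
               score = unname(r$scores[seq_along(r$top)]),
               rank = seq_along(r$top),
               stringsAsFactors = FALSE)
}

#' Write a score table
#'
#' @param scoreVector a \code{ScoreVector}.
#' @param path TSV path.
#' @export
writeScoreTable <- function(scoreVector, path) {
    s <- sort(scores(scoreVector), decreasing = TRUE)
    df <- data.frame(drug_id = names(s),
                     score = sprintf("%.17g", unname(s)),
                     pattern = patternLabel(scoreVector),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
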