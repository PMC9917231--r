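# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: explicit summation, dense linear algebra, and plain
# loops, never calling the code paths they verify.

# Upper-tail hypergeometric probability P(X >= F) by explicit summation of
# binomial-coefficient ratios (exact for the small counts used in tests).
oracleHyper <- function(Q, M, q, F) {
    f <- seq.int(F, min(M, q))
    if (length(f) == 0L) return(0)
    sum(choose(M, f) * choose(Q - M, q - f)) / choose(Q, q)
}

# Stationary RWR scores by direct linear solve of
# (I - (1 - r) W) s = r s0.
oracleRWR <- function(W, seedIds, r = 0.7) {
    nodes <- colnames(W)
    s0 <- setNames(numeric(length(nodes)), nodes)
    s0[seedIds] <- 1 / length(seedIds)
    s <- solve(diag(length(nodes)) - (1 - r) * as.matrix(W), r * s0)
    setNames(as.vector(s), nodes)
}

# Descending score ranking of non-seed drugs, ties by id, top fraction.
oracleTop <- function(scores, seedIds, frac = 0.05) {
    nonseed <- setdiff(names(scores), seedIds)
    o <- order(-scores[nonseed], nonseed)
    k <- ceiling(frac * length(nonseed))
    nonseed[o][seq_len(k)]
}

oraclePercentile <- function(x, p = 95) {
    s <- sort(x)
    s[[max(1L, ceiling(p / 100 * length(s)))]]
}

# Naive replay of one delete-n-out run on a prebuilt transition matrix:
# exhaustive subsets, linear-solve scoring, nearest-rank threshold.
oracleDeleteNOut <- function(Wmat, seedIds, n, r = 0.7, frac = 0.05,
                             p = 95) {
    removals <- combn(seedIds, n, simplify = FALSE)
    tops <- lapply(removals, function(rem) {
        retained <- setdiff(seedIds, rem)
        oracleTop(oracleRWR(Wmat, retained, r), retained, frac)
    })
    freq <- table(unlist(tops))
    thr <- oraclePercentile(as.numeric(freq), p)
    list(topLists = tops, freq = freq, threshold = thr,
         candidates = sort(names(freq)[freq >= thr]))
}

# Build a DrugSimilarityNetwork from an explicit edge list; every edge is
# functional (A = 1) unless a B value above the threshold is supplied.
toyNetwork <- function(from, to, A = 1L, B = 0, threshold = 0.5) {
    k <- length(from)
    pairs <- data.frame(
        drug_i = from, drug_j = to,
        functional = rep_len(as.integer(A), k),
        S2 = NA_real_, S3 = NA_real_, S4 = NA_real_,
        SATC = rep_len(as.numeric(B), k),
        stringsAsFactors = FALSE)
    pairs$clinical_significant <- !is.na(pairs$SATC) &
        pairs$SATC >= threshold
    buildNetwork(pairs, threshold)
}

# Random graph on n nodes where every node has degree >= 1 (a ring plus
# random chords); optionally random clinical B weights above threshold.
randomToyNetwork <- function(n, extra = n, weighted = FALSE,
                             threshold = 0.5) {
    ids <- sprintf("d%02d", seq_len(n))
    from <- ids
    to <- ids[c(2:n, 1L)]
    if (extra > 0L) {
        f2 <- sample(ids, extra, replace = TRUE)
        t2 <- sample(ids, extra, replace = TRUE)
        ok <- f2 != t2
        from <- c(from, f2[ok])
        to <- c(to, t2[ok])
    }
    key <- paste(pmin(from, to), pmax(from, to))
    keep <- !duplicated(key)
    from <- from[keep]; to <- to[keep]
    k <- length(from)
    if (weighted) {
        A <- sample(0:1, k, replace = TRUE)
        B <- ifelse(runif(k) < 0.5,
                    runif(k, threshold, 1), 0)
        fix <- A == 0L & B == 0           # every edge must carry weight
        A[fix] <- 1L
    } else {
        A <- rep(1L, k)
        B <- rep(0, k)
    }
    toyNetwork(from, to, A = A, B = B, threshold = threshold)
}
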