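test_that("weight patterns enumerate to simplest distinct ratios", {
    pats <- enumerateWeightPatterns(9)
    expect_length(pats, 54L)
    labs <- vapply(pats, patternLabel, character(1))
    expect_false(anyDuplicated(labs) > 0)
    expect_false("1:1" %in% labs)
    expect_length(enumerateWeightPatterns(9, includeEqual = TRUE), 55L)
    # independent count: coprime ordered pairs in 1..9
    brute <- sum(outer(1:9, 1:9,
                       Vectorize(function(a, b) {
                           while (b) { t <- b; b <- a %% b; a <- t }; a
                       })) == 1L)
    expect_equal(brute, 55L)
    expect_error(enumerateWeightPatterns(0), "positive")
})

test_that("coefficient pairs reduce to the simplest ratio", {
    expect_equal(patternLabel(WeightPattern(2, 6)), "1:3")
    expect_equal(WeightPattern(2, 4), WeightPattern(1, 2))
    expect_equal(WeightPattern(3, 6), WeightPattern(1, 2))
    expect_false("2:6" %in%
        vapply(enumerateWeightPatterns(9), patternLabel, character(1)))
    # the unweighted sentinel is not the 1:1 ratio
    expect_false(identical(unweightedPattern(), WeightPattern(1, 1)))
})

test_that("transition matrices are column stochastic", {
    two <- toyNetwork("a", "b")
    W <- transitionMatrix(two)
    expect_equal(as.matrix(W@W),
                 matrix(c(0, 1, 1, 0), 2,
                        dimnames = list(c("a", "b"), c("a", "b"))))
    set.seed(13)
    for (i in 1:5) {
        net <- randomToyNetwork(15, extra = 20, weighted = TRUE)
        for (p in list(unweightedPattern(), WeightPattern(1, 2),
                       WeightPattern(9, 1))) {
            W <- transitionMatrix(net, p)
            expect_equal(unname(Matrix::colSums(W@W)),
                         rep(1, ncol(W@W)))
            expect_true(all(W@W@x >= 0))
        }
    }
})

test_that("reduced coefficient pairs give the identical transition matrix", {
    set.seed(17)
    net <- randomToyNetwork(15, extra = 20, weighted = TRUE)
    W1 <- transitionMatrix(net, WeightPattern(1, 3))
    W2 <- transitionMatrix(net, WeightPattern(2, 6))
    expect_identical(as.matrix(W1@W), as.matrix(W2@W))
})

test_that("restart probability 1 returns the restart vector", {
    net <- toyNetwork(c("a", "b"), c("b", "c"))
    sv <- rwrScore(transitionMatrix(net), "a",
                   RWRConfig(restart = 1))
    expect_equal(unname(scores(sv)[c("a", "b", "c")]), c(1, 0, 0))
})

test_that("small-graph scores match the closed-form solution", {
    two <- transitionMatrix(toyNetwork("a", "b"))
    sv <- rwrScore(two, "a")
    expect_equal(unname(scores(sv)[c("a", "b")]),
                 c(0.7 / 0.91, 0.3 * 0.7 / 0.91), tolerance = 1e-8)
    expect_equal(unname(scores(sv)[c("a", "b")]), c(0.76923, 0.23077),
                 tolerance = 1e-4)

    path <- transitionMatrix(toyNetwork(c("a", "b"), c("b", "c")))
    sv <- rwrScore(path, "a")
    expect_equal(unname(scores(sv)[c("a", "b", "c")]),
                 unname(oracleRWR(path@W, "a")[c("a", "b", "c")]),
                 tolerance = 1e-8)
    expect_equal(unname(scores(sv)[c("a", "b", "c")]),
                 c(0.73462, 0.23077, 0.03462), tolerance = 1e-4)
})

test_that("scores stay a probability vector at every iteration", {
    set.seed(23)
    net <- randomToyNetwork(20, extra = 25)
    W <- transitionMatrix(net)@W
    nodes <- colnames(W)
    s <- setNames(numeric(length(nodes)), nodes)
    s[sample(nodes, 3)] <- 1 / 3
    s0 <- s
    for (it in 1:25) {
        s <- 0.3 * as.vector(W %*% s) + 0.7 * s0
        expect_equal(sum(s), 1, tolerance = 1e-12)
        expect_true(all(s >= 0))
    }
    sv <- rwrScore(transitionMatrix(net), names(s0)[s0 > 0])
    expect_equal(sum(scores(sv)), 1, tolerance = 1e-9)
})

test_that("seed resolution and convergence failures are reported", {
    net <- toyNetwork(c("a", "b"), c("b", "c"))
    W <- transitionMatrix(net)
    expect_warning(sv <- rwrScore(W, c("a", "zz")), "zz")
    expect_equal(sv@seeds, "a")
    expect_error(suppressWarnings(rwrScore(W, "zz")), "no seed")
    expect_error(rwrScore(W, "a", RWRConfig(tol = 1e-300, maxIter = 5L)),
                 "did not converge")
})

test_that("ranking excludes seeds, breaks ties by id, takes the ceiling", {
    ids <- sprintf("d%02d", 1:41)
    net <- toyNetwork(rep("d41", 40), ids[1:40])  # star, hub = seed
    sv <- rwrScore(transitionMatrix(net), "d41")
    top <- rankDrugs(sv, topFraction = 0.05)
    expect_equal(nrow(top), 2L)           # ceiling(0.05 * 40)
    # all leaves tie: lexicographically smallest ids win
    expect_equal(top$drug_id, c("d01", "d02"))
    expect_false("d41" %in% top$drug_id)
    # distinct scores: output order equals score order
    set.seed(3)
    net2 <- randomToyNetwork(20, extra = 25)
    sv2 <- rwrScore(transitionMatrix(net2), c("d01", "d02"))
    full <- rankDrugs(sv2, topFraction = 0.99)
    expect_equal(full$drug_id,
                 oracleTop(scores(sv2), c("d01", "d02"), 0.99))
})

test_that("drugs adjacent to several seeds outscore unattached drugs", {
    fx <- defaultFixture()
    sv <- rwrScore(fx$W0, fx$dat$seeds)
    et <- edgeTable(fx$net)
    seedIds <- drugIds(fx$dat$seeds)
    nbrSeeds <- function(id) {
        sum(et$drug_i %in% seedIds & et$drug_j == id) +
            sum(et$drug_j %in% seedIds & et$drug_i == id)
    }
    nonseed <- setdiff(nodeIds(fx$net), seedIds)
    k <- vapply(nonseed, nbrSeeds, numeric(1))
    close <- nonseed[k >= 2]
    far <- nonseed[k == 0]
    expect_gt(min(scores(sv)[close]), max(scores(sv)[far]))
})
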