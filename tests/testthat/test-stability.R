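# Toy network with a clear community: 4 seeds all attached to two bridge
# drugs, plus a background ring.
.stabilityToy <- function(nSeeds = 4, nBg = 60, seedPrefix = "s") {
    seeds <- sprintf("%s%02d", seedPrefix, seq_len(nSeeds))
    bridges <- c("p01", "p02")
    bg <- sprintf("b%02d", seq_len(nBg))
    from <- c(rep(seeds, each = 2),
              utils::combn(seeds, 2)[1, ],
              bg)
    to <- c(rep(bridges, nSeeds),
            utils::combn(seeds, 2)[2, ],
            bg[c(2:nBg, 1)])
    list(net = toyNetwork(from, to), seeds = seeds, bridges = bridges)
}

test_that("leave-one-out recall is 1 on a seed clique and 0 across components", {
    toy <- .stabilityToy()
    rec <- loocvRecall(toy$net, toy$seeds)
    expect_equal(rec$recall, 1)
    expect_true(all(rec$hits))

    # two seeds in disconnected components with rich local neighbourhoods
    cliqueEdges <- function(ids) {
        cmb <- utils::combn(ids, 2)
        list(from = cmb[1, ], to = cmb[2, ])
    }
    c1 <- cliqueEdges(c("s1", sprintf("u%02d", 1:10)))
    c2 <- cliqueEdges(c("s2", sprintf("v%02d", 1:10)))
    net2 <- toyNetwork(c(c1$from, c2$from), c(c1$to, c2$to))
    rec2 <- loocvRecall(net2, c("s1", "s2"))
    expect_equal(rec2$recall, 0)
})

test_that("a left-out seed absent from the network counts as a miss", {
    toy <- .stabilityToy()
    rec <- loocvRecall(toy$net, c(toy$seeds, "ghost"))
    expect_false(rec$hits[["ghost"]])
    expect_equal(rec$recall, length(toy$seeds) / (length(toy$seeds) + 1))
})

test_that("exhaustive delete-n-out matches the brute-force replay oracle", {
    set.seed(91)
    for (rep in 1:3) {
        net <- randomToyNetwork(25, extra = 40, weighted = rep > 1)
        seeds <- sort(sample(nodeIds(net), 6))
        pat <- if (rep > 1) WeightPattern(2, 3) else unweightedPattern()
        W <- transitionMatrix(net, pat)
        for (n in c(1L, 3L)) {
            run <- deleteNOut(W, seeds, pat, n = n)
            orc <- oracleDeleteNOut(W@W, seeds, n)
            expect_equal(run@nSubsets, choose(6, n))
            expect_false(run@sampled)
            expect_equal(candidates(run), orc$candidates)
            expect_equal(frequencyThreshold(run), orc$threshold)
            f <- frequencies(run)
            expect_equal(f[sort(names(f))],
                         setNames(as.numeric(orc$freq[sort(names(f))]),
                                  sort(names(f))))
        }
    }
})

test_that("frequency mass is conserved across top lists", {
    toy <- .stabilityToy()
    run <- deleteNOut(toy$net, toy$seeds, n = 2)
    expect_equal(sum(frequencies(run)),
                 sum(lengths(run@topLists)))
})

test_that("identical top lists make every listed drug a candidate", {
    # 3 seeds in a triangle, both bridges attached to all three: by
    # symmetry every delete-1-out subset ranks the bridges on top
    toy <- .stabilityToy(nSeeds = 3)
    run <- deleteNOut(toy$net, toy$seeds, n = 1)
    expect_equal(run@nSubsets, 3L)
    listsEqual <- all(vapply(run@topLists,
                             function(x) identical(sort(x),
                                                   sort(run@topLists[[1]])),
                             logical(1)))
    if (listsEqual) {
        expect_true(all(frequencies(run) == 3))
        expect_equal(frequencyThreshold(run), 3)
        expect_setequal(candidates(run), run@topLists[[1]])
    }
    expect_true(all(toy$bridges %in% candidates(run)))
})

test_that("subset sampling caps, is distinct, and is seed-reproducible", {
    set.seed(77)
    net <- randomToyNetwork(30, extra = 50)
    seeds <- sort(sample(nodeIds(net), 10))
    # C(10, 5) = 252 > 40: sampled branch
    r1 <- deleteNOut(net, seeds, n = 5, rngSeed = 123L, subsetCap = 40L)
    r2 <- deleteNOut(net, seeds, n = 5, rngSeed = 123L, subsetCap = 40L)
    r3 <- deleteNOut(net, seeds, n = 5, rngSeed = 321L, subsetCap = 40L)
    expect_true(r1@sampled)
    expect_equal(r1@nSubsets, 40L)
    expect_identical(frequencies(r1), frequencies(r2))
    expect_identical(candidates(r1), candidates(r2))
    expect_identical(r1@topLists, r2@topLists)
    expect_false(identical(r1@topLists, r3@topLists))
    expect_error(deleteNOut(net, seeds, n = 5, subsetCap = 40L),
                 "rngSeed")
    # exhaustive branch ignores the RNG entirely
    e1 <- deleteNOut(net, seeds, n = 1, rngSeed = 1L)
    e2 <- deleteNOut(net, seeds, n = 1, rngSeed = 999L)
    expect_identical(frequencies(e1), frequencies(e2))
    expect_error(deleteNOut(net, seeds, n = 10), "1 <= n")
})

test_that("the stability screen follows the containment stopping rule", {
    toy <- .stabilityToy(nSeeds = 5)
    res <- suppressWarnings(runStability(toy$net, toy$seeds,
                                         rngSeed = 1L))
    # independent replay of the published rule: run every depth with the
    # oracle, stop at the first containment failure
    W <- transitionMatrix(toy$net)
    orc <- lapply(1:4, function(n) oracleDeleteNOut(W@W, toy$seeds, n))
    expStop <- 4L
    expFailed <- FALSE
    for (n in 2:4) {
        if (!all(orc[[n]]$candidates %in% orc[[n - 1]]$candidates)) {
            expStop <- n
            expFailed <- TRUE
            break
        }
    }
    expect_equal(stopN(res), expStop)
    expect_equal(res@containmentFailed, expFailed)
    expect_equal(stableCandidates(res), orc[[expStop]]$candidates)
    expect_equal(stableCandidates(res),
                 candidates(res@runs[[stopN(res)]]))
    # the n = 0 baseline is recorded
    expect_true(all(toy$bridges %in% res@baseline))
    for (n in seq_len(stopN(res)))
        expect_equal(candidates(res@runs[[n]]), orc[[n]]$candidates)
})

test_that("stability results are deterministic at sampled scale", {
    set.seed(55)
    net <- randomToyNetwork(30, extra = 50)
    seeds <- sort(sample(nodeIds(net), 8))
    r1 <- suppressWarnings(runStability(net, seeds, rngSeed = 42L,
                                        subsetCap = 20L))
    r2 <- suppressWarnings(runStability(net, seeds, rngSeed = 42L,
                                        subsetCap = 20L))
    expect_identical(stableCandidates(r1), stableCandidates(r2))
    expect_identical(lapply(r1@runs, frequencies),
                     lapply(r2@runs, frequencies))
    expect_identical(stopN(r1), stopN(r2))
})

test_that("fixedNStability equals deleteNOut at the same depth", {
    toy <- .stabilityToy()
    a <- fixedNStability(toy$net, toy$seeds, nFixed = 1)
    b <- deleteNOut(toy$net, toy$seeds, n = 1)
    expect_identical(frequencies(a), frequencies(b))
    expect_identical(candidates(a), candidates(b))
})
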