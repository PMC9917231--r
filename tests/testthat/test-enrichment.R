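# Worked configuration: universe of 10 genes, one set of 4, a drug with 3
# in-universe targets overlapping the set in 2 genes.
.enrichFixture <- function() {
    genes <- paste0("g", 1:10)
    gsc <- GeneSetCollection(list(h = genes[1:4],
                                  rest = genes))  # keeps universe = 10
    list(gsc = gsc, genes = genes)
}

test_that("hypergeometric p-value matches explicit enumeration", {
    fx <- .enrichFixture()
    # targets: 2 inside h, 1 outside
    er <- enrichDrug(c("g1", "g2", "g5"), fx$gsc)
    expect_equal(enrichmentPvalues(er)[1L, "h"], 40 / 120)
    expect_equal(enrichmentPvalues(er)[1L, "h"],
                 oracleHyper(Q = 10, M = 4, q = 3, F = 2))
})

test_that("boundary cases: no overlap gives 1, set equal to universe gives 1", {
    fx <- .enrichFixture()
    er0 <- enrichDrug(c("g5", "g6"), fx$gsc)        # F = 0 for h
    expect_identical(enrichmentPvalues(er0)[1L, "h"], 1)
    # 'rest' equals the universe: overlap is forced to q, no surprise
    expect_identical(enrichmentPvalues(er0)[1L, "rest"], 1)
})

test_that("p-values are monotone non-increasing in the overlap", {
    for (Q in c(8L, 12L)) {
        genes <- paste0("g", seq_len(Q))
        M <- 5L; q <- 5L
        gsc <- GeneSetCollection(list(h = genes[seq_len(M)], all = genes))
        feasibleF <- seq.int(max(0L, q - (Q - M)), min(M, q))
        ps <- vapply(feasibleF, function(F) {
            tg <- c(genes[seq_len(F)],
                    genes[M + seq_len(q - F)])
            enrichmentPvalues(enrichDrug(tg, gsc))[1L, "h"]
        }, numeric(1L))
        expect_true(all(diff(ps) <= 1e-12))
    }
})

test_that("indicator thresholds raw p-values inclusively", {
    fx <- .enrichFixture()
    er <- enrichDrug(c("g1", "g2", "g5"), fx$gsc)
    p <- enrichmentPvalues(er)[1L, "h"]
    # alpha exactly at the p-value: the tie counts as enriched
    tie <- enrichDrug(c("g1", "g2", "g5"), fx$gsc, alpha = p)
    expect_true(enrichmentIndicator(tie)[1L, "h"])
    below <- enrichDrug(c("g1", "g2", "g5"), fx$gsc, alpha = p * 0.99)
    expect_false(enrichmentIndicator(below)[1L, "h"])
})

test_that("untestable drugs and invalid alpha are rejected", {
    fx <- .enrichFixture()
    expect_error(enrichDrug(c("zz1", "zz2"), fx$gsc), "q = 0")
    expect_error(enrichDrug("g1", fx$gsc, alpha = 0), "alpha")
    expect_error(enrichDrug("g1", fx$gsc, alpha = 1), "alpha")
    ds <- DrugSet(c("a", "b"), targets = list("g1", "zz"))
    expect_message(er <- hallmarkEnrichment(ds, fx$gsc), "dropped")
    expect_equal(drugIds(er), "a")
})

test_that("optional multiple-testing correction adjusts within drug", {
    genes <- paste0("g", 1:20)
    gsc <- GeneSetCollection(list(s1 = genes[1:5], s2 = genes[6:10],
                                  s3 = genes[11:20]))
    tg <- c("g1", "g2", "g6")
    raw <- enrichmentPvalues(enrichDrug(tg, gsc))
    ds <- DrugSet("d", targets = list(tg))
    adj <- enrichmentPvalues(hallmarkEnrichment(ds, gsc,
                                                correction = "BH"))
    expect_equal(adj[1L, ], p.adjust(raw[1L, ], "BH"))
})

test_that("functional similarity follows shared enriched sets", {
    genes <- paste0("g", 1:30)
    gsc <- GeneSetCollection(list(s1 = genes[1:5], s2 = genes[6:10],
                                  s3 = genes[11:15], all = genes))
    pa <- enrichDrug(genes[1:4], gsc)     # enriched in s1
    pb <- enrichDrug(genes[c(1:3, 6:8)], gsc)  # s1 and s2
    pc <- enrichDrug(genes[11:14], gsc)   # s3 only
    pn <- enrichDrug(genes[c(5, 10, 15, 20, 25)], gsc)  # nothing
    expect_equal(functionalSimilarity(pa, pa), 1L)
    expect_equal(functionalSimilarity(pa, pb), 1L)
    expect_equal(functionalSimilarity(pa, pc), 0L)
    # all-zero profile is similar to nobody, itself included
    expect_equal(functionalSimilarity(pn, pn), 0L)
    expect_equal(functionalSimilarity(pa, pn), 0L)
    # symmetric matrix form agrees with the pairwise form
    ds <- DrugSet(c("a", "b", "c"),
                  targets = list(genes[1:4], genes[c(1:3, 6:8)],
                                 genes[11:14]))
    M <- functionalSimilarity(hallmarkEnrichment(ds, gsc))
    expect_identical(M, t(M))
    expect_equal(M["a", "b"], 1L)
    expect_equal(M["a", "c"], 0L)
})

test_that("functional similarity rejects mismatched collections", {
    genes <- paste0("g", 1:10)
    g1 <- GeneSetCollection(list(s1 = genes[1:5], all = genes))
    g2 <- GeneSetCollection(list(sX = genes[1:5], all = genes))
    expect_error(functionalSimilarity(enrichDrug(genes[1:3], g1),
                                      enrichDrug(genes[1:3], g2)),
                 "different gene-set collections")
})

test_that("functional similarity is invariant to gene-set order", {
    genes <- paste0("g", 1:30)
    sets <- list(s1 = genes[1:5], s2 = genes[6:10], s3 = genes[11:30])
    ds <- DrugSet(c("a", "b"),
                  targets = list(genes[1:4], genes[c(2:4, 7)]))
    m1 <- functionalSimilarity(hallmarkEnrichment(
        ds, GeneSetCollection(sets)))
    m2 <- functionalSimilarity(hallmarkEnrichment(
        ds, GeneSetCollection(sets[c(3, 1, 2)])))
    expect_identical(m1, m2)
})
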