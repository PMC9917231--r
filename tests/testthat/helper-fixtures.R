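# Shared fixtures, built once per test session.

.fixtures <- new.env(parent = emptyenv())

# Default synthetic scenario with its similarity layer and unweighted
# transition matrix; several test files reuse it.
defaultFixture <- function() {
    if (is.null(.fixtures$default)) {
        sc <- SyntheticScenario()
        dat <- generateSyntheticData(sc)
        sim <- drugPairSimilarities(dat$drugs, dat$geneSets)
        net <- buildNetwork(sim$pairs, sim$threshold, dat$drugs)
        .fixtures$default <- list(
            scenario = sc, dat = dat, sim = sim, net = net,
            W0 = transitionMatrix(net, unweightedPattern()))
    }
    .fixtures$default
}

# Small drug collection with hand-checkable similarity structure.
tinyDrugs <- function() {
    DrugSet(
        c("DB01", "DB02", "DB03", "DB04", "DB05"),
        targets = list(c("A", "B"), c("B", "C"), c("D", "E"),
                       c("A", "E"), "F"),
        atcCodes = list("L01XE03", c("L01XE03", "N02BA01"), "L01XE07",
                        "N02BA01", character(0)))
}
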