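#' Construct a synthetic scenario
#'
#' Parameters default to a desk-scale study: 150 drugs over 400 genes in
#' 20 gene sets, a 10-drug seed cluster, 4 planted positives carrying 6
#' planted essential genes, and 15 cell lines (two thirds labelled with
#' the scenario cancer). See the class documentation for the meaning of
#' each slot.
#'
#' @param ... slot overrides, e.g. \code{nDrugs = 60}.
#' @return a validated \code{SyntheticScenario}.
#' @export
SyntheticScenario <- function(...) {
    args <- list(...)
    intSlots <- c("nDrugs", "nGenes", "nGeneSets", "atcBranching",
                  "seedClusterSize", "nPlantedPositives",
                  "nPlantedEssentialGenes", "nCellLines", "rngSeed")
    for (nm in intersect(names(args), intSlots))
        args[[nm]] <- as.integer(args[[nm]])
    obj <- do.call(methods::new, c("SyntheticScenario", args))
    methods::validObject(obj)
    obj
}

## Deterministic (RNG-free) layout shared by the generator and
## expectedTruth: identifier spaces, gene-set partition, planted indices,
## ATC tree leaves. The seed cluster is split into two sub-communities
## with distinct planted gene sets and distinct ATC branches; planted
## positives bridge both, so they stay closer to every retained seed
## subset than any removed seed is.
.syntheticLayout <- function(sc) {
    if (sc@nGeneSets < 3L)
        stop("the planted design needs at least 3 gene sets")
    genes <- sprintf("G%04d", seq_len(sc@nGenes))
    setIdx <- sort(rep_len(seq_len(sc@nGeneSets), sc@nGenes))
    sets <- split(genes, setIdx)
    names(sets) <- sprintf("HM_SET_%02d", seq_len(sc@nGeneSets))

    drugIds <- sprintf("SD%04d", seq_len(sc@nDrugs))
    seedIds <- drugIds[seq_len(sc@seedClusterSize)]
    nGroupA <- as.integer(ceiling(sc@seedClusterSize / 2))
    seedGroupA <- seedIds[seq_len(nGroupA)]
    seedGroupB <- setdiff(seedIds, seedGroupA)
    posIds <- drugIds[sc@seedClusterSize + seq_len(sc@nPlantedPositives)]

    essPool <- sets[[3L]]
    if (sc@nPlantedEssentialGenes > length(essPool))
        stop("nPlantedEssentialGenes exceeds the donor gene set size")
    essential <- essPool[seq_len(sc@nPlantedEssentialGenes)]

    b <- sc@atcBranching
    if (b[2L] < 2L)
        stop("the planted design needs at least 2 therapeutic subgroups")
    tree <- expand.grid(
        l5 = sprintf("%02d", seq_len(b[5L])),
        l4 = LETTERS[seq_len(b[4L])],
        l3 = LETTERS[seq_len(b[3L])],
        l2 = sprintf("%02d", seq_len(b[2L])),
        l1 = LETTERS[seq_len(b[1L])],
        stringsAsFactors = FALSE)
    leaves <- paste0(tree$l1, tree$l2, tree$l3, tree$l4, tree$l5)
    ## the two seed branches sit under different level-2 codes, so the
    ## sub-communities are clinically dissimilar and only the planted
    ## positives bridge them; their whole level-3 neighbourhoods are
    ## reserved so background drugs never reach them above SATC = 1/3
    prefixA <- "A01AA"
    prefixB <- "A02AA"
    branchA <- leaves[startsWith(leaves, prefixA)]
    branchB <- leaves[startsWith(leaves, prefixB)]
    backgroundLeaves <- leaves[!startsWith(leaves, "A01A") &
                               !startsWith(leaves, "A02A")]

    cell <- sprintf("CL%03d", seq_len(sc@nCellLines))
    nCancer <- as.integer(ceiling(sc@cancerLineFraction * sc@nCellLines))
    lin <- stats::setNames(
        c(rep(sc@cancer, nCancer), rep("OTHER", sc@nCellLines - nCancer)),
        cell)

    list(genes = genes, sets = sets, drugIds = drugIds, seedIds = seedIds,
         seedGroupA = seedGroupA, seedGroupB = seedGroupB,
         posIds = posIds, essential = essential,
         branchA = branchA, branchB = branchB,
         backgroundLeaves = backgroundLeaves,
         cellLines = cell, lineage = lin, nCancer = nCancer)
}

#' Ground truth of a synthetic scenario
#'
#' The planted positives and planted essential genes, derivable without
#' running the generator (the planted layout is deterministic; only noise
#' draws use the RNG).
#'
#' @param scenario a \code{SyntheticScenario}.
#' @return list with \code{positives}, \code{essentialGenes},
#'   \code{seeds}.
#' @export
expectedTruth <- function(scenario) {
    lay <- .syntheticLayout(scenario)
    list(positives = lay$posIds, essentialGenes = lay$essential,
         seeds = lay$seedIds)
}

#' Generate the synthetic datasets in memory
#'
#' Emits a drug collection, gene-set collection, gene-effect matrix and
#' seed set with planted structure: the seed cluster consists of two
#' sub-communities, each sharing a planted gene set and a level-4 ATC
#' branch (mirroring the partial mutual similarity of real known
#' therapeutics); planted positives bridge both sub-communities under
#' both similarity channels and their targets include the planted
#' essential genes; background drugs draw targets from a random "home"
#' gene set plus Poisson noise targets, and random background ATC codes. Planted essential genes
#' score below -0.5 in a fixed fraction of the cancer's cell lines;
#' background scores are centred at 0 with a scale that makes chance
#' essential calls rare but possible. Deterministic given
#' \code{scenario@rngSeed}; the caller's RNG state is left untouched.
#'
#' @param scenario a \code{SyntheticScenario}.
#' @return list with \code{drugs} (\code{DrugSet}), \code{geneSets}
#'   (\code{GeneSetCollection}), \code{effects}
#'   (\code{GeneEffectMatrix}), \code{seeds} (\code{SeedSet}) and
#'   \code{truth} (as \code{\link{expectedTruth}}).
#' @export
generateSyntheticData <- function(scenario) {
    stopifnot(is(scenario, "SyntheticScenario"))
    methods::validObject(scenario)
    lay <- .syntheticLayout(scenario)

    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(oldSeed)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", oldSeed, envir = globalenv())
    })
    set.seed(scenario@rngSeed)

    setA <- lay$sets[[1L]]
    setB <- lay$sets[[2L]]
    nDrugs <- scenario@nDrugs
    targetsL <- vector("list", nDrugs)
    codesL <- vector("list", nDrugs)
    nSeed <- scenario@seedClusterSize
    nPos <- scenario@nPlantedPositives

    ## seed cluster, two sub-communities: group A targets the first
    ## planted set and sits in ATC branch A, group B the second set and
    ## branch B
    for (i in seq_len(nSeed)) {
        grpA <- lay$drugIds[i] %in% lay$seedGroupA
        home <- if (grpA) setA else setB
        branch <- if (grpA) lay$branchA else lay$branchB
        targetsL[[i]] <- sample(home, min(length(home), sample(4:6, 1L)))
        codesL[[i]] <- branch[(i - 1L) %% length(branch) + 1L]
    }
    ## planted positives bridge both sub-communities: targets in both
    ## planted sets plus their share of the planted essential genes
    ## (round-robin covers all of them), one ATC code in each branch
    for (p in seq_len(nPos)) {
        i <- nSeed + p
        ess <- lay$essential[
            (seq_along(lay$essential) - 1L) %% nPos + 1L == p]
        targetsL[[i]] <- c(sample(setA, min(length(setA), 3L)),
                           sample(setB, min(length(setB), 3L)),
                           ess)
        codesL[[i]] <- c(lay$branchA[(i - 1L) %% length(lay$branchA) + 1L],
                         lay$branchB[(i - 1L) %% length(lay$branchB) + 1L])
    }
    ## background drugs
    for (i in seq.int(nSeed + nPos + 1L, length.out = nDrugs - nSeed - nPos)) {
        home <- lay$sets[[sample(3:scenario@nGeneSets, 1L)]]
        tg <- sample(home, min(length(home), sample(3:7, 1L)))
        nNoise <- stats::rpois(1L, scenario@noiseTargetRate)
        if (nNoise > 0L)
            tg <- union(tg, sample(lay$genes, min(nNoise,
                                                  length(lay$genes))))
        targetsL[[i]] <- tg
        cd <- sample(lay$backgroundLeaves, 1L)
        if (stats::runif(1L) < scenario@noiseCodeProb)
            cd <- union(cd, sample(c(lay$branchA, lay$branchB,
                                     lay$backgroundLeaves), 1L))
        codesL[[i]] <- cd
    }

    drugs <- DrugSet(lay$drugIds,
                     drugName = paste0("Synthetic drug ", lay$drugIds),
                     targets = targetsL, atcCodes = codesL)
    gsc <- GeneSetCollection(lay$sets)

    ## gene effects: background noise, then planted essentiality, then a
    ## missingness mask over non-planted entries only
    m <- matrix(stats::rnorm(scenario@nCellLines * scenario@nGenes,
                             mean = 0, sd = 0.13),
                nrow = scenario@nCellLines,
                dimnames = list(lay$cellLines, lay$genes))
    cancerLines <- names(lay$lineage)[lay$lineage == scenario@cancer]
    nHit <- max(1L, as.integer(ceiling(scenario@essentialFraction *
                                       length(cancerLines))))
    planted <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
    for (g in lay$essential) {
        hit <- sample(cancerLines, nHit)
        m[hit, g] <- -0.55 - abs(stats::rnorm(nHit, 0, 0.2))
        planted[hit, g] <- TRUE
    }
    if (scenario@missingRate > 0) {
        mask <- matrix(stats::runif(length(m)) < scenario@missingRate,
                       nrow(m)) & !planted
        m[mask] <- NA_real_
    }
    effects <- GeneEffectMatrix(m, lay$lineage)

    seeds <- SeedSet(scenario@cancer, lay$seedIds, drugSet = drugs)
    list(drugs = drugs, geneSets = gsc, effects = effects, seeds = seeds,
         truth = list(positives = lay$posIds,
                      essentialGenes = lay$essential,
                      seeds = lay$seedIds))
}

#' Generate a synthetic scenario and write its files
#'
#' Writes the five standard inputs (drug table TSV, GMT, gene-effect CSV,
#' lineage TSV, seed list) into \code{dir}. Byte-identical across runs
#' with the same scenario.
#'
#' @param scenario a \code{SyntheticScenario}.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the file \code{paths}, the in-memory
#'   \code{data} and the planted \code{truth}.
#' @export
generateScenario <- function(scenario, dir) {
    dat <- generateSyntheticData(scenario)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
        drugs = file.path(dir, "drugs.tsv"),
        gmt = file.path(dir, "gene_sets.gmt"),
        effects = file.path(dir, "gene_effects.csv"),
        lineage = file.path(dir, "lineage.tsv"),
        seeds = file.path(dir, "seeds.txt"))
    writeDrugTable(dat$drugs, paths$drugs)
    writeGmt(dat$geneSets, paths$gmt)
    writeGeneEffects(dat$effects, paths$effects, paths$lineage)
    writeSeedList(dat$seeds, paths$seeds)
    invisible(list(paths = paths, data = dat, truth = dat$truth))
}
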