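#' Default pipeline configuration
#'
#' All defaults mirror the standard parameterisation of the method:
#' enrichment alpha 0.05, clinical threshold at the 95th percentile,
#' restart probability 0.7, L1 tolerance 1e-10, top fraction 5%, weight
#' coefficients up to 9 with the 1:1 ratio excluded, 10,000-subset
#' sampling cap, gene-effect essentiality cutoff -0.5.
#'
#' @param alpha enrichment significance level.
#' @param percentile clinical-similarity threshold percentile.
#' @param restart RWR restart probability.
#' @param tol RWR L1 convergence bound.
#' @param topFraction fraction of non-seed drugs kept per ranking.
#' @param maxCoefficient largest weighting coefficient.
#' @param includeEqualWeights keep the 1:1 ratio.
#' @param subsetCap delete-n-out subset sampling cap.
#' @param cutoff gene-effect essentiality cutoff.
#' @param minLines minimum depleting cell lines for a druggable target.
#' @param rngSeed base RNG seed for all stochastic steps.
#' @return a named list of parameters.
#' @export
pipelineConfig <- function(alpha = 0.05, percentile = 95, restart = 0.7,
                           tol = 1e-10, topFraction = 0.05,
                           maxCoefficient = 9, includeEqualWeights = FALSE,
                           subsetCap = 10000L, cutoff = -0.5,
                           minLines = 1L, rngSeed = 1L) {
    list(alpha = alpha, percentile = percentile, restart = restart,
         tol = tol, topFraction = topFraction,
         maxCoefficient = as.integer(maxCoefficient),
         includeEqualWeights = includeEqualWeights,
         subsetCap = as.integer(subsetCap), cutoff = cutoff,
         minLines = as.integer(minLines), rngSeed = as.integer(rngSeed))
}

#' Read a flat YAML pipeline configuration
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file of \code{key: value} pairs.
#' @return as \code{\link{pipelineConfig}}.
#' @export
readPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(pipelineConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    do.call(pipelineConfig, vals)
}

#' Run the full repositioning pipeline
#'
#' Chains every stage: pairwise similarities and the empirical clinical
#' threshold; the union similarity network; leave-one-out recall and the
#' delete-n-out stability screen under the unweighted pattern (fixing the
#' stopping depth); per-pattern delete-n-out at that depth for every
#' weighting pattern; candidate intersection; survival-essential
#' druggable targets; and the final repositionable drugs with their rank
#' report.
#'
#' @param drugs a \code{DrugSet}.
#' @param geneSets a \code{GeneSetCollection}.
#' @param effects a \code{GeneEffectMatrix}.
#' @param seeds a \code{SeedSet} (its cancer label selects cell lines).
#' @param config list from \code{\link{pipelineConfig}}.
#' @param outDir optional directory; when given, stage outputs and a
#'   provenance manifest are written there.
#' @param verbose print stage progress.
#' @return list with \code{result} (a \code{RepositioningResult}),
#'   \code{network}, \code{threshold}, \code{recall} (leave-one-out, with
#'   per-seed hits), \code{stability} (unweighted
#'   \code{StabilityResult}), \code{patternRuns} (per-pattern
#'   \code{StabilityRun}), and \code{patterns}.
#' @export
runPipeline <- function(drugs, geneSets, effects, seeds,
                        config = pipelineConfig(), outDir = NULL,
                        verbose = TRUE) {
    say <- function(...) if (verbose) message(...)
    rwrCfg <- RWRConfig(restart = config$restart, tol = config$tol)

    say("* pairwise similarities")
    sim <- drugPairSimilarities(drugs, geneSets, alpha = config$alpha,
                                percentile = config$percentile)
    say("* building network")
    net <- buildNetwork(sim$pairs, sim$threshold, drugs)
    say(sprintf("  %d nodes, %d edges", length(net),
                nrow(edgeTable(net))))

    W0 <- transitionMatrix(net, unweightedPattern())
    say("* leave-one-out recall (unweighted)")
    recall <- loocvRecall(W0, seeds, config = rwrCfg,
                          topFraction = config$topFraction)
    say(sprintf("  recall = %.3f", recall$recall))

    say("* delete-n-out stability screen (unweighted)")
    stab <- runStability(W0, seeds, config = rwrCfg,
                         rngSeed = config$rngSeed,
                         subsetCap = config$subsetCap,
                         topFraction = config$topFraction,
                         percentile = config$percentile)
    dUnweighted <- stableCandidates(stab)
    say(sprintf("  stop at n = %d; %d stable candidate(s)", stopN(stab),
                length(dUnweighted)))

    patterns <- enumerateWeightPatterns(config$maxCoefficient,
                                        config$includeEqualWeights)
    say(sprintf("* delete-%d-out under %d weighting pattern(s)",
                stopN(stab), length(patterns)))
    patternRuns <- vector("list", length(patterns))
    names(patternRuns) <- vapply(patterns, patternLabel, character(1L))
    for (j in seq_along(patterns)) {
        Wj <- transitionMatrix(net, patterns[[j]])
        patternRuns[[j]] <- fixedNStability(
            Wj, seeds, patterns[[j]], nFixed = stopN(stab),
            config = rwrCfg, rngSeed = config$rngSeed + 1000L + j,
            subsetCap = config$subsetCap,
            topFraction = config$topFraction,
            percentile = config$percentile)
    }
    perPattern <- lapply(patternRuns, candidates)

    say("* candidate intersection and druggability screen")
    inter <- intersectCandidates(dUnweighted, perPattern)
    targ <- druggableTargets(effects, cancer = seeds@cancer,
                             cutoff = config$cutoff,
                             minLines = config$minLines)
    fin <- finalDrugs(inter$dP, drugs, targ$genes)

    allRuns <- c(stab@runs, patternRuns)
    ranks <- rankReport(allRuns, fin$dR)

    support <- targ$support[targ$genes]
    result <- new("RepositioningResult",
                  dUnweighted = dUnweighted,
                  dWeighted = inter$dWeighted,
                  dP = inter$dP,
                  dR = fin$dR,
                  druggableGenes = targ$genes,
                  geneSupport = support,
                  qualifyingTargets = fin$qualifyingTargets,
                  rankTable = ranks)
    out <- list(result = result, network = net,
                threshold = sim$threshold, recall = recall,
                stability = stab, patternRuns = patternRuns,
                patterns = patterns)
    if (!is.null(outDir))
        .writePipelineOutputs(out, drugs, config, outDir)
    out
}

.writePipelineOutputs <- function(out, drugs, config, outDir) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeEdgeList(out$network, file.path(outDir, "network_edges.tsv"))
    res <- out$result
    nm <- drugNames(drugs)
    rt <- res@rankTable
    report <- data.frame(
        drug_id = rt$drug_id,
        name = unname(nm[rt$drug_id]),
        average_rank = rt$average_rank,
        qualifying_targets = .joinMulti(
            res@qualifyingTargets[rt$drug_id]),
        n_supporting_cell_lines = vapply(
            res@qualifyingTargets[rt$drug_id],
            function(g) sum(res@geneSupport[g]), numeric(1L)),
        stringsAsFactors = FALSE)
    utils::write.table(report, file.path(outDir, "final_drugs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
        config = config,
        threshold = thresholdValue(out$threshold),
        loocv_recall = out$recall$recall,
        stop_n = stopN(out$stability),
        n_patterns = length(out$patterns),
        n_stable_unweighted = length(res@dUnweighted),
        n_stable_weighted = length(res@dWeighted),
        n_initial_predicted = length(res@dP),
        n_final = length(res@dR),
        final_drugs = res@dR,
        druggable_targets = res@druggableGenes)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(outDir)
}

#' Run the pipeline from files
#'
#' File-level front end used by the command-line interface: reads the
#' standard inputs and calls \code{\link{runPipeline}}.
#'
#' @param drugPath drug table TSV.
#' @param gmtPath gene-set GMT.
#' @param effectsPath gene-effect CSV.
#' @param lineagePath lineage TSV.
#' @param seedPath seed list (one drug id per line).
#' @param cancer cancer label of the seed set.
#' @param config list from \code{\link{pipelineConfig}}.
#' @param outDir optional output directory.
#' @param verbose print stage progress.
#' @return as \code{\link{runPipeline}}.
#' @export
runPipelineFiles <- function(drugPath, gmtPath, effectsPath, lineagePath,
                             seedPath, cancer,
                             config = pipelineConfig(), outDir = NULL,
                             verbose = TRUE) {
    for (p in c(drugPath, gmtPath, effectsPath, lineagePath, seedPath))
        if (!file.exists(p)) stop("input file not found: ", p)
    drugs <- readDrugTable(drugPath)
    gsc <- readGmt(gmtPath)
    gem <- readGeneEffects(effectsPath, lineagePath)
    seeds <- readSeedList(seedPath, cancer, drugSet = drugs)
    res <- runPipeline(drugs, gsc, gem, seeds, config = config,
                       outDir = outDir, verbose = verbose)
    if (!is.null(outDir)) {
        hashes <- tools::md5sum(c(drugPath, gmtPath, effectsPath,
                                  lineagePath, seedPath))
        jsonlite::write_json(as.list(hashes),
                             file.path(outDir, "input_hashes.json"),
                             auto_unbox = TRUE)
    }
    res
}
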