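#' Pipeline configuration
#'
#' Collects every stage parameter of the analysis with the study's
#' defaults: 1e-5 noise floor, 250000 mapped-read minimum, 90% prevalence,
#' five-replicate cap, 100 classifier runs, 0.05 significance level,
#' twofold rule, and StARS/bootstrap settings (r = 50, f = 0.8). The
#' configuration round-trips losslessly through JSON
#' ([writePipelineConfig()] / [readPipelineConfig()]).
#'
#' @param caseGroup case label.
#' @param controlGroups control labels.
#' @param cohortSpec optional [cohortSpec()] for synthetic input.
#' @param inputPath optional TSV path (see [readTaxaMatrix()]) for real
#'   input; exactly one of `cohortSpec`/`inputPath` must be given.
#' @param stages stages to run, a subset of `"diversity"`, `"signature"`,
#'   `"da"`, `"network"`, `"functional"`.
#' @param rfcMerge optional named character vector merging group labels
#'   for the classification stage only (e.g. pooling external healthy
#'   cohorts under one label).
#' @param noiseFloor,minReads,prevalence,replicateCap stage thresholds,
#'   see the abundance and composition module documentation.
#' @param rfcRuns,rfcTrees,alpha,foldThresh classification and testing
#'   parameters, see [importanceRuns()] and [consensusDa()].
#' @param stars list of StARS settings (`nSubsamples`, `beta`,
#'   `subsampleSize` or NULL for the default).
#' @param bootstrap list with `r` and `f`.
#' @param familyCounts,roleMap optional functional-annotation inputs
#'   ([generateFamilyCounts()] layout); simulated when absent and the
#'   functional stage is enabled.
#' @param seed master seed; per-stage seeds are derived as fixed offsets
#'   from it.
#' @return object of class `PipelineConfig`.
#' @export
pipelineConfig <- function(caseGroup, controlGroups, cohortSpec = NULL,
                           inputPath = NULL,
                           stages = c("diversity", "signature", "da",
                                      "network", "functional"),
                           rfcMerge = NULL, noiseFloor = 1e-5,
                           minReads = 250000, prevalence = 0.90,
                           replicateCap = 5, rfcRuns = 100,
                           rfcTrees = 500, alpha = 0.05, foldThresh = 2,
                           stars = list(nSubsamples = 20, beta = 0.1,
                                        subsampleSize = NULL),
                           bootstrap = list(r = 50, f = 0.8),
                           familyCounts = NULL, roleMap = NULL,
                           seed = 1L) {
    stopifnot(xor(is.null(cohortSpec), is.null(inputPath)),
              noiseFloor >= 0, minReads >= 0,
              prevalence > 0, prevalence <= 1, replicateCap >= 1,
              rfcRuns >= 2, alpha > 0, alpha < 1, foldThresh >= 1,
              bootstrap$r >= 1, bootstrap$f >= 0, bootstrap$f <= 1,
              all(stages %in% c("diversity", "signature", "da", "network",
                                "functional")))
    structure(list(caseGroup = caseGroup, controlGroups = controlGroups,
                   cohortSpec = cohortSpec, inputPath = inputPath,
                   stages = stages, rfcMerge = rfcMerge,
                   noiseFloor = noiseFloor, minReads = minReads,
                   prevalence = prevalence, replicateCap = replicateCap,
                   rfcRuns = rfcRuns, rfcTrees = rfcTrees, alpha = alpha,
                   foldThresh = foldThresh, stars = stars,
                   bootstrap = bootstrap, familyCounts = familyCounts,
                   roleMap = roleMap, seed = as.integer(seed)),
              class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param config a `PipelineConfig`.
#' @param path JSON file path.
#' @export
writePipelineConfig <- function(config, path) {
    x <- unclass(config)
    x$cohortSpec <- if (!is.null(x$cohortSpec)) unclass(x$cohortSpec)
    if (!is.null(x$familyCounts))
        x$familyCounts <- list(species = rownames(x$familyCounts),
                               families = colnames(x$familyCounts),
                               values = as.vector(x$familyCounts))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    cs <- NULL
    if (!is.null(x$cohortSpec)) {
        y <- x$cohortSpec
        groups <- lapply(y$groups, function(g)
            list(nSubjects = g$nSubjects, repProbs = unlist(g$repProbs)))
        cs <- cohortSpec(groups = groups, D = y$D, sparsity = y$sparsity,
                         daSpec = if (!is.null(y$daSpec))
                             as.data.frame(y$daSpec),
                         noiseFloor = y$noiseFloor,
                         subjectSd = y$subjectSd,
                         baseMeanSd = y$baseMeanSd,
                         ageRanges = if (length(y$ageRanges))
                             lapply(y$ageRanges, unlist),
                         sexProb = if (length(y$sexProb))
                             unlist(y$sexProb),
                         seed = y$seed)
    }
    fc <- NULL
    if (!is.null(x$familyCounts))
        fc <- matrix(x$familyCounts$values,
                     nrow = length(x$familyCounts$species),
                     dimnames = list(x$familyCounts$species,
                                     x$familyCounts$families))
    stars <- x$stars
    if (is.null(stars$subsampleSize)) stars["subsampleSize"] <- list(NULL)
    pipelineConfig(caseGroup = x$caseGroup,
                   controlGroups = unlist(x$controlGroups),
                   cohortSpec = cs, inputPath = x$inputPath,
                   stages = unlist(x$stages),
                   rfcMerge = if (!is.null(x$rfcMerge)) unlist(x$rfcMerge),
                   noiseFloor = x$noiseFloor, minReads = x$minReads,
                   prevalence = x$prevalence,
                   replicateCap = x$replicateCap, rfcRuns = x$rfcRuns,
                   rfcTrees = x$rfcTrees, alpha = x$alpha,
                   foldThresh = x$foldThresh, stars = stars,
                   bootstrap = x$bootstrap, familyCounts = fc,
                   roleMap = if (!is.null(x$roleMap))
                       as.data.frame(x$roleMap),
                   seed = x$seed)
}

.tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation or loading, replicate capping,
#' prevalence filtering (with re-closure), CLR transformation, diversity
#' and dissimilarity profiling, signature-species selection with
#' classifier evaluation, multi-control consensus differential abundance,
#' per-group association networks with centrality and cross-network
#' comparison, and functional-capacity comparison. All stage outputs are
#' written as TSV/JSON under `outDir` together with a provenance manifest
#' (parameters, derived seeds, package version; no timestamps, so a fixed
#' seed reproduces the bundle byte for byte).
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if missing).
#' @return invisible list with the in-memory stage results.
#' @export
runPipeline <- function(config, outDir) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seeds <- list(cap = config$seed + 1L, rfc = config$seed + 2L,
                  split = config$seed + 3L, stars = config$seed + 4L,
                  boot = config$seed + 5L, fam = config$seed + 6L)
    res <- list(config = config, seeds = seeds)

    if (!is.null(config$cohortSpec)) {
        gen <- generateCohort(config$cohortSpec)
        me <- gen$experiment
        res$truth <- gen$truth
        jsonlite::write_json(
            list(daSpecies = gen$truth@daSpecies,
                 nTrueEdges = sum(gen$truth@precisionSupport) / 2,
                 seed = gen$truth@seed),
            file.path(outDir, "truth.json"),
            auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
        me <- readTaxaMatrix(config$inputPath)
    }

    me <- capReplicates(me, config$replicateCap, seed = seeds$cap)
    prevalent <- prevalenceFilter(me, config$prevalence)
    if (length(prevalent) < 5)
        stop("fewer than 5 species pass the prevalence filter")
    writeTaxaMatrix(me, file.path(outDir, "abundance_full.tsv"))
    me <- subsetSpecies(me, prevalent)
    me <- clrTransform(me)
    res$experiment <- me
    writeTaxaMatrix(me, file.path(outDir, "abundance_prevalent.tsv"))
    .tsv(data.frame(sample = colnames(me), t(clrValues(me)),
                    check.names = FALSE),
         file.path(outDir, "clr.tsv"))

    if ("diversity" %in% config$stages) {
        h <- shannonEntropy(me)
        .tsv(data.frame(sample = colnames(me), group = groupLabels(me),
                        shannon = as.numeric(h)),
             file.path(outDir, "diversity.tsv"))
        dp <- dissimilarityProfiles(me)
        res$dissimilarity <- dp
        qs <- do.call(rbind, lapply(names(dp$profiles), function(g) {
            pr <- dp$profiles[[g]]
            data.frame(group = g,
                       type = c("intra", "inter"),
                       n = c(length(pr$intra), length(pr$inter)),
                       median = c(stats::median(pr$intra),
                                  stats::median(pr$inter)),
                       q25 = c(stats::quantile(pr$intra, 0.25,
                                               names = FALSE),
                               stats::quantile(pr$inter, 0.25,
                                               names = FALSE)),
                       q75 = c(stats::quantile(pr$intra, 0.75,
                                               names = FALSE),
                               stats::quantile(pr$inter, 0.75,
                                               names = FALSE)))
        }))
        .tsv(qs, file.path(outDir, "dissimilarity_summary.tsv"))
        .tsv(dp$tests, file.path(outDir, "dissimilarity_tests.tsv"))
    }

    signatureSpecies <- prevalent
    if ("signature" %in% config$stages) {
        ft <- buildFeatureTable(me, mergeGroups = config$rfcMerge)
        imp <- importanceRuns(ft$features, ft$labels, R = config$rfcRuns,
                              seed = seeds$rfc,
                              numTrees = config$rfcTrees,
                              noisePool = clrValues(me))
        sig <- significantFeatures(imp, alpha = config$alpha)
        res$signature <- sig
        .tsv(sig, file.path(outDir, "signature.tsv"))
        signatureSpecies <- intersect(sig$feature[sig$selected],
                                      rownames(me))
        ev <- evaluateClassifier(ft$features, ft$labels,
                                 seed = seeds$split,
                                 numTrees = config$rfcTrees)
        res$classifier <- ev
        .tsv(data.frame(class = names(ev$f1PerClass),
                        f1 = as.numeric(ev$f1PerClass),
                        weightedF1 = ev$weightedF1),
             file.path(outDir, "classifier_f1.tsv"))
        .tsv(as.data.frame(ev$confusion),
             file.path(outDir, "classifier_confusion.tsv"))
    }

    daLabels <- NULL
    if ("da" %in% config$stages) {
        da <- consensusDa(me, config$caseGroup, config$controlGroups,
                          qThresh = config$alpha,
                          foldThresh = config$foldThresh)
        res$da <- da
        .tsv(da$perComparison, file.path(outDir, "da_per_comparison.tsv"))
        .tsv(da$consensus, file.path(outDir, "da_consensus.tsv"))
        daLabels <- stats::setNames(rep("ns", nrow(me)), rownames(me))
        daLabels[da$consensus$species] <- da$consensus$direction
    }

    if ("network" %in% config$stages) {
        netSpecies <- if (length(signatureSpecies) >= 5) signatureSpecies
                      else prevalent
        nets <- list()
        groups <- unique(groupLabels(me))
        for (i in seq_along(groups)) {
            g <- groups[i]
            sub <- me[, groupLabels(me) == g]
            xg <- t(clrValues(sub)[netSpecies, , drop = FALSE])
            sel <- starsSelect(xg, nSubsamples = config$stars$nSubsamples,
                               subsampleSize = config$stars$subsampleSize,
                               beta = config$stars$beta,
                               seed = seeds$stars + i)
            om <- bootstrapStabilize(xg, sel$lambda,
                                     r = config$bootstrap$r,
                                     f = config$bootstrap$f,
                                     seed = seeds$boot + i)
            net <- buildNetwork(om)
            nets[[g]] <- net
            writeNetwork(net,
                         file.path(outDir,
                                   sprintf("network_%s_edges.tsv", g)),
                         file.path(outDir,
                                   sprintf("network_%s.graphml", g)))
            ev <- if (nrow(edgeTable(net)))
                eigenvectorCentrality(net)
            else stats::setNames(numeric(length(netSpecies)), netSpecies)
            .tsv(data.frame(species = netSpecies,
                            degree = as.integer(nodeDegrees(net)),
                            evc = as.numeric(ev[netSpecies]),
                            da = if (is.null(daLabels)) NA_character_
                                 else daLabels[netSpecies]),
                 file.path(outDir, sprintf("network_%s_nodes.tsv", g)))
        }
        res$networks <- nets
        cmp <- list()
        for (g in setdiff(groups, config$caseGroup))
            cmp[[g]] <- compareNetworks(nets[[config$caseGroup]],
                                        nets[[g]], daLabels = daLabels)
        res$networkComparison <- cmp
        jsonlite::write_json(
            lapply(cmp, function(z)
                list(nUniqueCase = length(z$uniqueA),
                     nUniqueOther = length(z$uniqueB),
                     nShared = length(z$shared),
                     topOverlap = z$topOverlap)),
            file.path(outDir, "network_comparison.json"),
            auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    if ("functional" %in% config$stages) {
        if (is.null(config$familyCounts)) {
            fam <- generateFamilyCounts(rownames(relAbundance(me)),
                                        seed = seeds$fam)
            counts <- fam$counts; roleMap <- fam$roleMap
        } else {
            counts <- config$familyCounts; roleMap <- config$roleMap
        }
        prof <- weightFamilyProfile(me, counts,
                                    prevalentSpecies = prevalent)
        fda <- familyDa(prof, config$caseGroup, config$controlGroups,
                        qThresh = config$alpha,
                        foldThresh = config$foldThresh)
        res$functional <- fda
        .tsv(fda$perComparison, file.path(outDir, "functional_da.tsv"))
        .tsv(aggregateRoles(fda, roleMap),
             file.path(outDir, "functional_roles.tsv"))
    }

    manifest <- list(
        package = "miCompass",
        version = as.character(utils::packageVersion("miCompass")),
        seed = config$seed, stageSeeds = seeds, stages = config$stages,
        parameters = list(noiseFloor = config$noiseFloor,
                          minReads = config$minReads,
                          prevalence = config$prevalence,
                          replicateCap = config$replicateCap,
                          rfcRuns = config$rfcRuns,
                          alpha = config$alpha,
                          foldThresh = config$foldThresh,
                          stars = config$stars,
                          bootstrap = config$bootstrap),
        caseGroup = config$caseGroup,
        controlGroups = config$controlGroups,
        nSamples = ncol(me), nPrevalentSpecies = length(prevalent),
        nSignatureSpecies = length(signatureSpecies))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(res)
}
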