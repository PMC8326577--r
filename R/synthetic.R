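#' Sample a sparse, positive-definite precision matrix
#'
#' Draws the ground-truth precision matrix of a latent Gaussian graphical
#' model. Off-diagonal support is either supplied or drawn edge-wise with
#' probability `sparsity`; nonzero entries get magnitudes uniform in
#' \[0.1, 0.4\] with random sign, and the diagonal is raised until the
#' smallest eigenvalue is at least 0.05, which guarantees invertibility.
#'
#' @param D number of species (>= 2).
#' @param sparsity expected fraction of nonzero off-diagonal pairs, in (0,1).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param support optional symmetric binary matrix forcing the support.
#' @return list with `precision` (D x D), `support` (binary, zero diagonal)
#'   and `signs` (sign of the true partial correlation per edge).
#' @examples
#' pm <- samplePrecisionMatrix(10, 0.1, seed = 1)
#' min(eigen(pm$precision)$values) > 0
#' @export
samplePrecisionMatrix <- function(D, sparsity, seed = NULL, support = NULL) {
    stopifnot(D >= 2)
    if (!is.null(seed)) set.seed(seed)
    if (is.null(support)) {
        stopifnot(sparsity > 0, sparsity < 1)
        support <- matrix(0L, D, D)
        up <- upper.tri(support)
        support[up] <- as.integer(stats::runif(sum(up)) < sparsity)
        support <- support + t(support)
    } else {
        stopifnot(nrow(support) == D, isTRUE(all.equal(support, t(support))))
        support <- (support != 0) * 1L
        diag(support) <- 0L
    }
    vals <- matrix(0, D, D)
    up <- upper.tri(vals)
    nup <- sum(support[up])
    if (nup > 0) {
        v <- stats::runif(nup, 0.1, 0.4) *
            sample(c(-1, 1), nup, replace = TRUE)
        vals[up][support[up] == 1] <- v
    }
    omega <- vals + t(vals)
    diag(omega) <- 1
    ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < 0.05) diag(omega) <- diag(omega) + (0.05 - ev)
    signs <- -sign(omega) * support
    diag(signs) <- 0
    list(precision = omega, support = support, signs = signs)
}

#' Specify a synthetic cohort
#'
#' Collects the design of a simulated multi-group study: group sizes,
#' per-subject replicate-count distributions (1 to 5 replicates, mirroring
#' a five-sample-per-subject cap), the latent association structure, and
#' any planted group effects.
#'
#' @param groups named list; each element is `list(nSubjects =, repProbs =)`
#'   where `repProbs` is a probability vector over 1..5 replicates.
#' @param D number of species (>= 5).
#' @param sparsity expected true-edge density of the latent precision
#'   matrix, in (0,1).
#' @param daSpec optional data.frame with columns `species` (index or name),
#'   `group`, `log2fc`; each row plants a group effect of `log2fc` log2
#'   units on one species. Planted effects must be at least one log2 unit
#'   (twofold) in magnitude.
#' @param noiseFloor relative abundances strictly below this are zeroed and
#'   the sample re-closed; the default matches the 1e-5 profiling floor.
#' @param subjectSd standard deviation of the per-subject random intercept
#'   shared by all replicates of a subject (log-abundance units).
#' @param baseMeanSd standard deviation of the per-species baseline latent
#'   means, controlling abundance unevenness.
#' @param ageRanges named list of `c(min, max)` ages per group.
#' @param sexProb named numeric, probability of "female" per group.
#' @param seed integer master seed for the cohort.
#' @return object of class `CohortSpec`.
#' @seealso [generateCohort()], [defaultCohortSpec()]
#' @export
cohortSpec <- function(groups, D = 50, sparsity = 0.08, daSpec = NULL,
                       noiseFloor = 1e-5, subjectSd = 0.5, baseMeanSd = 1,
                       ageRanges = NULL, sexProb = NULL, seed = 1L) {
    stopifnot(length(groups) >= 1, !is.null(names(groups)), D >= 5,
              sparsity > 0, sparsity < 1, noiseFloor >= 0, subjectSd >= 0)
    for (g in groups) {
        stopifnot(g$nSubjects >= 1, length(g$repProbs) == 5,
                  all(g$repProbs >= 0),
                  abs(sum(g$repProbs) - 1) < 1e-8)
    }
    if (!is.null(daSpec)) {
        stopifnot(all(c("species", "group", "log2fc") %in% colnames(daSpec)))
        if (any(abs(daSpec$log2fc) < 1))
            stop("planted effects must be at least one log2 unit (twofold)")
        if (!all(daSpec$group %in% names(groups)))
            stop("daSpec references an unknown group")
    }
    structure(list(groups = groups, D = D, sparsity = sparsity,
                   daSpec = daSpec, noiseFloor = noiseFloor,
                   subjectSd = subjectSd, baseMeanSd = baseMeanSd,
                   ageRanges = ageRanges, sexProb = sexProb,
                   seed = as.integer(seed)),
              class = "CohortSpec")
}

#' Default cohort design
#'
#' A desk-scale analogue of a multi-cohort IBD study: one case group with
#' replicate sampling (mean ~2.5 replicates per subject), one internal
#' control, one replicate-free external control and one external control
#' with denser replicate sampling (mean ~3.3), with group-specific age
#' ranges and sex balance.
#'
#' @param seed master seed.
#' @param D number of species.
#' @param daSpec optional planted effects, see [cohortSpec()].
#' @return a `CohortSpec`.
#' @export
defaultCohortSpec <- function(seed = 1L, D = 50, daSpec = NULL) {
    cohortSpec(
        groups = list(
            IBD = list(nSubjects = 40,
                       repProbs = c(0.25, 0.30, 0.20, 0.15, 0.10)),
            nonIBD = list(nSubjects = 25,
                          repProbs = c(0.25, 0.30, 0.20, 0.15, 0.10)),
            Healthy1 = list(nSubjects = 60, repProbs = c(1, 0, 0, 0, 0)),
            Healthy2 = list(nSubjects = 20,
                            repProbs = c(0.05, 0.15, 0.35, 0.35, 0.10))),
        D = D, sparsity = 0.08, daSpec = daSpec,
        ageRanges = list(IBD = c(6, 40), nonIBD = c(18, 60),
                         Healthy1 = c(18, 40), Healthy2 = c(18, 65)),
        sexProb = c(IBD = 0.5, nonIBD = 0.5, Healthy1 = 0.5,
                    Healthy2 = 0.65),
        seed = seed)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Latent log absolute abundances are multivariate Gaussian with the
#' sampled sparse precision matrix; planted effects shift designated
#' species' group means; a per-subject Gaussian intercept is shared across
#' a subject's replicates (making within-subject samples more similar than
#' between-subject ones); abundances are exponentiated, closed to relative
#' abundances, noise-floored and re-closed. Fully deterministic under the
#' spec's seed.
#'
#' @param spec a [cohortSpec()].
#' @return list with `experiment` (a [MicrobiomeExperiment-class] with age
#'   and sex metadata) and `truth` (a [SyntheticTruth-class]).
#' @examples
#' cs <- cohortSpec(list(a = list(nSubjects = 5, repProbs = c(1, 0, 0, 0, 0)),
#'                       b = list(nSubjects = 5, repProbs = c(1, 0, 0, 0, 0))),
#'                  D = 10, seed = 7)
#' gc <- generateCohort(cs)
#' colSums(relAbundance(gc$experiment))
#' @export
generateCohort <- function(spec) {
    stopifnot(inherits(spec, "CohortSpec"))
    set.seed(spec$seed)
    D <- spec$D
    species <- sprintf("sp%03d", seq_len(D))
    pm <- samplePrecisionMatrix(D, spec$sparsity)
    sigma <- solve(pm$precision)
    mu0 <- stats::rnorm(D, 0, spec$baseMeanSd)

    gnames <- names(spec$groups)
    groupMeans <- matrix(mu0, D, length(gnames),
                         dimnames = list(species, gnames))
    daDf <- data.frame(species = character(), group = character(),
                       log2fc = numeric(), direction = character(),
                       stringsAsFactors = FALSE)
    if (!is.null(spec$daSpec)) {
        ds <- spec$daSpec
        sp <- if (is.numeric(ds$species)) species[ds$species]
              else as.character(ds$species)
        if (any(is.na(sp)) || !all(sp %in% species))
            stop("daSpec references an unknown species")
        for (i in seq_len(nrow(ds)))
            groupMeans[sp[i], ds$group[i]] <-
                groupMeans[sp[i], ds$group[i]] + log(2) * ds$log2fc[i]
        daDf <- data.frame(species = sp, group = as.character(ds$group),
                           log2fc = ds$log2fc,
                           direction = ifelse(ds$log2fc > 0, "elevated",
                                              "depleted"),
                           stringsAsFactors = FALSE)
    }

    grp <- character(); reps <- integer()
    for (g in gnames) {
        ns <- spec$groups[[g]]$nSubjects
        r <- sample(1:5, ns, replace = TRUE,
                    prob = spec$groups[[g]]$repProbs)
        grp <- c(grp, rep(g, ns)); reps <- c(reps, r)
    }
    # subject ids are numbered in a shuffled global order: real study ids
    # carry no diagnosis information, so their lexicographic label codes
    # must not be contiguous by group either
    subj <- sprintf("subj%04d", sample(length(grp)))
    n <- sum(reps)
    sampleSubj <- rep(subj, reps)
    sampleGrp <- rep(grp, reps)
    repIdx <- unlist(lapply(reps, seq_len))
    sampleIds <- sprintf("%s_r%d", sampleSubj, repIdx)

    intercepts <- matrix(stats::rnorm(length(subj) * D, 0, spec$subjectSd),
                         nrow = length(subj))
    rownames(intercepts) <- subj
    eps <- MASS::mvrnorm(n, mu = rep(0, D), Sigma = sigma)
    z <- t(groupMeans)[sampleGrp, , drop = FALSE] +
        intercepts[sampleSubj, , drop = FALSE] + eps
    a <- exp(z)
    rel <- a / rowSums(a)
    rel[rel < spec$noiseFloor] <- 0
    if (any(rowSums(rel) == 0)) stop("a sample lost all species to the floor")
    rel <- rel / rowSums(rel)
    abund <- t(rel)
    dimnames(abund) <- list(species, sampleIds)

    age <- sex <- NULL
    if (!is.null(spec$ageRanges)) {
        ar <- spec$ageRanges
        subjAge <- vapply(seq_along(subj), function(i) {
            r <- ar[[grp[i]]]
            round(stats::runif(1, r[1], r[2]))
        }, numeric(1))
        names(subjAge) <- subj
        age <- subjAge[sampleSubj]
    }
    if (!is.null(spec$sexProb)) {
        subjSex <- ifelse(stats::runif(length(subj)) <
                          spec$sexProb[grp], "female", "male")
        names(subjSex) <- subj
        sex <- subjSex[sampleSubj]
    }

    me <- MicrobiomeExperiment(abund, subject = sampleSubj,
                               group = sampleGrp, age = age, sex = sex)
    truth <- new("SyntheticTruth", precision = pm$precision,
                 precisionSupport = pm$support, edgeSigns = pm$signs,
                 daSpecies = daDf, groupMeans = groupMeans,
                 genomeProportions = numeric(0), seed = spec$seed)
    list(experiment = me, truth = truth)
}

#' Simulate a read-compatibility table
#'
#' Assigns each read a true source genome from the mixture proportions;
#' with probability `ambiguity` a read is additionally compatible with one
#' other genome chosen uniformly (so with two genomes, an ambiguous read is
#' compatible with both). Stands in for a multi-mapping short-read
#' alignment against a reference genome collection.
#'
#' @param proportions named numeric mixture proportions, summing to 1.
#' @param nReads number of mapped reads to simulate (>= 1).
#' @param ambiguity fraction of multi-mapping reads, in \[0,1\].
#' @param seed optional integer seed.
#' @return data.frame with columns `read` and `genomes` (comma-separated
#'   compatible genome ids); attributes `truth` (the proportions) and
#'   `sourceCounts` (reads per true source genome).
#' @export
generateReadCompatibility <- function(proportions, nReads, ambiguity = 0,
                                      seed = NULL) {
    stopifnot(abs(sum(proportions) - 1) < 1e-8, nReads >= 1,
              ambiguity >= 0, ambiguity <= 1, length(proportions) >= 1)
    if (!is.null(seed)) set.seed(seed)
    gn <- names(proportions)
    if (is.null(gn)) gn <- sprintf("g%d", seq_along(proportions))
    K <- length(gn)
    src <- sample.int(K, nReads, replace = TRUE, prob = proportions)
    genomes <- gn[src]
    if (K > 1 && ambiguity > 0) {
        amb <- stats::runif(nReads) < ambiguity
        extraOff <- sample.int(K - 1, sum(amb), replace = TRUE)
        extra <- ((src[amb] - 1 + extraOff) %% K) + 1
        genomes[amb] <- paste(gn[pmin(src[amb], extra)],
                              gn[pmax(src[amb], extra)], sep = ",")
    }
    out <- data.frame(read = sprintf("r%06d", seq_len(nReads)),
                      genomes = genomes, stringsAsFactors = FALSE)
    attr(out, "truth") <- stats::setNames(as.numeric(proportions), gn)
    attr(out, "sourceCounts") <- table(factor(gn[src], levels = gn))
    out
}

#' Simulate per-genome protein-family count tables
#'
#' Generates nonnegative integer family counts per species genome, a
#' family-to-role map, and optional planted enrichments: rows of
#' `plantedRoles` add `boost` extra copies of a family to a species so that
#' role-level shifts emerge downstream when that species is abundant.
#'
#' @param species character vector of species/genome ids.
#' @param nFamilies number of protein families (>= nRoles).
#' @param nRoles number of functional roles families are grouped into.
#' @param plantedRoles optional data.frame with columns `species`, `family`,
#'   `boost`.
#' @param seed optional integer seed.
#' @param baseLambda Poisson mean of the background counts.
#' @return list with `counts` (species x families integer matrix) and
#'   `roleMap` (data.frame family, role).
#' @export
generateFamilyCounts <- function(species, nFamilies = 40, nRoles = 8,
                                 plantedRoles = NULL, seed = NULL,
                                 baseLambda = 5) {
    stopifnot(nFamilies >= nRoles, nRoles >= 1)
    if (!is.null(seed)) set.seed(seed)
    fams <- sprintf("fam%03d", seq_len(nFamilies))
    roles <- sprintf("role%02d", rep_len(seq_len(nRoles), nFamilies))
    counts <- matrix(stats::rpois(length(species) * nFamilies, baseLambda),
                     nrow = length(species),
                     dimnames = list(species, fams))
    if (!is.null(plantedRoles)) {
        stopifnot(all(c("species", "family", "boost") %in%
                      colnames(plantedRoles)))
        if (!all(plantedRoles$family %in% fams))
            stop("plantedRoles references an unknown family")
        if (!all(plantedRoles$species %in% species))
            stop("plantedRoles references an unknown species")
        for (i in seq_len(nrow(plantedRoles)))
            counts[plantedRoles$species[i], plantedRoles$family[i]] <-
                counts[plantedRoles$species[i], plantedRoles$family[i]] +
                as.integer(plantedRoles$boost[i])
    }
    list(counts = counts,
         roleMap = data.frame(family = fams, role = roles,
                              stringsAsFactors = FALSE))
}
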