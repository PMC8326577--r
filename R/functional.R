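#' Abundance-weighted protein-family profiles
#'
#' Builds per-sample functional-capacity profiles from per-genome
#' protein-family counts: the abundance of family \eqn{f} in a sample is
#' \eqn{\sum_s a_s \cdot count(s, f)} over the prevalent species, with
#' \eqn{a_s} the species' relative abundance. Profiles are closed to sum
#' to 1 per sample and CLR-transformed across families. Weighting by the
#' CLR values themselves is available for comparison but is ill-posed
#' (CLR values of sub-geometric-mean species are negative), so plain
#' relative abundances are the default weights.
#'
#' @param x a [MicrobiomeExperiment-class].
#' @param counts species x families count matrix, e.g. from
#'   [generateFamilyCounts()].
#' @param prevalentSpecies species used for annotation (typically
#'   [prevalenceFilter()] output); all must have a count row.
#' @param weights `"relabund"` (default) or `"clr"`.
#' @param zeroPolicy,pseudo passed to [clrTransform()].
#' @return a [MicrobiomeExperiment-class] whose rows are protein families
#'   (assays `"relabund"` and `"clr"`), carrying the sample metadata of
#'   `x`.
#' @export
weightFamilyProfile <- function(x, counts, prevalentSpecies,
                                weights = c("relabund", "clr"),
                                zeroPolicy = "multiplicative",
                                pseudo = 5e-6) {
    weights <- match.arg(weights)
    stopifnot(all(prevalentSpecies %in% rownames(relAbundance(x))))
    if (!all(prevalentSpecies %in% rownames(counts)))
        stop("species without an annotation row: ",
             paste(setdiff(prevalentSpecies, rownames(counts)),
                   collapse = ", "))
    w <- if (weights == "relabund")
        relAbundance(x)[prevalentSpecies, , drop = FALSE]
    else clrValues(x)[prevalentSpecies, , drop = FALSE]
    prof <- t(counts[prevalentSpecies, , drop = FALSE]) %*% w
    tot <- colSums(prof)
    if (any(tot <= 0))
        stop("a sample has non-positive total family abundance")
    prof <- sweep(prof, 2, tot, "/")
    cd <- colData(x)
    fe <- MicrobiomeExperiment(prof, subject = cd$subject,
                               group = cd$group)
    clrTransform(fe, zeroPolicy = zeroPolicy, pseudo = pseudo)
}

#' Consensus differential abundance of protein families
#'
#' Applies the species-level consensus machinery ([consensusDa()]) to the
#' family profiles: Mann-Whitney on CLR-transformed family abundances per
#' case-vs-control comparison, Benjamini-Hochberg within each comparison,
#' and the twofold consensus rule across every control group.
#'
#' @param profiles family-level experiment from [weightFamilyProfile()].
#' @inheritParams consensusDa
#' @return a `DaResult` over families.
#' @export
familyDa <- function(profiles, caseGroup, controlGroups, qThresh = 0.05,
                     foldThresh = 2) {
    consensusDa(profiles, caseGroup, controlGroups, qThresh = qThresh,
                foldThresh = foldThresh)
}

#' Role-level summary of differentially abundant families
#'
#' Groups the consensus-DA families by their functional role, reporting
#' direction and member families per role.
#'
#' @param da a `DaResult` over families (from [familyDa()]).
#' @param roleMap data.frame with columns `family`, `role`.
#' @return data.frame with `role`, `direction`, `nFamilies`, `families`.
#' @export
aggregateRoles <- function(da, roleMap) {
    cons <- da$consensus
    if (!nrow(cons))
        return(data.frame(role = character(), direction = character(),
                          nFamilies = integer(), families = character(),
                          stringsAsFactors = FALSE))
    if (!all(cons$species %in% roleMap$family))
        stop("a differentially abundant family has no role")
    cons$role <- roleMap$role[match(cons$species, roleMap$family)]
    out <- do.call(rbind, lapply(
        split(cons, list(cons$role, cons$direction), drop = TRUE),
        function(d) data.frame(role = d$role[1], direction = d$direction[1],
                               nFamilies = nrow(d),
                               families = paste(sort(d$species),
                                                collapse = ","),
                               stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out[order(out$role, out$direction), , drop = FALSE]
}

#' Role-level abundance sums
#'
#' Sums family relative abundances by role; roles partition the families,
#' so the role sums conserve each sample's total.
#'
#' @param profiles family-level experiment from [weightFamilyProfile()].
#' @param roleMap data.frame with columns `family`, `role`.
#' @return roles x samples matrix.
#' @export
roleAbundance <- function(profiles, roleMap) {
    ab <- relAbundance(profiles)
    stopifnot(all(rownames(ab) %in% roleMap$family))
    role <- roleMap$role[match(rownames(ab), roleMap$family)]
    rowsum(ab, role)
}
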