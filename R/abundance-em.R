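#' EM estimation of genome mixture proportions from read compatibilities
#'
#' Reads that map to several reference genomes are soft-assigned with an
#' expectation-maximisation algorithm for the multinomial mixture
#' \eqn{\prod_{reads} \sum_{g\ compatible} \pi_g w_{rg}}. The E-step computes
#' per-read responsibilities proportional to \eqn{\pi_g w_{rg}} over the
#' read's compatible set; the M-step sets \eqn{\pi} to the mean
#' responsibility. Reads with identical compatibility sets are collapsed
#' into patterns, so runtime scales with the number of distinct sets, not
#' with read count. Alignment weights default to uniform over a read's
#' compatible set.
#'
#' @param table data.frame with columns `read` and `genomes`
#'   (comma-separated genome ids), e.g. from
#'   [generateReadCompatibility()] or [readCompatibilityTable()].
#' @param tol convergence threshold on the maximum absolute change of any
#'   proportion between iterations.
#' @param maxIter iteration cap.
#' @param genomes optional genome universe; defaults to the ids observed.
#' @return object of class `AbundanceEstimate`: list with `proportions`
#'   (named, summing to 1), `nMappedReads`, and `logLik` (per-iteration
#'   trace, non-decreasing).
#' @examples
#' tab <- data.frame(read = sprintf("r%d", 1:10),
#'                   genomes = rep(c("A", "B"), c(3, 7)))
#' emEstimate(tab)$proportions
#' @export
emEstimate <- function(table, tol = 1e-8, maxIter = 1000, genomes = NULL) {
    stopifnot(is.data.frame(table), nrow(table) > 0, tol > 0)
    keys <- as.character(table$genomes)
    if (any(!nzchar(keys))) stop("every read must list >= 1 genome")
    # collapse reads by raw compatibility string; only the (few) distinct
    # patterns are parsed, so runtime is independent of read count
    cnt <- table(keys)
    patSets <- strsplit(names(cnt), ",", fixed = TRUE)
    if (any(lengths(patSets) == 0))
        stop("every read must list >= 1 genome")
    if (is.null(genomes)) genomes <- sort(unique(unlist(patSets)))
    else if (!all(unlist(patSets) %in% genomes))
        stop("table contains genomes outside the declared universe")
    K <- length(genomes)
    patIdx <- lapply(patSets, match, genomes)
    w <- as.numeric(cnt)
    n <- sum(w)

    pi <- rep(1 / K, K)
    ll <- numeric(0)
    for (it in seq_len(maxIter)) {
        contrib <- numeric(K)
        llik <- 0
        for (p in seq_along(patIdx)) {
            idx <- patIdx[[p]]
            pr <- pi[idx]
            s <- sum(pr)
            llik <- llik + w[p] * (log(s) - log(length(idx)))
            contrib[idx] <- contrib[idx] + w[p] * pr / s
        }
        ll <- c(ll, llik)
        piNew <- contrib / n
        delta <- max(abs(piNew - pi))
        pi <- piNew
        if (delta < tol) break
    }
    structure(list(proportions = stats::setNames(pi, genomes),
                   nMappedReads = as.integer(n), logLik = ll),
              class = "AbundanceEstimate")
}

#' Mapped-read quality-control threshold
#'
#' Samples with fewer than `minReads` mapped reads give unreliable
#' taxonomic profiles and are dropped; a sample with exactly `minReads`
#' is kept (the rule is strictly "less than").
#'
#' @param estimate an `AbundanceEstimate` (or anything with a
#'   `nMappedReads` element).
#' @param minReads minimum mapped-read count, default 250000.
#' @return `TRUE` to keep the sample, `FALSE` to drop it.
#' @export
qcMinMapped <- function(estimate, minReads = 250000) {
    estimate$nMappedReads >= minReads
}

#' Zero out sub-noise relative abundances
#'
#' Entries strictly below `floor` are treated as statistical noise and set
#' to 0; the remaining entries are re-closed so the composition sums to 1.
#'
#' @param proportions nonnegative numeric vector summing to 1.
#' @param floor noise threshold, default 1e-5.
#' @return re-closed proportions with sub-floor entries zeroed.
#' @export
applyNoiseFloor <- function(proportions, floor = 1e-5) {
    stopifnot(abs(sum(proportions) - 1) < 1e-6, all(proportions >= 0))
    proportions[proportions < floor] <- 0
    s <- sum(proportions)
    if (s == 0) stop("all entries fall below the noise floor")
    proportions / s
}

#' Aggregate strain-level proportions to species level
#'
#' @param proportions named numeric vector of strain proportions.
#' @param strainToSpecies named character vector mapping every strain id to
#'   a species id.
#' @return named numeric vector of species proportions (total preserved).
#' @export
aggregateStrains <- function(proportions, strainToSpecies) {
    ids <- names(proportions)
    if (is.null(ids) || !all(ids %in% names(strainToSpecies)))
        stop("every strain id must have a species assignment")
    sp <- strainToSpecies[ids]
    out <- tapply(proportions, sp, sum)
    stats::setNames(as.numeric(out), names(out))
}

#' Profile one sample from its read-compatibility table
#'
#' Runs the fixed stage order QC (mapped-read minimum), EM estimation,
#' noise floor, strain-to-species aggregation and final closure.
#'
#' @inheritParams emEstimate
#' @param strainToSpecies optional strain-to-species map; `NULL` keeps
#'   genome-level ids.
#' @param minReads QC threshold, see [qcMinMapped()].
#' @param floor noise floor, see [applyNoiseFloor()].
#' @return named species proportions, or `NULL` when the sample fails QC.
#' @export
profileSample <- function(table, strainToSpecies = NULL, minReads = 250000,
                          floor = 1e-5, tol = 1e-8, maxIter = 1000) {
    if (nrow(table) < minReads) return(NULL)
    est <- emEstimate(table, tol = tol, maxIter = maxIter)
    if (!qcMinMapped(est, minReads)) return(NULL)
    p <- applyNoiseFloor(est$proportions, floor)
    if (!is.null(strainToSpecies)) p <- aggregateStrains(p, strainToSpecies)
    p / sum(p)
}
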