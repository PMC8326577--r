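#' Centred log-ratio transformation
#'
#' Maps each composition \eqn{x} to \eqn{\ln(x_j / G(x))} where \eqn{G(x)}
#' is the geometric mean of the vector, so every transformed row sums to 0.
#' Zeros are resolved first by multiplicative replacement: zero entries are
#' set to a pseudo-abundance (default half the 1e-5 noise floor) and the
#' nonzero entries down-scaled to preserve the unit sum, keeping the
#' logarithms finite while staying below the noise threshold.
#'
#' @param x a [MicrobiomeExperiment-class] (a `"clr"` assay is added) or a
#'   numeric matrix with one composition per row (rows sum to 1).
#' @param zeroPolicy `"multiplicative"` (default) or `"none"` (error on any
#'   zero).
#' @param pseudo pseudo-abundance for zero replacement.
#' @return same class as `x`; for a matrix, the CLR matrix with a
#'   `zeroPolicy` attribute; for an experiment, the experiment with a
#'   `"clr"` assay and the policy recorded in `metadata()`.
#' @examples
#' clrTransform(matrix(c(0.5, 0.25, 0.25), 1))
#' @export
setGeneric("clrTransform",
           function(x, zeroPolicy = "multiplicative", pseudo = 5e-6)
               standardGeneric("clrTransform"))

.clrRows <- function(x, zeroPolicy, pseudo) {
    stopifnot(all(x >= 0))
    if (any(rowSums(x) == 0)) stop("a composition is entirely zero")
    stopifnot(all(abs(rowSums(x) - 1) < 1e-6))
    if (any(x == 0)) {
        if (zeroPolicy == "none")
            stop("zeros present and zeroPolicy = 'none'")
        nz <- rowSums(x == 0)
        scl <- 1 - nz * pseudo
        if (any(scl <= 0)) stop("pseudo-abundance too large for this matrix")
        x <- x * scl
        x[x == 0] <- pseudo
    }
    lx <- log(x)
    out <- lx - rowMeans(lx)
    attr(out, "zeroPolicy") <- list(policy = zeroPolicy, pseudo = pseudo)
    out
}

#' @rdname clrTransform
#' @export
setMethod("clrTransform", "matrix", function(x, zeroPolicy, pseudo) {
    .clrRows(x, zeroPolicy, pseudo)
})

#' @rdname clrTransform
#' @export
setMethod("clrTransform", "MicrobiomeExperiment",
          function(x, zeroPolicy, pseudo) {
    clr <- .clrRows(t(relAbundance(x)), zeroPolicy, pseudo)
    assay(x, "clr") <- t(clr)
    metadata(x)$zeroPolicy <- attr(clr, "zeroPolicy")
    x
})

#' Prevalence filter with per-group union
#'
#' A species passes for a group when it is nonzero in at least
#' `threshold` of the group's samples; the retained set is the union of
#' the per-group passers, so a species highly prevalent in any one
#' diagnosis group is kept. Presence is defined on the noise-floored
#' abundances (nonzero after flooring).
#'
#' @param x a [MicrobiomeExperiment-class].
#' @param threshold prevalence fraction in (0, 1], default 0.90.
#' @return character vector of retained species ids.
#' @export
prevalenceFilter <- function(x, threshold = 0.90) {
    stopifnot(threshold > 0, threshold <= 1)
    ab <- relAbundance(x)
    grp <- groupLabels(x)
    if (any(table(grp) == 0)) stop("empty group")
    keep <- rep(FALSE, nrow(ab))
    for (g in unique(grp)) {
        sub <- ab[, grp == g, drop = FALSE]
        keep <- keep |
            (rowSums(sub > 0) >= threshold * ncol(sub) - 1e-9)
    }
    rownames(ab)[keep]
}

#' Cap the number of replicates per subject
#'
#' Subjects contributing more than `maxPerSubject` samples have exactly
#' `maxPerSubject` randomly chosen samples retained, limiting
#' over-representation of longitudinally sampled subjects.
#'
#' @param x a [MicrobiomeExperiment-class].
#' @param maxPerSubject replicate cap, default 5.
#' @param seed integer seed making the random selection reproducible.
#' @return the subsampled experiment.
#' @export
capReplicates <- function(x, maxPerSubject = 5, seed = 1L) {
    stopifnot(maxPerSubject >= 1)
    set.seed(seed)
    sub <- subjectIds(x)
    keep <- unlist(lapply(split(seq_along(sub), sub), function(idx) {
        if (length(idx) <= maxPerSubject) idx
        else sort(sample(idx, maxPerSubject))
    }), use.names = FALSE)
    x[, sort(keep)]
}

#' Shannon entropy (bits)
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} over the nonzero entries of a
#' relative-abundance vector. Computed on the untransformed relative
#' abundances.
#'
#' @param x relative-abundance vector summing to 1, or a
#'   [MicrobiomeExperiment-class] (per-sample entropies).
#' @return entropy in bits (vector input) or a named per-sample vector.
#' @export
shannonEntropy <- function(x) {
    if (is(x, "MicrobiomeExperiment"))
        return(apply(relAbundance(x), 2, shannonEntropy))
    stopifnot(abs(sum(x) - 1) < 1e-6, all(x >= 0))
    p <- x[x > 0]
    -sum(p * log2(p))
}

#' Bray-Curtis dissimilarity between two samples
#'
#' \eqn{BCD = 1 - 2 C_{ij} / (S_i + S_j)} where \eqn{C_{ij}} is the summed
#' element-wise minimum of the two abundance vectors and \eqn{S_i, S_j}
#' their totals; 0 for identical communities, 1 for disjoint ones.
#'
#' @param v1,v2 nonnegative abundance vectors of equal length.
#' @return dissimilarity in \[0, 1\].
#' @export
brayCurtis <- function(v1, v2) {
    stopifnot(length(v1) == length(v2), all(v1 >= 0), all(v2 >= 0))
    s <- sum(v1) + sum(v2)
    if (s == 0) stop("both vectors are entirely zero")
    1 - 2 * sum(pmin(v1, v2)) / s
}

#' Intrapersonal and interpersonal dissimilarity profiles
#'
#' For each diagnosis group, collects the Bray-Curtis dissimilarities of
#' all within-subject sample pairs (intrapersonal) and all between-subject
#' pairs within the group (interpersonal), and compares the distributions
#' between groups with two-sided Mann-Whitney tests.
#'
#' @param x a [MicrobiomeExperiment-class].
#' @return list with `profiles` (per group, `intra` and `inter` numeric
#'   vectors) and `tests` (data.frame of pairwise group comparisons with
#'   columns `type`, `groupA`, `groupB`, `p`).
#' @export
dissimilarityProfiles <- function(x) {
    ab <- relAbundance(x)
    grp <- groupLabels(x)
    sub <- subjectIds(x)
    profiles <- list()
    for (g in unique(grp)) {
        idx <- which(grp == g)
        if (length(unique(sub[idx])) < 2)
            warning("group '", g,
                    "' has fewer than 2 subjects; interpersonal skipped")
        intra <- numeric(); inter <- numeric()
        if (length(idx) >= 2) {
            pairs <- utils::combn(idx, 2)
            d <- vapply(seq_len(ncol(pairs)), function(k)
                brayCurtis(ab[, pairs[1, k]], ab[, pairs[2, k]]),
                numeric(1))
            same <- sub[pairs[1, ]] == sub[pairs[2, ]]
            intra <- d[same]
            if (length(unique(sub[idx])) >= 2) inter <- d[!same]
        }
        profiles[[g]] <- list(intra = intra, inter = inter)
    }
    gs <- names(profiles)
    tests <- data.frame(type = character(), groupA = character(),
                        groupB = character(), p = numeric(),
                        stringsAsFactors = FALSE)
    if (length(gs) >= 2) {
        cmb <- utils::combn(gs, 2)
        for (k in seq_len(ncol(cmb))) {
            for (type in c("intra", "inter")) {
                a <- profiles[[cmb[1, k]]][[type]]
                b <- profiles[[cmb[2, k]]][[type]]
                if (length(a) >= 2 && length(b) >= 2) {
                    p <- suppressWarnings(
                        stats::wilcox.test(a, b)$p.value)
                    tests <- rbind(tests, data.frame(
                        type = type, groupA = cmb[1, k], groupB = cmb[2, k],
                        p = p, stringsAsFactors = FALSE))
                }
            }
        }
    }
    list(profiles = profiles, tests = tests)
}
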