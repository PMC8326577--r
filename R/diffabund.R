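#' Per-species Mann-Whitney tests on CLR values
#'
#' Two-sided rank-sum test for every species between two diagnosis groups,
#' computed on the CLR-transformed abundances.
#'
#' @param x a [MicrobiomeExperiment-class] with a `"clr"` assay.
#' @param groupA,groupB group labels to compare (>= 2 samples each).
#' @return data.frame with columns `species`, `U`, `p`.
#' @export
mwuPerSpecies <- function(x, groupA, groupB) {
    clr <- clrValues(x)
    grp <- groupLabels(x)
    ia <- which(grp == groupA); ib <- which(grp == groupB)
    if (length(ia) < 2 || length(ib) < 2)
        stop("both groups need >= 2 samples")
    stat <- vapply(seq_len(nrow(clr)), function(j) {
        wt <- suppressWarnings(stats::wilcox.test(clr[j, ia], clr[j, ib]))
        c(wt$statistic, wt$p.value)
    }, numeric(2))
    data.frame(species = rownames(clr), U = stat[1, ], p = stat[2, ],
               stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up procedure: with ordered p-values \eqn{p_{(1)} \le \dots \le
#' p_{(m)}}, \eqn{q_{(i)} = \min_{j \ge i} (m p_{(j)} / j)} capped at 1,
#' mapped back to the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bhAdjust <- function(p) {
    stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
    m <- length(p)
    if (m == 0) return(numeric(0))
    o <- order(p)
    q <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    q[order(o)]
}

#' Fold change between group abundances
#'
#' Fold difference of a species between two groups, computed by default as
#' the ratio of zero-replaced geometric means of its relative abundance
#' (the compositional analogue of the mean, consistent with testing on
#' CLR values); an arithmetic-mean ratio is available as an alternative.
#' The reported fold is always >= 1, with `higherIn` naming the group with
#' the larger mean.
#'
#' @param x a [MicrobiomeExperiment-class].
#' @param groupA,groupB group labels.
#' @param species species ids; default all.
#' @param method `"geometric"` (default) or `"arithmetic"`.
#' @param pseudo zero replacement used inside geometric means.
#' @return data.frame with `species`, `fold` (>= 1), `higherIn`
#'   (`groupA`/`groupB`/`"none"`), `log2fc` (signed, A relative to B).
#' @export
foldChange <- function(x, groupA, groupB, species = NULL,
                       method = c("geometric", "arithmetic"),
                       pseudo = 5e-6) {
    method <- match.arg(method)
    ab <- relAbundance(x)
    if (is.null(species)) species <- rownames(ab)
    stopifnot(all(species %in% rownames(ab)))
    grp <- groupLabels(x)
    mfun <- if (method == "geometric")
        function(v) exp(mean(log(pmax(v, pseudo))))
    else function(v) mean(v)
    ma <- apply(ab[species, grp == groupA, drop = FALSE], 1, mfun)
    mb <- apply(ab[species, grp == groupB, drop = FALSE], 1, mfun)
    fold <- pmax(ma, mb) / pmin(ma, mb)
    data.frame(species = species, fold = as.numeric(fold),
               higherIn = ifelse(ma > mb, groupA,
                                 ifelse(mb > ma, groupB, "none")),
               log2fc = as.numeric(log2(ma / mb)),
               stringsAsFactors = FALSE)
}

#' Multi-control consensus differential abundance
#'
#' Compares the case group to every control group individually: per
#' comparison, Mann-Whitney tests on CLR values across species with
#' Benjamini-Hochberg correction (within the comparison), plus the fold
#' change of the group means. A species reaches consensus when it is
#' significant (q < `qThresh`) with at least a `foldThresh`-fold
#' difference in the same direction against every control.
#'
#' @param x a [MicrobiomeExperiment-class] with a `"clr"` assay.
#' @param caseGroup case label.
#' @param controlGroups character vector of control labels (case must not
#'   appear among them).
#' @param qThresh,foldThresh consensus thresholds (defaults 0.05 and 2).
#' @param foldMethod passed to [foldChange()].
#' @return object of class `DaResult`: list with `perComparison` (long
#'   data.frame: species x control with U, p, q, fold, direction and a
#'   significance code: * q<0.05, ** q<0.01, *** q<0.001) and `consensus`
#'   (data.frame `species`, `direction` = elevated/depleted in the case).
#' @export
consensusDa <- function(x, caseGroup, controlGroups, qThresh = 0.05,
                        foldThresh = 2, foldMethod = "geometric") {
    if (caseGroup %in% controlGroups)
        stop("case group must not appear among the controls")
    stopifnot(length(controlGroups) >= 1)
    per <- NULL
    for (ctrl in controlGroups) {
        mwu <- mwuPerSpecies(x, caseGroup, ctrl)
        mwu$q <- bhAdjust(mwu$p)
        fc <- foldChange(x, caseGroup, ctrl, method = foldMethod)
        stopifnot(identical(mwu$species, fc$species))
        per <- rbind(per, data.frame(
            species = mwu$species, control = ctrl, U = mwu$U, p = mwu$p,
            q = mwu$q, fold = fc$fold,
            direction = ifelse(fc$higherIn == caseGroup, "elevated",
                               ifelse(fc$higherIn == ctrl, "depleted",
                                      "none")),
            stringsAsFactors = FALSE))
    }
    per$code <- cut(per$q, c(-Inf, 0.001, 0.01, 0.05, Inf),
                    labels = c("***", "**", "*", ""))
    cons <- do.call(rbind, lapply(split(per, per$species), function(d) {
        ok <- all(d$q < qThresh) && all(d$fold >= foldThresh) &&
            length(unique(d$direction)) == 1 && d$direction[1] != "none"
        if (ok) data.frame(species = d$species[1],
                           direction = d$direction[1],
                           stringsAsFactors = FALSE)
    }))
    if (is.null(cons))
        cons <- data.frame(species = character(), direction = character(),
                           stringsAsFactors = FALSE)
    rownames(cons) <- NULL
    structure(list(perComparison = per, consensus = cons,
                   caseGroup = caseGroup, controlGroups = controlGroups,
                   qThresh = qThresh, foldThresh = foldThresh),
              class = "DaResult")
}

#' @export
print.DaResult <- function(x, ...) {
    cat("DaResult: ", x$caseGroup, " vs {",
        paste(x$controlGroups, collapse = ", "), "}: ",
        nrow(x$consensus), " consensus species (",
        sum(x$consensus$direction == "elevated"), " elevated, ",
        sum(x$consensus$direction == "depleted"), " depleted)\n", sep = "")
    invisible(x)
}
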