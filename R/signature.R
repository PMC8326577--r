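#' Build a feature table for classification
#'
#' Assembles the per-sample feature matrix used by the signature-selection
#' stage: CLR-transformed species abundances plus label-encoded metadata
#' (age, sex, and the unique subject id, the latter letting the forest
#' account for replicate structure). Categorical metadata are encoded as
#' deterministic lexicographic integer codes. Group labels can be merged,
#' e.g. pooling several healthy cohorts under one label.
#'
#' @param x a [MicrobiomeExperiment-class] with a `"clr"` assay.
#' @param mergeGroups optional named character vector mapping original
#'   group labels to merged ones, e.g. `c(Healthy1 = "Healthy",
#'   Healthy2 = "Healthy")`.
#' @param species optional subset of species to use (e.g. the prevalent
#'   set); default all.
#' @return list with `features` (numeric data.frame, samples x features)
#'   and `labels` (factor).
#' @export
buildFeatureTable <- function(x, mergeGroups = NULL, species = NULL) {
    clr <- t(clrValues(x))
    if (!is.null(species)) clr <- clr[, species, drop = FALSE]
    feat <- as.data.frame(clr)
    cd <- colData(x)
    if ("age" %in% colnames(cd)) feat$age <- as.numeric(cd$age)
    if ("sex" %in% colnames(cd))
        feat$sex <- .labelEncode(as.character(cd$sex))
    feat$subject_id <- .labelEncode(subjectIds(x))
    lab <- groupLabels(x)
    if (!is.null(mergeGroups)) {
        hit <- lab %in% names(mergeGroups)
        lab[hit] <- mergeGroups[lab[hit]]
    }
    if (anyNA(feat)) stop("feature table contains missing values")
    list(features = feat, labels = factor(lab))
}

.labelEncode <- function(x) as.integer(factor(x, levels = sort(unique(x))))

#' Draw a random-noise feature column
#'
#' Samples `n` values from a normal distribution whose mean and standard
#' deviation match the pooled entries of the CLR matrix, giving a null
#' feature that resembles the transformed abundances. A fresh column is
#' drawn for every classifier run.
#'
#' @param clr numeric matrix of CLR values (pooled for the moment
#'   estimates).
#' @param n number of values to draw (one per sample).
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
makeNoiseFeature <- function(clr, n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    v <- as.vector(clr)
    s <- stats::sd(v)
    if (is.na(s)) s <- 0
    stats::rnorm(n, mean = mean(v), sd = s)
}

#' Repeated random-forest importance runs with a planted noise feature
#'
#' Fits `R` random-forest classifiers on all samples; each run appends a
#' freshly drawn noise column (see [makeNoiseFeature()]) before fitting
#' and records every feature's impurity importance, normalised to sum to 1
#' within the run. Run-level seeds are derived deterministically from the
#' master seed.
#'
#' @param features numeric data.frame, samples x features.
#' @param labels factor of class labels (>= 2 classes).
#' @param R number of runs, default 100.
#' @param seed master seed.
#' @param numTrees trees per forest.
#' @param noisePool optional matrix the noise moments are estimated from;
#'   defaults to the species-feature columns of `features`.
#' @return matrix R x (features + 1) of per-run importances; the noise
#'   column is named `".noise"`.
#' @export
importanceRuns <- function(features, labels, R = 100, seed = 1L,
                           numTrees = 500, noisePool = NULL) {
    labels <- factor(labels)
    if (nlevels(labels) < 2) stop("need >= 2 label classes")
    stopifnot(R >= 2)
    if (is.null(noisePool)) noisePool <- as.matrix(features)
    n <- nrow(features)
    out <- matrix(NA_real_, R, ncol(features) + 1,
                  dimnames = list(NULL, c(colnames(features), ".noise")))
    for (r in seq_len(R)) {
        rs <- seed + r
        noise <- makeNoiseFeature(noisePool, n, seed = rs)
        d <- cbind(features, .noise = noise)
        fit <- ranger::ranger(x = d, y = labels, num.trees = numTrees,
                              importance = "impurity", seed = rs,
                              num.threads = 1)
        imp <- fit$variable.importance
        tot <- sum(imp)
        out[r, names(imp)] <- if (tot > 0) imp / tot else 0
    }
    out
}

#' Select features whose importance beats the noise feature
#'
#' Candidates are the features whose mean importance across runs exceeds
#' the noise feature's mean importance. Each candidate's per-run
#' importances are compared to the noise importances with a two-sided
#' Mann-Whitney U test; Benjamini-Hochberg correction is applied across
#' candidates, and features with q below `alpha` are selected (the
#' "signature" set).
#'
#' @param importances matrix from [importanceRuns()] including the
#'   `".noise"` column.
#' @param alpha q-value threshold, default 0.05.
#' @return data.frame with columns `feature`, `meanImportance`, `U`, `p`,
#'   `q`, `selected` (non-candidates carry NA statistics).
#' @export
significantFeatures <- function(importances, alpha = 0.05) {
    stopifnot(".noise" %in% colnames(importances))
    noise <- importances[, ".noise"]
    feats <- setdiff(colnames(importances), ".noise")
    m <- colMeans(importances[, feats, drop = FALSE])
    out <- data.frame(feature = feats, meanImportance = as.numeric(m),
                      U = NA_real_, p = NA_real_, q = NA_real_,
                      selected = FALSE, stringsAsFactors = FALSE)
    cand <- which(m > mean(noise))
    if (length(cand)) {
        stat <- vapply(feats[cand], function(f) {
            wt <- suppressWarnings(
                stats::wilcox.test(importances[, f], noise))
            c(wt$statistic, wt$p.value)
        }, numeric(2))
        out$U[cand] <- stat[1, ]
        out$p[cand] <- stat[2, ]
        out$q[cand] <- bhAdjust(stat[2, ])
        out$selected[cand] <- out$q[cand] < alpha
    }
    out
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall values in \[0, 1\].
#' @return \eqn{F1 = 2pr/(p+r)} (0 when both are 0).
#' @export
f1Score <- function(precision, recall) {
    ifelse(precision + recall == 0, 0,
           2 * precision * recall / (precision + recall))
}

#' Train/test evaluation of the random-forest classifier
#'
#' Stratified split (70/30 by default), forest fit on the training part,
#' per-class F1 on the held-out part, weighted-average F1 by class
#' support, and the confusion table for misclassification analysis.
#'
#' @inheritParams importanceRuns
#' @param trainFraction fraction of each class used for training.
#' @return list with `f1PerClass`, `weightedF1`, `confusion` (rows = true
#'   class, columns = predicted).
#' @export
evaluateClassifier <- function(features, labels, trainFraction = 0.70,
                               seed = 1L, numTrees = 500) {
    labels <- factor(labels)
    if (nlevels(labels) < 2) stop("need >= 2 label classes")
    set.seed(seed)
    train <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
        k <- round(trainFraction * length(idx))
        if (k < 1 || k >= length(idx))
            stop("a class would be absent from one split")
        sample(idx, k)
    }), use.names = FALSE)
    test <- setdiff(seq_along(labels), train)
    fit <- ranger::ranger(x = features[train, , drop = FALSE],
                          y = droplevels(labels[train]),
                          num.trees = numTrees, seed = seed,
                          num.threads = 1)
    pred <- stats::predict(fit, features[test, , drop = FALSE])$predictions
    truth <- factor(labels[test], levels = levels(labels))
    pred <- factor(pred, levels = levels(labels))
    conf <- table(truth = truth, predicted = pred)
    f1 <- vapply(levels(labels), function(cl) {
        tp <- conf[cl, cl]
        prec <- if (sum(conf[, cl]) == 0) 0 else tp / sum(conf[, cl])
        rec <- if (sum(conf[cl, ]) == 0) 0 else tp / sum(conf[cl, ])
        f1Score(prec, rec)
    }, numeric(1))
    support <- rowSums(conf)
    list(f1PerClass = f1,
         weightedF1 = sum(f1 * support) / sum(support),
         confusion = conf)
}
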