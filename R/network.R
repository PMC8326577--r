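#' @useDynLib miCompass, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.edgeTol <- 1e-8

.adjOf <- function(theta) {
    a <- abs(theta) > .edgeTol
    diag(a) <- FALSE
    a
}

#' Sparse precision matrices along an l1-penalty path
#'
#' For each penalty \eqn{\lambda}, estimates the precision matrix
#' maximising the penalised Gaussian log-likelihood
#' \eqn{\log\det\Omega - tr(S\Omega) - \lambda\|\Omega\|_{1,off}}
#' over the empirical covariance \eqn{S} of the CLR data, via blockwise
#' coordinate descent (warm-started along the path). Off-diagonal entries
#' with magnitude above 1e-8 count as edges; the support shrinks as
#' \eqn{\lambda} grows.
#'
#' @param x numeric matrix of CLR values, samples x species, or a
#'   [MicrobiomeExperiment-class] with a `"clr"` assay.
#' @param lambdas penalty values; default [defaultLambdas()] of the
#'   covariance.
#' @return list with `lambdas`, `thetas` (one symmetric precision matrix
#'   per penalty) and `S`.
#' @export
glassoPath <- function(x, lambdas = NULL) {
    if (is(x, "MicrobiomeExperiment")) x <- t(clrValues(x))
    stopifnot(nrow(x) >= 2)
    S <- stats::cov(x)
    if (any(!is.finite(S))) stop("non-finite covariance")
    if (is.null(lambdas)) lambdas <- defaultLambdas(S)
    stopifnot(all(lambdas > 0))
    thetas <- glasso_path_cpp(S, lambdas)
    for (i in seq_along(thetas))
        dimnames(thetas[[i]]) <- dimnames(S)
    list(lambdas = lambdas, thetas = thetas, S = S)
}

#' Default penalty path
#'
#' 30 log-spaced values from \eqn{\lambda_{max}} (the smallest penalty
#' giving an empty graph: the largest absolute off-diagonal covariance)
#' down to `ratio` times \eqn{\lambda_{max}}.
#'
#' @param S covariance matrix.
#' @param nLambda path length.
#' @param ratio smallest-to-largest penalty ratio.
#' @return decreasing numeric vector.
#' @export
defaultLambdas <- function(S, nLambda = 30, ratio = 0.01) {
    lmax <- max(abs(S[upper.tri(S)]))
    if (lmax <= 0) lmax <- 1e-3
    exp(seq(log(lmax), log(ratio * lmax), length.out = nLambda))
}

#' StARS selection of the penalty
#'
#' Stability approach to regularisation selection: graphs are re-estimated
#' on random subsamples (without replacement); for each penalty the
#' edge-wise instability is the mean over species pairs of
#' \eqn{2\hat\theta(1-\hat\theta)}, with \eqn{\hat\theta} the fraction of
#' subsample graphs containing the pair. The selected penalty is the
#' smallest one whose running supremum of instability (over larger
#' penalties) stays at or below `beta`, i.e. the densest graph that is
#' still stable.
#'
#' @inheritParams glassoPath
#' @param nSubsamples number of subsamples, default 20.
#' @param subsampleSize default \eqn{\lfloor 10\sqrt n \rfloor}, capped at
#'   \eqn{\lfloor 0.8 n \rfloor} so small cohorts still produce distinct
#'   subsamples.
#' @param beta instability threshold, default 0.1.
#' @param seed integer seed for the subsampling.
#' @return list with `lambda` (selected), `lambdas`, `instability`
#'   (monotonised), `rawInstability`.
#' @export
starsSelect <- function(x, lambdas = NULL, nSubsamples = 20,
                        subsampleSize = NULL, beta = 0.1, seed = 1L) {
    if (is(x, "MicrobiomeExperiment")) x <- t(clrValues(x))
    n <- nrow(x)
    if (is.null(subsampleSize))
        subsampleSize <- min(floor(0.8 * n), floor(10 * sqrt(n)))
    stopifnot(subsampleSize <= n, subsampleSize >= 2)
    if (is.null(lambdas)) lambdas <- defaultLambdas(stats::cov(x))
    ord <- order(lambdas, decreasing = TRUE)
    lambdas <- lambdas[ord]
    D <- ncol(x)
    nPairs <- D * (D - 1) / 2
    up <- upper.tri(matrix(0, D, D))
    freq <- matrix(0, length(lambdas), nPairs)
    set.seed(seed)
    for (b in seq_len(nSubsamples)) {
        idx <- sample.int(n, subsampleSize)
        fit <- glassoPath(x[idx, , drop = FALSE], lambdas)
        for (i in seq_along(lambdas))
            freq[i, ] <- freq[i, ] + .adjOf(fit$thetas[[i]])[up]
    }
    theta <- freq / nSubsamples
    raw <- rowMeans(2 * theta * (1 - theta))
    mono <- cummax(raw)  # supremum over penalties >= current (decreasing order)
    ok <- which(mono <= beta)
    if (!length(ok)) {
        warning("no penalty meets the instability threshold; ",
                "returning the largest")
        sel <- lambdas[1]
    } else sel <- lambdas[max(ok)]
    list(lambda = sel, lambdas = lambdas, instability = mono,
         rawInstability = raw)
}

#' Bootstrap edge-retention rule
#'
#' An edge estimated on the full data is kept only when it reappears in at
#' least \eqn{f r} of the \eqn{r} bootstrap refits ("f*r or greater").
#'
#' @param nNonzero number of bootstrap fits in which the entry is nonzero.
#' @param r number of bootstrap replicates.
#' @param f required fraction in \[0, 1\].
#' @return logical.
#' @export
edgeKeepRule <- function(nNonzero, r, f) {
    stopifnot(f >= 0, f <= 1, r >= 1)
    nNonzero >= f * r - 1e-9
}

#' Bootstrap stabilisation of the precision matrix
#'
#' Fits the precision matrix on the full data at the selected penalty,
#' refits it on `r` bootstrap resamples (size n, drawn with replacement),
#' and zeroes every off-diagonal entry that is not nonzero in at least
#' `f * r` of the refits. The diagonal is untouched and no edge is ever
#' added.
#'
#' @inheritParams glassoPath
#' @param lambda penalty (typically from [starsSelect()]).
#' @param r bootstrap replicates, default 50.
#' @param f retention fraction, default 0.8.
#' @param seed integer seed.
#' @return the stabilised precision matrix Omega'.
#' @export
bootstrapStabilize <- function(x, lambda, r = 50, f = 0.8, seed = 1L) {
    if (is(x, "MicrobiomeExperiment")) x <- t(clrValues(x))
    stopifnot(r >= 1, f >= 0, f <= 1)
    omega <- glassoPath(x, lambda)$thetas[[1]]
    n <- nrow(x)
    counts <- matrix(0, ncol(x), ncol(x))
    set.seed(seed)
    for (b in seq_len(r)) {
        idx <- sample.int(n, n, replace = TRUE)
        counts <- counts +
            .adjOf(glassoPath(x[idx, , drop = FALSE], lambda)$thetas[[1]])
    }
    keep <- edgeKeepRule(counts, r, f) & .adjOf(omega)
    out <- omega * keep
    diag(out) <- diag(omega)
    dimnames(out) <- dimnames(omega)
    out
}

#' Build the signed association network from a precision matrix
#'
#' One edge per nonzero off-diagonal entry of the (stabilised) precision
#' matrix; the edge sign is the sign of the partial correlation
#' \eqn{-\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}}, so a negative
#' precision entry yields a positive association.
#'
#' @param omega symmetric precision matrix with species dimnames (or
#'   unnamed; ids are generated).
#' @return an [AssociationNetwork-class].
#' @export
buildNetwork <- function(omega) {
    stopifnot(isTRUE(all.equal(omega, t(omega), tolerance = 1e-6)))
    sp <- rownames(omega)
    if (is.null(sp)) sp <- sprintf("sp%03d", seq_len(nrow(omega)))
    adj <- .adjOf(omega)
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    edges <- data.frame(from = sp[idx[, 1]], to = sp[idx[, 2]],
                        sign = as.integer(sign(-omega[idx])),
                        stringsAsFactors = FALSE)
    new("AssociationNetwork", species = sp, edges = edges,
        precision = omega)
}

.adjacencyMatrix <- function(net) {
    k <- length(net@species)
    a <- matrix(0, k, k, dimnames = list(net@species, net@species))
    e <- net@edges
    if (nrow(e)) {
        a[cbind(e$from, e$to)] <- 1
        a[cbind(e$to, e$from)] <- 1
    }
    a
}

#' Eigenvector centrality
#'
#' Solves \eqn{x_i = \lambda^{-1} \sum_j A_{ij} x_j} on the unweighted,
#' unsigned adjacency matrix by power iteration (on \eqn{A + I}, which
#' shares eigenvectors with \eqn{A} and converges on bipartite graphs
#' too). For disconnected graphs the largest connected component is
#' scored and all other nodes get 0; the result is nonnegative with unit
#' Euclidean norm.
#'
#' @param net an [AssociationNetwork-class] with at least one edge.
#' @param tol,maxIter power-iteration controls.
#' @return named numeric vector over all nodes.
#' @export
eigenvectorCentrality <- function(net, tol = 1e-12, maxIter = 10000) {
    if (nrow(net@edges) == 0) stop("network has no edges")
    a <- .adjacencyMatrix(net)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    comp <- igraph::components(g)
    big <- which.max(comp$csize)
    idx <- which(comp$membership == big)
    m <- a[idx, idx, drop = FALSE]
    x <- rep(1 / sqrt(length(idx)), length(idx))
    for (i in seq_len(maxIter)) {
        y <- as.vector(m %*% x) + x
        y <- y / sqrt(sum(y^2))
        if (max(abs(y - x)) < tol) { x <- y; break }
        x <- y
    }
    out <- stats::setNames(numeric(length(net@species)), net@species)
    out[idx] <- x
    out / sqrt(sum(out^2))
}

.edgeKeys <- function(net) {
    e <- net@edges
    if (!nrow(e)) return(character(0))
    paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "|")
}

#' Compare two association networks
#'
#' Reports the edges unique to each network and shared by both, the
#' overlap of the top-`topK` eigenvector-centrality node sets, the
#' fraction of connected nodes in each differential-abundance category,
#' and the fraction of negative edges incident to DA-elevated species.
#'
#' @param netA,netB [AssociationNetwork-class] objects over a shared node
#'   universe.
#' @param daLabels optional named character vector over species with
#'   values `"elevated"`, `"depleted"` or `"ns"`.
#' @param topK size of the high-centrality set, default 10.
#' @return list with `uniqueA`, `uniqueB`, `shared` (edge keys
#'   `"a|b"`), `topOverlap` (+ the two top sets), and per-network
#'   `daNodeFractions` and `negEdgeElevatedFraction` when `daLabels` is
#'   given.
#' @export
compareNetworks <- function(netA, netB, daLabels = NULL, topK = 10) {
    stopifnot(setequal(netA@species, netB@species))
    ka <- .edgeKeys(netA); kb <- .edgeKeys(netB)
    out <- list(uniqueA = setdiff(ka, kb), uniqueB = setdiff(kb, ka),
                shared = intersect(ka, kb))
    topset <- function(net) {
        if (nrow(net@edges) == 0) return(character(0))
        ev <- eigenvectorCentrality(net)
        names(sort(ev, decreasing = TRUE))[seq_len(min(topK, length(ev)))]
    }
    ta <- topset(netA); tb <- topset(netB)
    out$topA <- ta; out$topB <- tb
    out$topOverlap <- length(intersect(ta, tb))
    if (!is.null(daLabels)) {
        daStats <- function(net) {
            deg <- nodeDegrees(net)
            nodes <- names(deg)[deg > 0]
            frac <- prop.table(table(factor(daLabels[nodes],
                levels = c("elevated", "depleted", "ns"))))
            e <- net@edges
            neg <- e[e$sign < 0, , drop = FALSE]
            negFrac <- if (nrow(neg) == 0) NA_real_ else
                mean(daLabels[neg$from] == "elevated" |
                     daLabels[neg$to] == "elevated")
            list(daNodeFractions = frac,
                 negEdgeElevatedFraction = negFrac)
        }
        out$statsA <- daStats(netA)
        out$statsB <- daStats(netB)
    }
    out
}

#' Edge F1 against a reference support
#'
#' Harmonic mean of edge precision and recall of an estimated support
#' (adjacency or network) against a reference binary support; the
#' standard score for support-recovery benchmarks.
#'
#' @param estimated an [AssociationNetwork-class] or binary matrix.
#' @param truth binary reference support matrix.
#' @return F1 in \[0, 1\] (0 when either side has no edges).
#' @export
edgeF1 <- function(estimated, truth) {
    a <- if (is(estimated, "AssociationNetwork"))
        .adjacencyMatrix(estimated) else (estimated != 0) * 1
    t0 <- (truth != 0) * 1
    up <- upper.tri(t0)
    tp <- sum(a[up] & t0[up])
    fp <- sum(a[up] & !t0[up])
    fn <- sum(!a[up] & t0[up])
    if (tp == 0) return(0)
    f1Score(tp / (tp + fp), tp / (tp + fn))
}
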