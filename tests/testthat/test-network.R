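test_that("penalised precision estimation shrinks to the right supports", {
    set.seed(20)
    x <- MASS::mvrnorm(200, rep(0, 4), diag(4))
    S <- stats::cov(x)
    lmax <- max(abs(S[upper.tri(S)]))
    # at and beyond lambda_max the graph is empty (diagonal estimate)
    fit <- glassoPath(x, c(2 * lmax, lmax * 1.0001))
    for (th in fit$thetas)
        expect_equal(sum(abs(th[upper.tri(th)]) > 1e-8), 0)

    # chain truth 1-2-3, n = 2000: mid-path penalty recovers exactly the
    # chain; the marginally dependent (1,3) pair stays excluded
    chain <- matrix(0, 3, 3)
    chain[1, 2] <- chain[2, 1] <- chain[2, 3] <- chain[3, 2] <- 1
    pm <- samplePrecisionMatrix(3, 0.5, seed = 2, support = chain)
    xc <- MASS::mvrnorm(2000, rep(0, 3), solve(pm$precision))
    Sc <- stats::cov(xc)
    lam <- 0.1 * max(abs(Sc[upper.tri(Sc)]))
    th <- glassoPath(xc, lam)$thetas[[1]]
    expect_gt(abs(th[1, 2]), 1e-8)
    expect_gt(abs(th[2, 3]), 1e-8)
    expect_lt(abs(th[1, 3]), 1e-8)

    # nearly unpenalised estimate approaches the inverse covariance
    thSmall <- glassoPath(xc, 1e-5)$thetas[[1]]
    expect_lt(norm(thSmall - solve(Sc), "F") / norm(solve(Sc), "F"), 0.05)
})

test_that("edge count along the penalty path is non-increasing", {
    set.seed(21)
    pm <- samplePrecisionMatrix(15, 0.15)
    x <- MASS::mvrnorm(150, rep(0, 15), solve(pm$precision))
    fit <- glassoPath(x)
    counts <- vapply(fit$thetas, function(t)
        sum(abs(t[upper.tri(t)]) > 1e-8), numeric(1))
    # path is decreasing in lambda, so counts must be non-decreasing
    expect_true(all(diff(counts) >= 0))
})

test_that("StARS selects stable penalties and degenerates sensibly", {
    set.seed(22)
    pm <- samplePrecisionMatrix(10, 0.15)
    x <- MASS::mvrnorm(80, rep(0, 10), solve(pm$precision))
    # identical subsamples (subsampleSize = n): zero instability at all
    # penalties, so beta = 0 picks the densest (smallest) penalty
    sel <- starsSelect(x, nSubsamples = 5, subsampleSize = nrow(x),
                       beta = 0, seed = 1)
    expect_true(all(sel$instability == 0))
    expect_equal(sel$lambda, min(sel$lambdas))
    sel2 <- starsSelect(x, seed = 2)
    expect_true(sel2$lambda %in% sel2$lambdas)
    expect_true(all(diff(sel2$instability) >= 0))  # monotonised
})

test_that("bootstrap stabilisation prunes with the f*r-or-greater rule", {
    expect_true(edgeKeepRule(40, 50, 0.8))
    expect_false(edgeKeepRule(39, 50, 0.8))
    expect_true(all(edgeKeepRule(0:50, 50, 0)))

    set.seed(23)
    pm <- samplePrecisionMatrix(12, 0.15)
    x <- MASS::mvrnorm(100, rep(0, 12), solve(pm$precision))
    lam <- defaultLambdas(stats::cov(x))[15]
    full <- glassoPath(x, lam)$thetas[[1]]
    edgesOf <- function(m) {
        a <- abs(m) > 1e-8; diag(a) <- FALSE
        which(a[upper.tri(a)])
    }
    omF0 <- bootstrapStabilize(x, lam, r = 20, f = 0, seed = 3)
    expect_equal(edgesOf(omF0), edgesOf(full))  # f = 0 keeps everything
    om8 <- bootstrapStabilize(x, lam, r = 20, f = 0.8, seed = 3)
    om1 <- bootstrapStabilize(x, lam, r = 20, f = 1, seed = 3)
    expect_true(all(edgesOf(om1) %in% edgesOf(om8)))
    expect_true(all(edgesOf(om8) %in% edgesOf(omF0)))
    expect_true(all(edgesOf(om8) %in% edgesOf(full)))  # never adds
    expect_equal(diag(om8), diag(full))
})

test_that("network construction applies the partial-correlation sign", {
    om <- diag(3)
    expect_equal(nrow(edgeTable(buildNetwork(om))), 0)
    om[1, 2] <- om[2, 1] <- -0.4   # negative precision -> positive assoc.
    om[2, 3] <- om[3, 2] <- 0.3    # positive precision -> negative assoc.
    net <- buildNetwork(om)
    e <- edgeTable(net)
    expect_equal(nrow(e), 2)
    expect_equal(e$sign[e$from == "sp001"], 1L)
    expect_equal(e$sign[e$to == "sp003"], -1L)
    expect_equal(unname(nodeDegrees(net)), c(1, 2, 1))
})

test_that("eigenvector centrality matches closed forms and dense eigen", {
    star <- matrix(0, 5, 5)
    star[1, 2:5] <- star[2:5, 1] <- 1
    evStar <- eigenvectorCentrality(buildNetwork(-star + diag(5) * 2))
    expect_equal(unname(which.max(evStar)), 1)
    expect_true(all(evStar[1] > evStar[-1]))

    p3 <- matrix(0, 3, 3)
    p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
    evP3 <- eigenvectorCentrality(buildNetwork(-p3 + diag(3) * 2))
    expect_equal(unname(evP3 / evP3[1]), c(1, sqrt(2), 1),
                 tolerance = 1e-8)

    k4 <- matrix(1, 4, 4) - diag(4)
    evK4 <- eigenvectorCentrality(buildNetwork(-k4 + diag(4) * 4))
    expect_equal(unname(evK4), rep(0.5, 4), tolerance = 1e-8)
    expect_equal(sum(evK4^2), 1)
    expect_error(eigenvectorCentrality(buildNetwork(diag(3))),
                 "no edges")

    # dense eigen-decomposition oracle on random graphs
    set.seed(24)
    for (i in 1:50) {
        D <- sample(5:40, 1)
        a <- matrix(0, D, D)
        up <- upper.tri(a)
        a[up] <- rbinom(sum(up), 1, 0.15)
        a <- a + t(a)
        if (sum(a) == 0) next
        net <- buildNetwork(-a + diag(D) * (max(rowSums(a)) + 1))
        ev <- eigenvectorCentrality(net)
        g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
        comp <- igraph::components(g)
        idx <- which(comp$membership == which.max(comp$csize))
        ref <- eigen(a[idx, idx], symmetric = TRUE)$vectors[, 1]
        ref <- abs(ref) / sqrt(sum(ref^2))
        expect_equal(unname(ev[idx]), unname(ref), tolerance = 1e-8)
        expect_true(all(ev[-idx] == 0))
    }
})

test_that("network comparison reports unique edges and centrality overlap", {
    a <- matrix(0, 6, 6)
    a[1, 2] <- a[2, 3] <- a[3, 4] <- a[4, 5] <- a[5, 6] <- 1
    a <- a + t(a)
    omA <- -a + diag(6) * 3
    netA <- buildNetwork(omA)
    same <- compareNetworks(netA, netA, topK = 4)
    expect_length(same$uniqueA, 0)
    expect_equal(same$topOverlap, 4)

    b <- matrix(0, 6, 6)
    b[1, 3] <- b[2, 4] <- 1
    b <- b + t(b)
    netB <- buildNetwork(-b + diag(6) * 3)
    disj <- compareNetworks(netA, netB)
    expect_length(disj$shared, 0)
    expect_length(disj$uniqueA, 5)
    expect_length(disj$uniqueB, 2)

    # truths differing by known edges are reported exactly
    omC <- omA
    omC[1, 2] <- omC[2, 1] <- 0
    netC <- buildNetwork(omC)
    diffAB <- compareNetworks(netA, netC)
    expect_equal(diffAB$uniqueA, "sp001|sp002")
    expect_length(diffAB$uniqueB, 0)

    da <- setNames(rep("ns", 6), sprintf("sp%03d", 1:6))
    da[c("sp001", "sp002")] <- "elevated"
    withDa <- compareNetworks(netA, netB, daLabels = da)
    expect_equal(sum(withDa$statsA$daNodeFractions), 1)
})
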