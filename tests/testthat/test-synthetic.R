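test_that("precision sampler honours support, sign and positive definiteness", {
    # empty support -> diagonal matrix, diagonal inverse, zero edges
    empty <- samplePrecisionMatrix(5, 0.5, seed = 1,
                                   support = matrix(0, 5, 5))
    expect_true(all(empty$precision[upper.tri(empty$precision)] == 0))
    inv <- solve(empty$precision)
    expect_true(all(abs(inv[upper.tri(inv)]) < 1e-12))
    expect_equal(sum(empty$support), 0)

    # forced chain 1-2-3: precision has exactly those off-diagonal nonzeros,
    # so 1 and 3 are conditionally independent given 2 even though their
    # covariance (the inverse) links them
    chain <- matrix(0, 3, 3); chain[1, 2] <- chain[2, 1] <- 1
    chain[2, 3] <- chain[3, 2] <- 1
    pm <- samplePrecisionMatrix(3, 0.5, seed = 2, support = chain)
    expect_true(all(pm$support == chain))
    expect_equal(pm$precision[1, 3], 0)
    expect_true(abs(pm$precision[1, 2]) >= 0.1)
    sigma <- solve(pm$precision)
    expect_gt(abs(sigma[1, 3]), 1e-8)  # marginal dependence survives
    expect_equal(solve(sigma)[1, 3], 0, tolerance = 1e-10)
    expect_equal(pm$signs[1, 2], -sign(pm$precision[1, 2]))

    # random draw: PD and support fraction near target
    pm30 <- samplePrecisionMatrix(30, 0.1, seed = 1)
    expect_gt(min(eigen(pm30$precision, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
    frac <- sum(pm30$support) / (30 * 29)
    expect_gt(frac, 0.05); expect_lt(frac, 0.15)
})

test_that("generated cohorts are closed, deterministic, and carry truth", {
    # D = 50 keeps the planted species' base share small, so the 4-fold
    # absolute effect is not eaten by compositional renormalisation
    spec <- twoGroupSpec(100, 50, seed = 11,
                         daSpec = data.frame(species = 1, group = "case",
                                             log2fc = 2))
    g1 <- generateCohort(spec)
    g2 <- generateCohort(spec)
    expect_identical(relAbundance(g1$experiment),
                     relAbundance(g2$experiment))
    expect_true(all(abs(colSums(relAbundance(g1$experiment)) - 1) < 1e-9))
    expect_identical(g1$truth@daSpecies$species, "sp001")

    # planted +2 log2 effect: case group mean exceeds control >= twofold
    ab <- relAbundance(g1$experiment)
    grp <- groupLabels(g1$experiment)
    ratio <- mean(ab["sp001", grp == "case"]) /
        mean(ab["sp001", grp == "ctrl"])
    expect_gte(ratio, 2)

    expect_error(generateCohort(
        twoGroupSpec(5, 10, 1, daSpec = data.frame(
            species = "nope", group = "case", log2fc = 2))),
        "unknown species")
    expect_error(cohortSpec(list(a = list(nSubjects = 5,
                                          repProbs = c(1, 0, 0, 0, 0))),
                            daSpec = data.frame(species = 1, group = "a",
                                                log2fc = 0.5)),
                 "twofold")
})

test_that("cohort CLR covariance matches the latent model", {
    # CLR centres the latent log abundances, so cov(CLR) ~ F Sigma F with
    # F = I - J/D; checked at n = 2000, D = 10
    spec <- cohortSpec(list(g = list(nSubjects = 2000,
                                     repProbs = c(1, 0, 0, 0, 0))),
                       D = 10, subjectSd = 0, noiseFloor = 0, seed = 21)
    g <- generateCohort(spec)
    emp <- stats::cov(t(clrValues(clrTransform(g$experiment))))
    F <- diag(10) - matrix(1 / 10, 10, 10)
    expected <- F %*% solve(g$truth@precision) %*% F
    relErr <- norm(emp - expected, "F") / norm(expected, "F")
    expect_lt(relErr, 0.2)
})

test_that("subject intercepts make replicates more similar than strangers", {
    spec <- cohortSpec(list(g = list(nSubjects = 30,
                                     repProbs = c(0, 0.5, 0.5, 0, 0))),
                       D = 20, subjectSd = 0.8, seed = 31)
    g <- generateCohort(spec)
    dp <- dissimilarityProfiles(g$experiment)
    expect_lt(median(dp$profiles$g$intra), median(dp$profiles$g$inter))
})

test_that("read-compatibility simulation matches its mixture truth", {
    rc <- generateReadCompatibility(c(A = 0.3, B = 0.7), 10000,
                                    ambiguity = 0, seed = 1)
    counts <- attr(rc, "sourceCounts")
    expect_equal(sum(counts), 10000)
    # binomial 3-sigma band around 0.3
    expect_lt(abs(counts[["A"]] / 10000 - 0.3),
              3 * sqrt(0.3 * 0.7 / 10000))
    expect_true(all(rc$genomes %in% c("A", "B")))

    rcAmb <- generateReadCompatibility(c(A = 0.5, B = 0.5), 500,
                                       ambiguity = 1, seed = 2)
    expect_true(all(rcAmb$genomes == "A,B"))

    # a 200k-read sample fails the mapped-read QC
    small <- generateReadCompatibility(c(A = 0.5, B = 0.5), 200000,
                                       ambiguity = 0, seed = 3)
    expect_null(profileSample(small))
})

test_that("family-count simulation plants enrichments deterministically", {
    sp <- c("spA", "spB")
    f1 <- generateFamilyCounts(sp, nFamilies = 6, nRoles = 2, seed = 5)
    f2 <- generateFamilyCounts(sp, nFamilies = 6, nRoles = 2, seed = 5)
    expect_identical(f1$counts, f2$counts)
    expect_true(all(f1$counts >= 0))
    expect_equal(nrow(f1$roleMap), 6)

    planted <- generateFamilyCounts(sp, nFamilies = 6, nRoles = 2,
                                    plantedRoles = data.frame(
                                        species = "spA", family = "fam001",
                                        boost = 50), seed = 5)
    expect_equal(planted$counts["spA", "fam001"],
                 f1$counts["spA", "fam001"] + 50)
    expect_error(generateFamilyCounts(sp, 6, 2, plantedRoles = data.frame(
        species = "spA", family = "fam099", boost = 1), seed = 5),
        "unknown family")
})

test_that("null cohorts yield (almost) no consensus DA calls", {
    frac <- vapply(1:20, function(s) {
        g <- generateCohort(cohortSpec(
            list(a = list(nSubjects = 30, repProbs = c(1, 0, 0, 0, 0)),
                 b = list(nSubjects = 30, repProbs = c(1, 0, 0, 0, 0))),
            D = 20, subjectSd = 0.3, seed = 100 + s))
        me <- clrTransform(g$experiment)
        nrow(consensusDa(me, "a", "b")$consensus) / 20
    }, numeric(1))
    expect_lte(mean(frac), 0.10)
})
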