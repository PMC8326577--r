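test_that("per-species MWU matches known p-values and rank invariance", {
    # 6 samples, 2 species; sp1 strictly increasing across samples
    comp <- cbind(sp1 = c(1, 2, 3, 4, 5, 6))
    comp <- cbind(comp, sp2 = 10 - comp[, 1])
    me <- makeME(comp, group = rep(c("a", "b"), each = 3))
    me <- clrTransform(me)
    res <- mwuPerSpecies(me, "a", "b")
    # {1,2,3} vs {4,5,6} on the CLR scale (monotone in sp1): U = 0,
    # exact two-sided p = 2/20 = 0.1
    expect_equal(res$U[1], 0)
    expect_equal(res$p[1], 0.1)
    expect_error(mwuPerSpecies(me[, 1:3], "a", "b"), ">= 2 samples")

    # one group a permutation of the other: U = n1 n2 / 2, p in the ~1
    # region
    set.seed(13)
    v <- runif(5)
    comp2 <- cbind(c(v, rev(v)), 1 - c(v, rev(v)))
    me2 <- clrTransform(makeME(comp2, group = rep(c("a", "b"), each = 5)))
    res2 <- mwuPerSpecies(me2, "a", "b")
    expect_equal(res2$U[1], 12.5)
    expect_gt(res2$p[1], 0.9)
})

test_that("MWU agrees with exhaustive permutation enumeration", {
    set.seed(14)
    for (i in 1:100) {
        n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
        x <- runif(n1); y <- runif(n2)
        ref <- mwuEnum(x, y)
        wt <- stats::wilcox.test(x, y)
        expect_equal(unname(wt$statistic), ref$U)
        expect_equal(wt$p.value, ref$p, tolerance = 1e-12)
    }
})

test_that("BH adjustment matches the step-up reference", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    set.seed(15)
    for (i in 1:1000) {
        p <- runif(sample(1:40, 1))
        expect_equal(bhAdjust(p), stats::p.adjust(p, "BH"),
                     tolerance = 1e-12)
    }
})

test_that("fold changes reflect constructed and planted effects", {
    # constant compositions: species 1 exactly twice as abundant in A
    comp <- rbind(matrix(rep(c(0.4, 0.6), 5), ncol = 2, byrow = TRUE),
                  matrix(rep(c(0.2, 0.8), 5), ncol = 2, byrow = TRUE))
    me <- makeME(comp, group = rep(c("A", "B"), each = 5))
    fc <- foldChange(me, "A", "B")
    expect_equal(fc$fold[1], 2)
    expect_equal(fc$higherIn[1], "A")
    expect_equal(fc$log2fc[1], 1)
    # identical groups: fold 1, no direction
    same <- makeME(matrix(rep(c(0.3, 0.7), 8), ncol = 2, byrow = TRUE),
                   group = rep(c("A", "B"), 4))
    fcSame <- foldChange(same, "A", "B")
    expect_equal(fcSame$fold, c(1, 1))
    expect_true(all(fcSame$higherIn == "none"))

    # planted +2 log2 effect measured on the relative-abundance scale:
    # compositional renormalisation pulls the 4-fold absolute effect down
    folds <- vapply(1:10, function(s) {
        g <- generateCohort(twoGroupSpec(
            50, 50, seed = s, daSpec = data.frame(
                species = 1, group = "case", log2fc = 2)))
        foldChange(g$experiment, "case", "ctrl",
                   species = "sp001")$fold
    }, numeric(1))
    expect_gt(mean(folds), 3.5)
    expect_lt(mean(folds), 4.6)
})

test_that("consensus requires every control at q, fold and direction", {
    set.seed(16)
    jitter <- function(a, n) {
        v <- pmax(a + rnorm(n, 0, 0.002), 1e-4)
        cbind(v, 1 - v)
    }
    # case vs ctrl1: fold 3; case vs ctrl2: fold 1.5 (below the rule)
    comp <- rbind(jitter(0.30, 8), jitter(0.10, 8), jitter(0.20, 8))
    me <- clrTransform(makeME(comp, group = rep(c("case", "c1", "c2"),
                                                each = 8)))
    da <- consensusDa(me, "case", c("c1", "c2"))
    per <- da$perComparison
    sp1 <- per[per$species == "sp001", ]
    expect_true(all(sp1$q < 0.05))
    expect_false("sp001" %in% da$consensus$species)  # fold 1.5 vs c2

    # significant vs only some controls is not consensus
    comp2 <- rbind(jitter(0.30, 8), jitter(0.10, 8), jitter(0.30, 8))
    me2 <- clrTransform(makeME(comp2, group = rep(c("case", "c1", "c2"),
                                                  each = 8)))
    expect_false("sp001" %in%
                 consensusDa(me2, "case", c("c1", "c2"))$consensus$species)
    expect_true("sp001" %in%
                consensusDa(me2, "case", "c1")$consensus$species)
    expect_error(consensusDa(me2, "case", c("case", "c1")),
                 "must not appear")
})

test_that("adding a control group never grows the consensus set", {
    g <- generateCohort(cohortSpec(
        list(case = list(nSubjects = 40, repProbs = c(1, 0, 0, 0, 0)),
             c1 = list(nSubjects = 40, repProbs = c(1, 0, 0, 0, 0)),
             c2 = list(nSubjects = 40, repProbs = c(1, 0, 0, 0, 0))),
        D = 30, subjectSd = 0,
        daSpec = data.frame(species = 1:4, group = "case",
                            log2fc = c(2, 2, -2, 1.2)),
        seed = 17))
    me <- clrTransform(g$experiment)
    one <- consensusDa(me, "case", "c1")$consensus$species
    two <- consensusDa(me, "case", c("c1", "c2"))$consensus$species
    expect_true(all(two %in% one))
    # direction consistency holds by construction of the consensus flag
    da <- consensusDa(me, "case", c("c1", "c2"))
    for (sp in da$consensus$species) {
        dirs <- da$perComparison$direction[da$perComparison$species == sp]
        expect_length(unique(dirs), 1)
    }
})
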