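test_that("CLR matches closed-form values and the zero-sum identity", {
    expect_equal(as.numeric(clrTransform(matrix(1 / 3, 1, 3))),
                 c(0, 0, 0))
    got <- as.numeric(clrTransform(matrix(c(0.5, 0.25, 0.25), 1)))
    expect_equal(round(got, 4), c(0.4621, -0.2310, -0.2310))
    set.seed(1)
    m <- matrix(runif(40), 5); m <- m / rowSums(m)
    out <- clrTransform(m)
    expect_equal(unname(rowSums(out)), rep(0, 5), tolerance = 1e-9)
    # scale invariance: closure removes any positive per-row scalar
    m2 <- 7 * m
    expect_equal(unname(clrTransform(m2 / rowSums(m2))), unname(out))
})

test_that("CLR zero handling stays finite and below the noise threshold", {
    m <- matrix(c(0.6, 0.4, 0, 0.5, 0.25, 0.25), 2, byrow = TRUE)
    out <- clrTransform(m)
    expect_true(all(is.finite(out)))
    expect_equal(unname(rowSums(out)), c(0, 0), tolerance = 1e-9)
    expect_error(clrTransform(matrix(c(0, 0, 1, 0), 2)),
                 "entirely zero")
    expect_error(clrTransform(m, zeroPolicy = "none"), "zeros present")
    me <- clrTransform(makeME(m, group = c("a", "a")))
    expect_equal(S4Vectors::metadata(me)$zeroPolicy$pseudo, 5e-6)
})

test_that("Shannon entropy matches closed forms and is maximal at uniform", {
    expect_equal(shannonEntropy(rep(0.25, 4)), 2)
    expect_equal(shannonEntropy(c(1, 0, 0)), 0)
    expect_equal(shannonEntropy(c(0.5, 0.25, 0.25)), 1.5)
    set.seed(2)
    for (i in 1:20) {
        p <- runif(8); p <- p / sum(p)
        h <- shannonEntropy(p)
        expect_gte(h, 0); expect_lte(h, log2(8) + 1e-12)
    }
    expect_lt(shannonEntropy(c(0.5, 0.3, 0.1, 0.1)), log2(4))
})

test_that("Bray-Curtis matches closed forms and vegan on random data", {
    expect_equal(brayCurtis(c(0.2, 0.8), c(0.2, 0.8)), 0)
    expect_equal(brayCurtis(c(1, 0), c(0, 1)), 1)
    expect_equal(brayCurtis(c(0.6, 0.4, 0), c(0.2, 0.4, 0.4)), 0.4)
    expect_error(brayCurtis(c(0, 0), c(0, 0)), "entirely zero")
    set.seed(3)
    m <- matrix(runif(50), 10)
    ref <- as.matrix(vegan::vegdist(m, method = "bray"))
    for (i in 1:9) {
        expect_equal(brayCurtis(m[i, ], m[i + 1, ]), ref[i, i + 1],
                     tolerance = 1e-12)
        expect_equal(brayCurtis(m[i, ], m[i + 1, ]),
                     brayCurtis(m[i + 1, ], m[i, ]))
    }
})

test_that("prevalence filter applies the 90% rule per group with a union", {
    # species1: 9/10 in group A (passes); species2: 8/10 in both (fails);
    # species3: 8/10 in A but 10/10 in B (union keeps it)
    presA <- cbind(c(rep(1, 9), 0), c(rep(1, 8), 0, 0),
                   c(rep(1, 8), 0, 0), rep(1, 10))
    presB <- cbind(rep(1, 10), c(rep(1, 8), 0, 0), rep(1, 10),
                   rep(1, 10))
    m <- rbind(presA, presB) + 0
    m[m == 1] <- 0.25
    me <- makeME(cbind(m[, 1:3], 1 - rowSums(m[, 1:3, drop = FALSE])),
                 group = rep(c("A", "B"), each = 10))
    kept <- prevalenceFilter(me, 0.90)
    expect_true("sp001" %in% kept)
    expect_false("sp002" %in% kept)
    expect_true("sp003" %in% kept)
    expect_setequal(prevalenceFilter(me, 1e-9),
                    c("sp001", "sp002", "sp003", "sp004"))
    expect_true("sp004" %in% prevalenceFilter(me, 1.0))
    expect_false("sp002" %in% prevalenceFilter(me, 1.0))
})

test_that("replicate capping retains at most five samples per subject", {
    set.seed(6)
    m <- matrix(runif(12 * 4), 12)
    me <- makeME(m, group = rep("g", 12),
                 subject = rep(c("s1", "s2"), c(7, 5)))
    capped <- capReplicates(me, 5, seed = 9)
    expect_equal(sum(subjectIds(capped) == "s1"), 5)
    expect_equal(sum(subjectIds(capped) == "s2"), 5)
    capped2 <- capReplicates(me, 5, seed = 9)
    expect_identical(colnames(capped), colnames(capped2))
    few <- capReplicates(me[, 1:3], 5, seed = 1)
    expect_equal(ncol(few), 3)
})

test_that("dissimilarity profiles count pairs correctly", {
    set.seed(7)
    # one subject, three replicates: C(3,2) = 3 intrapersonal pairs
    me1 <- makeME(matrix(runif(12), 3), group = rep("g", 3),
                  subject = rep("s1", 3))
    expect_warning(dp1 <- dissimilarityProfiles(me1), "fewer than 2")
    expect_length(dp1$profiles$g$intra, 3)
    # two subjects x two replicates: 2 intra, 4 inter
    me2 <- makeME(matrix(runif(16), 4), group = rep("g", 4),
                  subject = c("s1", "s1", "s2", "s2"))
    dp2 <- dissimilarityProfiles(me2)
    expect_length(dp2$profiles$g$intra, 2)
    expect_length(dp2$profiles$g$inter, 4)
})
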