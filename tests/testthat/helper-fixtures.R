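# Build a MicrobiomeExperiment from a samples x species matrix (rows are
# closed automatically).
makeME <- function(m, group, subject = NULL, species = NULL) {
    if (is.null(subject)) subject <- sprintf("subj%02d", seq_len(nrow(m)))
    if (is.null(species)) species <- sprintf("sp%03d", seq_len(ncol(m)))
    m <- m / rowSums(m)
    ab <- t(m)
    dimnames(ab) <- list(species, sprintf("s%03d", seq_len(nrow(m))))
    MicrobiomeExperiment(ab, subject = subject, group = group)
}

# Two-group cohort spec shorthand: single replicate per subject.
twoGroupSpec <- function(nPer, D, seed, daSpec = NULL, subjectSd = 0) {
    cohortSpec(list(case = list(nSubjects = nPer,
                                repProbs = c(1, 0, 0, 0, 0)),
                    ctrl = list(nSubjects = nPer,
                                repProbs = c(1, 0, 0, 0, 0))),
               D = D, daSpec = daSpec, subjectSd = subjectSd, seed = seed)
}

# Exhaustive-enumeration Mann-Whitney oracle (assumes no ties): U counts
# pairs x > y; two-sided p from the full permutation distribution.
mwuEnum <- function(x, y) {
    pooled <- c(x, y)
    n1 <- length(x)
    idx <- utils::combn(length(pooled), n1)
    Uall <- apply(idx, 2, function(i)
        sum(outer(pooled[i], pooled[-i], ">")))
    u <- sum(outer(x, y, ">"))
    list(U = u,
         p = min(1, 2 * min(mean(Uall <= u), mean(Uall >= u))))
}

# Small random read-compatibility table.
randomTable <- function(seed, K = 3, n = 60) {
    set.seed(seed)
    gn <- LETTERS[seq_len(K)]
    sets <- vapply(seq_len(n), function(i)
        paste(sort(sample(gn, sample.int(K, 1))), collapse = ","),
        character(1))
    data.frame(read = sprintf("r%03d", seq_len(n)), genomes = sets,
               stringsAsFactors = FALSE)
}
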