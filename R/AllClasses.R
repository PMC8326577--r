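#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames assay<- colData colData<-
NULL

#' MicrobiomeExperiment: sample-taxa relative abundances with cohort metadata
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with the layout used
#' throughout the package: species as rows, samples as columns, a `"relabund"`
#' assay holding per-sample relative abundances (each column sums to 1), and
#' column metadata identifying the subject and diagnosis group of every
#' sample. A `"clr"` assay is added by [clrTransform()].
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [MicrobiomeExperiment()], [clrTransform()], [generateCohort()]
#' @export
setClass("MicrobiomeExperiment", contains = "SummarizedExperiment")

setValidity("MicrobiomeExperiment", function(object) {
    msg <- character()
    if (!"relabund" %in% assayNames(object))
        msg <- c(msg, "assay 'relabund' is required")
    else {
        x <- assay(object, "relabund")
        if (any(x < 0)) msg <- c(msg, "relative abundances must be >= 0")
        cs <- colSums(x)
        if (any(abs(cs - 1) > 1e-6))
            msg <- c(msg, "every sample (column) must sum to 1")
    }
    cd <- colData(object)
    for (f in c("subject", "group"))
        if (!f %in% colnames(cd))
            msg <- c(msg, sprintf("colData field '%s' is required", f))
    if (all(c("subject", "group") %in% colnames(cd))) {
        per <- tapply(as.character(cd$group), as.character(cd$subject),
                      function(g) length(unique(g)))
        if (any(per > 1))
            msg <- c(msg, "each subject must belong to exactly one group")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a MicrobiomeExperiment
#'
#' @param abund numeric matrix of relative abundances, species x samples
#'   (columns sum to 1) with row and column names.
#' @param subject character vector, one subject id per sample.
#' @param group character vector, one diagnosis-group label per sample.
#' @param age,sex optional per-sample metadata used by the classification
#'   stage.
#' @return a [MicrobiomeExperiment-class] object.
#' @examples
#' ab <- matrix(c(.5, .5, .25, .75), 2, dimnames = list(c("sp1", "sp2"),
#'                                                      c("s1", "s2")))
#' me <- MicrobiomeExperiment(ab, subject = c("a", "b"),
#'                            group = c("case", "ctrl"))
#' @export
MicrobiomeExperiment <- function(abund, subject, group, age = NULL,
                                 sex = NULL) {
    stopifnot(is.matrix(abund), !is.null(rownames(abund)),
              !is.null(colnames(abund)),
              length(subject) == ncol(abund), length(group) == ncol(abund))
    cd <- DataFrame(subject = as.character(subject),
                    group = as.character(group),
                    row.names = colnames(abund))
    if (!is.null(age)) cd$age <- as.numeric(age)
    if (!is.null(sex)) cd$sex <- as.character(sex)
    se <- SummarizedExperiment(assays = list(relabund = abund), colData = cd)
    new("MicrobiomeExperiment", se)
}

#' Ground truth of a synthetic cohort
#'
#' Records everything the generator knows: the support and signs of the
#' latent precision matrix (the true association network), the planted
#' differentially abundant species with their log2 fold changes, per-group
#' latent mean vectors, the genome mixture proportions used for read
#' simulation, and the seed.
#'
#' @slot precision true latent precision matrix (D x D).
#' @slot precisionSupport symmetric binary matrix; 1 marks a true edge.
#' @slot edgeSigns sign of the true partial correlation per edge.
#' @slot daSpecies data.frame with columns `species`, `log2fc`, `direction`.
#' @slot groupMeans matrix of per-group latent log-abundance means
#'   (species x groups).
#' @slot genomeProportions named numeric, true mixture proportions.
#' @slot seed integer seed the cohort was generated under.
#' @export
setClass("SyntheticTruth",
    representation(precision = "matrix", precisionSupport = "matrix",
                   edgeSigns = "matrix", daSpecies = "data.frame",
                   groupMeans = "matrix", genomeProportions = "numeric",
                   seed = "integer"))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    s <- object@precisionSupport
    if (nrow(s) != ncol(s) || !isTRUE(all.equal(s, t(s))))
        msg <- c(msg, "precisionSupport must be symmetric")
    if (any(diag(s) != 0))
        msg <- c(msg, "precisionSupport must have a zero diagonal")
    if (nrow(object@daSpecies) &&
        any(abs(object@daSpecies$log2fc) < 1))
        msg <- c(msg, "planted DA species must have |log2 fold change| >= 1")
    if (length(msg)) msg else TRUE
})

#' Signed bacterial association network
#'
#' Unweighted signed graph over species: an edge joins two species whenever
#' the stabilised precision matrix has a nonzero off-diagonal entry; the
#' edge sign is the sign of the corresponding partial correlation.
#'
#' @slot species node universe (character).
#' @slot edges data.frame with columns `from`, `to`, `sign` (+1/-1).
#' @slot precision the stabilised precision matrix the network was built
#'   from (may be of zero size when constructed from an edge list).
#' @seealso [buildNetwork()], [nodeDegrees()], [eigenvectorCentrality()]
#' @export
setClass("AssociationNetwork",
    representation(species = "character", edges = "data.frame",
                   precision = "matrix"))

setValidity("AssociationNetwork", function(object) {
    e <- object@edges
    msg <- character()
    if (!all(c("from", "to", "sign") %in% colnames(e)))
        msg <- c(msg, "edges need columns from, to, sign")
    else {
        if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
        if (!all(c(e$from, e$to) %in% object@species))
            msg <- c(msg, "edge endpoints must be declared species")
        if (nrow(e) && !all(e$sign %in% c(-1, 1)))
            msg <- c(msg, "edge signs must be -1 or +1")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "MicrobiomeExperiment", function(object) {
    cat(class(object), ": ", nrow(object), " species x ", ncol(object),
        " samples\n", sep = "")
    g <- table(colData(object)$group)
    cat("groups: ", paste(names(g), g, sep = "=", collapse = ", "), "\n",
        sep = "")
    cat("assays: ", paste(assayNames(object), collapse = ", "), "\n",
        sep = "")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth: ", nrow(object@precisionSupport), " species, ",
        sum(object@precisionSupport) / 2, " true edges, ",
        nrow(object@daSpecies), " planted DA species (seed ", object@seed,
        ")\n", sep = "")
})

setMethod("show", "AssociationNetwork", function(object) {
    cat("AssociationNetwork: ", length(object@species), " nodes, ",
        nrow(object@edges), " edges (",
        sum(object@edges$sign < 0), " negative)\n", sep = "")
})
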