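#' Read and write sample-taxa matrices as TSV
#'
#' The on-disk layout is one row per sample: columns `sample`, `subject`,
#' `group`, optional `age` and `sex`, then one column per species holding
#' relative abundances.
#'
#' @param x a [MicrobiomeExperiment-class].
#' @param path file path.
#' @return `writeTaxaMatrix` returns `path` invisibly; `readTaxaMatrix`
#'   returns a [MicrobiomeExperiment-class].
#' @export
writeTaxaMatrix <- function(x, path) {
    cd <- colData(x)
    df <- data.frame(sample = colnames(x), subject = cd$subject,
                     group = cd$group, stringsAsFactors = FALSE)
    if ("age" %in% colnames(cd)) df$age <- cd$age
    if ("sex" %in% colnames(cd)) df$sex <- cd$sex
    df <- cbind(df, as.data.frame(t(relAbundance(x))))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeTaxaMatrix
#' @export
readTaxaMatrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    meta <- intersect(c("sample", "subject", "group", "age", "sex"),
                      colnames(df))
    sp <- setdiff(colnames(df), meta)
    ab <- t(as.matrix(df[, sp, drop = FALSE]))
    colnames(ab) <- df$sample
    MicrobiomeExperiment(ab, subject = df$subject, group = df$group,
                         age = if ("age" %in% meta) df$age,
                         sex = if ("sex" %in% meta) df$sex)
}

#' Read a read-compatibility table from TSV
#'
#' Expected columns: `read` and `genomes` (comma-separated genome ids),
#' e.g. produced by an external SAM/BAM converter.
#'
#' @param path file path.
#' @return data.frame usable by [emEstimate()].
#' @export
readCompatibilityTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("read", "genomes") %in% colnames(df)))
    df
}

#' Write an association network
#'
#' Writes the signed edge list as TSV (`from`, `to`, `sign`) and
#' optionally the graph as GraphML.
#'
#' @param net an [AssociationNetwork-class].
#' @param edgePath TSV path for the edge list.
#' @param graphmlPath optional GraphML path.
#' @return `edgePath` invisibly.
#' @export
writeNetwork <- function(net, edgePath, graphmlPath = NULL) {
    utils::write.table(edgeTable(net), edgePath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(graphmlPath)) {
        g <- igraph::graph_from_data_frame(
            edgeTable(net), directed = FALSE,
            vertices = data.frame(name = net@species))
        igraph::write_graph(g, graphmlPath, format = "graphml")
    }
    invisible(edgePath)
}

#' Subset an experiment to a species set and re-close
#'
#' Restricting a composition to a subset of its parts breaks the unit
#' sum, so columns are renormalised; any existing `"clr"` assay is
#' recomputed on the sub-composition.
#'
#' @param x a [MicrobiomeExperiment-class].
#' @param species species ids to retain.
#' @return a re-closed [MicrobiomeExperiment-class].
#' @export
subsetSpecies <- function(x, species) {
    stopifnot(all(species %in% rownames(x)))
    ab <- relAbundance(x)[species, , drop = FALSE]
    cs <- colSums(ab)
    if (any(cs == 0)) stop("a sample has zero abundance over the subset")
    ab <- sweep(ab, 2, cs, "/")
    cd <- colData(x)
    out <- MicrobiomeExperiment(ab, subject = cd$subject, group = cd$group,
                                age = if ("age" %in% colnames(cd)) cd$age,
                                sex = if ("sex" %in% colnames(cd)) cd$sex)
    if ("clr" %in% assayNames(x)) {
        zp <- metadata(x)$zeroPolicy
        out <- clrTransform(out, zeroPolicy = zp$policy, pseudo = zp$pseudo)
    }
    out
}
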