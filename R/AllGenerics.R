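#' Accessors for package classes
#'
#' `relAbundance()` returns the species x samples relative-abundance matrix;
#' `clrValues()` the CLR-transformed matrix (computed by [clrTransform()]);
#' `subjectIds()` and `groupLabels()` the per-sample annotations;
#' `edgeTable()` the signed edge list of a network; `nodeDegrees()` the
#' per-node degree on the unsigned graph.
#'
#' @param object a [MicrobiomeExperiment-class] or
#'   [AssociationNetwork-class].
#' @return matrix, character vector or data.frame as described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("relAbundance", function(object) standardGeneric("relAbundance"))

#' @rdname accessors
#' @export
setGeneric("clrValues", function(object) standardGeneric("clrValues"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(object) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("nodeDegrees", function(object) standardGeneric("nodeDegrees"))

#' @rdname accessors
#' @export
setMethod("relAbundance", "MicrobiomeExperiment",
          function(object) assay(object, "relabund"))

#' @rdname accessors
#' @export
setMethod("clrValues", "MicrobiomeExperiment", function(object) {
    if (!"clr" %in% assayNames(object))
        stop("no 'clr' assay: run clrTransform() first")
    assay(object, "clr")
})

#' @rdname accessors
#' @export
setMethod("subjectIds", "MicrobiomeExperiment",
          function(object) as.character(colData(object)$subject))

#' @rdname accessors
#' @export
setMethod("groupLabels", "MicrobiomeExperiment",
          function(object) as.character(colData(object)$group))

#' @rdname accessors
#' @export
setMethod("edgeTable", "AssociationNetwork", function(object) object@edges)

#' @rdname accessors
#' @export
setMethod("nodeDegrees", "AssociationNetwork", function(object) {
    d <- stats::setNames(integer(length(object@species)), object@species)
    if (nrow(object@edges)) {
        t1 <- table(c(object@edges$from, object@edges$to))
        d[names(t1)] <- as.integer(t1)
    }
    d
})
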