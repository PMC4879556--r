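#' Accessors for discoex S4 containers
#'
#' Small accessor generics in the Bioconductor style: slot access from user
#' code should go through these rather than \code{@}.
#'
#' @param object an S4 object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("arrayIds", function(object) standardGeneric("arrayIds"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("scaleTag", function(object) standardGeneric("scaleTag"))
#' @rdname accessors
#' @export
setGeneric("selectionTable", function(object) standardGeneric("selectionTable"))
#' @rdname accessors
#' @export
setGeneric("selectedArrays", function(object) standardGeneric("selectedArrays"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("excludedGenes", function(object) standardGeneric("excludedGenes"))
#' @rdname accessors
#' @export
setGeneric("networkParams", function(object) standardGeneric("networkParams"))
#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(object) standardGeneric("clusterMembers"))
#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(object) standardGeneric("clusterSizes"))
#' @rdname accessors
#' @export
setGeneric("remainderGenes", function(object) standardGeneric("remainderGenes"))
#' @rdname accessors
#' @export
setGeneric("promoterSequences",
    function(object) standardGeneric("promoterSequences"))
#' @rdname accessors
#' @export
setGeneric("promoterMask", function(object) standardGeneric("promoterMask"))
#' @rdname accessors
#' @export
setGeneric("promoterInfo", function(object) standardGeneric("promoterInfo"))
#' @rdname accessors
#' @export
setGeneric("motifPPM", function(object) standardGeneric("motifPPM"))
#' @rdname accessors
#' @export
setGeneric("motifSites", function(object) standardGeneric("motifSites"))
#' @rdname accessors
#' @export
setGeneric("motifWidth", function(object) standardGeneric("motifWidth"))
#' @rdname accessors
#' @export
setGeneric("motifName", function(object) standardGeneric("motifName"))
#' @rdname accessors
#' @export
setGeneric("motifLLR", function(object) standardGeneric("motifLLR"))
#' @rdname accessors
#' @export
setGeneric("emTrace", function(object) standardGeneric("emTrace"))
#' @rdname accessors
#' @export
setGeneric("annotationMapping",
    function(object) standardGeneric("annotationMapping"))
#' @rdname accessors
#' @export
setGeneric("annotationUniverse",
    function(object) standardGeneric("annotationUniverse"))
#' @rdname accessors
#' @export
setGeneric("backgroundOrder",
    function(object) standardGeneric("backgroundOrder"))
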