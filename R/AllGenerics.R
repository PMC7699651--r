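#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setGeneric("layerName", function(x) standardGeneric("layerName"))
#' @rdname accessors
#' @export
setGeneric("isDirected", function(x) standardGeneric("isDirected"))
#' @rdname accessors
#' @export
setGeneric("layerNodes", function(x) standardGeneric("layerNodes"))
#' @rdname accessors
#' @export
setGeneric("layerEdges", function(x) standardGeneric("layerEdges"))
#' @rdname accessors
#' @export
setGeneric("grnLayer", function(x) standardGeneric("grnLayer"))
#' @rdname accessors
#' @export
setGeneric("ppiLayer", function(x) standardGeneric("ppiLayer"))
#' @rdname accessors
#' @export
setGeneric("metLayer", function(x) standardGeneric("metLayer"))
#' @rdname accessors
#' @export
setGeneric("geneProteinMap", function(x) standardGeneric("geneProteinMap"))
#' @rdname accessors
#' @export
setGeneric("proteinMetaboliteMap",
           function(x) standardGeneric("proteinMetaboliteMap"))
#' @rdname accessors
#' @export
setGeneric("supportDegrees", function(x) standardGeneric("supportDegrees"))

#' @rdname cascadeAccessors
#' @export
setGeneric("finalFractions", function(x) standardGeneric("finalFractions"))
#' @rdname cascadeAccessors
#' @export
setGeneric("failedNodes",
           function(x, layer = c("gene", "protein", "metabolite"), round = NULL)
             standardGeneric("failedNodes"))
#' @rdname cascadeAccessors
#' @export
setGeneric("nRounds", function(x) standardGeneric("nRounds"))

#' @rdname gfEval
#' @export
setGeneric("gfEval", function(gf, x) standardGeneric("gfEval"))
#' @rdname gfEval
#' @export
setGeneric("gfBranch", function(gf, x) standardGeneric("gfBranch"))
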