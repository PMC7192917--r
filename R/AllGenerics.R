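# Accessor generics. Slot access outside the package should go through these.

#' @title Accessors
#' @description Accessor generics for the package's S4 classes.
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))
#' @rdname accessors
#' @export
setGeneric("ppiGraph", function(x) standardGeneric("ppiGraph"))
#' @rdname accessors
#' @export
setGeneric("ppiNodes", function(x) standardGeneric("ppiNodes"))
#' @rdname accessors
#' @export
setGeneric("ppiEdges", function(x) standardGeneric("ppiEdges"))
#' @rdname accessors
#' @export
setGeneric("moduleSupport", function(x) standardGeneric("moduleSupport"))
#' @rdname accessors
#' @export
setGeneric("moduleActivity", function(x) standardGeneric("moduleActivity"))
#' @rdname accessors
#' @export
setGeneric("moduleLoading", function(x) standardGeneric("moduleLoading"))
#' @rdname accessors
#' @export
setGeneric("residualError", function(x) standardGeneric("residualError"))
#' @rdname accessors
#' @export
setGeneric("modules", function(x) standardGeneric("modules"))
#' @rdname accessors
#' @export
setGeneric("globalResidual", function(x) standardGeneric("globalResidual"))
#' @rdname accessors
#' @export
setGeneric("phenoData", function(x) standardGeneric("phenoData"))
#' @rdname accessors
#' @export
setGeneric("phenotypeName", function(x) standardGeneric("phenotypeName"))
#' @rdname accessors
#' @export
setGeneric("rhoValues", function(x) standardGeneric("rhoValues"))

#' @rdname accessors
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)
#' @rdname accessors
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("cellIds", "ExpressionMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("stage", "ExpressionMatrix", function(x) x@stage)
#' @rdname accessors
setMethod("ppiGraph", "PPIGraph", function(x) x@graph)
#' @rdname accessors
setMethod("ppiNodes", "PPIGraph", function(x) igraph::V(x@graph)$name)
#' @rdname accessors
setMethod("ppiEdges", "PPIGraph", function(x) {
  e <- igraph::as_edgelist(x@graph, names = TRUE)
  colnames(e) <- c("from", "to")
  e
})
#' @rdname accessors
setMethod("moduleSupport", "NetworkModule", function(x) x@support)
#' @rdname accessors
setMethod("moduleActivity", "NetworkModule", function(x) x@activity)
#' @rdname accessors
setMethod("moduleLoading", "NetworkModule", function(x) x@loading)
#' @rdname accessors
setMethod("residualError", "NetworkModule", function(x) x@residualError)
#' @rdname accessors
setMethod("modules", "Decomposition", function(x) x@modules)
#' @rdname accessors
setMethod("globalResidual", "Decomposition", function(x) x@globalResidual)
#' @rdname accessors
setMethod("phenoData", "PhenotypeTable", function(x) x@data)
#' @rdname accessors
setMethod("phenotypeName", "PhenotypeCorrelation", function(x) x@phenotype)
#' @rdname accessors
setMethod("phenotypeName", "CellProjection", function(x) x@phenotype)
#' @rdname accessors
setMethod("rhoValues", "PhenotypeCorrelation", function(x) x@rho)
#' @rdname accessors
setMethod("rhoValues", "CellProjection", function(x) x@rho)
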