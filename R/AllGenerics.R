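#' @rdname MetabolicModel-class
#' @param x,object a `MetabolicModel`, `OntologyGraph`, `BackgroundTable`
#'   or `FluxState`.
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("pathways", function(x) standardGeneric("pathways"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("biomassReaction", function(x) standardGeneric("biomassReaction"))

#' @rdname MetabolicModel-class
#' @export
setGeneric("exchangeReactions", function(x) standardGeneric("exchangeReactions"))

#' @rdname OntologyGraph-class
#' @param x an `OntologyGraph`.
#' @export
setGeneric("ontologyTerms", function(x) standardGeneric("ontologyTerms"))

#' @rdname OntologyGraph-class
#' @export
setGeneric("isaEdges", function(x) standardGeneric("isaEdges"))

#' @rdname BackgroundTable-class
#' @export
setGeneric("backgroundStats", function(x) standardGeneric("backgroundStats"))

#' @rdname FluxState-class
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' @rdname FluxState-class
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname FluxState-class
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))
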