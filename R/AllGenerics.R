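#' @title Generics and accessors
#' @name ESSim-generics
#' @description Accessor generics for the package's S4 classes. Slots are
#'   never meant to be reached with `@` by users.
NULL

#' @rdname ESSim-generics
#' @param object an ESSim S4 object.
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @rdname ESSim-generics
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))

#' @rdname ESSim-generics
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname ESSim-generics
#' @export
setGeneric("objectiveId", function(object) standardGeneric("objectiveId"))

#' @rdname ESSim-generics
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))

#' @rdname ESSim-generics
#' @export
setGeneric("reactionBounds", function(object) standardGeneric("reactionBounds"))

#' @rdname ESSim-generics
#' @export
setGeneric("gprRules", function(object) standardGeneric("gprRules"))

#' @rdname ESSim-generics
#' @export
setGeneric("escores", function(object) standardGeneric("escores"))

#' @rdname ESSim-generics
#' @param level cardinality of the stored sets to return; NULL for all.
#' @export
setGeneric("lethalSets", function(object, level = NULL) standardGeneric("lethalSets"))

#' @rdname ESSim-generics
#' @export
setGeneric("candidateIds", function(object) standardGeneric("candidateIds"))

#' @rdname ESSim-generics
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @rdname ESSim-generics
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' @rdname ESSim-generics
#' @export
setGeneric("solutionStatus", function(object) standardGeneric("solutionStatus"))

#' @rdname ESSim-generics
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))

#' @rdname ESSim-generics
#' @export
setGeneric("graphNodes", function(object) standardGeneric("graphNodes"))

#' @rdname ESSim-generics
#' @export
setGeneric("comparisonTable", function(object) standardGeneric("comparisonTable"))

#' @rdname ESSim-generics
#' @export
setGeneric("comparisonSummary", function(object) standardGeneric("comparisonSummary"))
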