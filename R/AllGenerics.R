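#' @name meomics-accessors
#' @title Accessors for MEModel and GrowthSolution objects
#' @param object an [MEModel-class] or [GrowthSolution-class].
#' @param ... passed to methods.
#' @return `metabolites`, `genes`, `expressionSubsystems` return character
#'   vectors; `reactions` the reaction table (data.frame); `stoichiometry`
#'   the affine coefficient table; `growthReaction` and `muMaxHint` scalars;
#'   `translationReaction` the translation reaction id of a gene;
#'   `reactionSubsystems` a named character of subsystem labels;
#'   `muStar` / `fluxes` / `solutionStatus` the solution components.
NULL

#' @rdname meomics-accessors
#' @export
setGeneric("metabolites", function(object, ...) standardGeneric("metabolites"))
#' @rdname meomics-accessors
#' @export
setGeneric("reactions", function(object, ...) standardGeneric("reactions"))
#' @rdname meomics-accessors
#' @export
setGeneric("stoichiometry", function(object, ...) standardGeneric("stoichiometry"))
#' @rdname meomics-accessors
#' @export
setGeneric("genes", function(object, ...) standardGeneric("genes"))
#' @rdname meomics-accessors
#' @export
setGeneric("growthReaction", function(object, ...) standardGeneric("growthReaction"))
#' @rdname meomics-accessors
#' @export
setGeneric("muMaxHint", function(object, ...) standardGeneric("muMaxHint"))
#' @rdname meomics-accessors
#' @export
setGeneric("expressionSubsystems", function(object, ...) standardGeneric("expressionSubsystems"))
#' @rdname meomics-accessors
#' @param gene gene identifier.
#' @export
setGeneric("translationReaction", function(object, gene, ...) standardGeneric("translationReaction"))
#' @rdname meomics-accessors
#' @export
setGeneric("reactionSubsystems", function(object, ...) standardGeneric("reactionSubsystems"))
#' @rdname meomics-accessors
#' @export
setGeneric("muStar", function(object, ...) standardGeneric("muStar"))
#' @rdname meomics-accessors
#' @export
setGeneric("fluxes", function(object, ...) standardGeneric("fluxes"))
#' @rdname meomics-accessors
#' @export
setGeneric("solutionStatus", function(object, ...) standardGeneric("solutionStatus"))

#' @rdname meomics-accessors
setMethod("metabolites", "MEModel", function(object, ...) object@metabolites)
#' @rdname meomics-accessors
setMethod("reactions", "MEModel", function(object, ...) object@reactions)
#' @rdname meomics-accessors
setMethod("stoichiometry", "MEModel", function(object, ...) object@stoichiometry)
#' @rdname meomics-accessors
setMethod("genes", "MEModel", function(object, ...) object@genes)
#' @rdname meomics-accessors
setMethod("growthReaction", "MEModel", function(object, ...) object@growthReactionId)
#' @rdname meomics-accessors
setMethod("muMaxHint", "MEModel", function(object, ...) object@muMaxHint)
#' @rdname meomics-accessors
setMethod("expressionSubsystems", "MEModel",
          function(object, ...) object@expressionSubsystems)
#' @rdname meomics-accessors
setMethod("translationReaction", "MEModel", function(object, gene, ...) {
  if (!gene %in% names(object@translationOf)) {
    stop("unknown gene: ", gene, call. = FALSE)
  }
  unname(object@translationOf[gene])
})
#' @rdname meomics-accessors
setMethod("reactionSubsystems", "MEModel", function(object, ...) {
  setNames(object@reactions$subsystem, object@reactions$id)
})
#' @rdname meomics-accessors
setMethod("muStar", "GrowthSolution", function(object, ...) object@muStar)
#' @rdname meomics-accessors
setMethod("fluxes", "GrowthSolution", function(object, ...) object@fluxes)
#' @rdname meomics-accessors
setMethod("solutionStatus", "GrowthSolution", function(object, ...) object@status)

#' @rdname evaluateStoichiometry
#' @export
setGeneric("evaluateStoichiometry", function(model, mu, ...)
  standardGeneric("evaluateStoichiometry"))
#' @rdname isFeasible
#' @export
setGeneric("isFeasible", function(model, mu, ...) standardGeneric("isFeasible"))
#' @rdname maximizeGrowth
#' @export
setGeneric("maximizeGrowth", function(model, ...) standardGeneric("maximizeGrowth"))
#' @rdname fluxVariability
#' @export
setGeneric("fluxVariability", function(model, muStar, ...)
  standardGeneric("fluxVariability"))
#' @rdname geneEssentiality
#' @export
setGeneric("geneEssentiality", function(model, gene, ...)
  standardGeneric("geneEssentiality"))
#' @rdname substrateScan
#' @export
setGeneric("substrateScan", function(model, exchangeId, uptakeValues, ...)
  standardGeneric("substrateScan"))
#' @rdname stripExpression
#' @export
setGeneric("stripExpression", function(model, ...) standardGeneric("stripExpression"))
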