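#' @describeIn ESSim-generics reaction ids of a model.
setMethod("reactionIds", "MetabolicModel", function(object) object@reactions$id)

#' @describeIn ESSim-generics metabolite ids of a model.
setMethod("metaboliteIds", "MetabolicModel", function(object) object@metabolites$id)

#' @describeIn ESSim-generics gene ids of a model.
setMethod("geneIds", "MetabolicModel", function(object) object@genes)

#' @describeIn ESSim-generics objective reaction id.
setMethod("objectiveId", "MetabolicModel", function(object) object@objectiveId)

#' @describeIn ESSim-generics sparse stoichiometric matrix.
setMethod("stoichiometry", "MetabolicModel", function(object) object@stoichiometry)

#' @describeIn ESSim-generics data.frame of id, lower_bound, upper_bound.
setMethod("reactionBounds", "MetabolicModel", function(object)
  object@reactions[, c("id", "lower_bound", "upper_bound")])

#' @describeIn ESSim-generics named list of parsed GPR trees (NULL = none).
setMethod("gprRules", "MetabolicModel", function(object) object@gpr)

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel '", object@modelId, "'\n", sep = "")
  cat("  ", nrow(object@reactions), " reactions, ",
      nrow(object@metabolites), " metabolites, ",
      length(object@genes), " genes\n", sep = "")
  cat("  objective: ", object@objectiveId, "\n", sep = "")
})

#' @describeIn ESSim-generics named flux vector of a solution.
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)

#' @describeIn ESSim-generics objective value of a solution.
setMethod("objectiveValue", "FluxSolution", function(object) object@objectiveValue)

#' @describeIn ESSim-generics solver status of a solution.
setMethod("solutionStatus", "FluxSolution", function(object) object@status)

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution:", object@status,
      sprintf("(objective = %.6g)\n", object@objectiveValue))
})

#' @describeIn ESSim-generics stored minimal lethal sets, optionally of one
#'   cardinality.
setMethod("lethalSets", "LethalSetCollection", function(object, level = NULL) {
  if (is.null(level)) return(object@setsByLevel)
  stopifnot(level >= 1, level <= object@levelN)
  object@setsByLevel[[as.character(level)]]
})

#' @describeIn ESSim-generics analyzed candidate ids (length = X).
setMethod("candidateIds", "LethalSetCollection", function(object) object@candidateIds)

setMethod("show", "LethalSetCollection", function(object) {
  cat("LethalSetCollection (", object@targetKind, ", level ",
      object@levelN, ")\n", sep = "")
  cat("  candidates (X): ", length(object@candidateIds), "\n", sep = "")
  for (j in seq_len(object@levelN))
    cat("  level ", j, ": ", length(object@setsByLevel[[j]]),
        " minimal lethal sets\n", sep = "")
})

#' @describeIn ESSim-generics named numeric score vector of an EScoreTable.
setMethod("escores", "EScoreTable", function(object) object@scores)

#' @describeIn ESSim-generics candidate ids of an EScoreTable.
setMethod("candidateIds", "EScoreTable", function(object) names(object@scores))

setMethod("show", "EScoreTable", function(object) {
  cat("EScoreTable (", object@targetKind, ", level ", object@levelN,
      ", X = ", object@X, ")\n", sep = "")
  s <- sort(object@scores, decreasing = TRUE)
  cat("  essential (score 1): ", sum(object@scores >= 1 - 1e-12),
      "; non-zero: ", sum(object@scores > 0), " of ", length(s), "\n", sep = "")
  print(head(round(s, 6), 5))
})

setMethod("show", "InvolvementCounts", function(object) {
  cat("InvolvementCounts for", object@targetId, "\n")
  print(object@y)
})

#' @describeIn ESSim-generics edge data.frame of a derived graph.
setMethod("graphEdges", "DerivedGraph", function(object) object@edges)

#' @describeIn ESSim-generics node ids of a derived graph.
setMethod("graphNodes", "DerivedGraph", function(object) object@nodes)

setMethod("show", "DerivedGraph", function(object) {
  cat("DerivedGraph ", toupper(object@kind), ": ", length(object@nodes),
      " nodes, ", nrow(object@edges), " directed edges",
      if (length(object@currencyRemoved))
        paste0(" (", length(object@currencyRemoved), " currency metabolites removed)"),
      "\n", sep = "")
})

#' @describeIn ESSim-generics per-target comparison data.frame.
setMethod("comparisonTable", "ComparisonReport", function(object) object@table)

#' @describeIn ESSim-generics summary list of a comparison.
setMethod("comparisonSummary", "ComparisonReport", function(object) object@summary)

setMethod("show", "ComparisonReport", function(object) {
  s <- object@summary
  cat("ComparisonReport:", nrow(object@table), "targets\n")
  cat(sprintf("  up %d / down %d / unchanged %d\n", s$up, s$down, s$unchanged))
  cat(sprintf("  mean score: a = %.6g, b = %.6g\n", s$mean_a, s$mean_b))
})
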