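#' @title Core S4 classes
#' @name ESSim-classes
#' @description S4 containers for metabolic models, flux solutions,
#'   minimal-lethal-set collections, essentiality score tables, derived
#'   topology graphs and cross-model comparison reports.
NULL

#' MetabolicModel: a constraint-based metabolic model
#'
#' Holds the stoichiometric matrix (metabolites x reactions), per-reaction
#' flux bounds in mmol/gDW/h, gene-protein-reaction (GPR) boolean rules and
#' the identifier of the objective reaction. Reversibility is encoded
#' purely in the bounds (negative lower bound), never by duplicating
#' reactions, so knocking out a reaction id silences both directions.
#'
#' @slot modelId character model identifier.
#' @slot stoichiometry a [Matrix::dgCMatrix-class], rows named by
#'   metabolite id, columns by reaction id; negative = consumed.
#' @slot metabolites data.frame with columns `id`, `name`, `compartment`.
#' @slot reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gpr` (rule string, "" if none), `subsystem`.
#' @slot gpr named list of parsed GPR expression trees (NULL when absent).
#' @slot genes character vector of gene ids (declared genes plus every
#'   gene referenced by a GPR).
#' @slot objectiveId id of the reaction whose flux is maximized.
#' @exportClass MetabolicModel
setClass("MetabolicModel",
  representation(
    modelId = "character",
    stoichiometry = "dgCMatrix",
    metabolites = "data.frame",
    reactions = "data.frame",
    gpr = "list",
    genes = "character",
    objectiveId = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character()
  mid <- object@metabolites$id
  rid <- object@reactions$id
  if (anyDuplicated(mid) || any(!nzchar(mid)))
    msg <- c(msg, "metabolite ids must be non-empty and unique")
  if (anyDuplicated(rid) || any(!nzchar(rid)))
    msg <- c(msg, "reaction ids must be non-empty and unique")
  S <- object@stoichiometry
  if (!identical(dim(S), c(length(mid), length(rid))) ||
      !identical(rownames(S), mid) || !identical(colnames(S), rid))
    msg <- c(msg, "stoichiometry dimnames must match metabolite/reaction ids")
  bad <- object@reactions$lower_bound > object@reactions$upper_bound
  if (any(bad))
    msg <- c(msg, paste0("lower_bound > upper_bound for: ",
                         paste(rid[bad], collapse = ", ")))
  if (length(object@objectiveId) != 1L || !(object@objectiveId %in% rid))
    msg <- c(msg, "objectiveId must name exactly one existing reaction")
  leaves <- unique(unlist(lapply(object@gpr, gprGenes), use.names = FALSE))
  orphan <- setdiff(leaves, object@genes)
  if (length(orphan))
    msg <- c(msg, paste0("GPR references undeclared genes: ",
                         paste(orphan, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' FluxSolution: result of one flux balance analysis
#'
#' @slot status "optimal" or "infeasible".
#' @slot objectiveValue flux through the objective reaction (0 when
#'   infeasible).
#' @slot fluxes named numeric vector of reaction fluxes (empty when
#'   infeasible).
#' @exportClass FluxSolution
setClass("FluxSolution",
  representation(status = "character", objectiveValue = "numeric",
                 fluxes = "numeric")
)

#' AnalysisConfig: parameters of an essentiality analysis
#'
#' @slot levelN maximal cardinality of knockout sets searched (>= 1).
#' @slot targets "reactions" or "genes".
#' @slot excludedIds ids removed from knockout candidacy (pseudo reactions
#'   such as maintenance ATPases); the objective reaction is always
#'   excluded automatically.
#' @slot lethalityEpsilon absolute objective-flux cutoff below which a
#'   knockout counts as lethal; `NA` selects the default
#'   `max(1e-6, 0.05 * wild-type objective)`.
#' @slot solverName LP backend name (only "simplex" is built in).
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
  representation(levelN = "integer", targets = "character",
                 excludedIds = "character", lethalityEpsilon = "numeric",
                 solverName = "character")
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (length(object@levelN) != 1L || is.na(object@levelN) || object@levelN < 1L)
    msg <- c(msg, "levelN must be a single integer >= 1")
  if (!object@targets %in% c("reactions", "genes"))
    msg <- c(msg, "targets must be 'reactions' or 'genes'")
  if (length(msg)) msg else TRUE
})

#' Create an analysis configuration
#'
#' @param levelN maximal knockout-set cardinality searched (default 3,
#'   balancing resolution against cost).
#' @param targets knock out `"reactions"` or `"genes"`.
#' @param excludedIds reaction/gene ids excluded from candidacy.
#' @param lethalityEpsilon absolute lethality cutoff on the objective flux;
#'   `NA` (default) uses `max(1e-6, 0.05 * wild-type objective)`, i.e. a
#'   knockout is lethal when it destroys at least 95% of the attainable
#'   objective.
#' @param solverName LP backend identifier.
#' @return an [AnalysisConfig-class] object.
#' @examples
#' analysisConfig(levelN = 2, excludedIds = "ATPM")
#' @export
analysisConfig <- function(levelN = 3L, targets = c("reactions", "genes"),
                           excludedIds = character(),
                           lethalityEpsilon = NA_real_,
                           solverName = "simplex") {
  new("AnalysisConfig", levelN = as.integer(levelN),
      targets = match.arg(targets),
      excludedIds = as.character(excludedIds),
      lethalityEpsilon = as.numeric(lethalityEpsilon),
      solverName = solverName)
}

#' LethalSetCollection: minimal lethal knockout sets grouped by cardinality
#'
#' Stores, for each level j in 1..levelN, the unordered id-sets of
#' cardinality j whose knockout abolishes the objective while no proper
#' subset does ("true" synthetic lethals). Level 1 holds the essential
#' singletons.
#'
#' @slot levelN maximal cardinality searched.
#' @slot targetKind "reactions" or "genes".
#' @slot setsByLevel list indexed "1".."levelN"; each element a list of
#'   sorted character vectors.
#' @slot candidateIds ordered ids analyzed; its length is the
#'   normalization constant X.
#' @exportClass LethalSetCollection
setClass("LethalSetCollection",
  representation(levelN = "integer", targetKind = "character",
                 setsByLevel = "list", candidateIds = "character")
)

setValidity("LethalSetCollection", function(object) {
  msg <- character()
  lv <- object@setsByLevel
  if (!identical(names(lv), as.character(seq_len(object@levelN))))
    msg <- c(msg, "setsByLevel must be named '1'..'levelN'")
  all_sets <- unlist(lv, recursive = FALSE, use.names = FALSE)
  for (j in seq_along(lv)) {
    sz <- lengths(lv[[j]])
    if (length(sz) && any(sz != j))
      msg <- c(msg, sprintf("level %d contains sets of wrong cardinality", j))
  }
  ids <- unique(unlist(all_sets, use.names = FALSE))
  if (length(setdiff(ids, object@candidateIds)))
    msg <- c(msg, "stored sets reference ids outside candidateIds")
  # minimality: no stored set contains another stored set
  if (length(all_sets) > 1L) {
    keys <- vapply(all_sets, paste, "", collapse = "\r")
    if (anyDuplicated(keys)) msg <- c(msg, "duplicate stored sets")
    srt <- all_sets[order(lengths(all_sets))]
    for (a in seq_along(srt)) {
      for (b in seq_len(a - 1L)) {
        if (length(srt[[b]]) < length(srt[[a]]) &&
            all(srt[[b]] %in% srt[[a]])) {
          msg <- c(msg, "minimality violated: a stored set contains another")
          break
        }
      }
      if (length(msg)) break
    }
  }
  if (length(msg)) msg else TRUE
})

#' EScoreTable: per-target essentiality scores
#'
#' The score of target i is
#' \deqn{ES_i = y_{i1} + \sum_{j=2}^{n} y_{ij} (j-1)! / X^{j-1}}
#' where \eqn{y_{ij}} counts the minimal lethal sets of cardinality j that
#' contain i and X is the number of candidate targets. Essential targets
#' score exactly 1; scores are expected to lie in [0, 1] (a violation is
#' reported as a warning, never silently clamped).
#'
#' @slot scores named numeric vector over all candidate ids.
#' @slot counts integer matrix of involvement counts, candidates x levels.
#' @slot X number of candidate targets (normalization base).
#' @slot levelN analysis level.
#' @slot targetKind "reactions" or "genes".
#' @exportClass EScoreTable
setClass("EScoreTable",
  representation(scores = "numeric", counts = "matrix", X = "integer",
                 levelN = "integer", targetKind = "character")
)

#' InvolvementCounts: per-level lethal-set membership of one target
#'
#' @slot targetId the target.
#' @slot y named integer vector, `y[j]` = number of stored cardinality-j
#'   minimal lethal sets containing the target.
#' @exportClass InvolvementCounts
setClass("InvolvementCounts",
  representation(targetId = "character", y = "integer"))

#' DerivedGraph: directed graph derived from a metabolic model
#'
#' Metabolite-metabolite (MMN), reaction-reaction (RRN) or gene-gene (GGN)
#' connectivity graph. For RRN/GGN, currency metabolites (ubiquitous
#' cofactors/carriers) are removed before edges are drawn so that they do
#' not create spurious shortcuts.
#'
#' @slot kind "mmn", "rrn" or "ggn".
#' @slot nodes node ids.
#' @slot edges data.frame with columns `from`, `to` (no self-loops).
#' @slot currencyRemoved metabolite ids excluded during construction.
#' @exportClass DerivedGraph
setClass("DerivedGraph",
  representation(kind = "character", nodes = "character",
                 edges = "data.frame", currencyRemoved = "character")
)

setValidity("DerivedGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("from", "to") %in% names(e)))
    msg <- c(msg, "edges needs 'from' and 'to' columns")
  else {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    if (length(setdiff(c(e$from, e$to), object@nodes)))
      msg <- c(msg, "edges reference undeclared nodes")
  }
  if (length(msg)) msg else TRUE
})

#' ComparisonReport: per-target deltas between two score tables
#'
#' @slot table data.frame with columns `id`, `score_a`, `score_b`,
#'   `delta` (b - a) and `status` (up/down/unchanged/only_a/only_b).
#' @slot summary list with up/down/unchanged counts and mean score per
#'   model.
#' @exportClass ComparisonReport
setClass("ComparisonReport",
  representation(table = "data.frame", summary = "list"))
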