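#' Construct a MetabolicModel from parts
#'
#' Lower-level constructor used by the readers and the fixture
#' generators. Zero stoichiometric coefficients are dropped; the gene
#' list is the union of declared genes and every GPR leaf.
#'
#' @param modelId model identifier.
#' @param metabolites data.frame with columns `id` and optionally `name`,
#'   `compartment`.
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound` and optionally `name`, `gpr`, `subsystem`.
#' @param stoichiometry list named by reaction id; each element a named
#'   numeric vector of metabolite coefficients (negative = consumed).
#' @param objectiveId reaction id to maximize.
#' @param genes optional declared gene ids.
#' @return a validated [MetabolicModel-class].
#' @export
metabolicModel <- function(modelId, metabolites, reactions, stoichiometry,
                           objectiveId, genes = character()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  mids <- metabolites$id
  rids <- reactions$id

  i <- integer(); j <- integer(); x <- numeric()
  for (k in seq_along(rids)) {
    sto <- stoichiometry[[rids[k]]]
    if (is.null(sto)) next
    sto <- sto[sto != 0]
    if (!length(sto)) next
    mi <- match(names(sto), mids)
    if (anyNA(mi))
      stop("reaction '", rids[k], "' references unknown metabolites: ",
           paste(names(sto)[is.na(mi)], collapse = ", "))
    i <- c(i, mi); j <- c(j, rep(k, length(sto))); x <- c(x, unname(sto))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(mids), length(rids)),
                            dimnames = list(mids, rids))
  gpr <- list()
  for (k in seq_along(rids)) {
    tree <- parseGPR(reactions$gpr[k])
    if (!is.null(tree)) gpr[[rids[k]]] <- tree
  }
  leaves <- unique(unlist(lapply(gpr, gprGenes), use.names = FALSE))
  genes <- sort(unique(c(as.character(genes), leaves)))
  m <- new("MetabolicModel", modelId = as.character(modelId),
           stoichiometry = as(S, "CsparseMatrix"),
           metabolites = metabolites[, c("id", "name", "compartment")],
           reactions = reactions[, c("id", "name", "lower_bound",
                                     "upper_bound", "gpr", "subsystem")],
           gpr = gpr, genes = genes, objectiveId = as.character(objectiveId))
  validObject(m)
  m
}

#' Knock out reactions or genes
#'
#' Reaction targets have both flux bounds set to zero. Gene targets
#' disable every reaction whose GPR rule evaluates FALSE under the
#' deletion set (reactions without a rule are untouched). The input model
#' is never modified. The operation is idempotent and order-independent.
#'
#' @param model a [MetabolicModel-class].
#' @param targetIds ids to delete.
#' @param targets `"reactions"` or `"genes"`.
#' @return a new model with the knockout applied.
#' @examples
#' m <- fig1aModel()
#' reactionBounds(applyKnockout(m, "A"))
#' @export
applyKnockout <- function(model, targetIds,
                          targets = c("reactions", "genes")) {
  stopifnot(is(model, "MetabolicModel"))
  targets <- match.arg(targets)
  targetIds <- unique(as.character(targetIds))
  if (!length(targetIds)) return(model)
  if (targets == "reactions") {
    unknown <- setdiff(targetIds, model@reactions$id)
    if (length(unknown))
      stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
    off <- targetIds
  } else {
    unknown <- setdiff(targetIds, model@genes)
    if (length(unknown))
      stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
    off <- .disabledReactions(model, targetIds)
  }
  k <- model@reactions$id %in% off
  model@reactions$lower_bound[k] <- 0
  model@reactions$upper_bound[k] <- 0
  model
}

#' Tabular model summary
#'
#' @param model a [MetabolicModel-class].
#' @param path optional TSV destination; when given, the table is written
#'   with columns id, lower_bound, upper_bound, gpr.
#' @return the summary data.frame, invisibly when written.
#' @export
modelSummary <- function(model, path = NULL) {
  df <- model@reactions[, c("id", "lower_bound", "upper_bound", "gpr")]
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
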