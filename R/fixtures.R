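## Built-in toy models and the parametric synthetic-model generator.
##
## The toys are defined by their minimal-lethal-set structure (which the
## worked examples pin down exactly) rather than by any particular
## drawing: the essentiality score depends only on that structure and on
## the candidate count X. All fixture fluxes use unit stoichiometry and
## an uptake bound of 10 so that LP answers are hand-checkable.

.fixtureModel <- function(modelId, reactions, objectiveId) {
  mids <- sort(unique(unlist(lapply(reactions, function(r)
    names(r$sto)), use.names = FALSE)))
  mets <- data.frame(id = mids, name = mids, compartment = "c",
                     stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = vapply(reactions, `[[`, "", "id"),
    name = vapply(reactions, `[[`, "", "id"),
    lower_bound = vapply(reactions, function(r)
      if (is.null(r$lb)) 0 else r$lb, 0),
    upper_bound = vapply(reactions, function(r)
      if (is.null(r$ub)) 1000 else r$ub, 0),
    gpr = vapply(reactions, function(r)
      if (is.null(r$gpr)) "" else r$gpr, ""),
    subsystem = "", stringsAsFactors = FALSE)
  sto <- lapply(reactions, `[[`, "sto")
  names(sto) <- rxns$id
  metabolicModel(modelId, mets, rxns, sto, objectiveId)
}

#' Toy model A: one essential trunk and one synthetic-lethal branch pair
#'
#' Four candidate reactions (X = 4) plus an objective. Reaction A is the
#' sole source feeding metabolite M1 and is essential; C and D are
#' parallel branches that each can convert M1 into the objective
#' precursor P, so the pair \{C, D\} is the only minimal synthetic-lethal
#' set at level 2; B is a side branch that never limits the objective.
#' The complete level-2 minimal lethal structure is therefore
#' \{\{A\}, \{C, D\}\} and the level-2 score of C is 1/4 = 0.25.
#' Each reaction carries a one-gene GPR (`gA`..`gD`) so the same
#' structure is exercised at gene level.
#'
#' @return a [MetabolicModel-class].
#' @examples
#' escores(computeEScore(enumerateMinimalLethalSets(
#'   fig1aModel(), analysisConfig(levelN = 2))))
#' @export
fig1aModel <- function() {
  .fixtureModel("toyA", list(
    list(id = "A", sto = c(M1 = 1), ub = 10, gpr = "gA"),
    list(id = "B", sto = c(M1 = -1, M2 = 1), gpr = "gB"),
    list(id = "C", sto = c(M1 = -1, P = 1), gpr = "gC"),
    list(id = "D", sto = c(M1 = -1, P = 1), gpr = "gD"),
    list(id = "OBJ", sto = c(P = -1))
  ), "OBJ")
}

#' Toy model B: a hot-spot reaction shared by two synthetic-lethal pairs
#'
#' Same shape as [fig1aModel()] but D is a direct route to the objective
#' precursor while B and C form a serial bypass, so D is involved in two
#' minimal pairs (\{B, D\} and \{C, D\}) and scores 0.5 at level 2 -
#' twice the score of B or C. Demonstrates that the score concentrates on
#' over-represented "hot spot" targets.
#'
#' @return a [MetabolicModel-class].
#' @export
fig1bModel <- function() {
  .fixtureModel("toyB", list(
    list(id = "A", sto = c(M1 = 1), ub = 10, gpr = "gA"),
    list(id = "B", sto = c(M1 = -1, M2 = 1), gpr = "gB"),
    list(id = "C", sto = c(M2 = -1, P = 1), gpr = "gC"),
    list(id = "D", sto = c(M1 = -1, P = 1), gpr = "gD"),
    list(id = "OBJ", sto = c(P = -1))
  ), "OBJ")
}

#' Describe the lethal structure of a synthetic model
#'
#' @param essentialIds reactions intended to be singly essential.
#' @param slGroups list of id sets (size >= 2) intended to be exactly the
#'   minimal synthetic-lethal groups. Groups must be disjoint, or form
#'   size-2 "star" families sharing one common member.
#' @param nDecoys number of additional blocked decoy reactions.
#' @return a `LethalStructureSpec` list.
#' @export
lethalStructureSpec <- function(essentialIds = character(),
                                slGroups = list(), nDecoys = 0L) {
  essentialIds <- as.character(essentialIds)
  slGroups <- lapply(slGroups, function(g) sort(as.character(g)))
  if (any(lengths(slGroups) < 2L))
    stop("every slGroup needs at least 2 members")
  hit <- intersect(essentialIds, unlist(slGroups))
  if (length(hit))
    stop("ids cannot be both essential and in an slGroup: ",
         paste(hit, collapse = ", "))
  ids <- c(essentialIds, unlist(slGroups))
  structure(list(essentialIds = essentialIds, slGroups = slGroups,
                 nDecoys = as.integer(nDecoys),
                 nTargets = length(unique(ids)) + as.integer(nDecoys)),
            class = "LethalStructureSpec")
}

## partition groups into realizable segments: singleton components become
## parallel bundles; components whose pairwise overlaps all run through a
## single shared member (and whose groups are all pairs) become a "star"
## (direct branch = shared member, serial chain = the other members).
.groupComponents <- function(groups) {
  n <- length(groups)
  if (!n) return(list())
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (comp[a] != comp[b] && length(intersect(groups[[a]], groups[[b]]))) {
        comp[comp == comp[b]] <- comp[a]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(unique(comp), function(ci) groups[comp == ci])
}

#' Generate a mass-balanced model with a prescribed lethal structure
#'
#' Builds a linear pathway whose serial segments realize the essential
#' singletons and whose parallel branch bundles realize the
#' synthetic-lethal groups; decoy reactions are blocked side branches
#' that can never carry flux. The realized minimal lethal structure is
#' verified against the request with [bruteForceLethalSets()] at build
#' time, so the returned model is a certified test case. Reaction order
#' and decoy attachment points are shuffled reproducibly from `seed`.
#' Gene rules: `gprStyle = "one_to_one"` gives every candidate reaction
#' its own gene; `"random"` decorates a random subset with two-gene
#' isozyme (OR) or complex (AND) rules over fresh genes.
#'
#' @param spec a [lethalStructureSpec()].
#' @param seed integer seed (reproducible generation).
#' @param gprStyle gene-rule decoration, see Details.
#' @return a [MetabolicModel-class].
#' @examples
#' m <- synthModel(lethalStructureSpec("A", list(c("C", "D"))), seed = 1)
#' findEssential(m)   # "A"
#' @export
synthModel <- function(spec, seed = 1L,
                       gprStyle = c("one_to_one", "random")) {
  stopifnot(inherits(spec, "LethalStructureSpec"))
  gprStyle <- match.arg(gprStyle)
  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(seed)

  comps <- .groupComponents(spec$slGroups)
  segments <- c(lapply(spec$essentialIds, function(e)
    list(type = "serial", id = e)),
    lapply(comps, function(grps) {
      if (length(grps) == 1L) return(list(type = "bundle", ids = grps[[1]]))
      shared <- Reduce(intersect, grps)
      if (length(shared) != 1L || any(lengths(grps) != 2L))
        stop("unrealizable slGroups: overlapping groups must be size-2 ",
             "sets sharing exactly one common member")
      list(type = "star", shared = shared,
           others = sort(setdiff(unique(unlist(grps)), shared)))
    }))
  if (length(segments) > 1L) segments <- segments[sample(length(segments))]

  mcount <- 0L
  newMet <- function() { mcount <<- mcount + 1L; sprintf("m%02d", mcount) }
  rxns <- list(list(id = "SRC", sto = setNames(1, "m_in"), ub = 10))
  prev <- "m_in"
  for (seg in segments) {
    nxt <- newMet()
    if (seg$type == "serial") {
      rxns <- c(rxns, list(list(id = seg$id,
                                sto = setNames(c(-1, 1), c(prev, nxt)))))
    } else if (seg$type == "bundle") {
      for (id in seg$ids)
        rxns <- c(rxns, list(list(id = id,
                                  sto = setNames(c(-1, 1), c(prev, nxt)))))
    } else {
      rxns <- c(rxns, list(list(id = seg$shared,
                                sto = setNames(c(-1, 1), c(prev, nxt)))))
      chainPrev <- prev
      for (k in seq_along(seg$others)) {
        chainNext <- if (k == length(seg$others)) nxt else newMet()
        rxns <- c(rxns, list(list(id = seg$others[k],
                                  sto = setNames(c(-1, 1),
                                                 c(chainPrev, chainNext)))))
        chainPrev <- chainNext
      }
    }
    prev <- nxt
  }
  if (spec$nDecoys > 0L) {
    anchors <- c("m_in", vapply(seq_len(mcount), function(i)
      sprintf("m%02d", i), ""))
    for (k in seq_len(spec$nDecoys)) {
      dead <- newMet()
      rxns <- c(rxns, list(list(id = sprintf("decoy%02d", k),
                                sto = setNames(c(-1, 1),
                                               c(sample(anchors, 1), dead)))))
    }
  }
  rxns <- c(rxns, list(list(id = "OBJ", sto = setNames(-1, prev))))

  targetIdx <- which(!vapply(rxns, `[[`, "", "id") %in% c("OBJ"))
  gcount <- 0L
  for (k in targetIdx) {
    rid <- rxns[[k]]$id
    if (gprStyle == "one_to_one") {
      rxns[[k]]$gpr <- paste0("g_", rid)
    } else {
      style <- sample(c("single", "or", "and"), 1, prob = c(.6, .25, .15))
      gcount <- gcount + 2L
      rxns[[k]]$gpr <- switch(style,
        single = paste0("g_", rid),
        or = sprintf("g%03da or g%03db", gcount, gcount),
        and = sprintf("g%03da and g%03db", gcount, gcount))
    }
  }
  model <- .fixtureModel(sprintf("synth_seed%d", seed), rxns, "OBJ")

  ## certify the realized reaction-level lethal structure
  maxCard <- max(c(1L, lengths(spec$slGroups)))
  got <- bruteForceLethalSets(model, analysisConfig(
    levelN = maxCard, excludedIds = "SRC"))
  wantKeys <- sort(c(spec$essentialIds,
                     vapply(spec$slGroups, paste, "", collapse = "\r")))
  gotKeys <- sort(vapply(
    unlist(lethalSets(got), recursive = FALSE, use.names = FALSE),
    paste, "", collapse = "\r"))
  if (!identical(wantKeys, gotKeys))
    stop("generated model does not realize the requested lethal ",
         "structure (requested ", length(wantKeys), " sets, realized ",
         length(gotKeys), "); the requested groups interact")
  model
}
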