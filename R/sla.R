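## Enumeration of essential targets and minimal ("true") synthetic-lethal
## sets up to level n.
##
## Two routes to the same ground truth:
##  * enumerateMinimalLethalSets(): the production path. Candidate targets
##    at each depth are restricted to the support of a minimum-|v| optimal
##    solution of the current knockout model (any lethal set must
##    intersect the support of every surviving optimal flux distribution,
##    so the restriction loses nothing), and non-lethal LP solutions are
##    cached as "survival certificates": a knockout set disjoint from a
##    cached solution's support cannot be lethal and needs no LP.
##  * bruteForceLethalSets(): plain exhaustive search, one LP per
##    combination, no certificates, no support pruning. Slow and simple;
##    the correctness oracle for the production path.
##
## Minimality: a lethal set is stored only when no proper subset is
## lethal, which removes the redundancy of trivial supersets (a pair
## containing an essential reaction is not a "true" synthetic lethal).

.SUPPORT_TOL <- 1e-8

## shared engine over one model + config
.slaEngine <- function(model, config, usePool = TRUE) {
  kind <- config@targets
  if (kind == "genes") model <- logicalTransform(model)
  ctx <- .lpContext(model)
  wt <- .solveRaw(ctx, ctx$lb, ctx$ub)
  if (wt$status != "optimal")
    stop("wild-type model is infeasible; cannot analyze lethality")
  f0 <- wt$objective
  eps <- .lethalEps(config, f0)
  if (f0 <= eps)
    stop("wild-type objective (", signif(f0, 6),
         ") does not exceed the lethality threshold (", signif(eps, 6), ")")
  if (kind == "reactions") {
    cand <- sort(setdiff(ctx$rids, c(model@objectiveId, config@excludedIds)))
  } else {
    cand <- sort(setdiff(model@genes, config@excludedIds))
  }
  rxnGenes <- NULL
  if (kind == "genes")
    rxnGenes <- lapply(setNames(ctx$rids, ctx$rids),
                       function(r) gprGenes(model@gpr[[r]]))
  eng <- new.env(parent = emptyenv())
  eng$ctx <- ctx; eng$model <- model; eng$kind <- kind
  eng$f0 <- f0; eng$eps <- eps; eng$cand <- cand
  ## certificate pool: row s, column r TRUE when the s-th cached
  ## non-lethal solution carries zero flux through reaction r
  eng$poolZero <- matrix(logical(0), 0L, ctx$n)
  eng$usePool <- usePool
  eng$nLP <- 0L
  eng$geneMemo <- new.env(parent = emptyenv())
  eng$rxnGenes <- rxnGenes
  eng
}

## reaction indices silenced by a knockout of target ids
.koIdx <- function(eng, ids) {
  if (eng$kind == "reactions") return(match(ids, eng$ctx$rids))
  if (!length(ids)) return(integer())
  off <- .disabledReactions(eng$model, ids)
  match(off, eng$ctx$rids)
}

.koLP <- function(eng, rxIdx) {
  lb <- eng$ctx$lb; ub <- eng$ctx$ub
  lb[rxIdx] <- 0; ub[rxIdx] <- 0
  eng$nLP <- eng$nLP + 1L
  .solveRaw(eng$ctx, lb, ub)
}

## lethality with certificate cache (and gene-signature memoization)
.engLethal <- function(eng, ids) {
  rxIdx <- .koIdx(eng, ids)
  if (!length(rxIdx)) return(FALSE)   # knockout silences nothing
  key <- NULL
  if (eng$kind == "genes") {
    key <- paste(sort(rxIdx), collapse = ",")
    hit <- eng$geneMemo[[key]]
    if (!is.null(hit)) return(hit)
  }
  res <- NA
  if (eng$usePool && nrow(eng$poolZero) &&
      any(rowSums(eng$poolZero[, rxIdx, drop = FALSE]) == length(rxIdx)))
    res <- FALSE   # a cached surviving solution avoids the whole knockout
  if (is.na(res)) {
    sol <- .koLP(eng, rxIdx)
    if (sol$status != "optimal" || sol$objective <= eng$eps) {
      res <- TRUE
    } else {
      res <- FALSE
      if (eng$usePool && nrow(eng$poolZero) < 500L)
        eng$poolZero <- rbind(eng$poolZero, abs(sol$x) <= .SUPPORT_TOL)
    }
  }
  if (!is.null(key)) eng$geneMemo[[key]] <- res
  res
}

## support (reaction indices) of the minimum-|v| optimal solution of the
## knockout model defined by a non-lethal target-id prefix
.engL1Support <- function(eng, ids) {
  rxIdx <- .koIdx(eng, ids)
  lb <- eng$ctx$lb; ub <- eng$ctx$ub
  lb[rxIdx] <- 0; ub[rxIdx] <- 0
  fko <- .solveRaw(eng$ctx, lb, ub)
  if (fko$status != "optimal") return(integer())
  ctx2 <- eng$ctx; ctx2$lb <- lb; ctx2$ub <- ub
  v <- .minAbsSolution(ctx2, lb, ub, fko$objective)
  if (is.null(v)) return(which(abs(fko$x) > .SUPPORT_TOL))
  which(abs(v) > .SUPPORT_TOL)
}

## target-kind candidates reachable from a reaction-index support
.engSupportTargets <- function(eng, suppIdx) {
  if (eng$kind == "reactions") return(eng$ctx$rids[suppIdx])
  unique(unlist(eng$rxnGenes[suppIdx], use.names = FALSE))
}

#' Essential single targets
#'
#' The candidate reactions (or genes) whose single knockout is lethal,
#' in lexicographic order. Candidates are all reactions (or genes) except
#' the objective reaction and `excludedIds`.
#'
#' @param model a [MetabolicModel-class].
#' @param config an [AnalysisConfig-class].
#' @return sorted character vector of essential ids.
#' @examples
#' findEssential(fig1aModel(), analysisConfig())   # "A"
#' @export
findEssential <- function(model, config = analysisConfig()) {
  eng <- .slaEngine(model, config)
  eng$cand[vapply(eng$cand, function(id) .engLethal(eng, id), NA)]
}

.emptyLevels <- function(n) setNames(rep(list(list()), n), as.character(seq_len(n)))

.makeCollection <- function(levelN, kind, setsByLevel, cand) {
  for (j in seq_along(setsByLevel)) {
    s <- setsByLevel[[j]]
    if (length(s))
      setsByLevel[[j]] <- s[order(vapply(s, paste, "", collapse = "\r"))]
  }
  new("LethalSetCollection", levelN = as.integer(levelN), targetKind = kind,
      setsByLevel = setsByLevel, candidateIds = cand)
}

## mutable store of lethal-set keys (environment, so updates stick)
.newStore <- function(levelN) {
  st <- new.env(parent = emptyenv())
  st$keys <- new.env(parent = emptyenv())
  st$any <- logical(levelN)
  st
}

## does `s` (sorted ids) contain a stored lethal subset?
.hasLethalSubset <- function(store, s) {
  j <- length(s)
  if (j <= 1L) return(FALSE)
  for (sz in seq_len(j - 1L)) {
    if (!store$any[sz]) next
    sub <- combn(s, sz, paste, collapse = "\r")
    for (k in sub) if (!is.null(store$keys[[k]])) return(TRUE)
  }
  FALSE
}

.storeSet <- function(store, s) {
  store$keys[[paste(s, collapse = "\r")]] <- TRUE
  store$any[length(s)] <- TRUE
}

#' Enumerate minimal lethal knockout sets up to level n
#'
#' Finds every essential singleton and every "true" synthetic-lethal set
#' of cardinality up to `levelN`: lethal sets none of whose proper subsets
#' is lethal. The objective reaction and `excludedIds` never appear in
#' any set. Gene-level runs operate on the logically transformed model
#' (minimal-DNF GPRs) and memoize lethality by the disabled-reaction
#' signature, so flux-equivalent gene sets cost one LP.
#'
#' Method `"pruned"` restricts candidates at depth j to the support of a
#' minimum-|v| optimal solution of the (j-1)-knockout model; `"exhaustive"`
#' tests all combinations, skipping those ruled out by cached non-lethal
#' solutions. `"auto"` picks `"pruned"` for 200 or more non-essential
#' candidates. Both yield identical, complete collections; they differ
#' only in cost profile.
#'
#' @param model a [MetabolicModel-class].
#' @param config an [AnalysisConfig-class]; `levelN` above 3 triggers a
#'   cost warning.
#' @param method candidate-restriction strategy, see Details.
#' @param checkpointDir optional directory; the collection is flushed
#'   there after each completed level (`lethal_sets_level<j>.tsv`).
#' @return a [LethalSetCollection-class].
#' @examples
#' col <- enumerateMinimalLethalSets(fig1aModel(), analysisConfig(levelN = 2))
#' lethalSets(col, 2)    # list(c("C", "D"))
#' @export
enumerateMinimalLethalSets <- function(model, config = analysisConfig(),
                                       method = c("auto", "pruned", "exhaustive"),
                                       checkpointDir = NULL) {
  method <- match.arg(method)
  if (config@levelN < 1L) stop("levelN must be >= 1")
  if (config@levelN > 3L)
    warning("levelN = ", config@levelN,
            " can be very costly on genome-scale models")
  eng <- .slaEngine(model, config)
  ess <- eng$cand[vapply(eng$cand, function(id) .engLethal(eng, id), NA)]
  U <- setdiff(eng$cand, ess)
  if (method == "auto")
    method <- if (length(U) >= 200L) "pruned" else "exhaustive"
  sets <- .emptyLevels(config@levelN)
  sets[["1"]] <- as.list(ess)
  stored <- .newStore(config@levelN)
  for (e in ess) .storeSet(stored, e)
  .flush <- function(j) {
    if (is.null(checkpointDir)) return(invisible())
    dir.create(checkpointDir, showWarnings = FALSE, recursive = TRUE)
    part <- .makeCollection(config@levelN, eng$kind, sets, eng$cand)
    writeLethalSets(part, file.path(checkpointDir,
                                    sprintf("lethal_sets_level%d.tsv", j)))
  }
  .flush(1L)
  if (config@levelN >= 2L && length(U) >= 2L) {
    if (method == "exhaustive") {
      for (j in 2:config@levelN) {
        if (length(U) < j) break
        combos <- combn(U, j, simplify = FALSE)
        for (s in combos) {
          if (.hasLethalSubset(stored, s)) next
          if (.engLethal(eng, s)) {
            sets[[j]] <- c(sets[[j]], list(s))
            .storeSet(stored, s)
          }
        }
        .flush(j)
      }
    } else {
      ## support-restricted breadth-first growth: any lethal set must
      ## intersect the support of the wild-type minimum-|v| solution, and
      ## its remainder must intersect the support of the corresponding
      ## knockout model's minimum-|v| solution, level by level.
      tested <- new.env(parent = emptyenv())
      supp1 <- .engL1Support(eng, character())
      frontier <- as.list(sort(intersect(.engSupportTargets(eng, supp1), U)))
      for (j in 2:config@levelN) {
        newFrontier <- list()
        for (prefix in frontier) {
          supp <- .engL1Support(eng, prefix)
          cands <- setdiff(intersect(.engSupportTargets(eng, supp), U), prefix)
          for (id in sort(cands)) {
            s <- sort(c(prefix, id))
            key <- paste(s, collapse = "\r")
            if (!is.null(tested[[key]])) next
            tested[[key]] <- TRUE
            if (.hasLethalSubset(stored, s)) next
            if (.engLethal(eng, s)) {
              sets[[j]] <- c(sets[[j]], list(s))
              .storeSet(stored, s)
            } else if (j < config@levelN) {
              newFrontier[[length(newFrontier) + 1L]] <- s
            }
          }
        }
        frontier <- newFrontier
        .flush(j)
      }
    }
  }
  .makeCollection(config@levelN, eng$kind, sets, eng$cand)
}

#' Exhaustive ground-truth enumeration
#'
#' Tests every combination of candidates up to `levelN` with one LP each
#' (no certificates, no support pruning) and applies the same minimality
#' filter as [enumerateMinimalLethalSets()]. Intentionally simple: it is
#' the correctness oracle for the production path, and refuses problems
#' whose combination count exceeds `maxCombinations`.
#'
#' @param model a [MetabolicModel-class].
#' @param config an [AnalysisConfig-class].
#' @param maxCombinations refusal budget on the total number of
#'   combinations.
#' @return a [LethalSetCollection-class].
#' @export
bruteForceLethalSets <- function(model, config = analysisConfig(),
                                 maxCombinations = 2e5) {
  eng <- .slaEngine(model, config, usePool = FALSE)
  X <- length(eng$cand)
  total <- sum(choose(X, seq_len(config@levelN)))
  if (total > maxCombinations)
    stop("exhaustive enumeration would need ", format(total, big.mark = ","),
         " combinations (budget ", format(maxCombinations, big.mark = ","), ")")
  ess <- eng$cand[vapply(eng$cand, function(id) .engLethal(eng, id), NA)]
  U <- setdiff(eng$cand, ess)
  sets <- .emptyLevels(config@levelN)
  sets[["1"]] <- as.list(ess)
  stored <- .newStore(config@levelN)
  for (e in ess) .storeSet(stored, e)
  if (config@levelN >= 2L && length(U) >= 2L) {
    for (j in 2:config@levelN) {
      if (length(U) < j) break
      for (s in combn(U, j, simplify = FALSE)) {
        if (.hasLethalSubset(stored, s)) next
        if (.engLethal(eng, s)) {
          sets[[j]] <- c(sets[[j]], list(s))
          .storeSet(stored, s)
        }
      }
    }
  }
  .makeCollection(config@levelN, eng$kind, sets, eng$cand)
}

#' Write / read a lethal-set collection
#'
#' TSV layout: columns `level` and `members` (comma-joined ids), one row
#' per stored set, preceded by `#` header lines carrying the level,
#' target kind and candidate ids so that files round-trip. JSON carries
#' the same fields natively; the format is chosen by file extension.
#'
#' @param collection a [LethalSetCollection-class].
#' @param path destination (`.tsv` or `.json`).
#' @return `path` invisibly (writer); a collection (reader).
#' @export
writeLethalSets <- function(collection, path) {
  stopifnot(is(collection, "LethalSetCollection"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(
      level_n = collection@levelN,
      target_kind = collection@targetKind,
      candidate_ids = collection@candidateIds,
      sets = lapply(seq_len(collection@levelN), function(j)
        lapply(collection@setsByLevel[[j]], identity))),
      path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# level_n\t", collection@levelN),
    paste0("# target_kind\t", collection@targetKind),
    paste0("# candidate_ids\t", paste(collection@candidateIds, collapse = ",")),
    "level\tmembers"), con)
  for (j in seq_len(collection@levelN))
    for (s in collection@setsByLevel[[j]])
      writeLines(paste0(j, "\t", paste(s, collapse = ",")), con)
  invisible(path)
}

#' @rdname writeLethalSets
#' @export
readLethalSets <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    sets <- setNames(lapply(j$sets, function(lv)
      lapply(lv, function(s) sort(unlist(s)))), as.character(seq_along(j$sets)))
    return(.makeCollection(j$level_n, j$target_kind, sets,
                           unlist(j$candidate_ids)))
  }
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  field <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key))]
    sub(paste0("^# ", key, "\t"), "", ln)
  }
  levelN <- as.integer(field("level_n"))
  kind <- field("target_kind")
  cand <- strsplit(field("candidate_ids"), ",", fixed = TRUE)[[1]]
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1]  # column header
  sets <- .emptyLevels(levelN)
  for (ln in body) {
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    j <- as.integer(parts[1])
    s <- sort(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    sets[[j]] <- c(sets[[j]], list(s))
  }
  .makeCollection(levelN, kind, sets, cand)
}
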