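## Cross-model score comparison and the rank-correlation utilities used
## when benchmarking essentiality scores against centralities or external
## essentiality measurements.

.DELTA_TOL <- 1e-9

#' Compare two essentiality score tables
#'
#' Aligns two tables over the union of their target ids and classifies
#' every target as up / down / unchanged (tolerance 1e-9 on the delta) or
#' only_a / only_b when scored in a single model. `carryoverIds` handles
#' targets removed from model b (e.g. the deleted reaction of a knockout
#' strain): their score_b is set equal to score_a before deltas are
#' computed, so the deletion itself does not show up as a change.
#'
#' @param tableA an [EScoreTable-class] (reference, e.g. wild type).
#' @param tableB an [EScoreTable-class] (comparison, e.g. mutant).
#' @param carryoverIds ids present in `tableA` whose score is copied into
#'   `tableB` when absent there.
#' @return a [ComparisonReport-class].
#' @examples
#' colA <- enumerateMinimalLethalSets(fig1aModel(), analysisConfig(levelN = 2))
#' ta <- computeEScore(colA)
#' comparisonSummary(compareEScores(ta, ta))$unchanged   # all of them
#' @export
compareEScores <- function(tableA, tableB, carryoverIds = character()) {
  stopifnot(is(tableA, "EScoreTable"), is(tableB, "EScoreTable"))
  a <- escores(tableA); b <- escores(tableB)
  missingCarry <- setdiff(carryoverIds, names(a))
  if (length(missingCarry))
    stop("carryover id(s) not in table a: ",
         paste(missingCarry, collapse = ", "))
  for (id in setdiff(carryoverIds, names(b))) b[id] <- a[id]
  ids <- sort(union(names(a), names(b)))
  inA <- ids %in% names(a); inB <- ids %in% names(b)
  sa <- ifelse(inA, a[ids], NA_real_)
  sb <- ifelse(inB, b[ids], NA_real_)
  delta <- sb - sa
  status <- ifelse(!inA, "only_b",
            ifelse(!inB, "only_a",
            ifelse(delta > .DELTA_TOL, "up",
            ifelse(delta < -.DELTA_TOL, "down", "unchanged"))))
  df <- data.frame(id = ids, score_a = unname(sa), score_b = unname(sb),
                   delta = unname(delta), status = status,
                   stringsAsFactors = FALSE)
  summary <- list(up = sum(status == "up"), down = sum(status == "down"),
                  unchanged = sum(status == "unchanged"),
                  only_a = sum(status == "only_a"),
                  only_b = sum(status == "only_b"),
                  mean_a = mean(a), mean_b = mean(b))
  new("ComparisonReport", table = df, summary = summary)
}

#' Spearman rank correlation with average ranks
#'
#' Rho is the Pearson correlation of mid-ranks (average ranks for ties);
#' the two-sided p-value uses the large-sample t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with elements `rho` and `p`.
#' @examples
#' spearmanRank(1:5, c(1, 3, 2, 5, 4))   # rho = 0.8
#' @export
spearmanRank <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = max(p, .Machine$double.xmin))
}

#' Cross-tabulate essentiality scores against a centrality
#'
#' Partitions targets by (score zero / non-zero) x (centrality zero /
#' non-zero). "Zero score" means exactly 0 (uninvolved targets are
#' structurally zero); centrality is compared against 1e-12 to absorb
#' floating-point dust. Targets present in only one input get 0 for the
#' missing quantity, so excluded pseudo reactions and the objective can
#' participate in the partition; the id universes must overlap.
#'
#' @param escoreTable an [EScoreTable-class].
#' @param centralityTable data.frame from [centralities()].
#' @param centrality which centrality column to use.
#' @return list with `counts` (2x2 matrix, rows escore zero/nonzero,
#'   columns centrality zero/nonzero) and `members` (id lists per cell).
#' @export
scoreOverlapCounts <- function(escoreTable, centralityTable,
                               centrality = "betweenness") {
  stopifnot(is(escoreTable, "EScoreTable"))
  stopifnot(centrality %in% names(centralityTable))
  es <- escores(escoreTable)
  bc <- setNames(centralityTable[[centrality]], centralityTable$node)
  if (!length(intersect(names(es), names(bc))))
    stop("score table and centrality table share no ids")
  ids <- sort(union(names(es), names(bc)))
  esAll <- ifelse(ids %in% names(es), es[ids], 0)
  bcAll <- ifelse(ids %in% names(bc), bc[ids], 0)
  esNZ <- esAll != 0
  bcNZ <- abs(bcAll) > 1e-12
  cellIds <- list(
    zero_zero = ids[!esNZ & !bcNZ],
    zero_nonzero = ids[!esNZ & bcNZ],
    nonzero_zero = ids[esNZ & !bcNZ],
    nonzero_nonzero = ids[esNZ & bcNZ])
  counts <- matrix(lengths(cellIds)[c(1, 2, 3, 4)], 2, 2, byrow = TRUE,
                   dimnames = list(escore = c("zero", "nonzero"),
                                   centrality = c("zero", "nonzero")))
  list(counts = counts, members = cellIds)
}

#' Write overlap counts as JSON
#'
#' Serializes the result of [scoreOverlapCounts()] (cell counts plus the
#' member id lists).
#'
#' @param overlap list returned by [scoreOverlapCounts()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeOverlapCounts <- function(overlap, path) {
  stopifnot(is.list(overlap), !is.null(overlap$counts))
  jsonlite::write_json(list(
    counts = list(
      zero_zero = overlap$counts["zero", "zero"],
      zero_nonzero = overlap$counts["zero", "nonzero"],
      nonzero_zero = overlap$counts["nonzero", "zero"],
      nonzero_nonzero = overlap$counts["nonzero", "nonzero"]),
    members = overlap$members), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Mean score per subsystem
#'
#' Pathway-level aggregation: the grouped mean of scores keyed by a
#' target-to-subsystem map (typically the `subsystem` column of the
#' model's reaction table, when the source file provides one).
#'
#' @param escoreTable an [EScoreTable-class].
#' @param subsystems named character vector mapping target id to
#'   subsystem label; unmapped targets are grouped under "".
#' @return data.frame with columns `subsystem`, `n`, `mean_escore`.
#' @export
subsystemSummary <- function(escoreTable, subsystems) {
  es <- escores(escoreTable)
  grp <- subsystems[names(es)]
  grp[is.na(grp)] <- ""
  agg <- aggregate(list(mean_escore = unname(es)),
                   by = list(subsystem = unname(grp)), FUN = mean)
  cnt <- as.data.frame(table(subsystem = unname(grp)),
                       stringsAsFactors = FALSE)
  names(cnt)[2] <- "n"
  out <- merge(cnt, agg, by = "subsystem")
  out[order(-out$mean_escore), ]
}

#' Write a comparison report
#'
#' TSV with the per-target table plus a one-page text summary next to it
#' when `summaryPath` is given.
#'
#' @param report a [ComparisonReport-class].
#' @param path TSV destination.
#' @param summaryPath optional text-summary destination.
#' @return `path`, invisibly.
#' @export
writeComparison <- function(report, path, summaryPath = NULL) {
  stopifnot(is(report, "ComparisonReport"))
  write.table(report@table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(summaryPath)) {
    s <- report@summary
    lines <- c(
      "Essentiality score comparison",
      sprintf("targets compared: %d", nrow(report@table)),
      sprintf("up: %d   down: %d   unchanged: %d", s$up, s$down, s$unchanged),
      sprintf("only in a: %d   only in b: %d", s$only_a, s$only_b),
      sprintf("mean score a: %.6g   mean score b: %.6g", s$mean_a, s$mean_b))
    top <- report@table[order(-report@table$delta), ]
    top <- top[top$status == "up", ][seq_len(min(5, s$up)), ]
    if (nrow(top))
      lines <- c(lines, "largest increases:",
                 sprintf("  %s  %+0.6f", top$id, top$delta))
    writeLines(lines, summaryPath)
  }
  invisible(path)
}
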