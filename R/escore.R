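## Essentiality scores from a minimal-lethal-set collection.
##
## For candidate i with involvement counts y_ij (number of stored minimal
## lethal sets of cardinality j containing i) and X candidates:
##
##     ES_i = y_i1 + sum_{j=2..n} y_ij * (j-1)! / X^(j-1)
##
## The (j-1)!/X^(j-1) weight normalizes each unordered involvement by the
## X^(j-1) ordered-with-repetition combinations a fixed target can appear
## in at level j: an unordered set containing i corresponds to (j-1)!
## orderings of its remaining members, so (j-1)! * y_ij is the ordered
## involvement count. Essential targets have y_i1 = 1 and (by minimality)
## no higher-level involvement, hence score exactly 1; X-normalization
## makes scores comparable across models.

#' Ordered level-n combination population per target
#'
#' The number of ordered, repetition-allowed knockout combinations of
#' cardinality `n` that involve one fixed target in a model with `X`
#' candidates: `X^(n-1)`. This is the population that motivates the
#' `(j-1)!/X^(j-1)` weights of the score.
#'
#' @param X number of candidate targets (>= 1).
#' @param n analysis level (>= 1).
#' @return a whole number.
#' @examples
#' combinationCount(4, 2)   # 4
#' combinationCount(4, 3)   # 16
#' @export
combinationCount <- function(X, n) {
  stopifnot(X >= 1, n >= 1)
  X^(n - 1)
}

#' Involvement counts of one target
#'
#' @param collection a [LethalSetCollection-class].
#' @param targetId a candidate id.
#' @return an [InvolvementCounts-class]: `y[j]` = number of stored
#'   cardinality-j sets containing the target.
#' @examples
#' col <- enumerateMinimalLethalSets(fig1aModel(), analysisConfig(levelN = 2))
#' countInvolvements(col, "C")   # y = c(`1` = 0, `2` = 1)
#' @export
countInvolvements <- function(collection, targetId) {
  stopifnot(is(collection, "LethalSetCollection"))
  if (!targetId %in% collection@candidateIds)
    stop("unknown target id: ", targetId)
  y <- vapply(seq_len(collection@levelN), function(j)
    sum(vapply(collection@setsByLevel[[j]], function(s) targetId %in% s, NA)),
    0L)
  new("InvolvementCounts", targetId = targetId,
      y = setNames(y, as.character(seq_len(collection@levelN))))
}

#' Compute essentiality scores
#'
#' Converts a minimal-lethal-set collection into per-target scores (see
#' the class documentation of [EScoreTable-class] for the formula).
#' Targets appearing in no stored set score 0; essential targets score
#' exactly 1. A score above 1 for a non-essential target would contradict
#' the expected bound and triggers a warning, but the raw value is
#' reported unclamped.
#'
#' @param collection a [LethalSetCollection-class].
#' @return an [EScoreTable-class].
#' @examples
#' col <- enumerateMinimalLethalSets(fig1aModel(), analysisConfig(levelN = 2))
#' escores(computeEScore(col))[c("A", "C")]   # 1 and 0.25
#' @export
computeEScore <- function(collection) {
  stopifnot(is(collection, "LethalSetCollection"))
  cand <- collection@candidateIds
  X <- length(cand)
  if (X < 1L) stop("collection has no candidate targets")
  n <- collection@levelN
  counts <- matrix(0L, nrow = X, ncol = n,
                   dimnames = list(cand, as.character(seq_len(n))))
  for (j in seq_len(n)) {
    for (s in collection@setsByLevel[[j]]) {
      counts[s, j] <- counts[s, j] + 1L
    }
  }
  w <- vapply(seq_len(n), function(j)
    if (j == 1) 1 else factorial(j - 1) / X^(j - 1), 0)
  scores <- as.numeric(counts %*% w)
  names(scores) <- cand
  over <- scores > 1 + 1e-12 & counts[, 1] == 0L
  if (any(over))
    warning("EScore exceeds 1 for non-essential target(s): ",
            paste(cand[over], collapse = ", "),
            " - reported unclamped")
  new("EScoreTable", scores = scores, counts = counts, X = X,
      levelN = as.integer(n), targetKind = collection@targetKind)
}

#' Write an essentiality score table as TSV
#'
#' Columns: `target_id`, `escore` (rounded to 6 decimals), `y_1..y_n`,
#' `X`, `n`.
#'
#' @param table an [EScoreTable-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeEScoreTable <- function(table, path) {
  stopifnot(is(table, "EScoreTable"))
  df <- data.frame(target_id = names(table@scores),
                   escore = round(table@scores, 6))
  cn <- paste0("y_", colnames(table@counts))
  for (k in seq_along(cn)) df[[cn[k]]] <- table@counts[, k]
  df$X <- table@X
  df$n <- table@levelN
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
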