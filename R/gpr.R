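## Gene-protein-reaction (GPR) boolean rules.
##
## A rule is stored as a parse tree: a character scalar is a gene leaf; an
## internal node is list(op = "and"|"or", args = list(...)). NULL means
## "no rule" and such reactions are never disabled by gene deletions.

#' Parse a GPR rule string
#'
#' Accepts the usual dialects: `and`/`or` (any case), `&`/`&&`, `|`/`||`,
#' and parentheses, e.g. `"(b0001 and b0002) or b0003"`.
#'
#' @param rule a single rule string; `""`/`NA` yield `NULL` (no rule).
#' @return a GPR expression tree, or `NULL`.
#' @examples
#' parseGPR("(g1 and g2) or g3")
#' @export
parseGPR <- function(rule) {
  if (is.null(rule) || length(rule) == 0L || is.na(rule) || !nzchar(trimws(rule)))
    return(NULL)
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^\\s()&|]+|&&?|\\|\\|?", rule, perl = TRUE))[[1]]
  toks <- toks[nzchar(trimws(toks))]
  norm <- function(t) {
    tl <- tolower(t)
    if (tl %in% c("and", "&", "&&")) "and"
    else if (tl %in% c("or", "|", "||")) "or"
    else t
  }
  toks <- vapply(toks, norm, "", USE.NAMES = FALSE)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("malformed GPR rule '", rule, "': unexpected end")
    if (t == "(") {
      e <- parse_or()
      if (!identical(take(), ")"))
        stop("malformed GPR rule '", rule, "': missing ')'")
      return(e)
    }
    if (t %in% c(")", "and", "or"))
      stop("malformed GPR rule '", rule, "': unexpected '", t, "'")
    t
  }
  parse_and <- function() {
    args <- list(parse_factor())
    while (identical(peek(), "and")) { take(); args <- c(args, list(parse_factor())) }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (identical(peek(), "or")) { take(); args <- c(args, list(parse_and())) }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  out <- parse_or()
  if (pos <= length(toks))
    stop("malformed GPR rule '", rule, "': trailing tokens")
  out
}

#' Render a GPR tree back to a rule string
#' @param tree a GPR expression tree (or `NULL`).
#' @return a rule string ("" for `NULL`).
#' @export
gprToString <- function(tree) {
  if (is.null(tree)) return("")
  rec <- function(t, parent_op = "") {
    if (is.character(t)) return(t)
    parts <- vapply(t$args, rec, "", parent_op = t$op)
    s <- paste(parts, collapse = paste0(" ", t$op, " "))
    if (nzchar(parent_op) && parent_op != t$op) paste0("(", s, ")") else s
  }
  rec(tree)
}

#' Genes referenced by a GPR tree
#' @param tree a GPR expression tree (or `NULL`).
#' @return character vector of unique gene ids.
#' @export
gprGenes <- function(tree) {
  if (is.null(tree)) return(character())
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gprGenes), use.names = FALSE))
}

#' Evaluate a GPR rule under a gene deletion set
#'
#' Deleted genes are assigned FALSE, every other gene TRUE; the rule is
#' TRUE when the reaction can still be catalyzed. Reactions without a rule
#' (`NULL`) always evaluate TRUE, so they are never disabled by gene
#' deletions.
#'
#' @param rule a GPR expression tree (or `NULL`).
#' @param deletedGenes character vector of deleted gene ids.
#' @return logical scalar.
#' @examples
#' evaluateGPR(parseGPR("g1 or g2"), "g1")        # TRUE  (isozyme left)
#' evaluateGPR(parseGPR("g1 and g2"), "g1")       # FALSE (complex broken)
#' @export
evaluateGPR <- function(rule, deletedGenes = character()) {
  if (is.null(rule)) return(TRUE)
  if (is.character(rule)) return(!(rule %in% deletedGenes))
  vals <- vapply(rule$args, evaluateGPR, NA, deletedGenes = deletedGenes)
  if (rule$op == "and") all(vals) else any(vals)
}

## minimal disjunctive normal form: list of sorted gene-id vectors, no
## disjunct a superset of another, no duplicates.
.gprDNF <- function(tree, max_disjuncts = 1e5) {
  if (is.null(tree)) return(NULL)
  rec <- function(t) {
    if (is.character(t)) return(list(t))
    parts <- lapply(t$args, rec)
    if (t$op == "or") {
      out <- unlist(parts, recursive = FALSE, use.names = FALSE)
    } else {
      out <- list(character())
      for (p in parts) {
        out <- unlist(lapply(out, function(a)
          lapply(p, function(b) unique(c(a, b)))),
          recursive = FALSE, use.names = FALSE)
        if (length(out) > max_disjuncts)
          stop("GPR rule expands to more than ", max_disjuncts,
               " disjuncts; refusing")
      }
    }
    out
  }
  dis <- lapply(rec(tree), function(d) sort(unique(d)))
  dis <- dis[!duplicated(vapply(dis, paste, "", collapse = "\r"))]
  # prune disjuncts that are supersets of another (absorption)
  if (length(dis) > 1L) {
    dis <- dis[order(lengths(dis))]
    keep <- rep(TRUE, length(dis))
    for (a in seq_along(dis)) {
      if (!keep[a]) next
      for (b in seq_len(a - 1L)) {
        if (keep[b] && all(dis[[b]] %in% dis[[a]])) { keep[a] <- FALSE; break }
      }
    }
    dis <- dis[keep]
  }
  dis[order(vapply(dis, paste, "", collapse = "\r"))]
}

.dnfToTree <- function(dnf) {
  if (is.null(dnf) || length(dnf) == 0L) return(NULL)
  term <- function(d) if (length(d) == 1L) d else list(op = "and", args = as.list(d))
  if (length(dnf) == 1L) term(dnf[[1]])
  else list(op = "or", args = lapply(dnf, term))
}

#' Canonicalize all GPR rules of a model to minimal DNF
#'
#' Rewrites every rule as an OR of minimal AND-clauses (each clause a
#' minimal gene set sufficient for activity; clauses that are supersets of
#' other clauses are absorbed). Gene-deletion outcomes are provably
#' unchanged for every deletion set, but redundant enzymes become explicit
#' and gene-set lethality checks reduce to set comparisons.
#'
#' @param model a [MetabolicModel-class].
#' @return the model with canonicalized rules.
#' @examples
#' m <- fig1aModel()
#' m2 <- logicalTransform(m)
#' @export
logicalTransform <- function(model) {
  stopifnot(is(model, "MetabolicModel"))
  for (rid in names(model@gpr)) {
    tree <- model@gpr[[rid]]
    if (is.null(tree)) next
    nt <- .dnfToTree(.gprDNF(tree))
    model@gpr[[rid]] <- nt
    model@reactions$gpr[model@reactions$id == rid] <- gprToString(nt)
  }
  validObject(model)
  model
}

## reactions disabled by a gene deletion set (character ids)
.disabledReactions <- function(model, deletedGenes) {
  if (length(deletedGenes) == 0L) return(character())
  hit <- vapply(model@reactions$id, function(rid) {
    tree <- model@gpr[[rid]]
    !is.null(tree) && !evaluateGPR(tree, deletedGenes)
  }, NA)
  model@reactions$id[hit]
}
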