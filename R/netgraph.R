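## Topology baselines: directed metabolite-metabolite (MMN),
## reaction-reaction (RRN) and gene-gene (GGN) graphs, and the four
## classical centralities computed on the largest weakly connected
## component.

#' Default currency metabolites
#'
#' Ubiquitous cofactors and carriers removed before building RRN/GGN
#' graphs so they do not short-circuit the network: ATP/ADP/AMP,
#' NAD(P)(H), water, protons, CO2, phosphate, pyrophosphate, coenzyme A
#' and oxygen. Entries are compartment-free base names; they match a
#' metabolite whose id equals the entry or equals the entry plus a
#' `_<compartment>` suffix (e.g. `atp` matches `atp_c`). Fully
#' overridable via the `currencyIds` argument of [buildGraph()], where a
#' compartment-qualified id such as `atp_c` matches only that
#' compartment.
#'
#' @return character vector of base names.
#' @export
defaultCurrencyMetabolites <- function() {
  c("atp", "adp", "amp", "nad", "nadh", "nadp", "nadph",
    "h2o", "h", "co2", "pi", "ppi", "coa", "o2")
}

## resolve currency entries against model metabolite ids
.currencyMatch <- function(metIds, currencyIds) {
  if (!length(currencyIds)) return(character())
  hit <- metIds[metIds %in% currencyIds |
                  sub("_[^_]+$", "", metIds) %in% currencyIds]
  unknown <- setdiff(currencyIds,
                     c(metIds, unique(sub("_[^_]+$", "", metIds))))
  if (length(unknown))
    warning("currency entries matching no metabolite (ignored): ",
            paste(unknown, collapse = ", "))
  hit
}

## per-reaction substrate/product metabolite ids; reversible reactions
## (lb < 0 < ub) contribute both orientations
.reactionSides <- function(model) {
  S <- model@stoichiometry
  rids <- model@reactions$id
  rev <- model@reactions$lower_bound < 0 & model@reactions$upper_bound > 0
  subs <- vector("list", length(rids)); prods <- vector("list", length(rids))
  for (k in seq_along(rids)) {
    col <- S[, k]
    sb <- rownames(S)[col < 0]; pr <- rownames(S)[col > 0]
    if (rev[k]) { both <- union(sb, pr); sb <- both; pr <- both }
    subs[[k]] <- sb; prods[[k]] <- pr
  }
  names(subs) <- rids; names(prods) <- rids
  list(subs = subs, prods = prods)
}

#' Derive a connectivity graph from a model
#'
#' * MMN: metabolite m1 -> m2 when some reaction consumes m1 and produces
#'   m2 (reversible reactions contribute both orientations).
#' * RRN: reaction r1 -> r2 when a non-currency product of r1 is a
#'   substrate of r2.
#' * GGN: gene g1 -> g2 when g1 occurs in the GPR of some r1 and g2 in
#'   some r2 with an RRN edge r1 -> r2.
#'
#' Currency metabolites are removed for RRN/GGN only; the MMN keeps them
#' (they are nodes there, not mediators).
#'
#' @param model a [MetabolicModel-class].
#' @param kind `"mmn"`, `"rrn"` or `"ggn"`.
#' @param currencyIds currency metabolite list (base names or
#'   compartment-qualified ids); see [defaultCurrencyMetabolites()].
#' @return a [DerivedGraph-class].
#' @examples
#' g <- buildGraph(fig1aModel(), "rrn", currencyIds = character())
#' graphEdges(g)
#' @export
buildGraph <- function(model, kind = c("mmn", "rrn", "ggn"),
                       currencyIds = defaultCurrencyMetabolites()) {
  stopifnot(is(model, "MetabolicModel"))
  kind <- match.arg(kind)
  sides <- .reactionSides(model)
  if (kind == "mmn") {
    from <- character(); to <- character()
    for (k in seq_along(sides$subs)) {
      sb <- sides$subs[[k]]; pr <- sides$prods[[k]]
      if (length(sb) && length(pr)) {
        grid <- expand.grid(from = sb, to = pr, stringsAsFactors = FALSE)
        from <- c(from, grid$from); to <- c(to, grid$to)
      }
    }
    e <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
    e <- e[e$from != e$to, , drop = FALSE]
    return(new("DerivedGraph", kind = "mmn", nodes = model@metabolites$id,
               edges = e, currencyRemoved = character()))
  }
  cur <- .currencyMatch(model@metabolites$id, currencyIds)
  subs <- lapply(sides$subs, setdiff, cur)
  prods <- lapply(sides$prods, setdiff, cur)
  rids <- model@reactions$id
  from <- character(); to <- character()
  ## r1 -> r2 when a product of r1 is consumed by r2
  met2cons <- new.env(parent = emptyenv())
  for (k in seq_along(rids))
    for (m in subs[[k]])
      met2cons[[m]] <- c(met2cons[[m]], rids[k])
  for (k in seq_along(rids)) {
    cons <- unique(unlist(lapply(prods[[k]], function(m) met2cons[[m]]),
                          use.names = FALSE))
    cons <- setdiff(cons, rids[k])
    if (length(cons)) { from <- c(from, rep(rids[k], length(cons))); to <- c(to, cons) }
  }
  rrn <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  if (kind == "rrn")
    return(new("DerivedGraph", kind = "rrn", nodes = rids, edges = rrn,
               currencyRemoved = cur))
  ## GGN from the RRN
  rxnGenes <- lapply(setNames(rids, rids), function(r) gprGenes(model@gpr[[r]]))
  gfrom <- character(); gto <- character()
  for (k in seq_len(nrow(rrn))) {
    g1 <- rxnGenes[[rrn$from[k]]]; g2 <- rxnGenes[[rrn$to[k]]]
    if (length(g1) && length(g2)) {
      grid <- expand.grid(from = g1, to = g2, stringsAsFactors = FALSE)
      gfrom <- c(gfrom, grid$from); gto <- c(gto, grid$to)
    }
  }
  e <- unique(data.frame(from = gfrom, to = gto, stringsAsFactors = FALSE))
  e <- e[e$from != e$to, , drop = FALSE]
  new("DerivedGraph", kind = "ggn", nodes = model@genes, edges = e,
      currencyRemoved = cur)
}

#' Convert a derived graph to igraph
#' @param graph a [DerivedGraph-class].
#' @return an [igraph::igraph] directed graph.
#' @export
asIgraph <- function(graph) {
  stopifnot(is(graph, "DerivedGraph"))
  igraph::graph_from_data_frame(graph@edges, directed = TRUE,
                                vertices = data.frame(name = graph@nodes))
}

#' Node centralities of a derived graph
#'
#' Betweenness (directed shortest-path counts), closeness, eccentricity
#' and degree (in + out), computed on the largest weakly connected
#' component; closeness and eccentricity use undirected path lengths so
#' that they stay finite inside the component. Nodes outside the
#' component carry zero centralities and `in_lcc = FALSE`.
#'
#' @param graph a [DerivedGraph-class] with at least one node.
#' @param normalized normalize betweenness by the number of node pairs
#'   (rank-equivalent either way).
#' @param path optional TSV destination.
#' @return data.frame with columns `node`, `betweenness`, `closeness`,
#'   `eccentricity`, `degree`, `in_lcc`.
#' @export
centralities <- function(graph, normalized = FALSE, path = NULL) {
  stopifnot(is(graph, "DerivedGraph"))
  if (!length(graph@nodes)) stop("graph has no nodes")
  g <- asIgraph(graph)
  comp <- igraph::components(g, mode = "weak")
  biggest <- which.max(comp$csize)
  inLcc <- comp$membership == biggest
  sub <- igraph::induced_subgraph(g, which(inLcc))
  out <- data.frame(node = graph@nodes, betweenness = 0, closeness = 0,
                    eccentricity = 0, degree = 0L, in_lcc = inLcc,
                    stringsAsFactors = FALSE)
  idx <- match(igraph::V(sub)$name, graph@nodes)
  out$betweenness[idx] <- igraph::betweenness(sub, directed = TRUE,
                                              normalized = normalized)
  if (igraph::vcount(sub) > 1L) {
    out$closeness[idx] <- igraph::closeness(sub, mode = "all",
                                            normalized = TRUE)
    out$eccentricity[idx] <- igraph::eccentricity(sub, mode = "all")
  }
  out$degree[idx] <- igraph::degree(sub, mode = "all")
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Write a derived graph as an edge-list TSV
#' @param graph a [DerivedGraph-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeGraphEdges <- function(graph, path) {
  stopifnot(is(graph, "DerivedGraph"))
  write.table(graph@edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
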