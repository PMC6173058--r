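# derived graphs (MMN/RRN/GGN) and centrality baselines

chain3 <- function() {
  metabolicModel("chain3",
    data.frame(id = c("m1", "m2", "m3", "p")),
    data.frame(id = c("r1", "r2", "r3", "obj"), lower_bound = 0,
               upper_bound = c(10, 1000, 1000, 1000),
               gpr = c("gx", "gy", "gz", "")),
    list(r1 = c(m1 = 1), r2 = c(m1 = -1, m2 = 1),
         r3 = c(m2 = -1, m3 = 1), obj = c(m3 = -1)), "obj")
}

test_that("a linear chain gives a reaction-reaction path", {
  g <- buildGraph(chain3(), "rrn", currencyIds = character())
  e <- graphEdges(g)
  expect_setequal(paste(e$from, e$to), c("r1 r2", "r2 r3", "r3 obj"))
})

test_that("currency removal severs mediated edges and never adds any", {
  m <- chain3()
  gAll <- buildGraph(m, "rrn", currencyIds = character())
  gCut <- buildGraph(m, "rrn", currencyIds = c("m1", "m2", "m3"))
  expect_identical(nrow(graphEdges(gCut)), 0L)
  expect_setequal(g <- gCut@currencyRemoved, c("m1", "m2", "m3"))
  # dropping an id from the currency list can only add edges back
  gPart <- buildGraph(m, "rrn", currencyIds = c("m1", "m3"))
  expect_gte(nrow(graphEdges(gPart)), nrow(graphEdges(gCut)))
  expect_gte(nrow(graphEdges(gAll)), nrow(graphEdges(gPart)))
  # compartment-suffix matching: "atp" matches "atp_c"
  m2 <- metabolicModel("cur",
    data.frame(id = c("atp_c", "x_c")),
    data.frame(id = c("r1", "r2"), lower_bound = 0, upper_bound = 10),
    list(r1 = c(atp_c = 1, x_c = 1), r2 = c(atp_c = -1, x_c = -1)), "r2")
  gc <- buildGraph(m2, "rrn", currencyIds = "atp")
  expect_identical(gc@currencyRemoved, "atp_c")
  expect_warning(buildGraph(m2, "rrn", currencyIds = c("atp", "bogus")),
                 "bogus")
})

test_that("reversible reactions contribute both MMN orientations", {
  m <- metabolicModel("rev",
    data.frame(id = c("A", "B")),
    data.frame(id = c("conv", "src", "obj"),
               lower_bound = c(-1000, 0, 0), upper_bound = 1000),
    list(conv = c(A = -1, B = 1), src = c(A = 1), obj = c(B = -1)), "obj")
  e <- graphEdges(buildGraph(m, "mmn"))
  expect_true(all(c("A B", "B A") %in% paste(e$from, e$to)))
})

test_that("the gene-gene graph follows reaction adjacency", {
  g <- buildGraph(chain3(), "ggn", currencyIds = character())
  e <- graphEdges(g)
  expect_setequal(paste(e$from, e$to), c("gx gy", "gy gz"))
  expect_setequal(graphNodes(g), c("gx", "gy", "gz"))
})

test_that("centralities behave on canonical digraphs", {
  # middle of a path mediates all paths; endpoints mediate none
  path <- new("DerivedGraph", kind = "rrn", nodes = c("a", "b", "c"),
              edges = data.frame(from = c("a", "b"), to = c("b", "c")),
              currencyRemoved = character())
  ct <- centralities(path)
  expect_gt(ct$betweenness[ct$node == "b"], 0)
  expect_equal(ct$betweenness[ct$node %in% c("a", "c")], c(0, 0))
  expect_equal(ct$degree, c(1L, 2L, 1L))

  # 4-cycle: perfect symmetry, all betweenness equal (2 shortest paths
  # of length 2 and 3 cross each node)
  cyc <- new("DerivedGraph", kind = "rrn", nodes = letters[1:4],
             edges = data.frame(from = letters[1:4],
                                to = letters[c(2, 3, 4, 1)]),
             currencyRemoved = character())
  bc <- centralities(cyc)$betweenness
  expect_true(all(bc == bc[1]))
  expect_gt(bc[1], 0)

  # isolated node: outside the largest component, all zeros
  iso <- new("DerivedGraph", kind = "rrn", nodes = c("a", "b", "z"),
             edges = data.frame(from = "a", to = "b"),
             currencyRemoved = character())
  ct <- centralities(iso)
  expect_false(ct$in_lcc[ct$node == "z"])
  expect_equal(unlist(ct[ct$node == "z",
                         c("betweenness", "closeness", "eccentricity", "degree")]),
               c(betweenness = 0, closeness = 0, eccentricity = 0, degree = 0))
  expect_error(centralities(new("DerivedGraph", kind = "rrn",
                                nodes = character(),
                                edges = data.frame(from = character(),
                                                   to = character()),
                                currencyRemoved = character())),
               "no nodes")
})

test_that("centralities are invariant under node relabeling", {
  m <- ecoli_model()
  g <- suppressWarnings(buildGraph(m, "rrn"))   # core model lacks ppi
  ct <- centralities(g)
  # relabel: permute node identities consistently
  perm <- setNames(paste0("n", seq_along(g@nodes)), g@nodes)
  g2 <- new("DerivedGraph", kind = "rrn", nodes = unname(perm[g@nodes]),
            edges = data.frame(from = unname(perm[g@edges$from]),
                               to = unname(perm[g@edges$to])),
            currencyRemoved = character())
  ct2 <- centralities(g2)
  expect_equal(ct2$betweenness[match(perm[ct$node], ct2$node)],
               ct$betweenness)
  expect_equal(ct2$degree[match(perm[ct$node], ct2$node)], ct$degree)
})

test_that("graph exports write edge lists", {
  g <- buildGraph(chain3(), "rrn", currencyIds = character())
  path <- tempfile(fileext = ".tsv")
  writeGraphEdges(g, path)
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(df), nrow(graphEdges(g)))
})
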