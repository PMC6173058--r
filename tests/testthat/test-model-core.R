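# model representation, file input, GPR logic and knockout semantics

test_that("the shipped E. coli core model loads with the published shape", {
  m <- ecoli_model()
  expect_s4_class(m, "MetabolicModel")
  expect_length(reactionIds(m), 95)
  expect_length(metaboliteIds(m), 72)
  expect_length(geneIds(m), 137)
  expect_identical(objectiveId(m), "Biomass_Ecoli_core")
  # reversibility is encoded in bounds, never by duplicated reactions
  expect_false(anyDuplicated(reactionIds(m)) > 0)
  b <- reactionBounds(m)
  expect_true(all(b$lower_bound <= b$upper_bound))
  expect_equal(b$lower_bound[b$id == "EX_glc__D_e"], -10)
})

test_that("a minimal single-reaction SBML document parses", {
  path <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    ' xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    ' level="3" version="1" fbc:required="false">',
    '<model id="mini" fbc:strict="true">',
    '<listOfParameters>',
    '<parameter id="lb0" value="0" constant="true"/>',
    '<parameter id="ub10" value="10" constant="true"/>',
    '</listOfParameters>',
    '<listOfSpecies><species id="M_x" compartment="c"/></listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R_only" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub10">',
    '<listOfProducts><speciesReference species="M_x" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>'), path)
  m <- loadModel(path, objectiveId = "only")
  expect_length(reactionIds(m), 1)
  expect_length(metaboliteIds(m), 1)
  expect_identical(reactionIds(m), "only")   # R_ prefix stripped
})

test_that("SBML and JSON readers agree on the same toy model", {
  sb <- loadModel(system.file("extdata", "fig1a.xml", package = "ESSim"))
  mem <- fig1aModel()
  expect_setequal(reactionIds(sb), reactionIds(mem))
  expect_identical(objectiveId(sb), "OBJ")
  bs <- reactionBounds(sb); bm <- reactionBounds(mem)
  expect_equal(bs[order(bs$id), ], bm[order(bm$id), ],
               ignore_attr = TRUE)
  expect_equal(as.matrix(stoichiometry(sb))[metaboliteIds(mem), reactionIds(mem)],
               as.matrix(stoichiometry(mem)))
  # GPR truth tables identical
  for (r in reactionIds(mem))
    expect_identical(evaluateGPR(gprRules(sb)[[r]], "gC"),
                     evaluateGPR(gprRules(mem)[[r]], "gC"))
})

test_that("JSON serialization round-trips a model", {
  m <- fig1aModel()
  path <- tempfile(fileext = ".json")
  writeModelJSON(m, path)
  m2 <- loadModel(path)
  expect_identical(reactionIds(m2), reactionIds(m))
  expect_equal(reactionBounds(m2), reactionBounds(m))
  expect_equal(as.matrix(stoichiometry(m2)), as.matrix(stoichiometry(m)))
  expect_identical(objectiveId(m2), objectiveId(m))
  # GPR truth tables survive the round trip for all single deletions
  for (r in reactionIds(m)) for (g in geneIds(m))
    expect_identical(evaluateGPR(gprRules(m2)[[r]], g),
                     evaluateGPR(gprRules(m)[[r]], g))
})

test_that("loading errors are informative", {
  expect_error(loadModel(tempfile()), "not found")
  bad <- tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(loadModel(bad), "malformed")
  noobj <- tempfile(fileext = ".json")
  writeLines('{"id":"x","metabolites":[{"id":"m"}],
    "reactions":[{"id":"r","metabolites":{"m":1},"lower_bound":0,"upper_bound":1}],
    "genes":[]}', noobj)
  expect_error(loadModel(noobj), "objective")
  expect_s4_class(loadModel(noobj, objectiveId = "r"), "MetabolicModel")
  orphan <- tempfile(fileext = ".json")
  writeLines('{"id":"x","metabolites":[{"id":"m"}],
    "reactions":[{"id":"r","metabolites":{"m":1},"lower_bound":0,
      "upper_bound":1,"gene_reaction_rule":"gX or gY",
      "objective_coefficient":1}],
    "genes":[{"id":"gX"}]}', orphan)
  expect_error(loadModel(orphan), "undeclared genes: gY")
})

test_that("GPR evaluation follows the boolean semantics", {
  expect_true(evaluateGPR(parseGPR("g1 or g2"), "g1"))
  expect_false(evaluateGPR(parseGPR("g1 and g2"), "g1"))
  expect_false(evaluateGPR(parseGPR("(g1 and g2) or g3"), c("g1", "g3")))
  expect_true(evaluateGPR(parseGPR("(g1 and g2) or g3"), "g1"))
  expect_true(evaluateGPR(NULL, c("g1", "g2")))   # no rule, never disabled
  expect_error(parseGPR("g1 and (g2"), "malformed")
})

test_that("logical transformation canonicalizes without changing outcomes", {
  expect_identical(gprToString(ESSim:::.dnfToTree(ESSim:::.gprDNF(
    parseGPR("g1 or g1")))), "g1")
  expect_identical(gprToString(ESSim:::.dnfToTree(ESSim:::.gprDNF(
    parseGPR("(g1 and g2) or g1")))), "g1")
  expect_identical(gprToString(ESSim:::.dnfToTree(ESSim:::.gprDNF(
    parseGPR("g1 and (g2 or g3)")))), "(g1 and g2) or (g1 and g3)")

  # truth-table equivalence, exhaustively over all deletion sets
  rules <- c("g1 and (g2 or g3)", "(g1 and g2) or (g2 and g3) or g1",
             "((g1 or g2) and (g3 or g4)) or (g1 and g4)",
             "g1 or (g2 and (g3 or (g4 and g5)))")
  for (rule in rules) {
    tree <- parseGPR(rule)
    dnf <- ESSim:::.dnfToTree(ESSim:::.gprDNF(tree))
    genes <- gprGenes(tree)
    for (k in 0:length(genes)) {
      combos <- combn(genes, k, simplify = FALSE)
      for (del in combos)
        expect_identical(evaluateGPR(dnf, del), evaluateGPR(tree, del),
                         info = paste(rule, "del:", paste(del, collapse = ",")))
    }
  }
})

test_that("logicalTransform on the core model preserves gene-deletion outcomes", {
  m <- ecoli_model()
  mt <- logicalTransform(m)
  set.seed(11)
  for (k in 1:40) {
    del <- sample(geneIds(m), sample(1:3, 1))
    expect_identical(ESSim:::.disabledReactions(mt, del),
                     ESSim:::.disabledReactions(m, del))
  }
})

test_that("knockouts zero bounds, are idempotent and order-independent", {
  m <- ecoli_model()
  ko <- applyKnockout(m, "LDH_D")
  b <- reactionBounds(ko)
  expect_equal(unlist(b[b$id == "LDH_D", c("lower_bound", "upper_bound")]),
               c(lower_bound = 0, upper_bound = 0))
  # original untouched
  expect_false(all(reactionBounds(m)[reactionBounds(m)$id == "LDH_D",
                                     c("lower_bound", "upper_bound")] == 0))
  expect_equal(reactionBounds(applyKnockout(m, character())),
               reactionBounds(m))
  ab <- applyKnockout(applyKnockout(m, "PFK"), c("PFK", "FBA"))
  ba <- applyKnockout(applyKnockout(m, "FBA"), "PFK")
  expect_equal(reactionBounds(ab), reactionBounds(ba))
  expect_error(applyKnockout(m, "NOPE"), "NOPE")
})

test_that("gene knockouts disable reactions through their GPR", {
  m <- fig1aModel()
  ko <- applyKnockout(m, c("gC"), targets = "genes")
  b <- reactionBounds(ko)
  expect_equal(b$upper_bound[b$id == "C"], 0)
  expect_gt(b$upper_bound[b$id == "D"], 0)
  # isozyme rule: only the double deletion disables
  m2 <- metabolicModel("iso",
    data.frame(id = c("m1", "p")),
    data.frame(id = c("up", "r1", "obj"),
               lower_bound = 0, upper_bound = c(10, 1000, 1000),
               gpr = c("", "g1 or g2", "")),
    list(up = c(m1 = 1), r1 = c(m1 = -1, p = 1), obj = c(p = -1)),
    "obj")
  b1 <- reactionBounds(applyKnockout(m2, "g1", targets = "genes"))
  expect_gt(b1$upper_bound[b1$id == "r1"], 0)
  b12 <- reactionBounds(applyKnockout(m2, c("g1", "g2"), targets = "genes"))
  expect_equal(b12$upper_bound[b12$id == "r1"], 0)
})
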