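# enumeration of essential targets and minimal synthetic-lethal sets

test_that("essential singles of the toys and the core model", {
  expect_identical(findEssential(fig1aModel()), "A")
  # fully redundant parallel branches: nothing is essential
  par2 <- metabolicModel("par",
    data.frame(id = c("m1", "p")),
    data.frame(id = c("up", "r1", "r2", "obj"), lower_bound = 0,
               upper_bound = c(10, 1000, 1000, 1000)),
    list(up = c(m1 = 1), r1 = c(m1 = -1, p = 1),
         r2 = c(m1 = -1, p = 1), obj = c(p = -1)), "obj")
  expect_identical(findEssential(par2, analysisConfig(excludedIds = "up")),
                   character())
  ess <- findEssential(ecoli_model(), analysisConfig(excludedIds = "ATPM"))
  expect_true(all(c("EX_glc__D_e", "EX_h_e", "EX_nh4_e", "RPI") %in% ess))
  expect_identical(ess, sort(ess))
})

test_that("level-2 enumeration of toy A finds exactly {A} and {C,D}", {
  col <- enumerateMinimalLethalSets(fig1aModel(), analysisConfig(levelN = 2))
  expect_identical(set_keys(col), c("A", "C+D"))
  expect_identical(candidateIds(col), c("A", "B", "C", "D"))
  # n = 1 collapses to the essential list
  col1 <- enumerateMinimalLethalSets(fig1aModel(), analysisConfig(levelN = 1))
  expect_identical(unlist(lethalSets(col1, 1)), findEssential(fig1aModel()))
  expect_length(lethalSets(col1), 1)
})

test_that("brute force agrees with hand enumeration on the parallel-pairs fixture", {
  m <- parallel_pairs_model()
  col <- bruteForceLethalSets(m, analysisConfig(levelN = 2,
                                                excludedIds = "SRC"))
  expect_identical(set_keys(col, 1), character())
  expect_identical(set_keys(col, 2), c("a1+a2", "b1+b2", "c1+c2"))
})

test_that("brute force refuses absurd budgets with the required count", {
  expect_error(
    bruteForceLethalSets(ecoli_model(),
                         analysisConfig(levelN = 3, excludedIds = "ATPM"),
                         maxCombinations = 1000),
    "combinations")
})

test_that("pruned and exhaustive methods agree on randomized models (both target kinds)", {
  for (s in 1:8) {
    m <- randomLethalModel(s)
    for (tg in c("reactions", "genes")) {
      cfg <- analysisConfig(levelN = 3, targets = tg, excludedIds = "SRC")
      a <- enumerateMinimalLethalSets(m, cfg, method = "pruned")
      b <- bruteForceLethalSets(m, cfg)
      expect_identical(lethalSets(a), lethalSets(b),
                       info = sprintf("seed %d, %s", s, tg))
      expect_identical(candidateIds(a), candidateIds(b))
    }
  }
})

test_that("every stored set is lethal and minimal (spot check by direct FBA)", {
  m <- randomLethalModel(23)
  cfg <- analysisConfig(levelN = 3, excludedIds = "SRC")
  col <- enumerateMinimalLethalSets(m, cfg)
  sets <- unlist(lethalSets(col), recursive = FALSE, use.names = FALSE)
  expect_gt(length(sets), 0)
  for (s in sets) {
    expect_true(isLethal(m, s, config = cfg))
    for (r in s)
      expect_false(isLethal(m, setdiff(s, r), config = cfg))
  }
})

test_that("excluded ids and the objective never appear in stored sets", {
  col <- ecoli_level3()
  members <- unique(unlist(lethalSets(col)))
  expect_false("ATPM" %in% members)
  expect_false("Biomass_Ecoli_core" %in% members)
  expect_false("ATPM" %in% candidateIds(col))
  expect_length(candidateIds(col), 93)
})

test_that("repeated runs are deterministic", {
  m <- randomLethalModel(5)
  cfg <- analysisConfig(levelN = 3, excludedIds = "SRC")
  a <- enumerateMinimalLethalSets(m, cfg)
  b <- enumerateMinimalLethalSets(m, cfg)
  expect_identical(lethalSets(a), lethalSets(b))
})

test_that("collections round-trip through TSV and JSON", {
  col <- enumerateMinimalLethalSets(fig1bModel(), analysisConfig(levelN = 2))
  for (ext in c(".tsv", ".json")) {
    path <- tempfile(fileext = ext)
    writeLethalSets(col, path)
    back <- readLethalSets(path)
    expect_identical(lethalSets(back), lethalSets(col))
    expect_identical(candidateIds(back), candidateIds(col))
    expect_identical(back@levelN, col@levelN)
  }
})

test_that("checkpoint files are flushed per level", {
  dir <- tempfile()
  col <- enumerateMinimalLethalSets(fig1aModel(), analysisConfig(levelN = 2),
                                    checkpointDir = dir)
  expect_true(file.exists(file.path(dir, "lethal_sets_level1.tsv")))
  expect_true(file.exists(file.path(dir, "lethal_sets_level2.tsv")))
  flushed <- readLethalSets(file.path(dir, "lethal_sets_level2.tsv"))
  expect_identical(lethalSets(flushed), lethalSets(col))
})

test_that("levels above 3 warn about cost but still work", {
  m <- parallel_pairs_model()
  expect_warning(
    col <- enumerateMinimalLethalSets(
      m, analysisConfig(levelN = 4, excludedIds = "SRC")),
    "costly")
  expect_identical(set_keys(col, 2), c("a1+a2", "b1+b2", "c1+c2"))
  expect_length(lethalSets(col, 4), 0)
})
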