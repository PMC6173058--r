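# shared fixtures and a per-session cache for the expensive
# genome-scale runs so several test files can reuse one enumeration
.cache <- new.env(parent = emptyenv())

ecoli_model <- function() {
  if (is.null(.cache$ecoli))
    .cache$ecoli <- loadModel(system.file("extdata", "e_coli_core.json",
                                          package = "ESSim"))
  .cache$ecoli
}

# level-3 reaction-level run of the core model, ATPM excluded
ecoli_level3 <- function() {
  if (is.null(.cache$lvl3))
    .cache$lvl3 <- enumerateMinimalLethalSets(
      ecoli_model(), analysisConfig(levelN = 3, excludedIds = "ATPM"))
  .cache$lvl3
}

ecoli_mutant_level3 <- function() {
  if (is.null(.cache$lvl3mut)) {
    mut <- removeReactions(ecoli_model(), "LDH_D")
    .cache$lvl3mut <- enumerateMinimalLethalSets(
      mut, analysisConfig(levelN = 3, excludedIds = "ATPM"))
  }
  .cache$lvl3mut
}

# a linear chain SRC -> m1 -> ... -> OBJ with three 2-way parallel
# branch bundles in series: exactly three synthetic-lethal pairs
parallel_pairs_model <- function() {
  synthModel(lethalStructureSpec(
    essentialIds = character(),
    slGroups = list(c("a1", "a2"), c("b1", "b2"), c("c1", "c2"))),
    seed = 42)
}

# collections as comparable plain structures
set_keys <- function(collection, level = NULL) {
  sets <- if (is.null(level)) {
    unlist(lethalSets(collection), recursive = FALSE, use.names = FALSE)
  } else lethalSets(collection, level)
  sort(vapply(sets, paste, "", collapse = "+"))
}
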