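---
title: "Essentiality scoring of metabolic reactions and genes with ESSim"
author: "ESSim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Essentiality scoring of metabolic reactions and genes with ESSim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ESSim)
```

## The problem

Constraint-based (genome-scale) metabolic models describe a cell's
metabolism as a stoichiometric matrix $S$ with per-reaction flux bounds
and gene-protein-reaction (GPR) boolean rules. Flux balance analysis
(FBA) predicts a growth phenotype by maximizing the flux $v_{obj}$ of an
objective reaction subject to $Sv = 0$ and $lb \le v \le ub$. The usual
essentiality analysis asks a binary question — does deleting a reaction
or gene abolish growth? — which labels only a handful of targets in a
well-buffered network and says nothing about the redundancy structure
behind all the others.

ESSim turns the *synthetic lethality* structure of the model into a
graded, cross-model-comparable essentiality score. It enumerates every
minimal lethal knockout set up to a cardinality $n$ (the analysis level)
and aggregates, per target, how often and at what cardinality the target
participates.

## The score

Let $X$ be the number of candidate targets (all reactions or all genes,
minus the objective reaction and user-excluded pseudo reactions such as
a maintenance ATPase), and let $y_{ij}$ be the number of *minimal*
lethal sets of cardinality $j$ that contain target $i$. Then

$$ES_i \;=\; y_{i1} \;+\; \sum_{j=2}^{n} \frac{y_{ij}\,(j-1)!}{X^{\,j-1}}.$$

The weight has a counting interpretation: at level $j$ a fixed target
can appear in $X^{j-1}$ ordered, repetition-allowed knockout
combinations, and an unordered lethal set containing $i$ corresponds to
$(j-1)!$ orderings of its remaining members, so each term is the ordered
involvement fraction of target $i$ at level $j$
(`combinationCount(X, n)` exposes the population size $X^{n-1}$).
Essential targets have $y_{i1} = 1$ and, because only minimal sets are
counted, no higher-level involvement — they score exactly 1 at every
level. Scores of non-essential targets grow with the level
(every added term is non-negative) and concentrate on "hot spots" that
back up several fragile routes at once. Because the weights are
normalized by the model's own $X$, scores are comparable between models
of different size, which is what makes wild-type versus knockout-strain
comparisons meaningful.

Only *minimal* ("true") lethal sets are stored: a set is discarded when
any proper subset is already lethal. Without this rule every superset
of an essential reaction would inflate the counts of its partners.

## Lethality and its threshold

A knockout is lethal when the optimum of the knocked-out model drops to
or below a threshold (an infeasible model is lethal by definition). LP
optima are never exactly zero numerically, and published model analyses
almost universally use a growth-fraction cutoff, so the default
threshold is

$$\varepsilon \;=\; \max(10^{-6},\; 0.05 \times v_{obj}^{WT}),$$

i.e. a knockout counts as lethal when it destroys at least 95% of the
attainable objective. With this convention the E. coli core model
analyses in this package (essential exchanges, the wild-type versus
*ldh*-knockout comparison in the README) reproduce their reference
values; the threshold is a modeling choice, and `lethalityEpsilon` in
`analysisConfig()` overrides it with any absolute value. All enumeration
results on the core model are insensitive to the exact cutoff over
several orders of magnitude (the optimum under a knockout either stays
near the wild-type value or collapses), so the choice matters only for
marginal knockouts.

## Enumeration: pruned search plus an exhaustive oracle

`bruteForceLethalSets()` tests every combination with one LP each — the
simple, slow ground truth, guarded by a combination budget.

`enumerateMinimalLethalSets()` reaches the same collection with two
sound devices:

* **Survival certificates.** Every non-lethal LP solution is cached as
  its flux support. A candidate knockout set disjoint from any cached
  support cannot be lethal (that solution survives it), so no LP is
  needed. On the 95-reaction core model this resolves the overwhelming
  majority of the ~79,000 level-3 combinations without a solve.
* **Support restriction.** Any lethal set must intersect the support of
  *every* surviving optimal solution. The search therefore grows
  prefixes by candidates drawn from the support of a minimum-$|v|$
  optimal solution (computed by an LP over split fluxes $v = p - q$) of
  the current knockout model: the first member from the wild-type
  support, the second from the support of the first member's knockout
  model, and so on. This is complete for the same reason it is sound —
  a set avoiding the support leaves that solution feasible.

Both devices are exact, so `method = "pruned"`, `method = "exhaustive"`
and the brute-force oracle agree; the test suite verifies identity on
dozens of randomized models for both reaction and gene targeting, and a
`runOracleCheck()` entry point repeats that verification on demand.
Gene-level runs first canonicalize all GPR rules to minimal disjunctive
normal form (`logicalTransform()`; outcomes provably unchanged, isozyme
redundancy made explicit) and memoize lethality by the
disabled-reaction signature, since many gene sets silence the same
reactions.

Level defaults to 3 in the pipeline runners: level 2 misses the
three-way redundancy that is common in central metabolism, while level
4 multiplies cost for little extra resolution on models of this size.
Runs above level 3 warn about cost. Collections can be flushed per
level to a checkpoint directory.

## The LP layer

No linear-programming backend is available as an R package in this
stack, and FBA-sized problems are small and dense, so the package
carries its own bounded-variable two-phase revised simplex
(RcppArmadillo, dense basis factorization per iteration, Bland's rule
fallback against cycling; `1e-9` pivot tolerance). On the core model
(72 x 95) a solve takes ~20 ms and the full level-3 enumeration ~20 s.
Wild-type growth of the shipped core model reproduces the textbook
value 0.8739 /h to 12 digits. Degenerate optima are harmless: the
objective value is unique, and both pruning devices only consume
*feasibility* of solutions, never a particular vertex.

## Topology baselines

For benchmarking, `buildGraph()` derives directed metabolite-metabolite
(MMN), reaction-reaction (RRN) and gene-gene (GGN) graphs, and
`centralities()` computes betweenness, closeness, eccentricity and
degree on the largest weakly connected component (nodes outside it get
zeros and a flag). Currency metabolites — ubiquitous cofactors and
carriers (ATP/ADP/AMP, NAD(P)(H), H2O, H+, CO2, Pi, PPi, CoA, O2 by
default, compartment-aware and fully overridable) — are removed before
RRN/GGN construction so they do not short-circuit the network; the MMN
keeps them as ordinary nodes. Conventions that the literature leaves
open were fixed once: weak connectivity defines the component
(retaining more nodes than strong connectivity), reversible reactions
contribute both edge orientations, betweenness is directed and
unnormalized by default, and closeness/eccentricity use undirected
distances so they stay finite. Cell counts in score-versus-betweenness
cross-tabulations shift by a few units under other defensible
conventions (e.g. dropping O2 or CO2 from the currency list); rank-type
conclusions are stable.

## Synthetic test models

`synthModel()` realizes a requested lethal structure — serial segments
for essential singletons, k-way parallel bundles for k-way minimal
groups, "star" families (a direct branch shared by several pairs) for
overlapping pairs, plus blocked decoy reactions — as a mass-balanced
model with unit stoichiometry and uptake bound 10, so every LP answer
is hand-checkable. The generator *certifies* its output against the
brute-force oracle at build time and refuses structures it cannot
realize exactly. `randomLethalModel()` draws small random structures
(up to ~10 candidates) and decorates reactions with random isozyme (OR)
and complex (AND) gene rules.

What these fixtures emulate is the redundancy topology of real
networks: serial fragility, parallel buffering, shared backups. What
they do not emulate: realistic stoichiometric coupling through shared
cofactors, reversible loops, or growth-rate trade-offs — a passing
oracle check shows the enumeration and scoring machinery is exact, not
that any biological conclusion transfers. The E. coli core model tests
cover the realistic-coupling side.

## Problem sizes used in the tests

The test suite runs the full level-3 reaction analysis of the shipped
95-reaction E. coli core model (wild type and an LDH_D-deletion mutant)
and 50+ randomized oracle-equivalence models with up to 12 candidates at
level 3 for both target kinds; the whole suite completes in a few
minutes on one CPU. Genome-scale models (thousands of reactions) are
within reach of the same code path via the pruned method and
checkpointing, but are deliberately not exercised in the tests.

## Known limitations

* Scores depend on the model's medium (bounds) and objective; they are
  properties of a model under a condition, not of a gene in general.
* The $ES_i \le 1$ bound for non-essential targets is asserted and
  diagnosed (a violation warns and is reported unclamped) but not
  proven; it held in every model analyzed here.
* Level-4+ completeness of the pruned path follows the same argument
  but is not separately certified; use the exhaustive method where
  feasible.
* RAVEN-style SBML without a declared objective requires an explicit
  `objectiveId` — the package refuses to guess.
* The built-in simplex is dense; models beyond ~5,000 reactions would
  want a sparse LP backend behind the same `solverName` seam.
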