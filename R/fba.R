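## Flux balance analysis on top of the built-in bounded-variable simplex.
## Every LP in the package is of the form min/max c'v s.t. S v = 0,
## lb <= v <= ub, possibly with extra rows appended (objective-fixing for
## the minimum-|v| refinement).

## internal dense LP view of a model
.lpContext <- function(model) {
  S <- as.matrix(model@stoichiometry)
  list(S = S,
       m = nrow(S), n = ncol(S),
       lb = model@reactions$lower_bound,
       ub = model@reactions$upper_bound,
       rids = model@reactions$id,
       objIdx = match(model@objectiveId, model@reactions$id))
}

.solveRaw <- function(ctx, lb, ub) {
  cc <- numeric(ctx$n); cc[ctx$objIdx] <- 1
  res <- .lp_simplex(ctx$S, numeric(ctx$m), cc, lb, ub, maximize = TRUE)
  if (res$status == "iteration_limit")
    stop("LP solver failed: iteration limit reached")
  res
}

#' Solve flux balance analysis
#'
#' Maximizes the flux of the objective reaction subject to steady-state
#' mass balance (S v = 0) and the flux bounds. The objective value is
#' deterministic; the primal flux vector may be one of several degenerate
#' optima.
#'
#' @param model a [MetabolicModel-class].
#' @return a [FluxSolution-class].
#' @examples
#' m <- fig1aModel()
#' objectiveValue(solveFBA(m))   # 10: uptake-limited
#' @export
solveFBA <- function(model) {
  stopifnot(is(model, "MetabolicModel"))
  ctx <- .lpContext(model)
  res <- .solveRaw(ctx, ctx$lb, ctx$ub)
  if (res$status != "optimal")
    return(new("FluxSolution", status = "infeasible", objectiveValue = 0,
               fluxes = numeric()))
  new("FluxSolution", status = "optimal", objectiveValue = res$objective,
      fluxes = setNames(res$x, ctx$rids))
}

## Minimum-L1-norm flux vector among (near-)optimal solutions: the sparse
## "active core" certificate used by the pruned synthetic-lethality
## search. Split v = p - q with p, q >= 0 and minimize sum(p + q) while
## requiring the objective flux to stay within a 1e-6 relative margin of
## `fstar`. Returns NULL when the underlying model is infeasible.
.minAbsSolution <- function(ctx, lb, ub, fstar) {
  n <- ctx$n; m <- ctx$m
  lp <- pmax(lb, 0); up <- pmax(ub, 0)
  lq <- pmax(-ub, 0); uq <- pmax(-lb, 0)
  # columns: p (n), q (n), slack for objective row (1)
  A <- cbind(ctx$S, -ctx$S, numeric(m))
  orow <- numeric(2 * n + 1)
  orow[ctx$objIdx] <- 1; orow[n + ctx$objIdx] <- -1; orow[2 * n + 1] <- -1
  A <- rbind(A, orow)
  b <- c(numeric(m), fstar * (1 - 1e-6))
  cc <- c(rep(1, 2 * n), 0)
  res <- .lp_simplex(A, b, cc, c(lp, lq, 0), c(up, uq, Inf),
                     maximize = FALSE)
  if (res$status != "optimal") return(NULL)
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  setNames(v, ctx$rids)
}

#' Minimum-total-flux optimal solution
#'
#' Finds a flux vector of minimal summed absolute flux among the solutions
#' attaining (within a 1e-6 relative margin) the optimal objective. Its
#' support is the sparse "active core" of the model, which the pruned
#' synthetic-lethality search uses to restrict knockout candidates.
#'
#' @param model a [MetabolicModel-class].
#' @return a [FluxSolution-class] (status "infeasible" when the model
#'   cannot grow at all).
#' @export
minAbsFluxSolution <- function(model) {
  stopifnot(is(model, "MetabolicModel"))
  ctx <- .lpContext(model)
  res <- .solveRaw(ctx, ctx$lb, ctx$ub)
  if (res$status != "optimal")
    return(new("FluxSolution", status = "infeasible", objectiveValue = 0,
               fluxes = numeric()))
  v <- .minAbsSolution(ctx, ctx$lb, ctx$ub, res$objective)
  if (is.null(v))
    return(new("FluxSolution", status = "infeasible", objectiveValue = 0,
               fluxes = numeric()))
  new("FluxSolution", status = "optimal", objectiveValue = unname(v[ctx$objIdx]),
      fluxes = v)
}

## lethality threshold: absolute override, else 5% of wild-type objective.
## Lethality is "loss of at least 95% of attainable objective flux", the
## usual growth-threshold convention for in silico essentiality.
.lethalEps <- function(config, wildTypeObjective) {
  if (!is.na(config@lethalityEpsilon)) return(config@lethalityEpsilon)
  max(1e-6, 0.05 * wildTypeObjective)
}

#' Is a knockout set lethal?
#'
#' A knockout is lethal when the optimal objective flux of the knocked-out
#' model falls to or below the lethality threshold (an infeasible model
#' counts as lethal). With the default configuration the threshold is
#' `max(1e-6, 0.05 * wild-type objective)`.
#'
#' @param model a [MetabolicModel-class] (wild type).
#' @param knockout ids to delete.
#' @param targets `"reactions"` or `"genes"`.
#' @param config an [AnalysisConfig-class]; only `lethalityEpsilon` and
#'   `targets` are consulted (`targets` defaults to the `targets`
#'   argument).
#' @return logical scalar.
#' @examples
#' isLethal(fig1aModel(), "A")          # TRUE: sole source reaction
#' isLethal(fig1aModel(), "C")          # FALSE: D still feeds the objective
#' isLethal(fig1aModel(), c("C", "D"))  # TRUE: synthetic lethal pair
#' @export
isLethal <- function(model, knockout, targets = c("reactions", "genes"),
                     config = analysisConfig(targets = targets)) {
  targets <- match.arg(targets)
  wt <- solveFBA(model)
  eps <- .lethalEps(config, objectiveValue(wt))
  ko <- applyKnockout(model, knockout, targets)
  sol <- solveFBA(ko)
  solutionStatus(sol) != "optimal" || objectiveValue(sol) <= eps
}
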