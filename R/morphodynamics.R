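# Growth orchestration: division -> mechanical relaxation -> reaction-diffusion.

#' Growth-simulation configuration
#'
#' @param mech a [MechParams-class]
#' @param rd an [RDParams-class]
#' @param nStart,nEnd starting and final cell counts (defaults 10 and 1000)
#' @param fluctuation relative amplitude of the initial equilibrium
#'   fluctuation (default 0.01)
#' @param seed integer seed for the whole run
#' @param snapshotCells cell counts at which to keep network+state snapshots
#' @return a [SimulationConfig-class]
#' @export
simulationConfig <- function(mech = mechParams(), rd = rdParams(),
                             nStart = 10, nEnd = 1000, fluctuation = 0.01,
                             seed = 1, snapshotCells = c(250, 500, 1000)) {
  new("SimulationConfig", mech = mech, rd = rd, nStart = nStart, nEnd = nEnd,
      fluctuation = fluctuation, seed = seed, snapshotCells = snapshotCells)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d -> %d cells, fluctuation %g, seed %d\n",
              as.integer(object@nStart), as.integer(object@nEnd),
              object@fluctuation, as.integer(object@seed)))
  show(object@mech)
  show(object@rd)
})

#' Run one growth simulation
#'
#' Initializes the network at `nStart` cells and the state at the perturbed
#' homogeneous equilibrium, then repeats cycles of (1) division of the
#' largest cell by a wall through its centroid at a uniform random angle,
#' (2) mechanical relaxation of vertex positions, and (3) one full
#' reaction-diffusion run, until the network has `nEnd` cells. Daughters
#' inherit the mother's concentrations unchanged. Fully deterministic per
#' seed: all randomness (initial geometry, fluctuation, division angles and
#' their redraws) comes from one stream seeded once at the start.
#'
#' @param config a [SimulationConfig-class]
#' @return list with `network`, `state`, `snapshots` (named list of
#'   `list(network, state)` keyed by cell count) and `log` (per-cycle
#'   data.frame: cycle, nCells, relaxIterations, relaxConverged)
#' @examples
#' res <- runSimulation(simulationConfig(nStart = 10, nEnd = 14, seed = 1))
#' nCells(res$network)
#' @export
runSimulation <- function(config) {
  validObject(config)
  set.seed(as.integer(config@seed))
  net <- initNetwork(as.integer(config@nStart), seed = NULL, mech = config@mech)
  state <- perturbEquilibrium(net, config@rd, config@fluctuation, seed = NULL)

  snapshots <- list()
  keep <- as.integer(config@snapshotCells)
  logRows <- list()
  cycle <- 0L
  if (nCells(net) %in% keep)
    snapshots[[as.character(nCells(net))]] <- list(network = net, state = state)

  while (nCells(net) < config@nEnd) {
    cycle <- cycle + 1L
    mother <- largestCell(net)
    net <- divideCellRandom(net, mother)
    state <- rdState(c(state@u, state@u[mother]), c(state@v, state@v[mother]))
    net <- relaxNetwork(net, config@mech)
    state <- rdRun(state, net, config@rd)
    logRows[[cycle]] <- data.frame(
      cycle = cycle, nCells = nCells(net),
      relaxIterations = net@status$iterations,
      relaxConverged = net@status$converged)
    if (nCells(net) %in% keep)
      snapshots[[as.character(nCells(net))]] <- list(network = net, state = state)
  }
  list(network = net, state = state, snapshots = snapshots,
       log = if (length(logRows)) do.call(rbind, logRows) else
         data.frame(cycle = integer(), nCells = integer(),
                    relaxIterations = integer(), relaxConverged = logical()))
}

#' Run independent replicate simulations
#'
#' Replicate k runs [runSimulation()] with seed `baseSeed + k - 1`; each
#' replicate redraws the initial geometry, the fluctuation and all division
#' angles. Final states are classified with [classifyPattern()].
#'
#' @param config a [SimulationConfig-class] (its seed is ignored)
#' @param nRep number of replicates (>= 1)
#' @param baseSeed seed of the first replicate
#' @param grid optional one-row data.frame locating the sweep in parameter
#'   space (stored in the result)
#' @return a [SweepResult-class]
#' @export
runReplicates <- function(config, nRep, baseSeed = config@seed, grid = NULL) {
  if (nRep < 1) stop("nRep must be at least 1")
  results <- vector("list", nRep)
  for (k in seq_len(nRep)) {
    cfg <- config
    cfg@seed <- as.numeric(baseSeed) + k - 1
    res <- runSimulation(cfg)
    results[[k]] <- list(network = res$network, state = res$state,
                         summary = classifyPattern(res$network, res$state,
                                                   config@rd),
                         seed = cfg@seed)
  }
  new("SweepResult", results = results,
      grid = if (is.null(grid)) data.frame() else grid)
}

setMethod("show", "SweepResult", function(object) {
  labs <- vapply(object@results, function(r) r$summary@rootLabel, character(1))
  cat("SweepResult with", length(object@results), "replicates\n")
  if (nrow(object@grid)) {
    cat("  grid point:",
        paste(names(object@grid), unlist(object@grid), sep = "=", collapse = " "),
        "\n")
  }
  print(table(rootLabel = labs))
})

#' Pattern summaries of a sweep
#' @param sweep a [SweepResult-class]
#' @return data.frame with one row per replicate: seed, polarity, nRegions,
#'   rootLabel, minimum circularity
#' @export
sweepSummary <- function(sweep) {
  do.call(rbind, lapply(sweep@results, function(r) {
    s <- r$summary
    data.frame(seed = r$seed,
               polarity = if (length(s@polarity)) s@polarity else NA_character_,
               nRegions = s@nRegions, rootLabel = s@rootLabel,
               circularityMin = if (nrow(s@regionMetrics))
                 min(s@regionMetrics$circularity) else NA_real_)
  }))
}

#' Sweep a parameter grid
#'
#' Cartesian sweep over activator synthesis strengths, inhibitor synthesis
#' strengths and saturation modes, with `nRep` replicates per grid point.
#' Each saturation mode fixes the pair (uMax factor, alphaM): the reference
#' regimes are `high` (uMax = 10 u0, alphaM = 1) giving spotted patterns and
#' `low` (uMax = 1.1 u0, alphaM = -0.1) giving reverse-spotted patterns.
#'
#' @param alphaSValues,gammaValues non-empty numeric grids
#' @param uMaxModes named list of `list(uMaxFactor, alphaM)` pairs
#' @param config base [SimulationConfig-class] (its `rd` supplies all other
#'   constants)
#' @param nRep replicates per grid point
#' @param baseSeed seed of the first replicate of the first grid point;
#'   successive grid points use consecutive seed blocks
#' @return list with `sweeps` (list of [SweepResult-class]) and `summary`
#'   (data.frame of pattern-class frequencies per grid point)
#' @export
runGrid <- function(alphaSValues, gammaValues,
                    uMaxModes = list(high = list(uMaxFactor = 10, alphaM = 1.0),
                                     low = list(uMaxFactor = 1.1, alphaM = -0.1)),
                    config = simulationConfig(), nRep = 20,
                    baseSeed = config@seed) {
  if (length(alphaSValues) == 0) stop("alphaSValues must be non-empty")
  if (length(gammaValues) == 0) stop("gammaValues must be non-empty")
  if (length(uMaxModes) == 0) stop("uMaxModes must be non-empty")
  sweeps <- list()
  rows <- list()
  seed <- as.numeric(baseSeed)
  for (m in names(uMaxModes)) {
    mode <- uMaxModes[[m]]
    for (a in alphaSValues) for (g in gammaValues) {
      rd <- rdParams(alphaS = a, alphaD = config@rd@alphaD,
                     alphaM = mode$alphaM, beta = config@rd@beta, gamma = g,
                     delta = config@rd@delta, epsilon = config@rd@epsilon,
                     Du = config@rd@Du, Dv = config@rd@Dv,
                     uMaxFactor = mode$uMaxFactor,
                     dt = config@rd@dt, Td = config@rd@Td)
      cfg <- config
      cfg@rd <- rd
      grid <- data.frame(alphaS = a, gamma = g,
                         uMaxFactor = mode$uMaxFactor, alphaM = mode$alphaM,
                         mode = m)
      sw <- runReplicates(cfg, nRep, baseSeed = seed, grid = grid)
      seed <- seed + nRep
      sweeps[[length(sweeps) + 1L]] <- sw
      ss <- sweepSummary(sw)
      rows[[length(rows) + 1L]] <- cbind(
        grid,
        meanRegions = mean(ss$nRegions),
        spottedFrac = mean(ss$polarity == "spotted", na.rm = TRUE),
        t(as.matrix(table(factor(ss$rootLabel,
                                 levels = c("1", "2", "3", "4", "C", "other"))))))
    }
  }
  list(sweeps = sweeps, summary = do.call(rbind, rows))
}
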