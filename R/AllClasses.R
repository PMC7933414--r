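#' Polygonal cell network (vertex model)
#'
#' Cells are simple polygons tightly arranged in 2-D, separated by straight
#' walls and sharing vertices. The network is stored as a vertex coordinate
#' matrix plus one counter-clockwise vertex cycle per cell; the wall table
#' (endpoints and the one or two adjacent cells) is derived bookkeeping kept
#' in sync by the constructors and by [divideCell()].
#'
#' @slot pos numeric matrix, one row per vertex, columns x and y
#'   (dimensionless length units).
#' @slot cells list of integer vectors; element i is cell i's vertex cycle,
#'   counter-clockwise.
#' @slot walls data.frame with columns `v1`, `v2` (vertex ids, `v1 < v2`),
#'   `c1`, `c2` (adjacent cell ids; `c2` is `NA` for boundary walls).
#' @slot status list of bookkeeping from the last mechanical relaxation
#'   (`iterations`, `converged`, `max_step`).
#'
#' @export
setClass("CellNetwork",
  representation(pos = "matrix", cells = "list", walls = "data.frame",
                 status = "list"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@pos) != 2) msg <- c(msg, "pos must have two columns")
    if (!all(is.finite(object@pos))) msg <- c(msg, "vertex positions must be finite")
    nv <- nrow(object@pos)
    for (cyc in object@cells) {
      if (length(cyc) < 3) { msg <- c(msg, "every cell needs at least 3 vertices"); break }
      if (any(cyc < 1L | cyc > nv)) { msg <- c(msg, "cell cycle references unknown vertex"); break }
    }
    if (nrow(object@walls) > 0 &&
        !all(c("v1", "v2", "c1", "c2") %in% names(object@walls)))
      msg <- c(msg, "walls must have columns v1, v2, c1, c2")
    if (length(msg)) msg else TRUE
  })

#' Mechanical parameters of the vertex model
#'
#' Wall elasticity pulls wall lengths toward the rest length `l0` with
#' spring constant `kS`; each cell presses outward on its walls with turgor
#' pressure `kP` divided by its area; vertices move overdamped with mobility
#' `kT`. `T` is the simulated time between successive divisions of the
#' largest cell. The `relax*` fields control the explicit-Euler relaxation
#' of vertex positions toward mechanical equilibrium.
#'
#' @slot kT,kS,l0,kP,T positive numerics (defaults 0.5, 1.0, 0.3, 1.0, 50).
#' @slot relaxDt,relaxTol,relaxMaxIter Euler step, per-step displacement
#'   threshold declaring equilibrium, and iteration cap.
#' @export
setClass("MechParams",
  representation(kT = "numeric", kS = "numeric", l0 = "numeric",
                 kP = "numeric", T = "numeric", relaxDt = "numeric",
                 relaxTol = "numeric", relaxMaxIter = "numeric"),
  validity = function(object) {
    vals <- c(object@kT, object@kS, object@l0, object@kP, object@T,
              object@relaxDt, object@relaxTol, object@relaxMaxIter)
    if (any(!is.finite(vals)) || any(vals <= 0))
      "all mechanical parameters must be positive and finite" else TRUE
  })

#' Reaction-diffusion parameters of the activator-inhibitor system
#'
#' Per-cell dynamics on the cell adjacency graph:
#' `du/dt = phi(epsilon + alphaS*u - beta*v) - (alphaD + psi)*u + Du*sum_j(u_j - u_i)`,
#' `dv/dt = gamma*u - delta*v + Dv*sum_j(v_j - v_i)`,
#' where `phi` clamps activator synthesis to `[0, alphaD*uMax]` and `psi`
#' adds `alphaM` to the activator decay rate in marginal (boundary) cells.
#'
#' @slot alphaS activator self-induction strength.
#' @slot alphaD activator decay rate.
#' @slot alphaM extra activator decay in marginal cells (may be negative).
#' @slot beta repression of the activator by the inhibitor.
#' @slot gamma induction of the inhibitor by the activator.
#' @slot delta inhibitor decay rate.
#' @slot epsilon basal activator synthesis.
#' @slot Du,Dv diffusion coefficients (per-neighbour, unweighted).
#' @slot uMax activator saturation value (must exceed the homogeneous
#'   equilibrium u0 when that equilibrium exists).
#' @slot dt Euler time step (default 0.02).
#' @slot Td total simulated time per reaction-diffusion run (default 50).
#' @export
setClass("RDParams",
  representation(alphaS = "numeric", alphaD = "numeric", alphaM = "numeric",
                 beta = "numeric", gamma = "numeric", delta = "numeric",
                 epsilon = "numeric", Du = "numeric", Dv = "numeric",
                 uMax = "numeric", dt = "numeric", Td = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@dt <= 0) msg <- c(msg, "dt must be positive")
    if (object@Td < object@dt) msg <- c(msg, "Td must be at least dt")
    if (object@Du < 0 || object@Dv < 0) msg <- c(msg, "diffusion coefficients must be non-negative")
    if (object@uMax <= 0) msg <- c(msg, "uMax must be positive")
    den <- object@beta * object@gamma - (object@alphaS - object@alphaD) * object@delta
    if (den > 0) {
      u0 <- object@delta * object@epsilon / den
      if (object@uMax <= u0) msg <- c(msg, "uMax must exceed the homogeneous equilibrium u0")
    }
    if (length(msg)) msg else TRUE
  })

#' Per-cell activator/inhibitor state
#'
#' @slot u,v numeric vectors of activator and inhibitor concentrations,
#'   aligned with the cell ids of a [CellNetwork-class].
#' @export
setClass("RDState",
  representation(u = "numeric", v = "numeric"),
  validity = function(object) {
    if (length(object@u) != length(object@v))
      "u and v must have the same length"
    else if (any(!is.finite(object@u)) || any(!is.finite(object@v)))
      "concentrations must be finite"
    else if (any(object@u < 0) || any(object@v < 0))
      "concentrations must be non-negative"
    else TRUE
  })

#' Growth-simulation configuration
#'
#' @slot mech a [MechParams-class].
#' @slot rd an [RDParams-class].
#' @slot nStart,nEnd starting and final cell counts (defaults 10 and 1000).
#' @slot fluctuation relative amplitude of the uniform fluctuation applied
#'   to the homogeneous equilibrium at initialization (default 0.01).
#' @slot seed integer seed driving all randomness of the run.
#' @slot snapshotCells cell counts at which network+state snapshots are kept.
#' @export
setClass("SimulationConfig",
  representation(mech = "MechParams", rd = "RDParams", nStart = "numeric",
                 nEnd = "numeric", fluctuation = "numeric", seed = "numeric",
                 snapshotCells = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nStart < 1) msg <- c(msg, "nStart must be at least 1")
    if (object@nEnd < object@nStart) msg <- c(msg, "nEnd must be at least nStart")
    if (object@fluctuation < 0 || object@fluctuation >= 1)
      msg <- c(msg, "fluctuation must be in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Classified final pattern of the activator field
#'
#' @slot polarity `"spotted"` (minority phase has high activator),
#'   `"reverse_spotted"` (minority phase low), or `NA` for homogeneous fields.
#' @slot nRegions number of connected minority-phase regions.
#' @slot rootLabel one of `"1", "2", "3", "4", "C", "other"`.
#' @slot regionMetrics data.frame with one row per region: `area`,
#'   `areaFraction`, `perimeter`, `circularity`, `centroidX`, `centroidY`,
#'   `angularExtent` (radians around the network centroid).
#' @slot homogeneous logical; `TRUE` when the field was declared flat.
#' @export
setClass("PatternSummary",
  representation(polarity = "character", nRegions = "integer",
                 rootLabel = "character", regionMetrics = "data.frame",
                 homogeneous = "logical"),
  validity = function(object) {
    if (object@nRegions != nrow(object@regionMetrics))
      "nRegions must match the number of regionMetrics rows"
    else if (!object@rootLabel %in% c("1", "2", "3", "4", "C", "other"))
      "rootLabel must be one of 1, 2, 3, 4, C, other"
    else TRUE
  })

#' Replicate sweep result
#'
#' @slot results list with one entry per replicate: `network`, `state`,
#'   `summary` (a [PatternSummary-class]) and `seed`.
#' @slot grid one-row data.frame locating the sweep in parameter space
#'   (`alphaS`, `gamma`, `uMaxFactor`, `alphaM`), or zero rows if not from
#'   a grid.
#' @export
setClass("SweepResult",
  representation(results = "list", grid = "data.frame"),
  validity = function(object) {
    ok <- vapply(object@results, function(r)
      all(c("network", "state", "summary", "seed") %in% names(r)), logical(1))
    if (!all(ok)) "each replicate needs network, state, summary and seed" else TRUE
  })

#' Generative model for synthetic dental cohorts
#'
#' Encodes the study design the association statistics assume: genotype
#' frequencies, covariate distributions and per-tooth logistic effects on
#' the dichotomized root classes.
#'
#' @slot n cohort size.
#' @slot genotypeProbs probabilities of VV, VA, AA (sum to 1).
#' @slot ageRange min and max age in years (uniform integer ages).
#' @slot femaleProb probability of female sex.
#' @slot regionProbs probabilities of region scores 0..4 (number of
#'   grandparents from the Ryukyu Islands).
#' @slot rootEffects data.frame with columns `tooth`, `test` (the class
#'   modelled as the logistic "test" outcome), `prevalence` (marginal
#'   prevalence of the test class), `betaGenotype`, `betaAge`, `betaSex`,
#'   `betaRegion` (log odds ratios; genotype coded as A-allele dosage 0/1/2,
#'   sex as male = 0 / female = 1).
#' @slot discordantRate probability that a generated individual has
#'   different root codes on the left and right side.
#' @export
setClass("CohortModel",
  representation(n = "numeric", genotypeProbs = "numeric",
                 ageRange = "numeric", femaleProb = "numeric",
                 regionProbs = "numeric", rootEffects = "data.frame",
                 discordantRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@n < 1) msg <- c(msg, "n must be at least 1")
    if (length(object@genotypeProbs) != 3 ||
        abs(sum(object@genotypeProbs) - 1) > 1e-8 || any(object@genotypeProbs < 0))
      msg <- c(msg, "genotypeProbs must be 3 non-negative values summing to 1")
    if (length(object@regionProbs) != 5 ||
        abs(sum(object@regionProbs) - 1) > 1e-8)
      msg <- c(msg, "regionProbs must be 5 values summing to 1")
    if (object@discordantRate < 0 || object@discordantRate > 1)
      msg <- c(msg, "discordantRate must be in [0, 1]")
    need <- c("tooth", "test", "prevalence", "betaGenotype", "betaAge",
              "betaSex", "betaRegion")
    if (!all(need %in% names(object@rootEffects)))
      msg <- c(msg, "rootEffects is missing required columns")
    if (length(msg)) msg else TRUE
  })
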