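# Activator-inhibitor dynamics on the cell adjacency graph.

#' Reaction-diffusion parameter set
#'
#' Defaults are the reference constants of the root-patterning simulations:
#' `alphaD = beta = delta = epsilon = 1`, `Du = 0.25`, `Dv = 0.5`, Euler step
#' `dt = 0.02` and per-cycle duration `Td = 50`. The saturation value can be
#' given directly (`uMax`) or as a multiple of the homogeneous equilibrium
#' (`uMaxFactor`, default 10; the low-saturation regime uses 1.1).
#'
#' @param alphaS activator self-induction strength (default 1.8).
#' @param alphaD,alphaM,beta,gamma,delta,epsilon,Du,Dv see [RDParams-class].
#' @param uMax saturation value, or `NULL` to derive it from `uMaxFactor`.
#' @param uMaxFactor saturation as a multiple of u0 (used when `uMax` is NULL).
#' @param dt,Td Euler step and total time per run.
#' @return an [RDParams-class]
#' @examples
#' p <- rdParams(alphaS = 1.8, gamma = 1.0)
#' equilibriumState(p)   # u0 = v0 = 5
#' @export
rdParams <- function(alphaS = 1.8, alphaD = 1.0, alphaM = 1.0, beta = 1.0,
                     gamma = 1.0, delta = 1.0, epsilon = 1.0,
                     Du = 0.25, Dv = 0.5, uMax = NULL, uMaxFactor = 10,
                     dt = 0.02, Td = 50) {
  if (is.null(uMax)) {
    den <- beta * gamma - (alphaS - alphaD) * delta
    if (den <= 0)
      stop("no positive homogeneous equilibrium: beta*gamma - (alphaS - alphaD)*delta <= 0")
    uMax <- uMaxFactor * delta * epsilon / den
  }
  new("RDParams", alphaS = alphaS, alphaD = alphaD, alphaM = alphaM,
      beta = beta, gamma = gamma, delta = delta, epsilon = epsilon,
      Du = Du, Dv = Dv, uMax = uMax, dt = dt, Td = Td)
}

setMethod("show", "RDParams", function(object) {
  cat(sprintf(
    "RDParams: alphaS=%g alphaD=%g alphaM=%g beta=%g gamma=%g delta=%g epsilon=%g\n          Du=%g Dv=%g uMax=%g dt=%g Td=%g\n",
    object@alphaS, object@alphaD, object@alphaM, object@beta, object@gamma,
    object@delta, object@epsilon, object@Du, object@Dv, object@uMax,
    object@dt, object@Td))
})

#' Homogeneous equilibrium of non-marginal cells
#'
#' `u0 = delta*epsilon / (beta*gamma - (alphaS - alphaD)*delta)` and
#' `v0 = gamma*epsilon / (beta*gamma - (alphaS - alphaD)*delta)`; defined
#' only when the denominator is positive.
#'
#' @param params an [RDParams-class]
#' @return list with elements `u0` and `v0`
#' @export
equilibriumState <- function(params) {
  den <- params@beta * params@gamma -
    (params@alphaS - params@alphaD) * params@delta
  if (den <= 0)
    stop("no positive homogeneous equilibrium: denominator <= 0")
  list(u0 = params@delta * params@epsilon / den,
       v0 = params@gamma * params@epsilon / den)
}

#' Saturating synthesis clamp
#'
#' Piecewise-linear clamp applied to the activator synthesis rate:
#' 0 below 0, identity on `[0, alphaD*uMax]`, `alphaD*uMax` above.
#'
#' @param x numeric vector
#' @param params an [RDParams-class]
#' @return clamped numeric vector
#' @export
phiClamp <- function(x, params) {
  pmin(pmax(x, 0), params@alphaD * params@uMax)
}

#' Marginal-cell decay modifier
#'
#' `alphaM` for marginal (boundary) cells, 0 otherwise; added to the
#' activator decay rate. Keeps activator spots away from the network edge
#' when positive.
#'
#' @param network a [CellNetwork-class]
#' @param cellId integer cell id
#' @param params an [RDParams-class]
#' @return numeric scalar
#' @export
psiMarginal <- function(network, cellId, params) {
  if (isMarginal(network, cellId)) params@alphaM else 0
}

#' Per-cell state constructor
#' @param u,v numeric vectors (equal length) of activator and inhibitor
#' @return an [RDState-class]
#' @export
rdState <- function(u, v) new("RDState", u = as.numeric(u), v = as.numeric(v))

setMethod("show", "RDState", function(object) {
  cat(sprintf("RDState over %d cells: u in [%.4g, %.4g], v in [%.4g, %.4g]\n",
              length(object@u), min(object@u), max(object@u),
              min(object@v), max(object@v)))
})

#' Activator concentrations
#' @param state an [RDState-class]
#' @return numeric vector
#' @export
activator <- function(state) state@u

#' Inhibitor concentrations
#' @param state an [RDState-class]
#' @return numeric vector
#' @export
inhibitor <- function(state) state@v

.rdInputs <- function(state, network) {
  n <- nCells(network)
  if (length(state@u) != n)
    stop("state has ", length(state@u), " cells but network has ", n)
  adj <- adjacencyList(network)
  lens <- lengths(adj)
  list(ptr = as.integer(c(0L, cumsum(lens))),
       idx = as.integer(unlist(adj, use.names = FALSE) - 1L),
       marginal = marginalCells(network))
}

.rdRunSteps <- function(state, network, params, nSteps) {
  inp <- .rdInputs(state, network)
  res <- cpp_rd_run(state@u, state@v, inp$ptr, inp$idx, inp$marginal,
                    params@alphaS, params@alphaD, params@alphaM,
                    params@beta, params@gamma, params@delta, params@epsilon,
                    params@Du, params@Dv, params@uMax, params@dt,
                    as.integer(nSteps))
  rdState(res$u, res$v)
}

#' One forward-Euler step of the activator-inhibitor dynamics
#'
#' Updates every cell's `u` and `v` by one step `dt`, then clips `u` to
#' `[0, uMax]` and `v` to `[0, Inf)`.
#'
#' @param state an [RDState-class] aligned to `network`
#' @param network a [CellNetwork-class]
#' @param params an [RDParams-class]
#' @return the updated [RDState-class]
#' @export
rdStep <- function(state, network, params) .rdRunSteps(state, network, params, 1L)

#' Run the reaction-diffusion dynamics for one full cycle
#'
#' Applies exactly `round(Td/dt)` Euler steps (2500 at the defaults),
#' approximating the near-steady state reached within one division interval.
#'
#' @inheritParams rdStep
#' @return the final [RDState-class]
#' @export
rdRun <- function(state, network, params) {
  .rdRunSteps(state, network, params, round(params@Td / params@dt))
}

#' Equilibrium state with a uniform random fluctuation
#'
#' `u_i = u0 * (1 + fraction * r_i)` and `v_i = v0 * (1 + fraction * s_i)`
#' with `r_i, s_i` independent uniform on `[-1, 1]` (all `r` drawn first,
#' then all `s`). Deterministic per seed.
#'
#' @param network a [CellNetwork-class]
#' @param params an [RDParams-class]
#' @param fraction relative fluctuation amplitude in `[0, 1)` (default 0.01)
#' @param seed optional integer seed; `NULL` uses the current RNG state
#' @return an [RDState-class]
#' @export
perturbEquilibrium <- function(network, params, fraction = 0.01, seed = NULL) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  eq <- equilibriumState(params)
  n <- nCells(network)
  r <- runif(n, -1, 1)
  s <- runif(n, -1, 1)
  rdState(eq$u0 * (1 + fraction * r), eq$v0 * (1 + fraction * s))
}

#' Write the per-cell state as CSV
#'
#' Columns: `cell_id, x_centroid, y_centroid, u, v, marginal` (0/1).
#'
#' @param state an [RDState-class]
#' @param network the matching [CellNetwork-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeStateCSV <- function(state, network, path) {
  cen <- cellCentroids(network)
  df <- data.frame(cell_id = seq_len(nCells(network)),
                   x_centroid = cen[, 1], y_centroid = cen[, 2],
                   u = state@u, v = state@v,
                   marginal = as.integer(marginalCells(network)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
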