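# Vertex-model mechanics: wall elasticity and turgor pressure.

#' Mechanical parameter set
#'
#' Defaults are the standard vertex-model constants used throughout the
#' growth simulations: mobility `kT = 0.5`, wall spring constant `kS = 1.0`,
#' rest length `l0 = 0.3`, turgor constant `kP = 1.0` and division interval
#' `T = 50`. Relaxation runs explicit Euler with step `relaxDt = 0.2` until
#' the largest per-step vertex displacement drops below `relaxTol = 4e-4`
#' (equivalently, until all vertex forces satisfy `|kT * F| < 2e-3`), capped
#' at `relaxMaxIter = 1e4` iterations. The step is comfortably inside the
#' stability limit of the overdamped spring dynamics (~ `2/(kT*kS)`), and
#' the displacement tolerance scales with the step so the implied force
#' threshold at equilibrium is step-independent.
#'
#' @param kT,kS,l0,kP,T,relaxDt,relaxTol,relaxMaxIter see [MechParams-class]
#' @return a [MechParams-class]
#' @examples
#' mechParams()
#' @export
mechParams <- function(kT = 0.5, kS = 1.0, l0 = 0.3, kP = 1.0, T = 50,
                       relaxDt = 0.2, relaxTol = 4e-4, relaxMaxIter = 1e4) {
  new("MechParams", kT = kT, kS = kS, l0 = l0, kP = kP, T = T,
      relaxDt = relaxDt, relaxTol = relaxTol, relaxMaxIter = relaxMaxIter)
}

setMethod("show", "MechParams", function(object) {
  cat(sprintf(
    "MechParams: kT=%g kS=%g l0=%g kP=%g T=%g (relax dt=%g tol=%g maxIter=%g)\n",
    object@kT, object@kS, object@l0, object@kP, object@T,
    object@relaxDt, object@relaxTol, object@relaxMaxIter))
})

.forceInputs <- function(network) {
  if (nrow(network@walls) > 0) {
    dx <- network@pos[network@walls$v2, 1] - network@pos[network@walls$v1, 1]
    dy <- network@pos[network@walls$v2, 2] - network@pos[network@walls$v1, 2]
    if (any(dx * dx + dy * dy < 1e-24))
      stop("degenerate zero-length wall; forces undefined")
  }
  csr <- .csrCells(network@cells)
  list(wv1 = as.integer(network@walls$v1 - 1L),
       wv2 = as.integer(network@walls$v2 - 1L),
       ptr = csr$ptr, idx = csr$idx)
}

#' Forces on every vertex
#'
#' Each wall pulls its endpoints toward the rest length with magnitude
#' `kS * (l - l0)` along the wall axis, and each adjacent cell pushes both
#' endpoints outward, perpendicular to the wall, with magnitude `kP / area`.
#' Boundary walls receive pressure from their single cell only.
#'
#' @param network a [CellNetwork-class]
#' @param mech a [MechParams-class]
#' @return numeric matrix, one force row (Fx, Fy) per vertex
#' @export
vertexForces <- function(network, mech = mechParams()) {
  inp <- .forceInputs(network)
  cpp_vertex_forces(network@pos, inp$wv1, inp$wv2, inp$ptr, inp$idx,
                    mech@kS, mech@l0, mech@kP)
}

#' Force on one vertex
#' @param network a [CellNetwork-class]
#' @param vertexId integer vertex id
#' @param mech a [MechParams-class]
#' @return numeric length-2 force vector
#' @export
vertexForce <- function(network, vertexId, mech = mechParams()) {
  if (!is.numeric(vertexId) || length(vertexId) != 1 ||
      vertexId < 1 || vertexId > nVertices(network))
    stop("unknown vertex id: ", vertexId)
  vertexForces(network, mech)[vertexId, ]
}

#' Relax vertex positions to mechanical equilibrium
#'
#' Integrates the overdamped vertex dynamics `du_i/dt = kT * F_i` by explicit
#' Euler until the largest per-step displacement falls below `relaxTol`, or
#' `relaxMaxIter` steps have been taken. Non-convergence is recorded in the
#' returned network's `status` (not an error). A post-check verifies no cell
#' was turned inside out (all signed areas remain positive).
#'
#' @param network a [CellNetwork-class]
#' @param mech a [MechParams-class]
#' @param maxIter optional override of `relaxMaxIter`
#' @return the relaxed [CellNetwork-class]; inspect `relaxStatus()` for
#'   iteration count and convergence
#' @export
relaxNetwork <- function(network, mech = mechParams(), maxIter = NULL) {
  inp <- .forceInputs(network)
  cap <- as.integer(if (is.null(maxIter)) mech@relaxMaxIter else maxIter)
  # near-degenerate cells (e.g. thin Voronoi slivers) can overshoot and turn
  # inside out at the standard step; retry deterministically from the
  # original positions with a smaller step before giving up
  for (shrink in c(1, 5, 25)) {
    res <- cpp_relax(network@pos, inp$wv1, inp$wv2, inp$ptr, inp$idx,
                     mech@kT, mech@kS, mech@l0, mech@kP,
                     mech@relaxDt / shrink, mech@relaxTol / shrink,
                     cap * shrink)
    if (all(cpp_cell_areas(res$pos, inp$ptr, inp$idx) > 0)) {
      out <- network
      out@pos <- res$pos
      out@status <- list(iterations = res$iterations, converged = res$converged,
                         max_step = res$max_step)
      return(out)
    }
  }
  stop("relaxation produced a non-positive cell area (wall crossing)")
}

#' Status of the last relaxation
#' @param network a [CellNetwork-class]
#' @return list with `iterations`, `converged`, `max_step` (empty if the
#'   network was never relaxed)
#' @export
relaxStatus <- function(network) network@status
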