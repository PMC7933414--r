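# Construction and interrogation of the polygonal cell network.

# -- internal geometry helpers -------------------------------------------------

.polyArea <- function(P) {
  n <- nrow(P)
  j <- c(2:n, 1)
  0.5 * sum(P[, 1] * P[j, 2] - P[j, 1] * P[, 2])
}

.polyCentroid <- function(P) {
  n <- nrow(P)
  j <- c(2:n, 1)
  cr <- P[, 1] * P[j, 2] - P[j, 1] * P[, 2]
  A <- 0.5 * sum(cr)
  if (abs(A) < 1e-300) return(colMeans(P))
  c(sum((P[, 1] + P[j, 1]) * cr), sum((P[, 2] + P[j, 2]) * cr)) / (6 * A)
}

# CSR encoding (0-based) of the cell cycles, as the compiled core expects.
.csrCells <- function(cells) {
  lens <- lengths(cells)
  list(ptr = as.integer(c(0L, cumsum(lens))),
       idx = as.integer(unlist(cells, use.names = FALSE) - 1L))
}

# Rebuild the wall table from the cell cycles. Each undirected vertex pair
# occurring in a cycle is one wall; interior walls occur in exactly two cells.
.buildWalls <- function(cells, nVert) {
  from <- unlist(lapply(cells, function(cyc) cyc), use.names = FALSE)
  to <- unlist(lapply(cells, function(cyc) c(cyc[-1], cyc[1])), use.names = FALSE)
  cellOf <- rep.int(seq_along(cells), lengths(cells))
  a <- pmin(from, to); b <- pmax(from, to)
  key <- (a - 1) * as.double(nVert) + b
  o <- order(key, cellOf)
  key <- key[o]; a <- a[o]; b <- b[o]; cellOf <- cellOf[o]
  first <- !duplicated(key)
  idx <- cumsum(first)
  nW <- sum(first)
  c1 <- integer(nW); c2 <- rep(NA_integer_, nW)
  seen <- integer(nW)
  for (k in seq_along(key)) {
    w <- idx[k]
    seen[w] <- seen[w] + 1L
    if (seen[w] == 1L) c1[w] <- cellOf[k]
    else if (seen[w] == 2L) c2[w] <- cellOf[k]
    else stop("wall shared by more than two cells; network invalid")
  }
  data.frame(v1 = a[first], v2 = b[first], c1 = c1, c2 = c2)
}

.newNetwork <- function(pos, cells, status = list()) {
  cells <- lapply(cells, as.integer)
  # enforce counter-clockwise orientation (positive shoelace area)
  for (i in seq_along(cells)) {
    if (.polyArea(pos[cells[[i]], , drop = FALSE]) < 0)
      cells[[i]] <- rev(cells[[i]])
  }
  net <- new("CellNetwork", pos = pos, cells = cells,
             walls = .buildWalls(cells, nrow(pos)), status = status)
  areas <- cellAreas(net)
  if (any(areas <= 0)) stop("degenerate cell with non-positive area")
  net
}

# -- initial network: Voronoi partition of random points in a disk -------------

.diskPolygon <- function(nSides = 24L, radius = 1) {
  th <- 2 * pi * (seq_len(nSides) - 1) / nSides
  cbind(radius * cos(th), radius * sin(th))
}

# Sutherland-Hodgman clip of a convex polygon by the half-plane of points
# closer to p than to q (keep dot(x - m, d) <= 0 with m midpoint, d = q - p).
.clipHalfPlane <- function(poly, p, q) {
  m <- (p + q) / 2
  d <- q - p
  s <- (poly[, 1] - m[1]) * d[1] + (poly[, 2] - m[2]) * d[2]
  n <- nrow(poly)
  out <- vector("list", 2L * n)
  nOut <- 0L
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    pin <- s[k] <= 0; qin <- s[k2] <= 0
    if (pin) { nOut <- nOut + 1L; out[[nOut]] <- poly[k, ] }
    if (xor(pin, qin)) {
      t <- s[k] / (s[k] - s[k2])
      nOut <- nOut + 1L
      out[[nOut]] <- poly[k, ] + t * (poly[k2, ] - poly[k, ])
    }
  }
  do.call(rbind, out[seq_len(nOut)])
}

.samplePointsInDisk <- function(n, minSep) {
  pts <- matrix(NA_real_, n, 2)
  got <- 0L
  tries <- 0L
  while (got < n) {
    r <- sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
    p <- c(r * cos(th), r * sin(th))
    ok <- got == 0L ||
      min((pts[seq_len(got), 1] - p[1])^2 + (pts[seq_len(got), 2] - p[2])^2) > minSep^2
    if (ok) { got <- got + 1L; pts[got, ] <- p }
    tries <- tries + 1L
    if (tries > 200L * n) { tries <- 0L; minSep <- 0.8 * minSep }
  }
  pts
}

# Merge vertices closer than tol, returning the vertex table and per-cell
# cycles of merged ids.
.mergeVertices <- function(polys, tol = 1e-7) {
  verts <- matrix(numeric(0), 0, 2)
  cycles <- vector("list", length(polys))
  for (i in seq_along(polys)) {
    P <- polys[[i]]
    ids <- integer(nrow(P))
    for (k in seq_len(nrow(P))) {
      if (nrow(verts) > 0) {
        d2 <- (verts[, 1] - P[k, 1])^2 + (verts[, 2] - P[k, 2])^2
        hit <- which(d2 < tol^2)
      } else hit <- integer(0)
      if (length(hit)) ids[k] <- hit[1]
      else { verts <- rbind(verts, P[k, ]); ids[k] <- nrow(verts) }
    }
    ids <- ids[c(TRUE, ids[-1] != ids[-length(ids)])]   # drop consecutive dups
    if (length(ids) > 1 && ids[1] == ids[length(ids)]) ids <- ids[-length(ids)]
    cycles[[i]] <- ids
  }
  list(pos = verts, cells = cycles)
}

#' Build an initial mechanically relaxed cell network
#'
#' Partitions a disk (approximated by a regular 24-gon) into `nCells`
#' Voronoi cells of uniformly sampled interior points, then relaxes vertex
#' positions to mechanical equilibrium. Deterministic for a fixed seed.
#'
#' @param nCells number of cells (>= 1).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param mech a [MechParams-class]; see [mechParams()].
#' @param relax logical; relax to mechanical equilibrium after construction.
#' @return a [CellNetwork-class]
#' @examples
#' net <- initNetwork(10, seed = 42)
#' nCells(net)
#' @export
initNetwork <- function(nCells, seed = NULL, mech = mechParams(), relax = TRUE) {
  if (!is.numeric(nCells) || length(nCells) != 1 || nCells < 1)
    stop("nCells must be a single integer >= 1")
  nCells <- as.integer(nCells)
  if (!is.null(seed)) set.seed(seed)
  if (nCells == 1L) {
    P <- .diskPolygon(6L, radius = 0.6)
    net <- .newNetwork(P, list(seq_len(6)))
  } else {
    disk <- .diskPolygon(24L, radius = 1)
    pts <- .samplePointsInDisk(nCells, minSep = 0.7 * sqrt(pi / nCells))
    polys <- vector("list", nCells)
    for (i in seq_len(nCells)) {
      poly <- disk
      for (j in seq_len(nCells)) {
        if (j == i) next
        poly <- .clipHalfPlane(poly, pts[i, ], pts[j, ])
        if (is.null(poly) || nrow(poly) < 3) stop("degenerate Voronoi cell")
      }
      polys[[i]] <- poly
    }
    merged <- .mergeVertices(polys)
    net <- .newNetwork(merged$pos, merged$cells)
  }
  if (relax) net <- relaxNetwork(net, mech)
  net
}

# -- accessors -----------------------------------------------------------------

#' @describeIn nCells number of cells
#' @export
setMethod("nCells", "CellNetwork", function(object) length(object@cells))

#' @describeIn nVertices number of vertices
#' @export
setMethod("nVertices", "CellNetwork", function(object) nrow(object@pos))

#' @describeIn nWalls number of walls
#' @export
setMethod("nWalls", "CellNetwork", function(object) nrow(object@walls))

#' Vertex coordinate matrix
#' @param network a [CellNetwork-class]
#' @return numeric matrix with columns x, y
#' @export
vertexPositions <- function(network) network@pos

#' Wall table of a network
#' @param network a [CellNetwork-class]
#' @return data.frame with columns v1, v2, c1, c2 (c2 NA on the boundary)
#' @export
networkWalls <- function(network) network@walls

#' Vertex cycle of one cell
#' @param network a [CellNetwork-class]
#' @param cellId integer cell id
#' @return integer vector of vertex ids, counter-clockwise
#' @export
cellVertices <- function(network, cellId) {
  .checkCellId(network, cellId)
  network@cells[[cellId]]
}

.checkCellId <- function(network, cellId) {
  if (!is.numeric(cellId) || length(cellId) != 1 ||
      cellId < 1 || cellId > nCells(network) || cellId != round(cellId))
    stop("unknown cell id: ", cellId)
  invisible(TRUE)
}

#' Areas of all cells
#' @param network a [CellNetwork-class]
#' @return numeric vector of shoelace areas, one per cell
#' @export
cellAreas <- function(network) {
  csr <- .csrCells(network@cells)
  cpp_cell_areas(network@pos, csr$ptr, csr$idx)
}

#' @describeIn cellArea shoelace area of one cell
#' @export
setMethod("cellArea", "CellNetwork", function(network, cellId) {
  .checkCellId(network, cellId)
  .polyArea(network@pos[network@cells[[cellId]], , drop = FALSE])
})

#' Area centroid of one cell
#' @param network a [CellNetwork-class]
#' @param cellId integer cell id
#' @return numeric length-2 vector (x, y)
#' @export
cellCentroid <- function(network, cellId) {
  .checkCellId(network, cellId)
  .polyCentroid(network@pos[network@cells[[cellId]], , drop = FALSE])
}

#' Centroids of all cells
#' @param network a [CellNetwork-class]
#' @return numeric matrix, one row per cell
#' @export
cellCentroids <- function(network) {
  t(vapply(network@cells,
           function(cyc) .polyCentroid(network@pos[cyc, , drop = FALSE]),
           numeric(2)))
}

#' @describeIn largestCell maximum-area cell, smallest id on ties
#' @export
setMethod("largestCell", "CellNetwork", function(network) {
  if (nCells(network) == 0) stop("network has no cells")
  which.max(cellAreas(network))   # which.max returns the first (smallest id) maximum
})

#' @describeIn cellNeighbors wall-sharing neighbours of one cell
#' @export
setMethod("cellNeighbors", "CellNetwork", function(network, cellId) {
  .checkCellId(network, cellId)
  w <- network@walls
  inner <- !is.na(w$c2)
  nb <- c(w$c2[inner & w$c1 == cellId], w$c1[inner & w$c2 == cellId])
  sort(unique(nb))
})

#' Cell adjacency as a list of neighbour vectors
#' @param network a [CellNetwork-class]
#' @return list; element i holds the sorted neighbour ids of cell i
#' @export
adjacencyList <- function(network) {
  w <- network@walls
  inner <- !is.na(w$c2)
  a <- w$c1[inner]; b <- w$c2[inner]
  adj <- vector("list", nCells(network))
  pairs <- unique(data.frame(a = c(a, b), b = c(b, a)))
  sp <- split(pairs$b, pairs$a)
  for (nm in names(sp)) adj[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
  for (i in seq_along(adj)) if (is.null(adj[[i]])) adj[[i]] <- integer(0)
  adj
}

#' Marginality of all cells
#' @param network a [CellNetwork-class]
#' @return logical vector; `TRUE` for cells with at least one boundary wall
#' @export
marginalCells <- function(network) {
  w <- network@walls
  boundary <- is.na(w$c2)
  out <- logical(nCells(network))
  out[unique(w$c1[boundary])] <- TRUE
  out
}

#' @describeIn isMarginal boundary test for one cell
#' @export
setMethod("isMarginal", "CellNetwork", function(network, cellId) {
  .checkCellId(network, cellId)
  marginalCells(network)[cellId]
})

setMethod("show", "CellNetwork", function(object) {
  cat("CellNetwork with", nCells(object), "cells,", nVertices(object),
      "vertices,", nWalls(object), "walls\n")
  if (length(object@status)) {
    st <- object@status
    cat("  last relaxation:", st$iterations, "iterations, converged:",
        st$converged, "\n")
  }
  cat("  total area:", format(sum(cellAreas(object)), digits = 5),
      "| marginal cells:", sum(marginalCells(object)), "\n")
})
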