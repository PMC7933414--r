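# Division of a cell by a straight wall through its gravity centre.

#' Condition signalling that a division line should be redrawn
#'
#' Raised when the division line passes through (or too close to) an
#' existing vertex, or does not cross exactly two walls of the cell.
#' Callers drawing random angles catch this class and redraw.
#' @param message diagnostic text
#' @return a condition object of class `divisionRetry`
#' @export
divisionRetryCondition <- function(message) {
  structure(class = c("divisionRetry", "error", "condition"),
            list(message = message, call = sys.call(-1)))
}

#' Divide a cell by a wall through its centroid
#'
#' The line through the cell's area centroid at the given angle must cross
#' exactly two of the cell's walls; the cell is replaced by two daughters
#' separated by a new straight wall, and the two new vertices are inserted
#' into the cycles of the neighbouring cells sharing the crossed walls.
#' Daughter areas sum exactly to the mother's area. The first daughter keeps
#' the mother's id; the second gets id `nCells + 1`.
#'
#' @param network a [CellNetwork-class]
#' @param cellId id of the cell to divide
#' @param angle direction of the division line, radians
#' @return the updated [CellNetwork-class] (cell count + 1)
#' @seealso [divisionRetryCondition()] for the redraw signal
#' @export
divideCell <- function(network, cellId, angle) {
  .checkCellId(network, cellId)
  cyc <- network@cells[[cellId]]
  P <- network@pos[cyc, , drop = FALSE]
  n <- length(cyc)
  C <- .polyCentroid(P)
  d <- c(cos(angle), sin(angle))
  nrm <- c(-d[2], d[1])
  s <- (P[, 1] - C[1]) * nrm[1] + (P[, 2] - C[2]) * nrm[2]

  scale <- sqrt(max((P[, 1] - C[1])^2 + (P[, 2] - C[2])^2))
  if (any(abs(s) < 1e-9 * scale))
    stop(divisionRetryCondition("division line passes through an existing vertex"))

  nxt <- c(2:n, 1)
  crossing <- which(s * s[nxt] < 0)
  if (length(crossing) != 2)
    stop(divisionRetryCondition("division line does not cross exactly two walls"))

  cut <- lapply(crossing, function(k) {
    k2 <- if (k == n) 1L else k + 1L
    t <- s[k] / (s[k] - s[k2])
    if (t < 1e-6 || t > 1 - 1e-6)
      stop(divisionRetryCondition("division line grazes an existing vertex"))
    list(k = k, k2 = k2, point = P[k, ] + t * (P[k2, ] - P[k, ]))
  })

  pos <- rbind(network@pos, cut[[1]]$point, cut[[2]]$point)
  x1 <- nrow(pos) - 1L   # new vertex on the first crossed wall
  x2 <- nrow(pos)        # new vertex on the second crossed wall

  i1 <- cut[[1]]$k; i2 <- cut[[2]]$k   # i1 < i2 by construction of which()
  # daughter A: X1 -> cyc[i1+1 .. i2] -> X2 (chord closes it)
  dA <- c(x1, cyc[(i1 + 1):i2], x2)
  # daughter B: X2 -> cyc[i2+1 .. n], cyc[1 .. i1] -> X1
  tail2 <- if (i2 < n) cyc[(i2 + 1):n] else integer(0)
  dB <- c(x2, tail2, cyc[1:i1], x1)

  cells <- network@cells
  cells[[cellId]] <- dA
  cells[[length(cells) + 1L]] <- dB

  # insert the new vertices into the neighbours sharing the crossed walls
  w <- network@walls
  for (j in 1:2) {
    a <- cyc[cut[[j]]$k]; b <- cyc[cut[[j]]$k2]
    xNew <- if (j == 1) x1 else x2
    hit <- which((w$v1 == min(a, b)) & (w$v2 == max(a, b)))
    other <- c(w$c1[hit], w$c2[hit])
    other <- other[!is.na(other) & other != cellId]
    if (length(other)) {
      oc <- cells[[other]]
      m <- length(oc)
      onxt <- c(2:m, 1)
      k <- which((oc == a & oc[onxt] == b) | (oc == b & oc[onxt] == a))
      if (length(k) != 1) stop("inconsistent neighbour cycle during division")
      cells[[other]] <- append(oc, xNew, after = k)
    }
  }

  .newNetwork(pos, cells, status = network@status)
}

#' Divide a cell at a random angle, redrawing on degenerate lines
#'
#' Draws angles uniformly on `[0, pi)` from the current RNG stream until the
#' division succeeds, up to `maxRetries` redraws.
#'
#' @param network a [CellNetwork-class]
#' @param cellId id of the cell to divide
#' @param maxRetries redraw cap (default 100)
#' @return the updated [CellNetwork-class]
#' @export
divideCellRandom <- function(network, cellId, maxRetries = 100L) {
  for (k in seq_len(maxRetries)) {
    angle <- runif(1, 0, pi)
    out <- tryCatch(divideCell(network, cellId, angle),
                    divisionRetry = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("no valid division line found after ", maxRetries, " attempts")
}
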