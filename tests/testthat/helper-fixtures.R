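# Hand-built networks and independent oracles shared across tests.

# single unit-square cell
squareNet <- function() {
  pos <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  RootRD:::.newNetwork(pos, list(1:4))
}

# unit square split into two 0.5 x 1 rectangles (cells share the middle wall)
twoCellNet <- function() {
  pos <- rbind(c(0, 0), c(0.5, 0), c(1, 0), c(1, 1), c(0.5, 1), c(0, 1))
  RootRD:::.newNetwork(pos, list(c(1, 2, 5, 6), c(2, 3, 4, 5)))
}

# two rectangles of areas 1 and 2 sharing a wall
unequalNet <- function() {
  pos <- rbind(c(0, 0), c(1, 0), c(3, 0), c(3, 1), c(1, 1), c(0, 1))
  RootRD:::.newNetwork(pos, list(c(1, 2, 5, 6), c(2, 3, 4, 5)))
}

# regular hexagon with side 1, one cell
hexNet <- function() {
  th <- 2 * pi * (0:5) / 6
  RootRD:::.newNetwork(cbind(cos(th), sin(th)), list(1:6))
}

# annulus of n quadrilateral sector cells; cyclic adjacency, all marginal
ringNet <- function(n, r0 = 1, r1 = 2) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  inner <- cbind(r0 * cos(th), r0 * sin(th))
  outer <- cbind(r1 * cos(th), r1 * sin(th))
  pos <- rbind(inner, outer)
  cells <- lapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    c(i, j, n + j, n + i)
  })
  RootRD:::.newNetwork(pos, cells)
}

# grow a network by random largest-cell divisions (no RD), for structure tests
grownNet <- function(nEnd, seed = 1, relaxEvery = TRUE) {
  set.seed(seed)
  net <- initNetwork(10, seed = NULL)
  m <- mechParams(relaxMaxIter = 2000)
  while (nCells(net) < nEnd) {
    net <- divideCellRandom(net, largestCell(net))
    if (relaxEvery) net <- relaxNetwork(net, m)
  }
  net
}

# independent flood-fill component oracle over an adjacency list
floodFillComponents <- function(adj, members) {
  members <- sort(members)
  unseen <- rep(TRUE, length(members))
  names(unseen) <- members
  comps <- list()
  for (s in members) {
    if (!unseen[as.character(s)]) next
    queue <- s
    unseen[as.character(s)] <- FALSE
    comp <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      for (nb in adj[[cur]]) {
        key <- as.character(nb)
        if (nb %in% members && isTRUE(unseen[key])) {
          unseen[key] <- FALSE
          queue <- c(queue, nb)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# polygon area by fan triangulation from the first vertex (oracle)
triangulationArea <- function(P) {
  a <- 0
  for (k in 2:(nrow(P) - 1)) {
    v1 <- P[k, ] - P[1, ]; v2 <- P[k + 1, ] - P[1, ]
    a <- a + 0.5 * (v1[1] * v2[2] - v1[2] * v2[1])
  }
  a
}

# Jacobian eigenvalue oracle for the linearized activator-inhibitor system
# on a graph with Laplacian L (all cells non-marginal or alphaM = 0)
rdJacobianMaxRe <- function(params, L) {
  n <- nrow(L)
  fu <- params@alphaS - params@alphaD
  fv <- -params@beta
  gu <- params@gamma
  gv <- -params@delta
  J <- rbind(cbind(fu * diag(n) - params@Du * L, fv * diag(n)),
             cbind(gu * diag(n), gv * diag(n) - params@Dv * L))
  max(Re(eigen(J, only.values = TRUE)$values))
}

# cycle-graph Laplacian
cycleLaplacian <- function(n) {
  L <- diag(2, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    L[i, j] <- L[i, j] - 1
    L[j, i] <- L[j, i] - 1
  }
  L
}
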