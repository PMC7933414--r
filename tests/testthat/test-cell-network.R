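# Construction, geometry and bookkeeping of the polygonal cell network.

test_that("initNetwork builds valid networks of the requested size", {
  net1 <- initNetwork(1, seed = 5)
  expect_equal(nCells(net1), 1)
  expect_true(all(is.na(networkWalls(net1)$c2)))   # every wall is boundary

  net <- initNetwork(10, seed = 42)
  expect_equal(nCells(net), 10)
  expect_true(all(cellAreas(net) > 0))
  expect_error(initNetwork(0), "nCells")
})

test_that("initNetwork is deterministic per seed and seed-sensitive", {
  a <- initNetwork(10, seed = 42)
  b <- initNetwork(10, seed = 42)
  expect_identical(vertexPositions(a), vertexPositions(b))
  expect_identical(a@cells, b@cells)
  c <- initNetwork(10, seed = 43)
  expect_false(isTRUE(all.equal(dim(vertexPositions(a)),
                                dim(vertexPositions(c)))) &&
               isTRUE(all.equal(vertexPositions(a), vertexPositions(c))))
})

test_that("cell areas match closed forms and a triangulation oracle", {
  expect_equal(cellArea(squareNet(), 1), 1.0)
  expect_equal(cellArea(hexNet(), 1), 3 * sqrt(3) / 2, tolerance = 1e-12)
  expect_error(cellArea(squareNet(), 5), "unknown cell")

  net <- initNetwork(10, seed = 7)
  for (i in seq_len(nCells(net))) {
    P <- vertexPositions(net)[cellVertices(net, i), , drop = FALSE]
    expect_equal(cellArea(net, i), triangulationArea(P), tolerance = 1e-12)
  }
})

test_that("largestCell picks the maximum area, smallest id on ties", {
  expect_equal(largestCell(unequalNet()), 2)
  expect_equal(largestCell(twoCellNet()), 1)   # exact tie -> smaller id
})

test_that("divideCell splits through the centroid and conserves area", {
  net <- squareNet()
  out <- divideCell(net, 1, 0)   # horizontal line through (0.5, 0.5)
  expect_equal(nCells(out), 2)
  a <- cellAreas(out)
  expect_equal(sort(a), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(a), 1.0, tolerance = 1e-10)

  # line through two opposite vertices -> retry signal
  expect_condition(divideCell(squareNet(), 1, pi / 4), class = "divisionRetry")
})

test_that("division conserves area and the Euler characteristic on grown networks", {
  set.seed(31)
  net <- initNetwork(10, seed = 31)
  for (k in 1:25) {
    mother <- largestCell(net)
    before <- cellArea(net, mother)
    net2 <- divideCellRandom(net, mother)
    expect_equal(nCells(net2), nCells(net) + 1)
    daughters <- c(mother, nCells(net2))
    expect_equal(sum(cellAreas(net2)[daughters]), before, tolerance = 1e-10)
    # planar subdivision: V - E + F = 2 counting the outer face
    expect_equal(nVertices(net2) - nWalls(net2) + (nCells(net2) + 1), 2)
    # no degenerate daughters: every cell keeps positive area
    expect_true(all(cellAreas(net2) > 0))
    expect_false(largestCell(net2) %in% which(cellAreas(net2) < 1e-12))
    net <- relaxNetwork(net2, mechParams(relaxMaxIter = 500))
  }
})

test_that("vertex forces follow the elastic and pressure laws", {
  # elasticity: unit square with negligible pressure; each vertex joins two
  # walls of length 1, each pulling with k_S (l - l0) = 0.7 toward the
  # neighbours, so |F| = 0.7 * sqrt(2) pointing into the square
  net <- squareNet()
  mech <- mechParams(kS = 1, l0 = 0.3, kP = 1e-9)
  f <- vertexForce(net, 1, mech)
  expect_equal(f, c(0.7, 0.7), tolerance = 1e-6)

  # pressure: unit-area cell pushes each wall outward with k_P / V = 1;
  # suppress elasticity with a tiny spring constant
  mech2 <- mechParams(kS = 1e-9, l0 = 0.3, kP = 1)
  f2 <- vertexForces(net, mech2)
  expect_equal(f2[1, ], c(-1, -1), tolerance = 1e-6)   # corner pushed outward
  expect_equal(f2[3, ], c(1, 1), tolerance = 1e-6)
})

test_that("relaxation reduces forces and satisfies its stopping rule", {
  mech <- mechParams()
  net <- initNetwork(10, seed = 11, relax = FALSE)
  f0 <- max(sqrt(rowSums(vertexForces(net, mech)^2)))
  relaxed <- relaxNetwork(net, mech)
  expect_true(relaxStatus(relaxed)$converged)
  f1 <- max(sqrt(rowSums(vertexForces(relaxed, mech)^2)))
  expect_lt(f1, f0)
  # stopping rule: per-step displacement below tolerance at exit
  expect_true(all(mech@kT * sqrt(rowSums(vertexForces(relaxed, mech)^2)) *
                    mech@relaxDt < mech@relaxTol))
  # max force decreases across successive short relaxation windows
  net2 <- squareNet()
  fs <- numeric(6)
  cur <- net2
  for (k in 1:6) {
    fs[k] <- max(sqrt(rowSums(vertexForces(cur, mech)^2)))
    cur <- relaxNetwork(cur, mech, maxIter = 20)
  }
  expect_true(all(diff(fs) <= 1e-8))
  # relaxing an equilibrium leaves it (numerically) in place
  again <- relaxNetwork(relaxed, mech)
  expect_lt(max(abs(vertexPositions(again) - vertexPositions(relaxed))), 1e-3)
})

test_that("adjacency is symmetric and marginality matches the wall table", {
  net <- grownNet(40, seed = 3)
  adj <- adjacencyList(net)
  for (a in seq_len(nCells(net))) {
    expect_identical(adj[[a]], cellNeighbors(net, a))
    for (b in adj[[a]]) expect_true(a %in% adj[[b]])
  }
  expect_identical(cellNeighbors(twoCellNet(), 1), 2L)
  expect_identical(cellNeighbors(twoCellNet(), 2), 1L)
  expect_length(cellNeighbors(initNetwork(1, seed = 1), 1), 0)

  expect_true(isMarginal(initNetwork(1, seed = 1), 1))
  expect_true(all(marginalCells(twoCellNet())))
  marg <- marginalCells(net)
  expect_true(any(marg) && any(!marg))   # big disk has interior cells
  # recompute marginality from the wall table alone
  w <- networkWalls(net)
  manual <- vapply(seq_len(nCells(net)), function(i)
    any(is.na(w$c2[w$c1 == i])), logical(1))
  expect_identical(marg, manual)
})

test_that("network JSON round-trips and SVG snapshots are written", {
  net <- grownNet(15, seed = 9)
  path <- tempfile(fileext = ".json")
  writeNetworkJSON(net, path)
  back <- readNetworkJSON(path)
  expect_equal(nCells(back), nCells(net))
  expect_equal(nWalls(back), nWalls(net))
  expect_equal(vertexPositions(back), vertexPositions(net), tolerance = 1e-12)
  expect_equal(cellAreas(back), cellAreas(net), tolerance = 1e-10)

  svg <- tempfile(fileext = ".svg")
  writeNetworkSVG(net, svg, values = cellAreas(net))
  expect_true(file.size(svg) > 200)
})
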