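# Binarization, region extraction and root-type labelling.

# one moderately grown network shared across painting tests
paintNet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- grownNet(170, seed = 12)
    cache
  }
})

paintParams <- rdParams(alphaS = 1.8, gamma = 1.0)   # u0 = 5

# paint HIGH disks / an arc onto a network; returns an RDState
paintDisks <- function(net, k, rotation = 0) {
  cen <- cellCentroids(net)
  areas <- cellAreas(net)
  mid <- colSums(cen * areas) / sum(areas)
  R <- sqrt(max((cen[, 1] - mid[1])^2 + (cen[, 2] - mid[2])^2))
  centers <- if (k == 1) matrix(mid, 1) else {
    th <- rotation + 2 * pi * (seq_len(k) - 1) / k
    cbind(mid[1] + 0.55 * R * cos(th), mid[2] + 0.55 * R * sin(th))
  }
  r <- 0.16 * R
  high <- rep(FALSE, nCells(net))
  for (j in seq_len(nrow(centers))) {
    d <- sqrt((cen[, 1] - centers[j, 1])^2 + (cen[, 2] - centers[j, 2])^2)
    high <- high | (d < r)
  }
  rdState(ifelse(high, 10, 1), rep(1, nCells(net)))
}

paintArc <- function(net, rotation = 0, span = 4 * pi / 3) {
  cen <- cellCentroids(net)
  areas <- cellAreas(net)
  mid <- colSums(cen * areas) / sum(areas)
  d <- sqrt((cen[, 1] - mid[1])^2 + (cen[, 2] - mid[2])^2)
  R <- max(d)
  ang <- (atan2(cen[, 2] - mid[2], cen[, 1] - mid[1]) - rotation) %% (2 * pi)
  high <- d > 0.5 * R & d < 0.85 * R & ang < span
  rdState(ifelse(high, 10, 1), rep(1, nCells(net)))
}

test_that("binarization finds the midrange split and flags flat fields", {
  net <- paintNet()
  st <- paintDisks(net, 2)
  lab <- binarizeActivator(st, net, paintParams)
  expect_false(attr(lab, "homogeneous"))
  expect_identical(as.logical(lab), activator(st) > 5.5)

  flat <- rdState(rep(5, nCells(net)) + 1e-4 * seq_len(nCells(net)) / nCells(net),
                  rep(5, nCells(net)))
  labFlat <- binarizeActivator(flat, net, paintParams)
  expect_true(attr(labFlat, "homogeneous"))

  # affine rescaling of u leaves the labels unchanged
  st2 <- rdState(3 * activator(st) + 7, inhibitor(st))
  lab2 <- binarizeActivator(st2, net, paintParams)
  expect_identical(as.logical(lab2), as.logical(lab))
})

test_that("region extraction matches a flood-fill oracle on random labelings", {
  net <- grownNet(50, seed = 14)
  adj <- adjacencyList(net)
  set.seed(77)
  for (k in 1:20) {
    labels <- runif(nCells(net)) < 0.3
    reg <- activatorRegions(net, labels)
    oracle <- floodFillComponents(adj, which(reg$minority))
    expect_equal(length(reg$components), length(oracle))
    expect_identical(reg$components[order(vapply(reg$components, min, numeric(1)))],
                     oracle)
  }
})

test_that("degenerate labelings behave as specified", {
  net <- grownNet(30, seed = 15)
  # one HIGH cell in a sea of LOW: one spotted region
  labels <- rep(FALSE, nCells(net)); labels[4] <- TRUE
  reg <- activatorRegions(net, labels)
  expect_equal(reg$polarity, "spotted")
  expect_length(reg$components, 1)
  expect_identical(reg$components[[1]], 4L)
  # all LOW: zero regions, HIGH-minority tie-break
  regAll <- activatorRegions(net, rep(FALSE, nCells(net)))
  expect_equal(regAll$polarity, "spotted")
  expect_length(regAll$components, 0)
})

test_that("classify recovers painted disk counts and the arc label", {
  net <- paintNet()
  set.seed(31)
  hits <- 0L
  trials <- 0L
  for (rep in 1:20) for (k in 1:4) {
    trials <- trials + 1L
    st <- paintDisks(net, k, rotation = runif(1, 0, 2 * pi))
    ps <- classifyPattern(net, st, paintParams)
    hits <- hits + as.integer(ps@rootLabel == as.character(k) &&
                                ps@polarity == "spotted")
  }
  for (rep in 1:20) {
    trials <- trials + 1L
    ps <- classifyPattern(net, paintArc(net, rotation = runif(1, 0, 2 * pi)),
                          paintParams)
    hits <- hits + as.integer(ps@rootLabel == "C" && ps@nRegions == 1L)
  }
  expect_gte(hits / trials, 0.95)
})

test_that("classification is invariant to rotation and cell relabeling", {
  net <- paintNet()
  st <- paintDisks(net, 3, rotation = 0.4)
  ref <- classifyPattern(net, st, paintParams)
  expect_equal(ref@rootLabel, "3")

  # rigid rotation of every vertex
  th <- 1.1
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- RootRD:::.newNetwork(vertexPositions(net) %*% Rm, net@cells)
  psRot <- classifyPattern(rot, st, paintParams)
  expect_equal(psRot@rootLabel, ref@rootLabel)
  expect_equal(psRot@nRegions, ref@nRegions)
  expect_equal(psRot@polarity, ref@polarity)

  # relabeling: reverse the cell order
  perm <- rev(seq_len(nCells(net)))
  relab <- RootRD:::.newNetwork(vertexPositions(net), net@cells[perm])
  stPerm <- rdState(activator(st)[perm], inhibitor(st)[perm])
  psPerm <- classifyPattern(relab, stPerm, paintParams)
  expect_equal(psPerm@rootLabel, ref@rootLabel)
  expect_equal(psPerm@nRegions, ref@nRegions)
})

test_that("homogeneous fields classify as zero regions, label other", {
  net <- grownNet(30, seed = 16)
  st <- rdState(rep(5, nCells(net)), rep(5, nCells(net)))
  ps <- classifyPattern(net, st, paintParams)
  expect_true(ps@homogeneous)
  expect_equal(ps@nRegions, 0L)
  expect_equal(ps@rootLabel, "other")
})
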