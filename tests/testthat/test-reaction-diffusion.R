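# Activator-inhibitor dynamics: equilibria, clamps, Euler stepping,
# conservation, and the linear-stability oracle.

test_that("the homogeneous equilibrium follows the closed form", {
  eq <- equilibriumState(rdParams(alphaS = 1.8, gamma = 1.0))
  expect_equal(eq$u0, 5.0)
  expect_equal(eq$v0, 5.0)
  expect_equal(equilibriumState(rdParams(alphaS = 1.5))$u0, 2.0)
  expect_error(rdParams(alphaS = 2.0), "equilibrium")
  expect_error(equilibriumState(new("RDParams", alphaS = 2, alphaD = 1,
                                    alphaM = 0, beta = 1, gamma = 1, delta = 1,
                                    epsilon = 1, Du = .25, Dv = .5, uMax = 99,
                                    dt = .02, Td = 50)), "denominator")
})

test_that("phi clamps synthesis and psi switches on marginality", {
  p <- rdParams(alphaS = 1.8, uMax = 50)   # alphaD * uMax = 50
  expect_equal(phiClamp(-0.5, p), 0)
  expect_equal(phiClamp(1.0, p), 1.0)
  expect_equal(phiClamp(100, p), 50)

  single <- initNetwork(1, seed = 1)
  expect_equal(psiMarginal(single, 1, p), p@alphaM)
  net <- grownNet(40, seed = 3)
  interior <- which(!marginalCells(net))[1]
  expect_equal(psiMarginal(net, interior, p), 0)
  p0 <- rdParams(alphaM = 0)
  expect_equal(psiMarginal(single, 1, p0), 0)
})

test_that("the homogeneous state is a fixed point of rdStep when alphaM = 0", {
  net <- ringNet(8)
  p <- rdParams(alphaS = 1.8, gamma = 1.0, alphaM = 0)
  eq <- equilibriumState(p)
  st <- rdState(rep(eq$u0, 8), rep(eq$v0, 8))
  out <- rdStep(st, net, p)
  expect_equal(activator(out), activator(st), tolerance = 1e-15)
  expect_equal(inhibitor(out), inhibitor(st), tolerance = 1e-15)
  # and after a full 2500-step run
  out2 <- rdRun(st, net, p)
  expect_equal(activator(out2), activator(st), tolerance = 1e-12)
})

test_that("a single Euler step matches the hand-computed update", {
  single <- initNetwork(1, seed = 2)
  p <- rdParams(alphaS = 1.8, alphaM = 0, uMax = 50, dt = 0.02)
  out <- rdStep(rdState(0, 0), single, p)
  expect_equal(activator(out), 0.02)   # du = phi(epsilon) = 1, dt = 0.02
  expect_equal(inhibitor(out), 0)
  expect_error(rdStep(rdState(c(0, 0), c(0, 0)), single, p), "cells")
})

test_that("decay-only dynamics shrink the total activator geometrically", {
  net <- grownNet(25, seed = 5)
  n <- nCells(net)
  p <- rdParams(alphaS = 0, beta = 0, gamma = 0, epsilon = 0,
                alphaD = 1, alphaM = 0, uMax = 100, dt = 0.02)
  set.seed(9)
  st <- rdState(runif(n, 1, 3), runif(n, 1, 3))
  out <- rdStep(st, net, p)
  # diffusion sums to zero over the network, so only decay changes the total
  expect_equal(sum(activator(out)), (1 - p@alphaD * p@dt) * sum(activator(st)),
               tolerance = 1e-12)
})

test_that("pure diffusion conserves the totals and respects the clamps", {
  net <- grownNet(25, seed = 6)
  n <- nCells(net)
  p <- rdParams(alphaS = 0, alphaD = 0, alphaM = 0, beta = 0, gamma = 0,
                delta = 0, epsilon = 0, uMax = 1000, dt = 0.02)
  set.seed(10)
  st <- rdState(runif(n, 0, 10), runif(n, 0, 10))
  out <- st
  for (k in 1:50) out <- rdStep(out, net, p)
  expect_equal(sum(activator(out)), sum(activator(st)), tolerance = 1e-12)
  expect_equal(sum(inhibitor(out)), sum(inhibitor(st)), tolerance = 1e-12)

  # clamp property under strong dynamics
  p2 <- rdParams(alphaS = 1.8, gamma = 1, alphaM = 1, uMaxFactor = 1.1)
  st2 <- perturbEquilibrium(net, p2, 0.01, seed = 1)
  out2 <- rdRun(st2, net, p2)
  expect_true(all(activator(out2) >= 0 & activator(out2) <= p2@uMax))
  expect_true(all(inhibitor(out2) >= 0))
})

test_that("perturbEquilibrium respects amplitude, determinism and zero fraction", {
  net <- grownNet(30, seed = 7)
  p <- rdParams(alphaS = 1.8, gamma = 1.0)
  eq <- equilibriumState(p)
  st0 <- perturbEquilibrium(net, p, 0, seed = 4)
  expect_equal(activator(st0), rep(eq$u0, nCells(net)))
  st1 <- perturbEquilibrium(net, p, 0.01, seed = 4)
  expect_true(all(abs(activator(st1) / eq$u0 - 1) <= 0.01))
  st2 <- perturbEquilibrium(net, p, 0.01, seed = 4)
  expect_identical(activator(st1), activator(st2))
  expect_error(perturbEquilibrium(net, p, 1.2), "fraction")
})

test_that("pattern growth or decay matches the Jacobian eigenvalue oracle", {
  n <- 12
  net <- ringNet(n)
  L <- cycleLaplacian(n)

  growthFactor <- function(p) {
    eq <- equilibriumState(p)
    set.seed(21)
    st <- rdState(eq$u0 * (1 + 1e-5 * runif(n, -1, 1)),
                  eq$v0 * (1 + 1e-5 * runif(n, -1, 1)))
    v0 <- var(activator(st))
    out <- st
    for (k in 1:10) out <- rdRun(out, net, p)   # T = 500
    var(activator(out)) / v0
  }

  # reference constants: oracle says linearly stable -> perturbation decays
  pStable <- rdParams(alphaS = 1.8, gamma = 1.0, alphaM = 0, uMaxFactor = 10)
  expect_lt(rdJacobianMaxRe(pStable, L), -1e-3)
  expect_lt(growthFactor(pStable), 0.5)

  # high inhibitor/activator diffusion ratio: oracle says unstable -> grows
  pUnstable <- rdParams(alphaS = 1.8, gamma = 1.0, alphaM = 0,
                        Du = 0.05, Dv = 2.0, uMaxFactor = 10)
  expect_gt(rdJacobianMaxRe(pUnstable, L), 1e-3)
  expect_gt(growthFactor(pUnstable), 2)
})

test_that("state CSV dumps carry centroids and marginality", {
  net <- grownNet(15, seed = 8)
  p <- rdParams()
  st <- perturbEquilibrium(net, p, 0.01, seed = 2)
  path <- tempfile(fileext = ".csv")
  writeStateCSV(st, net, path)
  df <- read.csv(path)
  expect_equal(nrow(df), nCells(net))
  expect_identical(names(df), c("cell_id", "x_centroid", "y_centroid",
                                "u", "v", "marginal"))
  expect_equal(df$u, activator(st))
  expect_equal(df$marginal, as.integer(marginalCells(net)))
})
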