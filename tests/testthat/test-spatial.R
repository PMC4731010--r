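# Lattice simulator: growth model identities, conservation, stability,
# symmetry, and the fine-timestep diffusion oracle.

test_that("Gompertz capacity honors its analytic identities and refits exactly", {
  g <- gompertzGrowth(Kcap = 2.5, kg = 0.012, tI = 350)
  expect_equal(gompertzCapacity(g, 1e7), 2.5, tolerance = 1e-9)
  expect_equal(gompertzCapacity(g, 350), 2.5 / exp(1), tolerance = 1e-12)

  t <- seq(0, 1000, by = 10)
  fit <- fitGompertz(t, gompertzCapacity(g, t))
  expect_equal(fit@Kcap, g@Kcap, tolerance = 1e-6)
  expect_equal(fit@kg, g@kg, tolerance = 1e-6)
  expect_equal(fit@tI, g@tI, tolerance = 1e-4)
})

test_that("with no production or decay total HSL is conserved over 1,000 steps", {
  sp <- diffusionOnlyParams(kDeg = 0)
  lay <- pointReleaseLayout(9, c6 = 1000)
  state <- initialGridState(lay, sp)
  total0 <- sum(state@c6)
  dt <- 0.2 * stableTimeStep(lay, sp)
  for (k in 1:1000) state <- stepGrid(state, lay, sp, dt)
  expect_equal(sum(state@c6), total0, tolerance = 1e-9)
  expect_true(all(state@c6 >= 0))
})

test_that("a uniform field under no-flux boundaries stays uniform", {
  sp <- diffusionOnlyParams(kDeg = 0.001)
  lay <- gridLayout(matrix("empty", 6, 6), initC6 = matrix(50, 6, 6))
  traj <- simulateGrid(lay, sp, horizon = 300, recordEvery = 300)
  final <- traj@states[[length(traj@states)]]@c6
  expect_lt(diff(range(final)), 1e-12 * mean(final))
})

test_that("the explicit scheme rejects unstable steps, naming the bound", {
  sp <- diffusionOnlyParams()
  lay <- pointReleaseLayout(5)
  bound <- stableTimeStep(lay, sp)
  state <- initialGridState(lay, sp)
  expect_error(stepGrid(state, lay, sp, bound * 1.5),
               "maximum admissible dt")
  expect_s4_class(stepGrid(state, lay, sp, bound * 0.5), "GridState")
})

test_that("point-release profiles match a 4x finer-timestep reference within 1%", {
  sp <- diffusionOnlyParams(kDeg = 0.001)
  lay <- pointReleaseLayout(9, c6 = 1000)
  # step small enough that decay is also resolved, not just diffusion
  dt <- min(0.2 * stableTimeStep(lay, sp), 4)
  coarse <- simulateGrid(lay, sp, horizon = 600, dt = dt, recordEvery = 600)
  fine <- simulateGrid(lay, sp, horizon = 600, dt = dt / 4, recordEvery = 600)
  a <- coarse@states[[length(coarse@states)]]@c6
  b <- fine@states[[length(fine@states)]]@c6
  expect_lt(max(abs(a - b)) / max(b), 0.01)
  # radial symmetry about the center
  expect_equal(a, a[nrow(a):1, ], tolerance = 1e-12)
  expect_equal(a, a[, ncol(a):1], tolerance = 1e-12)
})

test_that("simulations are deterministic and reflection-covariant", {
  sp <- defaultSpatialParams()
  lay <- senderReceiverLayout(nRows = 3, nCols = 5)
  t1 <- simulateGrid(lay, sp, horizon = 200, recordEvery = 100)
  t2 <- simulateGrid(lay, sp, horizon = 200, recordEvery = 100)
  expect_identical(t1@states[[3]]@c6, t2@states[[3]]@c6)

  # mirrored layout gives mirrored fields
  mlay <- gridLayout(lay@devices[, ncol(lay@devices):1], pitch = lay@pitch)
  t3 <- simulateGrid(mlay, sp, horizon = 200, recordEvery = 100)
  expect_equal(t3@states[[3]]@c6, t1@states[[3]]@c6[, ncol(lay@devices):1],
               tolerance = 1e-12)
})

test_that("HSL mass balance tracks production minus decay with sealed edges", {
  sp <- defaultSpatialParams()
  lay <- senderReceiverLayout(nRows = 3, nCols = 4)
  state <- initialGridState(lay, sp)
  dt <- 0.5
  for (k in 1:200) {
    prod <- sum(sp@kSyn6 * state@synLuxI * state@capacity) * dt
    dec <- sum(sp@kDeg6 * state@c6) * dt
    nxt <- stepGrid(state, lay, sp, dt)
    expect_equal(sum(nxt@c6) - sum(state@c6), prod - dec,
                 tolerance = 1e-9 * max(1, sum(state@c6)))
    state <- nxt
  }
})

test_that("an all-empty layout accumulates no reporter signal", {
  sp <- defaultSpatialParams()
  lay <- gridLayout(matrix("empty", 4, 4))
  traj <- simulateGrid(lay, sp, horizon = 300, recordEvery = 300)
  final <- traj@states[[length(traj@states)]]
  expect_true(all(final@cfp == 0))
  expect_true(all(final@yfp == 0))
  expect_true(all(final@capacity == 0))
})

test_that("a single saturated square under clamped signal reproduces the liquid-culture transfer", {
  sp <- defaultSpatialParams()
  sp@kDeg6 <- 0; sp@kDeg12 <- 0; sp@kSyn6 <- 0; sp@kSyn12 <- 0
  sp@growth <- gompertzGrowth(Kcap = 1, kg = 1, tI = -20) # instantly saturated
  for (c12 in c(0, 10, 200)) {
    lay <- gridLayout(matrix("receiver", 1, 1),
                      initC12 = matrix(c12, 1, 1))
    traj <- simulateGrid(lay, sp, horizon = 100, dt = 1, recordEvery = 100)
    final <- traj@states[[length(traj@states)]]
    # YFP accumulation rate equals the Hill transfer at the clamped dose
    expect_equal(final@yfp[1, 1] / 100, hillRate(sp@pLas81Hill, c12),
                 tolerance = 0.02)
  }
})

test_that("stripe assays never activate without an initial signal", {
  st <- runStripeExperiment(sp = defaultSpatialParams(), nStripes = 3,
                            initC12 = 0, horizon = 1200)
  expect_true(all(is.na(st$report$activationTime)))
  expect_false(st$propagated)
})
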