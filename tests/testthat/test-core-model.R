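# Equilibrium transfer functions: analytic limits, invariants, and the
# full mass-action steady-state cross-check.

test_that("zero input returns the basal rate and saturating C6 reaches the analytic limit", {
  p <- fullParams()
  expect_identical(simplifiedRate(p, 0, 0), p@a0)

  # with no LasR pathway, the C6 -> Inf limit is (a0 + a1R KGR r^2)/(1 + KGR r^2)
  p2 <- fullParams(s = 0)
  lim <- (p2@a0 + p2@a1R * p2@KGR * p2@r^2) / (1 + p2@KGR * p2@r^2)
  expect_equal(simplifiedRate(p2, 1e12, 0), lim, tolerance = 1e-9)

  h <- hillTransfer(basal = 1, vmax = 9, ec50 = 20, hill = 2)
  expect_identical(hillRate(h, 0), 1)
  expect_equal(hillRate(h, 20), (1 + 9) / 2)
})

test_that("output is bounded by the extreme rates and monotone where activation dominates", {
  set.seed(11)
  grid <- 10^seq(-1, 4.5, length.out = 25)
  for (k in 1:10) {
    p <- randomParams(n = runif(1, 0.5, 4))
    f <- outer(grid, grid, function(a, b) simplifiedRate(p, a, b))
    expect_true(all(f >= min(p@a0, p@a1R, p@a1S) - 1e-12))
    expect_true(all(f <= max(p@a0, p@a1R, p@a1S) + 1e-12))
    # single-signal dose responses are nondecreasing when both activated
    # states outproduce basal equally (with unequal a1R/a1S the mixture of
    # regulator pools can genuinely trade a strong activator for a weak
    # one, so monotonicity is only guaranteed in this regime)
    q <- p
    q@a1S <- q@a1R
    if (q@a1R >= q@a0) {
      f6 <- simplifiedRate(q, grid, 0)
      f12 <- simplifiedRate(q, 0, grid)
      expect_true(all(diff(f6) >= -1e-9 * max(f6)))
      expect_true(all(diff(f12) >= -1e-9 * max(f12)))
    }
  }
  # the characterized regime itself is monotone along both axes
  for (nm in c("pLux", "pLux76", "pLas81")) {
    p <- presetParams(nm)
    expect_true(all(diff(simplifiedRate(p, grid, 0)) >= -1e-12))
    expect_true(all(diff(simplifiedRate(p, 0, grid)) >= -1e-12))
  }
})

test_that("(KGR, r) and (KGS, s) enter only through KGR r^2 / KGS s^2", {
  p <- fullParams(r = 2, s = 3)
  c6 <- c(0, 5, 500, 2e4)
  c12 <- c(1, 80, 1e4, 0)
  base <- simplifiedRate(p, c6, c12)
  # a power-of-two rescaling is exact in floating point: bit identity
  q <- p
  q@r <- p@r * 4; q@KGR <- p@KGR / 16
  q@s <- p@s / 2; q@KGS <- p@KGS * 4
  expect_identical(simplifiedRate(q, c6, c12), base)
  # arbitrary rescalings agree to rounding error
  for (cc in c(10, 0.037)) {
    q <- p
    q@r <- p@r * cc; q@KGR <- p@KGR / cc^2
    q@s <- p@s / cc; q@KGS <- p@KGS * cc^2
    expect_equal(simplifiedRate(q, c6, c12), base, tolerance = 1e-12)
  }
})

test_that("with a single regulator the transfer function reduces to the hand-derived closed form", {
  # KGS = 0, C12 = 0: f = (a0 + a1R K (u)^n) / (1 + K u^n), u = KR6 C6/(1 + KR6 C6)
  p <- fullParams(s = 0)
  p@KGS <- 0
  C6 <- 10^seq(-1, 5, length.out = 40)
  u <- p@KR6 * C6 / (1 + p@KR6 * C6)
  K <- p@KGR * p@r^2
  byHand <- (p@a0 + p@a1R * K * u^p@n) / (1 + K * u^p@n)
  expect_equal(simplifiedRate(p, C6, 0), byHand, tolerance = 1e-12)
})

test_that("hill transfer is monotone nondecreasing on a dense grid", {
  h <- hillTransfer(basal = 0.5, vmax = 400, ec50 = 12, hill = 1.7)
  v <- hillRate(h, 10^seq(-3, 6, length.out = 500))
  expect_true(all(diff(v) >= 0))
})

test_that("full mass-action steady state conserves total promoter and matches the closed form", {
  set.seed(23)
  for (k in 1:3) {
    p <- randomParams(n = 2)
    spec <- fullModelSpec(p)
    cg <- 10^seq(log10(0.1), log10(25000), length.out = 5)
    for (C6 in cg) for (C12 in cg) {
      res <- fullEquilibriumRate(spec, C6, C12, details = TRUE)
      Ptot <- spec@geneProduction / spec@gamma
      expect_equal(sum(res$species[c("G", "GD6", "GD12", "GE6", "GE12")]),
                   Ptot, tolerance = 1e-6)
      expect_lt(abs(res$rate - simplifiedRate(p, C6, C12)) /
                  max(simplifiedRate(p, C6, C12), 1e-9), 0.05)
    }
  }
  # no complexes at zero input
  p <- fullParams()
  expect_equal(fullEquilibriumRate(fullModelSpec(p), 0, 0), p@a0,
               tolerance = 1e-6)
})

test_that("invalid inputs are rejected", {
  p <- fullParams()
  expect_error(simplifiedRate(p, -1, 0), "must be >= 0")
  expect_error(crosstalkParams(KR6 = -1), "association")
  expect_error(hillTransfer(basal = 5, vmax = 1, ec50 = 10, hill = 2),
               "vmax")
  expect_error(fullModelSpec(fullParams(n = 1.5)), "n must equal 2")
})
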