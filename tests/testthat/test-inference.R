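# Ensemble sampler correctness on analytic targets, likelihood identities,
# and the staged inference operations at reduced scale.

test_that("the ensemble sampler reproduces a correlated Gaussian target", {
  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  Sinv <- solve(S)
  logPost <- function(th) -0.5 * drop(t(th - c(1, -2)) %*% Sinv %*% (th - c(1, -2)))
  run <- ensembleMCMC(logPost, c(0, 0), nSteps = 1500, seed = 42, nWalkers = 20)
  flat <- matrix(aperm(run$chain[501:1500, , ], c(2, 1, 3)), ncol = 2)
  expect_equal(colMeans(flat), c(1, -2), tolerance = 0.1)
  expect_equal(cov(flat), S, tolerance = 0.15)
  expect_gt(run$acceptance, 0.2)
})

test_that("identical seeds give bit-identical chains", {
  logPost <- function(th) -0.5 * sum(th^2)
  r1 <- ensembleMCMC(logPost, c(0, 0, 0), nSteps = 50, seed = 7)
  r2 <- ensembleMCMC(logPost, c(0, 0, 0), nSteps = 50, seed = 7)
  expect_identical(r1$chain, r2$chain)
  r3 <- ensembleMCMC(logPost, c(0, 0, 0), nSteps = 50, seed = 8)
  expect_false(identical(r1$chain, r3$chain))
})

test_that("the Gaussian likelihood obeys its analytic identities", {
  p <- fullParams()
  C6 <- doseLadder(6)
  pred <- simplifiedRate(p, C6, 0)
  sdRep <- rep(1, 6) # large enough that the 10% floor is inactive
  dr <- doseResponse("dev", "pLux",
                     data.frame(C6 = C6, C12 = 0, arabinose = 0,
                                rho = pred, sd = sdRep, n = 1))
  # data at the predictions: log-lik is just the normalization sum
  expect_equal(crosstalkLogLik(p, dr), 6 * dnorm(0, 0, 1, log = TRUE))
  # shifting one observation by k sd lowers log-lik by k^2/2
  for (k in c(1, 2.5)) {
    dr2 <- dr
    dr2@data$rho[3] <- pred[3] + k * 1
    expect_equal(crosstalkLogLik(p, dr) - crosstalkLogLik(p, dr2), k^2 / 2)
  }
})

test_that("the 1-parameter maximum-likelihood point matches a brute-force grid scan", {
  set.seed(5)
  p <- fullParams(s = 0)
  C6 <- doseLadder(10)
  rho <- simplifiedRate(p, C6, 0) * exp(rnorm(10, 0, 0.05))
  dr <- doseResponse("dev", "pLux",
                     data.frame(C6 = C6, C12 = 0, arabinose = 0,
                                rho = rho, sd = NA, n = 1))
  ll <- function(lk) {
    q <- p; q@KR6 <- 10^lk
    crosstalkLogLik(q, dr)
  }
  grid <- seq(-4, 0, length.out = 2001)
  gridBest <- grid[which.max(vapply(grid, ll, numeric(1)))]
  opt <- optimize(ll, c(-4, 0), maximum = TRUE, tol = 1e-8)
  expect_equal(opt$maximum, gridBest, tolerance = 0.005)
  expect_equal(opt$maximum, log10(p@KR6), tolerance = 0.1)
})

test_that("a parameter with no data influence returns its prior", {
  p <- fullParams(r = 1, s = 0) # LasR absent: KS12 cannot matter
  d <- quickDesign(channels = list(YFP = p), doses6 = doseLadder(6),
                   replicates = 2L, cv = 0.05, seed = 3)
  dr <- buildDoseResponse(quietly(subtractBackground(generatePlate(d))))
  ps <- quietly(fitCrosstalkMCMC(
    list(list(dr = dr, promoter = "pLux", r = 1, s = 0)),
    list(pLux = p), free = c("KR6", "KS12"), draws = 3000, seed = 6,
    minPostSteps = 400))
  ks12 <- ps@draws[, "KS12"]
  pr <- defaultPriors()$KS12
  # compare to the flat prior via the empirical CDF
  u <- (ks12 - pr[1]) / diff(pr)
  ksStat <- max(abs(sort(u) - (seq_along(u) / length(u))))
  expect_lt(ksStat, 0.12)
})

test_that("fixing r for the pCat baseline resolves the (KGR, r) confounding", {
  p <- fullParams(s = 0)
  d <- quickDesign(channels = list(YFP = p), doses6 = doseLadder(8),
                   replicates = 3L, cv = 0.05, seed = 10)
  dr <- buildDoseResponse(quietly(subtractBackground(generatePlate(d))))
  entry <- function(rFixed) list(list(dr = dr, promoter = "pLux",
                                      r = rFixed, s = 0))
  fixed <- quietly(fitCrosstalkMCMC(entry(1), list(pLux = p),
                                    free = c("KR6", "pLux.KGR"),
                                    draws = 3000, seed = 2, minPostSteps = 1000))
  loose <- quietly(fitCrosstalkMCMC(entry(1), list(pLux = p),
                                    free = c("KR6", "pLux.KGR", "r"),
                                    draws = 3000, seed = 2, minPostSteps = 1000))
  expect_lt(sd(fixed@draws[, "pLux.KGR"]), sd(loose@draws[, "pLux.KGR"]))
})

test_that("posterior width shrinks as replication grows", {
  p <- fullParams(s = 0)
  widths <- vapply(c(1L, 3L, 9L), function(reps) {
    d <- plateDesign(channels = list(YFP = p), doses6 = doseLadder(8),
                     replicates = reps, cv = 0.1, seed = 20 + reps)
    dr <- buildDoseResponse(quietly(subtractBackground(generatePlate(d))))
    ps <- quietly(fitCrosstalkMCMC(
      list(list(dr = dr, promoter = "pLux", r = 1, s = 0)),
      list(pLux = p), free = "KR6", draws = 1500, seed = 4,
      minPostSteps = 300))
    ci <- credibleIntervals(ps)
    ci["KR6", "hi"] - ci["KR6", "lo"]
  }, numeric(1))
  expect_lt(widths[3], widths[1])
})

test_that("device-level inference localizes an absent receiver at the prior floor", {
  dev <- presetDevice(r = 0.011, s = 2.97) # r at the prior's lower edge
  des <- designPreset("fig3D", replicates = 2, seed = 31)
  des@channels$CFP@r <- 0.011; des@channels$YFP@r <- 0.011
  pe <- quietly(subtractBackground(generatePlate(des)))
  drC <- buildDoseResponse(pe, "CFP", "RFP", promoter = "pLux76")
  drY <- buildDoseResponse(pe, "YFP", "RFP", promoter = "pLas81")
  fit <- quietly(inferDeviceLevels(drC, drY, dev, draws = 2000, seed = 5))
  expect_lt(fit$ci["r", "median"], 0.1)   # mass at the lower bound
  expect_gt(fit$ci["s", "lo"], 2)         # s unaffected
  expect_lt(fit$ci["s", "hi"], 4.5)
})

test_that("arabinose-to-level transfer evaluates its limits and fits monotonically", {
  at <- araTransfer(basalLevel = 0.4, vmaxLevel = 20, ec50Ara = 1, hillAra = 2)
  expect_identical(araLevel(at, 0), 0.4)
  ara <- seq(0, 8, by = 0.25)
  expect_true(all(diff(araLevel(at, ara)) >= 0))
})
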