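# Signal-to-crosstalk objective and receiver-level optimization.

test_that("channel responses delegate exactly to the transfer function", {
  dev <- presetDevice()
  doses <- c(0, 10, 100, 5000)
  expect_identical(channelResponse(dev, "CFP", doses, 0),
                   simplifiedRate(dev@cfpParams, doses, 0))
  expect_identical(channelResponse(dev, "YFP", 0, doses),
                   simplifiedRate(dev@yfpParams, 0, doses))
  expect_identical(channelResponse(dev, "CFP", 0, 0), dev@cfpParams@a0)
})

test_that("a symmetric device scores exactly 1 and swapping inverts the ratio", {
  p <- presetParams("pLux76_mrfp")
  p@KGS <- 0.5 # give the channel both interactions
  sym <- twoChannelDevice(p, p)
  expect_identical(signalToCrosstalk(sym)$ratio, 1)

  dev <- presetDevice()
  fwd <- signalToCrosstalk(dev)$ratio
  swp <- signalToCrosstalk(twoChannelDevice(dev@yfpParams, dev@cfpParams))$ratio
  expect_equal(fwd * swp, 1, tolerance = 1e-12)
})

test_that("a vanished crosstalk term is reported as infinite with a flag", {
  cfp <- presetParams("pLux76_mrfp") # KGS = 0
  cfp@KR12 <- 0                      # and no chemical crosstalk either
  yfp <- presetParams("pLas81_mrfp")
  yfp@KR12 <- 0
  dev <- twoChannelDevice(cfp, yfp)
  dev@cfpParams@a0 <- 0
  res <- signalToCrosstalk(dev)
  expect_true(res$degenerate)
  expect_identical(res$ratio, Inf)
})

test_that("grid optimization equals brute force and refinement never loses", {
  dev <- presetDevice()
  opt <- optimizeLevels(dev, c(0.5, 30), c(0.5, 30), nGrid = 25)
  # brute-force recomputation over the same grid
  brute <- mapply(function(r, s)
    signalToCrosstalk(setDeviceLevels(dev, r, s))$ratio,
    opt$landscape$r, opt$landscape$s)
  expect_equal(opt$landscape$ratio, unname(brute))
  expect_gte(opt$ratioStar, max(brute))
  # the reported optimum is achievable
  expect_equal(signalToCrosstalk(setDeviceLevels(dev, opt$rStar, opt$sStar))$ratio,
               opt$ratioStar, tolerance = 1e-9)
})

test_that("an objective blind to LasR reports s as unidentifiable", {
  cfp <- presetParams("pLux76_mrfp") # KGS already 0
  yfp <- presetParams("pLas81_mrfp")
  cfp@KS6 <- 0; cfp@KS12 <- 0; cfp@KGS <- 0
  yfp@KS6 <- 0; yfp@KS12 <- 0; yfp@KGS <- 0
  dev <- twoChannelDevice(cfp, yfp)
  opt <- optimizeLevels(dev, c(0.5, 30), c(0.5, 30), nGrid = 25)
  expect_true(is.na(opt$sStar))
  expect_true(opt$rIdentifiable)
})

test_that("with chemical crosstalk present the optimal LuxR level is interior", {
  dev <- presetDevice()
  opt <- optimizeLevels(dev, c(0.05, 500), c(0.05, 500), nGrid = 40)
  expect_gt(opt$rStar, 0.05 * 1.5)
  expect_lt(opt$rStar, 500 / 1.5)
})
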