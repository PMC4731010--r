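# Ratiometric activity extraction: exactness on clean data, scaling
# invariances, window determinism, background handling, replicate
# summaries.

mkPlate <- function(yfp, cfp, time = seq(0, 990, by = 10)) {
  plateExperiment(time, list(YFP = cbind(W1 = yfp), CFP = cbind(W1 = cfp)),
                  data.frame(well = "W1"))
}

test_that("exact proportionality and constant targets give exact activities", {
  t <- seq(0, 990, by = 10)
  cfp <- 5 + 0.3 * t + 1e-4 * t^2
  est <- estimateActivity(mkPlate(3 * cfp + 7, cfp), "W1")
  expect_equal(est$rho, 3, tolerance = 1e-12)

  est0 <- estimateActivity(mkPlate(rep(4, length(t)), cfp), "W1")
  expect_equal(est0$rho, 0)
})

test_that("activity scales with affine rescaling of either channel", {
  t <- seq(0, 990, by = 10)
  set.seed(4)
  cfp <- 10 + 0.4 * t + rnorm(length(t), 0, 2)
  yfp <- 2 + 0.9 * t + rnorm(length(t), 0, 2)
  base <- estimateActivity(mkPlate(yfp, cfp), "W1")
  up <- estimateActivity(mkPlate(5 * yfp + 11, cfp), "W1")
  expect_equal(up$rho, 5 * base$rho, tolerance = 1e-10)
  dn <- estimateActivity(mkPlate(yfp, 2 * cfp - 3), "W1")
  expect_equal(dn$rho, base$rho / 2, tolerance = 1e-10)
})

test_that("window selection is deterministic and extraction errors are informative", {
  t <- seq(0, 990, by = 10)
  set.seed(9)
  cfp <- cumsum(abs(rnorm(length(t))))
  yfp <- 2 * cfp
  e1 <- estimateActivity(mkPlate(yfp, cfp), "W1")
  e2 <- estimateActivity(mkPlate(yfp, cfp), "W1")
  expect_identical(e1$window, e2$window)

  # declining reference -> degenerate
  expect_error(estimateActivity(mkPlate(yfp, rev(cfp)), "W1"),
               "degenerate reference")
  # too few points
  short <- plateExperiment(seq(0, 70, 10),
                           list(YFP = cbind(W1 = 1:8), CFP = cbind(W1 = 1:8)),
                           data.frame(well = "W1"))
  expect_error(estimateActivity(short, "W1", window = c(1, 3)), "4 points")
})

test_that("background subtraction removes blanks exactly and clips at zero", {
  d <- quickDesign(doses6 = 100, cv = 0, bgMean = 40, bgSd = 0)
  pe <- generatePlate(d)
  corr <- quietly(subtractBackground(pe))
  blankCols <- SummarizedExperiment::colData(corr)$is_blank
  expect_true(all(abs(SummarizedExperiment::assay(corr, "YFP")[, blankCols]) < 1e-9))

  # zero blank leaves data untouched
  d0 <- quickDesign(doses6 = 100, bgMean = 0, bgSd = 0)
  pe0 <- generatePlate(d0)
  same <- quietly(subtractBackground(pe0))
  expect_equal(SummarizedExperiment::assay(same, "YFP"),
               SummarizedExperiment::assay(pe0, "YFP"))

  # noisy additive offset removed to within the blanks' sampling error
  dn <- plateDesign(doses6 = 1000, replicates = 4L, cv = 0, bgMean = 100,
                    bgSd = 3, nBlanks = 30L, seed = 8)
  pen <- generatePlate(dn)
  cor2 <- quietly(subtractBackground(pen))
  truth <- S4Vectors::metadata(pen)$truth
  est <- estimateActivity(cor2, truth$well[1])
  expect_lt(abs(est$rho - truth$activity[1]) / truth$activity[1], 0.02)
})

test_that("dose-response summaries follow replicate conventions", {
  d <- quickDesign(doses6 = c(10, 100), replicates = 3L)
  dr <- buildDoseResponse(quietly(subtractBackground(generatePlate(d))))
  expect_equal(dr@data$n, c(3, 3))
  expect_equal(dr@data$sd, c(0, 0), tolerance = 1e-10) # identical replicates

  d1 <- quickDesign(doses6 = 10, replicates = 1L)
  dr1 <- buildDoseResponse(quietly(subtractBackground(generatePlate(d1))))
  expect_true(is.na(dr1@data$sd)) # undefined, not zero

  # mixed devices among measurement wells are rejected
  pe <- generatePlate(quickDesign(doses6 = c(10, 100), replicates = 1L))
  SummarizedExperiment::colData(pe)$device[1] <- "other"
  expect_error(buildDoseResponse(pe), "multiple devices")
})

test_that("generator dose-response round-trips onto the generating curve", {
  p <- fullParams()
  d <- plateDesign(channels = list(YFP = p), doses6 = doseLadder(6),
                   replicates = 3L, cv = 0.08, seed = 13)
  pe <- quietly(subtractBackground(generatePlate(d)))
  dr <- buildDoseResponse(pe)
  pred <- simplifiedRate(p, dr@data$C6, dr@data$C12)
  expect_true(all(abs(dr@data$rho - pred) <
                    pmax(4 * dr@data$sd / sqrt(dr@data$n), 0.12 * pred)))
})
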