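# Synthetic-data generator: determinism, noise calibration, ground-truth
# fidelity, and lossless round trips through the package's own readers.

test_that("noiseless generation round-trips through activity extraction", {
  p <- fullParams()
  p@a0 <- 1; p@a1R <- 1; p@a1S <- 1 # activity pinned at 1 RPU everywhere
  d <- quickDesign(channels = list(YFP = p), doses6 = 100)
  est <- estimateActivity(generatePlate(d), 1)
  expect_equal(est$rho, 1, tolerance = 1e-6)
})

test_that("generation is seed-deterministic", {
  d <- plateDesign(doses6 = c(10, 100), replicates = 2L, cv = 0.1, seed = 99)
  a <- SummarizedExperiment::assay(generatePlate(d), "YFP")
  b <- SummarizedExperiment::assay(generatePlate(d), "YFP")
  expect_identical(a, b)
  d@seed <- 100
  expect_false(identical(a, SummarizedExperiment::assay(generatePlate(d), "YFP")))
})

test_that("ground truth reproduces the generating transfer function", {
  p <- fullParams()
  d <- plateDesign(channels = list(YFP = p), doses6 = c(50, 500),
                   doses12 = c(200), replicates = 1L, seed = 2)
  truth <- S4Vectors::metadata(generatePlate(d))$truth
  expect_equal(truth$activity,
               simplifiedRate(p, truth$C6, truth$C12))
})

test_that("grid generation at zero noise equals the simulator bitwise", {
  sp <- defaultSpatialParams()
  lay <- senderReceiverLayout(nRows = 3, nCols = 4)
  g <- generateGrid(lay, sp, horizon = 150, recordEvery = 75, cv = 0, seed = 1)
  expect_identical(g$observed@states[[2]]@cfp, g$truth@states[[2]]@cfp)

  # RFP proxy (capacity) is untouched by construction before noise
  gn <- generateGrid(lay, sp, horizon = 150, recordEvery = 75, cv = 0.1,
                     seed = 1)
  expect_identical(gn$truth@states[[2]]@capacity,
                   g$truth@states[[2]]@capacity)
})

test_that("measurement noise has the designed coefficient of variation", {
  sp <- defaultSpatialParams()
  lay <- gridLayout(matrix("constitutive_control", 15, 15))
  g <- generateGrid(lay, sp, horizon = 600, recordEvery = 100, cv = 0.1,
                    seed = 12)
  rel <- unlist(lapply(2:length(g$truth@states), function(k) {
    tr <- g$truth@states[[k]]@cfp
    ob <- g$observed@states[[k]]@cfp
    (ob / tr)[tr > 0]
  }))
  expect_gt(length(rel), 1000)
  expect_gt(sd(rel), 0.08)
  expect_lt(sd(rel), 0.12)
})

test_that("plate CSVs round-trip losslessly through the package readers", {
  d <- plateDesign(doses6 = c(10, 1000), replicates = 2L, cv = 0.05, seed = 4)
  pe <- generatePlate(d)
  vf <- tempfile(fileext = ".csv"); cf <- tempfile(fileext = ".csv")
  writePlateCSV(pe, vf, cf)
  back <- readPlateCSV(vf, cf)
  for (ch in SummarizedExperiment::assayNames(pe))
    expect_equal(SummarizedExperiment::assay(back, ch),
                 SummarizedExperiment::assay(pe, ch), tolerance = 1e-12)
  expect_identical(colnames(back), colnames(pe))
  unlink(c(vf, cf))
})

test_that("design presets build valid designs in the documented regimes", {
  for (nm in c("fig1B", "fig1C", "fig1F_luxr", "fig1F_lasr", "fig3D")) {
    d <- designPreset(nm, replicates = 1L)
    expect_s4_class(d, "PlateDesign")
    expect_true(validObject(d))
  }
  # the strong-expression device is more sensitive than the weak one
  strong <- designPreset("fig1B")@channels$YFP
  weak <- designPreset("fig1C")@channels$YFP
  mid <- function(p) {
    f <- simplifiedRate(p, doseLadder(40, 0.1, 25000), 0)
    doseLadder(40, 0.1, 25000)[which.min(abs(f - (min(f) + max(f)) / 2))]
  }
  expect_lt(mid(strong), mid(weak))
})
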