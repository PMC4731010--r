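# Shared fixtures: small parameter sets, quick designs and layouts used
# across test files. Everything is generated in code at test time.

quietly <- function(expr) suppressMessages(suppressWarnings(expr))

# a fully general parameter set exercising every term of the transfer
# function
fullParams <- function(r = 1, s = 1, n = 2) {
  crosstalkParams(KR6 = 0.015, KR12 = 1.5e-4, KS6 = 2e-9, KS12 = 0.002,
                  KGR = 4, KGS = 0.1, a0 = 0.05, a1R = 12, a1S = 7.7,
                  n = n, r = r, s = s)
}

# random valid parameter set (log-uniform scales)
randomParams <- function(n = 2) {
  crosstalkParams(KR6 = 10^runif(1, -4, -1), KR12 = 10^runif(1, -6, -3),
                  KS6 = 10^runif(1, -8, -5), KS12 = 10^runif(1, -4, -1),
                  KGR = 10^runif(1, -1, 1), KGS = 10^runif(1, -2, 0.5),
                  a0 = 10^runif(1, -2, 0), a1R = 10^runif(1, 0, 1.5),
                  a1S = 10^runif(1, 0, 1), n = n,
                  r = 10^runif(1, -0.5, 1), s = 10^runif(1, -0.5, 1))
}

# minimal plate design: one device, few doses, quick to generate
quickDesign <- function(..., doses6 = c(100, 1000), replicates = 1L,
                        cv = 0, bgMean = 0, bgSd = 0, seed = 1) {
  plateDesign(doses6 = doses6, replicates = replicates, cv = cv,
              bgMean = bgMean, bgSd = bgSd, seed = seed, ...)
}

# small all-receiver layout with a point HSL release in the middle
pointReleaseLayout <- function(n = 7, c6 = 1000) {
  init <- matrix(0, n, n)
  init[ceiling(n / 2), ceiling(n / 2)] <- c6
  gridLayout(matrix("empty", n, n), initC6 = init)
}

# spatial parameters with signaling disabled (pure diffusion)
diffusionOnlyParams <- function(D = 0.003, kDeg = 0) {
  sp <- defaultSpatialParams()
  sp@kSyn6 <- 0; sp@kSyn12 <- 0
  sp@kDeg6 <- kDeg; sp@kDeg12 <- kDeg
  sp@D6 <- D; sp@D12 <- D
  sp
}
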