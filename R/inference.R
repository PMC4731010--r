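# Bayesian inference of crosstalk parameters from dose-response data:
# Gaussian likelihood on ratiometric activities, log10-uniform priors, and
# an affine-invariant ensemble (stretch-move) MCMC sampler.

#' Affine-invariant ensemble MCMC sampler
#'
#' Goodman-Weare stretch-move sampler: an ensemble of walkers explores the
#' target by proposing moves along lines through pairs of walkers, with the
#' stretch variable drawn from g(z) proportional to 1/sqrt(z) on [1/a, a].
#' Affine invariance makes the sampler insensitive to the strong parameter
#' correlations typical of partially identified binding constants.
#'
#' @param logPost function(theta) returning the log posterior density
#'   (may return -Inf outside the support).
#' @param init numeric matrix (nWalkers x d) of starting positions, or a
#'   vector of length d around which walkers are scattered in a relative
#'   1\% ball.
#' @param nSteps number of ensemble steps.
#' @param seed integer seed; identical seeds give bit-identical chains.
#' @param nWalkers number of walkers (default 4d, minimum 2d + 2, even).
#' @param a stretch-scale parameter (> 1).
#' @return A list with \code{chain} (nSteps x nWalkers x d array),
#'   \code{logp} (nSteps x nWalkers), \code{acceptance} (mean rate).
#' @references Goodman & Weare (2010) Comm. App. Math. Comp. Sci. 5:65-80.
#' @export
ensembleMCMC <- function(logPost, init, nSteps, seed = 1, nWalkers = NULL,
                         a = 2) {
  set.seed(seed)
  if (is.matrix(init)) {
    X <- init
    d <- ncol(X)
    nWalkers <- nrow(X)
  } else {
    d <- length(init)
    if (is.null(nWalkers)) nWalkers <- max(4L * d, 2L * d + 2L)
    if (nWalkers %% 2L) nWalkers <- nWalkers + 1L
    X <- matrix(rep(init, each = nWalkers), nWalkers, d)
    X <- X * (1 + 0.01 * matrix(rnorm(nWalkers * d), nWalkers, d)) +
      1e-4 * matrix(rnorm(nWalkers * d), nWalkers, d)
  }
  if (nWalkers < 2 * d + 2)
    stop("need at least 2d + 2 walkers for the stretch move")
  lp <- apply(X, 1, logPost)
  if (all(!is.finite(lp))) stop("no walker starts inside the support")
  # nudge stray walkers onto the best start
  bad <- !is.finite(lp)
  if (any(bad)) {
    best <- which.max(lp)
    X[bad, ] <- rep(X[best, ], each = sum(bad)) *
      (1 + 1e-3 * matrix(rnorm(sum(bad) * d), sum(bad), d))
    lp[bad] <- apply(X[bad, , drop = FALSE], 1, logPost)
    lp[!is.finite(lp)] <- logPost(X[best, ]) - 1e6
  }
  halves <- split(seq_len(nWalkers),
                  rep(1:2, each = ceiling(nWalkers / 2))[seq_len(nWalkers)])
  chain <- array(NA_real_, c(nSteps, nWalkers, d))
  logp <- matrix(NA_real_, nSteps, nWalkers)
  nAcc <- 0L
  for (step in seq_len(nSteps)) {
    for (h in 1:2) {
      idx <- halves[[h]]
      comp <- halves[[3L - h]]
      m <- length(idx)
      z <- ((a - 1) * runif(m) + 1)^2 / a
      j <- comp[sample.int(length(comp), m, replace = TRUE)]
      prop <- X[j, , drop = FALSE] + z * (X[idx, , drop = FALSE] -
                                            X[j, , drop = FALSE])
      lpProp <- apply(prop, 1, logPost)
      logRatio <- (d - 1) * log(z) + lpProp - lp[idx]
      acc <- log(runif(m)) < logRatio
      acc[!is.finite(lpProp)] <- FALSE
      X[idx[acc], ] <- prop[acc, , drop = FALSE]
      lp[idx[acc]] <- lpProp[acc]
      nAcc <- nAcc + sum(acc)
    }
    chain[step, , ] <- X
    logp[step, ] <- lp
  }
  list(chain = chain, logp = logp,
       acceptance = nAcc / (nSteps * nWalkers))
}

# Split-Rhat over walker chains (each walker split in half).
splitRhat <- function(chain) {
  nSteps <- dim(chain)[1]
  half <- floor(nSteps / 2)
  apply(chain, 3, function(m) {
    pieces <- cbind(m[seq_len(half), , drop = FALSE],
                    m[(nSteps - half + 1):nSteps, , drop = FALSE])
    mns <- colMeans(pieces)
    vars <- apply(pieces, 2, var)
    W <- mean(vars)
    B <- half * var(mns)
    if (W <= 0) return(1)
    sqrt(((half - 1) / half * W + B / half) / W)
  })
}

# Crude effective sample size: initial positive sequence estimator on the
# ensemble-mean trace, scaled by the number of walkers.
crudeESS <- function(chain) {
  nSteps <- dim(chain)[1]
  nWalkers <- dim(chain)[2]
  apply(chain, 3, function(m) {
    x <- rowMeans(m)
    v <- var(x)
    if (v <= 0) return(nSteps * nWalkers)
    tauSum <- 0
    for (lag in seq_len(min(nSteps - 2, 200))) {
      rho <- cor(x[seq_len(nSteps - lag)], x[(lag + 1):nSteps])
      if (!is.finite(rho) || rho < 0.05) break
      tauSum <- tauSum + rho
    }
    max(1, nSteps / (1 + 2 * tauSum)) * nWalkers
  })
}

#' Default log10-uniform prior ranges
#'
#' Broad scale-parameter priors: association constants span 1e-6 to 1e2
#' (1/nM for the HSL constants, dimensionless for the promoter constants),
#' transcription rates 1e-3 to 1e4 RPU, cooperativity 0.5 to 4, receiver
#' levels 1e-2 to 1e2 pCat units.
#'
#' @return Named list of \code{c(lo, hi)} bounds on the log10 scale.
#' @export
defaultPriors <- function() {
  K <- c(-6, 2)
  a <- c(-3, 4)
  list(KR6 = K, KR12 = K, KS6 = K, KS12 = K, KGR = K, KGS = K,
       a0 = a, a1R = a, a1S = a, n = log10(c(0.5, 4)),
       r = c(-2, 2), s = c(-2, 2))
}

# Strip a scoped free-parameter name ("pLux.KGR" -> "KGR").
baseName <- function(nm) sub("^.*\\.", "", nm)

# Apply a log10 parameter vector onto a named list of promoter parameter
# objects. Unscoped names are shared across all promoters; "promoter.field"
# names touch one promoter.
applyTheta <- function(promoters, free, theta) {
  for (k in seq_along(free)) {
    nm <- free[k]
    val <- 10^theta[k]
    if (grepl("\\.", nm)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      slot(promoters[[parts[1]]], parts[2]) <- val
    } else {
      for (pn in names(promoters)) slot(promoters[[pn]], nm) <- val
    }
  }
  promoters
}

#' Gaussian log-likelihood of a dose-response dataset
#'
#' The mean activity at each dose is modeled as the equilibrium
#' transcription rate, with Gaussian error whose scale is the standard
#' error of the replicate mean floored at a multiplicative fraction of the
#' predicted mean (absorbing day-to-day effects not captured by replicate
#' scatter).
#'
#' @param params a \linkS4class{CrosstalkParams} for the dataset's context.
#' @param dr a \linkS4class{DoseResponse}.
#' @param sdFloor multiplicative error floor (fraction of predicted mean).
#' @return Log-likelihood (sum over dose points); -Inf (with a warning)
#'   when the model prediction is non-finite.
#' @export
crosstalkLogLik <- function(params, dr, sdFloor = 0.1) {
  d <- dr@data
  pred <- rateCore(params, d$C6, d$C12)
  if (any(!is.finite(pred))) {
    warning("non-finite model prediction")
    return(-Inf)
  }
  sem <- ifelse(is.na(d$sd), 0, d$sd / sqrt(d$n))
  sdEff <- pmax(sem, sdFloor * abs(pred), 1e-6)
  sum(dnorm(d$rho, pred, sdEff, log = TRUE))
}

# Internal: log-posterior factory for a set of datasets under a sharing map.
crosstalkLogPost <- function(entries, promoters, free, priors, sdFloor) {
  lo <- vapply(free, function(nm) priors[[baseName(nm)]][1], numeric(1))
  hi <- vapply(free, function(nm) priors[[baseName(nm)]][2], numeric(1))
  pre <- lapply(entries, function(e) {
    d <- e$dr@data
    list(C6 = d$C6, C12 = d$C12, rho = d$rho,
         sem = ifelse(is.na(d$sd), 0, d$sd / sqrt(d$n)),
         promoter = e$promoter, r = e$r, s = e$s)
  })
  # entry-level receiver levels are design constants unless sampled
  rFree <- "r" %in% free
  sFree <- "s" %in% free
  function(theta) {
    if (any(theta < lo | theta > hi)) return(-Inf)
    prom <- applyTheta(promoters, free, theta)
    ll <- 0
    for (e in pre) {
      p <- prom[[e$promoter]]
      if (!rFree) p@r <- e$r
      if (!sFree) p@s <- e$s
      pred <- rateCore(p, e$C6, e$C12)
      if (any(!is.finite(pred))) return(-Inf)
      sdEff <- pmax(e$sem, sdFloor * abs(pred), 1e-6)
      ll <- ll + sum(dnorm(e$rho, pred, sdEff, log = TRUE))
    }
    ll
  }
}

#' Fit crosstalk parameters by ensemble MCMC
#'
#' Joint fit of one or more dose-response datasets under a
#' parameter-sharing map. Each dataset entry names the promoter context it
#' was measured in and the (known) receiver levels of its device; receiver
#' levels are fixed at 1 for pCat-driven devices, which defines the unit
#' of the confounded products KGR r^2 / KGS s^2. Free parameters are
#' sampled on the log10 scale under log10-uniform priors; names without a
#' prefix (e.g. "KR6") are shared across all promoter contexts while
#' prefixed names (e.g. "pLux.KGR") are promoter-specific.
#'
#' Sampling uses \code{\link{ensembleMCMC}} with \code{4 x} parameter-count
#' walkers initialized near a Nelder-Mead posterior mode; the first half of
#' the chain is discarded as warmup and at least \code{draws} flattened
#' post-warmup draws are retained.
#'
#' @param entries list of dataset entries, each a list with elements
#'   \code{dr} (\linkS4class{DoseResponse}), \code{promoter} (name into
#'   \code{promoters}), \code{r}, \code{s} (device receiver levels, pCat
#'   units).
#' @param promoters named list of baseline \linkS4class{CrosstalkParams},
#'   one per promoter context; fixed parameters keep these values.
#' @param free character vector of free parameter names.
#' @param draws minimum number of retained post-warmup draws.
#' @param seed integer seed (chains are reproducible bit-for-bit).
#' @param priors named list of log10 prior bounds
#'   (\code{\link{defaultPriors}}).
#' @param sdFloor multiplicative error floor for the likelihood.
#' @param nOptimStarts random restarts for the mode search.
#' @param minPostSteps minimum post-warmup ensemble steps (chains this long
#'   are needed to traverse weakly identified parameter ridges; retained
#'   draws are thinned back to about \code{draws}).
#' @return A \linkS4class{PosteriorSample}. A convergence warning (not an
#'   error) is issued if any split-Rhat exceeds 1.1.
#' @export
fitCrosstalkMCMC <- function(entries, promoters, free, draws = 5000,
                             seed = 1, priors = defaultPriors(),
                             sdFloor = 0.1, nOptimStarts = 4,
                             minPostSteps = 1500L) {
  stopifnot(length(free) >= 1)
  for (e in entries) {
    stopifnot(is(e$dr, "DoseResponse"), e$promoter %in% names(promoters))
  }
  logPost <- crosstalkLogPost(entries, promoters, free, priors, sdFloor)
  lo <- vapply(free, function(nm) priors[[baseName(nm)]][1], numeric(1))
  hi <- vapply(free, function(nm) priors[[baseName(nm)]][2], numeric(1))

  set.seed(seed)
  modes <- list()
  vals <- numeric(0)
  for (k in seq_len(nOptimStarts)) {
    start <- lo + runif(length(free)) * (hi - lo)
    opt <- tryCatch(
      optim(start, function(th) -logPost(th), method = "Nelder-Mead",
            control = list(maxit = 600)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value)) {
      modes[[length(modes) + 1L]] <- opt$par
      vals <- c(vals, -opt$value)
    }
  }
  if (!length(modes)) {
    modes <- list((lo + hi) / 2)
    vals <- 0
  }
  # keep endpoints within ~30 log-lik units of the best: distinct points on
  # posterior ridges seed an ensemble that already spans them
  keepM <- vals >= max(vals) - 30
  modes <- modes[keepM]
  best <- modes[[which.max(vals[keepM])]]

  d <- length(free)
  nWalkers <- 4L * d
  if (nWalkers %% 2L) nWalkers <- nWalkers + 1L
  # run long enough both to mix along posterior ridges and to retain the
  # requested number of flattened draws after 50% warmup and thinning
  nStepsPost <- max(ceiling(draws / nWalkers), minPostSteps)
  nSteps <- 2L * nStepsPost
  init <- matrix(unlist(lapply(seq_len(nWalkers), function(w)
    modes[[((w - 1L) %% length(modes)) + 1L]])), nWalkers, d, byrow = TRUE)
  init <- init + 0.1 * matrix(rnorm(nWalkers * d), nWalkers, d)
  init <- pmin(pmax(init, matrix(lo + 1e-9, nWalkers, d, byrow = TRUE)),
               matrix(hi - 1e-9, nWalkers, d, byrow = TRUE))
  run <- ensembleMCMC(logPost, init, nSteps, seed = seed + 1L)

  keep <- (nSteps - nStepsPost + 1L):nSteps
  thin <- max(1L, floor(nStepsPost * nWalkers / draws))
  keep <- keep[seq(1L, length(keep), by = thin)]
  post <- run$chain[keep, , , drop = FALSE]
  flat <- matrix(aperm(post, c(2, 1, 3)), ncol = d)
  colnames(flat) <- free
  lpFlat <- as.vector(t(run$logp[keep, , drop = FALSE]))
  rhat <- splitRhat(post)
  names(rhat) <- free
  if (any(rhat > 1.1))
    warning("convergence warning: split-Rhat > 1.1 for ",
            paste(free[rhat > 1.1], collapse = ", "))
  new("PosteriorSample", draws = flat, paramNames = free, logPost = lpFlat,
      diagnostics = list(acceptance = run$acceptance, rhat = rhat,
                         ess = setNames(crudeESS(post), free),
                         nWalkers = nWalkers, nSteps = nSteps),
      seed = seed)
}

#' Central credible intervals of a posterior sample
#' @param ps a \linkS4class{PosteriorSample}.
#' @param level credible level (default 0.95).
#' @return Matrix with rows = parameters, columns \code{lo}, \code{median},
#'   \code{hi} (log10 scale).
#' @export
credibleIntervals <- function(ps, level = 0.95) {
  alpha <- (1 - level) / 2
  q <- t(apply(ps@draws, 2, quantile, probs = c(alpha, 0.5, 1 - alpha)))
  dimnames(q) <- list(ps@paramNames, c("lo", "median", "hi"))
  q
}

#' Infer receiver expression levels of a two-channel device
#'
#' Two-parameter posterior over (r, s) -- the LuxR and LasR levels in pCat
#' units -- conditioned on the device's dose responses in both fluorescence
#' channels, with all promoter constants fixed from a prior fit.
#'
#' @param drCfp,drYfp \linkS4class{DoseResponse} datasets for the
#'   pLux76/CFP and pLas81/YFP channels.
#' @param device a \linkS4class{TwoChannelDevice} carrying the fixed
#'   promoter constants (its levels are ignored).
#' @param draws,seed,priors,sdFloor passed to the sampler.
#' @return A list with \code{posterior} (\linkS4class{PosteriorSample} over
#'   log10 r, s), \code{estimate} (medians on the natural scale) and
#'   \code{ci} (95\% intervals, natural scale).
#' @examples
#' \donttest{
#' dev <- presetDevice(r = 5.89, s = 2.97)
#' pe <- generatePlate(designPreset("fig3D", replicates = 3, seed = 7))
#' pe <- subtractBackground(pe)
#' drC <- buildDoseResponse(pe, "CFP", "RFP", promoter = "pLux76")
#' drY <- buildDoseResponse(pe, "YFP", "RFP", promoter = "pLas81")
#' fit <- inferDeviceLevels(drC, drY, dev, draws = 2000, seed = 1)
#' fit$estimate
#' }
#' @export
inferDeviceLevels <- function(drCfp, drYfp, device, draws = 5000, seed = 1,
                              priors = defaultPriors(), sdFloor = 0.1) {
  promoters <- list(cfp = device@cfpParams, yfp = device@yfpParams)
  free <- c("r", "s")
  logPost <- function(theta) {
    if (theta[1] < priors$r[1] || theta[1] > priors$r[2] ||
        theta[2] < priors$s[1] || theta[2] > priors$s[2]) return(-Inf)
    ll <- 0
    for (nm in names(promoters)) {
      p <- promoters[[nm]]
      p@r <- 10^theta[1]
      p@s <- 10^theta[2]
      dr <- if (nm == "cfp") drCfp else drYfp
      ll <- ll + crosstalkLogLik(p, dr, sdFloor)
    }
    ll
  }
  set.seed(seed)
  grid <- as.matrix(expand.grid(r = seq(priors$r[1], priors$r[2], length.out = 25),
                                s = seq(priors$s[1], priors$s[2], length.out = 25)))
  vals <- apply(grid, 1, logPost)
  best <- grid[which.max(vals), ]
  opt <- optim(best, function(th) -logPost(th), method = "Nelder-Mead")
  nWalkers <- 10L
  nStepsPost <- ceiling(draws / nWalkers)
  init <- matrix(rep(opt$par, each = nWalkers), nWalkers, 2) +
    0.02 * matrix(rnorm(nWalkers * 2), nWalkers, 2)
  run <- ensembleMCMC(logPost, init, 2L * nStepsPost, seed = seed + 1L)
  keep <- (nStepsPost + 1L):(2L * nStepsPost)
  post <- run$chain[keep, , , drop = FALSE]
  flat <- matrix(aperm(post, c(2, 1, 3)), ncol = 2)
  colnames(flat) <- free
  ps <- new("PosteriorSample", draws = flat, paramNames = free,
            logPost = as.vector(t(run$logp[keep, ])),
            diagnostics = list(acceptance = run$acceptance,
                               rhat = setNames(splitRhat(post), free),
                               ess = setNames(crudeESS(post), free),
                               nWalkers = nWalkers, nSteps = 2L * nStepsPost),
            seed = seed)
  ci <- 10^credibleIntervals(ps)
  list(posterior = ps,
       estimate = c(r = unname(ci["r", "median"]), s = unname(ci["s", "median"])),
       ci = ci)
}

#' Infer the arabinose-to-receiver-level transfer curve
#'
#' Stage 1: at each arabinose concentration, the inducible receiver's level
#' is given a one-parameter posterior conditioned on that concentration's
#' dose-response data (promoter constants fixed). Stage 2: a saturating
#' Hill curve linking arabinose to level is fitted to the posterior-median
#' levels by weighted least squares; its parameterization (vmax = basal +
#' positive increment) makes the fitted curve monotone nondecreasing by
#' construction. Uncertainty bands come from refitting the curve to
#' resampled posterior draws of the per-concentration levels.
#'
#' @param entries list with one element per arabinose level: a list with
#'   \code{dr} (\linkS4class{DoseResponse}), \code{ara} (mM),
#'   \code{promoter}, and the fixed level of the other receiver
#'   (\code{otherLevel}).
#' @param promoters named list of fixed \linkS4class{CrosstalkParams}.
#' @param receiver which receiver is induced ("LuxR" or "LasR").
#' @param draws,seed,sdFloor,priors sampler settings.
#' @param nBand number of posterior refits for the uncertainty band.
#' @return A list with \code{transfer} (\linkS4class{AraTransfer}),
#'   \code{levels} (data frame: ara, median and 95\% CI of the level) and
#'   \code{bandDraws} (matrix of Hill parameter draws: basal, vmax, ec50,
#'   hill).
#' @export
inferAraTransfer <- function(entries, promoters, receiver = c("LuxR", "LasR"),
                             draws = 1500, seed = 1, sdFloor = 0.1,
                             priors = defaultPriors(), nBand = 50) {
  receiver <- match.arg(receiver)
  if (length(entries) < 3)
    stop("need datasets at >= 3 arabinose levels")
  lvName <- if (receiver == "LuxR") "r" else "s"
  levelPosts <- vector("list", length(entries))
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    p <- promoters[[e$promoter]]
    if (receiver == "LuxR") p@s <- e$otherLevel else p@r <- e$otherLevel
    rng <- priors[[lvName]]
    logPost <- function(theta) {
      if (theta < rng[1] || theta > rng[2]) return(-Inf)
      if (receiver == "LuxR") p@r <- 10^theta else p@s <- 10^theta
      crosstalkLogLik(p, e$dr, sdFloor)
    }
    gridv <- seq(rng[1], rng[2], length.out = 60)
    start <- gridv[which.max(vapply(gridv, logPost, numeric(1)))]
    init <- matrix(start + 0.02 * rnorm(6), 6, 1)
    nStepsPost <- ceiling(draws / 6)
    run <- ensembleMCMC(logPost, init, 2L * nStepsPost, seed = seed + k)
    keep <- (nStepsPost + 1L):(2L * nStepsPost)
    levelPosts[[k]] <- 10^as.vector(run$chain[keep, , 1])
  }
  ara <- vapply(entries, function(e) e$ara, numeric(1))
  med <- vapply(levelPosts, median, numeric(1))
  lo <- vapply(levelPosts, quantile, numeric(1), probs = 0.025)
  hi <- vapply(levelPosts, quantile, numeric(1), probs = 0.975)
  w <- 1 / pmax((hi - lo) / 4, 1e-3)^2

  fitHill <- function(y, w) {
    # q = (log basal, log increment, log ec50, log hill)
    sse <- function(q) {
      at <- araTransfer(exp(q[1]), exp(q[1]) + exp(q[2]), exp(q[3]),
                        exp(q[4]))
      sum(w * (araLevel(at, ara) - y)^2)
    }
    q0 <- c(log(max(min(y), 1e-3)),
            log(max(max(y) - min(y), 1e-3)),
            log(max(median(ara[ara > 0]), 0.1)), log(1.5))
    opt <- optim(q0, sse, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    araTransfer(exp(opt$par[1]), exp(opt$par[1]) + exp(opt$par[2]),
                exp(opt$par[3]), exp(opt$par[4]))
  }
  transfer <- fitHill(med, w)
  set.seed(seed)
  bandDraws <- t(vapply(seq_len(nBand), function(b) {
    y <- vapply(levelPosts, function(lp) lp[sample.int(length(lp), 1)],
                numeric(1))
    at <- fitHill(y, w)
    c(basal = at@basalLevel, vmax = at@vmaxLevel, ec50 = at@ec50Ara,
      hill = at@hillAra)
  }, numeric(4)))
  list(transfer = transfer,
       levels = data.frame(ara = ara, level = med, lo = lo, hi = hi),
       bandDraws = bandDraws)
}

#' One repetition of the end-to-end parameter-recovery study
#'
#' Simulation-based calibration of the full pipeline at the characterized
#' system's regime: two single-receiver reporter devices on the wild-type
#' promoter (LuxR-only and LasR-only, pCat-level expression) are simulated
#' as plate-fluorometer experiments across both HSL dose ladders,
#' activities are extracted ratiometrically, and the shared binding
#' constants plus promoter parameters are re-inferred by ensemble MCMC.
#' Returns per-parameter 95\% credible intervals against the generating
#' truth.
#'
#' @param seed integer seed controlling both data generation and sampling.
#' @param draws retained posterior draws.
#' @param replicates replicate wells per dose.
#' @param nDoses doses per HSL ladder.
#' @return Data frame with columns \code{param}, \code{truth} (log10),
#'   \code{lo}, \code{median}, \code{hi} (log10 credible bounds) and
#'   \code{covered}.
#' @export
crosstalkRecoveryRun <- function(seed, draws = 5000, replicates = 3L,
                                 nDoses = 12) {
  pLux <- presetParams("pLux")
  pA <- pLux; pA@r <- 1; pA@s <- 0
  pB <- pLux; pB@r <- 0; pB@s <- 1
  mk <- function(p, name, sd) {
    plateDesign(deviceName = name, channels = list(YFP = p),
                doses6 = doseLadder(nDoses), doses12 = doseLadder(nDoses),
                replicates = replicates, seed = sd)
  }
  peA <- suppressMessages(subtractBackground(generatePlate(
    mk(pA, "pCatR123", seed))))
  peB <- suppressMessages(subtractBackground(generatePlate(
    mk(pB, "pCatS123", seed + 1000000L))))
  entries <- list(
    list(dr = buildDoseResponse(peA), promoter = "pLux", r = 1, s = 0),
    list(dr = buildDoseResponse(peB), promoter = "pLux", r = 0, s = 1))
  free <- c("KR6", "KR12", "KS6", "KS12", "pLux.KGR", "pLux.KGS",
            "pLux.a1R", "pLux.a1S")
  ps <- suppressWarnings(fitCrosstalkMCMC(entries, list(pLux = pLux), free,
                                          draws = draws, seed = seed))
  ci <- credibleIntervals(ps)
  truth <- log10(c(pLux@KR6, pLux@KR12, pLux@KS6, pLux@KS12, pLux@KGR,
                   pLux@KGS, pLux@a1R, pLux@a1S))
  data.frame(param = free, truth = truth, lo = ci[, "lo"],
             median = ci[, "median"], hi = ci[, "hi"],
             covered = truth >= ci[, "lo"] & truth <= ci[, "hi"],
             row.names = NULL)
}
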