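# Synthetic plate-fluorometer and grid-membrane data with known ground
# truth, for calibrating and testing the extraction/inference pipeline.

setClassUnion("AraTransferOrNULL", c("AraTransfer", "NULL"))

#' Design of a synthetic plate-fluorometer experiment
#'
#' Describes one device measured over HSL dose ladders and arabinose
#' levels: the equilibrium transfer function of each fluorescent target
#' channel, the dose design, the growth model, and the noise model
#' (per-channel multiplicative lognormal noise with coefficient of
#' variation \code{cv}, plus additive Gaussian background).
#'
#' @slot deviceName character id.
#' @slot channels named list of \linkS4class{CrosstalkParams}, one per
#'   target fluorescence channel (e.g. \code{list(YFP = pLuxParams)}).
#' @slot referenceChannel name of the constitutive reference channel
#'   (activity 1 RPU by definition).
#' @slot araReceiver which receiver is arabinose-inducible ("none",
#'   "LuxR" or "LasR").
#' @slot araTransfer the \linkS4class{AraTransfer} used when
#'   \code{araReceiver != "none"}.
#' @slot doses6,doses12 HSL dose ladders, nM (each dose measured with the
#'   other signal absent).
#' @slot arabinose arabinose levels, mM.
#' @slot replicates replicate wells per condition.
#' @slot cadence,horizon measurement interval and span, min.
#' @slot cv multiplicative noise CV per channel.
#' @slot bgMean,bgSd additive background fluorescence mean/sd, a.u.
#' @slot growth per-well \linkS4class{GompertzGrowth}.
#' @slot nBlanks number of blank wells.
#' @slot seed RNG seed recorded with the design.
#' @export
setClass("PlateDesign",
  representation(deviceName = "character", channels = "list",
                 referenceChannel = "character",
                 araReceiver = "character", araTransfer = "AraTransferOrNULL",
                 doses6 = "numeric", doses12 = "numeric",
                 arabinose = "numeric", replicates = "integer",
                 cadence = "numeric", horizon = "numeric",
                 cv = "numeric", bgMean = "numeric", bgSd = "numeric",
                 growth = "GompertzGrowth", nBlanks = "integer",
                 seed = "numeric"))

setValidity("PlateDesign", function(object) {
  if (length(object@channels) < 1 || is.null(names(object@channels)))
    return("at least one named target channel required")
  if (!all(vapply(object@channels, is, logical(1), "CrosstalkParams")))
    return("channels must be CrosstalkParams objects")
  if (object@referenceChannel %in% names(object@channels))
    return("reference channel must be distinct from target channels")
  if (!object@araReceiver %in% c("none", "LuxR", "LasR"))
    return("araReceiver must be 'none', 'LuxR' or 'LasR'")
  if (object@araReceiver != "none" && is.null(object@araTransfer))
    return("araTransfer required when a receiver is arabinose-inducible")
  if (object@replicates < 1) return("replicates must be >= 1")
  if (object@cv < 0 || object@bgSd < 0) return("noise parameters must be >= 0")
  if (object@cadence <= 0 || object@horizon < 7 * object@cadence)
    return("horizon must cover at least 8 measurements")
  TRUE
})

#' Construct a plate design
#'
#' Defaults emulate the liquid-culture assay conditions: readings every 10
#' minutes for 1,000 minutes, doses spanning 10 nM to 25 uM, three
#' replicates, arabinose from 0 to 8 mM when induction is used.
#'
#' @param deviceName device id.
#' @param channels named list of target-channel \linkS4class{CrosstalkParams};
#'   default is the wild-type pLux reporter read out in YFP.
#' @param referenceChannel reference channel name.
#' @param doses6,doses12 dose ladders, nM.
#' @param arabinose arabinose levels, mM.
#' @param araReceiver,araTransfer inducible-receiver configuration.
#' @param replicates wells per condition.
#' @param cadence,horizon sampling interval and span, min.
#' @param cv multiplicative noise CV.
#' @param bgMean,bgSd additive background mean and sd, a.u.
#' @param growth a \linkS4class{GompertzGrowth}.
#' @param nBlanks blank wells.
#' @param seed RNG seed.
#' @return A \linkS4class{PlateDesign}.
#' @export
plateDesign <- function(deviceName = "pCatLL123",
                        channels = list(YFP = presetParams("pLux")),
                        referenceChannel = "CFP",
                        doses6 = numeric(0), doses12 = numeric(0),
                        arabinose = 0, araReceiver = "none",
                        araTransfer = NULL,
                        replicates = 3L, cadence = 10, horizon = 1000,
                        cv = 0.1, bgMean = 50, bgSd = 5,
                        growth = gompertzGrowth(), nBlanks = 3L, seed = 1) {
  new("PlateDesign", deviceName = deviceName, channels = channels,
      referenceChannel = referenceChannel, araReceiver = araReceiver,
      araTransfer = araTransfer, doses6 = doses6, doses12 = doses12,
      arabinose = arabinose, replicates = as.integer(replicates),
      cadence = cadence, horizon = horizon, cv = cv, bgMean = bgMean,
      bgSd = bgSd, growth = growth, nBlanks = as.integer(nBlanks),
      seed = seed)
}

setMethod("show", "PlateDesign", function(object) {
  cat(sprintf("PlateDesign '%s': channels %s vs %s; %d C6 + %d C12 doses x %d ara x %d reps\n",
              object@deviceName, paste(names(object@channels), collapse = "/"),
              object@referenceChannel, length(object@doses6),
              length(object@doses12), length(object@arabinose),
              object@replicates))
})

#' Built-in regime-plausible parameter presets
#'
#' Ground-truth parameter sets used by the synthetic-data generator and the
#' worked examples. They reproduce the qualitative regime of the
#' characterized system -- LuxR binds 3OC6HSL ~100x more tightly than
#' 3OC12HSL, LasR binds 3OC12HSL ~1e6x more tightly than 3OC6HSL, pLux76
#' has no measurable LasR affinity (KGS = 0), pLas81 has ~100x more LasR
#' than LuxR affinity -- without claiming the system's exact constants.
#'
#' @param name one of "pLux", "pLux76", "pLas81" (pR-referenced units,
#'   receiver levels r = s = 1) or "pLux76_mrfp", "pLas81_mrfp" (the
#'   optimized double-receiver context, mRFP1-referenced units).
#' @return A \linkS4class{CrosstalkParams}.
#' @examples
#' presetParams("pLux76")
#' @export
presetParams <- function(name = c("pLux", "pLux76", "pLas81",
                                  "pLux76_mrfp", "pLas81_mrfp")) {
  name <- match.arg(name)
  rec <- list(KR6 = 0.015, KR12 = 1.5e-4, KS6 = 2e-9, KS12 = 0.002, n = 2)
  args <- switch(name,
    pLux = c(rec, list(KGR = 4, KGS = 0.1, a0 = 0.05, a1R = 12, a1S = 7.7)),
    pLux76 = c(rec, list(KGR = 0.3, KGS = 0, a0 = 0.05, a1R = 12, a1S = 7.7)),
    pLas81 = c(rec, list(KGR = 0.04, KGS = 1, a0 = 0.05, a1R = 12, a1S = 7.7)),
    # mRFP1-referenced units (the chromosomal reference is ~55x weaker than pR)
    pLux76_mrfp = c(rec, list(KGR = 0.3, KGS = 0, a0 = 2.8, a1R = 660,
                              a1S = 430)),
    pLas81_mrfp = c(rec, list(KGR = 0.04, KGS = 1, a0 = 2.8, a1R = 660,
                              a1S = 430)))
  do.call(crosstalkParams, args)
}

#' The optimized two-channel receiver device
#'
#' pLux76 -> eCFP and pLas81 -> eYFP read against chromosomal mRFP1, at the
#' given receiver expression levels.
#'
#' @param r,s LuxR/LasR levels in pCat units (defaults: the levels of the
#'   optimized construct).
#' @return A \linkS4class{TwoChannelDevice}.
#' @export
presetDevice <- function(r = 5.89, s = 2.97) {
  cfp <- presetParams("pLux76_mrfp"); yfp <- presetParams("pLas81_mrfp")
  cfp@r <- r; cfp@s <- s; yfp@r <- r; yfp@s <- s
  twoChannelDevice(cfp, yfp)
}

#' Named plate-design presets
#'
#' Reduced-scale designs emulating the characterization experiments:
#' \describe{
#'   \item{fig1B}{wild-type pLux with strong expression of both receivers,
#'     12-dose ladders of each HSL.}
#'   \item{fig1C}{wild-type pLux with weak (pCat) expression of both
#'     receivers.}
#'   \item{fig1F_luxr, fig1F_lasr}{single-receiver pLux devices (the
#'     crosstalk-source experiment).}
#'   \item{fig3D}{the optimized double receiver pR33S175: CFP and YFP
#'     channels against mRFP1.}
#' }
#'
#' @param name preset id.
#' @param replicates,seed overrides.
#' @return A \linkS4class{PlateDesign}.
#' @export
designPreset <- function(name = c("fig1B", "fig1C", "fig1F_luxr",
                                  "fig1F_lasr", "fig3D"),
                         replicates = 3L, seed = 1) {
  name <- match.arg(name)
  ladder <- doseLadder()
  strong <- 50 # pLlacO1-driven receiver level, pCat units
  mk <- function(deviceName, p, ...) {
    plateDesign(deviceName = deviceName, channels = list(YFP = p),
                doses6 = ladder, doses12 = ladder,
                replicates = replicates, seed = seed, ...)
  }
  switch(name,
    fig1B = {
      p <- presetParams("pLux"); p@r <- strong; p@s <- strong
      mk("pR0011LL123", p)
    },
    fig1C = mk("pCatLL123", presetParams("pLux")),
    fig1F_luxr = {
      p <- presetParams("pLux"); p@s <- 0
      mk("pCatR123", p)
    },
    fig1F_lasr = {
      p <- presetParams("pLux"); p@r <- 0
      mk("pCatS123", p)
    },
    fig3D = {
      dev <- presetDevice()
      plateDesign(deviceName = "pR33S175",
                  channels = list(CFP = dev@cfpParams, YFP = dev@yfpParams),
                  referenceChannel = "RFP",
                  doses6 = ladder, doses12 = ladder,
                  replicates = replicates, seed = seed)
    })
}

#' Log-spaced HSL dose ladder
#' @param n number of non-zero doses.
#' @param from,to range, nM (default 10 nM to 25 uM).
#' @param zero include a zero dose first.
#' @return Numeric vector of doses, nM.
#' @export
doseLadder <- function(n = 12, from = 10, to = 25000, zero = FALSE) {
  d <- 10^seq(log10(from), log10(to), length.out = n)
  if (zero) c(0, d) else d
}

# Receiver levels of a design's channel parameters at a given arabinose
# concentration.
designLevels <- function(design, params, ara) {
  r <- params@r; s <- params@s
  if (design@araReceiver == "LuxR") r <- araLevel(design@araTransfer, ara)
  if (design@araReceiver == "LasR") s <- araLevel(design@araTransfer, ara)
  c(r = r, s = s)
}

#' Generate a synthetic plate-fluorometer experiment
#'
#' For every (dose, arabinose, replicate) condition a well is simulated:
#' population capacity follows the design's Gompertz growth model; the
#' constitutive reference channel accumulates at 1 RPU x capacity; each
#' target channel accumulates at its promoter's equilibrium transcription
#' rate (given the well's clamped HSL doses and arabinose-dependent
#' receiver levels) x capacity; OD tracks capacity. Measurements are then
#' corrupted with per-channel lognormal multiplicative noise (CV
#' \code{design@cv}) and additive Gaussian background; blank wells carry
#' background only. The ground truth (per-well true activities and the
#' design itself) is stored in the experiment's metadata.
#'
#' @param design a \linkS4class{PlateDesign}.
#' @return A plate experiment (see \code{\link{plateExperiment}}) with
#'   \code{metadata(pe)$truth}.
#' @examples
#' pe <- generatePlate(designPreset("fig1C", replicates = 1))
#' buildDoseResponse(subtractBackground(pe))
#' @export
generatePlate <- function(design) {
  validObject(design)
  set.seed(design@seed)
  time <- seq(0, design@horizon, by = design@cadence)
  g <- design@growth
  cap <- g@Kcap * exp(-exp(-g@kg * (time - g@tI)))
  # accumulated expression capacity: integral of cap over time (trapezoid)
  acc <- c(0, cumsum((cap[-1] + cap[-length(cap)]) / 2 * diff(time)))

  conds <- expand.grid(rep = seq_len(design@replicates),
                       ara = design@arabinose,
                       dose = c(design@doses6, design@doses12),
                       stringsAsFactors = FALSE)
  n6 <- length(design@doses6)
  conds$species <- rep(rep(c("3OC6HSL", "3OC12HSL"),
                           c(n6, length(design@doses12))),
                       each = design@replicates * length(design@arabinose))
  nW <- nrow(conds) + design@nBlanks
  wells <- sprintf("W%03d", seq_len(nW))
  isBlank <- c(rep(FALSE, nrow(conds)), rep(TRUE, design@nBlanks))

  channels <- c(names(design@channels), design@referenceChannel, "OD")
  assays <- lapply(channels, function(ch) matrix(0, length(time), nW))
  names(assays) <- channels
  truth <- vector("list", nW)
  sdlog <- sqrt(log(1 + design@cv^2))

  noisy <- function(x) {
    x * exp(rnorm(length(x), 0, sdlog)) +
      rnorm(length(x), design@bgMean, design@bgSd)
  }

  for (i in seq_len(nW)) {
    if (isBlank[i]) {
      for (ch in channels)
        assays[[ch]][, i] <- rnorm(length(time), design@bgMean, design@bgSd)
      next
    }
    C6 <- if (conds$species[i] == "3OC6HSL") conds$dose[i] else 0
    C12 <- if (conds$species[i] == "3OC12HSL") conds$dose[i] else 0
    for (ch in names(design@channels)) {
      p <- design@channels[[ch]]
      lv <- designLevels(design, p, conds$ara[i])
      p@r <- unname(lv["r"]); p@s <- unname(lv["s"])
      act <- simplifiedRate(p, C6, C12)
      assays[[ch]][, i] <- noisy(act * acc)
      truth[[i]] <- rbind(truth[[i]],
                          data.frame(well = wells[i], channel = ch,
                                     C6 = C6, C12 = C12,
                                     arabinose = conds$ara[i],
                                     activity = act))
    }
    assays[[design@referenceChannel]][, i] <- noisy(acc)
    assays[["OD"]][, i] <- cap * exp(rnorm(length(time), 0, sdlog)) + 0.04
  }

  cond <- data.frame(well = wells,
                     device = design@deviceName,
                     hsl_species = c(conds$species, rep("none", design@nBlanks)),
                     hsl_nM = c(conds$dose, rep(0, design@nBlanks)),
                     arabinose_mM = c(conds$ara, rep(0, design@nBlanks)),
                     replicate = c(conds$rep, seq_len(design@nBlanks)),
                     is_blank = isBlank)
  pe <- plateExperiment(time, assays, cond)
  S4Vectors::metadata(pe)$truth <- do.call(rbind, truth)
  S4Vectors::metadata(pe)$design <- design
  S4Vectors::metadata(pe)$seed <- design@seed
  pe
}

#' Generate a noisy grid-membrane trajectory
#'
#' Runs the lattice simulator (\code{\link{simulateGrid}}) and overlays
#' per-square multiplicative lognormal measurement noise on the
#' fluorescence fields; the noiseless trajectory is kept as ground truth.
#'
#' @param layout a \linkS4class{GridLayout}.
#' @param sp a \linkS4class{SpatialParams}.
#' @param horizon,recordEvery simulation span and snapshot cadence, min.
#' @param cv measurement noise CV (0 returns the simulator output
#'   unchanged).
#' @param seed RNG seed.
#' @return A list with \code{observed} and \code{truth}
#'   \linkS4class{GridTrajectory} objects and the \code{seed}.
#' @export
generateGrid <- function(layout, sp, horizon = 1500, recordEvery = 50,
                         cv = 0.1, seed = 1) {
  truth <- simulateGrid(layout, sp, horizon = horizon,
                        recordEvery = recordEvery)
  observed <- truth
  if (cv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + cv^2))
    observed@states <- lapply(truth@states, function(st) {
      for (f in c("cfp", "yfp", "capacity")) {
        m <- slot(st, f)
        slot(st, f) <- m * matrix(exp(rnorm(length(m), 0, sdlog)),
                                  nrow(m), ncol(m))
      }
      st
    })
  }
  list(observed = observed, truth = truth, seed = seed)
}

#' Export a grid trajectory as long-format CSV
#'
#' @param traj a \linkS4class{GridTrajectory}.
#' @param file output path.
#' @return Invisibly, the path. Columns: time, row, col, channel, value.
#' @export
writeGridCSV <- function(traj, file) {
  rows <- lapply(seq_along(traj@times), function(k) {
    st <- traj@states[[k]]
    do.call(rbind, lapply(c(capacity = "capacity", CFP = "cfp", YFP = "yfp",
                            C6 = "c6", C12 = "c12"), function(f) {
      m <- slot(st, f)
      data.frame(time = st@time,
                 row = rep(seq_len(nrow(m)), ncol(m)),
                 col = rep(seq_len(ncol(m)), each = nrow(m)),
                 value = as.vector(m))
    }))
  })
  long <- do.call(rbind, rows)
  long$channel <- rep(rep(c("capacity", "CFP", "YFP", "C6", "C12"),
                          each = nrow(traj@states[[1]]@c6) *
                            ncol(traj@states[[1]]@c6)),
                      length(traj@times))
  long <- long[, c("time", "row", "col", "channel", "value")]
  write.csv(long, file, row.names = FALSE)
  invisible(file)
}
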