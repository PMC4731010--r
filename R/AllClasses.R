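#' @import methods
#' @importFrom stats dnorm lm coef optim runif rnorm sd quantile median setNames var cor
#' @importFrom utils read.csv write.csv head tail
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Equilibrium crosstalk parameters for one promoter/receiver context
#'
#' Holds all constants of the closed-form equilibrium transcription transfer
#' function for a promoter activated by HSL-bound LuxR/LasR dimers:
#' association constants of each receiver protein for each signal
#' (\code{KR6}, \code{KR12}, \code{KS6}, \code{KS12}, units 1/nM), effective
#' association constants of the activating regulator complexes for the
#' promoter (\code{KGR}, \code{KGS}, dimensionless -- they absorb the
#' receiver concentration scale), basal and maximal transcription rates
#' (\code{a0}, \code{a1R}, \code{a1S}, in relative promoter units, RPU),
#' the cooperativity exponent \code{n}, and the intracellular receiver
#' levels \code{r} (LuxR) and \code{s} (LasR) relative to constitutive
#' expression from the weak reference promoter pCat.
#'
#' Receiver-specific constants (\code{KR6}..\code{KS12}, \code{r}, \code{s})
#' are shared across promoters within one strain; promoter-specific fields
#' (\code{KGR}, \code{KGS}, \code{a0}, \code{a1R}, \code{a1S}) differ
#' between pLux, pLux76 and pLas81.
#'
#' @slot KR6,KR12,KS6,KS12 numeric(1), association constants, 1/nM.
#' @slot KGR,KGS numeric(1), promoter association constants, dimensionless.
#' @slot a0,a1R,a1S numeric(1), transcription rates, RPU.
#' @slot n numeric(1), cooperativity exponent (> 0).
#' @slot r,s numeric(1), receiver levels in pCat units (>= 0).
#' @export
setClass("CrosstalkParams",
  representation(
    KR6 = "numeric", KR12 = "numeric", KS6 = "numeric", KS12 = "numeric",
    KGR = "numeric", KGS = "numeric",
    a0 = "numeric", a1R = "numeric", a1S = "numeric",
    n = "numeric", r = "numeric", s = "numeric"
  )
)

setValidity("CrosstalkParams", function(object) {
  v <- c(KR6 = object@KR6, KR12 = object@KR12, KS6 = object@KS6,
         KS12 = object@KS12, KGR = object@KGR, KGS = object@KGS,
         a0 = object@a0, a1R = object@a1R, a1S = object@a1S,
         n = object@n, r = object@r, s = object@s)
  if (any(lengths(lapply(v, identity)) != 1) || any(!is.finite(v)))
    return("all parameters must be finite scalars")
  if (any(v[c("KR6", "KR12", "KS6", "KS12", "KGR", "KGS")] < 0))
    return("association constants must be >= 0")
  if (any(v[c("a0", "a1R", "a1S")] < 0))
    return("transcription rates must be >= 0")
  if (v["n"] <= 0) return("cooperativity n must be > 0")
  if (v["r"] < 0 || v["s"] < 0) return("receiver levels r, s must be >= 0")
  TRUE
})

#' Construct a CrosstalkParams object
#'
#' @param KR6,KR12,KS6,KS12 association constants of LuxR/LasR for
#'   3OC6HSL/3OC12HSL, 1/nM.
#' @param KGR,KGS promoter association constants of the LuxR-/LasR-based
#'   regulator complexes, dimensionless.
#' @param a0 basal transcription rate, RPU.
#' @param a1R,a1S maximal transcription rates when bound by the LuxR or LasR
#'   complex, RPU.
#' @param n cooperativity exponent.
#' @param r,s intracellular LuxR/LasR levels relative to pCat expression.
#' @return A \linkS4class{CrosstalkParams} object.
#' @examples
#' p <- crosstalkParams(KR6 = 0.0015, KR12 = 1.5e-5, KS6 = 2e-9, KS12 = 0.002,
#'                      KGR = 4, KGS = 0.1, a0 = 0.05, a1R = 12, a1S = 7.7)
#' simplifiedRate(p, C6 = 500, C12 = 0)
#' @export
crosstalkParams <- function(KR6 = 0, KR12 = 0, KS6 = 0, KS12 = 0,
                            KGR = 0, KGS = 0, a0 = 0, a1R = 0, a1S = 0,
                            n = 2, r = 1, s = 1) {
  new("CrosstalkParams", KR6 = KR6, KR12 = KR12, KS6 = KS6, KS12 = KS12,
      KGR = KGR, KGS = KGS, a0 = a0, a1R = a1R, a1S = a1S, n = n, r = r, s = s)
}

setMethod("show", "CrosstalkParams", function(object) {
  cat("CrosstalkParams\n")
  cat(sprintf("  LuxR:  KR6 = %.3g  KR12 = %.3g 1/nM   level r = %.3g\n",
              object@KR6, object@KR12, object@r))
  cat(sprintf("  LasR:  KS6 = %.3g  KS12 = %.3g 1/nM   level s = %.3g\n",
              object@KS6, object@KS12, object@s))
  cat(sprintf("  promoter: KGR = %.3g  KGS = %.3g   n = %.3g\n",
              object@KGR, object@KGS, object@n))
  cat(sprintf("  rates (RPU): a0 = %.3g  a1R = %.3g  a1S = %.3g\n",
              object@a0, object@a1R, object@a1S))
})

#' Full mass-action model specification
#'
#' Kinetic closure of the equilibrium crosstalk model: a common forward
#' binding rate \code{kf} (reverse rates derived as kf/K, since only ratios
#' are identifiable at equilibrium), growth dilution \code{gamma} acting on
#' every species, zero-order production of free promoter and of the receiver
#' proteins, and a receiver concentration scale \code{receiverScale} (nM per
#' pCat unit) that maps the dimensionless promoter constants of
#' \linkS4class{CrosstalkParams} onto bimolecular association constants.
#'
#' @slot params a \linkS4class{CrosstalkParams} (its \code{n} must be 2:
#'   cooperativity arises mechanically from regulator dimerization).
#' @slot gamma growth-dilution rate, 1/min.
#' @slot kf common forward binding rate, 1/(nM min).
#' @slot geneProduction zero-order production rate of free promoter, nM/min.
#' @slot receiverProductionR,receiverProductionS zero-order LuxR/LasR
#'   production rates, nM/min.
#' @slot receiverScale nM of receiver protein per pCat unit.
#' @slot dimerScale dimensionless fraction setting how weak dimerization is
#'   relative to promoter binding (the product is pinned to the observable
#'   KGR/KGS); small values keep monomer sequestration into dimers
#'   negligible, as the closed-form model assumes.
#' @export
setClass("FullModelSpec",
  representation(
    params = "CrosstalkParams",
    gamma = "numeric", kf = "numeric",
    geneProduction = "numeric",
    receiverProductionR = "numeric", receiverProductionS = "numeric",
    receiverScale = "numeric", dimerScale = "numeric"
  )
)

setValidity("FullModelSpec", function(object) {
  if (object@gamma <= 0) return("gamma must be > 0")
  if (object@kf <= 0) return("kf must be > 0")
  if (object@geneProduction <= 0) return("geneProduction must be > 0")
  if (object@receiverScale <= 0) return("receiverScale must be > 0")
  if (object@dimerScale <= 0 || object@dimerScale > 1)
    return("dimerScale must be in (0, 1]")
  if (object@receiverProductionR < 0 || object@receiverProductionS < 0)
    return("receiver production rates must be >= 0")
  if (abs(object@params@n - 2) > 1e-12)
    return("the full mass-action model dimerizes regulators, so params@n must equal 2")
  TRUE
})

#' Construct a FullModelSpec
#'
#' Receiver production rates default to \code{gamma * level * receiverScale}
#' so that, at steady state, total receiver protein equals its pCat-relative
#' level times the concentration scale.
#'
#' @param params a \linkS4class{CrosstalkParams} with \code{n = 2}.
#' @param gamma growth-dilution rate, 1/min.
#' @param kf common forward binding rate, 1/(nM min). The default makes
#'   binding equilibrate much faster than dilution.
#' @param geneProduction zero-order promoter production, nM/min.
#' @param receiverScale receiver protein concentration per pCat unit, nM.
#' @param receiverProductionR,receiverProductionS optional overrides of the
#'   zero-order receiver production rates, nM/min.
#' @param dimerScale fraction of receiver protein dimerized at full
#'   occupancy; keep small so the dimer pool does not deplete monomers.
#' @return A \linkS4class{FullModelSpec}.
#' @export
fullModelSpec <- function(params, gamma = 1e-4, kf = 10,
                          geneProduction = NULL, receiverScale = 10,
                          receiverProductionR = NULL,
                          receiverProductionS = NULL, dimerScale = 1e-3) {
  if (is.null(geneProduction)) geneProduction <- gamma * 0.01
  if (is.null(receiverProductionR))
    receiverProductionR <- gamma * params@r * receiverScale
  if (is.null(receiverProductionS))
    receiverProductionS <- gamma * params@s * receiverScale
  new("FullModelSpec", params = params, gamma = gamma, kf = kf,
      geneProduction = geneProduction,
      receiverProductionR = receiverProductionR,
      receiverProductionS = receiverProductionS,
      receiverScale = receiverScale, dimerScale = dimerScale)
}

setMethod("show", "FullModelSpec", function(object) {
  cat("FullModelSpec\n")
  cat(sprintf("  gamma = %.3g 1/min, kf = %.3g 1/(nM min), receiverScale = %.3g nM\n",
              object@gamma, object@kf, object@receiverScale))
  cat(sprintf("  productions (nM/min): promoter %.3g, LuxR %.3g, LasR %.3g\n",
              object@geneProduction, object@receiverProductionR,
              object@receiverProductionS))
  show(object@params)
})

#' Empirical Hill transfer function
#'
#' Saturating dose response \code{basal + (vmax - basal) C^h / (ec50^h + C^h)}
#' used for the optimized receiver's pLas81 channel in spatial contexts.
#'
#' @slot basal,vmax RPU; \code{vmax >= basal >= 0}.
#' @slot ec50 half-maximal concentration, nM.
#' @slot hill Hill exponent (> 0).
#' @export
setClass("HillTransfer",
  representation(basal = "numeric", vmax = "numeric",
                 ec50 = "numeric", hill = "numeric"))

setValidity("HillTransfer", function(object) {
  if (object@basal < 0) return("basal must be >= 0")
  if (object@vmax < object@basal) return("vmax must be >= basal")
  if (object@ec50 <= 0) return("ec50 must be > 0")
  if (object@hill <= 0) return("hill must be > 0")
  TRUE
})

#' @param basal,vmax basal and saturating response, RPU.
#' @param ec50 half-maximal concentration, nM.
#' @param hill Hill exponent.
#' @return A \linkS4class{HillTransfer}.
#' @rdname HillTransfer-class
#' @export
hillTransfer <- function(basal, vmax, ec50, hill) {
  new("HillTransfer", basal = basal, vmax = vmax, ec50 = ec50, hill = hill)
}

setMethod("show", "HillTransfer", function(object) {
  cat(sprintf("HillTransfer: basal %.3g, vmax %.3g RPU, ec50 %.3g nM, hill %.3g\n",
              object@basal, object@vmax, object@ec50, object@hill))
})

#' Arabinose-to-receiver-level transfer curve
#'
#' Saturating relationship between arabinose concentration (mM) and the
#' pCat-relative expression level of an inducibly expressed receiver
#' protein.
#'
#' @slot basalLevel,vmaxLevel receiver levels in pCat units at zero and
#'   saturating arabinose.
#' @slot ec50Ara half-maximal arabinose concentration, mM.
#' @slot hillAra Hill exponent.
#' @export
setClass("AraTransfer",
  representation(basalLevel = "numeric", vmaxLevel = "numeric",
                 ec50Ara = "numeric", hillAra = "numeric"))

setValidity("AraTransfer", function(object) {
  if (object@basalLevel < 0 || object@vmaxLevel < 0)
    return("levels must be >= 0")
  if (object@ec50Ara <= 0) return("ec50Ara must be > 0")
  if (object@hillAra <= 0) return("hillAra must be > 0")
  TRUE
})

#' @param basalLevel,vmaxLevel receiver levels (pCat units) at 0 / saturating
#'   arabinose.
#' @param ec50Ara half-maximal arabinose, mM.
#' @param hillAra Hill exponent.
#' @return An \linkS4class{AraTransfer}.
#' @rdname AraTransfer-class
#' @export
araTransfer <- function(basalLevel, vmaxLevel, ec50Ara, hillAra = 1.5) {
  new("AraTransfer", basalLevel = basalLevel, vmaxLevel = vmaxLevel,
      ec50Ara = ec50Ara, hillAra = hillAra)
}

setMethod("show", "AraTransfer", function(object) {
  cat(sprintf("AraTransfer: level %.3g -> %.3g pCat units, ec50 %.3g mM, hill %.3g\n",
              object@basalLevel, object@vmaxLevel, object@ec50Ara,
              object@hillAra))
})

#' Evaluate an arabinose-to-level transfer curve
#' @param at an \linkS4class{AraTransfer}.
#' @param ara arabinose concentration(s), mM.
#' @return Receiver level(s) in pCat units.
#' @export
araLevel <- function(at, ara) {
  stopifnot(all(ara >= 0))
  u <- ara^at@hillAra
  at@basalLevel + (at@vmaxLevel - at@basalLevel) * u / (at@ec50Ara^at@hillAra + u)
}

#' Gompertz growth model for a population's gene-expression capacity
#'
#' Capacity follows \code{Kcap * exp(-exp(-kg (t - tI)))}: sigmoidal growth
#' with carrying capacity \code{Kcap}, rate \code{kg} (1/min) and inflection
#' time \code{tI} (min). The value at \code{t = tI} is \code{Kcap / e}.
#'
#' @slot Kcap carrying capacity (> 0), gene-expression capacity units.
#' @slot kg growth rate (> 0), 1/min.
#' @slot tI inflection time, min.
#' @export
setClass("GompertzGrowth",
  representation(Kcap = "numeric", kg = "numeric", tI = "numeric"))

setValidity("GompertzGrowth", function(object) {
  if (object@Kcap <= 0) return("Kcap must be > 0")
  if (object@kg <= 0) return("kg must be > 0")
  TRUE
})

#' @param Kcap carrying capacity.
#' @param kg growth rate, 1/min.
#' @param tI inflection time, min.
#' @return A \linkS4class{GompertzGrowth}.
#' @rdname GompertzGrowth-class
#' @export
gompertzGrowth <- function(Kcap = 1, kg = 0.01, tI = 400) {
  new("GompertzGrowth", Kcap = Kcap, kg = kg, tI = tI)
}

setMethod("show", "GompertzGrowth", function(object) {
  cat(sprintf("GompertzGrowth: Kcap %.3g, kg %.3g 1/min, tI %.3g min (t0 fraction %.3g)\n",
              object@Kcap, object@kg, object@tI,
              exp(-exp(object@kg * object@tI))))
})

#' Two-channel receiver device
#'
#' A double reporter expressing eCFP under the LuxR-specific promoter pLux76
#' and eYFP under the LasR-specific promoter pLas81, with both receiver
#' proteins expressed at levels (r, s). The two promoter contexts must share
#' all receiver-specific constants.
#'
#' @slot cfpParams \linkS4class{CrosstalkParams} for the pLux76/eCFP channel.
#' @slot yfpParams \linkS4class{CrosstalkParams} for the pLas81/eYFP channel.
#' @export
setClass("TwoChannelDevice",
  representation(cfpParams = "CrosstalkParams", yfpParams = "CrosstalkParams"))

setValidity("TwoChannelDevice", function(object) {
  shared <- c("KR6", "KR12", "KS6", "KS12", "n", "r", "s")
  for (f in shared) {
    if (!isTRUE(all.equal(slot(object@cfpParams, f), slot(object@yfpParams, f))))
      return(sprintf("receiver-specific field '%s' must be shared across channels", f))
  }
  TRUE
})

#' @param cfpParams,yfpParams per-channel \linkS4class{CrosstalkParams};
#'   receiver-specific fields must agree.
#' @return A \linkS4class{TwoChannelDevice}.
#' @rdname TwoChannelDevice-class
#' @export
twoChannelDevice <- function(cfpParams, yfpParams) {
  new("TwoChannelDevice", cfpParams = cfpParams, yfpParams = yfpParams)
}

#' Set the receiver levels of a two-channel device
#' @param device a \linkS4class{TwoChannelDevice}.
#' @param r,s LuxR/LasR levels in pCat units.
#' @return The device with both channels' levels replaced.
#' @export
setDeviceLevels <- function(device, r, s) {
  for (ch in c("cfpParams", "yfpParams")) {
    p <- slot(device, ch)
    p@r <- r
    p@s <- s
    slot(device, ch) <- p
  }
  validObject(device)
  device
}

setMethod("show", "TwoChannelDevice", function(object) {
  cat(sprintf("TwoChannelDevice (r = %.3g, s = %.3g pCat units)\n",
              object@cfpParams@r, object@cfpParams@s))
  cat("-- CFP channel (pLux76):\n"); show(object@cfpParams)
  cat("-- YFP channel (pLas81):\n"); show(object@yfpParams)
})

#' Dose-response dataset
#'
#' Replicate-summarized relative promoter activity versus HSL dose for one
#' device/promoter context: a data frame with columns \code{C6}, \code{C12}
#' (nM), \code{arabinose} (mM), \code{rho} (mean activity, RPU), \code{sd}
#' (across replicates; NA when n = 1) and \code{n} (replicates).
#'
#' @slot device,promoter character(1) identifiers.
#' @slot data the per-dose data frame.
#' @export
setClass("DoseResponse",
  representation(device = "character", promoter = "character",
                 data = "data.frame"))

setValidity("DoseResponse", function(object) {
  need <- c("C6", "C12", "arabinose", "rho", "sd", "n")
  if (!all(need %in% names(object@data)))
    return(paste("data must have columns", paste(need, collapse = ", ")))
  d <- object@data
  if (any(d$C6 < 0 | d$C12 < 0 | d$arabinose < 0)) return("doses must be >= 0")
  if (any(d$n > 1 & (is.na(d$sd) | d$sd < 0)))
    return("sd must be a non-negative number wherever n > 1")
  TRUE
})

#' @param device,promoter identifiers.
#' @param data per-dose data frame (C6, C12, arabinose, rho, sd, n).
#' @return A \linkS4class{DoseResponse}.
#' @rdname DoseResponse-class
#' @export
doseResponse <- function(device, promoter, data) {
  new("DoseResponse", device = device, promoter = promoter,
      data = as.data.frame(data))
}

setMethod("show", "DoseResponse", function(object) {
  cat(sprintf("DoseResponse: device %s, promoter %s, %d dose points\n",
              object@device, object@promoter, nrow(object@data)))
  print(head(object@data, 4))
  if (nrow(object@data) > 4) cat("  ...\n")
})

#' MCMC posterior sample
#'
#' Draws over log10-parameters from the affine-invariant ensemble sampler,
#' with the per-draw log-posterior, chain diagnostics (mean acceptance rate,
#' split-Rhat and a crude effective sample size per parameter) and the seed
#' used.
#'
#' @slot draws numeric matrix, draw x parameter, log10 scale.
#' @slot paramNames character, column names of \code{draws}.
#' @slot logPost numeric, log-posterior per retained draw.
#' @slot diagnostics list with elements \code{acceptance}, \code{rhat},
#'   \code{ess}, \code{nWalkers}, \code{nSteps}.
#' @slot seed integer seed.
#' @export
setClass("PosteriorSample",
  representation(draws = "matrix", paramNames = "character",
                 logPost = "numeric", diagnostics = "list", seed = "numeric"))

setValidity("PosteriorSample", function(object) {
  if (ncol(object@draws) != length(object@paramNames))
    return("paramNames length must match draw columns")
  if (nrow(object@draws) != length(object@logPost))
    return("one log-posterior value per draw required")
  if (any(!is.finite(object@logPost)))
    return("log-posterior values must be finite")
  TRUE
})

setMethod("show", "PosteriorSample", function(object) {
  cat(sprintf("PosteriorSample: %d draws x %d parameters (seed %s)\n",
              nrow(object@draws), ncol(object@draws),
              format(object@seed)))
  s <- posteriorSummary(object)
  print(s, digits = 3)
  cat(sprintf("  mean acceptance %.2f; max split-Rhat %.3f\n",
              object@diagnostics$acceptance, max(object@diagnostics$rhat)))
})

#' Summarize a posterior sample
#' @param ps a \linkS4class{PosteriorSample}.
#' @param probs quantiles to report.
#' @return data frame with median and credible-interval bounds per parameter
#'   (log10 scale).
#' @export
posteriorSummary <- function(ps, probs = c(0.025, 0.5, 0.975)) {
  q <- t(apply(ps@draws, 2, quantile, probs = probs))
  colnames(q) <- paste0("q", probs * 100)
  data.frame(parameter = ps@paramNames, q, row.names = NULL,
             check.names = FALSE)
}

#' Grid-membrane layout
#'
#' Device assignment per lattice square of a hydrophobic-grid membrane, plus
#' the square pitch and any exogenous HSL fields present at t = 0. Device
#' identifiers come from the registry in \code{\link{gridDeviceRegistry}}.
#'
#' @slot devices character matrix of device ids (n_rows x n_cols).
#' @slot pitch square pitch, mm.
#' @slot initC6,initC12 initial HSL fields, nM per square.
#' @export
setClass("GridLayout",
  representation(devices = "matrix", pitch = "numeric",
                 initC6 = "matrix", initC12 = "matrix"))

setValidity("GridLayout", function(object) {
  if (!is.character(object@devices)) return("devices must be a character matrix")
  bad <- setdiff(unique(c(object@devices)), gridDeviceRegistry())
  if (length(bad))
    return(paste("unknown device id(s):", paste(bad, collapse = ", ")))
  if (object@pitch <= 0) return("pitch must be > 0")
  if (!identical(dim(object@devices), dim(object@initC6)) ||
      !identical(dim(object@devices), dim(object@initC12)))
    return("initC6/initC12 must match the device grid dimensions")
  if (any(object@initC6 < 0) || any(object@initC12 < 0))
    return("initial HSL fields must be >= 0")
  TRUE
})

#' @param devices character matrix of device ids.
#' @param pitch square pitch, mm.
#' @param initC6,initC12 optional initial HSL matrices, nM (default 0).
#' @return A \linkS4class{GridLayout}.
#' @rdname GridLayout-class
#' @export
gridLayout <- function(devices, pitch = 3, initC6 = NULL, initC12 = NULL) {
  z <- matrix(0, nrow(devices), ncol(devices))
  if (is.null(initC6)) initC6 <- z
  if (is.null(initC12)) initC12 <- z
  new("GridLayout", devices = devices, pitch = pitch,
      initC6 = initC6, initC12 = initC12)
}

setMethod("show", "GridLayout", function(object) {
  cat(sprintf("GridLayout: %d x %d squares, pitch %.3g mm\n",
              nrow(object@devices), ncol(object@devices), object@pitch))
  tab <- table(object@devices)
  cat("  devices:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
})

#' Spatial model parameters
#'
#' Effective parameters of the compartment reaction-diffusion model: HSL
#' exchange between adjacent squares (diffusivities \code{D6}, \code{D12},
#' mm^2/min), synthesis rates per unit synthase activity and population
#' capacity (\code{kSyn6}, \code{kSyn12}, nM/(RPU min) at full capacity),
#' first-order decay (\code{kDeg6}, \code{kDeg12}, 1/min), the per-square
#' Gompertz growth model, the double-receiver transfer functions (pLux76 via
#' the equilibrium model; pLas81 via its Hill refit), constitutive sender
#' activities and the global synthase production scale used in bifurcation
#' scans.
#'
#' @slot D6,D12 effective diffusivities, mm^2/min.
#' @slot kSyn6,kSyn12 synthesis rates, nM/(RPU min) at capacity 1.
#' @slot kDeg6,kDeg12 decay rates, 1/min.
#' @slot growth a \linkS4class{GompertzGrowth} (capacity normalized to 1).
#' @slot receiver a \linkS4class{TwoChannelDevice} (pLux76 CFP channel).
#' @slot pLas81Hill a \linkS4class{HillTransfer} (YFP channel and
#'   pLas81-driven synthase expression).
#' @slot senderAct6,senderAct12 constitutive synthase activities of the
#'   sender devices, RPU.
#' @slot synthaseDilution first-order dilution of synthase activity, 1/min.
#' @slot productionScale global multiplier on synthase production.
#' @export
setClass("SpatialParams",
  representation(D6 = "numeric", D12 = "numeric",
                 kSyn6 = "numeric", kSyn12 = "numeric",
                 kDeg6 = "numeric", kDeg12 = "numeric",
                 growth = "GompertzGrowth",
                 receiver = "TwoChannelDevice",
                 pLas81Hill = "HillTransfer",
                 senderAct6 = "numeric", senderAct12 = "numeric",
                 synthaseDilution = "numeric",
                 productionScale = "numeric"))

setValidity("SpatialParams", function(object) {
  v <- c(object@D6, object@D12, object@kSyn6, object@kSyn12,
         object@kDeg6, object@kDeg12, object@senderAct6, object@senderAct12,
         object@synthaseDilution, object@productionScale)
  if (any(v < 0)) return("all spatial parameters must be >= 0")
  TRUE
})

setMethod("show", "SpatialParams", function(object) {
  cat("SpatialParams\n")
  cat(sprintf("  D6 = %.3g, D12 = %.3g mm^2/min; decay %.3g / %.3g 1/min\n",
              object@D6, object@D12, object@kDeg6, object@kDeg12))
  cat(sprintf("  synthesis %.3g / %.3g nM/(RPU min); production scale %.3g\n",
              object@kSyn6, object@kSyn12, object@productionScale))
})

#' Per-square lattice state
#'
#' Time-evolving state of a grid simulation: normalized capacity (0..1 of
#' carrying capacity), accumulated CFP/YFP reporter signal, synthase
#' activities (LuxI makes 3OC6HSL, LasI makes 3OC12HSL) and local HSL
#' concentrations. The RFP channel equals capacity by construction (the
#' chromosomal mRFP1 proxy).
#'
#' @slot time minutes since plating.
#' @slot capacity,cfp,yfp,synLuxI,synLasI,c6,c12 numeric matrices.
#' @export
setClass("GridState",
  representation(time = "numeric", capacity = "matrix", cfp = "matrix",
                 yfp = "matrix", synLuxI = "matrix", synLasI = "matrix",
                 c6 = "matrix", c12 = "matrix"))

setValidity("GridState", function(object) {
  mats <- list(object@capacity, object@cfp, object@yfp,
               object@synLuxI, object@synLasI, object@c6, object@c12)
  if (any(vapply(mats, function(m) any(m < -1e-12), logical(1))))
    return("state fields must be non-negative")
  TRUE
})

setMethod("show", "GridState", function(object) {
  cat(sprintf("GridState at t = %.1f min (%d x %d)\n", object@time,
              nrow(object@c6), ncol(object@c6)))
  cat(sprintf("  total C6 %.4g nM, total C12 %.4g nM, mean capacity %.3g\n",
              sum(object@c6), sum(object@c12), mean(object@capacity)))
})

#' Grid simulation trajectory
#'
#' Time-indexed snapshots of a lattice simulation together with the layout
#' and parameters that produced it.
#'
#' @slot times recorded times, min.
#' @slot states list of \linkS4class{GridState} snapshots.
#' @slot layout the \linkS4class{GridLayout} simulated.
#' @slot dt the time step used, min.
#' @export
setClass("GridTrajectory",
  representation(times = "numeric", states = "list", layout = "GridLayout",
                 dt = "numeric"))

setMethod("show", "GridTrajectory", function(object) {
  cat(sprintf("GridTrajectory: %d snapshots over %.0f min (dt = %.3g min)\n",
              length(object@times), max(object@times), object@dt))
  show(object@layout)
})
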