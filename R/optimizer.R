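# Signal-to-crosstalk optimization of the two-channel receiver over
# receiver-expression space.

#' Response of one channel of a two-channel device
#'
#' Equilibrium transcription rate of the chosen channel's promoter at the
#' given doses, delegating to \code{\link{simplifiedRate}} under that
#' channel's constants.
#'
#' @param device a \linkS4class{TwoChannelDevice}.
#' @param channel "CFP" (pLux76) or "YFP" (pLas81).
#' @param C6,C12 doses, nM.
#' @return RPU.
#' @export
channelResponse <- function(device, channel = c("CFP", "YFP"), C6, C12) {
  channel <- match.arg(channel)
  p <- if (channel == "CFP") device@cfpParams else device@yfpParams
  simplifiedRate(p, C6, C12)
}

#' Signal-to-crosstalk ratio of a two-channel device
#'
#' The design objective for the double receiver:
#' \deqn{\frac{CFP_{C6} \times YFP_{C12}}{CFP_{C12} \times YFP_{C6}}}
#' where each term is the channel's response to a single signal at
#' \code{dose} nM with the other signal absent. A symmetric device (both
#' channels identical) scores exactly 1, and swapping the two promoter
#' blocks inverts the ratio.
#'
#' @param device a \linkS4class{TwoChannelDevice}.
#' @param dose evaluation dose, nM (default 100 nM).
#' @return A list with \code{ratio} and \code{degenerate} (TRUE with
#'   \code{ratio = Inf} when a crosstalk term is exactly zero, i.e. below
#'   basal resolution).
#' @export
signalToCrosstalk <- function(device, dose = 100) {
  cfp6 <- channelResponse(device, "CFP", dose, 0)
  cfp12 <- channelResponse(device, "CFP", 0, dose)
  yfp6 <- channelResponse(device, "YFP", dose, 0)
  yfp12 <- channelResponse(device, "YFP", 0, dose)
  if (any(!is.finite(c(cfp6, cfp12, yfp6, yfp12))))
    stop("non-finite channel response")
  num <- cfp6 * yfp12
  den <- cfp12 * yfp6
  if (den == 0) return(list(ratio = Inf, degenerate = TRUE))
  list(ratio = num / den, degenerate = FALSE)
}

#' Optimize receiver expression levels for signal over crosstalk
#'
#' Evaluates the signal-to-crosstalk ratio over a log-spaced (r, s) grid
#' (receiver levels span orders of magnitude) and refines the best grid
#' point by bounded local search. When the objective is flat along one
#' axis (e.g. no LasR interaction anywhere), that level is reported as
#' unidentifiable (NA) and the other is optimized on its marginal.
#'
#' @param device a \linkS4class{TwoChannelDevice} template (its levels are
#'   overwritten).
#' @param rRange,sRange level ranges, pCat units (positive).
#' @param nGrid grid density per axis (>= 25).
#' @param dose evaluation dose, nM.
#' @return A list with \code{rStar}, \code{sStar}, \code{ratioStar},
#'   \code{landscape} (data frame r, s, ratio for isoline plotting) and
#'   \code{sIdentifiable}/\code{rIdentifiable} flags.
#' @examples
#' dev <- presetDevice()
#' opt <- optimizeLevels(dev, c(0.5, 50), c(0.5, 50), nGrid = 25)
#' c(opt$rStar, opt$sStar, opt$ratioStar)
#' @export
optimizeLevels <- function(device, rRange = c(0.1, 100),
                           sRange = c(0.1, 100), nGrid = 50, dose = 100) {
  stopifnot(all(rRange > 0), all(sRange > 0), nGrid >= 25)
  rGrid <- 10^seq(log10(rRange[1]), log10(rRange[2]), length.out = nGrid)
  sGrid <- 10^seq(log10(sRange[1]), log10(sRange[2]), length.out = nGrid)
  obj <- function(r, s) {
    signalToCrosstalk(setDeviceLevels(device, r, s), dose)$ratio
  }
  landscape <- expand.grid(r = rGrid, s = sGrid)
  landscape$ratio <- mapply(obj, landscape$r, landscape$s)

  bestIdx <- which.max(landscape$ratio)
  # identifiability along each axis: does the objective vary at all?
  varies <- function(margin) {
    agg <- tapply(landscape$ratio, landscape[[margin]], mean)
    diff(range(agg)) > 1e-9 * max(abs(agg), 1e-300)
  }
  rIdent <- varies("r")
  sIdent <- varies("s")

  rStar <- landscape$r[bestIdx]
  sStar <- landscape$s[bestIdx]
  ratioStar <- landscape$ratio[bestIdx]
  if (is.finite(ratioStar)) {
    # local refinement in log10 space, never worse than the grid optimum
    fn <- function(q) {
      r <- min(max(10^q[1], rRange[1]), rRange[2])
      s <- min(max(10^q[2], sRange[1]), sRange[2])
      -obj(r, s)
    }
    opt <- optim(log10(c(rStar, sStar)), fn, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-12))
    if (-opt$value >= ratioStar) {
      rStar <- min(max(10^opt$par[1], rRange[1]), rRange[2])
      sStar <- min(max(10^opt$par[2], sRange[1]), sRange[2])
      ratioStar <- -opt$value
    }
  }
  list(rStar = if (rIdent) rStar else NA_real_,
       sStar = if (sIdent) sStar else NA_real_,
       ratioStar = ratioStar, landscape = landscape,
       rIdentifiable = rIdent, sIdentifiable = sIdent)
}
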