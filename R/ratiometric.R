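# Ratiometric promoter-activity extraction from multi-channel
# plate-fluorometer time series.

#' Build a PlateExperiment from channel matrices
#'
#' A PlateExperiment is a \link[SummarizedExperiment]{SummarizedExperiment}
#' with one assay per channel (matrices time x well), \code{rowData} holding
#' the time grid (minutes) and \code{colData} the per-well conditions
#' (device, HSL species and dose in nM, arabinose in mM, replicate index,
#' blank flag).
#'
#' @param time numeric vector of measurement times, minutes, strictly
#'   increasing.
#' @param assays named list of channel matrices (rows = time points,
#'   columns = wells), e.g. YFP, CFP, RFP, OD.
#' @param conditions data frame with one row per well; must contain a
#'   \code{well} column. Missing standard columns (\code{device},
#'   \code{hsl_species}, \code{hsl_nM}, \code{arabinose_mM},
#'   \code{replicate}, \code{is_blank}) are filled with defaults.
#' @return A \code{SummarizedExperiment} ("plate experiment").
#' @export
plateExperiment <- function(time, assays, conditions) {
  stopifnot(length(assays) >= 1, !is.null(names(assays)))
  if (is.unsorted(time, strictly = TRUE))
    stop("time must be strictly increasing")
  nT <- length(time)
  nW <- ncol(assays[[1]])
  for (a in assays) {
    if (!all(dim(a) == c(nT, nW)))
      stop("all channel matrices must be time x well with equal dimensions")
    if (any(!is.finite(a))) stop("channel values must be finite")
  }
  if (!"well" %in% names(conditions)) stop("conditions must have a 'well' column")
  if (nrow(conditions) != nW) stop("one condition row per well required")
  defaults <- list(device = "unknown", hsl_species = "none", hsl_nM = 0,
                   arabinose_mM = 0, replicate = 1L, is_blank = FALSE)
  for (nm in names(defaults))
    if (!nm %in% names(conditions)) conditions[[nm]] <- defaults[[nm]]
  assays <- lapply(assays, function(a) {
    colnames(a) <- conditions$well
    a
  })
  SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(time_min = time),
    colData = S4Vectors::DataFrame(conditions, row.names = conditions$well))
}

#' Times of a plate experiment
#' @param pe a plate experiment.
#' @return Numeric vector of times, minutes.
#' @export
plateTimes <- function(pe) SummarizedExperiment::rowData(pe)$time_min

#' Read a plate experiment from long-format CSV
#'
#' @param valuesFile CSV with columns \code{well,time_min,channel,value}
#'   (comma-separated, header required, UTF-8).
#' @param conditionsFile CSV keyed by \code{well} with the condition
#'   metadata columns.
#' @return A plate experiment (see \code{\link{plateExperiment}}).
#' @export
readPlateCSV <- function(valuesFile, conditionsFile) {
  v <- read.csv(valuesFile)
  need <- c("well", "time_min", "channel", "value")
  if (!all(need %in% names(v)))
    stop("values file must have columns ", paste(need, collapse = ", "))
  cond <- read.csv(conditionsFile)
  time <- sort(unique(v$time_min))
  wells <- cond$well
  assays <- lapply(split(v, v$channel), function(d) {
    m <- matrix(NA_real_, length(time), length(wells),
                dimnames = list(NULL, wells))
    m[cbind(match(d$time_min, time), match(d$well, wells))] <- d$value
    if (any(is.na(m))) stop("missing (well, time) combinations for a channel")
    m
  })
  plateExperiment(time, assays, cond)
}

#' Write a plate experiment to long-format CSV
#'
#' @param pe a plate experiment.
#' @param valuesFile,conditionsFile output paths.
#' @return Invisibly, the two paths.
#' @export
writePlateCSV <- function(pe, valuesFile, conditionsFile) {
  time <- plateTimes(pe)
  wells <- colnames(pe)
  long <- do.call(rbind, lapply(SummarizedExperiment::assayNames(pe), function(ch) {
    m <- SummarizedExperiment::assay(pe, ch)
    data.frame(well = rep(wells, each = length(time)),
               time_min = rep(time, length(wells)),
               channel = ch, value = as.vector(m))
  }))
  write.csv(long, valuesFile, row.names = FALSE)
  write.csv(as.data.frame(SummarizedExperiment::colData(pe)), conditionsFile,
            row.names = FALSE)
  invisible(c(valuesFile, conditionsFile))
}

#' Subtract blank-well background from a plate experiment
#'
#' Per channel and time point, the mean over blank wells (either those
#' flagged \code{is_blank} in the experiment's \code{colData}, or all wells
#' of a separately supplied blank experiment) is subtracted from every well.
#' Negative corrected values are clipped to zero and the clip count is
#' reported in a message.
#'
#' @param pe a plate experiment.
#' @param blanks optional plate experiment holding only blank wells; by
#'   default the blanks are taken from \code{pe} itself.
#' @return The background-corrected plate experiment (blank wells retained,
#'   corrected like the rest).
#' @export
subtractBackground <- function(pe, blanks = NULL) {
  if (is.null(blanks)) {
    keep <- SummarizedExperiment::colData(pe)$is_blank
    if (!any(keep)) stop("no blank wells flagged and no blanks supplied")
    blanks <- pe[, keep]
  }
  if (!isTRUE(all.equal(plateTimes(pe), plateTimes(blanks))))
    stop("blank wells must share the plate's time grid")
  clipped <- 0L
  for (ch in SummarizedExperiment::assayNames(pe)) {
    if (!ch %in% SummarizedExperiment::assayNames(blanks))
      stop("blank experiment lacks channel ", ch)
    bg <- rowMeans(SummarizedExperiment::assay(blanks, ch))
    m <- SummarizedExperiment::assay(pe, ch) - bg
    clipped <- clipped + sum(m < 0)
    SummarizedExperiment::assay(pe, ch) <- pmax(m, 0)
  }
  if (clipped > 0)
    message(sprintf("subtractBackground: clipped %d negative values to 0", clipped))
  pe
}

# Deterministic activity window: the sliding window (length ~ 1/3 of the
# series) over which the reference channel is best described as linearly
# accumulating (max R^2 of reference ~ time); ties break to the earliest
# window. Returns the index range.
selectActivityWindow <- function(time, reference, windowFraction = 1/3) {
  L <- length(time)
  w <- max(4L, ceiling(L * windowFraction))
  if (w > L) stop("series too short for window selection")
  # rolling first/second moments via cumulative sums
  roll <- function(x) {
    cs <- c(0, cumsum(x))
    cs[(w + 1):(L + 1)] - cs[1:(L - w + 1)]
  }
  St <- roll(time); Sy <- roll(reference)
  Stt <- roll(time^2); Syy <- roll(reference^2)
  Sty <- roll(time * reference)
  ctt <- Stt - St^2 / w
  cyy <- Syy - Sy^2 / w
  cty <- Sty - St * Sy / w
  r2 <- ifelse(cyy > 0, cty^2 / (ctt * cyy), -Inf)
  # prefer windows where the reference is actually accumulating
  score <- r2 * sign(cty)
  i <- which.max(score)
  c(i, i + w - 1L)
}

# Activity estimate from bare vectors (fast path shared by the plate
# accessors).
activityFromSeries <- function(time, target, reference, window = NULL) {
  if (is.null(window)) window <- selectActivityWindow(time, reference)
  idx <- window[1]:window[2]
  if (length(idx) < 4) stop("activity window shorter than 4 points")
  bT <- olsSlope(time[idx], target[idx])
  bR <- olsSlope(time[idx], reference[idx])
  if (bR["slope"] <= 0)
    stop("degenerate reference: no positive accumulation over the window")
  rho <- unname(bT["slope"] / bR["slope"])
  stderr <- abs(rho) * sqrt((bT["se"] / max(abs(bT["slope"]), 1e-300))^2 +
                              (bR["se"] / bR["slope"])^2)
  if (bT["slope"] == 0) stderr <- unname(bT["se"] / bR["slope"])
  list(rho = rho, stderr = unname(stderr),
       window = c(time[window[1]], time[window[2]]))
}

# OLS slope of y on x with a heteroscedasticity-robust (HC3) standard
# error: fluorescence noise is multiplicative, so residual variance grows
# along the window and the homoscedastic formula is anti-conservative.
olsSlope <- function(x, y) {
  xb <- x - mean(x)
  sxx <- sum(xb^2)
  b <- sum(xb * y) / sxx
  res <- y - mean(y) - b * xb
  h <- 1 / length(x) + xb^2 / sxx
  se <- sqrt(sum(xb^2 * (res / (1 - h))^2)) / sxx
  c(slope = b, se = se)
}

#' Estimate relative promoter activity from a well's time series
#'
#' Extracts the ratiometric promoter activity rho = d(target)/d(reference)
#' -- the activity of the target promoter in units of the reference
#' promoter's activity (RPU) -- over a deterministically selected
#' mid-exponential window (the sliding window in which the reference
#' channel accumulates most linearly). Both channels are regressed on time
#' within the window and rho is the ratio of the slopes, with a
#' delta-method standard error; when both channels are locally linear this
#' equals the slope of target against reference.
#'
#' @param pe a plate experiment.
#' @param well well identifier (column name) or index.
#' @param targetChannel,referenceChannel assay names, e.g. "YFP" and "CFP".
#' @param window optional integer index range \code{c(first, last)}
#'   overriding automatic window selection.
#' @return A list with elements \code{rho}, \code{stderr}, \code{window}
#'   (times, min), \code{reference}.
#' @examples
#' pe <- generatePlate(plateDesign(doses6 = 100, replicates = 1, seed = 1))
#' estimateActivity(pe, 1)
#' @export
estimateActivity <- function(pe, well, targetChannel = "YFP",
                             referenceChannel = "CFP", window = NULL) {
  time <- plateTimes(pe)
  if (length(time) < 8)
    stop("at least 8 time points required for activity extraction")
  for (ch in c(targetChannel, referenceChannel))
    if (!ch %in% SummarizedExperiment::assayNames(pe))
      stop("channel not present: ", ch)
  target <- SummarizedExperiment::assay(pe, targetChannel)[, well]
  reference <- SummarizedExperiment::assay(pe, referenceChannel)[, well]
  est <- activityFromSeries(time, target, reference, window)
  est$reference <- referenceChannel
  est
}

#' Collapse per-well activities into a dose-response dataset
#'
#' Extracts rho for every non-blank well and summarizes replicates per
#' (HSL species, dose, arabinose) condition: mean rho, standard deviation
#' across replicates (NA when a single replicate -- undefined, not zero)
#' and replicate count, ordered by dose.
#'
#' @param pe a plate experiment containing wells of a single device.
#' @param targetChannel,referenceChannel channels passed to
#'   \code{\link{estimateActivity}}.
#' @param promoter promoter id recorded in the result (default: the
#'   device's name).
#' @return A \linkS4class{DoseResponse}.
#' @export
buildDoseResponse <- function(pe, targetChannel = "YFP",
                              referenceChannel = "CFP", promoter = NULL) {
  cd <- as.data.frame(SummarizedExperiment::colData(pe))
  cd <- cd[!cd$is_blank, , drop = FALSE]
  if (nrow(cd) == 0) stop("no measurement wells")
  dev <- unique(cd$device)
  if (length(dev) != 1)
    stop("metadata mismatch: wells from multiple devices (",
         paste(dev, collapse = ", "), ")")
  time <- plateTimes(pe)
  tgt <- SummarizedExperiment::assay(pe, targetChannel)
  ref <- SummarizedExperiment::assay(pe, referenceChannel)
  rho <- vapply(cd$well, function(w)
    activityFromSeries(time, tgt[, w], ref[, w])$rho, numeric(1))
  key <- interaction(cd$hsl_species, cd$hsl_nM, cd$arabinose_mM, drop = TRUE)
  agg <- lapply(split(seq_len(nrow(cd)), key), function(ii) {
    data.frame(
      species = cd$hsl_species[ii[1]],
      C6 = if (cd$hsl_species[ii[1]] == "3OC6HSL") cd$hsl_nM[ii[1]] else 0,
      C12 = if (cd$hsl_species[ii[1]] == "3OC12HSL") cd$hsl_nM[ii[1]] else 0,
      arabinose = cd$arabinose_mM[ii[1]],
      rho = mean(rho[ii]),
      sd = if (length(ii) > 1) sd(rho[ii]) else NA_real_,
      n = length(ii))
  })
  d <- do.call(rbind, agg)
  d <- d[order(d$species, d$arabinose, d$C6 + d$C12), ]
  rownames(d) <- NULL
  if (is.null(promoter)) promoter <- dev
  doseResponse(device = dev, promoter = promoter,
               data = d[, c("C6", "C12", "arabinose", "rho", "sd", "n")])
}

#' Write a dose-response dataset as tidy CSV
#' @param dr a \linkS4class{DoseResponse}.
#' @param file output path.
#' @return Invisibly, the path.
#' @export
writeDoseResponseCSV <- function(dr, file) {
  d <- dr@data
  out <- data.frame(device = dr@device, promoter = dr@promoter,
                    hsl = ifelse(d$C12 > 0, "3OC12HSL",
                                 ifelse(d$C6 > 0, "3OC6HSL", "none")),
                    dose_nM = d$C6 + d$C12, arabinose_mM = d$arabinose,
                    rho = d$rho, sd = d$sd, n_reps = d$n)
  write.csv(out, file, row.names = FALSE)
  invisible(file)
}
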