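# Compartment-based reaction-diffusion simulation of discrete cell
# populations on hydrophobic-grid membranes. Each grid square is a
# well-mixed population; HSL signals exchange between 4-neighbor squares
# (no-flux boundaries) while cells stay put.

#' Registered grid device identifiers
#'
#' Device types assignable to grid squares: the optimized double receiver;
#' relay devices that send one signal in response to the other
#' (relay_C6toC12 = pLux76-LasI, receives 3OC6HSL and sends 3OC12HSL;
#' relay_C12toC6 = pLas81-LuxI, the converse); constitutive senders of
#' either signal; a 50:50 mixture of both relay populations; a
#' constitutive-control population (grows and fluoresces but does not
#' signal); and empty squares.
#'
#' @return Character vector of device ids.
#' @export
gridDeviceRegistry <- function() {
  c("receiver", "relay_C6toC12", "relay_C12toC6", "sender_C6", "sender_C12",
    "mixed_relays", "constitutive_control", "empty")
}

#' Gompertz population capacity
#'
#' @param g a \linkS4class{GompertzGrowth}.
#' @param t time(s), min (>= 0).
#' @return Capacity \code{Kcap exp(-exp(-kg (t - tI)))}; equals
#'   \code{Kcap/e} at the inflection time and approaches \code{Kcap} as t
#'   grows.
#' @export
gompertzCapacity <- function(g, t) {
  stopifnot(all(t >= 0))
  g@Kcap * exp(-exp(-g@kg * (t - g@tI)))
}

# Per-capita growth rate d log(capacity)/dt of the Gompertz curve.
gompertzMu <- function(g, t) g@kg * exp(-g@kg * (t - g@tI))

#' Fit a Gompertz growth model to a capacity curve
#'
#' Least-squares refit of (Kcap, kg, tI) on the log-log scale, used to
#' calibrate growth from constitutive mRFP1 traces.
#'
#' @param t times, min.
#' @param y capacities.
#' @param init optional \linkS4class{GompertzGrowth} starting point.
#' @return A \linkS4class{GompertzGrowth}.
#' @export
fitGompertz <- function(t, y, init = NULL) {
  stopifnot(length(t) == length(y), all(y > 0))
  if (is.null(init))
    init <- gompertzGrowth(Kcap = max(y) * 1.05, kg = 0.01,
                           tI = t[which.min(abs(y - max(y) / exp(1)))])
  sse <- function(q) {
    g <- gompertzGrowth(exp(q[1]), exp(q[2]), q[3])
    sum((gompertzCapacity(g, t) - y)^2)
  }
  opt <- optim(c(log(init@Kcap), log(init@kg), init@tI), sse,
               method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  opt <- optim(opt$par, sse, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  gompertzGrowth(exp(opt$par[1]), exp(opt$par[2]), opt$par[3])
}

#' Default spatial parameters
#'
#' Effective parameters of the lattice model. The diffusivities start from
#' the physical diffusivity of HSLs in aqueous agar (~5e-4 mm^2/s ~ 0.03
#' mm^2/min) and absorb membrane/agar partitioning; synthesis and decay
#' rates are effective values chosen once so that the closed relay loop is
#' supra-threshold when both relays share a compartment but sub-ignition
#' for a pure checkerboard -- the regime in which the characterized system
#' operates. They are order-of-magnitude defaults, not measured constants.
#'
#' @param productionScale global multiplier on synthase production (the
#'   bifurcation-scan control parameter).
#' @return A \linkS4class{SpatialParams}.
#' @export
defaultSpatialParams <- function(productionScale = 1) {
  new("SpatialParams",
      D6 = 0.003, D12 = 0.003,
      kSyn6 = 3.5e-4, kSyn12 = 4e-5,
      kDeg6 = 0.005, kDeg12 = 0.005,
      growth = gompertzGrowth(Kcap = 1, kg = 0.01, tI = 400),
      receiver = presetDevice(),
      pLas81Hill = hillTransfer(basal = 1, vmax = 500, ec50 = 10, hill = 2),
      senderAct6 = 100, senderAct12 = 100,
      synthaseDilution = 0.01,
      productionScale = productionScale)
}

# Promoter activities per device type at local signal levels.
# Returns synthase expression drives (RPU) and reporter activities.
deviceActivities <- function(devices, c6, c12, sp) {
  recDev <- sp@receiver
  actCfp <- matrix(simplifiedRate(recDev@cfpParams, as.vector(c6),
                                  as.vector(c12)), nrow(c6), ncol(c6))
  actYfp <- matrix(hillRate(sp@pLas81Hill, as.vector(c12)), nrow(c6), ncol(c6))

  hasReceiver <- devices %in% c("receiver", "relay_C6toC12", "relay_C12toC6",
                                "mixed_relays")
  # synthase expression: LuxI (makes C6) from pLas81; LasI (makes C12)
  # from pLux76 -- the pLux76-LasI relay uses the CFP channel's transfer,
  # the pLas81-LuxI relay the Hill refit of the YFP channel
  driveLuxI <- matrix(0, nrow(c6), ncol(c6))
  driveLasI <- matrix(0, nrow(c6), ncol(c6))
  driveLuxI[devices == "relay_C12toC6"] <- actYfp[devices == "relay_C12toC6"]
  driveLasI[devices == "relay_C6toC12"] <- actCfp[devices == "relay_C6toC12"]
  mixed <- devices == "mixed_relays"
  driveLuxI[mixed] <- 0.5 * actYfp[mixed]
  driveLasI[mixed] <- 0.5 * actCfp[mixed]
  driveLuxI[devices == "sender_C6"] <- sp@senderAct6
  driveLasI[devices == "sender_C12"] <- sp@senderAct12

  cfpAct <- matrix(0, nrow(c6), ncol(c6))
  yfpAct <- matrix(0, nrow(c6), ncol(c6))
  cfpAct[hasReceiver] <- actCfp[hasReceiver]
  yfpAct[hasReceiver] <- actYfp[hasReceiver]
  ctrl <- devices == "constitutive_control"
  cfpAct[ctrl] <- 1
  yfpAct[ctrl] <- 1
  list(driveLuxI = driveLuxI, driveLasI = driveLasI,
       cfpAct = cfpAct, yfpAct = yfpAct)
}

# Discrete 5-point Laplacian with no-flux (replicated-edge) boundaries.
noFluxLaplacian <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1, seq_len(nr - 1)), , drop = FALSE]
  down <- m[c(seq_len(nr - 1) + 1, nr), , drop = FALSE]
  left <- m[, c(1, seq_len(nc - 1)), drop = FALSE]
  right <- m[, c(seq_len(nc - 1) + 1, nc), drop = FALSE]
  up + down + left + right - 4 * m
}

#' Maximum stable time step for a layout/parameter combination
#' @param layout a \linkS4class{GridLayout}.
#' @param sp a \linkS4class{SpatialParams}.
#' @return Largest admissible explicit-Euler dt, min (diffusion stability
#'   bound h^2/(4 D)).
#' @export
stableTimeStep <- function(layout, sp) {
  Dmax <- max(sp@D6, sp@D12, 1e-12)
  layout@pitch^2 / (4 * Dmax)
}

#' Initial lattice state for a layout
#' @param layout a \linkS4class{GridLayout}.
#' @param sp a \linkS4class{SpatialParams}.
#' @return A \linkS4class{GridState} at t = 0.
#' @export
initialGridState <- function(layout, sp) {
  nr <- nrow(layout@devices); nc <- ncol(layout@devices)
  z <- matrix(0, nr, nc)
  cap0 <- gompertzCapacity(sp@growth, 0) / sp@growth@Kcap
  cap <- z
  cap[layout@devices != "empty"] <- cap0
  new("GridState", time = 0, capacity = cap, cfp = z, yfp = z,
      synLuxI = z, synLasI = z, c6 = layout@initC6, c12 = layout@initC12)
}

#' Advance a lattice state by one explicit-Euler step
#'
#' One update applies, in order: (i) analytic advance of each occupied
#' square's Gompertz capacity; (ii) per-square promoter activities from
#' the equilibrium transfer functions at the local signal levels; (iii)
#' synthase and reporter accumulation scaled by capacity; (iv) HSL
#' production, first-order decay, and 4-neighbor diffusive exchange with
#' no-flux boundaries.
#'
#' @param state a \linkS4class{GridState}.
#' @param layout a \linkS4class{GridLayout}.
#' @param sp a \linkS4class{SpatialParams}.
#' @param dt time step, min; must not exceed the diffusion stability bound.
#' @return The advanced \linkS4class{GridState}.
#' @export
stepGrid <- function(state, layout, sp, dt) {
  bound <- stableTimeStep(layout, sp)
  if (dt > bound)
    stop(sprintf("dt = %g min violates the diffusion stability bound; maximum admissible dt is %g min",
                 dt, bound))
  t1 <- state@time + dt
  occupied <- layout@devices != "empty"
  cap <- state@capacity
  cap[occupied] <- gompertzCapacity(sp@growth, t1) / sp@growth@Kcap
  act <- deviceActivities(layout@devices, state@c6, state@c12, sp)
  mu <- gompertzMu(sp@growth, state@time)

  synLuxI <- state@synLuxI + dt * (sp@productionScale * act$driveLuxI -
                                     (sp@synthaseDilution + mu) * state@synLuxI)
  synLasI <- state@synLasI + dt * (sp@productionScale * act$driveLasI -
                                     (sp@synthaseDilution + mu) * state@synLasI)
  synLuxI <- pmax(synLuxI, 0)
  synLasI <- pmax(synLasI, 0)

  h2 <- layout@pitch^2
  c6 <- state@c6 + dt * (sp@kSyn6 * state@synLuxI * state@capacity -
                           sp@kDeg6 * state@c6 +
                           (sp@D6 / h2) * noFluxLaplacian(state@c6))
  c12 <- state@c12 + dt * (sp@kSyn12 * state@synLasI * state@capacity -
                             sp@kDeg12 * state@c12 +
                             (sp@D12 / h2) * noFluxLaplacian(state@c12))
  cfp <- state@cfp + dt * act$cfpAct * state@capacity
  yfp <- state@yfp + dt * act$yfpAct * state@capacity

  new("GridState", time = t1, capacity = cap, cfp = cfp, yfp = yfp,
      synLuxI = synLuxI, synLasI = synLasI,
      c6 = pmax(c6, 0), c12 = pmax(c12, 0))
}

#' Simulate a gridded-membrane experiment
#'
#' Deterministic (seed-free) explicit-Euler simulation of a layout over a
#' time horizon. The default time step is 0.2x the diffusion stability
#' bound (capped at 1 min so reaction terms are also well resolved).
#'
#' @param layout a \linkS4class{GridLayout}.
#' @param sp a \linkS4class{SpatialParams}.
#' @param horizon simulated span, min.
#' @param dt time step, min (default: auto).
#' @param recordEvery snapshot cadence, min.
#' @return A \linkS4class{GridTrajectory}.
#' @examples
#' lay <- senderReceiverLayout(nRows = 4, nCols = 5)
#' traj <- simulateGrid(lay, defaultSpatialParams(), horizon = 200,
#'                      recordEvery = 100)
#' traj
#' @export
simulateGrid <- function(layout, sp, horizon = 1500, dt = NULL,
                         recordEvery = 50) {
  validObject(layout); validObject(sp)
  bound <- stableTimeStep(layout, sp)
  if (is.null(dt)) dt <- min(0.2 * bound, 1)
  if (dt > bound)
    stop(sprintf("dt = %g min violates the diffusion stability bound; maximum admissible dt is %g min",
                 dt, bound))
  nSteps <- ceiling(horizon / dt)
  recEvery <- max(1L, round(recordEvery / dt))
  state <- initialGridState(layout, sp)
  states <- list(state)
  times <- 0
  for (k in seq_len(nSteps)) {
    state <- stepGrid(state, layout, sp, dt)
    if (k %% recEvery == 0L || k == nSteps) {
      states[[length(states) + 1L]] <- state
      times <- c(times, state@time)
    }
  }
  new("GridTrajectory", times = times, states = states, layout = layout,
      dt = dt)
}

#' Sender-columns-plus-receiver-rows layout
#'
#' Receiver squares in rows with a 3OC6HSL sender column on the left edge
#' and a 3OC12HSL sender column on the right edge, emulating the
#' double-receiver membrane assay.
#'
#' @param nRows,nCols grid size (receiver block spans the interior).
#' @param pitch square pitch, mm.
#' @return A \linkS4class{GridLayout}.
#' @export
senderReceiverLayout <- function(nRows = 4, nCols = 8, pitch = 3) {
  dev <- matrix("receiver", nRows, nCols)
  dev[, 1] <- "sender_C6"
  dev[, nCols] <- "sender_C12"
  gridLayout(dev, pitch = pitch)
}

#' Alternating relay-stripe layout
#'
#' Horizontal stripes of width \code{stripeWidth} squares: stripe 1 is
#' \code{relayA}, stripe 2 \code{relayB}, alternating; an initial
#' exogenous 3OC12HSL band sits in extra empty rows above the first
#' stripe.
#'
#' @param relayA,relayB device ids for odd/even stripes ("empty" turns the
#'   even stripes into non-relaying receiver gaps via
#'   \code{"receiver"}; pass "receiver" explicitly for receiver+empty
#'   vector populations).
#' @param nStripes number of stripes.
#' @param stripeWidth stripe width, squares.
#' @param nCols lattice width, squares.
#' @param initC12 initial 3OC12HSL in the top band, nM.
#' @param bandRows rows of the exogenous signal band.
#' @param pitch square pitch, mm.
#' @return A \linkS4class{GridLayout}.
#' @export
relayStripeLayout <- function(relayA = "relay_C12toC6",
                              relayB = "relay_C6toC12",
                              nStripes = 4, stripeWidth = 2, nCols = 6,
                              initC12 = 20000, bandRows = 1, pitch = 3) {
  nRows <- bandRows + nStripes * stripeWidth
  dev <- matrix("empty", nRows, nCols)
  for (k in seq_len(nStripes)) {
    rows <- bandRows + ((k - 1) * stripeWidth + 1):(k * stripeWidth)
    dev[rows, ] <- if (k %% 2 == 1) relayA else relayB
  }
  c12 <- matrix(0, nRows, nCols)
  c12[seq_len(bandRows), ] <- initC12
  gridLayout(dev, pitch = pitch, initC12 = c12)
}

#' Checkerboard relay layout with optional mixed-population center
#'
#' Alternating squares of the two relay devices; optionally, a central
#' block of mixed (50:50) relay populations that can ignite the mutual
#' activation loop.
#'
#' @param n lattice side, squares.
#' @param centerSize side of the central mixed block (0 for none).
#' @param pitch square pitch, mm.
#' @return A \linkS4class{GridLayout}.
#' @export
checkerboardLayout <- function(n = 12, centerSize = 4, pitch = 3) {
  dev <- matrix("relay_C6toC12", n, n)
  parity <- outer(seq_len(n), seq_len(n), "+") %% 2 == 0
  dev[parity] <- "relay_C12toC6"
  if (centerSize > 0) {
    i0 <- floor((n - centerSize) / 2) + 1
    idx <- i0:(i0 + centerSize - 1)
    dev[idx, idx] <- "mixed_relays"
  }
  gridLayout(dev, pitch = pitch)
}

# Mean promoter activity of the receiving channel over a square subset.
stripeResponseActivity <- function(state, mask, device, sp) {
  if (device == "relay_C12toC6") {
    mean(hillRate(sp@pLas81Hill, state@c12[mask]))
  } else {
    mean(simplifiedRate(sp@receiver@cfpParams, state@c6[mask],
                        state@c12[mask]))
  }
}

#' Run a stripe signal-propagation experiment
#'
#' Simulates alternating relay stripes seeded with an exogenous 3OC12HSL
#' band and reports, per stripe, the first time its receiving channel's
#' promoter activity exceeds a threshold (a fraction of that transfer
#' function's dynamic range). Propagation is called when every stripe
#' activates and activation times are nondecreasing with distance from the
#' signal source; layouts alternating a relay with non-relaying squares
#' confine activation to directly induced stripes.
#'
#' @param relayA,relayB stripe devices (see
#'   \code{\link{relayStripeLayout}}).
#' @param sp a \linkS4class{SpatialParams}.
#' @param nStripes,stripeWidth,nCols,initC12 layout settings.
#' @param horizon simulated span, min.
#' @param thresholdFrac activation threshold as a fraction of each
#'   transfer function's dynamic range.
#' @return A list with \code{report} (data frame: stripe, device,
#'   activationTime) and \code{propagated} (logical).
#' @export
runStripeExperiment <- function(relayA = "relay_C12toC6",
                                relayB = "relay_C6toC12",
                                sp = defaultSpatialParams(),
                                nStripes = 4, stripeWidth = 2, nCols = 6,
                                initC12 = 20000, horizon = 6000,
                                thresholdFrac = 0.25) {
  layout <- relayStripeLayout(relayA, relayB, nStripes, stripeWidth, nCols,
                              initC12)
  traj <- simulateGrid(layout, sp, horizon = horizon, recordEvery = 25)
  bandRows <- nrow(layout@devices) - nStripes * stripeWidth
  thresholds <- c(
    relay_C12toC6 = sp@pLas81Hill@basal +
      thresholdFrac * (sp@pLas81Hill@vmax - sp@pLas81Hill@basal),
    relay_C6toC12 = {
      p <- sp@receiver@cfpParams
      sat <- simplifiedRate(p, 1e9, 0)
      p@a0 + thresholdFrac * (sat - p@a0)
    })
  report <- data.frame(stripe = seq_len(nStripes),
                       device = rep(c(relayA, relayB),
                                    length.out = nStripes),
                       activationTime = NA_real_)
  for (k in seq_len(nStripes)) {
    dev <- report$device[k]
    if (!dev %in% names(thresholds)) next # non-relay stripes never "send"
    rows <- bandRows + ((k - 1) * stripeWidth + 1):(k * stripeWidth)
    mask <- matrix(FALSE, nrow(layout@devices), ncol(layout@devices))
    mask[rows, ] <- TRUE
    for (j in seq_along(traj@times)) {
      a <- stripeResponseActivity(traj@states[[j]], mask, dev, sp)
      if (a > thresholds[[dev]]) {
        report$activationTime[k] <- traj@times[j]
        break
      }
    }
  }
  relayStripes <- report$device %in% names(thresholds)
  times <- report$activationTime[relayStripes]
  propagated <- all(relayStripes) && !any(is.na(times)) &&
    !is.unsorted(times)
  list(report = report, propagated = propagated, trajectory = traj)
}

#' Scan the relay positive-feedback loop for its ignition bifurcation
#'
#' Simulates the spatially homogeneous (single-compartment, saturating
#' capacity) closed loop coupling pLux76 -> LasI -> 3OC12HSL -> pLas81 ->
#' LuxI -> 3OC6HSL at a series of synthase production scale factors. For
#' each scale the steady output reached from the signal-free state is
#' classified "on" or "off" against the geometric midpoint between basal
#' and saturated loop output; the threshold scale separating the regimes
#' is then refined by bisection. Below the threshold the only reachable
#' state is near-basal; above it the mutual activation ignites.
#'
#' @param sp a \linkS4class{SpatialParams} (its \code{productionScale} is
#'   overridden by the scan).
#' @param scales ascending production scale factors (include 0 to verify
#'   the off state).
#' @param horizon integration span per scale, min.
#' @param bisectTol relative resolution of the refined threshold.
#' @return A list with \code{scan} (data frame: scale, output, on) and
#'   \code{threshold} (bisection estimate; NA when no sign change occurs).
#' @examples
#' scan <- bifurcationScan(scales = c(0, 0.5, 1, 2, 4), horizon = 3000)
#' scan$threshold
#' @export
bifurcationScan <- function(sp = defaultSpatialParams(),
                            scales = seq(0, 4, by = 0.25),
                            horizon = 8000, bisectTol = 0.02) {
  stopifnot(!is.unsorted(scales))
  cfp <- sp@receiver@cfpParams
  steadyOutput <- function(scale) {
    rhs <- function(t, y, parms) {
      luxI <- y[1]; lasI <- y[2]; c6 <- y[3]; c12 <- y[4]
      dLuxI <- scale * hillRate(sp@pLas81Hill, c12) -
        sp@synthaseDilution * luxI
      dLasI <- scale * simplifiedRate(cfp, c6, c12) -
        sp@synthaseDilution * lasI
      dc6 <- sp@kSyn6 * luxI - sp@kDeg6 * c6
      dc12 <- sp@kSyn12 * lasI - sp@kDeg12 * c12
      list(c(dLuxI, dLasI, dc6, dc12))
    }
    out <- deSolve::ode(c(0, 0, 0, 0), c(0, horizon), rhs, NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-10)
    yT <- out[nrow(out), -1]
    # loop output: the received 3OC12HSL-driven activity
    hillRate(sp@pLas81Hill, yT[4])
  }
  offRef <- sp@pLas81Hill@basal
  onRef <- sp@pLas81Hill@vmax
  cut <- sqrt(max(offRef, 1e-6) * onRef) # geometric midpoint
  outputs <- vapply(scales, steadyOutput, numeric(1))
  on <- outputs > cut
  threshold <- NA_real_
  flip <- which(diff(on) == 1)
  if (length(flip)) {
    lo <- scales[flip[1]]
    hi <- scales[flip[1] + 1]
    while ((hi - lo) > bisectTol * max(hi, 1e-6)) {
      mid <- (lo + hi) / 2
      if (steadyOutput(mid) > cut) hi <- mid else lo <- mid
    }
    threshold <- (lo + hi) / 2
  }
  list(scan = data.frame(scale = scales, output = outputs, on = on),
       threshold = threshold)
}

#' Normalized channel response over a trajectory snapshot
#'
#' Reporter accumulation divided by the accumulated expression capacity
#' (the time integral of the normalized growth curve) -- comparable to
#' ratiometric activity against the constitutive mRFP1 proxy, in RPU.
#'
#' @param traj a \linkS4class{GridTrajectory}.
#' @param sp the \linkS4class{SpatialParams} used in the simulation (for
#'   the growth curve).
#' @param when snapshot time, min (nearest recorded time used).
#' @param channel "CFP" or "YFP".
#' @return Matrix of normalized responses (NA for empty squares).
#' @export
gridResponse <- function(traj, sp, when, channel = c("CFP", "YFP")) {
  channel <- match.arg(channel)
  k <- which.min(abs(traj@times - when))
  st <- traj@states[[k]]
  f <- if (channel == "CFP") st@cfp else st@yfp
  occ <- traj@layout@devices != "empty"
  tt <- seq(0, st@time, length.out = 500)
  cap <- gompertzCapacity(sp@growth, tt) / sp@growth@Kcap
  acc <- sum((cap[-1] + cap[-length(cap)]) / 2 * diff(tt))
  out <- matrix(NA_real_, nrow(f), ncol(f))
  out[occ] <- f[occ] / max(acc, 1e-12)
  out
}
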