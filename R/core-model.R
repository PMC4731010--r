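# Equilibrium transcription transfer functions for the two-signal
# (3OC6HSL / 3OC12HSL), two-receiver (LuxR / LasR) crosstalk system.

#' Closed-form equilibrium transcription rate
#'
#' Evaluates the simplified equilibrium transfer function for a promoter
#' that can be activated by HSL-bound LuxR dimers and/or LasR dimers:
#' \deqn{f(C_6, C_{12}) = \frac{a_0 + a_{1R} W_R + a_{1S} W_S}{1 + W_R + W_S}}
#' with regulator occupancy weights
#' \deqn{W_R = K_{GR} r^2 \frac{K_{R6}^n C_6^n + K_{R12}^n C_{12}^n}
#'   {(1 + K_{R6} C_6 + K_{R12} C_{12})^n}}
#' and \eqn{W_S} defined analogously with \eqn{K_{GS}}, \eqn{s},
#' \eqn{K_{S6}}, \eqn{K_{S12}}. The output always lies between the smallest
#' and largest of \code{a0}, \code{a1R}, \code{a1S}; it depends on
#' \code{(KGR, r)} only through the product \code{KGR * r^2} (and likewise
#' for \code{(KGS, s)}), which is why receiver levels are only defined
#' relative to the pCat calibration.
#'
#' @param params a \linkS4class{CrosstalkParams}.
#' @param C6,C12 HSL concentrations, nM (vectors of equal length or length
#'   1 are recycled).
#' @return Transcription rate(s), RPU.
#' @examples
#' p <- crosstalkParams(KR6 = 0.0015, KR12 = 1.5e-5, KS6 = 2e-9,
#'                      KS12 = 0.002, KGR = 4, KGS = 0.1,
#'                      a0 = 0.05, a1R = 12, a1S = 7.7)
#' simplifiedRate(p, C6 = c(0, 100, 1e4), C12 = 0)
#' @export
simplifiedRate <- function(params, C6, C12) {
  validObject(params)
  if (any(C6 < 0) || any(C12 < 0))
    stop("HSL concentrations must be >= 0")
  rateCore(params, C6, C12)
}

# validation-free core used in likelihood hot loops
rateCore <- function(p, C6, C12) {
  WR <- occupancyWeight(p@KGR * p@r^2, p@KR6, p@KR12, p@n, C6, C12)
  WS <- occupancyWeight(p@KGS * p@s^2, p@KS6, p@KS12, p@n, C6, C12)
  (p@a0 + p@a1R * WR + p@a1S * WS) / (1 + WR + WS)
}

# Occupancy weight K r^2 (K6^n C6^n + K12^n C12^n) / (1 + K6 C6 + K12 C12)^n,
# computed in a form safe against overflow for large C^n.
occupancyWeight <- function(Kg, K6, K12, n, C6, C12) {
  if (Kg == 0) return(rep(0, max(length(C6), length(C12))))
  den <- 1 + K6 * C6 + K12 * C12
  u6 <- (K6 * C6) / den
  u12 <- (K12 * C12) / den
  Kg * (u6^n + u12^n)
}

#' Hill transfer function
#'
#' @param h a \linkS4class{HillTransfer}.
#' @param C inducer concentration(s), nM.
#' @return Response(s), RPU: \code{basal + (vmax - basal) C^h/(ec50^h + C^h)}.
#' @export
hillRate <- function(h, C) {
  validObject(h)
  if (any(C < 0)) stop("concentration must be >= 0")
  u <- (C / h@ec50)^h@hill
  h@basal + (h@vmax - h@basal) * u / (1 + u)
}

# Species ordering of the full mass-action model (HSL inputs clamped):
# free receivers, HSL-bound monomers, regulator dimers, free promoter and
# promoter-regulator complexes.
fullModelSpecies <- c("R", "S", "R6", "R12", "S6", "S12",
                      "D6", "D12", "E6", "E12",
                      "G", "GD6", "GD12", "GE6", "GE12")

# Right-hand side of the full-model ODEs. Association constants map onto
# bimolecular constants via the receiver concentration scale Rcat:
# dimerization K = 1/Rcat, promoter binding K = KGR/Rcat (so that the
# equilibrium promoter occupancy reproduces KGR r^2 at receiver level r).
fullModelRHS <- function(y, spec, C6, C12, gross = FALSE) {
  p <- spec@params
  kf <- spec@kf
  g <- spec@gamma
  Rcat <- spec@receiverScale
  eps <- spec@dimerScale
  Kdim <- eps / Rcat
  KGRb <- p@KGR / (eps * Rcat)
  KGSb <- p@KGS / (eps * Rcat)

  R <- y[1]; S <- y[2]
  R6 <- y[3]; R12 <- y[4]; S6 <- y[5]; S12 <- y[6]
  D6 <- y[7]; D12 <- y[8]; E6 <- y[9]; E12 <- y[10]
  G <- y[11]; GD6 <- y[12]; GD12 <- y[13]; GE6 <- y[14]; GE12 <- y[15]

  # binding/unbinding fluxes (reverse rate kf/K; K = 0 disables binding)
  bind <- function(K, a, b, ab) if (K > 0) kf * a * b - (kf / K) * ab else 0
  fR6 <- bind(p@KR6, R, C6, R6)
  fR12 <- bind(p@KR12, R, C12, R12)
  fS6 <- bind(p@KS6, S, C6, S6)
  fS12 <- bind(p@KS12, S, C12, S12)
  fD6 <- kf * R6 * R6 - (kf / Kdim) * D6
  fD12 <- kf * R12 * R12 - (kf / Kdim) * D12
  fE6 <- kf * S6 * S6 - (kf / Kdim) * E6
  fE12 <- kf * S12 * S12 - (kf / Kdim) * E12
  fGD6 <- bind(KGRb, G, D6, GD6)
  fGD12 <- bind(KGRb, G, D12, GD12)
  fGE6 <- bind(KGSb, G, E6, GE6)
  fGE12 <- bind(KGSb, G, E12, GE12)

  res <- c(
    spec@receiverProductionR - g * R - fR6 - fR12,
    spec@receiverProductionS - g * S - fS6 - fS12,
    fR6 - g * R6 - 2 * fD6,
    fR12 - g * R12 - 2 * fD12,
    fS6 - g * S6 - 2 * fE6,
    fS12 - g * S12 - 2 * fE12,
    fD6 - g * D6 - fGD6,
    fD12 - g * D12 - fGD12,
    fE6 - g * E6 - fGE6,
    fE12 - g * E12 - fGE12,
    spec@geneProduction - g * G - fGD6 - fGD12 - fGE6 - fGE12,
    fGD6 - g * GD6,
    fGD12 - g * GD12,
    fGE6 - g * GE6,
    fGE12 - g * GE12
  )
  if (!gross) return(res)
  # per-equation gross flux magnitudes, the natural residual scale
  a <- abs
  grossMag <- c(
    a(spec@receiverProductionR) + a(g * R) + a(fR6) + a(fR12),
    a(spec@receiverProductionS) + a(g * S) + a(fS6) + a(fS12),
    a(fR6) + a(g * R6) + 2 * a(fD6),
    a(fR12) + a(g * R12) + 2 * a(fD12),
    a(fS6) + a(g * S6) + 2 * a(fE6),
    a(fS12) + a(g * S12) + 2 * a(fE12),
    a(fD6) + a(g * D6) + a(fGD6),
    a(fD12) + a(g * D12) + a(fGD12),
    a(fE6) + a(g * E6) + a(fGE6),
    a(fE12) + a(g * E12) + a(fGE12),
    a(spec@geneProduction) + a(g * G) + a(fGD6) + a(fGD12) + a(fGE6) + a(fGE12),
    a(fGD6) + a(g * GD6),
    a(fGD12) + a(g * GD12),
    a(fGE6) + a(g * GE6),
    a(fGE12) + a(g * GE12)
  )
  list(res = res, gross = grossMag)
}

# Initial guess for the steady state from the detailed-balance relationships
# implied by the simplified model (good enough for Newton to converge).
fullModelGuess <- function(spec, C6, C12) {
  p <- spec@params
  Rcat <- spec@receiverScale
  Rtot <- spec@receiverProductionR / spec@gamma
  Stot <- spec@receiverProductionS / spec@gamma
  R <- Rtot / (1 + p@KR6 * C6 + p@KR12 * C12)
  S <- Stot / (1 + p@KS6 * C6 + p@KS12 * C12)
  R6 <- p@KR6 * R * C6; R12 <- p@KR12 * R * C12
  S6 <- p@KS6 * S * C6; S12 <- p@KS12 * S * C12
  eps <- spec@dimerScale
  D6 <- eps * R6^2 / Rcat; D12 <- eps * R12^2 / Rcat
  E6 <- eps * S6^2 / Rcat; E12 <- eps * S12^2 / Rcat
  KGRb <- p@KGR / (eps * Rcat); KGSb <- p@KGS / (eps * Rcat)
  Ptot <- spec@geneProduction / spec@gamma
  wG <- 1 + KGRb * (D6 + D12) + KGSb * (E6 + E12)
  G <- Ptot / wG
  c(R, S, R6, R12, S6, S12, D6, D12, E6, E12,
    G, KGRb * G * D6, KGRb * G * D12, KGSb * G * E6, KGSb * G * E12)
}

# Exact steady-state reduction: given free receiver and promoter
# concentrations (R, S, G), every complex follows in closed form from its
# own balance equation. Per signal k: the promoter complex balance gives
# G.Dk = kf G Dk / (gamma + kf/KG); substituting into the dimer balance
# makes Dk proportional to Rk^2; and the monomer balance then is a
# quadratic in Rk with a positive root. The remaining unknowns satisfy the
# three conservation laws (receiver and promoter production balancing
# dilution of every containing species), a well-conditioned 3-dimensional
# system.
fullModelBranch <- function(R, G, C, Kbind, KG, spec) {
  if (Kbind <= 0 || C <= 0) {
    return(list(Rk = 0, Dk = 0, GDk = 0))
  }
  kf <- spec@kf
  g <- spec@gamma
  Kdim <- spec@dimerScale / spec@receiverScale
  unbG <- if (KG > 0) g + kf / KG else Inf
  cG <- if (KG > 0) kf * G / unbG else 0         # GDk = cG * Dk
  cD <- kf / (kf / Kdim + g + kf * G * (if (KG > 0) g / unbG else 0))
  # Rk balance: kf R C = (kf/Kbind + g) Rk + 2 g (1 + cG) cD Rk^2
  a <- 2 * g * (1 + cG) * cD
  b <- kf / Kbind + g
  rhs <- kf * R * C
  Rk <- if (a > 0) {
    2 * rhs / (b + sqrt(b^2 + 4 * a * rhs))
  } else rhs / b
  Dk <- cD * Rk^2
  list(Rk = Rk, Dk = Dk, GDk = cG * Dk)
}

fullModelStateFromCore <- function(core, spec, C6, C12) {
  R <- core[1]; S <- core[2]; G <- core[3]
  p <- spec@params
  Rcat <- spec@receiverScale
  eps <- spec@dimerScale
  KGRb <- p@KGR / (eps * Rcat)
  KGSb <- p@KGS / (eps * Rcat)
  b6 <- fullModelBranch(R, G, C6, p@KR6, KGRb, spec)
  b12 <- fullModelBranch(R, G, C12, p@KR12, KGRb, spec)
  e6 <- fullModelBranch(S, G, C6, p@KS6, KGSb, spec)
  e12 <- fullModelBranch(S, G, C12, p@KS12, KGSb, spec)
  c(R, S, b6$Rk, b12$Rk, e6$Rk, e12$Rk,
    b6$Dk, b12$Dk, e6$Dk, e12$Dk,
    G, b6$GDk, b12$GDk, e6$GDk, e12$GDk)
}

# conservation residuals for the reduced system, normalized by production
fullModelCoreResid <- function(core, spec, C6, C12) {
  y <- fullModelStateFromCore(core, spec, C6, C12)
  g <- spec@gamma
  c(spec@receiverProductionR -
      g * (y[1] + y[3] + y[4] + 2 * (y[7] + y[8] + y[12] + y[13])),
    spec@receiverProductionS -
      g * (y[2] + y[5] + y[6] + 2 * (y[9] + y[10] + y[14] + y[15])),
    spec@geneProduction - g * (y[11] + y[12] + y[13] + y[14] + y[15])) /
    c(spec@receiverProductionR, spec@receiverProductionS,
      spec@geneProduction)
}

#' Equilibrium transcription rate of the full mass-action model
#'
#' Builds the mass-action ODE system for receiver production, HSL binding,
#' regulator dimerization, promoter binding and growth dilution of every
#' species (HSL concentrations are clamped external inputs), solves for its
#' steady state by damped Newton iteration (falling back to long-time
#' integration with \pkg{deSolve} when Newton stalls), and returns the
#' promoter-occupancy-weighted transcription rate
#' \code{(a0 [G] + a1R sum [G.Dk] + a1S sum [G.Ek]) / P_tot},
#' where \code{P_tot = geneProduction / gamma} is the conserved total
#' promoter concentration.
#'
#' @param spec a \linkS4class{FullModelSpec}.
#' @param C6,C12 clamped HSL concentrations, nM (scalars).
#' @param tol steady-state tolerance on the max-norm residual; each
#'   equation's residual is judged relative to its own gross mass-action
#'   flux magnitude (double-precision cancellation caps the achievable
#'   relative residual near 1e-8, which is the effective floor).
#' @param details if TRUE, also return the steady-state species vector and
#'   residual norm.
#' @return Transcription rate (RPU), or a list when \code{details = TRUE}.
#' @seealso \code{\link{simplifiedRate}}, its negligible-dilution closed
#'   form.
#' @export
fullEquilibriumRate <- function(spec, C6, C12, tol = 1e-10, details = FALSE) {
  validObject(spec)
  stopifnot(length(C6) == 1, length(C12) == 1, C6 >= 0, C12 >= 0)
  y0 <- fullModelGuess(spec, C6, C12)
  scale <- pmax(abs(y0), 1e-10)
  rhs <- function(x) fullModelRHS(x * scale, spec, C6, C12)
  # residuals are differences of large opposing mass-action fluxes, so each
  # equation is judged relative to its own gross flux magnitude (with tol
  # itself as the absolute floor)
  resid <- function(x) {
    r <- fullModelRHS(x * scale, spec, C6, C12, gross = TRUE)
    max(abs(r$res) / pmax(r$gross, 1))
  }
  relTol <- max(tol, 1e-8)

  newton <- function(x, maxit = 60) {
    for (it in seq_len(maxit)) {
      cur <- resid(x)
      if (cur < relTol) return(list(x = x, done = TRUE))
      f <- rhs(x)
      J <- numericJacobian(rhs, x)
      rs <- pmax(apply(abs(J), 1, max), 1e-300)
      step <- tryCatch(solve(J / rs, -f / rs), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      ok <- FALSE
      while (lam >= 1e-10) {
        x2 <- pmax(x + lam * step, 0)
        if (all(is.finite(x2)) && resid(x2) < cur) {
          x <- x2
          ok <- TRUE
          break
        }
        lam <- lam / 2
      }
      if (!ok) break
    }
    list(x = x, done = resid(x) < relTol)
  }

  # solve the reduced 3-unknown conservation system in log space
  guessCore <- log(pmax(c(y0[1], y0[2], y0[11]), 1e-300))
  coreResid <- function(q) fullModelCoreResid(exp(q), spec, C6, C12)
  q <- guessCore
  for (it in 1:100) {
    f <- coreResid(q)
    if (max(abs(f)) < 1e-12) break
    J <- numericJacobian(coreResid, q)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    while (lam >= 1e-12) {
      q2 <- q + lam * pmin(pmax(step, -5), 5)
      if (all(is.finite(coreResid(q2))) &&
          max(abs(coreResid(q2))) < max(abs(f))) break
      lam <- lam / 2
    }
    if (lam < 1e-12) break
    q <- q + lam * pmin(pmax(step, -5), 5)
  }
  out <- newton(fullModelStateFromCore(exp(q), spec, C6, C12) / scale)
  if (!out$done)
    stop(sprintf("steady state did not converge (scaled residual %.3g)",
                 resid(out$x)))
  y <- out$x * scale
  p <- spec@params
  Ptot <- spec@geneProduction / spec@gamma
  rate <- (p@a0 * y[11] + p@a1R * (y[12] + y[13]) +
             p@a1S * (y[14] + y[15])) / Ptot
  if (details) {
    names(y) <- fullModelSpecies
    return(list(rate = rate, species = y, residual = resid(out$x)))
  }
  rate
}

numericJacobian <- function(f, y, eps = 1e-7) {
  f0 <- f(y)
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- eps * max(abs(y[j]), 1e-8)
    y2 <- y
    y2[j] <- y2[j] + h
    J[, j] <- (f(y2) - f0) / h
  }
  J
}
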