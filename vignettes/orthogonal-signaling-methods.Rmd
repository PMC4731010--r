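---
title: "Modeling orthogonal AHL signaling: methods and design notes"
author: "orthosignal maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling orthogonal AHL signaling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthosignal)
```

## The system and the model

Two acyl-homoserine-lactone (AHL) quorum-sensing channels are modeled:
3OC6HSL sensed by LuxR and 3OC12HSL sensed by LasR. Either signal-bound
receiver dimerizes and can activate a promoter; *chemical* crosstalk is a
receiver binding its noncognate signal, *genetic* crosstalk a bound
receiver activating a noncognate promoter. The package's central object is
the equilibrium transcription rate of a promoter in a cell with receiver
levels $r$ (LuxR) and $s$ (LasR), both expressed relative to constitutive
expression from the weak pCat promoter:

$$
f(C_6, C_{12}) \;=\;
  \frac{a_0 + a_{1R} W_R + a_{1S} W_S}{1 + W_R + W_S},
\qquad
W_R = K_{GR}\, r^2\,
  \frac{K_{R6}^n C_6^n + K_{R12}^n C_{12}^n}
       {\left(1 + K_{R6} C_6 + K_{R12} C_{12}\right)^n},
$$

with $W_S$ built the same way from $K_{GS}, s, K_{S6}, K_{S12}$. The
$K_{Ri}, K_{Si}$ are association constants of each receiver for each
signal (1/nM); $K_{GR}, K_{GS}$ lump dimerization and promoter binding
(dimensionless, absorbing the receiver concentration scale); $a_0$,
$a_{1R}$, $a_{1S}$ are basal and complex-bound transcription rates in
relative promoter units (RPU). Two structural facts shape everything
downstream:

* the output is always bounded by the smallest and largest of $a_0,
  a_{1R}, a_{1S}$, and
* $(K_{GR}, r)$ enter only through $K_{GR} r^2$, so receiver levels are
  identifiable only relative to a calibration -- we pin $r = 1$ for
  pCat-driven devices, which defines the unit.

`simplifiedRate()` evaluates this closed form. `fullEquilibriumRate()` is
its independent oracle: the full mass-action network (receiver production,
HSL binding, dimerization, promoter binding, growth dilution $\gamma$ on
every species, zero-order promoter production balancing dilution) solved
to steady state. The solver exploits the network's structure: given the
free receiver and promoter concentrations, every complex follows in
closed form from its own balance equation (the promoter-complex balance
is linear, the dimer balance then linear, the bound-monomer balance a
quadratic with one positive root), leaving a well-conditioned
3-unknown conservation system solved by damped Newton in log space, after
which a full 15-species Newton polish certifies the residual. The closed form emerges from the network
when complex dilution is negligible next to unbinding, so the oracle's
default kinetic closure lives in that regime ($k_f = 10$/(nM min),
$\gamma = 10^{-4}$/min, and a dimerization scale keeping the dimer pool a
small fraction of total receiver). Agreement is within 5% relative error
over a $10\times10$ log-grid of doses spanning 0.1 nM to 25 µM for random
parameter draws with $n = 2$; the cooperativity exponent must be 2 there
because the oracle's dimerization step enforces it. In
`simplifiedRate()` itself, $n$ is a free parameter: the data the model is
fit to do not pin the mechanism, so we treat $n$ as inferable with prior
support (0.5, 4) and default 2 (dimerization).

Steady-state convergence is declared when every equation's residual falls
below $10^{-8}$ of its own gross flux magnitude; the per-equation relative
form matters because at 25 µM doses the opposing fluxes reach $10^7$
nM/min and double-precision cancellation caps the achievable absolute
residual far above any fixed tolerance a slow reaction would need.

## Ratiometric activity extraction

Plate-fluorometer experiments are stored as `SummarizedExperiment`s: one
assay per channel (time $\times$ well), well conditions in `colData`. The
measurand is relative promoter activity $\rho$ = d(target)/d(reference) in
RPU. After blank subtraction (`subtractBackground()`, negative values
clipped at zero with a reported count), `estimateActivity()`:

1. selects the activity window deterministically -- the sliding window of
   one third of the series over which the reference channel accumulates
   most linearly (maximal regression $R^2$ against time, ties to the
   earliest window); this lands in mid-exponential growth where both
   channels accumulate at quasi-constant rates;
2. regresses *each channel on time* within the window and reports
   $\rho = \hat b_{\text{target}} / \hat b_{\text{ref}}$ with a
   delta-method standard error.

We deliberately regress on time rather than target-on-reference: the
reference channel is itself noisy, and ordinary least squares against a
noisy regressor attenuates the slope. The time regression has an
error-free regressor, and when both channels are proportional to
accumulated capacity the ratio of time-slopes is exact regardless of
growth-curve curvature. Slope standard errors use the HC3
heteroscedasticity-robust form because fluorescence noise is
multiplicative (variance grows along the window); with homoscedastic
errors the 2-standard-error coverage of known activities fell measurably
short of nominal. The calibration experiment (200 noisy synthetic wells,
10% CV) is part of the test suite and of `scripts/acceptance.R`.

`buildDoseResponse()` collapses replicate wells per (HSL species, dose,
arabinose); a single replicate reports `sd = NA` (undefined), never 0.

## Inference

The likelihood is Gaussian on mean activities with scale
$\max(\mathrm{sd}/\sqrt{n_{\text{rep}}},\ 0.1\,|\hat\rho|)$: replicate
scatter where available, floored at 10% of the prediction to absorb
between-day variation that three replicates cannot estimate. Priors are
log10-uniform over wide ranges (association constants $10^{-6}$ to
$10^{2}$, rates $10^{-3}$ to $10^{4}$ RPU) -- scale parameters of unknown
magnitude. Sampling uses an affine-invariant ensemble (stretch-move)
sampler written in the package (`ensembleMCMC()`), with $4\times$
parameter-count walkers, 50% of the chain discarded as warmup, and at
least 5,000 flattened draws retained, thinned from chains long enough
(>= 1,500 post-warmup ensemble steps) to traverse the ridge-shaped
posteriors that weakly identified products such as $K_{GS} a_{1S}$
produce. Walkers start from several Nelder-Mead endpoints so the initial
ensemble already spans such ridges. Chains are bit-reproducible given a
seed; split-$\hat R > 1.1$ raises a warning, not an error, because
ridge-shaped posteriors mix slowly in the tails while the credible
intervals are already stable.

Fits are staged for tractability: promoter constants from single-receiver
devices first (`fitCrosstalkMCMC()` with a sharing map -- unprefixed
names shared across promoters, `"promoter.field"` names specific), then
receiver levels of new two-channel devices as a two-parameter posterior
with constants fixed (`inferDeviceLevels()`), then the
arabinose-to-receiver-level curve (`inferAraTransfer()`: per-concentration
level posteriors, then a monotone-by-construction saturating Hill fit with
uncertainty bands from posterior refits). A single global fit is possible
by passing every dataset to `fitCrosstalkMCMC()` at once.

Validation is by recovery, not by matching published parameter tables
(the source study's appendix tables are not reproduced here):
`crosstalkRecoveryRun()` simulates the full chain -- two single-receiver
reporter plates at 3 replicates x 12 doses, extraction, MCMC -- and the
test suite requires >= 90% credible-interval coverage of the generating
constants over 20 seeded repetitions, plus the diagnostic orderings of the
inferred affinities (LuxR prefers 3OC6HSL by about $10^2$; LasR prefers
3OC12HSL overwhelmingly, with only an upper bound on $K_{S6}$
recoverable -- its true value sits below anything the dose range can
measure, which is the point of calling that channel orthogonal).

## The design objective

For the two-channel receiver (pLux76 driving eCFP, pLas81 driving eYFP,
both receivers in one cell) the design score is the signal-to-crosstalk
ratio at 100 nM of each signal applied one at a time:

$$
\frac{\mathrm{CFP}_{C6} \times \mathrm{YFP}_{C12}}
     {\mathrm{CFP}_{C12} \times \mathrm{YFP}_{C6}}.
$$

`optimizeLevels()` maps this objective over a log-spaced $(r, s)$ grid
(levels span orders of magnitude) and polishes the best grid point by
local search that is never allowed to return less than the grid optimum.
A symmetric device scores exactly 1 and swapping the channels inverts the
ratio; both identities are asserted in tests. Raw (not basal-subtracted)
responses enter the four terms; with basal subtraction the objective would
diverge wherever a crosstalk term fell below basal, which the reported
`degenerate` flag already covers.

## The lattice model

Populations on hydrophobic-grid membranes are modeled as one well-mixed
compartment per 3-mm square: cells cannot cross the hydrophobic barrier,
signals can. Per square, gene-expression capacity follows a Gompertz
curve $K\exp(-\exp(-k_g(t - t_I)))$ (defaults $k_g = 0.01$/min, $t_I =
400$ min, matching plate-reader growth at 10-min cadence over 1,000 min);
the chromosomal mRFP1 proxy equals capacity by construction, so
reporter accumulations divided by accumulated capacity are comparable to
liquid-culture RPU. Synthase expression follows the local promoter
activity with first-order dilution (0.01/min plus the instantaneous
per-capita growth rate); HSLs are produced proportionally to synthase
times capacity, decay first-order, and exchange between 4-neighbor
squares through a discrete Laplacian with no-flux boundaries. Explicit
Euler stepping is auto-capped at 0.2x the diffusion stability bound
$h^2/4D$ (and at 1 min); a user-supplied step beyond the bound is
rejected with the admissible maximum named. The YFP channel of the
optimized receiver uses a Hill refit of its pLas81 response (default:
basal 1, vmax 500 RPU, EC50 10 nM, slope 2) in all spatial modeling; the
CFP channel uses the equilibrium transfer function.

Effective spatial defaults are deliberately modest about what they claim:
the source data needed to anchor them (inter-square transport, synthesis
and decay rates on membranes) are not available here, so defaults were
chosen once to put the simulator in the regime the engineered system
demonstrably occupies, and are documented as unanchored. Specifically,
inter-square exchange ($D = 0.003$ mm$^2$/min across a 3-mm pitch) is
deliberately an order of magnitude below free-agar AHL diffusivity --
the hydrophobic barrier and losses into the agar bulk make effective
square-to-square transport much weaker than local retention -- and decay
is $5\times10^{-3}$/min. Synthesis rates ($3.5\times10^{-4}$ and
$4\times10^{-5}$ nM/(RPU min) for 3OC6HSL and 3OC12HSL) place the closed
relay loop (pLux76->LasI->3OC12HSL->pLas81->LuxI->3OC6HSL) just above its
ignition threshold when both relay populations share a compartment and
safely below it when they only communicate across squares. In that regime
the package reproduces, and its tests assert, the system's qualitative
repertoire at the experimental horizon of 1,500 min (6,000 min for the
slower stripe wave; the simulated relay wave takes roughly 700-1,500 min
per stripe, slower than the measured system, which is consistent with
the deliberately conservative inter-square transport): receiver gradients
falling monotonically away from sender columns; relay squares in a
uniform bath responding uniformly in the received channel while imprinting
a spatial gradient in the sent channel; alternating relay stripes
propagating a 3OC12HSL trigger down the lattice while relay/non-relay
alternation confines activation to the induced stripes; a checkerboard
igniting and spreading only when seeded with a central mixed population;
and a finite production-scale threshold separating off from on in the
spatially homogeneous loop (`bifurcationScan()`, threshold by coarse scan
plus bisection; always off at scale 0). The checkerboard contrast is
asserted at the observation horizon: the uninduced lattice's basal drift
is slow enough to be invisible there, which mirrors what a finite
experiment can claim.

## Synthetic data

`generatePlate()` emulates the plate fluorometer: capacity-driven
accumulation of a constitutive reference and of model-driven targets,
lognormal multiplicative noise (default CV 10%, an artifact choice -- the
source reports replicate scatter but no error model), additive Gaussian
background, blank wells, 10-min cadence over 1,000 min, doses 10 nM to 25
µM, arabinose 0 to 8 mM through a saturating `AraTransfer` curve. Ground
truth (per-well activities and the design) rides in the experiment
metadata, and generated files round-trip losslessly through
`readPlateCSV()`/`writePlateCSV()`. `generateGrid()` overlays per-square
lognormal noise on simulator trajectories. What the generator does *not*
emulate -- plate-position effects, drift, maturation delays, pipetting
error correlated across a dose ladder -- bounds what passing tests can
say about real data: they validate the estimators and the inference
machinery under the stated noise model, not the biology of any particular
dataset.

Parameter presets (`presetParams()`, `presetDevice()`) are
regime-plausible stand-ins, not measured constants: they reproduce the
documented qualitative structure (affinity ratios of $\sim10^2$ and
$\gg 1$, a LuxR-specific promoter with no measurable LasR affinity, a
LasR-specific promoter with $\sim100\times$ discrimination, a
double-receiver device with maximal activities of roughly 600 and 500
RPU against chromosomal mRFP1 and EC50s of tens of nM) while making no
claim to the unpublished exact values.

## Problem sizes and reproducibility

The validation studies run at sizes chosen to make the full suite a
routine desk check: 20 recovery repetitions at 3 replicates x 12 doses
with 5,000 retained draws; 20 random parameter sets x 100 dose pairs for
the oracle comparison; 12 x 12 checkerboards; 200-well calibration
plates. Every stochastic step takes an explicit seed and is
bit-reproducible; simulations are seed-free and deterministic.
`scripts/acceptance.R --seed N --out results.json` re-runs the whole
battery from scratch and writes the headline numbers as JSON.

## Known limitations

* No stochastic (chemical master equation) simulation: the model is
  deterministic equilibrium plus deterministic lattice dynamics.
* The agar reservoir under the membrane is not an explicit compartment;
  its buffering is folded into effective diffusion and decay, so the
  defaults are effective parameters of this abstraction, and simulated
  wave speeds carry that calibration's imprint.
* No maturation delay on fluorescent reporters; no plate/day random
  effects in the likelihood; no model selection across alternative
  mechanisms.
* Receiver levels are only defined up to the pCat calibration; absolute
  intracellular concentrations are out of reach by construction.
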