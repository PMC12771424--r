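---
title: "Spectro-kinetic analysis of hexacoordinate hemoglobins"
author: "HbKinetics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectro-kinetic analysis of hexacoordinate hemoglobins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HbKinetics)
```

## The problem

Many plant and animal globins are *hexacoordinate*: in the absence of an
exogenous ligand, the distal histidine folds onto the heme iron and occupies
the sixth coordination site. An O~2~ or CO molecule can only bind after the
histidine dissociates, so the endogenous histidine and the exogenous ligand
compete for the same site. This single structural feature reshapes every
measurable binding property: it slows apparent ligand association, lowers
the operative oxygen affinity by a factor of $1 + K_H$, and correlates with
fast autoxidation of the oxy complex. Whether a globin transports oxygen or
does something else entirely often hinges on where it sits on the
pentacoordinate-to-hexacoordinate continuum.

HbKinetics implements the standard spectro-kinetic workflow by which this
continuum is quantified from three kinds of bench data — equilibrium visible
spectra, flash-photolysis / stopped-flow kinetic traces, and timed spectral
series of the oxy complex — together with a forward simulator of the
underlying kinetic scheme so that every analysis stage can be validated
against known ground truth.

## The kinetic scheme

The package's central model is the minimal mass-action scheme in which the
coordination equilibrium and the competition corrections below all hold:

$$\mathrm{Hb_{hexa}} \underset{k_{H,on}}{\overset{k_{H,off}}{\rightleftharpoons}}
  \mathrm{Hb_{penta}}
  \;\;\begin{matrix}
  \overset{k'_{O_2}[\mathrm{O_2}]}{\underset{k_{O_2}}{\rightleftharpoons}} \mathrm{HbO_2} \\[2pt]
  \overset{k'_{CO}[\mathrm{CO}]}{\underset{k_{CO}}{\rightleftharpoons}} \mathrm{HbCO}
  \end{matrix}$$

with ligands in pseudo-first-order excess (concentrations constant over a
relaxation). Units are fixed package-wide: seconds for time (autoxidation
reported in hours and minutes), µM for concentrations, µM⁻¹ s⁻¹ for
bimolecular rates, nm for wavelengths.

`simulateScheme()` integrates this linear system with a stiff-safe solver
(`deSolve::lsoda`, relative tolerance 1e-8, absolute 1e-10). The tolerances
are not cosmetic: a transient-absorption rebinding relaxation
(~4 × 10⁴ s⁻¹ in air) and a stopped-flow displacement (~0.3 s⁻¹) differ by
five orders of magnitude, and the simulator must serve both. Trajectories
renormalize integrator round-off so species fractions sum to one to 1e-9;
the test suite holds the solver to a matrix-exponential solution of the same
linear system to 1e-8 per species.

Deliberate simplifications: photolysis is instantaneous and complete (no
geminate, sub-ns rebinding and no instrument-response convolution — observed
kinetics are fitted as single exponentials after the flash), and there is no
temperature or pH dependence. These match the assumptions under which the
analysis equations below are derived.

## Coordination state from visible spectra

A ferrous-deoxy pentacoordinate heme shows one broad band near 555 nm; the
hexacoordinate bis-histidyl heme splits into bands near 530 and 560 nm with
a trough between them. The empirical reporter is the peak/trough ratio
$A_{555}/A_{540}$ (`peakTroughRatio()`), read at fixed wavelengths by linear
interpolation rather than by local extremum search — robust to noisy
shoulders and faithful to how the ratio is defined.

The ratio maps to the fraction of hexacoordinate heme $F_H$ through an
empirical calibration. The published anchor points are a fully
pentacoordinate reference (leghemoglobin a, ratio 1.2, $F_H = 0$), a fully
hexacoordinate one (neuroglobin, ratio 3.1, $F_H = 1$) and one interior
point (maize Hb1, ratio 1.8, $F_H = 0.48$) — and they are **not collinear**,
so the interior shape of the curve is genuinely uncertain. The design
choice here is to make the calibration a first-class, swappable input
(`CalibrationTable`): the default is monotone piecewise-linear through the
two boundary anchors (`defaultCalibration()`, optionally with the maize
interior anchor), and `calibrationFromBasis()` builds a dense,
self-consistent calibration from any basis-spectrum set, which is the right
choice for simulated data. Ratios outside the anchored range clamp to 0/1.

The coordination equilibrium constant follows from
$$F_H = \frac{K_H}{1 + K_H} \qquad\Longleftrightarrow\qquad K_H = \frac{F_H}{1-F_H}.$$
Estimates with $F_H \ge 0.999$ report $K_H = \infty$ with a warning rather
than a pseudo-precise large number: fully hexacoordinate references have
$K_H$ of order 1000, beyond what a ratio measurement resolves.

```{r coordination}
cal <- calibrationFromBasis()
sp <- equilibriumSpectrum(0.83)          # noiseless ferrous-deoxy mixture
coordinationFromSpectrum(sp, cal)
```

## Ligand-binding kinetics

Every kinetic measurement reduces to a single-exponential fit
$y(t) = \mathrm{offset} + \mathrm{amplitude}\cdot e^{-k_{obs}t}$
(`fitSingleExponential()`), after pointwise averaging of replicates
(`averageTraces()`). The fitter is Levenberg–Marquardt, initialized from a
log-linear regression on the baseline-subtracted signal, with a
deterministic ladder of fallback initial rates because noiseless synthetic
traces sit exactly on the model and can trip rank checks at unlucky starts.
Flat traces return a degenerate result (amplitude 0, no rate); fits with
$k_{obs} \le 0$ or $R^2 < 0.9$ are flagged, never silently accepted.

Three derived quantities follow:

* **Bimolecular association rates** (`bimolecularRate()`): the slope of
  $k_{obs}$ versus ligand concentration. Flash photolysis of the oxy or CO
  complex regenerates the pentacoordinate intermediate, so these slopes are
  association rates *to the pentacoordinate heme*
  ($k'_{O_2,pent}$, $k'_{CO,pent}$). A single-concentration design — e.g.
  O~2~ rebinding in air-equilibrated buffer, taken as 262 µM O~2~ — is
  accepted with a supplied dissociation rate. Negative intercepts are
  reported with a warning and left alone.
* **O~2~ dissociation with CO competition** (`correctO2Dissociation()`):
  mixing oxy-protein with CO-buffer gives an observed displacement rate that
  under-reports $k_{O_2}$, because dissociated O~2~ rebinds in competition
  with CO trapping. The correction
  $$k_{O_2} = k_{obs}\left(1 + \frac{k'_{O_2}[\mathrm{O_2}]}{k'_{CO}[\mathrm{CO}]}\right)$$
  depends only on the concentration *ratio* and is monotone in each
  concentration; these limits are property-tested.
* **Oxygen affinity** (`bindingConstants()`):
  $K_{O_2,pent} = k'_{O_2,pent}/k_{O_2}$ (µM⁻¹) for the pentacoordinate
  intermediate, then the hexacoordination correction
  $$K_{O_2} = \frac{K_{O_2,pent}}{1 + K_H}.$$
  A direct `kO2PentOverride` is supported because published equilibrium
  columns often carry unrounded intermediates that the printed rates cannot
  reproduce exactly; the result records which route was used.

```{r kinetics}
bindingConstants(148, 5.2, kH = fractionToKH(0.83))
```

When only one O~2~ flash concentration is available, the pipeline solves
the transient-absorption and stopped-flow equations jointly (they are
linear in $k'_{O_2}$), instead of assuming $k_{obs} \gg k_{O_2}$.

## Autoxidation

The oxy complex spontaneously oxidizes to the ferric state. The canonical
readout is the absorbance at 575 nm (the oxy alpha-band shoulder) versus
time, fitted to a single exponential **with an offset** — the ferric product
still absorbs at 575 nm, so a decay to zero would be physically wrong. The
rate is reported in h⁻¹ and the half-life as $t_{1/2} = 60\ln 2/k_{ox}$
minutes; the identity is enforced on every emitted result. An optional
cross-check decomposes full spectra onto the oxy/ferric basis pair, but the
575 nm fit is canonical. `autooxReferenceTable()` ships literature
comparison rates as printed (including two rows whose printed rate and
half-life are mutually inconsistent — preserved, and documented, as
source-table discrepancies).

```{r autoox}
fitAutoox(extractTimecourse(autoxidationSeries(kOx = 0.88, duration = 4)))
```

## What the simulator emulates — and what it does not

The generators render every observable the analysis consumes from Gaussian
basis spectra (`defaultBasisSpectra()`): band positions follow the
qualitative features above (555 penta; 530/560 hexa split; oxy alpha/beta
541/576; Soret bands at 403–431 nm so Soret-monitored traces have signal),
while widths and amplitudes are representative shapes chosen once, not
fitted to any instrument. Noise is additive i.i.d. Gaussian per point with
a seed; identical seed and parameters give bit-identical output. Default
time grids span seven half-lives of the expected relaxation.

Passing parameter-recovery tests on these data therefore shows that the
analysis chain is *internally correct* — it inverts its own generative
model to stated tolerances. It does not show robustness to what real
instrument data add: baseline drift, correlated noise, photolysis
heterogeneity, geminate rebinding, spectral overlap beyond two components,
or deviations of the true ratio-to-$F_H$ relationship from piecewise
linearity.

Two modeling choices deserve emphasis:

* **His rebinding in simulated kinetics.** The pipeline's simulated
  flash/stopped-flow experiments use a scheme with distal-His rebinding
  disabled. The analysis equations treat the photolyzed intermediate as
  purely pentacoordinate and ignore His competition (hexacoordination
  enters only through $K_H$ from the equilibrium spectrum); simulating with
  fast His rebinding active would make the single-exponential slope
  estimate $k'/(1+K_H)$ rather than $k'$, i.e. it would test a different
  model than the one the equations define. The full scheme remains
  available in `simulateScheme()` for studying exactly that bias.
* **Stopped-flow concentrations.** Post-mix $[\mathrm{O_2}]$ and
  $[\mathrm{CO}]$ after 1:1 mixing are instrument-dependent and are
  explicit free parameters, never guessed defaults. The worked examples use
  56.2 µM O~2~ / 1000 µM CO, which reproduce a 0.34 s⁻¹ displacement for
  the moss-globin rate set through the competition correction.

## Problem sizes and numerical choices

Defaults used by the examples and test suite: 200-point flash traces,
400-point stopped-flow traces, 25-spectrum autoxidation series at 1 nm
spectral resolution, 10 replicates averaged when noise is on. These are
representative of averaged bench data while keeping any simulation under a
second. Other fixed choices: exponential-fit convergence at relative 1e-12
(ftol) / 1e-10 (ptol) with at most 200 iterations; acceptance flag at
$R^2 \ge 0.9$; $F_H$ clamped to $[0,1]$ before inversion with the $K_H$ cap
at $F_H = 0.999$; trace containers require ≥ 3 points, three-parameter
fits ≥ 8.

## Known limitations

Single-exponential models only (no biphasic or stretched kinetics, no
global multi-trace fitting); O~2~ and CO only (no NO chemistry); the
ferric-state coordination is treated qualitatively (no ferric $K_H$); no
mechanistic autoxidation model (superoxide pathways, pH dependence); and
the empirical ratio-to-$F_H$ curve is exactly as good as the calibration
anchors supplied to it.
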