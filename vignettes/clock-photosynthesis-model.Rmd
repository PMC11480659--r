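---
title: "A forced clock model of photosynthesis under skeleton photoperiods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A forced clock model of photosynthesis under skeleton photoperiods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(circaphoto)
```

## The model

`circaphoto` models how the tea plant circadian clock relays photoperiod
information to photosynthesis. The core is a nine-variable
transcription–translation feedback loop over four merged transcript/protein
pairs — MCL/CL (*CCA1/LHY*), MP97/P97 (*PRR9/PRR7*), MP51/P51
(*PRR5/TOC1*), MEL/EL (*ELF4/LUX*) — plus the activated fraction P of a
photosensitive protein. Regulatory edges use squared Hill factors: the
decreasing form $1/(1+(X/K)^2)$ for repression and the increasing form
$(X/K)^2/(1+(X/K)^2)$ for activation. Translation and degradation are mass
action. Light enters three ways:

* a binary forcing $L(t)\in\{0,1\}$ from a `photoperiod_schedule` (with
  $D(t)=1-L(t)$), covering the experimental regimes 12L12D, 24L, and the
  skeleton photoperiods 6L6D and 3L3D, all referenced to ZT0 = lights-on;
* an acute dawn response: P obeys
  $dP/dt = p_{on}(1-P)D - p_{off}PL$, accumulating in darkness and being
  consumed by light, so the product $L(t)P$ spikes at dawn and acutely
  activates *CCA1* and *PRR9* transcription;
* the clock input LWD1, which has no modelled upstream regulator and is
  imposed as a second-order Fourier series. Under constant light the
  printed coefficient set with fundamental period 26 h is used; under
  entrained photoperiods the same waveform runs at the 24 h cycle length.

Six output variables (transcript/protein pairs for *Lhcb1*, *RbcS1*,
*atpA*) hang off CL: *Lhcb1* is CL-activated with a direct light term (day
peak), *RbcS1* and *atpA* are CL-repressed (night peaks). The four measured
photosynthetic parameters ($P_n$, $G_s$, $C_i$, $T_r$) are algebraic,
memoryless functions of the state,

$$P_i = \alpha_i + \frac{[CL]^2}{K_{i1}^2+[CL]^2}
      + \sum_{j=1}^{3}\frac{[X_j]^2}{H_{ij}^2+[X_j]^2},$$

bounded in $[\alpha_i, \alpha_i+4]$ and non-decreasing in every input.
The full model exposes 15 state variables and exactly 56 named parameters:
24 clock kinetic constants, 12 photosynthetic-gene kinetic constants, and
the 20 output-map constants $(\alpha_i, K_{i1}, H_{i1..3})$.

Because 56 parameters must cover 15 equations, some constants are shared
deliberately: one translation rate for the four clock proteins, one
degradation rate for the three non-*CCA1* clock transcripts, one EL
repression half-saturation for its two targets, one CL repression
half-saturation for MP51/MEL, one LWD half-saturation, one acute-light
coefficient, and one translation/degradation pair for the three photogene
proteins. MCL keeps separate light and dark turnover rates
(dark-stabilized), which is what produces the first-cycle peak delay when
darkness never comes.

## Simulation protocol

```{r}
m <- clock_model(schedule = "12L12D")
m
```

Integration uses the classical fixed-step fourth-order Runge–Kutta method
(`integrate_rk4()`), `dt = 0.05` h by default. The step divides 1.5 h, so
every light/dark switch of the experimental schedules falls on a grid
point; the final RK4 stage is evaluated infinitesimally inside the step so
no stage ever samples the forcing in the wrong light regime. The initial
state is 0.1 for all abundances and 0 for P; every reported simulation is
preceded by seven days of 12L12D entrainment (`entrain_then_switch()`),
mirroring the experimental acclimation, after which results are
insensitive to the initial state (checked to < 1% RMS against a 14-day
entrainment).

```{r}
tr <- entrain_then_switch(target = "12L12D", post_days = 5)
estimate_period(trajectory_series(tr, "M_Lhcb1"))
```

## Dynamical design of the basal parameter set

The packaged basal set was calibrated once (`scripts/calibrate.R`) against
the qualitative anchors reported for the entrained plant — CL transcript
peaking at dawn, P97 mid-morning (ZT6–9), P51 at dusk (ZT12), EL early
night (ZT12–15), *Lhcb1* in the light phase, *RbcS1*/*atpA* in the dark
phase — and two quantitative behaviours: a ~24.1 h entrained period and a
~25.9 h free-running period with a 1–2 h peak delay under constant light.
It is version-pinned in `default_clock_params()` and not revisited.

Two design points are worth stating plainly:

* **The free-run rides on LWD1.** Under constant light the binary forcing
  is silent and the dawn pulse dies out (P is consumed), so the only
  periodic drive left is the 26 h LWD1 series — exactly the input the
  original workflow fitted from constant-light expression data. The core
  loop is damped on its own, but its leading oscillatory mode (period
  ≈ 27.7 h under constant conditions) sits close to the forcing frequency
  and acts as a resonator: it amplifies the 26 h fundamental roughly
  five-fold over the 13 h harmonic of the bimodal LWD1 waveform, giving a
  clean once-per-cycle free-run that locks to 26.0 h after a transfer
  transient of about two cycles.
* **Transfer transients are excluded from period estimates.** Because
  re-phasing from the entrained state to the free-running phase takes
  roughly two cycles (the first peak-to-peak interval is ~28.5 h), the
  free-running period is estimated after discarding the first
  post-transfer day. This is the usual windowing choice in circadian
  rhythm analysis; with it the 6-day estimate is 26.11 h.

## Rhythm statistics

`estimate_period()` locates peaks as strict local maxima above the series
midrange. Densely sampled series are first smoothed with a running mean
spanning one-twelfth of the expected period so that sampling noise cannot
split a crest (candidates whose smoothing window is truncated at the
boundary are discarded); each surviving peak is refined by a least-squares
quadratic around the maximum. Period is the mean successive peak-to-peak
interval, phase the first peak time modulo the period, amplitude half the
raw peak-to-trough span. Fewer than two peaks raise a
`rhythm_undetectable` condition — the arrhythmic regime seen under the
short skeleton photoperiod — and such series contribute only to the SSE
term of the extended cost.

The fitting costs follow the printed conventions: `mse()` is a **sum** of
squared errors (not divided by $n$; a normalized variant sits behind a
flag), `cost_simple()` sums it over the photosynthetic genes, and
`cost_optimal()` adds squared peak-time and squared period differences
over the extended gene set, with phase differences wrapped to half a
period (unweighted, since no weighting is specified) so that a shift by a
full period costs nothing.

## Parameter estimation

`fit_fourier()` is exact linear least squares at fixed fundamental period
(the 26 h constant-light period is imposed, matching the printed
equation's hard-coded $2\pi/26$). `fit_output_params()` estimates the 20
output-map constants from photosynthetic-parameter time courses under the
constant-light training photoperiod with all 36 kinetic constants frozen;
the clock trajectory is simulated once, so the objective is a smooth
function of the 20 parameters and each output's five parameters separate.
We therefore use bounded quasi-Newton (`L-BFGS-B`) local searches —
half-saturations on a log scale — from Latin-hypercube start points under
a fixed seed; the best converged start wins, and identical inputs and
seed give identical results. Held-out photoperiods are predicted by
changing only the light input (`predict_under_photoperiods()`).

## Synthetic data

`generate_expression_dataset()` emulates the study's RT–qPCR design:
3 biological replicates, sampling every 3 h (1.5 h for 3L3D), values
formed as a rhythmic truth (model trajectory or parametric cosine) times
log-normal noise with `sdlog = 0.1` — fold-change error is multiplicative,
and the reference gene is assumed perfectly stable, matching the
$2^{-\Delta\Delta C_t}$ normalization assumption. The stomatal generator
reproduces the published table's layout (mean ± SE of three
pseudo-replicates per photoperiod and time). What these generators do
*not* emulate: amplification-efficiency differences, plate effects,
reference-gene instability, inter-plant phase dispersion, or any coupling
between replicates — so passing recovery tests demonstrate correctness of
the estimation machinery under the stated noise family, not robustness to
real qPCR artefacts.

## Numerical choices and degenerate inputs

* RK4 at `dt = 0.05` h agrees with an independent adaptive reference
  solver to < 10⁻⁴ relative RMS over ten days and changes by < 10⁻⁵ RMS
  when the step is halved.
* Schedules are half-open blocks `[start, end)` tiling the cycle exactly;
  construction rejects gaps, overlaps and non-positive cycle lengths.
* Hill functions reject non-positive half-saturations; derivative
  evaluation rejects negative states, and the integrator clamps round-off
  negatives to zero before evaluating rates.
* Aliased Fourier sampling grids (e.g. sampling at half the fundamental
  period) are reported as rank-deficient designs, not silently dropped.

## Known limitations

* **The rate equations are this package's own formulation.** The network
  wiring follows the tea-plant clock architecture (LWD1 activating
  *CCA1*, *PRR9* and *TOC1*; the PRR/TOC1 and evening-complex repressions)
  and the Hill/mass-action reaction grammar, and the basal numeric values
  are calibrated to the reported behaviour — phases, periods, delays —
  rather than taken from a published parameter table. Behaviour-level
  agreement is what the tests check; trajectory-level agreement with any
  other implementation is not claimed.
* **The autonomous core is damped.** Free-running rhythmicity requires
  the LWD1 forcing. Whether the plant's clock (or the original model) is
  self-sustained without LWD1 cannot be decided from the available text.
* **Practical identifiability of the output map is poor at study-like
  noise.** With 10% multiplicative noise on the photosynthetic-parameter
  series, several of the 20 output constants are not recoverable: the
  basal level $\alpha_i$ is nearly collinear with Hill terms whose inputs
  traverse only a saturated arc, and the antiphase *Lhcb1* and
  *RbcS1*/*atpA* contributions partially cancel, leaving a peak-to-trough
  signal (≈ 0.3 units on a 2.7-unit level for $P_n$) below the noise
  floor. Fits at that noise level routinely achieve a *lower* cost than
  the generating parameters, so this is an information limit of the
  design, not an optimizer failure. Noiseless recovery is within 10% for
  all 20 constants; noisy recovery of the full vector should not be
  expected, and fitted half-saturations from single noisy datasets should
  be read as curve descriptors, not as biochemical constants.
* Problem sizes used throughout the tests and examples (5–10 simulated
  days, 3 h grids, tens of optimizer starts) match the scale of the
  original experimental design; all are arguments if you need more.
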