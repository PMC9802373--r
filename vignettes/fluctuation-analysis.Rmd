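---
title: "Measuring topological domains in supercoiled DNA from extension fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring topological domains in supercoiled DNA from extension fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plectofluct)
```

## The physical problem

A double-stranded DNA molecule tethered between a surface and a magnetic
bead can be held at a fixed stretching force $f$ while magnet rotations fix
its linking number $Lk$. Overwinding by $\Delta Lk$ turns (supercoiling
density $\sigma = \Delta Lk / Lk_0$) first twists the stretched molecule and
then, past a force-dependent buckling density $\sigma_s$, nucleates a
plectoneme: an interwound superhelix that absorbs contour length and linking
difference. The instrument observable is the bead height, i.e. the
end-to-end extension $z(t)$.

This package implements a complete in-silico counterpart of such an
experiment and its analysis:

* an analytical model for the mean $\langle z\rangle$ and variance
  $\langle \Delta z^2 \rangle$ of the extension,
* a Metropolis Monte Carlo simulator of a discretized, self-avoiding,
  twistable wormlike chain at fixed linking number, with optional
  protein-bridging constraints,
* generators of synthetic bead-tracking traces with the statistical
  structure the analysis assumes, and
* the fluctuation-analysis pipeline that turns variance changes into
  looped-domain sizes, plectoneme torsional stiffness, and loop kinetics.

The central idea is that a protein bridging two sites inside a plectoneme
pinches off a *topological domain* of length $\Delta L$. The mean extension
is unchanged, but the extension variance drops by an amount proportional to
$\Delta L$, so fluctuations report domain formation and size in real time.

## Analytical model

Mean and variance follow from force derivatives of the free energy per
length $\mathcal F$:
$$\frac{\langle z\rangle}{L} = -\frac{d\mathcal F}{df}, \qquad
  \frac{\langle \Delta z^2\rangle}{L} = -k_BT \frac{d^2 \mathcal F}{df^2}
  = \frac{k_BT}{L}\frac{d\langle z\rangle}{df}.$$

**Stretched phase.** We use the Moroz–Nelson high-force form
$\mathcal S(\sigma; f) = -g(f) + \tfrac12 k_BT\, c_s(f)\, \omega_0^2
\sigma^2$ with $g(f) = f - \sqrt{k_BT f / A}$ the stretched-wormlike-chain
free energy and $c_s(f) = C\,[1 - \tfrac{C}{4A}\sqrt{k_BT/(Af)}]$ the
force-renormalized twist stiffness; $\omega_0 = 2\pi/(\text{helical repeat}
\times \text{rise})$. Defaults: $A = 40$ nm, $C = 100$ nm, repeat 10.5
bp/turn, rise 0.34 nm/bp, $T = 298$ K.

**Plectonemic phase.** A quadratic form with a constant effective torsional
stiffness $P$: $\mathcal P(\sigma) = \tfrac12 k_BT P \omega_0^2 \sigma^2$,
independent of force; default $P = 20$ nm.

**Coexistence.** Between $\sigma_s$ and $\sigma_p$ the equilibrium free
energy is the common tangent between $\mathcal S$ and $\mathcal P$, linear
in $\sigma$, giving
$$\frac{\langle z\rangle}{L} = \Gamma\,(\sigma_p - \sigma), \qquad
  \frac{\langle \Delta z^2\rangle}{L} =
  k_BT\Big(\frac{\partial\Gamma}{\partial f}(\sigma_p - \sigma)
        + \Gamma\frac{\partial \sigma_p}{\partial f}\Big).$$
Because both free energies are quadratic, the tangency conditions admit a
closed-form solution (implemented in `solve_coexistence()` and verified in
the tests against a brute-force grid minimization). Force derivatives are
taken by Richardson-refined central differences with a relative step of
$10^{-3}$; the closed-form mean extension makes these derivatives smooth
and accurate to much better than the $10^{-3}$ tolerance the test suite
enforces on the fluctuation–response identity.

The variance-per-length approaches
$$\kappa \equiv k_BT\, \Gamma\, \frac{\partial \sigma_p}{\partial f}$$
as $\sigma \to \sigma_p$. When a loop of length $\Delta L$ is pinched off
inside the plectoneme, the unlooped DNA keeps the same two-phase structure
with $L^* (\sigma_p - \sigma^*) = L (\sigma_p - \sigma)$, so the mean
extension is unchanged while the variance drops by $\kappa\, \Delta L$.
Inverting this relation is `infer_domain_size()`; $\kappa$ itself is
obtained by `calibrate_fluctuations()` exactly as in the experimental
protocol — extrapolate the linear postbuckling $\langle z\rangle$ to zero
(giving $\sigma_p$), then extrapolate the linearly increasing part of
$\langle \Delta z^2\rangle$ to $\sigma_p$ and divide by $L$.

```{r theory-example}
cx <- solve_coexistence(0.5)
cx
```

Known limitation (inherited from the model): the two-phase prediction
overestimates the absolute postbuckling slope; only its force *scaling*
($\Gamma \propto f^{-1/2}$, and $f^{-3/2}$, $f^{-5/2}$ for the variance
quantities) is quantitative, and that is what the acceptance tests assert.
Underwound DNA ($\sigma < 0$) and the fully plectonemic branch
($\sigma > \sigma_p$) are out of scope; the corresponding inputs are
refused rather than extrapolated.

## Monte Carlo simulator

The chain is a string of beads with exact segment length $a$ (default 2.5
nm; the campaigns below use $a = 5$ nm, see *Problem sizes*). Energies, in
units of $k_BT$:

* bending $(A/a)\sum_i (1 - \cos\theta_i)$,
* implicit twist $(2\pi^2 C/L)(\Delta Lk - Wr)^2$ — no per-bead triads; the
  twist is assumed uniformly distributed, so topology enters through the
  writhe only,
* stretching $-f z / k_BT$,
* a stiff harmonic alignment ($10 A/a$ per $1-\cos$) keeping the top
  tangent along the pulling axis; the bottom two beads are clamped.

The writhe uses the open-chain convention with both termini extended by
long vertical rays, computed as the exact closed-form Gauss integral over
straight segment pairs. During move evaluation, pairs of chain segments
whose midpoints are farther apart than $\max(18, 5a)$ nm use midpoint
quadrature of the Gauss integrand (error $O((a/r)^2)$ of an already tiny
term); every sampling point refreshes the writhe with the fully exact sum,
so bookkeeping drift cannot accumulate.

Moves are rigid rotations about an axis through a fixed bead: crankshaft
rotations of interior subchains, short pivots of the top tail, and
occasional pivots based anywhere along the chain (5% of proposals). The
long pivots matter: extension only changes through pivot moves, and the
slow mode of the postbuckling chain is the exchange of contour between the
stem and the plectoneme. Excluded volume (hard-core diameter 4 nm,
approximating electrostatics near 150 mM monovalent salt) is enforced by
sub-stepped sweep checks during the rotation plus an exact
segment–segment distance check of the final position; the hard core
applies beyond a contour separation of twice the excluded diameter, since
closer neighbours are governed by the bending potential and such short
loops cannot be threaded. Any move changing the writhe by more than 0.5
turns is additionally rejected as a strand-passage sentinel, so the
linking number is conserved exactly along a trajectory.

Postbuckling runs start from a pre-built interwound superhelix whose turn
count and contour are sized from the package's own two-phase solution
(equilibrium twist from the coexistence torque, plectonemic contour from
the lever rule), with one corrective rebuild to hit the target writhe.
This places the chain close to its equilibrium topology so that the
remaining relaxation is local. Equilibration is monitored by drifting
block means of $z$ and flagged with a warning.

Protein bridging is simulated by constraining two site beads (chosen by
`select_bridge_sites()`: mutual distance < 8 nm, both plectonemic,
antiparallel tangents): every proposal that would move one site without
the other — or either site's tangent bead — is rejected, while moves that
carry both rigidly are allowed, so the relative position *and* orientation
of the sites are preserved exactly (verified at every sampling point, with
an abort on drift). The linking number trapped in the loop is the writhe
of the chord-closed loop subchain plus its per-length share of the uniform
twist.

## Synthetic traces

`generate_ou_trace()` draws exact stationary Ornstein–Uhlenbeck samples at
the acquisition rate (default 1 kHz), the harmonic-well surrogate for bead
tracking: variance, correlation time and friction obey
$\tau_c = (\gamma/k_BT)\langle\Delta z^2\rangle$ by construction.
`generate_switching_trace()` adds continuous-time Markov switching among
discrete extension levels: dissociation/rebinding events at rate
$1/\tau_p$ whose destination is drawn from the stationary occupancies
(self-transitions allowed), which makes the observed dwell time in state
$i$ exponential with mean $\tau_i = \tau_p/(1 - p_i)$. Occupancies default
to a Gaussian in the trapped linking number with variance $\Delta L/(4\pi^2
P)$; the defaults ($\Delta L = 254$ nm, $P = 20$ nm, $\tau_p = 65$ s,
spacing 48 nm/turn) mirror the two-site enzyme observations this kind of
experiment produces. Camera blur and instrument drift are deliberately not
modelled (correlation times exceed the 1 ms sampling interval), and
state-dependent noise variance is off by default — so passing recovery
tests demonstrate the pipeline's statistical correctness, not robustness
to instrument artifacts.

## Analysis pipeline

* `windowed_stats()` — non-overlapping windows (default 1 s), per-window
  mean subtraction (suppressing slow drift), pooled unbiased variances,
  standard errors from window scatter.
* `autocorrelation_time()` — FFT autocorrelation integrated to its first
  zero crossing.
* `fit_rotation_curve()` — even quadratic prebuckling branch + linear
  postbuckling branch, split chosen by total residual sum of squares,
  buckling density from the branch intersection.
* `calibrate_fluctuations()` — the extrapolation protocol for $\sigma_p$
  and $\kappa$, with parametric-bootstrap confidence intervals. The
  variance fit can be windowed (`var_sigma_max`) to the regime where it
  still increases linearly — essential for short molecules, whose variance
  flattens early by finite size.
* `segment_states()` — 10 s sliding-average filter, level discovery from
  density peaks (with a prominence criterion suppressing bumps on
  transition ramps) constrained to a common spacing, nearest-level
  assignment with a hysteresis of 0.25 spacing. The hysteresis constant
  and the peak-prominence ratio (0.6) are our choices where the published
  protocol is silent.
* `plectoneme_stiffness()` — weighted log-quadratic fit of occupancies
  versus state index (free center), $P = \Delta L/(4\pi^2\langle \Delta
  \Delta Lk^2\rangle)$; exact on exactly Gaussian input.
* `dwell_time_analysis()` — dwells from the assignment run lengths; first
  and last (censored) dwells dropped; dwells shorter than the filter
  window excluded (the sliding average cannot resolve them) with the count
  reported; the left-truncated exponential MLE is simply
  $\hat\tau = \overline{d} - w$; per-state $\tau_p = (1 - p_i)\tau_i$; the
  summary $\tau_p$ averages the three most populated states.

## Problem sizes and numerical choices

The simulation campaigns in the tests and in `scripts/acceptance.R` use a
2 kbp molecule ($L = 680$ nm) at $f = 0.5$ pN with bead spacing $a = 5$ nm
(136 segments), independent replicas per linking number (3–4), and runs of
$4{-}5\times 10^5$ Metropolis steps each — a deliberate desk-scale choice:
the per-turn extension slope is contour-length independent in the
two-phase picture, so a short molecule stands in for the experimental 7.9
kbp construct. Two finite-size consequences are handled explicitly: the
linear postbuckling window of $\langle z\rangle$ ends near $\sigma \approx
0.05$ (the slope is fitted inside the window), and the variance increases
linearly only in early postbuckling (the calibration windows its variance
fit accordingly, and bridged loops are kept well below the full plectoneme
size). Replica scatter, not single-trajectory block averages, provides the
standard errors of campaign-level quantities; within a run, block averaging
is used.

Synthetic-trace studies use 100 Hz acquisition for multi-hour kinetics
recordings (the state dwell times of tens of seconds are unaffected by the
sampling rate) and 1 kHz elsewhere.

## What the validation shows — and does not

The test suite checks every estimator against forward-constructed ground
truth (exact algebraic inversions, OU closed forms, competing-exponential
dwell identities), checks the simulator against independent physical
oracles (discrete-wormlike-chain bend statistics, stretched-chain
extension, writhe quadrature), and checks the pipeline end-to-end on
simulated bridging. None of this certifies behaviour on real instrument
data with drift, blur, or heterogeneous tethers — those effects are
explicitly outside the generators' scope.
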