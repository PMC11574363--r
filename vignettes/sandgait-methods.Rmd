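---
title: "Walking on deformable sand: models and methods in sandgait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walking on deformable sand: models and methods in sandgait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sandgait)
```

## The scientific problem

When humans walk on sand, the foot sinks into the substrate and energy is
lost to its deformation. How much the gait changes — in timing, step
geometry, joint kinematics, muscle activation and the pendulum-like exchange
between potential and kinetic energy of the body's centre of mass (CoM) —
depends on how deep the foot sinks. `sandgait` implements the full
computational chain used to quantify these adaptations from synchronized
motion-capture (200 Hz markers, lab frame with z up and z = 0 at the hard
floor) and surface EMG (1110 Hz) recordings of walking passes over
substrates of graded sinkage depth, together with the statistical battery
used to compare substrates. Because studies of this kind rarely deposit raw
recordings, the package also contains a first-class synthetic study
generator with complete ground truth, so that every stage of the pipeline is
validated by parameter recovery rather than by eyeballing.

## Gait events and strides

Heel-strike and toe-off are detected from marker coordinates alone with the
classic coordinate-based rule: in the progression direction (signed by
`travel_direction`), the heel marker is furthest ahead of the sacral marker
at heel-strike and the hallux marker is furthest behind it at toe-off. So a
heel-strike is a local maximum of $s\,(x_\text{heel} - x_\text{SACR})$ and a
toe-off a local minimum of $s\,(x_\text{hallux} - x_\text{SACR})$.

Numerical choices, made once and exposed as arguments:

* The relative-position signal is low-pass filtered before peak picking
  (zero-phase Butterworth, 10 Hz cutoff, 2nd order per pass). Without this,
  millimetre-scale marker noise creates spurious micro-peaks.
* Candidate peaks must be separated by at least half the dominant period of
  the signal (estimated by FFT); ties on flat maxima go to the earliest
  frame.
* Toe-offs outside the span of detected heel-strikes (partial cycles at the
  trial edges) are discarded; a per-trial QC report
  (`event_qc()`) flags cycle-time outliers beyond 3 MAD in place of manual
  event checking.

Strides run from one heel-strike to the next ipsilateral heel-strike and are
invalidated (with a reason, never silently dropped) when they lack exactly
one interior toe-off or overlap a marker gap.

## Spatiotemporal parameters and foot sinkage

Per stride: cycle time, stance time (heel-strike to toe-off), swing time,
duty factor (stance/cycle), speed (mean progression velocity of the sacral
marker across the stride), stride length (ipsilateral heel x-displacement
between consecutive strikes) and stride width (lateral heel separation at
the stride's two strikes). Double support is computed from both sides' event
sequences as the time within the stride when both feet are in stance; when
the contralateral stance state at the stride start is unknown (no earlier
contralateral strike in the trial), it is reported missing rather than
undercounted. For perfectly periodic symmetric gait the identity
$t_{ds} = T_{cycle}(2\,DF - 1)$ holds to one frame, and the test suite
verifies this on generator output with stride-to-stride cycle variation
disabled; with natural cycle variability the identity is only approximate,
which is why it is not asserted on the default conditions.

Foot sinkage uses the published proxy: the substrate surface height minus
the lowest vertical position of the calcaneus and hallux markers within each
stride, in cm. Negative values (marker minimum above the surface, as happens
on the hard floor) are reported as-is and QC-flagged rather than clipped, so
calibration offsets remain visible. Left and right are pooled downstream.

The coefficient of variation (sd/mean) is computed on strides pooled across
participants per substrate — one CV per variable per substrate — with
relative changes reported against the hard floor.

## CoM energetics: R, RA and CO

The whole-body CoM comes from a 13-segment anthropometric model (bilateral
feet, shanks, thighs, upper arms, forearms-with-hands, plus head, trunk,
pelvis) with Dempster/Winter mass and CoM fractions shipped as an editable
CSV. Each segment CoM is $p_{prox} + f\,(p_{dist} - p_{prox})$ and the body
CoM the mass-fraction-weighted sum. A precomputed CoM channel (as exported
by kinematic-modelling software, or by the generator) can be mapped to the
schema role `COM` and used directly — the documented bypass.

Energies per stride: $E_{pot} = m g z$ ($g = 9.81$), $E_{kin} =
\tfrac12 m |v|^2$ with all three velocity components (a sagittal-only switch
exists), $E_{tot} = E_{pot} + E_{kin}$ exactly. Velocity is obtained by
central differences on the low-pass-filtered CoM. The filter is a
linear-phase windowed-sinc FIR at 10 Hz (1 Hz transition band), centred so
it is exactly zero phase, with unit DC gain so constants and linear trends
pass unchanged. Two choices here are deliberate and were revised during
development. First, the FIR's flat passband: Butterworth designs at these
low normalised cutoffs both droop in the passband and ring at the edges,
and the exchange statistics are sensitive to the kinetic-energy amplitude
and to the sample-level sign of its increments. Second, the 10 Hz cutoff
rather than the 6 Hz sometimes used for gait CoM: the CoM *speed* of
walking carries genuine harmonics above 5 Hz (the square-root relation
between kinetic energy and speed generates them even for a sinusoidal
energy), and a 6 Hz cutoff removes real signal, measurably biasing
congruity; at 10 Hz the pipeline matches the brute-force energy oracle to
a fraction of a unit on every synthetic stride. All zero-phase filters in
the package use odd-reflection padding, because unpadded forward-backward
filtering leaves edge transients long enough to corrupt the first and last
stride of a trial.

With sample increments $\Delta$, positive-increment (external-work) sums
$W_v = \sum \Delta E_{pot}^+$, $W_f = \sum \Delta E_{kin}^+$,
$W_{ext} = \sum \Delta E_{tot}^+$ give

* recovery $R = 100\,(W_v + W_f - W_{ext})/(W_v + W_f)$ (%),
* relative amplitude $RA$ = peak-to-peak $E_{pot}$ / peak-to-peak
  $E_{kin}$ (the amplitude-ratio convention; a work-ratio alternative is a
  documented open convention, and the direction of substrate effects is
  unchanged),
* congruity $CO$ = percentage of samples where the two energies move in the
  same direction, among samples where both move; increments below
  $10^{-12}$ J are treated as "not moving" to avoid sign(0) ambiguity.

$R = 100$ iff $E_{tot}$ is constant (the ideal pendulum); in-phase energies
give $R = 0$, $CO = 100$; quarter-phase gives $CO = 50$. These limits are
asserted exactly in the tests, and every synthetic stride's pipeline value
is compared against an independent brute-force oracle implementation
(`oracle_exchange()`, explicit loops, no shared code).

## Joint kinematics

Sagittal hip, knee and ankle angles are computed from three joint-centre
points projected on the plane of progression, not from a 6-DoF segment
model: commercial modelling software's conventions are proprietary, so
the package fixes its own and documents them — hip and knee flexion
positive, ankle dorsiflexion positive with the shank-foot angle offset by
90° so anatomical neutral reads 0°. ROM is per trial (max − min over all
samples), even though curves are analysed per stride. Per-stride curves are
normalised to 101 nodes (0–100% cycle, node 0 at heel-strike) by cubic
splines, exact on cubic polynomials and with endpoints preserved — the
standard grid for gait curves and the input format of the SPM stage.

## EMG

The chain follows standard practice for gait EMG: second-order Butterworth
high-pass at 12 Hz, applied forward-backward (zero phase; a single-pass
switch exists for strict comparisons with causal chains), full-wave
rectification, per-participant normalisation (every sample divided by that
participant's maximum rectified amplitude across all their trials per
muscle, so the participant maximum is exactly 1), stride cropping, and
trapezoidal integration over real stride time (iEMG, normalised amplitude ×
seconds). Time-based integration is the default because stance times differ
between substrates and cycle-normalised integration would hide exactly that
effect; a `cycle_normalized` switch provides the alternative. No envelope
smoothing is applied before integration; the 101-node nEMG curves for
plotting and SPM are rectified samples averaged within each cycle bin.

## The statistical battery

**Paired t-fields (1D-SPM).** Curves are averaged to one per participant
per condition first (required for a valid paired test; whether source
studies did this is typically unstated), then a paired t statistic is
computed at each of the 101 nodes. Field smoothness is estimated from
unit-variance-normalised residuals: with $v$ the mean squared node-to-node
gradient, $\text{FWHM} = \sqrt{4\ln 2 / v}$ (unit-variance white noise has
$v = 2$, FWHM ≈ 1.18 nodes). The random-field-theory critical threshold
solves $\alpha_{tail} = 1 - \exp\{-(\rho_0(u) + R_1 \rho_1(u))\}$ with
$R_1 = 100/\text{FWHM}$ resels, $\rho_0$ the t upper-tail probability and
$\rho_1(u) = \frac{\sqrt{4 \ln 2}}{2\pi}(1 + u^2/\nu)^{-(\nu-1)/2}$, by
monotone bisection on $u \in [0.5, 50]$ to $10^{-6}$. Tests are two-sided
(substrate differences can go either way), with alpha split across tails,
and Bonferroni-divided across the 6 pairwise substrate comparisons. The
zero-resel limit recovers the scalar t quantile. A sign-flip permutation
threshold (max-|t| distribution, exhaustive below $2^n$ patterns,
deterministic given a seed) serves as the nonparametric oracle; the suite
checks that RFT and permutation agree within 5% on matched smooth Gaussian
nulls, that the empirical family-wise error over 500 smooth-null
simulations stays in [0.025, 0.085], and that a 1-sd effect spanning nodes
20–40 is detected in ≥ 90% of replicates at n = 21. Calibration
simulations draw unit-variance smooth Gaussian fields by convolving white
noise with an $\ell_2$-normalised Gaussian kernel — normalising each field
by its own sample sd instead would distort the field distribution and bias
the power estimate. Cluster-level p-values are out of scope; clusters are
reported as significance regions.

**ANOVA + Tukey** on pooled sinkage depths delegates to R's `aov` and
`TukeyHSD` (the studentized-range machinery), with the degenerate
all-identical case returning F = 0, p = 1 explicitly. A hand sums-of-squares
oracle and a type-I-rate simulation guard it.

**Spearman correlograms** use average ranks for ties, p-values from the
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation, and order variables by the
first principal component of the correlation matrix (leading eigenvector,
sign fixed so its largest-magnitude entry is positive, loadings descending).
Inputs are trial means — one row per trial — matching how such correlograms
are built in practice; constant variables are flagged, not fatal.

**Linear mixed models** delegate to `lme4`/`lmerTest` (REML, random
intercept per participant, Satterthwaite degrees of freedom), exactly the
tooling such studies use themselves; the package's contract is therefore
validated by parameter recovery (a simulated −0.15 m/s substrate effect on
speed recovered within 3 s.e.; 95% CI coverage within [90%, 99%] over 200
null replicates), not by re-implementing the estimator.

## The synthetic study generator

`simulate_study()` emulates the study design: 21 participants (alternating
sexes, body mass ~ N(68.5, 9.2) kg, stature ~ N(1.73, 0.10) m), 3 hard-floor
and 5 trials per sand substrate each, 200 Hz markers, 1110 Hz EMG. Defaults
were chosen once to sit in the regime the study reports and are not
re-tuned: heel sinkage means 2.08/2.68/4.09 cm and hallux 3.43/4.26/5.23 cm
(wet building / dry building / play sand) with the observed spreads; mean
speeds 1.35/1.25/1.15/1.10 m/s declining as sinkage deepens across
substrates, while *within* a substrate depth couples positively to speed
(+0.8 cm per m/s); cycle times 1.02–1.14 s, duty factor 0.62; 1 mm marker
noise (typical optical mocap).

The generator controls the CoM analytically: the vertical position
oscillates twice per stride with amplitude 2.5 cm, and the kinetic energy is
*prescribed* as a sinusoid with configurable phase against the potential
energy (`ep_ek_phase`; 180° is the ideal pendulum), the progression speed
being back-solved from it. This construction makes the ideal limits exact
(matched amplitudes at 180° give oracle R = 100% on every stride) and the
phase sweep monotone. The default phase (170°) and kinetic amplitude
(0.08 m/s speed fluctuation) put default recovery near 59%, the magnitude
reported for human walking on these substrates. The generated CoM is
emitted as a direct `COM` channel alongside a full 13-segment skeleton; the
skeleton's legs are driven by two-harmonic joint-angle templates (generic
walking shapes with per-substrate constant flexion offsets ordered by
sinkage depth), so the angle stage recovers its templates exactly.
Ground-truth R/RA/CO are computed from the generated energy series by the
brute-force oracle; pipeline-vs-oracle comparisons run the real chain on
the `COM` channel, while the 13-segment weighted-sum path is verified
against an explicit-loop oracle and exercised end-to-end separately. Event
times are snapped to the 200 Hz frame grid so "within ±1 frame" recovery is
well-defined, and the right foot strikes at the midpoint of consecutive
left strikes (locally symmetric gait).

What the generator does **not** emulate: ground-reaction forces and
step-to-step collision work, foot slip, marker occlusion patterns, soft
tissue artefact, realistic waveform idiosyncrasies beyond two harmonics,
and any physics of sand deformation (stance-phase dips are half-sines of
the drawn depth). Passing recovery tests therefore demonstrates the
*pipeline's* correctness on data with known truth — not that real sand
data will be this clean.

## Problem sizes and determinism

The recovery tests run the full 21-participant study (378 trials, ≈ 7500
events, > 6000 strides) once per condition; calibration simulations use 500
replicates for FWER and power, 200 for CI coverage, 10 for RFT-permutation
agreement — sizes at which the Monte-Carlo error is comfortably inside the
acceptance bands. All stochastic stages take explicit seeds; identical
seeds give bit-identical studies, and EMG generation draws after marker
generation so disabling EMG does not perturb marker draws.

## Known limitations

* The C3D reader covers the common Intel-processor integer/float layout
  only (DEC/MIPS files are rejected with a clear error).
* RA's convention (amplitude ratio) and the congruity denominator
  (both-moving samples) are field conventions the source literature leaves
  ambiguous; both are documented and switchable where alternatives exist.
* Sagittal angles from three points ignore pelvis tilt; ROMs are internally
  consistent but not interchangeable with 6-DoF model outputs.
* The mixed-model stage reports Satterthwaite p-values as provided by
  lmerTest; no Kenward-Roger or bootstrap alternatives.
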