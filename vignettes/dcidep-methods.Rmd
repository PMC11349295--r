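---
title: "Modelling scanning-voltage DC-iDEP separation of organelle populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling scanning-voltage DC-iDEP separation of organelle populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcidep)
```

## The physical model

Direct-current insulator-based dielectrophoresis (DC-iDEP) separates
bioparticles in a microchannel whose insulating sawtooth walls pinch the
channel at a series of constrictions ("gates"). Two transport mechanisms
compete. Electrokinesis (electrophoresis plus electroosmosis) drives a
particle along the field,

$$ \mu_{EK} = \mu_{EP} + \mu_{EOF}, \qquad \vec v_{EK} = \mu_{EK}\,\vec E, $$

while dielectrophoresis couples the particle's polarizability to the
gradient of the squared field magnitude,

$$ \mu_{DEP} = \frac{\varepsilon_m\, r^2 f_{CM}}{3\eta}, \qquad
   \vec v_{DEP} = \mu_{DEP}\, \nabla |\vec E|^2, $$

with $\varepsilon_m$ the medium permittivity, $\eta$ its viscosity, $r$ the
particle radius and $f_{CM}$ the Clausius–Mossotti factor. Because gates
concentrate the field, $\nabla|\vec E|^2$ peaks on the approach to each
gate, and a particle is held wherever dielectrophoretic opposition balances
electrokinetic drive. Dividing the force balance by $\mu_{DEP}|\vec E|^2$
gives a purely field-side quantity, the *capture parameter*

$$ c(\vec x) \;=\; \frac{\nabla |\vec E|^2 \cdot \vec E}{|\vec E|^2}
   \quad [\mathrm{V/m^2}], $$

and a purely particle-side quantity, the electrokinetic-to-dielectrophoretic
mobility ratio $\mathrm{EKMr} = \mu_{EK}/\mu_{DEP}$, also in V/m².
A particle passes every gate whose peak capture parameter is below its EKMr
and is captured at the first gate where $c \ge \mathrm{EKMr}$ (equality
captures). Since $\vec E$ is linear in the applied voltage $V$, so is $c$:
each gate has a unit-voltage threshold $c_g$ and an operating threshold
$V c_g$. That is what makes the scanning protocol work: a high blocking
voltage (2100 V by default) raises every threshold above the whole sample's
EKMr range, and each 300 V step down (1800 → 600 V) lowers the thresholds so
that successively lower-EKMr subpopulations enter and spread along the gate
series. Reported EKMr values are magnitudes; in the repulsive-DEP regime
that traps particles upstream of a gate, $f_{CM}$ (and hence $\mu_{DEP}$) is
negative, and the trajectory integrator takes `mu_dep < 0` accordingly.

## Reference device and geometry choices

The reference channel is 3.5 cm long with 27 gates in 9 equal-width groups
of 3; gate openings step from 73 µm at the inlet to 25 µm at the outlet.
The printed endpoints (73, 25 µm) together with 9 groups force an exact
step of 6 µm, so the default schedule is the linear one
73, 67, …, 25 µm; an explicit width list can override it. Several shape
parameters are not fixed by the device description and are exposed as
configuration with defaults chosen once:

* `background_width_um = 200` — unconstricted channel width;
* `apex_angle_deg = 60` — tooth apex angle;
* `tip_flat_um = 6` — the tooth apex is truncated by a small flat.
  Photolithographically fabricated tips are never mathematically sharp, and
  a sharp re-entrant corner also makes the discretized field singular at
  the tip (see *Numerical choices*);
* `pitch_um` — defaults so the 27 gates are spaced uniformly along the
  3.5 cm channel;
* `depth_um = 20` — metadata only; the model is two-dimensional, as was the
  original finite-element treatment of this device family.

These choices set the absolute scale of the thresholds but not the logic of
the model; a single multiplicative calibration factor
(`calibrate_profile()`) can pin any gate's threshold to a measured EKMr.
The default pipeline pins gate 27 at 1800 V to 2.3×10¹⁰ V/m², the largest
EKMr at which particles are resolved at the highest readout voltage. With
the default geometry this factor comes out at 1.00 — the physical defaults
already place the 600–1800 V sweep across roughly 6×10⁸–2.3×10¹⁰ V/m², the
EKMr window the device probes — and the gate-27:gate-1 threshold ratio is
about 12.6, comparable to the spread of reported subpopulation EKMr values.

## Field solver

The electrostatic potential solves Laplace's equation on the rasterized
fluid domain: Dirichlet values on the inlet (applied voltage) and outlet
(ground), insulating walls elsewhere. The discretization is a finite-volume
5-point stencil in which each fluid cell exchanges flux only with fluid
neighbours, which makes the zero-normal-flux wall condition exact at the
discrete level. The sparse symmetric system is solved directly (CHOLMOD via
the Matrix package); the channel is long and thin, so the matrix is
effectively banded and the full 27-gate device at 3 µm spacing solves in a
few seconds with a relative residual below 10⁻¹⁰.

$\vec E = -\nabla\phi$ uses central differences in the interior and
one-sided differences against walls; $\nabla|\vec E|^2$ is differenced from
the assembled $|\vec E|^2$ grid rather than by differentiating field
components twice, to avoid compounding stencil errors. Cells where
$|\vec E|$ falls below 10⁻⁶ of the median field are flagged undefined
rather than producing spurious ratios.

### Threshold extraction

The per-gate threshold is the maximum positive capture parameter along the
channel centreline within an axial window spanning the tooth's
field-disturbance region (half-base plus half-height, plus a 2-cell
margin). The centreline is the path of a particle approaching the gate;
restricting to it matters because $c$ formally diverges at the tooth-tip
corners, where the fluid turns through a re-entrant angle and the Laplace
solution has an $r^{\pi/\omega}$ singularity. That corner value is a
discretization artefact a travelling particle never samples — with sharp
tips it grew without bound under grid refinement (measured ~50× the
centreline value at 2 µm spacing) while the centreline profile is smooth.
Tooth apexes are additionally snapped to grid cell centres during
rasterization so equal-width gates rasterize identically regardless of
sub-cell alignment; without this, nominally identical gates acquired
several-percent threshold jitter.

### Discretization accuracy

With the default truncated tips, halving the grid spacing moves individual
gate thresholds by at most ~6 % (typically under 3 %), the profile mean by
~2 %, and threshold *ratios* — which set where particles land relative to
one another — by well under 10 %. The residual slow component of
convergence is the corner-singularity pollution characteristic of
stairstep-boundary schemes. Absolute threshold scale is in any case a
calibrated quantity; the discretization uncertainty to keep in mind is a
few percent on the EKMr axis of computed spectra.

## Synthetic populations

Subpopulations are specified directly in EKMr space, the observable on
which the separation is indexed, as narrow log-normal components (default
log-sd 0.05; homogeneous subpopulations are expected to occupy a very
narrow EKMr range). Physical parameters are back-filled consistently —
radius drawn in the 150–200 nm range typical of insulin secretory vesicles,
$f_{CM}$ fixed, $\mu_{DEP}$ from the mobility formula, and
$\mu_{EK} = \mathrm{EKMr}\cdot\mu_{DEP}$ — so the round trip through
`dep_mobility()` and `ekmr()` reproduces the drawn EKMr exactly. The
default medium is a sucrose-based low-conductivity buffer
($\varepsilon_m = 78\,\varepsilon_0$, $\eta = 1.2$ mPa·s).

The two default condition presets anchor their component locations to the
EKMr values at which distribution features are reported for vesicles from
untreated ("n": 3.5, 5.5, 12, 18 ×10⁹ V/m²) and glucose-stimulated cells
("g": 4, 7.5, 11, 23 ×10⁹ V/m²). Component weights and dispersions are
illustrative defaults, not measured quantities.

`simulate_study()` emulates the reference experiment: 3 biological
replicates for "n", 4 for "g", 27 gates, five readout voltages. Replicate
variability has two sources chosen to mimic biological replication: each
replicate redraws its particles, and its mixture weights are perturbed
multiplicatively (`weight_jitter = 0.25` on the log scale) to emulate
preparation-to-preparation composition differences; additive Gaussian
readout noise (`noise_sd = 2` in summed-fluorescence units, clamped at
zero) models the camera. What the generator does *not* emulate: optical
blur between adjacent gates, bleaching, background drift, particle–particle
interactions inside a bolus, pressure-driven flow, and Joule heating. Tests
passing on synthetic data therefore validate the model's internal
consistency, not instrument physics.

## The scanning simulation

The capture core is deterministic, matching the deterministic capture
condition: at each voltage every particle advances from its current
location to the first gate at or downstream whose threshold meets its EKMr,
or exits. Equality captures; floating-point comparison uses a relative
tolerance of 10⁻¹². Blocking is modelled as capture at gate 1 with a
`blocked` flag, which keeps one bookkeeping state while preserving the
"prevented from entering" reading. Particles never move upstream when the
voltage drops, and each voltage step is an equilibrium snapshot (the ~90 s
settling time of the real protocol is not simulated). Particles are
treated independently; whether real particles can be overtaken or crowded
out at a shared gate is not observable in per-gate intensity data.

## From intensities to spectra

Per-gate intensities follow the experimental reduction: background
subtraction (clamped at zero), normalization within each (replicate,
voltage) dataset, aggregation of same-width gate triplets, and replicate
averaging (mean ± SEM). Two conventions are resolved explicitly:

* **Normalization denominator.** The experimental description admits both
  "highest intensity" and "all signals"; the default divides by the
  per-voltage maximum, and `normalize = "sum"` is available.
* **Order of operations.** Normalization is applied per replicate *before*
  replicate averaging, so replicates recorded at different illumination
  scales are comparable; each group's EKMr value is the applied voltage
  times the group-mean unit-voltage threshold (near-identical within a
  width group).

## The statistical comparison

`two_way_anova()` fits `intensity ~ condition * ekmr_level` with
sum-to-zero contrasts and reports a Type III effect table, which handles
the unbalanced 3-vs-4 replicate design; for the highest-order interaction
the F statistic is invariant to the sums-of-squares type, and main-effect
rows should be read as type-dependent. The reference design — 2 conditions
× 9 EKMr levels × (3, 4) replicates — gives interaction df 8 and error
df 45. Post hoc, each level's condition means are compared with a t
statistic on the pooled ANOVA error variance (a Welch fallback is
available), and raw p-values are Bonferroni-multiplied by the number of
levels, capped at 1, at α = 0.05.

One calibration subtlety is worth stating plainly. The F test assumes
independent homoscedastic errors. Per-replicate max-normalization violates
this: it pins each replicate's largest signal at 1 and induces negative
correlation across levels. Under a full-pipeline null simulation (both
conditions drawn from the same mixture) the interaction test is therefore
*conservative* — in our measurements it essentially never rejected at
α = 0.05. The type-I calibration test instead draws both conditions from
the same mixture-derived mean spectrum with independent observation noise,
which verifies the ANOVA machinery itself at nominal level. Analyses of
max-normalized spectra (including the original experimental analysis) should
expect conservative interaction p-values.

## The trajectory integrator as an independent check

`advect()` integrates
$\dot{\vec x} = \mu_{EK}\vec E + \mu_{DEP}\nabla|\vec E|^2$ with
Euler–Maruyama stepping, bilinear field interpolation, reflecting walls and
optional Brownian displacements (Stokes–Einstein diffusivity by default
when enabled). The step size adapts so no step exceeds half a grid cell
*and* is capped by the characteristic electrokinetic time scale — without
the cap, an adaptive step normalized to the local speed would carry a
particle straight through its stagnation point. Capture is declared when
the mean displacement over 500 consecutive steps falls below 0.01 cells.
On toy geometries with diffusion off, the integrator's final gate agrees
with the capture predictor for every tested particle whose EKMr differs
from all thresholds by more than 5 %; near-threshold ties are excluded as
genuinely ambiguous at finite numerical precision.

## Problem sizes and reproducibility

Default study sizes: 2000 particles per replicate, 7 replicates, 27 gates,
five voltages; the reference field solve uses 3 µm spacing (about 7×10⁵
unknowns). Test fixtures use smaller toys (3-gate devices, a few hundred
particles), chosen to exercise every code path at interactive speed. Every
stochastic step takes an explicit integer seed; per-replicate seeds are
derived deterministically from the base seed, and the same configuration
and seed reproduce byte-identical outputs, which the test suite asserts.

## Known limitations

* Two-dimensional electrostatics; depth is metadata. Field concentration
  in the depth direction is absorbed by the calibration factor.
* Absolute thresholds are calibrated, not ab-initio: tooth outline details
  of the fabricated device are unknown.
* The capture model is quasi-static and single-particle; bolus growth,
  shielding and crowding are not modelled.
* The conservativeness of the interaction test under max-normalization
  (above) is a property of the analysis convention, not of this
  implementation.
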