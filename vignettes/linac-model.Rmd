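---
title: "The linacsim machine model: physics, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The linacsim machine model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linacsim)
```

linacsim simulates, to first order and in real time, the photon-mode chain
of a klystron-driven medical linear accelerator: how the service-mode
controls (RF drive power, klystron pulse voltage, gun voltage, bend-magnet
and steering-coil currents, jaws, pulse structure) turn into the readouts a
physicist or service engineer watches during beam tuning (klystron output,
gun and target current, beam energy, dose rate, flatness, symmetry). It is a
teaching tool: every subsystem is an analytical model with empirically set
constants chosen to give realistic responses, not a predictive model of any
clinical machine.

## The chain, stage by stage

**Klystron.** A two-cavity bunching model gives the output power as
$P_{\mathrm{kly}} = 10\,P_{\max}\left(J_1(X)/X\right)^2 P_{\mathrm{RF}}/P_C$
with $X = 1.84\,(P_{\mathrm{RF}}/P_C)^{1/2}$, where $J_1$ is the first-order
Bessel function, $P_{\max}$ the voltage-dependent maximum output and $P_C$
the saturating drive level. The prefactor 10 normalizes the saturated output
to $P_{\max}$ (numerically, $10\,(J_1(1.84)/1.84)^2 = 1.00002$). $P_{\max}$
is linear in cathode voltage over the rated 100–145 kV window; $P_C$ is
taken proportional to voltage, its functional form being otherwise
unspecified. The anchors — 9 MW and 67 W at 125 kV, slope 0.1 MW/kV — place
the preset operating point at saturation, where drive fluctuations barely
move the output (the stable 55–80 W plateau). Drive is capped at $4P_C$: the
secondary lobes of $J_1$ beyond the first rise-and-fall are unphysical for
this model.

**Gun and waveguide.** The space-charge-limited triode gun follows the
Child–Langmuir law $i \propto V_{\mathrm{cath}}^{3/2}(1 -
V_{\mathrm{grid}}/V_{\mathrm{cut}})$; the proportionality constant and
perveance fold into one effective constant calibrated so a 7.5 kV cathode
setting draws 115 mA. The loaded beam energy follows the standing-wave load
line $E = \sqrt{P_{\mathrm{kly}} Z} - i Z/2$ with shunt impedance
$Z = 47.88\ \mathrm{M\Omega}$ (the steeper of the two standard load lines),
floored at zero for overloaded beams. Gun-voltage slider values are treated
as kV throughout, the unit of the parameter registry (control-panel captions
sometimes quote the same numbers as volts; the registry wins). The beam
leaving the guide is Gaussian in energy with a 3% relative RMS width — a
plausible teaching value, not a measured one; it interacts with the bend
window below.

**Bend magnet.** An ideal solenoidal bend passes kinetic energy
$E = \sqrt{(k_2 I)^2 + (m_ec^2)^2} - m_ec^2$. $k_2$ is calibrated from the
two-point condition that stepping from 6 to 10 MeV takes 40 A (the bend's
10 A/MeV characteristic), giving $k_2 = 0.10019$ MeV/A. The acceptance
window is $\pm 1.5\%$ of the set-point: with a 3% beam spread, a matched
beam transmits $\Phi(0.5)-\Phi(-0.5) \approx 38\%$, and detuning in either
direction visibly collapses the dose rate, which is the behaviour beam
tuning exercises rely on. The window half-width is a design choice (no
measured value exists for it); the matched 15 MeV coil current that follows
from the 10 A/MeV calibration is 154.7 A, a few percent above the 150 A
sometimes quoted for that operating point — the two published numbers are
mutually inconsistent under the bend relation, and this package follows the
calibration. Transmission uses the closed-form truncated-Gaussian mass and
mean. A degenerate (zero-width) spectrum transmits all or nothing.

**Steering.** Position coils deflect the beam a drift length $d = 30$ cm
upstream of the target, so 1 mrad of deflection moves the spot 0.03 cm *and*
tilts the incidence by 1 mrad; angle coils change only the angle. Gains are
0.1 mrad/mA on all coils. These values are not published; they were chosen
once to give symmetry responses of the observed shape (strictly linear in
coil current) at plausible magnitude, and the linearity — not the gain — is
the tested property.

**Target.** The target is tungsten (Z = 74, A = 183.84, density
19.3 g/cm³, radiation length 6.76 g/cm², thickness 0.10 cm) — typical for a
medical linac; material and thickness are otherwise unspecified in the
source material for this model. Electrons slow according to the bundled
total stopping power (midpoint-rule integration through the slabs, clamped
at zero once the beam ranges out). The per-slab photon yield is the linear
thick-target fit $K\,d\sigma/dK \propto Z^2(1 - 0.83\,K/E(x))$; emitted
photons are attenuated through the remaining target thickness and spread
over a radially symmetric Gaussian angular kernel of variance parameter
$\sigma_e^2 + \sigma_b^2$: the Highland multiple-scattering width (computed
with the incident energy, as the model prescribes, and saturated at 0.8 rad,
where the electrons are completely dispersed) plus the intrinsic emission
width $k_3\,m_ec^2/(E + m_ec^2)$ with $k_3 = 1$ (the shape factor has no
published value). The kernel normalization $1/\pi(\sigma_e^2+\sigma_b^2)$
integrates to one over the two-dimensional small-angle plane, which is the
dimensionally consistent reading and matches the small-angle Gaussian
approximation to the Schiff cross section. Yields carry arbitrary-but-
consistent units: the absolute dose scale is set once by the calibration
scalar, so only the relative spectral shape matters upstream.

**Filter and jaws.** The proprietary "gold standard" filter shapes used by
manufacturers are not available, so each flattening filter is *designed* by
numerically inverting the open beam: the unflattened dose profile at 1.5 cm
depth is computed for the design energy, and the conical copper thickness is
iterated (attenuation evaluated at the local fluence-weighted mean photon
energy, so beam hardening is tracked) until the filtered profile is flat
across 90% of the jaw half-opening, to half the 2% design tolerance. The
thickness is forced non-increasing with radius and the design is fully
deterministic. This preserves the behaviour that matters for teaching: flat
at the design energy, over-flattened (horns) below it, forward-peaked and
FFF-like above it. Jaws absorb perfectly, with a half-open $[-J/2, +J/2)$
aperture convention at the isocenter plane. Geometry defaults: filter at
12.5 cm, isocenter at 100 cm, 20 cm × 20 cm field.

**Dose.** Beyond the build-up region the dose rate is taken equal to
collision kerma: a quadrature over photon energy of the fluence attenuated
through the analysis depth of water, weighted by the water mass
energy-absorption coefficient. Depths shallower than 1.5 cm raise an error
(an explicit override exists for in-air maps) because the kerma
approximation does not hold there. The finite 0.1 cm focal spot is applied
as a separable Gaussian convolution whose width is magnified by
$(d_{\mathrm{SAD}} - d_f)/d_f = 7$, giving a geometric penumbra with the
closed-form 80–20% width of $1.683\sigma$. The discrete kernel is
renormalized to unit sum, so the map total is conserved away from grid
edges. Flatness is the dose at the 3/4-jaw off-axis point over the
central-axis dose (mean of the two mirrored points); symmetry is the signed
relative difference of those points in percent.

**Absolute calibration.** The model has no absolute dosimetry chain, so one
scalar, computed once per discretization and cached, fixes the 15 MV preset
at 420 cGy/min on the central axis at 1.5 cm depth with the reference pulse
structure (180 Hz, 5 µs — documented constants). Dose then scales linearly
with target current, PRF and pulse width. The 1.5 cm depth is itself a
documented choice: it is the only depth quoted alongside the flatness
definition, and the readout depth for the headline dose rate is not
otherwise specified.

## Presets

The 15 MV preset runs the klystron at its saturated point (125 kV, 67 W,
9 MW), with the gun at 12.25 kV so beam loading of the 240 mA beam lands the
loaded energy exactly at 15 MeV, and the bend coil matched (154.7 A). The
6 MV preset keeps the same klystron voltage and gun current but solves the
RF drive (≈9.7 W, well below saturation) so the loaded energy is exactly
6 MeV — low-energy modes on real machines likewise run the RF chain at
reduced power rather than drawing amps of gun current. Each preset selects
the filter flattened for its own energy. `settings_for_energy()` generalizes
the preset construction to any reachable energy while keeping a fixed
filter, which is how the flatness-versus-energy behaviour of a single 6 MV
filter is reproduced.

## Numerical choices

- Reference discretization: 200 depth slabs, 100 log-spaced photon-energy
  nodes on [0.05 MeV, E], 101 radial angle nodes on [0, 0.5 rad], and a
  0.2 cm dose grid over ±15 cm. All are configurable via `sim_options()`;
  the chain-level test suite runs at roughly half resolution in each
  dimension (120/60/61, 0.5 cm over ±12 cm), where the relative metrics it
  asserts are already converged.
- Material tables are 60-node log grids over 0.01–30 MeV with log-log
  interpolation (attenuation and stopping-power data are near power laws);
  interpolation is exact at nodes, and out-of-range queries are errors, not
  extrapolations. The bundled values are representative transcriptions of
  the standard reference compilations, adequate for a teaching-grade model
  in which the absolute yield scale is calibrated away.
- Electron slowing uses midpoint (second-order) steps; halving the step
  changes the exit energy of the reference target by well under 0.1%.
- The bend-matching scan uses a 0.01 A grid; because the acceptance window
  is proportional to the set-point, the transmitted-current optimum sits a
  relative ~5×10⁻⁴ above the beam energy, a sub-grid-step effect.
- Degenerate inputs: zero-thickness targets give empty spectra; beams that
  miss the acceptance window or range out below 0.3 MeV produce a zero dose
  grid with metrics reported as `NA`; overloaded load lines floor at zero
  energy; filter-design non-convergence is an error rather than a silent
  partial result.

## What the model does not capture

Grid-gating dynamics of the triode gun (the grid term exists in the API but
presets run at zero bias), temperature drift and automatic frequency
control, ion chambers and steering servos, electron mode and scattering
foils, magnetron/travelling-wave designs, collimator transmission and
scatter, the build-up region, electron contamination, and any absolute
dosimetry beyond the single calibration scalar. Constants are deliberately
*realistic rather than real*: the package must not be used to infer the
operating point of a clinical machine.
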