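---
title: "Modeling focused-ultrasound mild hyperthermia as a radiosensitizer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling focused-ultrasound mild hyperthermia as a radiosensitizer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fusht` simulates the physics and reproduces the statistics of a preclinical
treatment in which mild hyperthermia (42 °C for 20 min), induced by a
focused 350 kHz ultrasound transducer, is used to sensitize a subcutaneous
rodent glioma to a sub-ablative 2 Gy radiation dose.  This vignette is the
package's own account of the models, the numerical choices behind them, and
what the test suite does and does not establish.

## The acoustic model

The source is a spherical-cap ("bowl") transducer driven in continuous
wave.  The steady-state complex pressure at a field point $\mathbf{x}$ is
the Rayleigh–Sommerfeld integral over the radiating surface $S$,

$$ p(\mathbf{x}) = -\frac{i k \rho c u_0}{2\pi}
   \int_S \frac{e^{ikr}}{r}\, dS , $$

with $k$ the wavenumber in water, $u_0$ the uniform normal surface
velocity, and $r$ the element-to-point distance.  The package reports the
amplitude $|p|$, which is what drives heating under CW drive.  The cap is
discretized with a midpoint rule in polar and azimuthal angle
(`n_theta = 96`, `n_phi = 128`, ≈ 12 000 elements); doubling the element
count moves the focal amplitude by well under 0.5 % (asserted in the test
suite).  On the acoustic axis the same integral has a closed form (the
classical spherical-cap solution, extended to an annulus as a difference of
two caps); the numerical field is required to agree with it to better than
1 % — an oracle that is implemented independently of the field code.

**Effective radiating geometry.** The physical transducer is specified by
its housing: 44 mm diameter, 31.5 mm focal length, with a measured −3 dB
focus of 3.1 mm (lateral) × 15.4 mm (axial).  Exact linear diffraction for
a *uniform full 44 mm cap* predicts a 2.96 mm × 12.1 mm focus — the axial
length disagrees with the measurement by over 20 %, which is far outside
what numerical error can explain.  Transducers of this family carry a
coaxial port and an active element somewhat smaller than the housing, so
the package identifies an *equivalent source* instead: a radiating annulus
with outer (active) diameter 40 mm and a 12 mm central opening, chosen once
so that the simulated focus jointly matches the measured dimensions
(3.00 mm × 15.40 mm on a fine profile scan).  This is the same spirit as
hydrophone calibration: the free parameters of an idealised source are
fixed against measured field data, after which nothing is adjusted.  Both
diameters are exposed on `transducer_spec()` for users with a fully
specified source.

**Drive calibration.** `calibrate_transducer()` scales the surface pressure
so the lossless-water focal peak equals the requested focal pressure
(default 1 MPa).  The in-phantom peak is only ≈ 0.6 % lower, because the
propagation path is almost entirely water (27.7 mm of standoff vs 0.8 mm of
skin and 3 mm of tumor to the focus), so the distinction between water and
in-situ calibration is immaterial here.

**Layered propagation.** The phantom is water / 0.8 mm skin / 6 mm tumor
sphere embedded in muscle, with the tumor center at the geometric focus and
its proximal pole touching the skin.  The field is computed as the lossless
axisymmetric Rayleigh field (evaluated on a 0.1 mm radius–depth table and
bilinearly interpolated onto the grid) multiplied by a cumulative
attenuation factor $\exp(-\int \alpha\, dz)$ accumulated along each voxel
column, with $\alpha$ linear in frequency as the material table's
Np/(m·MHz) units imply.  Refraction and interface reflections are neglected
— impedance contrasts between these media are a few percent.  All
attenuated energy is deposited locally as heat:

$$ Q = \alpha(f)\, \frac{p^2}{\rho c} \; = \; 2\,\alpha I,
   \qquad I = \frac{p^2}{2 \rho c}. $$

Water has $\alpha = 0$ and receives no heating.

## The thermal model

Temperature obeys the Pennes bioheat equation

$$ \rho C \frac{\partial T}{\partial t} =
   \nabla\!\cdot\!(k \nabla T) + w_b C_b (T_a - T) + s(t)\, Q $$

with perfusion $w_b$ in kg/(m³·s), arterial temperature $T_a = 37$ °C and
blood specific heat $C_b = 3700$ J/(kg·°C) (the tissue value; blood
properties are not separately tabulated for this model).  The solver is an
explicit forward-Euler FTCS scheme in conservative flux form with
harmonic-mean face conductivities, so interface fluxes are consistent and
the insulated, perfusion-free scheme conserves the discrete enthalpy to
round-off (asserted).  The time step defaults to half the per-voxel
stability bound $\rho C / (2 d k / \Delta x^2 + w_b C_b)$; user-supplied
steps beyond the bound are refused.

Initial conditions are 37 °C in tissue and 23 °C in water.  The water
voxels of the two grid faces perpendicular to the beam axis are held at
their initial temperature; every other boundary is perfectly insulating
(the distal axial face of this domain is muscle, not water, so it is
insulating rather than clamped).  A 10-minute source-free equilibration
precedes treatment, which leaves the skin and outer tumor noticeably cooled
by the room-temperature coupling water — the tumor-center sensor sits near
34 °C at treatment start.

Water is modeled as a conducting solid (no convection), consistent with a
bioheat-only treatment of the coupling path.

**Control.** The experimental PID hardware gated a constant-amplitude
source ON/OFF; the package emulates it as an ideal relay with hysteresis:
OFF strictly above 42.0 °C, ON strictly below 41.5 °C, initial state ON,
consulted every solver step with the tumor-center voxel temperature.  The
closed-loop oscillation is validated against the two-rate relay-oscillator
closed form on a lumped single-voxel problem (2 % tolerance).

**Thermal dose.** CEM43 is accumulated online as
$\sum_i \Delta t_i\, R^{43 - T_i}$ (minutes) with $R = 0.5$ at or above
43 °C and $R = 0.25$ below (both exposed as arguments, since sub-43
conventions vary), sampled every second of simulated time; temperature is
treated as piecewise constant between samples.  Against the stored-snapshot
definition the online accumulation is exact.

## Problem sizes and numerical behavior

The default grid spans 40 × 40 × 50 mm at 0.4 mm spacing (≈ 10.6 points
per wavelength in water at 350 kHz; the field code refuses fewer than 6).
Two properties of this configuration matter:

* The 0.8 mm skin layer is exactly two voxels at 0.4 mm spacing.  Skin is
  by far the strongest absorber in the beam path (21.2 Np/(m·MHz)), and at
  spacings that do not divide the layer thickness the voxelized skin
  thickness jitters (a single 0.45 mm voxel at 0.45 mm spacing, 1.2 mm at
  0.6 mm), which measurably shifts the thermal answer.  Production runs
  should keep the spacing at a divisor of the layer thickness; the solver's
  own grid convergence (0.8 mm vs 0.4 mm, fixed smooth source, sensor trace
  within 0.2 °C) is asserted on a uniform medium where no such geometric
  aliasing exists.
* The relay-controlled treatment run (10 min equilibration + 20 min
  treatment) takes a few minutes of wall time at 0.4 mm on one CPU; the
  test suite and examples use coarser grids and shorter durations where the
  assertion does not need the full configuration.

## What the model predicts, and a known tension

With the defaults above, the simulated treatment deposits a volume-maximum
thermal dose close to 3.5 CEM43 — comfortably below tissue-damage
thresholds, and the quantity the acceptance script recomputes.  The
regulated sensor, however, approaches a conduction-limited plateau of
≈ 41.97 °C: a few hundredths of a degree *below* the 42.0 °C relay
threshold, so in this configuration the controller never actually switches
off.  The margin is razor thin: a 5 % increase in drive amplitude — well
inside the uncertainty of any hydrophone calibration — moves the crossing
to about 4.5 min of treatment time and produces sustained ON/OFF cycling.
We deliberately do not apply such a factor: the drive stays at the stated
1 MPa, the dose prediction is insensitive to the marginality (the dose
integral cares about the plateau temperature, not whether 42.0 is crossed),
and the corresponding test records the shortfall rather than hiding it.
Interestingly, a full 44 mm cap (the nominal geometry) performs *worse*
thermally — its focal lobe is 20 % shorter than measured, heating a smaller
tissue volume — which is further evidence for the annular effective source.

## The synthetic cohort generator

The generator emulates the study's four-arm design (control, FUS-HT alone,
2 Gy alone, combined; n = 8/10/8/10) with the published one-week group
means and SDs, plus a treatment-day preset (statistically homogeneous
groups) and a three-arm dose-escalation preset (n = 3).  Per animal, a
volume is drawn from a normal distribution truncated at a 1 mm³ floor.
Because naive truncation inflates the mean (by ≈ 12 % for the combined
arm, whose floor sits only 1.4 SD below target), the location parameter is
solved so the *truncated* mean equals the target; group means are then
recovered without bias (asserted to 2 standard errors over 2000
replicates).  A truncated normal rather than a lognormal is used because
the study reports arithmetic mean ± SD.  An aspect ratio $a$ is drawn
uniformly from [1.0, 1.6] (no shape data are published) and the caliper
pair recovered by inverting $V = \tfrac12 L W^2$ with $L = a W$.

The generator does **not** model within-animal longitudinal correlation,
measurement error of the caliper, or mechanistic growth; the analysis it
feeds is a day-7 cross-section, matching how the study reports its primary
endpoint.  Passing tests therefore show that the statistical chain (volume
formula, one-way ANOVA, pairwise Welch tests with Bonferroni correction,
m = 3 comparisons against the combined arm) behaves correctly at the
published effect sizes — not that real caliper data meet the generator's
distributional assumptions.

## Statistical conventions

* Volumes are analysed raw (no log transform), matching mean ± SD
  reporting.
* ANOVA is the classical equal-variance one-way F test; the degenerate
  all-identical case returns F = 0, p = 1.
* Pairwise tests are two-sided Welch t-tests with Welch–Satterthwaite
  degrees of freedom; the Bonferroni multiplier defaults to the number of
  comparisons performed and is configurable because the source study does
  not print it.
* Radiotherapy beam-on time is dose / (base rate × collimator output
  factor); the ≈ 3 mm target depth is carried as metadata with an optional
  percent-depth-dose hook (default 1), since the printed irradiation times
  are reproduced exactly by the depth-free formula.

## Known limitations

* Linear acoustics only: no nonlinearity, cavitation, standing waves or
  shear propagation; no refraction at interfaces.
* The equivalent-source geometry reproduces the measured focus but is not
  a vendor datasheet; users with full source specifications should set
  `active_diameter` and `central_opening` explicitly.
* The bioheat solver is explicit and single-grid; no temperature-dependent
  properties, no discrete vasculature, no MR-thermometry emulation.
* The caption of the source study's simulation figure quotes a 5 mm tumor
  while its methods state 6 mm; the package defaults to 6 mm and exposes
  `tumor_diameter_mm` (the 5 mm variant is one config line away).
* The water standoff is not published; the default places the geometric
  focus at the tumor center (standoff = focal length − skin − tumor
  radius), which is how the experiment was positioned.
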