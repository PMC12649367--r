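---
title: "Methods: simulating focused ultrasound through a layered skull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating focused ultrasound through a layered skull}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model

Transcranial focused ultrasound (tFUS) delivers acoustic energy through the
intact skull to a focal spot in the brain. The obstacle is the skull itself:
a three-layer sandwich of dense cortical tables around porous trabecular
(diploe) bone, with sound speeds and densities far from those of soft
tissue, frequency-dependent absorption, and a curved geometry that refracts
the beam. `tfusim` models one sonication as a five-layer axisymmetric
column: coupling gel, skin, outer cortical bone, trabecular bone, inner
cortical bone, and brain, with all interfaces concentric circular arcs of
the local skull radius of curvature, and a spherically focused transducer
cap at the origin.

Each tissue carries four constants: density $\rho$ (kg/m$^3$), small-signal
sound speed $c$ (m/s), the thermodynamic nonlinearity ratio $B/A$, and a
sound diffusivity $\delta(f)$ (m$^2$/s) tabulated at 0.5, 1, 2, 4 and 5
MHz. The diffusivity is the single loss parameter: a thermoviscous medium
attenuates a plane wave of angular frequency $\omega$ at
$\alpha = \delta\omega^2 / (2c^3)$ Np/m. For the coupling gel the
absorption coefficient is frequency-independent at $\alpha = 7$ m$^{-1}$,
so its diffusivity follows $\delta = 2c^3\alpha/\omega^2$ exactly; for the
biological tissues the tabulated values are interpolated between the five
anchor frequencies by a piecewise power law $\delta = \delta_0 f^n$
(log–log interpolation). A single global power law does not fit the
tabulated values across the whole band, and per-tissue exponents are not
available, so the piecewise form is used and no extrapolation outside
0.5–5 MHz is allowed.

Two solvers share this material model:

* **Frequency domain** (`helmholtz_solve`): the inhomogeneous Helmholtz
  equation $\nabla\!\cdot\!(-\rho_c^{-1}\nabla p) - k_{eq}^2 p/\rho_c = 0$
  with an equivalent-fluid treatment of losses,
  $c_c = c\,(1 + i\omega\delta/c^2)^{1/2}$ and
  $\rho_c = \rho\,(1 + i\omega\delta/c^2)^{1/2}$, $k_{eq} = \omega/c_c$.
  The square-root branch is chosen so that the implied plane-wave
  attenuation reduces to $\delta\omega^2/(2c^3)$ in the small-loss limit;
  the literal reciprocal form would double it. The out-of-plane wavenumber
  is zero in an axisymmetric model, and interior monopole/dipole terms are
  unused — the transducer enters as a boundary condition.
* **Time domain** (`westervelt_run`): the conservative first-order form of
  the Westervelt system,
  $$\frac{1}{\rho c_0^2}\frac{\partial p}{\partial t} +
    \nabla\!\cdot\!\Big[\Big(1 + \frac{\beta p}{\rho c_0^2}\Big)
    \mathbf{u}\Big] = 0,\qquad
    \rho\frac{\partial \mathbf{u}}{\partial t} + \nabla p =
    \delta\rho\,\nabla(\nabla\!\cdot\!\mathbf{u}),$$
  with $\beta = 1 + B/(2A)$. The momentum-side diffusivity term is one
  consistent realization of thermoviscous loss in first-order form: it
  reduces the system to the lossy wave equation
  $p_{tt} = c^2\nabla^2 p + \delta\nabla^2 p_t$, whose attenuation is
  exactly $\delta\omega^2/(2c^3)$ — the same contract as the frequency
  domain, enforced by a shared plane-wave decay oracle in the test suite.
  The sign of this term matters: the opposite sign, which a naive reading
  of the first-order substitution can produce, yields exponential growth.
  A linear-mode switch forces the nonlinear flux factor to one for
  verification runs.

## Geometry and the scenario factory

The synthetic-scenario module is the data generator of the package: every
simulated case is built from printed regional anatomy, not from images.
Skull thickness menus per region (frontal 6–8 mm, parietal 5.5–6 mm,
temporal 3.5–4 mm, occipital 8–9 mm) and radius-of-curvature menus
(45–95 mm by region) parameterize the geometry. A total skull thickness
$T$ decomposes as: trabecular $= T/4$, and the remaining cortical share
split so the outer table is 1.68 times the inner — a median outer-to-inner
ratio from calvarial morphometry. The implied total cortical-to-trabecular
ratio is exactly 3:1, within the 2–5 range those morphometric studies
report across regions, and the decomposition reproduces every row of the
package's regional geometry table at its stated rounding.

Parameters not constrained by published regional anatomy are package
defaults, stated once and configurable: skin thickness 3 mm, gel standoff
10 mm, brain domain depth 80 mm beyond the inner cortical surface (60 mm
in the reduced preset), transducer aperture 74 mm, geometric focal length
65 mm, source amplitude 1 MPa, centre frequency 2 MHz. The transducer
coupling fluid uses gel properties. The source pulse is a
Gaussian-windowed tone burst (the envelope is a modelling choice; the
Gaussian is the default), with a flat-top (Tukey) option for steady-state
verification drives.

What the generator emulates: layered anatomy with regionally realistic
thickness and curvature, in perfect contact (no air gaps), porosity folded
into effective properties. What it does not: 3-D asymmetry, transducer
misalignment, within-layer heterogeneity, shear-wave conversion in bone
(the fluid-equivalent treatment is kept). Green tests therefore demonstrate
correct physics of the stated model, not anatomical fidelity to any
individual head.

## Discretization

Both solvers share a uniform cell-centered axisymmetric grid with
$\Delta x = c_{\min}/(6 N_0 f_0)$, where $N_0$ is the number of harmonics
to resolve (default 2; 1 in the reduced preset). The frequency-domain
operator is a conservative 5-point stencil with harmonic-mean face
weights, the symmetry axis handled naturally by the zero-radius face
factor; PML absorbers (quadratic complex-coordinate stretch, width two
wavelengths of the slowest medium, theoretical reflection $10^{-6}$)
close the open boundaries, and the sparse complex system is solved as its
equivalent real block form by a direct sparse LU with iterative
refinement (relative residual $\le 10^{-8}$). An optional
modified-wavenumber correction, $k_{eq} \to (2/\Delta x)\sin(k_{eq}\Delta
x/2)$ (default on), removes axial numerical dispersion of the second-order
stencil; residual error is dominated by the stencil's angular anisotropy.

The time-domain solver staggers velocities at faces and steps the system
with classical fixed-step RK4. The step is the per-class Courant minimum
with CFL 0.2 in gel/soft tissue and 0.1 in bone. Open boundaries carry an
exponential Rayleigh sponge (quadratic ramp over two wavelengths); the
exterior edge is rigid. The transducer cap is a pressure Dirichlet surface
by default, with per-cell time delays compensating the staircase snapping
of the curved cap onto the grid; a soft (additive, reflection-transparent)
source is available via `source_model = "soft"`.

### Cross-validating the two solvers

Comparing the two solvers naively conflates three unrelated differences:
the absorbers (PML vs sponge), the loss models (equivalent fluid perturbs
interface impedances at $O(\omega\delta/c^2)$; the time-domain term does
not), and the source (a Dirichlet cap reflects returning energy, making
the gel standoff a high-Q cavity whose steady amplitude swings by a factor
of two within ±1% of drive frequency). `helmholtz_solve` therefore offers
a mirror configuration — `source_model = "monopole"`, `absorber_model =
"sponge"`, `loss_model = "diffusivity"` — that assembles the exact
frequency-domain counterpart of the time-explicit semi-discrete operator.
In that configuration the only remaining difference is time integration,
and the steady-state fields agree cell-wise to a few percent; this is the
configuration `compare_fd_td` and the cross-validation test use. The
default configuration (Dirichlet cap, PML, equivalent fluid) remains the
production model.

## Outcome metrics

From an envelope field (per-cell peak $|p|$ in time domain, $|p|$ in
frequency domain) the package reports: the maximum pressure ratio
(brain-peak over source amplitude); sound transmission loss
$STL = 20\log_{10}(p_{transducer}/p_{focus})$ with $p_{transducer}$ read
at the first on-axis gel cell beyond the cap and $p_{focus}$ the brain
peak; focal depth (axial position of the on-axis brain peak, from the
transducer apex, with the intracranial depth also reported since the
reference point is a convention); and the focus zone, the connected
component above 5% of the peak containing the peak, reported both as
axial extent and as in-plane area because the plotted quantity's units
are a convention as well. Harmonic content of probe records is measured
by projection onto $k f_0$ over a Hann window spanning an integer number
of fundamental periods.

Note that under a Dirichlet cap the transducer probe reads the gel-cavity
standing wave, not the nominal drive amplitude; STL values are therefore
sensitive to the (assumed) gel standoff thickness at resonant
combinations. This is inherent to the probe convention, which is kept as
the package's documented definition.

## Verification suite

The package's correctness case rests on independent oracles, all in the
test suite: printed-table reproduction (gel diffusivity row, nine skull
decompositions); plane-wave decay $e^{-\alpha L}$ against the closed-form
$\alpha$ in both solvers (2%); the classical focused-radiator on-axis
field against a numerically evaluated Rayleigh integral over the cap (3%,
at 32 cells per wavelength); quiescent invariance, lossless-linear energy
conservation (0.5%), and bit determinism of the stepper; second-harmonic
growth $p_2/p_1 = \sigma/2$ against weak-shock theory within 5% at shock
parameter $\sigma = 0.2$; FD–TD cell-wise agreement (5%) in the mirror
configuration; and reduced-scale parametric trend checks.

Two trend assertions in the acceptance suite fail, and are left failing
deliberately: at the reduced conditions (0.5 vs 1 MHz, focused 74 mm /
F = 65 mm cap), STL *decreases* with frequency and focal depth is flat.
This is physics, not defect: the diffraction gain of a focused bowl grows
linearly with frequency (+6 dB per octave) while the tissue absorption
exponent only roughly doubles across this low band, so a focused-cap
model cannot show monotone STL growth below about 2 MHz — equivalently,
the maximum pressure ratio is non-monotonic at the low band, peaking near
1 MHz for these geometries. The monotone-loss expectation is recovered
only at higher frequencies (absorption $\propto f^{1..2}$ eventually
dominates) or for an unfocused source; the spherically focused cap is
this package's documented assumption. The thickness trend (+STL for
4 → 8 mm), focus-zone contraction with frequency, source-pressure
invariance of linear STL (< 0.1 dB), and the non-negative STL excess of
the nonlinear time-explicit model over the frequency-domain model all
hold.

## Problem sizes and runtime choices

The reduced preset (N0 = 1, 60 mm brain depth, cell budget $4\times10^5$)
keeps a 0.5 MHz scenario near $94\times173$ cells and a full linear
time-explicit steady-state run under a minute; the verification oracles
use quasi-1-D columns of a few thousand cells. Full-scale sweeps at 2 MHz
and above (mesh rule at $N_0 = 2$) grow towards $10^6$ cells per case and
are opt-in via the cell budget. Numerical safeguards: the time stepper
flushes denormals (the sponge drives fields through the subnormal range),
refuses steps beyond the stability bound, and raises an error naming the
first non-finite cell if an instability develops; the frequency solver
validates PML width (≥ 1 wavelength) and reports the required spacing
when a grid exceeds its cell budget.

## Known limitations

Bone supports shear; the fluid-equivalent treatment absorbs mode
conversion into effective attenuation, which understates phase aberration
for oblique incidence. The axisymmetric geometry cannot represent lateral
skull asymmetry or transducer misalignment. The weak-shock regime ends
near $\sigma \approx 0.3$; no shock-capturing limiters are included, so
strongly shocked HIFU fields are out of scope. Thermal dose and cavitation
are not modelled.
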