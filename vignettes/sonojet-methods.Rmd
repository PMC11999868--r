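---
title: "Models and numerical methods in sonojet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in sonojet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonojet)
```

sonojet models the interaction of a single ultrasound-driven,
phospholipid-coated microbubble with the endothelial cell layer it
rests on, above a rigid plastic substrate — the standard in vitro
configuration of sonoporation studies. This vignette records the
models, the parameters that matter, the numerical choices, and what
the synthetic-data generators do and do not emulate.

## Radial dynamics

The bubble is assumed spherical with radius $R(t)$. The liquid phase
follows a Keller–Miksis equation (first-order in the wall Mach number
$\dot R/c_l$):

$$\left(1-\frac{\dot R}{c_l}\right) R\ddot R +
\frac{3}{2}\left(1-\frac{\dot R}{3c_l}\right)\dot R^2 =
\left(1+\frac{\dot R}{c_l}\right)\frac{p_L - p_0 - p_d(t)}{\rho_l} +
\frac{R}{\rho_l c_l}\frac{\mathrm{d}p_L}{\mathrm{d}t},$$

with liquid pressure at the wall

$$p_L = p_g + p_v - \frac{2\sigma(R)}{R}
- \frac{4\mu_l \dot R}{R} - \frac{4\kappa_s \dot R}{R^2}.$$

The $\ddot R$ contributions of the viscous terms inside
$\mathrm{d}p_L/\mathrm{d}t$ are collected on the left-hand side before
inversion, so the scheme needs no nested differentiation. An
incompressible modified Rayleigh–Plesset variant (radiation damping
only through the gas-pressure convection factor $1-3\kappa\dot R/c_l$)
is available via `compressibility = "none"` for comparison.

**Shell.** The coating follows the Marmottant description: surface
tension zero below the buckling radius $R_b$, elastic
($\sigma = \chi(R^2/R_b^2-1)$) between $R_b$ and the rupture radius
$R_r$, and the clean-interface value $\sigma_w$ beyond, with
$R_b = R_0/\sqrt{1+\sigma(R_0)/\chi}$. Shell dissipation enters
through the surface dilatational viscosity $\kappa_s$.

**Gas.** The gas core uses a reduced polytropic law
$p_g = p_{g0}(R_0/R)^{3\kappa}$ with
$p_{g0} = p_0 - p_v + 2\sigma(R_0)/R_0$ from mechanical equilibrium.
A full thermal description of the gas interior is outside the scope of
this package; the polytropic exponent is exposed
(`gas_model = "polytropic" | "isothermal" | "adiabatic"`) so a thermal
model can be slotted in later. The default $\kappa = 1.07$ is
appropriate for a perfluorobutane-like core near 1 MHz. A consequence
worth keeping in mind: the polytropic closure carries no thermal
dissipation, so large-amplitude collapses are somewhat more violent
than a thermally damped model would predict. This mostly affects
quantities that weigh the compression phase heavily (collapse wall
velocities, the per-cycle impulse phase); ratios and thresholds are
less sensitive.

**Parameter defaults** (all overridable):

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `rho_l`, `mu_l`, `c_l` | 998, 1e-3, 1482 | kg/m³, Pa s, m/s | water near 22 °C |
| `p0`, `p_v`, `sigma_w` | 101325, 2645, 0.072 | Pa, Pa, N/m | ambient, vapour, clean interface |
| `chi` | 0.5 | N/m | shell elastic modulus |
| `kappa_s` | 7e-9 | kg/s | shell surface viscosity |
| `sigma_R0` | 0.02 | N/m | initial tension at `R0` |
| `kappa` | 1.07 | — | polytropic exponent |
| `L`, `beta`, `c_beta` | 12e-6, 0.8, 1 | m, —, Pa s^β | cell thickness, spring-pot order and coefficient |

The shell triplet (`chi`, `kappa_s`, `sigma_R0`) is taken from typical
lipid-shell literature values for DSPC-based coatings; these
quantities are not measured per-bubble, so absolute predictions that
depend on them (e.g. the minimum jetting pressure) should be read as
order-of-magnitude anchors, while ratios and qualitative structure
(resonance location, threshold shape, stress ordering) are robust.

**Driving.** The pulse is
$p_d(t) = p_a\,\mathrm{env}(t)\sin(2\pi f t)$ on $[0, n_{cyc}/f]$ and
exactly zero outside. The envelope defaults to a linear ramp over the
first 5 of 20 carrier cycles, then unity; the exact experimental ramp
is instrument-specific, so a sampled hydrophone table can be supplied
instead (`envelope =` a `time_s`/`amplitude` data frame, CSV
round-trip via `read_envelope()`/`write_envelope()`). The spatial
gradient uses the plane-travelling-wave closure
$\partial p/\partial x = -(1/c_l)\,\partial p/\partial t$, projected
on the substrate normal by $\cos(\mathrm{angle})$; the default 15°
corresponds to a transducer insonifying 75° from the horizontal with a
horizontal substrate.

**Amplitude calibration.** In-chamber amplitudes differ from
free-field hydrophone values because of absorption and reflections.
`fit_amplitude()` infers the single multiplicative amplification
factor from a measured radius-time track by bounded 1-D least squares
(factor in $[0.2, 5]$, the physically plausible range); on synthetic
tracks with 80 nm quantization noise the factor is recovered to well
under 2%.

**Numerics.** Stiff adaptive integration (`lsoda`) at relative
tolerance $10^{-8}$, dense output resampled to a uniform grid of 200
samples per carrier period (the grid the fractional memory term
needs). Halving the tolerance moves the maximum expansion by under
0.1%. Integration failure or collapse below $10^{-3}R_0$ raises an
error carrying the last valid state.

## Translational dynamics and the cell layer

The centroid displacement $x(t)$ (positive towards the substrate)
obeys $F_I = F_{B1} + F_{B2} + F_{AM} + F_{VD} + F_{CR}$ with

- $F_{B1} = -V\,\partial p_d/\partial x$ (primary Bjerknes),
- $F_{B2} = -\rho_l V\ddot V/(16\pi(L-x)^2)$ (secondary Bjerknes; the
  rigid substrate acts as an in-phase mirror bubble),
- $F_{VD} = -\tfrac12\rho_l\pi R^2\dot x|\dot x| C_D$ with
  $C_D = 24/\mathrm{Re} + 6/(1+\sqrt{\mathrm{Re}}) + 0.4$; the
  $24/\mathrm{Re}$ term is split off analytically as Stokes drag
  $-6\pi\mu_l R\dot x$ so the $\dot x \to 0$ limit is regular,
- $F_{CR} = -\pi R^2 c_\beta\, \mathrm{d}^\beta \epsilon/\mathrm{d}t^\beta$
  with strain $\epsilon = x/L$: a single spring-pot captures the cell
  rheology at the extreme strain rates involved ($10^5$–$10^7$ s⁻¹),
- $F_{AM}$: the added-mass force is implemented as the time derivative
  of the added-mass momentum,
  $F_{AM} = -\tfrac{\mathrm d}{\mathrm dt}\big[\tfrac12\rho_l V\dot x\big]
  = -\tfrac12\rho_l(\dot V\dot x + V\ddot x)$, which is the
  dimensionally consistent reading; the momentum-like variant
  $-\tfrac12\rho_l(\dot V x + V\dot x)$ is retained behind
  `added_mass = "as_printed"` for comparison only.
- The bubble mass $m = \rho_g V_0$ is nearly negligible but retained
  for well-posedness; the $\ddot x$ terms of $F_I$ and $F_{AM}$ are
  collected before inversion. The history (Basset) force is omitted —
  justified at the translational Reynolds numbers encountered (the
  solver reports time-averaged $\mathrm{Re}$ and
  $\mathcal{U}\mathrm{Re}$ diagnostics as plain time averages over the
  pulse). Gravity/buoyancy is omitted; over a 20 µs pulse it is below
  $10^{-4}$ of the Bjerknes forcing.

**Caputo derivative.** The fractional derivative uses the L1 scheme on
the uniform grid with weights
$b_{k-j} = (k-j+1)^{1-\beta} - (k-j)^{1-\beta}$, keeping the full
strain history (about 4000 steps over 20 µs — trivial cost). The
scheme is exact for linear strain histories and converges at order
$\tau^{2-\beta}$; with $\beta \to 1$ and $c_\beta = \mu_{eff}$ it
reproduces an explicit Newtonian dashpot trajectory to under 2%.

**Time stepping.** Implicit trapezoid on the radial grid
($\tau = 1/(200f)$), solved per step by a Newton iteration on the
acceleration. The implicit solve matters: the secondary Bjerknes term
delivers stiff, large kicks at each collapse. Halving $\tau$ changes
$x_{max}$ by under 0.5%.

**Ultimate compression.** The strain is not capped. If the centroid
reaches the substrate ($x \to L$; in experiments, a transendothelial
tunnel) the integration stops and the event is flagged rather than
modelled — the mirror-image hydrodynamics is meaningless past that
point. Under the reference high-amplitude conditions (3 µm bubble,
160 kPa) this happens at about 6.5 µs.

## Kelvin impulse and jet anisotropy

Per ultrasound cycle (windows delimited by the upward zero crossings
of the carrier, one value per cycle), the package integrates
$I = -\int V\,\nabla p\,\mathrm{d}t$ separately for the
travelling-wave gradient and the substrate gradient
$\nabla p_{sub} = \rho_l\ddot V/(16\pi(L-x)^2)$ (so that
$F_{B2} = -V\nabla p_{sub}$). For a vapour bubble growing and
collapsing under a constant driving pressure $\Delta p$ the impulse
has the closed form $|I| = C R_0^4|\nabla p|\sqrt{\rho_l/\Delta p}$
with $C = 2\cdot\tfrac43\pi\sqrt{3/2}\cdot\tfrac13 B(11/6, 1/2)
\approx 4.789$; `rayleigh_prefactor()` recovers $C$ either by
time-domain integration of the collapse or by the equivalent
radius-domain quadrature. Inverting this closed form on the *virtual*
impulse computed with a unit gradient gives each cycle an equivalent
time-invariant driving pressure $\overline{\Delta p}$, and the
anisotropy parameter follows as
$\zeta = I/(C R_0^3\sqrt{\rho_l\overline{\Delta p}})$, with
$R_0$ the largest radius in the window. In the constant-gradient limit
the chain reproduces the definition
$\zeta = -\nabla p\,R_0/\Delta p$ to quadrature accuracy. Reports
expose both raw impulses and the $\zeta$-normalized values, plus the
ratio $|I_{sub}/I_{us}|$.

## Stress mechanisms

Six channels are assembled on a common grid: water-hammer pressure
$p_{jet} = \tfrac12\rho_l c_l u_{jet}$ (an event channel firing at
compression peaks once the 1 µm expansion threshold has been crossed),
jet stagnation pressure $\tfrac12\rho_l u_{jet}^2$, wall
impact/suction pressure $\tfrac12\rho_l|\dot R|\dot R$, oscillatory
shear $\mu_l\dot R/\delta$ and streaming shear
$\mu_l u_{stream}/\delta$ with
$\delta = \sqrt{2\mu_l/\rho_l\omega}$ (0.565 µm in water at 1 MHz),
and the Bjerknes cross-section pressures
$p_{B1} = -\tfrac43 R\,\partial p_d/\partial x$,
$p_{B2} = -\rho_l R\ddot V/(12\pi h^2)$.

Three deliberate choices:

- **Observation bandwidth.** Wall-velocity channels are computed from
  the radius series resampled at the high-speed-camera frame rate
  (10 Mfps) before differentiation, because this stress comparison is
  defined on observed bubble motion; differentiating the 5 ns solver
  grid instead would let sub-frame collapse spikes — invisible to any
  such measurement — dominate the impact channel. Pass
  `sample_rate = NULL` for the native grid if that is what you want.
- **Mirror validity.** $h$ defaults to the centroid-substrate distance
  $L - x(t)$, but is floored at the instantaneous bubble radius: the
  point-mirror approximation behind $p_{B2}$ does not hold closer than
  about one radius, and $1/h^2$ would otherwise diverge spuriously on
  approach to tunnel contact. The series also ends at contact.
- **Jet parameters.** $u_{jet}$ defaults to 60 m/s, the lower bound
  implied by a jet traversing a 6 µm bubble within a single 0.1 µs
  frame (`min_jet_speed()`); $R_{jet}$ defaults to $R_0/4$ (0.75 µm
  for the reference bubble) and only enters the contact-geometry
  outputs $\varrho = R_{jet}u_{jet}/c_l$ and
  $\varsigma = \varrho/c_l$, not the pressures.

## AFM Hertz fitting

`fit_modulus()` fits $F = \tfrac43 E/(1-\vartheta^2)\sqrt{\mathcal R}
\iota^{3/2}$ with the contact point as a free parameter: the model is
linear in $(\mathrm{baseline}, E)$ at fixed contact point, so the fit
profiles the contact point by a coarse scan plus golden-section
refinement with an inner linear solve. Curves without a clear contact
point — fewer than 10 post-contact samples, non-positive modulus, or a
fitted indentation signal within the residual noise — are flagged
invalid rather than forced. Aggregation follows the
median (grid points) → mean (locations) → mean ± sd (samples)
hierarchy used for soft hydrogel characterization. Indentation is
assumed computed upstream (displacement minus deflection); deflection
sensitivity calibration is out of scope, and synthetic curves are
generated directly in force-indentation space.

## Synthetic data: what it does and does not emulate

The generators reproduce the *statistical structure* the analysis
assumes: 10 Mfps sampling, uniform ±80 nm (half-pixel) quantization
noise on radius and position tracks — uniform, not Gaussian, because
pixel quantization is the noise source — ramped-pulse envelopes
sampled at ≥ 50 points per cycle, event sweeps over
$R_0 \in [1, 4]$ µm, and Hertzian force curves with baseline offset,
contact-point jitter and multiplicative noise. Every generator is a
pure function of (parameters, seed) and leaves the global RNG stream
untouched.

They do **not** emulate video imaging itself (feature extraction from
frames), non-spherical bubble shapes, shape-mode dynamics or jets —
the radial model is spherically symmetric, so passing
parameter-recovery tests on synthetic tracks demonstrates the
fidelity of the inference chain, not of the sphericity assumption on
real data. Likewise the jetting classification is a threshold rule on
radial expansion, not a jet simulation: shape-mode metadata (spherical
harmonic degree and order) can be stored but is not modelled.

## Problem sizes and runtimes

The reference simulations use 200 samples per carrier period
(4000–8000 steps per 20–40 µs window); a coupled radial +
translational run takes well under a second, the full threshold map
(13 radii × ~10 bisection steps, 1 kPa tolerance) about a minute. The
test suite and the reproduction script are sized accordingly.

## Known limitations

- The polytropic gas closure omits thermal damping; compression-phase
  extremes (collapse speeds, and anything derived from them on the
  native grid) are upper-ish estimates.
- Shell parameters are literature-typical, not per-bubble
  measurements; absolute thresholds inherit that uncertainty (about a
  factor of two), the resonance structure does not.
- The translational model ends at tunnel contact; post-contact
  mechanics (pore formation, bubble lodging) is out of scope.
- The spring-pot uses a single fractional element; dual-branch
  fractional rheologies that distinguish low and high rate responses
  are not implemented.
- The streaming stress uses a literature bound for $u_{stream}$
  (default 0.1 m/s) rather than computing the streaming flow field.
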