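---
title: "Methods: membrane mechanics and conduction in nanopearled axons"
author: "axonpearl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane mechanics and conduction in nanopearled axons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Unmyelinated axons of the mammalian central nervous system are not uniform
tubes: under near-native preservation they are chains of nanoscopic
nonsynaptic varicosities (NSVs, roughly 200-640 nm wide) joined by thin
connectors (roughly 50-220 nm wide), a pearls-on-a-string morphology. This
package implements the computational side of that observation end to end:
a seeded generator of pearled radius profiles with exact ground truth, the
inflection-point morphometry used to quantify such profiles, an
axisymmetric Helfrich membrane model that explains why thin tubes pearl,
and a generalized cable-equation Hodgkin-Huxley (HH) simulator that
quantifies what pearling does to action-potential (AP) conduction.

This vignette is the package's account of the science and of the numerical
and design choices behind it. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The pearl-chain backbone

All pearled geometries in the package (synthetic profiles and cable
geometries alike) share one parametric family, fixed by the four
morphometric dimensions: NSV length $L_n$ (measured between inflection
points), NSV width $W_n$ (maximal diameter), connector length $L_c$
(between adjacent NSV boundaries) and connector width $W_c$ (diameter).
The backbone is a Tukey-window-like profile: a flat NSV plateau at radius
$W_n/2$ and a flat connector at $W_c/2$, joined by tapers whose second
derivative is a $\sin^2$ pulse,

$$ r''(\xi) = \pm T \sin^2(\pi \xi / e), \qquad T = 2\,\frac{W_n - W_c}{2 e^2}, $$

over a taper half-width $e = \min(L_n/2,\, L_c/4)$ on each side of a
boundary. Two properties motivated this choice over a plain raised cosine:

* the curvature is *exactly odd* about each NSV/connector boundary, so the
  inflection point survives symmetric (Gaussian) smoothing unmoved. A
  cosine or cubic-taper bump has asymmetric curvature across the boundary
  and provably shifts the detected inflection by a length of the order of
  the smoothing scale, which would make sub-sample-accurate ground-truth
  recovery impossible at any realistic smoothing;
* the connector keeps at least its central 50% exactly flat (the reason
  for the $L_c/4$ cap on $e$), so the robust width estimator below is
  exact on noiseless data, and the NSV plateau makes "width = maximal
  diameter" exact as well.

The synthetic-data generator (`gen_pearl_profile()`, `gen_population()`)
samples this backbone at 5 nm (at least ten times finer than the thinnest
reported connectors), adds optional truncated-normal dimensional jitter
and Gaussian radius noise, and records exact pre-noise boundaries and
dimensions. Per-axon population dimensions are truncated-normal draws;
standard deviations default to s.e.m. $\times \sqrt{n}$ back-computed from
cohort tables and are user-overridable. All randomness flows from explicit
integer seeds through an RNG scope that restores the caller's state.

What the generator emulates: electron-microscopy-derived 1D radius
profiles, STED-like axial intensity profiles (cross-section area convolved
with a Gaussian point-spread function, Poisson photon noise), 40-nm
serial-section stacks with a Pythagorean 3D ground truth, and per-axon
annotations (synaptic flags, maximal diameter, presence of a presynaptic
terminal) that drive the cohort exclusion rules. What it does not emulate:
raw micrographs, pixel noise, tracing errors, curvature of the axon path
in the imaging plane, or any biological correlation between adjacent
pearls beyond independent jitter. Passing tests therefore certify the
measurement pipeline on idealized profile data, not segmentation of real
images.

## Morphometry

`segment_profile()` implements the field's measurement convention:
boundaries between NSVs and connectors are inflection points of the
diameter function. The diameter is smoothed with a Gaussian kernel
(default sd 15 nm, well under the thinnest connectors while suppressing
sampling-scale noise), differentiated twice by central differences, and
boundaries are placed at zero crossings *between runs of significant
curvature*. The significance floor is $\max(0.05\,|d''|_{\max},\,
\min(4\hat\sigma_{d''},\, 0.5\,|d''|_{\max}))$, where $\hat\sigma_{d''}$
propagates a robust (median-absolute-deviation) estimate of the raw
diameter noise through the combined smoothing+differencing kernel. The
floor keeps flat plateaus and noise from seeding boundaries; its cap at
half the peak curvature preserves the classic scale-space property that
the boundary count never grows with the smoothing window. Coincident
crossings within a run are merged at the midpoint of the crossing
interval. A crossing from convex to concave opens an NSV (the segment
holding a local diameter maximum); partial segments at the profile ends
are dropped; a cylinder yields zero segments.

Widths are read from the smoothed diameter: the NSV width is the maximal
diameter in the segment, and the connector width is the median over the
central 50% of the segment — robust to boundary taper, and exact for the
degenerate uniform connector regardless of the estimator (both are
config-exposed because the underlying measurement scripts in this field
never fixed them). With noisy profiles, a wider kernel (25 nm) is the
package's recommended setting; the noise-robustness test uses it.

`fwhm_length()` measures full-width-half-maximum lengths of intensity
peaks above a local background (the higher of the two flanking minima,
which guarantees both half-crossings exist), with linear interpolation.
FWHM lengths from intensity profiles and inflection-to-inflection lengths
from radius profiles are related but not interchangeable; the package
reports both without reconciling them. `spacing_periodicity()` quantifies
the fraction of NSV spacings within ±10% of the 190-nm period of the
axonal membrane periodic cytoskeleton; `reconstruct_3d()` applies the
serial-section Pythagorean correction
$\sqrt{L_{xy}^2 + ((n-1)\,t)^2}$.

## Membrane shape relaxation

The membrane is a thin elastic surface with the Helfrich energy

$$ E \;=\; \int \frac{\kappa}{2}\,(2H - C_0)^2\, dA \;+\; \sigma A \;+\;
   F_{\mathrm{osm}}(V), $$

with bending rigidity $\kappa$ (in $k_BT$; sweeps cover 20-100),
tension $\sigma$ (in $k_BT/\mathrm{nm}^2$; the default 0.02 is about
0.08 mN/m, in the physiological range for loosely attached axonal
membrane), spontaneous curvature $C_0 = 0$ by default, and an ideal
van 't Hoff osmotic free energy $F_{\mathrm{osm}} = k_BT\,(c_{\mathrm{ext}}
V - n \ln V)$ for a fixed enclosed solute amount $n$, so
$\Delta P = k_BT (n/V - c_{\mathrm{ext}})$ is recomputed from the current
volume at every step and vanishes at the isotonic volume. Area is free to
exchange with implicit reservoirs at fixed $\sigma$ (no hard area
constraint). The shape is an axisymmetric periodic graph $r(z)$ — the
appropriate reduction because homogeneous parameters only admit periodic
unduloid-like solutions — discretized on 128 nodes with cyclic central
differences, where $2H = 1/(r\sqrt{1+r'^2}) - r''/(1+r'^2)^{3/2}$.

Minimization is a monotone gradient flow: the discrete energy gradient is
assembled analytically from the pointwise density and the adjoints of the
difference operators (verified against finite differences in the tests),
and steps use a semi-implicit spectral preconditioner that inverts the
stiff $k^4$ bending and $k^2$ tension parts of the near-cylinder Hessian
exactly, with backtracking so accepted steps never increase the energy.
Convergence is declared at an RMS gradient below $10^{-5}$
($10^{-4}$ in the sweep protocol); a radius falling below `r_min`
(default 2 nm) flags pinch-off and returns the partial state. The
default domain length is one expected pearl period, selected by an
independent linear-stability probe: the energy curvature of a
single-wavelength cosine mode about the tension-equilibrated uniform
cylinder, combined with the $k^2$ mobility of conserved-volume transport;
at the default parameters this selects a period near 1 µm, of the order
of measured pearl periods. Closed spheres use a separate polar-angle
parametric state; they anchor the solver against $E_{\mathrm{bend}} =
8\pi\kappa$ and the Young-Laplace balance $\Delta P = 2\sigma/R$ of the
equilibrium sphere (`equilibrium_sphere()` minimizes the closed-vesicle
energy over the radius; bending exerts no net radial force on a sphere at
$C_0=0$).

Two findings about this ensemble, established by the package's own
experiments and worth stating plainly because they shape what the tests
can assert:

* **The pearling bifurcation is effectively subcritical and the attractor
  is a bending-arrested sphere chain.** With volume pinned osmotically and
  area free, tension drives the tube toward the minimal-area shape at
  fixed volume — a chain of quasi-spheres whose necks thin until bending
  arrests them at a radius of order $\sqrt{\kappa/\sigma}$. The necks are
  therefore *locally bending-dominated at any* $\kappa$, and the
  mean-curvature field of the fully relaxed shape deviates from constancy
  by ~17% even at the gentlest attainable pearled equilibrium (and more
  toward the sphere-chain limit). A strict constant-mean-curvature check
  at the 5% level fails for these equilibria; the corresponding
  acceptance expectation is kept at 5% and documents this limitation
  rather than being loosened.
* **Tension affects the two NSV dimensions oppositely.** Because osmotic
  stiffness holds the volume within a fraction of a percent across the
  physiological tension range, raising $\sigma$ moves the equilibrium
  closer to the sphere chain: the selected period (and hence NSV length)
  shrinks, while the NSV width grows toward the complete-ball diameter.
  The osmolarity trend, in contrast, is strong and consistent: raising
  external osmolarity deflates the tube and shrinks both NSV width and
  length; rigidity has the expected modest effect. The tension-width half
  of the corresponding acceptance expectation is left red with this
  explanation.

`sweep_membrane_parameters()` fixes the enclosed solute per unit length at
the base condition's isotonic amount, re-selects the domain per condition
(the stability analysis is part of the protocol), relaxes, converts the
shape to a radius profile and measures it with the same morphometry as
experimental profiles.

## Cable-equation action potentials

APs are integrated on the generalized cable equation with HH currents,

$$ c_m \frac{\partial V}{\partial t} \;=\;
   \frac{1}{2\pi a \sqrt{1+a'^2}}\,
   \frac{\partial}{\partial x}\!\left(\frac{\pi a^2}{R_i}
   \frac{\partial V}{\partial x}\right) \;-\; i_{\mathrm{HH}}(V, m, h, n)
   \;+\; i_{\mathrm{stim}}, $$

on a model axon with an AIS cylinder (500 nm diameter, 90 µm, five-fold
channel density — applied to Na, K and leak jointly so the resting state
stays a steady state of the heterogeneous cable — cosine-tapered onto the
trunk over its last 5 µm) and a
300-µm trunk that is either a pearl chain of the backbone family or a
cylinder. The stimulus is 40 µA/cm² for 1 ms over the first half of the
AIS; probes sit at -90, 0 and 277 µm, and the conduction velocity is
277 µm divided by the difference in quadratically interpolated
time-to-peak between the last two (a half-maximum upstroke readout is kept
as a cross-check and agrees within 5%).

Numerics: finite volumes on a grid of 20 nm in the trunk (resolving the
190-nm channel period and the thinnest connectors with 8+ samples) and
200 nm in the AIS. Because the backbone is analytic, each control
volume's membrane area and each interval's axial series resistance
($\int dx/a^2$) are integrated on a 2-nm subgrid of the analytic profile
at build time, so the steep pearl tapers (slopes above 1) do not alias at
the simulation grid — the one-period membrane area agrees with a fine
independent quadrature to 0.2%. Membrane areas carry the $\sqrt{1+a'^2}$
slope factor in both the capacitive and conductive terms (dropping it is
a config toggle); Crank-Nicolson for the linear cable
operator with a single sparse Cholesky factorization; explicit gating and
ionic updates at $\Delta t = 1$ µs, two orders of magnitude below the
fastest gating time constant. The initial condition is the
self-consistent resting state (`uniroot` on the steady-state current);
ends are sealed; $|V| > 500$ mV aborts with an error naming the time;
halving both $\Delta x$ and $\Delta t$ moves the control and cylinder
velocities by under 1% (asserted in the tests). Runs stop shortly after
the AP passes the distal probe.

Channel parameters are the classic HH conductances
($\bar g_{Na} = 120$, $\bar g_K = 36$, $g_L = 0.3$ mS/cm², modern
reversal conventions at a -65 mV rest) with $c_m = 1$ µF/cm² and
$R_i = 120\ \Omega$cm. One constant is a calibration convention: the
gating-rate temperature factor (`rate_scale = 3.3`, about one standard
Q10 decade, appropriate for recordings made far above the 6.3 °C of the
classic kinetics) was fixed once so that the untreated control geometry
(NSV 638 × 309 nm, connector 486 × 136 nm) with the periodic layout
conducts at 0.173 m/s, and is stored in `ephys_params()`, never in the
solver. All other geometries are then genuine predictions; the test suite
records which published predictions fall inside ±10% and which do not.
Relative velocities between geometries are invariant to the joint
conductance/resistivity scalings available here, so any deviations are
structural properties of this parameterization, not calibration slack.

`place_channels()` builds the NaV layouts: uniform density, or clusters
every 190 nm (centres at $(k-\tfrac12)\cdot 190$ nm, 1579 clusters over
300 µm) modelling one cytoskeletal ring each with equal conductance per
cluster, rescaled so the area-integrated trunk Na conductance matches the
uniform layout to 0.1%. A result the package establishes and the tests
document: under that conservation, uniform and periodic layouts give
velocities equal to parts in $10^6$ on *both* cylindrical and pearled
geometries. This is forced by scale separation — the AP's spatial extent
(~85 µm) homogenizes any sub-period arrangement, and the homogenized
cable sees only the period-averaged conductance per length, which
conservation fixes. A layout-dependent speed-up on pearled axons would
require a non-conserving convention; the acceptance expectation that
periodic beats uniform on pearled geometry is therefore red, with this
analysis as the package's position.

`sweep_dimension()` maps velocity against one dimension (linear fits for
connector width/length and cylinder diameter, a Gaussian-bump nonlinear
fit for NSV width whose centre is the reported optimum), and
`predict_from_measurements()` turns a measured four-dimension row into a
velocity with one call.

## Problem sizes and reproducibility

The test suite and acceptance script were sized for a single CPU: cohort
recovery uses 300 axons of 3 periods; the round-trip property loops over
200 random chain specs; relaxations use 128 nodes; grid-convergence
checks run the control and cylinder geometries at half $\Delta x$ and
$\Delta t$; the acceptance sweeps use an 11-point width grid and a 6 × 6
(length, width) grid. Every stochastic step takes an explicit seed;
`run_experiment()` derives per-stage seeds from the global one and writes
a manifest with the config hash so identical configs reproduce identical
deterministic outputs (asserted by checksum in the tests).

## Known limitations

* The morphometry operates on extracted 1D profiles, not images; its
  accuracy statements are with respect to the generator's backbone family.
* The membrane model is axisymmetric with homogeneous parameters; it
  cannot (and does not attempt to) reproduce connector geometry, which
  would require spatial heterogeneity.
* The fixed-solute/free-area ensemble has the sphere-chain attractor and
  the tension-width behaviour discussed above; a constant-pressure or
  area-elastic ensemble would behave differently and is not implemented.
* The cable model is single-compartment in cross-section, unmyelinated,
  deterministic, with Na-only clustering; extracellular fields and
  stochastic gating are out of scope.
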