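---
title: "A station-wise ring model of stent-graft deployment in aortic dissection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A station-wise ring model of stent-graft deployment in aortic dissection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stentring)
```

## The problem

Thoracic endovascular aortic repair (TEVAR) of type B aortic dissection
implants a self-expanding Nitinol stent-graft (SG) into the true lumen. The
device's final configuration — how far each stent ring opens, where the
struts sit — emerges from a contest between the wire's radial force, the
graft fabric, blood pressure inside the graft, and a vessel wall that is
*already stressed* in the imaged (diastolic) state. `stentring` reproduces
this contest at desk scale: instead of a 3D finite-element continuum, the
vessel is a sequence of independent thin rings ("stations") along the
centreline, and every stage of the procedure — tissue-parameter fitting,
diastolic pre-stress recovery, crimping, release, and the post-deployment
load swap — reduces to scalar constitutive laws and one radial equilibrium
per station.

What the ring reduction keeps: the nonlinear wall response, the
history-dependent superelastic wire, the oversizing contest between device
and vessel, the role of pre-stress and of graft internal pressure, and the
configuration metrics used to compare a simulation against a follow-up
scan. What it gives up: axial mechanics (delivery-path effects, spring-back
along the arch), tangential contact/friction, a separately pressurized
false lumen, and any patient-specific 3D geometry. Patient-level headline
numbers from imaging-based studies are therefore outside what this package
can or tries to reproduce; the qualitative mechanics are the target.

## Constitutive laws

**Wall.** Incompressible isotropic Yeoh hyperelasticity,
$W = c_{10}(\bar I_1-3) + c_{20}(\bar I_1-3)^2 + c_{30}(\bar I_1-3)^3$,
with the averaged dissected-aorta coefficients
$c_{10} = 17.5$, $c_{20} = 58.9$, $c_{30} = 116.1$ kPa as the default. Two
kinematic specializations are exported: uniaxial tension
($I_1 = \lambda^2 + 2/\lambda$,
$\sigma = 2(\lambda^2-\lambda^{-1})\,\partial W/\partial I_1$) for strip
tests, and the plane-strain ring
($I_1 = \lambda_\theta^2 + 1 + \lambda_\theta^{-2}$,
$\sigma_\theta = 2(\lambda_\theta^2-\lambda_\theta^{-2})\,
\partial W/\partial I_1$) for vessel stations. Both are verified in the
test suite against central finite differences of $W$ along their paths
(relative error $<10^{-6}$).

**Flap.** The intimal flap is linear elastic ($E = 277$ kPa,
$\nu = 0.49$), contributing $E(\lambda-1)$ over its own thickness to the
ring equilibrium of dissection stations. The false lumen is *not* a
separate pressurized chamber; its mechanical effect is absorbed into the
wall-plus-flap response of the dissection section — a stated limitation of
the ring reduction.

**Wire.** A 1D flag-shaped superelastic model with the standard constants
for stent-grade Nitinol: austenite slope $E_A = 51{,}700$ MPa up to the
forward-plateau onset at 600 MPa, linear hardening to 670 MPa while the
martensite fraction $\xi$ rises 0 to 1 carrying transformation strain
$\xi\,\varepsilon_L$ ($\varepsilon_L = 0.063$), martensite slope
$E_M = 47{,}800$ MPa beyond; unloading is elastic to 288 MPa, reverses
along the 288 to 254 MPa plateau, and recovers completely. Within any
branch the strain decomposes as
$\varepsilon = \sigma/E(\xi) + \xi\,\varepsilon_L$ with the linear
(Voigt-style) mixture modulus $E(\xi) = E_A + \xi(E_M-E_A)$ — the simplest
rule consistent with a table listing both moduli; the plateau interpolation
is likewise linear in $\xi$. Neither choice is claimed identical to any
commercial implementation; they are this package's documented
idealization. The compressive onset (900 MPa) is stored and validated but
unused: the ring model loads wire in tension only. Temperature and density
are metadata (quasi-static, isothermal). The incremental driver is
strain-controlled and resolves each step from the final strain alone
within a regime, so sub-stepping is exact; stress-controlled queries
root-find on the strain-controlled law.

```{r}
np <- nitinol_params()
s <- nitinol_drive(nitinol_state(), 0.0775, np)   # load to full martensite
c(stress_MPa = s$stress, xi = s$xi,
  transformation_strain = s$strain - s$stress / np$E_M)
```

## Tensile fitting

Strip tests (25 mm grip distance, 0.05 N preconditioning load, 40 × 10 mm
circumferential strips) are converted to Cauchy stress-stretch curves: the
stretch reference is the grip distance at which the force first reaches the
preload, and $\sigma = F\lambda/A_0$ under the incompressible
area-reduction $A = A_0/\lambda$. The displacement rate is metadata; no
viscoelasticity is modelled. The yield point — never formally defined in
strip-test protocols — is taken as the *first global stress maximum*
(physically the onset of tearing), with an explicit index override
available; fitting runs from zero stretch to that point.

Fitting is Levenberg-Marquardt nonlinear least squares
(`minpack.lm::nlsLM`) of the uniaxial Yeoh stress, initialized at
(10, 10, 10) kPa with a positivity bound on $c_{10}$ only, plus three
jittered restarts under a fixed internal seed to guard against local
minima. $R^2$ is computed on the fitted range. Per-sample parameters are
averaged arithmetically (parameters, not curves, are averaged). On
noiseless self-generated data the pipeline is an identity to better than
0.1% and $R^2 = 1$ to $10^{-10}$ — this is the package's parameter-recovery
acceptance check.

## The synthetic patient

`generate_vessel()` is a first-class module, not a fixture: it emulates the
anatomy of a dissected descending aorta as an ordered station table with
three contiguous landing sections. Defaults (all configurable, chosen once
and documented here):

* healthy proximal aorta, lumen radius 13 mm — the 28 mm device is
  oversized there;
* entry-tear region with an aneurysmal bulge to 15 mm radius — beyond the
  14 mm graft cap, so these ends open widest;
* dissection section tapering to a 3.25 mm radius (6.5 mm diameter, the
  narrowest-lumen figure the anatomy emulates) at arclength 150 mm, with a
  mild distal recovery;
* wall thickness 1.5 mm everywhere; an intimal flap of 0.6-1.6 mm
  thickness in the dissection section; 80 mmHg diastolic pressure;
* stations every 2.5 mm over 220 mm, straight centreline by default
  (optional constant curvature), optional smoothed radius noise, and
  deterministic output for a fixed `(config, seed)`.

The exact per-section radii of a real case are not published; 13/15/3.25 mm
are declared generator assumptions that place the device-vessel contest in
the physiologically interesting regime. What passing tests on this
generator shows is that the *mechanics* behave correctly — they say nothing
about any individual patient's geometry.

`generate_tensile_data()` inverts the strip-test pipeline exactly at zero
noise (multiplicative Gaussian noise optional), and
`reference_stent_configuration()` builds apex point sets with analytically
known open areas for metric validation.

## Pre-stress recovery

The imaged geometry is the *loaded* diastolic configuration, so the wall
must carry an initial hoop stress $\sigma_0$ per station. The fixed-point
iteration starts from zero stress, pressurizes each ring to 80 mmHg
(converted once, 0.1333224 kPa/mmHg; ramped in 8 continuation steps for
solver robustness — the static answer is ramp-independent and tested as
such), takes the total hoop stress at the resulting equilibrium as the next
$\sigma_0$ (under-relaxed by 0.7, configurable), and stops when the
pressurized radii match the imaged radii to within 0.5 mm — the standard
geometric criterion — with an iteration cap of 50. Neither the
under-relaxation nor the cap comes from any published protocol; both are
artifact decisions. At the fixed point the pressurized stretch is 1 and
$\sigma_0$ equals the thin-wall Laplace value $P r/h$, which the tests
verify in a stiffened-wall limit to 1%.

**Why pre-stretch rather than additive stress.** Interpreted literally as
an additive term, $\sigma_{tot} = \sigma_{hoop}(\lambda) + \sigma_0$, the
pressurized equilibrium of a 13-15 mm station is a limit-point-unstable
root for this tissue fit: the initial hoop slope $8c_{10} = 140$ kPa falls
below $2Pr/h \approx 185$-$213$ kPa, the pressure-radius curve slopes
downward at $\lambda = 1$, and the fixed-point update oscillates instead of
contracting. Physically, a diastolic artery does not operate on its
low-stiffness toe region: it is *pre-stretched* onto the stiffening branch.
The package therefore realizes $\sigma_0$ through the equivalent
circumferential pre-stretch $\lambda_{pre}$ solving
$\sigma_{hoop}(\lambda_{pre}) = \sigma_0$, composing stretches for any
further deformation (unloaded radius $r_{CT}/\lambda_{pre}$, unloaded
thickness $h_0\lambda_{pre}$). This has the same fixed point, coincides
with the additive form in the stiff-wall limit, and is stable because the
wall sits on its stiffening branch. The additive form remains available
(`model = "additive"`).

```{r}
vessel <- generate_vessel(seed = 1)
ps <- prestress_fixed_point(vessel)
ps
```

## Deployment and the three loading variants

Crimping the device from 28 to 7 mm drives a representative wire strain
$\varepsilon = \kappa (R_{nom} - r)/R_{nom}$ through the superelastic law.
$\kappa = 0.1$ is chosen so the crimp strain (0.075) lands just past the
forward plateau — inside the design window
$[\varepsilon_L,\ \varepsilon_L + \sigma_L^E/E_M + 0.01]$ — giving the
wire its characteristic asymmetry: high radial resistive force along the
loading plateau during crimping, lower chronic outward force along the
unloading plateau during release. Outward pressure is $\alpha\,\sigma$
with $\alpha = 0.05$ kPa/MPa, picked once so stent pressures land in the
tens-of-kPa range of arterial loads; with no published wire-level geometry,
$\kappa$ and $\alpha$ are free calibration constants, not reproductions.
The graft fabric is a radius cap: a steep linear penalty
($10^4$ kPa/mm) above the nominal radius. Its two physical roles —
limiting expansion and transmitting internal pressure — are both captured;
its membrane elasticity is not.

Pre-dilation raises every station with lumen diameter below 8 mm to a 4 mm
radius (new reference configuration); delivery reduces to direct placement
of the crimped rings at their landing stations, since a ring model has no
axial mechanics — the central simplification. Release then solves, per
strut-end station, the unilateral contact equilibrium
$P_{graft} + P_{stent}(r) = P_{wall}(r)$ by bracketed root-finding
(quasi-static; no explicit dynamics). If the implied contact pressure at
the root is negative the surfaces separate: the stent-graft free-expands to
the cap and the shielded wall finds its own zero-pressure equilibrium.

The three variants differ only in the wall state and graft loading:

* **A** — wall stress-free at the imaged geometry, no graft pressure;
* **B** — pre-stress applied, lumen pressure removed, no graft pressure;
* **C** — pre-stress applied and 80 mmHg inside the graft-covered ends
  (the bare proximal end P1 is uncovered and receives none).

Friction (tangential contact) is intentionally absent. On the default
patient the variants reproduce the expected qualitative picture: A
over-opens everywhere (no pre-tension to fight), B under-opens (the
depressurized wall recoils onto the stent), and C sits between them —
with per-end radii ordered $r_B \le r_C \le r_A$, the entry-tear ends
widest and the dissection ends narrowest, entry-tear wall stress reduced
(shielding) and dissection wall stress raised (the stent forcing the
narrowed lumen open). The pre-stretch composition above is what makes the
B/C wall incrementally stiffer than A's; with a purely additive
$\sigma_0$ the C-vs-A ordering inverts in the dissection, which is why the
additive form is not the default anywhere.

```{r}
sg <- stent_graft()
dep <- lapply(c(A = "A", B = "B", C = "C"), function(v)
  deploy(sg, vessel, deployment_config(variant = v), prestress = ps))
dep$C
wall_stress_report(dep$C, vessel)
```

## Configuration metrics

The local open area (LOA) of a strut end is the area enclosed by a closed
curve through its apex points: the least-squares plane of the apex cloud is
taken from the two dominant principal directions of the centred points (no
published plane-fitting convention exists to match), the points are closed
with a periodic cubic spline under chord-length parameterization, and the
area is integrated by Green's theorem on a dense sampling; a polygon
(shoelace) mode serves as a cross-check. The construction is rigid-body
invariant, and on $n$ equally spaced circle points converges to $\pi r^2$
(error below 0.1% at $n = 64$). Degenerate inputs (collinear points,
self-intersecting projected loops) are rejected by name.

The strut-centre deviation $e_c$ is the Euclidean distance between apex
centroids (centroid, not a centreline point — a documented choice), and a
true metric. Section summaries use the population SD (n denominator; no
convention is published to match). Simulated and reference configurations
share a coordinate frame here, so no image registration is performed; a
rigid pre-alignment hook is provided for externally registered data.

## Numerical choices, sizes, determinism

* Scalar roots: `stats::uniroot` to tolerance $10^{-12}$ (ring stretch)
  after a 400-point bracket scan that selects the branch continued from
  the unloaded state; $10^{-9}$ mm for deployment radii.
* Superelastic sub-stepping: $2\times10^{-4}$ strain within deployment,
  $10^{-5}$ where plateau onsets are being located; plateau $\xi$ solved
  in closed form (quadratic) with a root-finder fallback.
* Yield ties break to the first maximum; duplicate stretches are dropped
  after preload referencing.
* Default problem sizes — 89 stations (2.5 mm spacing), 18 strut ends,
  3 variants, 12 synthetic tensile samples of 50 points — are chosen so
  that every mechanism (taper, bulge, flap, separation, cap) is
  exercised while the whole pipeline remains a lightweight desk-scale
  computation.
* All generators are pure functions of `(config, seed)`; the pipeline
  embeds the seed and a configuration hash in every output file, and
  re-running with the same seed is byte-identical.

## Known limitations

One ring per station means no axial coupling: landing-zone migration,
spring-back of the device along a curved arch, and delivery-path effects
are invisible. The false lumen is not a pressure chamber, so retrograde FL
loading of the flap is folded into an effective wall. The graft is a cap,
not a membrane — fabric wrinkling and fold-gaps cannot appear. Wire-level
force magnitudes rest on the $\kappa, \alpha$ calibration; only
*relative* statements across variants and sections are meaningful. The
anisotropy of the dissected wall and any stiffness contrast between true-
and false-lumen sides are out of scope, as is any form of haemodynamics.
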