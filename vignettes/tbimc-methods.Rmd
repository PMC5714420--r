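---
title: "Methods: a fast voxel Monte Carlo dose engine for Co-60 TBI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a fast voxel Monte Carlo dose engine for Co-60 TBI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tbimc simulates the dose delivered by a cobalt-60 total-body-irradiation
(TBI) unit: a 2 cm-radius source 195.4 cm above the floor irradiates a
50 x 200 cm field through a stacked lead flattening filter, with the
patient (or phantom) lying on a table 6 cm above the floor. The engine is
deliberately minimal — it keeps only the physics that matters for TBI-grade
accuracy at 1.25 MeV — and this vignette records the model, its
approximations, the tunable parameters, and the design choices that were
genuinely open.

## Beam model

Cobalt-60 emits 1.17 and 1.33 MeV gammas in equal number; the engine uses
the single effective line at their mean, 1.25 MeV. Emission is
"aperture-targeted": each photon starts at a uniform point on the source
disk and is aimed at a uniform point on the field rectangle at floor level,
so no history is wasted outside the collimation. The angular emission law
inside the collimated cone is not specified by the treatment-head geometry
we model, and uniform-over-the-aperture is the simplest declared choice;
the resulting fluence at the floor is flat *before* the filter. Head
leakage, the electron-contamination acrylic sheet, the treatment table and
air interactions are all excluded.

Two consequences are worth stating plainly:

* **Inverse-square behaviour is geometric.** Divergence from the finite
  disk source is modeled exactly; fluence through horizontal planes falls
  as $1/d^2$.
* **The "flattening" invariant is not reproducible from the printed plate
  stack.** With six 0.3175 cm plates (diameters 7.62-33.0 cm) the central
  rays see 1.905 cm of lead (transmission ~0.28 at 1.25 MeV) while rays to
  the edge of the 200 cm field see at most one plate. That compensates an
  emission profile that is strongly peaked toward the axis — presumably the
  real collimator's — not the flat or cosine-cubed profiles one can justify
  from the stated geometry alone. Under our source model the filter
  therefore attenuates the centre roughly twice as strongly as the field
  edge (the mechanism of flattening), but the filtered entry-plane profile
  is not strictly flatter than the unfiltered one. The test-suite asserts
  the mechanism, not the unattainable profile comparison.

## Filter transport

Transmission through a lead thickness $t$ follows $A = e^{-\mu t}$, with
$t$ counted as 0.3175 cm per covering plate at the ray's lateral position
on the filter mid-plane (thin-stack approximation: the 1.9 cm stack is
negligible against the 25.4 cm source-filter distance). Plates are
concentric discs clipped to the 33 x 14 cm envelope (truncated in x, the
narrow field direction). Only zero- and single-scatter photons survive: an
interacting photon picks photoelectric, Compton or Rayleigh with
probabilities proportional to their shares of the lead attenuation
coefficient at 1.25 MeV; photoelectric absorbs it, Compton redirects and
degrades it (Eq. of Klein-Nishina kinematics), Rayleigh redirects it at
full energy; the scattered photon must then escape the remaining thickness
(sampled interaction depth, oblique exit path) without a second
interaction. No electrons leave the filter.

## Sampling tables

Both angular distributions are sampled by discretized inverse-CDF lookup:
the differential cross-section (Klein-Nishina times the solid-angle
Jacobian $\sin\theta$ for Compton; $(1+\cos^2\theta)\sin\theta F^2(q)$
with the lead atomic form factor for Rayleigh) is evaluated at 1 degree
resolution, cumulated, normalized, and expanded into 1001 equal-probability
slots; sampling is `round(u * 1000)` and a table lookup, with no per-event
comparison. Tables exist for every 10 keV from 10 keV to 1.25 MeV and
photon energies snap to the nearest row. The slot construction pins the
table CDF to the analytic CDF within one slot (1e-3), which is far below
every dosimetric effect of interest here; the test suite verifies both the
slot bound and the statistical agreement of large samples.

Two printed-formula ambiguities are resolved as explicit switches, both
defaulting to the standard physics: the Rayleigh angular factor is
$(1+\cos^2\theta)$ (`literal = TRUE` gives $1-\cos^2\theta$), and the
Compton recoil-electron polar angle uses
$\cot\varphi = (1 + h\nu/m_0c^2)\tan(\theta/2)$ (`literal = TRUE` flips
the inner sign, which sends recoils backwards and violates momentum
conservation — it exists only to reproduce the printed variant). The
recoil azimuth is the photon's plus 180 degrees, and direction rotations
use a local orthonormal frame tied to the global z-axis, which is the
well-posed form of the usual rotation matrix (a dedicated branch handles
near-vertical directions).

## Patient transport

The phantom is a voxel lattice (default 2.54 x 2.54 x 5 mm) carrying
Hounsfield units. Density follows the bilinear CT calibration
$\rho = 0.001\,\mathrm{HU} + 1.034$ for HU $\le 0$ and
$0.0006\,\mathrm{HU} + 1.034$ above, clamped to a floor of
0.001 g/cm^3; material classes are cut from density at
0.05 / 0.6 / 1.1 / 2.0 g/cm^3 (air, lung, soft tissue, bone, metal).
The paper-cited segmentation thresholds are not public; these are
conventional CT bands and are configurable in `density_model()`.

Photons advance in fixed steps of $h$ = 1 mm, accumulating optical depth
$\sum h/\lambda_j$ with $\lambda$ from the voxel at each step midpoint
(the midpoint rule is our declared resolution of the boundary-straddling
ambiguity; at $h$ = 1 mm it is symmetric and sub-voxel). One survival
threshold $u \sim U(0,1)$ is drawn per flight; the flight ends at the
first step where the accumulated transmission drops below it. Rayleigh
scattering is excluded in the patient; pair production is ignored
everywhere (1.25 MeV is below threshold for any relevant contribution).
Photoelectric events deposit the full photon energy locally — the
photo-electron range is sub-voxel at the energies where photoelectric
matters. Compton events sample the angle tables, split the energy exactly
($h\nu = h\nu' + T_e$), and hand the recoil electron to the CSDA
transport; particles below the 10 keV cutoff deposit locally.

Electrons travel in straight lines (no angular scatter, no straggling)
depositing $S_{col}(E)\,\rho\,h_e$ per sub-step. The sub-step is
$h_e = h/5$ = 0.2 mm with a shortened final step: at $h$ = 1 mm a single
step would exceed most Compton-electron CSDA ranges (a 0.3 MeV electron
has an 0.84 mm range) and quantize the buildup region; the finer sub-step
restores the ranges to within the discretization tolerance while leaving
the photon stepping at the published 1 mm. Energy accounting is exact:
entered = deposited + exited to floating-point precision, which the
acceptance suite checks at 1e-6 relative.

Dose is $\Delta E / (V \rho)$ per voxel (dose to medium); dose to water
multiplies by the water/medium mass collision stopping-power ratio at
0.3 MeV, the Bragg-Gray convention. Note the ratio for bone is ~1.13 and
for aluminum ~1.27: water stops electrons *harder* per gram than either.

## Physics data

Material tables are generated in code on a 10 keV grid, 10 keV-1.33 MeV:
Compton from the exact Klein-Nishina total cross-section times Z/A
(binding ignored, consistent with the transport model); collision stopping
powers from the Møller/Bethe formula with ICRU mean excitation energies
(the density effect, <1% below 1.25 MeV, is neglected); photoelectric and
Rayleigh components from embedded anchor curves following the standard
compilations, scaled between materials by effective atomic number. Both
minor channels are few-percent accurate at low energy, where they
contribute to scattered-photon absorption but negligibly to dose above
100 keV; lead is tabulated without K/L-edge structure because the
single-scatter rule means lead only ever attenuates photons of 0.212 MeV
or more. `write_material_tables()` serializes everything to CSV.

## Phantoms

`make_water_phantom()` builds the 31.8 x 48.4 x 30 cm validation tank
(HU = 0, density 1.034, base 6 cm above the floor);
`add_aluminum_insert()` places two 9.5 mm aluminum bars flanking a
measurement plane at 3 cm depth (bar spacing and lateral extent are
config parameters — the physical insert's exact spacing is not published;
the default gap is 3 mm). `make_layered_body()` builds a layered
soft-tissue/lung/bone slab with optional embedded blocks; it provides the
*material classes* of an anthropomorphic phantom for heterogeneity tests
and is explicitly not a replica of any physical phantom.
`read_ct_series()` imports a DICOM CT series (implicit/explicit VR little
endian) through a minimal reader written for this package.

What the generators emulate: geometry, densities and material classes of
the validation setups. What they do not: film dosimetry (energy response,
calibration, scanning), positioning uncertainty, CT artifacts, and real
anthropomorphic anatomy. Green tests therefore demonstrate the transport
and analysis chain on idealized media, not agreement with measured film.

## Depth of maximum in a broad beam

The engine reproduces the textbook Co-60 buildup: for a 2 x 2 cm beam the
central-axis curve is at a few percent of maximum at the surface, passes
~95% by 0.5 cm and is flat beyond (test suite). For the full TBI field,
however, the in-phantom scatter fluence keeps growing with depth faster
than the primary attenuates, and the simulated central-axis curve creeps
upward by a further ~1% between 0.5 cm and about 1 cm before rolling
over; the acceptance computation locates the curve's maximum near 1 cm.
From 0.5 cm onward the curve is flat to within about 1%, far inside the
noise of any film measurement of this geometry, so the distinction
between "maximum at 0.5 cm" and "plateau from 0.5 cm with a shallow crest
near 1 cm" is below the resolution of the validation data the model was
built against; the shallow-depth physics that sharpens the real maximum
(electron contamination, air scatter) is deliberately outside the model.
Because the maximum sits on a noisy plateau, `depth_of_maximum()` defaults
to the maximum of a fitted two-exponential buildup model
$A(e^{-ad} - e^{-bd})$, the standard way to locate a flat Monte Carlo
depth-dose maximum; the raw argmax is available and agrees at high
statistics.

## Evaluation tools

`extract_pdd()` and `extract_profile()` average over a small lateral or
axial window (default ~3 voxels) before normalizing — the published
analysis is equally noise-limited. `mean_relative_difference()` is the
pointwise $|a-b|/a$ mean in percent over points above a 10% threshold,
computed on the values as given (the reference convention is a declared
choice). `gamma_index()` is the standard global-normalization 2-D gamma
with a configurable low-dose cutoff (default 10% of maximum, the common
film-analysis default), bilinear refinement of the evaluated plane to at
least dta/3 spacing, and a search radius of 3 x dta (which bounds
reported gamma values but cannot alter pass/fail). The brute-force
exhaustive search is kept in the test suite as the oracle.
`estimate_efficiency()` implements the $1/(\delta^2 T)$ figure of merit
over repeat runs of a 2 cm scoring box.

## Problem sizes and reproducibility

The compiled core transports roughly 3e5 histories per second per core
through the water tank at 1 mm depth resolution (most of the cost is the
~8% of histories that enter the phantom). The shipped acceptance
computation uses 1e8 histories — a few minutes — giving roughly 1%
per-millimetre noise on the central-axis curve after a ±2 cm lateral
average; the test suite uses 2e4-2e7 per case. All randomness comes from one 64-bit Mersenne twister
seeded from the run configuration: identical seeds give bit-identical
dose arrays, which is itself an acceptance check. R-level sampling
helpers use R's own Mersenne twister via `set.seed()`.

## Known limitations

No electron lateral scatter, energy straggling or interface corrections;
no pair production or bremsstrahlung; no Doppler broadening or binding in
Compton; single-scatter-only filter; no absolute calibration (doses are
per-run energy densities, with any scalar calibration left to the user,
as the published workflow also scaled to film); lung blocks and couch
hardware are not modeled.
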