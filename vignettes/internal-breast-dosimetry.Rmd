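---
title: "Internal breast dosimetry by Monte Carlo: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal breast dosimetry by Monte Carlo: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammodose)
```

## The problem

Mammographic dose audits report the mean glandular dose (MGD/AGD), a
quantity that can only be computed, not measured: conversion factors
from incident air kerma to MGD come from Monte Carlo photon transport
in a model of the compressed breast. Before such simulations are
trusted they must be validated *internally* — point dosimeters and film
placed at several depths inside physical phantoms, compared with the
simulated local doses at matching positions, with a defensible
uncertainty on both sides. `mammodose` implements the full simulated
side of such a validation campaign, plus the calibration and
uncertainty models of the experimental side, so the whole comparison
can be rehearsed, extended and re-analyzed in software.

## Photon transport model

The engine is a forward photon Monte Carlo in the kerma approximation.

**Source.** An isotropic point source 655.5 mm above the detector
plane, collimated to the 300 × 240 mm detector field. Sampling a
primary draws a detector-plane intercept with density proportional to
the solid angle (a `cos³θ` factor on the plane) times the anode
heel-effect weight, then a photon energy from the spectrum's
photon-fluence distribution (with uniform jitter inside the 0.25 keV
bin). The heel model is separable,

`HE(d) = a + b d² + c d⁴` (d in cm),

fitted per axis by linear least squares and combined multiplicatively;
the default coefficients are the fitted values of the modelled clinical
unit (y axis: a = 1.0176, b = −8·10⁻⁴, c = −4.81·10⁻⁷; x axis:
a = 0.9971, b = −2·10⁻⁴, c = −3.94·10⁻⁷). Whether the original
surface fit was separable is not knowable from the published
coefficients; the multiplicative combination is the natural reading and
is renormalized to unit mean over the field where a normalized weight
is requested.

**Geometry.** Right-handed coordinates with the origin at the
chest-wall edge on the detector midline: x lateral, y chest wall →
nipple, z upward from the support-table top. The compression paddle
(3 mm polyethylene terephthalate) rests on the phantom top; the support
table (1.7 mm carbon fiber) lies between phantom and detector. Both are
explicit slabs in the random walk, so scattered photons see them.

**Tracking.** Woodcock (delta) tracking with a per-energy majorant
cross section. The world is partitioned into z-zones (air above and
below, paddle, phantom band, chip band, map-layer band, table), each
with its own majorant, so the dense TLD chips (which would otherwise
inflate the global majorant by a factor of ~3) cost fictitious
collisions only inside their own 0.38 mm band. A 2-material-slab
equivalence test against an explicit boundary-to-boundary voxel-walk
reference implementation guards this optimization.

**Interactions.** Photoelectric absorption deposits the full photon
energy locally. Incoherent scattering samples the free-electron
Klein–Nishina distribution by Kahn's rejection method and deposits the
electron energy locally (no binding, no Doppler broadening). Coherent
scattering deflects by the Thomson angular law without form factors.
Photons below 1 keV are absorbed on the spot. These are deliberate
desk-scale simplifications: at 28 kV secondary-electron ranges are far
below the voxel size (justifying local deposition), fluorescence from
low-Z tissue is negligible, and the scattering-model simplifications
are the accuracy-limiting approximations — they are confined to the
partial cross sections handed to the engine, so better models can be
swapped in by changing the data preparation only.

**Statistics.** Every tally accumulates per-history score sums `Σd` and
`Σd²`; the relative standard uncertainty is the history-by-history
estimator `σ² = (1/N)[Σd²/N − (Σd/N)²]`. Seeds are mandatory
everywhere; the RNG is a xoshiro256+ generator seeded by splitmix64,
independent of R's RNG state.

**Energy bookkeeping.** Emitted = deposited + escaped is tracked per
run and asserted to 10⁻⁶ relative in the test suite.

## Interaction data

Elemental μ/ρ (with photoelectric/coherent/incoherent partials) and
μen/ρ for H, Li, Be, C, N, O, F, Na, Mg, Al, P, S, Cl, Ar, K, Ca, Cu,
Rh and W are bundled as plain-text tables on a 1–40 keV grid with
absorption-edge refinement. The snapshot is computed (see
`data-raw/make_xsec_tables.py`) from Cromer–Liberman anomalous
scattering factors (photoabsorption, carrying the edge structure) and
IT92 atomic form factors (coherent, and the incoherent scattering
function through `S = Z(1 − (F/Z)²)`), then harmonized with smooth
global correction factors fitted so that the mixture-rule coefficients
reproduce standard dosimetric reference tables for dry air, water and
aluminum at 10–40 keV to within ~1%. Argon is included because it
carries ~8% of dry air's μen/ρ at 20 keV despite its 1.3% mass
fraction. Mixtures use mass-weighted additivity with log-log
interpolation and no extrapolation.

## Spectrum model

The tube spectrum is a Kramers-law thick-target bremsstrahlung shape,
`N(E) ∝ (kVp − E)/E`, filtered by the inherent beryllium window
(default 0.8 mm) and by a rhodium filter whose thickness is *tuned* —
exactly as one transfers a clinical beam quality onto a model — either
to a measured aluminum attenuation curve (least squares on transmission
residuals) or to a target first HVL (root finding; transmission is
strictly monotone in filter thickness). Characteristic tungsten lines
are omitted: K lines are not excited below ~69.5 kV and L lines are
assumed removed by the window and filter. The 0.25 keV default bin
resolves the rhodium K edge at 23.22 keV. The Kramers substitution is
the one deliberate departure from a measured/tabulated tube model: it
preserves the tuned beam quality (HVL) but carries a somewhat harder
high-energy tail than a real W/Rh spectrum at the same HVL, which is
the main reason simulated depth-penetration figures land about one
percentage point more penetrating than a measured beam would give. The
tuned rhodium thickness (~76 µm) absorbs the missing anode
self-filtration of the stand-in.

## Phantoms

**Homogeneous slab phantom.** A semicylinder (default radius 100 mm,
thickness 5 cm) of the 50/50 glandular/adipose mixture, flat face flush
with the chest-wall edge. The default footprint radius is a documented
assumption — the physical slab phantom's lateral dimensions are not
standardized here — and is configurable. The reference voxel pitch is
0.273 mm (read as a cubic voxel side); coarser grids are used for speed
where the geometry is piecewise-uniform anyway, and the voxelized
volume converges to the analytic semicylinder volume as the pitch
shrinks (tested).

**Synthetic anthropomorphic phantom.** A seeded generator emulating a
trinary classified compressed breast: 1.5 mm skin shell on the curved
surface and top/bottom faces, adipose interior, and glandular tissue
carved from a nearest-blob proximity field — a union of distinct
roughly-ellipsoidal cores (1500 centers, sizes 2–5 mm) whose centers
concentrate toward the phantom center in-plane and at mid-thickness
(standard deviation 0.25 × thickness in z). The glandular voxel count
is solved in closed form so the achieved glandular *mass* fraction hits
the target (default 10.9%, skin counted in the total mass but never as
glandular) up to voxel rounding; thresholding the proximity field by
order statistics makes the count exact and the phantom reproducible by
seed.

Two texture choices matter for the homogeneous-vs-heterogeneous dose
comparison and were fixed at design time. First, summed-Gaussian
"blob" fields degenerate into a single merged central cloud once blobs
overlap, which both over-concentrates the glandular depth distribution
and introduces strong glandular self-shielding; the proximity-field
union keeps structures strand-like at the millimetre scale of real
fibroglandular tissue. Second, the mid-thickness concentration encodes
the anatomical fact that fibroglandular tissue sits centrally in a
compressed breast, which is exactly why homogenizing it (spreading
glandular mass toward the high-dose entrance side) biases the average
glandular dose upward by around ten percent. What the generator does
*not* emulate: real ductal branching topology, the skin-fold geometry
of a compressed breast, 3D-printing material equivalence, or any
patient population variability — so passing tests show the pipeline
responds correctly to a *plausible* heterogeneous distribution, not
that it reproduces any individual breast.

**Homogenization.** Replacing the adipose+glandular interior by the
uniform mixture at the phantom's glandular-to-(glandular+adipose) mass
ratio conserves total tissue mass and overall glandularity identically
(the mixture density follows the inverse-volume rule, so volumes and
masses both balance); skin and air are untouched.

## Sensitive volumes and dose scoring

Thirty TLD-chip volumes (3.2 × 3.2 × 0.38 mm³, LiF:Mg,Cu,P at
2.48 g/cm³) are placed per depth on a 5-row × 6-column grid. The rows
sit at y = 15, 35, 55, 75 and 95 mm for the default 100 mm footprint
(scaled with the radius), columns spanning 80% of the local half-width:
a layout with rows beyond ~100 mm cannot fit the default footprint, so
the grid is defined relative to it; any layout can be supplied as a
data frame and is validated chip-by-chip against the footprint with the
offending position named. Chips are genuine material overrides in the
transport (photons see LiF), and the scored TLD-material dose converts
to air dose via the spectrum-averaged `(μen/ρ)` air-to-TLD ratio on the
depth-hardened spectrum — the ratio is depth-dependent, which is the
physical reason every dosimeter technology here needs depth-specific
calibration.

The 2D map layer mirrors a radiochromic film: a 0.38 mm TLD-material
sheet at the requested depth, pixelized (default 1 mm) with per-pixel
history-by-history uncertainty, allowed to overhang the phantom
footprint as a physical film does.

**Average glandular dose.** Per-voxel deposited energy is tallied
during transport. For trinary phantoms the AGD is total energy in
glandular voxels over glandular mass. For mixture voxels the deposited
energy is partitioned between the glandular and adipose components by
their mass energy-absorption shares,
`G = w_g(μen/ρ)_g / [w_g(μen/ρ)_g + (1−w_g)(μen/ρ)_a]`, averaged over
the (ideally mid-depth-hardened) spectrum. This G-factor weighting —
rather than weighting by mass fraction alone — is what makes the
glandular dose material-consistent between the heterogeneous and
homogenized representations: under equal fluence both give the
glandular dose `Φ E (μen/ρ)_g`, so the homogeneous-vs-heterogeneous
difference isolates the *spatial* redistribution of glandular tissue,
which is the quantity of interest.

## Normalization to absolute dose

The simulated incident air kerma is evaluated analytically (not by
tallying): primary fluence per history at a 3 × 3 cm² region starting
4 cm from the chest wall, laterally centered, just under the paddle
bottom (the exact scoring height is configurable; paddle bottom is the
default reading of "under the compression paddle"), including inverse
square, heel weight, paddle transmission and the air column. The scale
factor measured/simulated kerma then converts per-history doses to mGy.
The analytic evaluation is cross-checked in the tests against
closed-form limits (inverse square on a fixed ray bundle; paddle-on/off
ratio equal to the spectrum's Beer–Lambert paddle transmission).

## Dosimeter calibration and uncertainty models

Film: `dose(x) = a + b·x/ln x` on the net reflectance change `x`,
linear in (a, b) and fitted by least squares; the relative combined
uncertainty follows `u%(D) = a + b·exp(−D/c)`, falling monotonically to
its asymptote `a` — low doses (deep positions) are the noisy ones. TLD:
`D_i = Q_i K_calib / S_i` with per-chip sensitivities; MOSFET:
`D = mean(ΔV/CF)` over repeated exposures. Bundled depth-specific
calibration tables carry typical constants for all three technologies
at depths 0–4 cm; all dose functions refuse a calibration at the wrong
depth unless explicitly overridden, because beam hardening makes
cross-depth calibrations silently wrong (the dose-histogram analysis of
an in-phantom versus free-in-air film shows exactly this failure mode).

Uncertainty combination is quadrature at k = 1; Type B components are
specified as rectangular half-widths and converted by `u = a/√3` before
combining; Type A components are standard uncertainties as given. The
synthetic-reading generator perturbs true doses with Gaussian relative
noise and pushes them backward through the calibration, so dose
reconstruction is unbiased with RMSE equal to the injected noise — the
round trip, its zero-noise exactness and its noise scaling are all
tested.

## Numerical choices

- Energy grid for transport cross sections: 1–40 keV in 0.05 keV steps,
  linear interpolation (the bundled tables themselves interpolate
  log-log between tabulated points, with edge-straddling nodes).
- HVL root finding: bisection-style `uniroot` on [0.01, 5] mm to
  10⁻⁴ mm; filter tuning on a [20, 80] µm bracket (to 10⁻⁶ mm), with
  degenerate targets (single normalized point, monoenergetic input)
  rejected.
- Synthetic-phantom thresholding: exact order statistics, no iteration;
  ties broken by blob proximity ordering, deterministic by seed.
- Woodcock zone boundaries get a 10⁻⁶ mm push-through to avoid
  boundary sticking; zones thinner than 10⁻⁹ mm are dropped.
- Degenerate inputs error early with classed conditions
  (`mammodose_*`), e.g. zero-mass tallies, unseeded runs, chips outside
  the footprint, unordered histogram thresholds.

## Problem sizes

The shipped test-and-reproduction configuration uses 1–2 mm voxels and
5 × 10⁷ histories (split 1:4 between the entrance and the 4 cm layer,
which dominates the variance) for the headline depth-dose figure
(statistical σ ≈ 0.26 percentage points on the percent decrease), and
smaller scenes (10⁴–10⁶ histories) for equivalence and property tests.
These sizes were chosen so the entire campaign reruns from scratch in a
few minutes on a single CPU; the engine itself handles the 0.273 mm
reference pitch unchanged, only more slowly and with more memory.

## Package shape

Simulation state (materials, spectra, voxel phantoms, MC results) lives
in light S3 objects, as simulation engines in this field usually do;
everything tabular — tallies, depth-dose tables, calibration fits,
synthetic readings, agreement reports — is returned as a tibble so
results chain directly into dplyr/ggplot2 pipelines, and fitted objects
provide broom-style `tidy()`/`glance()` methods and `autoplot()`
visualizations.

## Known limitations

- The Kramers-law tube model, even after HVL tuning, is not a measured
  spectrum; depth-penetration quantities inherit a bias of order one
  percentage point from its harder high-energy tail.
- Free-electron Compton and form-factor-free coherent scattering
  mis-shape the scatter field at the few-percent level; both are
  data-level substitutions and swappable.
- No electron transport, fluorescence, or detector image formation; no
  polarization.
- The incoherent scattering function approximation
  `S = Z(1 − (F/Z)²)` and the global harmonization of the elemental
  tables bound the interaction data's accuracy at roughly the 1% level
  for the validated reference materials, and less certainly elsewhere
  (notably rhodium and tungsten, where only the tuning procedure
  protects beam-quality results).
- The synthetic phantom is a statistical stand-in, not a digitized
  breast; conclusions about real anatomical distributions require real
  classified volumes, which the phantom reader accepts in the same raw
  + sidecar format.
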