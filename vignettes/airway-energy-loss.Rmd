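---
title: "Methods: lumen morphometrics, energy-flux accounting and the orifice loss law"
author: "airwayflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lumen morphometrics, energy-flux accounting and the orifice loss law}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwayflux)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the conventions chosen where several were defensible, the
numerical choices, and what the synthetic-data verification does and does not
demonstrate about real airway data.

## The problem

Extrinsic tracheal compression narrows the airway lumen progressively; the
pressure loss across the narrowing, and hence the resistive component of the
work of breathing, grows roughly with the square of both the flowrate and the
reciprocal of the minimum area. The package turns the standard artefacts of
an airway-CFD workflow — a segmented lumen surface, a centerline, and
time-resolved planar flow samples — into three quantitative products:
a cross-sectional area profile with constriction metrics, station-wise energy
loss and resistance profiles, and a fitted orifice power law that lets losses
at unsimulated flowrates be predicted by scaling.

## Geometry: area profiles and constriction metrics

Cross-sections are obtained by intersecting the (watertight) surface mesh
with planes normal to the centerline. Tangents are estimated by central
differences on a centerline resampled to uniform arclength (1 mm by default,
comparable to the finest routine CT slice thickness); one-sided differences
are used at the ends. Each plane-mesh intersection is chained into closed
loops by exact edge-identity matching (each intersection point is computed
once per mesh edge), so loop closure is not sensitive to floating-point
coordinate comparisons; a vertex lying exactly on the slicing plane is nudged
to one side by 10⁻⁹ of the mesh extent. When several loops appear (near a
bifurcation), the loop whose area centroid is nearest the centerline point is
kept. Area is the planar polygon area of the loop; for an inscribed polygon
of a smooth section this converges at second order in the mesh edge length
(verified on cylinders in the test suite).

Profiles are reported as A(x) with x = arclength − carina offset, so the
carina sits at x = 0 and superior stations are negative. Constriction
metrics use a reference area: either interpolated at a user-named station
(conventionally the first tracheal ring — an anatomical landmark a mesh alone
cannot identify, hence user-supplied) or passed directly as `ref_area`, e.g.
when a post-operative lumen is judged against a pre-operative reference. The
ratio is (A_ref − A_min)/A_ref; a lumen wider than its reference yields a
negative ratio with a warning flag rather than an error. The constricted
length is the contiguous run around the minimum where A ≤ (1 − t)·A_ref,
with t = 0.35 by default (the conventional "reduced by 35% or more" rule) and
run endpoints located by linear interpolation in x. On a Gaussian dip
A(x) = A₀(1 − c·e^{−x²/2σ²}) this length has the closed form
2σ√(2 ln(c/t)), which the tests check to 1%.

## Planar flow samples and their reductions

A `plane_series` holds time-resolved samples on one plane: points (mm),
quadrature weights (mm², summing to the section area), a unit normal,
velocities (m/s) and static pressures (Pa). With these units
mm² × m/s ≡ mL/s, and Q[mL/s]/A[mm²] is a velocity in m/s, so the flowrate
and the orifice dynamic head need no hidden conversion factors; energy fluxes
convert to watts with a single 10⁻⁶.

Time averaging drops snapshots before a configurable start-up window and
reports, per point, the mean velocity, mean pressure and the fluctuation RMS
of the velocity *vector*, √(mean‖u − ū‖²). Turbulence intensity is defined
here as the area-weighted mean of that RMS divided by a reference velocity —
by convention the bulk velocity at a named reference plane (the first-ring
plane). Whether a per-component or vector-magnitude RMS is "the" TI differs
between codes; the vector convention was chosen and is stated in every run
log. Note two small, expected biases in finite samples: the RMS about the
sample mean underestimates the true RMS by the factor √(1 − 1/T) over T
snapshots, and the mean of an RMS estimate sits slightly below the true value
(Jensen); tests account for both.

Quadrature weights are built by mapping a polar grid onto the section through
its centroid (boundary radius per azimuthal sector by ray-polygon
intersection — valid for star-shaped sections, which airway lumen slices
are). Radial nodes sit at the root-mean-square radius of equal-f² annular
cells, which makes any integrand linear in f² (notably the parabolic
Poiseuille profile) integrate exactly; weights are then sum-normalised to the
polygon area. This is why plug and parabolic generator flows reproduce their
flowrate to rounding error rather than quadrature error.

## Energy flux, cumulative loss, resistance

For a rigid duct with steady inflow, and neglecting boundary shear work, the
time-mean energy balance reduces to comparing the mean energy flux

E_F = ∫_S (u·n)[P_s + ½ρ|u|²] dS

between stations: the accumulated loss up to x is E_F(inlet) − E_F(x), and
its slope is the local mean dissipation rate. Volume dissipation is never
evaluated pointwise — with planar samples only, dissipation is *inferred* as
flux differences, exactly as one does with CFD cut-planes. Two estimators are
provided: the product of time-averaged total pressure and normal velocity
(the common post-processing approximation) and the time average of the
per-snapshot integral. They agree exactly on steady fields; their difference
on fluctuating fields is the neglected turbulent-transport term, and
`cumulative_loss()` tabulates both plus the difference rather than hiding it.
Cumulative loss is only meaningful across planes carrying the same flow, so a
mass-conservation check (1% by default) guards the computation.

Resistance is R(x) = (⟨P_tot⟩_inlet − ⟨P_tot⟩_x)/Q with ⟨·⟩ the area-weighted
mean of time-mean pressure. Whether the area-averaged pressure should be
static or total is a genuine convention choice; **total** is the default
because it makes R(inlet) = 0 and the end-to-end R equal ΔP/Q, and because
the characteristic "overshoot" of R where the lumen expands downstream of a
compression is an artefact of averaging pressure across a growing area that
both conventions share. The static convention remains available
(`pressure = "static"`), and every pipeline log records which was used.

## The orifice power law

Across a severe constriction the loss is modelled as
ΔP = ½ρK(Q/A_C)ⁿ. Prediction is direct; fitting is least squares on log ΔP.
With n free this is ordinary log–log regression; with n fixed the single
parameter is K = exp(mean(log ΔP − log(½ρ(Q/A_C)ⁿ))) — the same objective
with the slope pinned, equivalent to relative-error least squares to first
order. The log-space form was chosen deliberately: it is scale invariant,
and under multiplicative noise its bias is O(σ²/2), whereas the literal
Σ((K·C−P)/P)² estimator carries a −2σ² bias that is material at realistic
noise levels. Every fit also reports K·ρ: because K and ρ enter only through
their product, a data set fitted under an assumed density identifies K only
up to that assumption. The package default is ρ = 1.2 kg/m³ (with
μ = 1.8×10⁻⁵ Pa·s) — room-air values, stated explicitly because published
loss coefficients in this area are sometimes quoted without their density,
which alone moves predictions by several percent. The literature benchmark
K = 1.2 for idealised tracheal stenoses is exported as
`K_REFERENCE_ORIFICE`.

Two scalings are provided and kept distinct on purpose: `scale_loss()`
multiplies a pressure loss by (Q₂/Q₁)ⁿ, the power law itself; and
`scale_resistance()` multiplies a resistance R = ΔP/Q by (Q₂/Q₁)^e — the
convention used in clinical quotations of "resistance at a higher
ventilation rate" with e = 2, even though the power law implies R ∝ Q^{n−1}.
Both conventions appear in the literature; the package implements each under
its own name rather than silently reinterpreting one as the other.

## The synthetic airway and flow generator

The generator stands in for CFD data that cannot be redistributed. Surfaces
are elliptical tubes whose **area** is modulated by a Gaussian dip,
A(x) = πr₀²(1 − c·e^{−(x−x₀)²/2σ²}) (the radii scale with the square root of
that factor), so the depth parameter c *is* the fractional area reduction and
the 35%-rule length has the closed form above. Defaults emulate the severe
compression studied: base area 117 mm² (r₀ = 6.103 mm), c = 0.825,
σ = 12.49 mm (giving a 32.7 mm constricted length), a 100 mm imaged tube, and
35 mm straight extrusions at both ends (about three hydraulic diameters, the
usual practice for moving boundary conditions away from the region of
interest). The default mesh edge of 0.6 mm keeps mesh-derived areas within
0.2% of the analytic law. The generated centerline is inset by one mesh edge
from the end caps so every slicing plane cuts the tube interior.

Flow fields are built per section: plug, parabolic, or a top-hat orifice jet,
rescaled so the discrete flowrate equals the requested Q exactly.
Fluctuations are white in time and space — isotropic Gaussian per component
with vector RMS a prescribed fraction of the local bulk velocity. This is
deliberately *not* a turbulence model: white noise suffices to exercise the
averaging, TI and turbulent-transport paths, but has no spectra, no spatial
correlation, no anisotropy, and no dependence on the geometry. Passing tests
therefore demonstrate that the *accounting operators* are correct, not that
any turbulence physics is reproduced.

`make_orifice_pressure_field()` injects a known loss: plug velocity Q/A(x)
per plane, static pressure following Bernoulli on the realised section areas,
and an irreversible total-pressure drop of ½ρK(Q/A_C)ⁿ applied across the
throat, distributed downstream over a mixing length (default 5 throat
hydraulic diameters, mimicking how a constriction jet's breakup spreads the
dissipation over a finite region) with a smoothstep ramp. Because the plug
profile makes plane total pressure uniform, the injected law is recovered by
the quadrature essentially exactly; the tests require 1% in the presence of
5% fluctuations.

## Determinism, problem sizes, degenerate inputs

All random stages are seeded; the generator saves and restores the global RNG
state, and rerunning a pipeline with the same configuration reproduces the
CSV report tables byte for byte (the tested surface — figures are advisory).
The analysis scripts and tests run the default geometry at a 0.6 mm mesh edge
(≈36k triangles), 1 mm profile stations, 24 flow snapshots and a 12×32
quadrature per plane: sizes chosen so the full suite completes in a few
minutes on one core while keeping every tolerance comfortably met; all are
configuration parameters, not constants.

Degenerate inputs are errors with named conditions: zero-length polylines,
planes that miss the mesh (`empty-section`), open intersection contours
(`topology`), emptied averaging windows, non-positive reference velocities,
flowrate-inconsistent datasets (`conservation`), area profiles without a
unique minimum (`invalid-spec` for the loss injector). Flat-bottomed area
minima are reported at the midpoint of the flat run; ties among minima break
toward the superior (smaller-x) station.

## Known limitations

* Planar sampling only: no wall shear stress, no pointwise dissipation, no
  volume fields. Dissipation localisation is limited by plane spacing.
* The centerline must be supplied (or comes from the generator); no
  skeletonisation from images, and no branch-aware handling beyond keeping
  the nearest intersection loop.
* The synthetic fluctuations are white; conclusions about real turbulent
  transport magnitudes cannot be drawn from them.
* K and ρ are confounded in all fits; comparisons across studies should use
  the reported K·ρ product unless densities are known to match.
* The quadrature's star-shaped mapping assumes each lumen section is
  star-shaped from its centroid — true for airway slices here, not for
  arbitrary cross-sections.
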