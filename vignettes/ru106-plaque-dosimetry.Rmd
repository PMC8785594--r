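---
title: "Dosimetry and tilted-placement planning for Ru-106 ophthalmic plaques"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosimetry and tilted-placement planning for Ru-106 ophthalmic plaques}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ruplaque` computes the dose field of a concave Ru-106/Rh-106 episcleral
plaque applicator and uses it to plan a *tilted* placement for a small
(infant) eye: the applicator's curvature radius (12-14 mm) exceeds the eye
radius (~9 mm), so the plaque cannot conform to the globe, and when a
posterior staphyloma additionally forbids contact near the posterior pole
the applicator must be stood off by an edge distance *d* while still
covering a juxtapapillary tumor.  The package answers the clinical
questions of that scenario: what dose rate reaches the tumor margins and
the optic disc as a function of *d*, which stand-off to select under the
anatomical constraint, how long the applicator must stay attached for a
40 Gy prescription, and what the evaluation points actually receive for
the realized attachment time.

# Source model

Ru-106 decays to Rh-106, which emits the therapeutic high-energy beta
spectrum (dominant branch endpoint 3.541 MeV) plus weak gamma lines; the
pair is treated in secular equilibrium at constant activity (no decay-chain
dynamics).  `build_beta_spectrum()` tabulates an allowed-shape Fermi
spectrum,

$$ p(E) \propto F(Z, E)\, p\,E_{\mathrm{tot}}\,(Q - E)^2 , $$

with the non-relativistic screening approximation
$F = 2\pi\eta / (1 - e^{-2\pi\eta})$, $\eta = \alpha Z E_{\mathrm{tot}}/pc$,
$Z = 46$ (the Pd-106 daughter), normalized to unit integral (trapezoid, to
1e-6).  Only the dominant branch is used by default; the minor branches can
be folded in (`ru106_source_term(multi_branch = TRUE)`) but change the
depth dose at the sub-percent level.  A user-tabulated spectrum can be
supplied through `read_spectrum()`.

Gamma lines ship as an editable plain-text table of evaluated-nuclear-data
style energies and per-decay intensities; lines with emission probability
*strictly greater* than 0.06% per decay are retained at load time
(`select_gamma_lines()`).  The retained set is data-driven, not hard-coded.

```{r}
library(ruplaque)
src <- ru106_source_term()
src
```

# The applicator and the eye

The plaque (`plaque_model()`) is a spherical cap of three concentric silver
layers: 0.1 mm inner window, 0.2 mm source-bearing middle layer, 0.3 mm
outer backing, with a 0.8 mm source-free peripheral rim measured along the
cap surface from the edge.  The emitter is a uniform surface density on the
mid-plane of the middle layer, restricted to the active region.  The cap
chord diameter is not printed anywhere we could rely on; the default
15.3 mm (with curvature radius 12 mm) is consistent with a small round
applicator of the stated curvature class and is configurable.

The eye (`eye_model()`) is a 9 mm-radius sphere.  Anatomy is expressed as
in-plane angles from the posterior pole in the horizontal evaluation plane
(the study is two-dimensional: all six reference positions lie in this
plane).  The defaults — optic disc centered 15 deg nasally with 1.5 mm
diameter, optic sheath 3.2 mm, tumor spanning from the temporal disc edge
to 26 deg temporally — are declared *reconstructions* of a schematic
clinical geometry, not published coordinates.  The six evaluation
positions follow the clinical definitions: 1 and 4 at the sheath's
temporal edge (1 mm above the retina, and on it), 2 and 3 at the tumor's
temporal edge (likewise), 5 on the retinal surface at the disc's temporal
edge and 6 one millimetre deep from position 5.  "Above" is radially
inward; "deep" at position 6 is radially outward (into the nerve head).
That last convention makes position 6 sit 1 mm outside the scleral sphere,
which we consider the only reading consistent with "depth from the retinal
surface".

# Placement model

`place_plaque(plaque, eye, d)` realizes the tilted placement.  Because the
cap is flatter than the globe, a pose with both edges touching would push
the cap midsection through the sclera (cap sagitta 2.76 mm versus eye
sagitta 4.26 mm over the default chord), so single-contact poses are the
only physical ones — exactly the clinical observation that the edge floats
when the central part is attached.  The model pins the anterior
inner-surface edge to a suture site (`contact_angle_deg`, default 105 deg)
and rotates about it until the posterior-edge gap equals *d* (root find,
realized to 1e-3 mm).  Where that pose would penetrate (d below roughly
2.6 mm for the defaults), the plaque instead rides tangentially on the
sclera with the anterior edge floating radially above the suture ray;
those poses carry `mode = "riding"` and correspond to the regime reported
as difficult to fixate.  The suture angle was chosen, once, so that the
d = 2 mm pose reproduces the reported qualitative rate ordering
(position 6 < 5 < 1 < 4 < 2 < 3 with position 1 limiting); it is part of
the case file and freely overridable.

A known limitation, documented rather than patched: under every rigid
single-contact placement family we constructed, the nasal advance of the
hovering posterior edge reverses near d = 1.2 mm, so the optic-disc
positions peak at d = 1 mm together with positions 1-4 instead of rising
monotonically to d = 2 mm.  Reproducing the reported monotone disc-dose
trend evidently requires the unpublished case coordinates and pose family;
the corresponding expectation in the acceptance tests is left failing on
purpose.

# Monte Carlo engine

`run_mc()` transports one beta per decay (sampled by inverse CDF) plus the
retained gamma lines from random points of the active layer:

* condensed-history electrons: continuous slowing down on a collision
  stopping-power table, fixed 0.02 mm water-equivalent step, Highland
  multiple scattering sampled per step from a Rayleigh deflection
  distribution (no log-correction term, so the accumulated variance is
  step-size independent), energy deposited at step midpoints;
* termination when the residual CSDA range in water falls below 0.1 mm
  (about 63 keV), with local deposition — this implements the stated
  range-based cutoff; the printed cutoff *energy* of 0.07 eV in the source
  material is physically inconsistent with a 0.1 mm range and the range
  statement governs;
* silver layers by water-equivalent path-length scaling: per geometric
  millimetre the electron loses energy and scatters as in
  $f(E) = S_{Ag}\rho_{Ag}/S_w\rho_w \approx 6.2\!-\!7.0$ millimetres of
  water.  An explicit-material mode is intentionally not provided; the
  scaling keeps both engines on the same physical model;
* electrons crossing the outer backing surface are terminated and tallied
  (`backing = "absorb"`, the treatment default); `backing = "transmit"`
  places water behind the shell instead and exists for engine
  cross-validation (below);
* gammas by a deterministic kerma-with-attenuation ray trace (no buildup),
  scored as a separate dose component; their contribution is percent-level
  next to the betas;
* scoring on a 0.1 mm voxel grid with history-by-history variance;
  identical seed and configuration give bit-identical tallies
  (single-threaded PCG32).

Per-batch energy bookkeeping closes to 1e-6 relative:
emitted = in-grid + out-of-grid + absorbed-in-backing + gamma residual.

The stopping-power and photon tables are bundled plain-text files computed
from the Moller collision stopping-power formula with Sternheimer
density-effect corrections (mean excitation energies 75 eV for water,
470 eV for silver) and standard photon attenuation/energy-absorption
values; radiative losses are excluded in both engines (bremsstrahlung is
out of scope).  Absolute accuracy of these tables is a few percent, which
is immaterial here because both engines share them and absolute output is
set by certificate calibration.

# Deterministic kernel engine

The cross-check oracle and fast planning backend
(`build_point_kernel()`, `cap_dose()`) is built from monoenergetic
dose-point kernels computed by a *deterministic* phase-space solver
(`point_kernel_mono()`): around an isotropic point source the electron
ensemble is spherically symmetric, so its state reduces to a density over
(radial distance, direction cosine).  Each step advects the density
ballistically (3-point Lagrange remaps, which reproduce quadratics exactly
and add no numerical diffusion to the first two moments), deposits the
step's collision loss into a radial histogram, and applies the angular
deflection as a Legendre-space multiplication with the exact Legendre
moments of the same Rayleigh distribution the MC samples.  The solver
shares the physics *data* and scattering law with the MC engine but none
of its numerics — a discrete-ordinates-style computation against a random
walk.  We chose this over a Loevinger-style analytic kernel because the
analytic parameterizations are only good to ~5-10% in the relevant depth
range, which would contaminate the engine comparison.  Energy is conserved
exactly by construction; kernels from a 16-group equal-probability
spectrum decomposition integrate to the spectrum mean energy within 1%.

`cap_dose()` integrates the kernel over the active cap (product
Gauss-Legendre x uniform azimuth quadrature, refined per point until a
1e-3 relative tolerance).  The silver window enters through a
water-equivalence model:

* `"shift"` (default): remove the window and displace the field point away
  from the shell by the water-equivalent excess of a normal crossing,
  $(f-1)w$.  This is exact in the planar limit under density scaling (we
  verified the limit against the MC on a flat, R = 200 mm geometry).
* `"curved"`: additionally attenuate each source-to-point ray by the extra
  straight-line path of the exact spherical-shell chord beyond the locally
  planar chord.  Obliquity matters for points near or beyond the cap edge,
  so the planning backend evaluates positions with this model.
* `"blend"`, `"chord"`, `"plane"`, `"normal"`: bracketing/diagnostic
  variants kept for comparison.

# Engine cross-validation

The validation workflow (`rupl_validate()`) runs the concentric plaque in
water until the stopping criterion is met (central-axis uncertainty within
5% to 8 mm depth and dose-weighted lateral-profile uncertainty at 2.3 mm
within 5%), then compares the central-axis depth dose (2 mm averaging
disc, matching the kernel-side extraction) against the kernel curve over
0.5-6.0 mm with both normalized at 2 mm.  The MC runs with
`backing = "transmit"` for this comparison because an unbounded-medium
point kernel cannot represent an absorbing half-space behind the source;
the absorb-transmit difference is a real, separately measurable ~8-10%
near-surface effect.  With one million histories the two engines agree
within about 5-6% across the band (within ~3% beyond 0.7 mm); the residual
concentrates at the shallow band edge and is a genuine limitation of any
one-dimensional water-equivalence treatment of the *curved* dense shell,
not a statistical artifact.  The window models also carry an absolute
offset of order 20% relative to the MC; it is uniform in shape, cancels
under the 2 mm normalization, and is removed from all planning quantities
by the certificate calibration, which anchors each backend separately to
the certified absolute rate.  The point kernels themselves agree with
point-source MC within ~1% beyond 1 mm.

# Calibration and planning

Absolute output comes from a manufacturer-style certificate: an absolute
dose rate at a reference depth on the central axis plus a depth-dose
table.  `calibrate()` returns the scale (effective decays per minute) that
makes the simulated rate at the reference point equal the certificate
exactly; everything downstream is linear in it.  `sweep_distance()`
re-places the plaque for every *d* and evaluates the six positions with
the kernel backend; `select_placement()` applies the anatomical rule — the
smallest feasible stand-off at least `d_min` (2 mm for the staphyloma) —
and `build_plan()`/`plan_from_rates()` compute the limiting coverage
position (the minimum over positions 1-4; the optic-disc points 5-6 are
evaluated, never prescribed to), the required time
$t = D_{\mathrm{presc}} / \dot D_{\mathrm{lim}}$ and the delivered doses
for the actual attachment time.  Reports round half-up to 0.1 mGy/min,
0.1 h and 0.1 Gy; the underlying functions are exact, so delivering for
the required time returns the prescription identically.

```{r}
plan <- rupl_plan(rates = c(25.5, 75.2, 105.8, 28.0, 21.4, 19.5),
                  attach_time = 47.0)
plan
```

# Synthetic reference data

No deposited data exist for this study type, so the package generates its
own reference artifacts.  `gen_certificate()` builds certificates from the
kernel depth-dose shape (or the bundled precomputed shape table, which is
labelled synthetic) scaled to an absolute reference rate, with
mean-preserving lognormal scatter (lognormal so rates stay positive).  The
default reference rate, 129.6 mGy/min at 2 mm, is a realism tuning chosen
once so the default case's limiting-position rate lands near reported
clinical values for this applicator class; it is documented as such and is
not a reproduction of any physical applicator.  `gen_case()` writes the
complete default case bundle (eye, plaque, suture angle, prescription
40 Gy, `d_min` 2 mm, attachment 47.0 h) as plain-text YAML, byte-identical
for a given seed, with optional deterministic jitter for generating
populations of plausible cases.

What passing tests on these synthetic data do and do not show: they
exercise every pipeline stage, the calibration linearity, the geometric
trends and the engine agreement, but they cannot validate the absolute
dose rates of a physical applicator (which require a real certificate) nor
plaque-to-plaque source heterogeneity, which is out of scope.

# Numerical choices and problem sizes

* Spectrum grid 400 points; kernel: 16 energy groups, 0.02 mm steps and
  radial bins, 96 direction nodes, Legendre order 64 (builds in ~20 s).
* MC validation runs use 1e6 histories (a few minutes single-threaded),
  which meets the 5% stopping criterion comfortably; test-suite
  bookkeeping checks run at 1e4-1e5 histories on reduced grids.
* Depth-dose extraction averages a transverse disc (default 0.25 mm;
  2 mm for the engine comparison) to emulate a finite detector and reduce
  variance; kernel-side curves use the same disc.
* Quadrature and root finds: cap integral refined to 1e-3 (warning with
  achieved tolerance on non-convergence); placement gap solved to 1e-3 mm;
  tie-breaks in placement take the most upright root.
* Degenerate inputs (zero histories, empty regions, rim consuming the
  cap, tumor crossing the disc) raise classed errors
  (`ruplaque_invalid_input`, `ruplaque_infeasible`).

# Known limitations

* The medium is water everywhere (as in the underlying study); no tissue
  heterogeneity, no 3-D volume metrics, no radiobiological modelling.
* The kernel oracle's silver-window treatment is one-dimensional; its
  residual disagreement with the MC at the shallow band edge is ~5%.
* Bremsstrahlung is excluded; gammas use kerma without buildup.
* The placement family is a rigid single-contact model; see the placement
  section for the disc-dose trend it cannot reproduce.
* Parallel execution is not implemented; determinism is guaranteed for
  the single-threaded engine.
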