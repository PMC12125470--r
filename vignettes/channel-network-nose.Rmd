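---
title: "Channel-network models of rodent nasal transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel-network models of rodent nasal transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`olfnet` trades the full 3-D anatomy of a rodent nasal cavity for a directed
network of straight channel segments. That reduction keeps the quantities the
analyses actually consume — per-channel flows and velocities, wall areas per
epithelium class, channel radii and lengths — while making every computation
fast, deterministic and testable. This vignette records the model, its
assumptions, the defaults, and the design decisions that were genuinely open.

## The synthetic nose

`build_nose()` realizes a fixed topology: a naris and vestibule in series,
then a bifurcation into (i) two wide, flat respiratory channels
(parallel-plate "slots" standing in for the maxilloturbinate region) and
(ii) a narrow dorsal-medial (DM) feed that fans out into `Np` parallel
circular olfactory columns; the columns reconverge into a collector that
merges with the respiratory route into the nasopharynx. This is the minimal
network that exhibits the two inspiratory flow regimes of macrosmatic noses:
a bulk respiratory stream that bypasses the olfactory recess and a DM stream
that feeds it.

Because the network is synthetic, its absolute dimensions are fixed by
**calibration, not by drawing**: `calibrate_to_morphometry()` applies a
two-parameter similarity transform (one transverse scale on all
cross-sections, one axial scale on all lengths) chosen in closed form so that
total wall area and airspace volume match morphometric targets. The mouse
preset targets the reported micro-CT values for a B6 mouse, 2.90 cm² and
0.0291 mL; rat whole-nose morphometry is not part of that table, so the rat
preset uses literature-plausible stand-ins (11.5 cm², 0.26 mL) and every
rat-specific number downstream is conditional on them.

Preset column geometry was chosen once, and is frozen:

| parameter | mouse | rat | why |
|---|---|---|---|
| parallel columns `Np` | 6 | 24 | see below |
| column radius `r` | 136 µm | 260 µm | velocity band + Golay regime |
| column length `Lc` | 7 mm | 15 mm | coiled-path length, sets `N = Lc/H` |
| DM flow fraction | 0.1 | 0.1 | controlling unknown, exposed in config |
| flow rate `Q` | 25 mL/min | 200 mL/min | median restful breathing |

The constraints behind these choices: (1) solved olfactory column velocities
must fall in the physiological bands (0.03–0.14 m/s mouse, 0.02–0.12 m/s rat
at the preset flow rates); (2) the operating velocity must sit *below* the
Golay optimum of the column (the regime in which parallelization pays); and
(3) the rat, with its more elaborate ethmoid recess, should reach a higher
peak plate number than the mouse. At the rat's eight-fold higher flow these
three constraints cannot be met simultaneously with ~10 columns of any
radius, which is why the rat preset uses 24 parallel columns — the per-species
column count of real noses is not well established, and the network treats it
as a structural parameter. Column lengths receive a 2% log-normal seeded
jitter so parallel paths are not exactly degenerate; identical spec + seed
reproduces the network bitwise.

The DM split deserves emphasis: no measurement pins the fraction of inspired
air entering the olfactory feed, and it controls every olfactory quantity
downstream. It is therefore *imposed* (default 0.1) rather than
resistance-derived, echoed into every provenance block, and trivially varied
in configuration.

`elongated_tube_variant()` replaces the column bank by a single circular tube
of **equal olfactory airspace volume**. The packing rule sets the tube length
equal to the mean column chain length `Lc` (it must fit the same physical
region the coils occupy), which fixes the tube radius at `sqrt(Np) · r`.
Under a shared DM feed, equal volume and equal length imply equal mean
velocity — the architectural comparison below is then driven purely by
channel caliber, which is the cleanest isolation of the "parallel coil"
effect available in a matched-flow design.

## Flow

Each segment is a Hagen–Poiseuille resistor (`8µL/πr⁴` circular,
`12µL/(w·g³)` parallel-plate); junction pressures come from dense nodal
analysis with the total flow injected at the naris and the DM feed stamped as
a flow source. Air is treated as incompressible, laminar, Newtonian and
quasi-steady; `dimensionless_numbers()` checks the screening groups
(quasi-steady when `W0 < 4` and `S < 1`, laminar when `Re < 2300`, all strict
inequalities) on any segment. The Strouhal stroke length defaults to the
segment length, a convention the user can override.

`secondary_strength()` evaluates `SS = sqrt(v²+w²)/sqrt(u²+v²+w²)` pointwise
on gridded velocity fields. The channel network itself has no secondary
flow, so `synthetic_swirl_field()` provides a solid-body-rotation fixture
with a closed-form SS for testing and demonstration; SS values comparable to
CFD cross-sections are *not* claimed by the network model.

## Odorant uptake

Inside a channel the odorant obeys steady advection–diffusion with a fully
developed laminar profile (axisymmetric for circular segments, planar for
slots), axial diffusion neglected on Péclet grounds. The air–mucus interface
enters as a Robin condition in dimensional form,

`D_a ∂C/∂n = −k_w C`, `k_w = D_m / (β d)`,

which avoids any ambiguity about the reference length used to
nondimensionalize the classical `∂C′/∂y′ + K C′ = 0` statement; `K` is still
computed and reported (with the segment hydraulic diameter) for
comparability. Defaults: mucus film `d = 10 µm` (order of magnitude for
rodent airway mucus; no measured value is available), water solvent at 310 K
(0.6913 cP), Wilke–Chang association factor 2.6. The Wilke–Chang correlation
is applied to the *mucus* phase only — it is a liquid-phase correlation — and
air-phase diffusivities come from the odorant table or the
Fuller–Schettler–Giddings gas correlation.

Numerics: the solver marches axially with backward-Euler steps, solving a
dense transverse system whose matrix is constant along the channel (one
factorization per segment); the wall row is a second-order one-sided Robin
stencil; the mixed-mean concentration uses flux-weighted trapezoid
quadrature. Wall fluxes are accounted conservatively from the mixed-mean
decrement, so network flux closure holds to machine precision rather than to
discretization error. Default resolution is 200 axial × 64 transverse nodes;
the suite checks 1% agreement against a doubled grid and against an
independently discretized finite-volume Crank–Nicolson oracle, plus the
well-mixed closed form `1 − exp(−k_w P L / Q)` in its validity regime (wall
Damköhler number `k_w r / D_a ≲ 0.03`) and the constant-wall-concentration
Graetz asymptote (local Sherwood number → 3.657) in the `K → ∞` limit.

At junctions the mixed-mean concentration mixes flux-weighted (the network
carries no transverse structure across junctions, so perfect mixing is the
only consistent closure); splits inherit the mixed value. `solubility_sweep()`
exposes the mechanism behind the single-peaked olfactory deposition curve:
at small `β` (very soluble) the anterior respiratory surfaces scrub the
stream before it reaches the recess, at large `β` nothing is absorbed
anywhere, and the olfactory fraction peaks in between — on a single
all-olfactory channel, with no anterior scrubbing, the curve is monotone
instead.

## Gas-chromatograph efficiency

Each olfactory channel is an open-tubular GC column whose stationary phase is
the mucus film. The plate height is the two-term Golay–Giddings form

`H(u) = B/u + C u`, `B = 2 D_g`,
`C = f_g(k) r²/D_g + f_s(k) d_f²/D_s`,

with `f_g(k) = (1+6k+11k²)/(24(1+k)²)`, `f_s(k) = 2k/(3(1+k)²)`, and the
retention factor closed from thin-film partitioning, `k = 2 d_f/(β r)`
(circular). The stationary-film term can be disabled in configuration. The
optimum is analytic: `u_opt = sqrt(B/C)`, `H_min = 2 sqrt(BC)`,
`N_peak = Lc/H_min`; `velocity_robustness()` returns the closed-form band
`{u : N(u) ≥ f·N_peak}`, whose endpoints satisfy `u_lo·u_hi = u_opt²`.

Two consequences of this form matter for interpretation. First, at the
channel radii and odorants of interest the mobile-phase term dominates, so
`H_min ∝ r` and `u_opt ∝ D_g/r`: the fat equal-volume tube has a much larger
plate height and a much lower optimal velocity than the narrow columns, which
is exactly why the parallel-coil architecture wins at matched volume and
flow — its per-channel velocity sits below `u_opt` while the tube runs above
its own. Second, the *fractional* bandwidth `log(u_hi/u_lo)` of a `B/u + Cu`
curve depends only on the fraction, not on the column, so the two species tie
exactly on that robustness measure; the *absolute* bandwidth (in m/s) is
wider for the mouse because its smaller columns place `u_opt` higher. Both
are reported.

The default comparison odorant is ethanol (M = 46.07 g/mol, Le Bas volume
59.2 cm³/mol, `β = 2.4e-4`, the air/water value near body temperature): a
light, highly mucus-soluble odorant whose large gas diffusivity
(≈1.24e-5 m²/s by Fuller) puts `u_opt` above rodent olfactory velocities —
the regime the coiled-turbinate argument describes. The absolute peak plate
numbers reported for the presets are conditional on the preset geometry and
this odorant; only orderings and ratios are treated as findings.

## Particle transport

The force balance per unit particle mass is

`du_p/dt = (f_D/τ)(u_f − u_p) + g(ρ_p − ρ_f)/ρ_p + F_s`,

with `τ = ρ_p d_p²/(18µ)`, the Schiller–Naumann drag factor
`f_D = 1 + 0.15 Re_p^0.687` (clamped at `Re_p = 1000` with a warning), and
the generalized Saffman shear-lift `F_s` (constant 2.594) available from a
local velocity-gradient tensor — off by default in network tracking, on in
single-channel validation, matching its near-wall relevance.

The integrator applies the exact exponential solution of the linearized drag
equation over each step, with gravity and lift held explicit. This
semi-implicit update is unconditionally stable, so the step size is set by
trajectory resolution (`dt = 0.01·L/U` per segment) rather than by `τ`; a
`τ`-limited step would make micrometre particles intractable for no accuracy
gain, since for `τ ≪ dt` the update reduces to the exact tracer-plus-drift
solution. A pure explicit scheme is provided for cross-checking and refuses
steps above `0.1 τ`.

Particles are released uniformly over the naris cross-section with the local
fluid velocity, advance through segment-local analytic profiles (parabolic or
plug), and are trapped at first wall contact of the particle *center*
(interception by the finite radius is neglected, which keeps the
sedimentation oracle `min(1, v_t L/(U h))` exact for the plug-flow test
channel). At junctions particles keep their global velocity while the local
fluid direction changes, so direction changes produce inertial impaction
drift naturally; the transverse entry coordinate preserves the normalized
exit coordinate. Deposition is summarized against the impaction factor
`ρ d_p² Q` in g/cm³·µm²·cm³/s, the units in which an impaction factor of
~100 corresponds to ~15 µm particles at 25 mL/min.

Two deliberate omissions: Brownian/diffusional deposition (the size range
1.5–43 µm is chosen to make it negligible) and rebound or resuspension.
Deposition of *small* particles in this model is sedimentation-dominated and
therefore decreases with flow rate; the claim "efficiency non-decreasing in
flow" is meaningful only in the inertial regime that the similarity
parameter `ρ d_p² Q` describes, and is tested there (20 µm).

## What the synthetic data can and cannot show

The generator emulates the *structure* the analyses need: serial respiratory
then parallel olfactory architecture, calibrated totals, epithelium
labelling, physiological flow splits and velocity bands. It does not emulate
coiling curvature (channels are straight, so Golay's straight-tube dispersion
is exact rather than an approximation, and curvature-induced secondary flow
is absent), the S-shaped recirculating paths of the real ethmoid recess,
expiratory flow, or compliant, mucus-covered walls with receptor kinetics.
Passing tests therefore demonstrate internal consistency of the methods and
the direction of architectural contrasts under matched conditions — not
quantitative agreement with any particular animal. Absolute plate numbers,
deposition fractions and SS statistics from image-based CFD depend on the
true geometry and are out of reach of a channel network by construction.

## Problem sizes

The shipped tests and the acceptance script run at the package's working
resolutions: uptake at 200×64 (reduced to ~100×32 inside sweeps over many
solubilities and to 40×16 on the 250-network randomized closure suite),
solubility grids of 13–21 points over `β ∈ [1e-10, 1]`, 100 randomized
topologies for conservation checks, and 2000 particles per size over the
1.5–43 µm range (the full release protocol of 8000 per size is available via
`full_protocol = TRUE`). These sizes were chosen so the statistical checks
(3× binomial standard errors) are decisive for the effects being tested.
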