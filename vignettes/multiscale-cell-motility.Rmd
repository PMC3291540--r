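---
title: "A multiscale model of cell polarization and motility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale model of cell polarization and motility}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

polarcpm simulates a single crawling cell as three coupled layers on a
periodic hexagonal lattice: a reaction–diffusion signalling network
(Rho-family GTPases and phosphoinositides), an orientation-resolved actin
cytoskeleton, and a Cellular Potts shape engine. This vignette describes the
model, the choices made where the design was genuinely open, the numerical
scheme, and what the package's tests do and do not establish.

## The signalling layer

Three small GTPases — Cdc42, Rac and Rho — each cycle between an active,
membrane-bound form (diffusion coefficient `D_act`, 0.2 µm²/s) and an
inactive form that exchanges with the cytosol. The effective diffusion of
the inactive forms is the time-fraction-weighted mean of the membrane and
cytosolic coefficients (`effective_inactive_diffusion()`); with the default
quarter of time on the membrane and `D_cyt = 20` µm²/s the inactive pool
diffuses roughly 75× faster than the active forms. That disparity, together
with conservation of each GTPase's total, is what lets a transient stimulus
leave behind a pinned activity front (wave pinning): the front stalls where
local bistable kinetics balance the depleted inactive pool.

Activation rates follow a mutual-inhibition architecture with Hill
coefficient 3: Rho inhibits Cdc42 activation (half-max `a_rho`), Cdc42
inhibits Rho activation (half-max `a_cdc`), Cdc42 amplifies Rac linearly
(`alpha_rac`) and Rac enhances Rho (`beta_rho`). Two placements are
deliberate and load-bearing:

* basal Rho sits *above* the half-max of its inhibition of Cdc42 (ratio
  1.3), so the rest state is sensitive to Rho relief — a stimulated patch
  that suppresses Rho is strongly disinhibited;
* basal Cdc42 sits *below* the knee of its inhibition of Rho (ratio 0.9),
  so the rest state does not engage the switch. This is what makes the
  homogeneous rest state an attractor with a finite (few-percent)
  nucleation threshold rather than a hair-trigger; placing both species at
  their half-maxes makes the rest state marginally unstable and was
  rejected during calibration.

The baseline activation input rates are never set directly: they are solved
from the requirement that the stated basal concentrations are an exact
steady state of the reaction terms (`solve_basal_rates()`). The solved
baseline Rho input is negative — Rho activation is effectively Rac-driven —
and the rate is floored at zero. Solving rather than fixing these rates
guarantees that the rest state is identical for every feedback strength
`eta`, which every cross-`eta` comparison in the package presupposes.

Three phosphoinositides (PIP, PIP₂, PIP₃) are produced, interconverted and
degraded with kinase activities that scale linearly with the GTPases: Rac
doubles PI5K and PI3K activity at `rac_2x`, Rho doubles PTEN at `rho_2x`.
Saturation of these couplings is deliberately omitted — the linear form is
the simplest that produces front-enriched PIP₂/PIP₃ — and the three rates
not free are again solved from the basal lipid levels.

### The tunable feedback

The feedback strength `eta` in [0, 1] interpolates how strongly PIP₂
gates Cdc42 and Rac activation: the activation rates are multiplied by
`(1 − eta) + eta · S(PIP₂)` where `S` is a Hill sigmoid (exponent
`fb_hill = 4`, half-max `fb_half_rel = 1.45` × basal PIP₂) normalized to
1 at basal PIP₂ and 0 at zero PIP₂. At `eta = 0` the lipids are spectators;
at `eta = 1` activation is impossible without PIP₂; the package standard is
`eta = 0.5`. Anchoring `S` at basal keeps the rest state `eta`-invariant.

One structural choice deserves emphasis. Applying the factor to Rac's
*entire* activation rate — baseline plus the Cdc42-proportional term —
closes a Rac → PI5K → PIP₂ → Rac self-amplification loop. In this
parameterization that loop destabilizes the polarized state: an immobilized
disk cell's front breaks into pole-to-pole sloshing oscillations with a
period near the pool-redistribution time `L²/D`, and a motile cell under
conflicting stimuli locks into a persistent double-lamellipod "dumbbell".
The package therefore applies the factor fully to the baseline term but
weights it on the amplification term by `fb_amp_weight` (default 0.5).
At this weight the polarized front of an immobilized cell is stationary,
conflicting fronts resolve faster with feedback than without, and the
motile cell crawls persistently. The weight is a real dial of the model:
at values near 1 the front becomes mobile enough for the shape-induced
reorientation behaviour described under *Known limitations*, at the price
of the oscillatory pathologies above.

## The actin layer

Filament density `F`, free barbed ends `B` and edge-bound pushing barbed
ends `Bp` are each resolved into six orientation classes at 60° spacing —
18 coupled fields, the six directions matching the lattice axes. Arp2/3 is
activated by PIP₂ (Hill threshold `P2_arp`) with Cdc42 synergy, diffuses,
and nucleates daughter barbed ends off mother filaments into the two
classes adjacent to the mother's (an equal ±60° split standing in for the
molecular branch angle). Ends are capped at a basal rate that PIP₂
suppresses sigmoidally; boundary sites whose PIP₂ exceeds
`le_pip2_rel` × basal count as leading edge and cap at `cap_le_fact` of
the rate. Gating the leading-edge reduction on PIP₂ rather than on the
local force balance is deliberate: a force-based flag is self-fulfilling
(any accidental push reduces capping, which builds more push) and
bootstraps a uniform actin ring around resting cells.

Free ends advect along their orientation at the free polymerization speed
with a conservative first-order upwind scheme; flux that would cross the
cell edge is blocked by the membrane and converted to pushing ends (per
unit edge length, one boundary site exposing `dx` of edge). Pushing ends
have no transport term. When the edge advances, pushing ends whose outlet
was covered are demoted back to free ends; when it retracts, the vacated
site's filaments and ends pile up on the occupied neighbours with their
orientations preserved, and piled ends whose outlet is open are promoted.
No end or filament mass is created or destroyed by any shape-engine event —
the test suite asserts the total end count to machine precision across
Monte-Carlo sweeps.

The resting cell is initialized at the actin fixed point where branching
balances capping (`basal_actin()`); with the default rates this is a small
but non-zero density, so a resting cell carries a quiet, isotropic
cytoskeleton rather than none.

## The shape engine

The cell is a set of occupied lattice sites evolving by Metropolis dynamics
on the energy `J·(boundary pair count up to 2nd-order neighbours) +
λ_area (a − A₀)² + λ_perim (p − P₀)²`. One Monte-Carlo sweep visits every
site in fresh random order; sites adjacent to the interface propose copying
a random neighbour's occupancy. A proposal's energy change is biased by the
local forces: pushing ends projected onto the move direction favour
protrusion, and Rho above `rho_thresh` drives contraction with coefficient
`lam_contract`. Changes that lower the biased energy by at least the yield
`H_yield` are certain; others are accepted with Boltzmann probability at
temperature `temp_T`.

Two numerical details matter:

* **Pair-count target.** The perimeter penalty's target is measured on the
  lattice from a disk of the target area, because the naive conversion
  (2 pairs per `dx` of perimeter) underestimates the staircase pair count
  by ~40%; using the naive target imposes a large spurious boundary
  tension that pinches resting cells apart.
* **Resolution scaling.** `λ_area`, `λ_perim` and the pair-count target are
  rescaled from the reference resolution (`dx_ref = 0.125` µm) so that the
  per-move restoring bias for a given relative deviation is
  resolution-independent; `J`, `temp_T`, `H_yield` and the force terms are
  per-move quantities and are left fixed. The timestep scales with `dx` so
  that the maximum edge speed `dx/dt` — and with it the calibrated
  force–velocity relation — is the same at every resolution.

`temp_T` and `H_yield` are not free: `calibrate_force_velocity()` fits the
shape engine's closed-form mean protrusion speed to the thermal-ratchet
force–velocity relation `v_poly · exp(−phi_mem/Bp)` over the biologically
relevant range of 10–120 pushing ends/µm. The speed curve alone only
constrains the difference of the extension and retraction acceptance
probabilities, leaving a direction along which the zero-load fluctuation
rate grows without bound; the fit therefore also anchors the zero-load
acceptance `exp(−H_yield/temp_T)` at 5%, the resting-edge fluctuation level
the temperature is understood to control. The fitted values (108.9, 274.6)
are the package defaults and the calibration is re-run as a test. The two
relations agree to ~0.06 µm/s RMS over the fitted range; exact agreement is
not achievable in this one-attempt-per-sweep idealization because the
Metropolis curve is convex where the ratchet curve saturates.

Cell fragmentation is allowed: if a sweep disconnects the cell, the largest
component is kept, the event is logged, and the discarded fragment's
contents are restored to the cell by the conservation renormalization.

## Moving-boundary bookkeeping

Each timestep is: explicit reaction update, actin kinetics and transport,
ADI diffusion of all ten concentration species on the current mask, then
(unless the shape is frozen) one Monte-Carlo sweep followed by
renormalization. A protruding pixel copies all concentrations from its
source (a locally flat profile); a retracting pixel's concentrations are
discarded; after the sweep every species is multiplied by the scalar that
restores its pre-sweep total, and the correction magnitudes are logged.
Alternative edge schemes (zero-fill plus heap-up, and an even split) are
available behind `edge_scheme` for robustness comparisons; the split scheme
produces qualitatively different, less stable dynamics in this
parameterization and is not a drop-in replacement.

Diffusion uses an alternating-direction implicit scheme native to the hex
lattice: three sequential implicit 1D solves, one along each principal
axis over a third of the timestep, on ring segments clipped to the mask
with no-flux ends (full rings solve periodically). The directional
coefficient carries the 2/3 factor that makes the three-pass composite
reproduce the isotropic hexagonal Laplacian; the scheme is unconditionally
stable, conserves masked totals to machine precision, and matches a 100×
finer explicit oracle to better than 1% in the tests. No-flux boundaries
make concentration isoclines meet the cell edge orthogonally; the tests
verify this on a polarized disk against the analytic radial normal (mean
deviation ≈ 6°; discrete staircase normals would add another ~10° of pure
quantization if used instead).

## Protocols and the synthetic stimuli

All inputs are generated in code. The standard polarizing stimulus
multiplies the Cdc42 activation rate by a linear ramp with 15% total
variation across the cell for 10 s; repolarization uses a later 3% ramp;
the conflicting-cue experiment uses a V-shaped profile (two opposed
gradients, 7.5% end-to-centre) for 10 s. A perfectly symmetric V on a
deterministic solver would never resolve, so the gradient protocols add a
small correlated perturbation at onset (1% of basal, 2 µm correlation
length); this is also the only seed dependence of frozen-shape runs and is
the package's convention for the "slight stochasticity" that selects a
winner. The noise protocol proper adds a Gaussian random field (default
25% of basal, 2 µm correlation) to active Cdc42 and Rac once at t = 0,
debiting the inactive pools so totals are conserved; iterated neighbour
averaging is calibrated so the realized Gaussian autocorrelation length
matches the request within 20%. Spatially correlated noise of at least
~5% is needed to polarize a resting cell at `eta = 0.5`; white or weaker
noise decays, which is the intended margin between CPM bookkeeping noise
(≤0.5% per sweep at desk scale) and genuine stimuli.

The ellipse experiment freezes a 2:1 ellipse at the standard area
(aspect ratio chosen as the documented default where no value was fixed);
walls and disk obstacles are permanently excluded sites whose copy
proposals are rejected, the no-flux condition at the contact following
automatically.

## Problem sizes and what the tests show

Desk scale resolves the standard 20 µm cell with ~50 sites across its
diameter (`dx = 0.4` µm, timestep 0.16 s); the conservation-guard run uses
the reference resolution (`dx = 0.125` µm, timestep 0.05 s, ~20,000 cell
sites). The full test suite runs in roughly ten minutes and the acceptance
script in under ten; both sizes are choices, and every quantitative result
in this vignette is recomputed by them at run time.

Passing tests establish internal consistency — conservation audits,
operator-level agreement with independent oracles, the acceptance law,
reproducibility from seeds — and the headline emergent behaviours at desk
scale: a stable resting cell; single-front polarization from a 15%
gradient; persistent crawling at ~0.1–0.2 µm/s; faster resolution of
conflicting fronts with PI feedback than without; interface straightening
that is faster and more complete with feedback. They do not establish
fidelity to any real cell: the generator emulates idealized stimuli on an
idealized disk, parameters are a self-consistent reconstruction rather
than measurements, and 2D topology hides thickness effects entirely.

## Known limitations

* **Stationarity versus reorientation.** With `fb_amp_weight = 0.5` the
  polarized front is deliberately stationary. The cost is that a frozen
  elliptical cell polarized along its short axis relaxes only ~10° toward
  the long axis and then stalls, and a sustained shallow rotated cue does
  not reorient an established front — the shape-induced reorientation
  regime lives at `fb_amp_weight` near 1, where the immobilized disk
  sloshes instead. The two regimes did not coexist anywhere in the
  parameter space explored; the package ships the stationary one and
  exposes the dial.
* **Conservation correction magnitude.** Per-sweep renormalization
  corrections scale with the net edge displacement per sweep times the
  front-to-mean concentration contrast over the cell's site count. At the
  reference resolution and timestep the motile steady state logs maxima
  near 0.2%; halving the timestep would halve it but also invalidate the
  force–velocity calibration above, so the package reports the honest
  value instead.
* Rho's rear localization is mild (the calibrated kinetics put the Rho
  maximum just behind the interface), so rear retraction is driven mostly
  by the area constraint rather than by contraction; `rho_thresh` is set
  high so contraction acts only in the strongest Rho zones.
* The model family's excluded features — receptor-level ligand binding,
  integrin mechanotransduction, intracellular fluid convection, explicit
  GEF/GAP/GDI species, actin-to-lipid feedback, severing, a G-actin pool
  and 3D geometry — are out of scope here too.
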