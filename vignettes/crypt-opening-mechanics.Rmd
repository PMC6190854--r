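---
title: "Elastic mechanics of gastric crypt-opening morphogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic mechanics of gastric crypt-opening morphogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cryptmech)
```

## The biological question

Under magnifying endoscopy the crypt openings of the gastric body and fundus
are round or oval dots, while those of the antrum (and of multiple white
flat lesions in the corpus) appear as lines or reticular grooves hidden
between marginal crypt epithelium (MCE) ridges. `cryptmech` implements a
desk-scale mechanical model of how the one morphology can evolve into the
other: ongoing stem-cell-driven regeneration loads the rim of the crypt
opening, the elastic epithelial sheet responds, and the interplay of four
mechanisms — continuous regeneration, Euler buckling with an
epithelial-mesenchymal-transition (EMT) force cap, viscoelastic hysteresis,
and stress-induced recruitment of neighbouring cell columns — stretches a
round opening into a line.

The package is a simulator, but its interface follows the classic R
modelling idiom: `run_crypt_sim()` plays the role of the fitting function
and returns a classed object with `print()`, `summary()`, `coef()`,
`plot()`, `residuals()` and `simulate()` methods.

## Model components

### Idealized geometry

In cross-section a gland that must transport and store liquid is a closed
curve; among closed curves of fixed perimeter the circle encloses the most
area (isoperimetric inequality), so the ideal opening is a circle, and the
ideal gland is a tube. `build_l_tube()` assembles the idealized gland as a
centerline with circular cross-sections: a vertical pit perpendicular to the
mucosal surface joined at a sharp right angle to a horizontal gland segment.
It is deliberately a schematic — a centerline-plus-sections model, not a
watertight mesh — because nothing downstream consumes a surface: the
simulator works on the opening contour, and the tube exists to fix the
geometric vocabulary (pit depth, gland length, cross-section index `m`).

Shape is quantified by `shape_metrics()`:

* **isoperimetric ratio** `4*pi*A/P^2`, computed by the shoelace formula on
  the counter-clockwise vertex list; 1 for a circle, decreasing toward 0 as
  the contour stretches;
* **aspect ratio**: the ratio of extents along the principal axes of the
  vertex second-moment matrix. Extent ratios (rather than eigenvalue
  ratios) make the measure exact for sampled ellipses. When the two
  eigenvalues tie, the axis closer to x is chosen, which makes the metric
  deterministic at no cost to rotation covariance in the generic case;
* **asymmetry**: twice the offset of the enclosed-area centroid from the
  midpoint of the major-axis extent, normalized by that extent. A symmetric
  oval scores 0; a teardrop (droplet) scores visibly above 0.1. The area
  centroid is used rather than the vertex mean because a teardrop's vertex
  projections can be symmetric even when its widths are not.

Both ratios are invariant to rigid motions and scaling; degenerate contours
(zero area or extent) are rejected rather than propagated.

### Force balance at the rim

The marginal crypt epithelium is modelled as a ring of point cells joined by
Hookean adhesion springs — in the ideal state cell–cell adhesion is the only
internal force, so springs are the whole constitutive law, and the cells are
reduced to their centres (deformation far from the loaded cell is
insensitive to the load's local details). At the focal rim cell the x-axis
balance reads `F_C = F_R*cos(theta1) + F_L*cos(theta2)`. Its symmetric
inversion `solve_symmetric_angles()` contains the model's one sharp number:
when all three force magnitudes are equal the opening angle is exactly
`theta1 + theta2 = 120` degrees, and the angle closes monotonically as the
pull grows, to 0 in the infinite-force limit — the stretched-line opening.
Beyond `F_C = 2*F_side` no symmetric solution exists; that regime is
reported as an error because physically the chain must recruit further
straightening, which `straightening_angle()` describes: the bond angle at
the right-hand neighbour tends to `pi` as the transmitted forces equalize.
The vertical balance is represented (`y_balance_residual()`, with each force
projected by its own angle) but never inverted: out-of-plane components do
not drive the in-plane shape change.

### Quasi-static relaxation

`relax_ring()` finds equilibria of the spring network. The scheme is an
overdamped inertial relaxation with adaptive damping (the FIRE family used
throughout particle and network mechanics), safeguarded so that total
elastic energy is non-increasing across accepted iterations up to the
rounding noise of the energy evaluation itself: a step that would raise the
energy beyond that noise is rejected, the pseudo-velocity reset and the step
size halved. Plain damped gradient iteration satisfies the same contracts
but needs orders of magnitude more iterations on ill-conditioned stretched
rings, which is why the inertial variant is the implementation; both are
overdamped fixed-point schemes on the net forces. Convergence is declared
when every free cell's net-force magnitude falls below `tol` (default
`1e-8` force units); exceeding the iteration cap (`1e5`) raises a typed
convergence error carrying the final residual.

A ring pulled at one cell has no equilibrium unless something reacts the
load, so the simulator pins the antipodal cell (the attachment of the rim
to the gland on the far side) and gives every cell a weak anchor spring to
its reference position (`anchor_stiffness`, default 0.02) standing for
attachment to the underlying lamina. The anchors also make the energy
Hessian positive definite, so the fixed point is isolated and can be
compared meaningfully — to `1e-6` in position — against an independent
oracle (direct BFGS minimization of the same energy), which the test suite
does on rings of up to 30 cells.

### Buckling and the EMT cap

Bending a sheet stretches material below the neutral surface and compresses
material above it, with strain `y/R` (`bending_strain()`), bending moment
`E*I/R` (`bending_moment()`), and second moment of area `I` computed about
the centroidal axis by midpoint quadrature with grid doubling and
Richardson extrapolation until the relative change is below `1e-8`
(`moment_of_inertia()`). For a pinned segment of end-to-end length `Lc`
(taken as one buckle wavelength, twice the cell-segment length `l`) the
sine mode `K*sin(pi*x/Lc)` solves the small-deflection beam equation
`y'' = -(pi/Lc)^2 * y`, and the critical axial load is the Euler force
`pi^2*E*I/Lc^2`. The small-slope identification of curvature with `y''` is
used as stated; it is only trustworthy for slopes below about 0.2, and the
amplitude-sweep check stays well inside that regime.

Two independent numerical routes corroborate the closed form:

* `discrete_chain_critical_load()` builds the bending stiffness and
  geometric softening matrices of an n-link pinned chain and finds the load
  at which transverse stiffness loses positive-definiteness (a generalized
  eigenvalue problem); it converges to the Euler force at O(1/n^2);
* `critical_load_from_amplitude()` detects the load from a finite-amplitude
  buckle by exact (nonlinear) bending energy against end-shortening work;
  the detected load is amplitude-independent to O((K*pi/Lc)^2), which is
  the operational meaning of "the Euler force does not depend on the
  deflection for small bending".

If the pull exceeded the Euler force the sheet would rupture. The model's
EMT rule (`emt_feedback()`) prevents that phenomenologically: whenever
`F_C` crosses `F_crit` an EMT event fires, the deflection is reduced in
proportion to the required force drop, and the pull returns to `F_crit`, so
after a burn-in the force always sits in the Euler-force vicinity (within
the tolerance band `epsilon`, default 5%). No molecular machinery is
modelled — the rule is the feedback arrow chain, nothing more.

### Viscoelastic hysteresis

Each division stretches the rim cell by `S_n = F/K` (Hooke), and the return
path dissipates energy against a constant viscous force `F_v`:
`S0_n = W_n / (F_v + K*S_n)` with `W_n = F*S_n`, so recovery is complete
only when `F_v = 0`. The minus signs of the underlying force law are
direction markers; the ledger works in magnitudes, because a literal signed
reading would produce negative distances. The net displacement accumulates
as `S_x = sum(S_n - S0_n)` (`accumulate_displacement()`), non-decreasing
always and strictly increasing exactly when `F_v > 0` — the mechanical
"memory" that keeps the opening stretched between divisions. A constant
per-event `F_v` is a declared modelling choice: the force law contains no
explicit time variable, so a rate-dependent drag would be an invention; the
lossless limit `F_v -> 0` is computed algebraically so that it is exact in
floating point. Dissipated energy per event, `W_n - K*S0_n^2/2`, is
reported and is provably non-negative.

### Depth attenuation

Deformation decays with distance from the loaded rim, so deeper
cross-sections of the pit displace less. `depth_profile()` uses
`S_x_m = S_x * exp(-lambda*m) + A_L[m]` — the exponential being the
simplest strictly monotone one-parameter decay law, with `lambda`
exposed in the configuration (default 0.5) — plus a per-depth schedule
`A_L` of added-cell lengths representing stress-induced differentiation of
neighbouring stem-cell columns near the replication zone. The trigger for
that recruitment is not modelled mechanistically; only its geometric
consequence (added length per depth) enters. Strict decrease in `m` is a
hard invariant: an `A_L` schedule that breaks it is rejected as a
configuration error, and a run that accumulated no displacement emits no
profile at all (an all-zero vector cannot decrease strictly). The auxiliary
depth-ordered length `D_L` carried alongside is deliberately opaque — it is
defined only up to being strictly increasing with depth, and the package
checks exactly that and nothing more.

## The simulator loop and its defaults

One `sim_step()` is: increment the pull by `delta_F_per_division`, let the
EMT cap act, relax the ring (warm-started from the previous equilibrium,
with anchors still tied to the reference ring so equilibria are
path-independent), and append the division to the ledger. `run_crypt_sim()`
iterates, classifies the contour at every step, and returns the trajectory.

The defaults are the package's reference study conditions, chosen once:

| parameter | default | meaning |
|---|---|---|
| units | all 1 | force, length and stiffness are dimensionless scales |
| `ring_size` | 24 | MCE cells on the rim; unit bond length |
| `E`, `I`, `Lc` | 1, 1, 2 | flexural scales; `Lc = 2l` with `l = 1` cell length, so `F_crit = pi^2/4` |
| `delta_F_per_division` | `0.05*F_crit` | no increment law exists in the biology; 5% of the critical load reaches the EMT regime after ~20 divisions |
| `F_v` | 0.5 | order-half of the unit spring force: visibly lossy but far from overdamped |
| `attenuation_lambda` | 0.5 | e-folding of displacement per cross-section |
| `n_cross_sections` | 5 | depth resolution of the pit |
| `emt_tolerance_band` | 0.05 | fractional excursion above `F_crit` tolerated |
| `anchor_stiffness` | 0.02 | weak tether: 2% of bond stiffness |
| `relax_tol` | `1e-6` | per-step force residual; shape metrics are insensitive well above this |

No physical unit system is attached because the underlying description
provides no measured parameter values; everything is scaled to the adhesion
spring. Classification thresholds (`opening_thresholds()`) are equally
conventions: `round` below aspect 1.15 with isoperimetric ratio above 0.9,
`droplet` past aspect 1.6, `linear` past aspect 8. The `groove` label is a
rendering convention for lattice compositions of neighbouring linear
openings (`compose_groove()`); a single pit can at most reach `linear`.

A 200-division run under these conditions (a few seconds on one core)
starts `round`, passes `oval` and `droplet`, and ends `linear` with the
isoperimetric ratio non-increasing and the aspect ratio non-decreasing at
every checkpoint; with EMT enabled the pull never leaves the Euler-force
vicinity after burn-in, and with EMT disabled it escapes. Those are the
property-level claims the test suite and `scripts/acceptance.R` recompute;
this vignette states nothing they do not measure.

```{r, eval = FALSE}
fit <- run_crypt_sim(sim_config())
summary(fit)
plot(fit)
```

## What the fixtures emulate — and what they do not

`make_fixture()` generates the test surface: resting rings and chains of
cells (optionally jittered, seeded), teardrop (piriform) contours for the
droplet stage, and ellipses for controlled aspect ratios. These are
idealized: real MCE rims are neither equally spaced nor uniformly stiff,
real openings are 3D and sectioned obliquely, and real tissue has
excluded-volume contacts the model omits (cells are centres; only springs
and applied forces act). Passing tests therefore certify the mechanics of
the idealized ring — equilibria against an independent minimizer, monotone
shape evolution, exact ledger identities — not agreement with histological
measurements, of which the model uses none.

## Numerical choices and degenerate inputs

* Contours are stored counter-clockwise; a duplicated closing vertex is
  dropped; consecutive duplicates, open contours (for the closed-contour
  metrics), and zero-area or zero-extent contours are errors.
* The relaxation energy guard accepts ties up to 16 machine epsilons of the
  energy magnitude — strict monotonicity below rounding noise is not
  measurable and enforcing it stalls the iteration.
* Quadrature in `moment_of_inertia()` starts at 64 midpoint cells, doubles,
  and Richardson-extrapolates; sections given as sampled profiles are
  linearly interpolated.
* The discrete-chain eigenproblem is symmetrized through a Cholesky factor
  of the geometric matrix, so `eigen(symmetric = TRUE)` applies.
* Serialization writes 17 significant digits, `\n` newlines, `.` decimal
  point, fixed column order; re-reading a trajectory reproduces the doubles
  bit-for-bit, and re-running an identical configuration reproduces the
  files byte-for-byte.
* The only randomness anywhere is fixture jitter and test-polygon
  generation, governed by one seed; the mechanics core is deterministic.

## Known limitations

* Post-buckling (large-deflection) equilibria, plastic failure and actual
  rupture are out of scope; the critical load is used only as a feedback
  threshold.
* The EMT rule caps force; it does not model cell-state transitions, and
  the deflection variable it reduces is a bookkeeping amplitude, not a
  resolved buckled profile of the ring.
* Depth attenuation is a one-parameter law applied to the accumulated
  displacement, not a resolved 3D elasticity solution.
* The multi-gland architecture of a real gastric unit (several glands per
  pit, gland fission) is simplified to one pit, one gland; the `groove`
  label is the only concession to neighbouring units.
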