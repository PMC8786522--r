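---
title: "Modelling tepid-sponge cooling of the forehead with the Pennes bioheat equation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tepid-sponge cooling of the forehead with the Pennes bioheat equation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioheat3d)
```

## The physical model

Tepid sponging treats fever by holding a cool wet cloth against the skin,
most often the forehead. `bioheat3d` models the heat transfer this drives
through the three tissue layers between the skin and the brain — scalp,
skull, and cerebrospinal fluid (CSF) — on a small cuboidal patch of the
forehead under the cloth. Living tissue does not conduct heat like inert
material: blood perfusion continuously exchanges heat with arterial blood,
and the tissue itself generates metabolic heat. The Pennes bioheat equation
captures all three mechanisms:

$$\rho c \frac{\partial T}{\partial t}
  = k \nabla^2 T + m_b c_b (T_A - T) + Q_m + Q_e,$$

with per-layer conductivity $k$, density $\rho$, and heat capacity $c$;
perfusion rate $m_b$ and blood heat capacity $c_b$; arterial temperature
$T_A$ (the fever temperature, 38–41 °C in the shipped scenarios); metabolic
heat $Q_m$; and an optional external volumetric source $Q_e$ (zero by
default — the cloth acts only through the surface boundary condition, not
as a volumetric sink).

The domain is a lattice of nodes with uniform spacing $h$ (2 mm by
default), depth axis $x$ (index $i$, $i = 0$ at the skin) and lateral axes
$y, z$ (signed indices $j, k$ centred on the patch). Boundary conditions:

* **Skin surface** ($x = 0$): either a Robin exchange with the cloth,
  $k\,\partial T/\partial x = h_e (T - T_w)$, with $T_w = 7$ °C the cloth
  temperature, or a Dirichlet clamp $T = T_w$;
* **Deep face** ($x = L$): Dirichlet at $T_A$ (the brain side stays at the
  fever temperature), or zero flux;
* **Lateral faces**: always zero flux — the patch is treated as a
  representative column of a laterally extended contact area.

The material database carries the published layer constants (scalp
$k = 0.342$, skull $0.651$, CSF $0.217$ W m⁻¹ K⁻¹, and so on), with the
scalp's metabolic heat split between a non-generating outer part and an
inner part at 1800 W m⁻³. The source only distinguishes "outer" and
"inner" scalp without defining the dividing depth, so the split defaults to
the scalp mid-thickness (2.25 mm of 4.5 mm) and is configurable
(`layer_field(scalp_split = ...)`).

## Two depth readings of the same geometry

The source description is internally inconsistent about depth: the layer
thicknesses sum to 10 mm (4.5 + 3.5 + 2 mm), yet the grid is described as
four 2-mm subintervals (8 mm) with the deep arterial plane variously at
$i = 4$ and $i = 5$. Neither reading can be called canonical, so both are
one switch apart: `preset_scenario(..., depth_nodes = 4)` (default; 8 mm
domain, 27 interior unknowns, matching the published 27-equation system)
and `depth_nodes = 5` (10 mm domain covering the full anatomical stack).
Layer boundaries always sit at their physical depths; a node's constants
come from the layer containing its depth, ties going to the deeper layer,
with no conductivity averaging across interfaces (a harmonic-mean scheme
would be the standard refinement, but the published per-node coefficient
structure is deliberately preserved).

## Steady solver

The steady solver assembles the seven-point-stencil equations

$$\sum_{\text{6 neighbours}} T - \Bigl(6 + \tfrac{h^2}{k} m_b c_b\Bigr) T_{i,j,k}
  = -\tfrac{h^2}{k}\bigl(m_b c_b T_A + Q_m + Q_e\bigr)$$

into a sparse system solved by direct LU factorisation (the systems are
tiny; an iterative path would gain nothing). Dirichlet neighbours fold into
the right-hand side. Lateral faces are eliminated by a zero-gradient copy
of the adjacent interior node, which reproduces the published 27-unknown
interior system exactly; in Robin mode the 25 surface-plane nodes join the
unknowns, with the ghost node beyond the skin eliminated at second order
through $k (T_1 - T_{-1})/2h = h_e (T_0 - T_w)$ (a first-order one-sided
variant exists for sensitivity checks, and measurably degrades the
convergence order from 2 to about 1). The matrix is strictly diagonally
dominant whenever perfusion is active, so the solve cannot fail on
admissible inputs; the residual is checked against $10^{-10}\,\lVert N
\rVert_\infty$ regardless.

Which surface condition to make the default was genuinely open: the
published account states both. Its steady tables were computed with the
surface *clamped* at 7 °C (they are described as a 27-unknown system with
known boundary values), and with the published $h_e = 0.64$ W m⁻² K⁻¹ the
Robin alternative is nearly an insulated wall — the steady field then sits
within half a degree of $T_A$ everywhere, which reproduces neither the
tables nor the intuition of a cooled forehead. An $h_e$ of a few hundred
W m⁻² K⁻¹ would be typical for wet contact, and back-solving the published
surface values implies roughly 260 W m⁻² K⁻¹, but the package does not
second-guess the printed constant. The replication presets therefore solve
the steady cases with `surface = "dirichlet"`, while transient presets
default to Robin so the skin can rewarm between cloth resets; both modes
are available everywhere.

## Transient solver

The transient path marches the same spatial operator with forward-time
centred-space (FTCS) explicit stepping:

$$T^{n+1} = T^n + \frac{\Delta t}{\rho c}\Bigl[
  k \frac{\sum_6 T^n - 6 T^n}{h^2} + m_b c_b (T_A - T^n) + Q_m + Q_e\Bigr].$$

(The printed update formula in the source contains sign and subscript
errors that make it inconsistent with its own PDE; the standard consistent
discretisation above is what is implemented.) The scheme is conditionally
stable: the self-weight stays non-negative only for

$$\Delta t \le \frac{\rho c\, h^2}{6k + h^2 m_b c_b},$$

which at $h = 2$ mm evaluates to 7.51 s (scalp), 2.47 s (skull), and
6.38 s (CSF) — the skull binds. A 2-minute reading interval therefore
cannot be the integration step; it is treated as an *output* interval, with
internal substepping at `safety_factor` (default 0.9) times the limit.
`ftcs_step()` refuses any larger step outright rather than damping or
sub-cycling silently, and `update_weights()` exposes the positivity
diagnostic. An unconditionally stable backward-Euler stepper
(`run_transient(method = "backward_euler")`) is provided for probing
large-step behaviour.

The sponging protocol: readings every 2 minutes up to 6 minutes, and the
cloth — which warms against the skin — is refreshed every 2 minutes. The
initial state fixes only the two extreme planes (surface at $T_w$, deep at
$T_A$); the interior default is depth-linear interpolation between them,
with uniform-at-$T_A$ and uniform-at-37 °C alternatives. At each reset tick
the surface plane is clamped back to $T_w$; between ticks it follows the
Robin condition. Snapshots are captured *before* the reset, so a reading
that coincides with a tick shows the rewarmed skin.

Numerical details worth knowing: the neighbour sum is accumulated in
per-axis pairs so that lateral mirror symmetry of a state is preserved
bitwise, not merely approximately; with zero-flux faces everywhere the
scheme conserves the trapezoid-weighted heat content to round-off; and the
explicit scheme is first order in time, so halving the default ~2.2 s
substep moves 6-minute outputs by a few hundredths of a degree (the change
shrinks linearly and falls below 10⁻³ °C once the substep reaches
~0.05 s). The steady and transient paths differ in one convention: the
steady reduction eliminates lateral face nodes by zero-gradient copy (to
match the published 27-unknown structure) while the transient evolves them
with central mirror ghosts (the conservative form); both impose zero
lateral flux and coincide exactly for laterally uniform forcing, which
covers every shipped scenario.

## Verification

Because the published numerics cannot be reproduced exactly (see below),
correctness rests on independent oracles:

* **Closed-form slab.** On a homogeneous, laterally insulated slab the
  steady problem reduces to the fin equation
  $k T'' - w (T - T_A) + Q = 0$, $w = m_b c_b$, with cosh/sinh solution for
  $w > 0$ and a quadratic for $w = 0$; `analytic_slab()` implements it with
  the Robin/Dirichlet end conditions resolved by a 2×2 solve, and
  `fd_slab_1d()` cross-checks it with a dense 10,000-node 1D solve
  (agreement ~10⁻⁷ °C). The 3D solver on such a slab is laterally uniform
  to 10⁻¹¹ and matches the closed form at every depth node.
* **Grid convergence.** `convergence_order()` measures the error against
  the closed form at $h = 2, 1, 0.5$ mm; the observed order is 2.00 with
  the central Robin ghost and ~0.95 with the one-sided option.
* **Brute force.** On the full lattice, the sparse solve is compared with
  an independent dense enumeration of the same equations (plain loops,
  base `solve()`); agreement is at machine precision.
* **Structural properties.** Discrete maximum principle (no sources, no
  perfusion), perfusion pull into $[\min T_{\text{surface}}, T_A]$, exact
  mirror symmetry, monotone centreline depth profiles, steady-limit
  equivalence of the long-time transient (max deviation ~10⁻¹³ °C after
  2 h), and forgetting of initial-condition noise. The randomized property
  suite draws layer constants from physiological ranges (conductivity
  0.2–0.7 W m⁻¹ K⁻¹, density 800–1600 kg m⁻³, heat capacity
  1500–4000 J kg⁻¹ K⁻¹, fever 37–41 °C, cloth 4–15 °C) under a fixed seed.

Problem sizes are kept small throughout — the production lattice is
5×5×5, the finest verification grids a few thousand unknowns, transient
runs a few thousand substeps — which is the regime the method targets.

## Replication of the published tables, and its limits

The six published tables (steady fields and 2/4/6-minute transients for
fevers of 38, 39.5, and 41 °C) ship as plain-CSV fixtures, transcribed
exactly as printed. `compare_reference()` produces per-node deviation
reports, and `symmetry_audit()` checks a table against its own $j \to -j$,
$k \to -k$ symmetry. The audit matters because the printed values violate
that symmetry in places — most glaringly a 1.00 °C mismatch between the
(3,0,1) and (3,0,−1) entries of the 41 °C steady table — and because the
tables rise by several degrees toward the lateral patch edges, which no
solution of the stated zero-lateral-flux problem can do (such solutions
are laterally uniform under laterally uniform boundary data). The surface
readings (e.g. 8.53 °C at the centre of a surface stated to be held at
7 °C) are likewise incompatible with both admissible surface treatments.
The replication reports therefore document agreement and misses node by
node at a ±0.5 °C assessment band rather than asserting agreement;
centre-column and deep-node values land close (the deep corner reading of
the 41 °C transient agrees to 0.01 °C), while lateral-edge and surface
entries miss by up to several degrees for the reasons above. Fixture
values are never altered; suspect rows are flagged and can be excluded
from headline maxima explicitly.

## What the generator of scenarios does and does not emulate

The shipped presets are the study conditions: an 8×8×8 mm forehead patch
at $h = 2$ mm, the three-layer stack with published constants, cloth at
7 °C, fevers of 38/39.5/41 °C, 2-minute reset-and-read protocol. Passing
tests show the solvers are correct for this idealised cuboid: flat layers,
constant per-layer properties, uniform perfusion at a single arterial
temperature, no sweating/evaporation, no hair or air gap, no curvature,
no thermoregulatory feedback. They do not show that a real forehead
follows these curves; the model's value is comparative (cases, protocols,
surface treatments), not predictive of clinical temperatures.

## Known limitations

* The stability guard uses the per-layer bound; with an extreme surface
  coefficient ($h_e \gtrsim k/h$, three orders above the published value)
  the Robin surface row could demand a slightly smaller step than the
  guard enforces — `update_weights()` makes this visible.
* Per-node layer coefficients (no interface flux averaging) follow the
  published scheme; heat flux across layer interfaces is therefore only
  first-order accurate at the jump, which is invisible in the shipped
  single-layer verification problems but would matter for refined
  multi-layer convergence studies.
* The pipeline is fully deterministic; there are no random seeds anywhere
  in the solvers.
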