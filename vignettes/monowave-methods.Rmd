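---
title: "Numerical methods and design choices in monowave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Numerical methods and design choices in monowave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(monowave)
```

monowave solves the monodomain reaction–diffusion equation
$\partial_t \underline{u} = \underline{P}\,\nabla\!\cdot(\mathbf{D}\nabla \underline{u}) + \underline{r}(\underline{u})$
on node-centered rectangular grids with explicit time stepping. This
vignette records the numerical choices, their rationale, and what the
shipped tests do and do not establish.

## Spatial discretization

**Diffusion tensor.** Anisotropy enters through the local fiber frame:
$\mathbf{D} = D_f\,e_f e_f^\top + D_s\,e_s e_s^\top + D_\times\,e_\times e_\times^\top$
with $e_\times = e_f \times e_s$ and diffusivities in mm²/ms. The frame
must be orthonormal to $10^{-6}$; the assembled tensor is validated
symmetric positive semidefinite via principal minors (tolerance
$10^{-9}$, scaled).

**Stencils.** Isotropic diffusion uses the classical $2N{+}1$-point
stencil with neighbor weights $D/\Delta x_n^2$. Full tensors use a
face-centered flux form: for each face between two interior vertices the
normal derivative is a two-point difference, tensor entries are averaged
to the face midpoint, and the in-face tangential derivatives of the
mixed terms are central differences averaged over the two face
endpoints, degrading to one-sided differences next to non-interior
vertices. This yields the 9-point (2D) / 19-point (3D) footprint and
reduces bit-for-bit to the isotropic stencil for diagonal constant
tensors.

**Boundaries and obstacles.** Zero-flux (Neumann) conditions and
exterior vertices (obstacle labels 0 in the `inhom` mask) are treated
identically: *the flux through any face touching a non-interior vertex
is zero*, i.e. the missing neighbor's weight is dropped from both the
neighbor and the center. Because every remaining face flux appears in
exactly two rows with opposite signs, the plain sum of the operator
output vanishes for **any** field and **any** mask — discrete
conservation is exact by construction, and explicit stepping conserves
$\sum u$ to rounding error. A node-mirror ghost treatment
($u_{-1} := u_1$, which doubles the opposite neighbor's weight) was
considered and rejected: it is only conservative under trapezoidal
quadrature and breaks the plain-sum conservation guarantee on obstacle
masks. The boundary rows are therefore first-order accurate at the
boundary, second-order in the interior — the usual trade of the
finite-volume closure. The diagonal of the assembled operator is set to
minus the off-diagonal row sum, so constants are annihilated to
rounding error.

**CFL bound.** For isotropic or diagonal diffusion the step bound is
$\Delta t < [2\,\mathrm{max}\underline{P}\sum_n D_{nn}/\Delta x_n^2]^{-1}$;
for full tensors a Gershgorin bound on the assembled weights,
$[\mathrm{max}\underline{P}\,\max_i \sum_{j\neq i} |w_{ij}|]^{-1}$, is
used (the two agree on interior-dominated isotropic grids). Both are
available; the stencil-weight bound is what the engine enforces. With
`dt = "auto"` the engine takes 0.9 × bound truncated to three
significant digits; an explicit dt above the bound is honored with a
warning, since deliberately unstable runs are themselves test cases.

## Time integration

Forward Euler (one right-hand-side evaluation per step) and classic RK4
(four evaluations, weights 1/6, 1/3, 1/3, 1/6) are available per state
variable via the model's stepping tags. For mixed tags the RK4 inner
stages hold euler-tagged variables at their step-start values; the two
schemes are then only coupled through the shared right-hand side, so the
composition is exact for decoupled systems and documented (and tested)
only there. Time is always computed as `step * dt`, never accumulated,
to avoid drift. Stability monitoring aborts a run when the state turns
non-finite *or* exceeds $10^{100}$ in magnitude: an unstable mode at
1.5 × the CFL bound doubles per step, so from physiological amplitudes
IEEE overflow alone would take several hundred further steps to appear
after the solution has already lost all meaning.

## Cell models

The shipped menu (cubic bistable "1VarPoly", Aliev–Panfilov, Barkley,
FitzHugh–Nagumo, Mitchell–Schaeffer, Fenton–Karma 3-variable BR set,
Bueno–Orovio minimal ventricular model EPI set, smooth Karma) is
transcribed from the standard published sources, recorded per model in
`$metadata$citation`. Parameters are the published defaults; every
constructor accepts overrides. Conventions worth noting:

* Resting states are exact fixed points: where a published initial
  condition is not a fixed point (the Bueno–Orovio gate $s$), the
  quasi-steady value at $u = 0$ is used instead — identical dynamics,
  cleaner invariants. FitzHugh–Nagumo's rest is solved numerically at
  construction.
* The smooth Karma recovery uses the smooth step
  $S(x) = (1+\tanh(kx))/2$ with steepness $k = 4$, chosen once so the
  resting state stays within $10^{-3}$ of $(0, 0)$ while the
  nonlinearity remains smooth.
* The cubic bistable model is $k\,u(1-u)(u-a)$ with $k = 8$,
  $a = 0.15$, picked for analytic tractability in tests.
* Each model declares an invariant box used by the boundedness tests.
  For Fenton–Karma the slow inward current can transiently push $u$
  above the plateau while $w$ is still high, so no rectangle is exactly
  forward-invariant; the declared start box is slightly smaller than
  the hold box and the test integrates space-clamped dynamics for
  1000 ms.
* Heaviside gates use the $u \ge \theta$ convention at equality.

Model wrappers add recording variables (diffusion term, reaction term,
LAT/LDT with linear-in-time crossing interpolation and sentinel −1 for
"never activated"), linear time/space/variable rescaling, and
multi-model composition dispatching on the `inhom` label. Recording
wrappers go *around* a multi-model, not inside it.

## Engine semantics

Per step: evaluate the rhs (projected diffusion + reaction + additive
stimuli) → advance by the per-variable scheme → apply set-mode stimuli
(set wins over dynamics) → run wrapper post-step updates (so LAT sees
stimulus jumps and the recorded diffusion matches the written frame) →
evaluate triggers and scheduled events → stability check → sample
sensors/electrograms and store frames when due. The initial condition
counts as a frame; sensors sample at the first step reaching one lag
after their previous sample; triggers fire on the false-to-true
transition of their (partition-aggregated) condition. The
waveback-passage condition arms itself only after the monitored value
has exceeded the threshold, so a resting sensor does not fire a
"downward" trigger spuriously at t = 0.

Domain splitting follows the x-slab contract: contiguous slabs whose
column counts differ by at most one (exterior vertices included in the
balance), one ghost column per side. The serial engine implements each
partition as a row slice of the global sparse operator — a test asserts
each slice references only slab ± 1 columns — and the per-row
accumulation order of the sparse matrix–vector product is independent of
the slicing, so 1, 2 and 4 partitions produce bit-identical frames.

Exterior vertices are stored at resting values in frames (files stay
dense rectangular arrays) and are masked by the `inhom` file in
analysis; they are never evaluated by reaction, stimulus or sensor code.

## Pseudo-electrograms

$\Phi_e(x_e, t)$ is the 1/r-kernel sum of the recorded diffusion term
over interior voxels with midpoint quadrature
(weight = prefactor × voxel volume / distance). No kernel
regularization is applied; instead the electrode must keep at least half
the smallest grid spacing away from any interior vertex. This keeps the
operation exactly linear in the source field. The prefactor
($\tau_e/4\pi$, ms) is entirely user-controlled, as its normalization
depends on the chosen diffusivity convention.

## Tips, filaments and phase defects

Phase singularities are located by scanning, in every coordinate-plane
family ($\binom{N}{2}$ of them), every voxel face whose four corners are
interior, and intersecting the bilinear interpolants of two chosen
surfaces — by default isolines of two state variables at per-model
isovalues, alternatively any two supplied layers (e.g. the
delayed-voltage pair). The two bilinear equations reduce to a quadratic
whose roots are computed with the numerically stable form; candidate
faces are prefiltered by a corner sign test. Degenerate faces where an
interpolant is constant at its isovalue contain an isoline segment, not
a point, and report nothing. Trajectory linking is deliberately simple:
greedy nearest-neighbor within a radius per frame gap (default
2 × max Δx; raise it when frames are far apart relative to tip speed),
with unmatched tips opening (birth) or closing (death at the first
missing frame) trajectories.

Activation-time phase is
$\varphi = \mathrm{wrap}(2\pi (t - \mathrm{LAT})/T)$ into $(-\pi, \pi]$
(half-period maps to $+\pi$). The phase-defect density is the cosine
method, $\varrho(x) = \langle (1 - \cos(\varphi(y) - \varphi(x)))/2
\rangle_{y \in \mathcal{N}(x)}$ over interior nearest neighbors: 0 for
locally smooth phase (second order in the local increment), and equal to
the fraction of cross-jump neighbors at a $\pi$ discontinuity (1/4 for
an interior vertex with one of four neighbors across the jump). Variant
definitions exist in the literature; this one is fixed, documented and
tested on synthetic fields.

## Scenario fixtures and what they show

Four deterministic scenarios at desk scale exercise the whole stack and
emit their configs as YAML (`write_scenario_config()`), doubling as
command-line examples:

* `scenario_planar_wave()` — smooth-Karma planar wave on 30 × 30 × 1 mm,
  monotone LAT, no tips.
* `scenario_s1s2_spiral()` — Aliev–Panfilov S1S2 rotor induction
  (D = 1.6 mm²/ms, Δx = 1 mm, Δt = 0.1 ms; trigger: voltage dropping
  below 0.1 at the central sensor). The scaled 60 × 60 default keeps the
  full protocol; a 120 × 120 variant is available. The S2 firing time is
  dynamic (≈ 40 ms on the scaled sheet) — the model's native time scale
  is treated as ms without an additional rescaling wrapper, so absolute
  protocol times are not comparable to rescaled-time setups.
* `scenario_inhom_multimodel()` — two smooth-Karma parameterizations,
  disk and rectangle obstacles at Δx = 0.2 mm, D = 0.031 mm²/ms, a
  planar stimulus at t = 0 and a half-plane probe at t = 600 ms.
* `scenario_benchmark_cuboid(dx, dt)` — Bueno–Orovio wave through a
  20 × 7 × 3 mm cuboid, fibers along the long axis, D_f = 0.12 mm²/ms
  with transverse anisotropy ratio 4. Refining Δx from 0.5 to 0.2 mm
  (fixed Δt = 0.05 ms) reduces the far-corner activation time
  (coarse-grid transversal slow-down); at Δx = 0.1 mm the bound is
  ≈ 0.028 ms, so Δt = 0.05 ms aborts with a stability error within a few
  dozen steps. Default durations (60 ms for the benchmark, 300 ms for
  the scaled S1S2) were sized to the phenomena they must contain — the
  far corner activates before 50 ms, the rotor appears within 100 ms of
  S2.

The generator grids are small, the models phenomenological, and the
fiber fields synthetic (constant or analytically varying). Passing tests
therefore establish the numerics — discretization correctness against
dense oracles, conservation, convergence orders, CFL behavior, format
round-trips, detection geometry — not clinical fidelity: no real
ventricular geometry, DT-MRI fiber field, or ionic-model validation
against experimental action potentials is implied.

## Known limitations

* Explicit stepping only: stiff ionic models at fine grids demand small
  Δt; there is no operator splitting or implicit diffusion.
* Domain decomposition only along x, mirroring the output-file layout;
  the in-process "partitions" reproduce the splitting contract, not
  distributed memory.
* Node-centered boundary closure is first-order at boundaries.
* Tip linking is greedy, not globally optimal assignment; for dense tip
  populations with large frame gaps it may fragment trajectories.
* Curved-surface geometries, tetrahedral meshes, bidomain extracellular
  fields and Luo–Rudy/ten Tusscher-class ionic models are out of scope.
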