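---
title: "Methods: coupled Purkinje–myocardium monodomain simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled Purkinje-myocardium monodomain simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiofvm)
```

## The model and its assumptions

`cardiofvm` solves the monodomain equation — the standard single-potential
reduction of the bidomain model, valid when intra- and extracellular
anisotropy ratios are assumed equal — on two coupled domains: a
three-dimensional myocardium and a one-dimensional Purkinje network.
Units are fixed everywhere: cm, ms, mV, mS/cm, kOhm, and stimulus currents
in pA/pF (the per-capacitance convention, so pA/pF = mV/ms at
C_m = 1 uF/cm²; C_m enters the diffusion side separately).

The myocardial conductivity tensor at each control volume is assembled from
an orthonormal fibre triad (f, s, n) and three scalars:
sigma = sigma_f f⊗f + sigma_t s⊗s + sigma_n n⊗n. Boundaries are no-flux
except at Purkinje–muscle junctions (PMJs), where a resistive flux couples
the terminal Purkinje volume to its N_PMJ nearest myocardial volumes through
a lumped junction resistance R_PMJ. The junction law, per terminal,

J_PMJ = (1/h_P²) Σ_k (V_P − V_Mk) / R_PMJ,

is applied with its reciprocal currents on the myocardial side. The
reciprocity is required by flux continuity across the junction — without it
no anterograde activation could occur at all — and makes the exchanged
currents sum to zero exactly at every step, which the test suite asserts.

## Finite-volume discretisation

**Myocardium.** Cubic control volumes of edge h_M on an integer lattice;
only active volumes are stored, so wedges and irregular shapes are the same
type as full cuboids (neighbour lookup hashes the lattice index). Volume
centers sit at (index + 0.5)·h_M, lattice indices are 0-based, and boxes
(stimuli, region tags) are half-open [lo, hi). Each face flux uses the two
face-adjacent volumes for the normal gradient, with the face conductivity
tensor taken as the arithmetic average of the two volume tensors;
cross-derivative (transverse) terms use centred differences over the face's
lateral neighbour pairs, dropping any pair with a missing member (zero-flux
closure). For axis-aligned fibres the assembly reduces exactly to the
classical 7-point anisotropic stencil, which the tests verify against an
independently coded oracle. Because the lateral-pair closure near boundaries
is not perfectly symmetric, the assembled operator is explicitly
symmetrised, ½(A + Aᵀ); the maximum relative asymmetry is recorded on the
system object and, should it ever exceed 1e−8, the solver layer switches
from CG to BiCG. Every contribution is a difference of potentials, so the
stiffness operator annihilates constants (zero row and column sums) and the
diffusion solve conserves total charge under no-flux boundaries.

**Purkinje.** One-dimensional control volumes of spacing h_P along a rooted
tree. Each node inherits the conductivity of the edge to its parent and
faces take the harmonic mean of the two adjacent volume conductivities — the
physically correct series composition for 1-D conduction. A branching volume
balances the upstream flux against one flux per child; terminal volumes
carry only the upstream flux, the PMJ term entering as an explicit source.
Volume measure is h_P³ (regular hexahedra), so both domains share one
backward-Euler form: (M + K)V^{n+1} = M V^{n+1/2} + S with
M = diag(h³ β C_m / Δt).

## Time integration and stability

Godunov operator splitting advances each diffusion step Δt_pde as: (1)
Δt_pde/Δt_ode explicit reaction sub-steps in both domains (the ratio must be
an exact integer; the benchmark default is 0.02/0.01 ms); (2) PMJ currents
evaluated at the half step; (3) two independent implicit diffusion solves
with the PMJ currents as right-hand-side sources. Reaction sub-steps use
forward Euler or Rush–Larsen; Rush–Larsen advances Hodgkin–Huxley gates
exactly for frozen coefficients, y ← y∞ + (y − y∞)exp(−Δt/τ), and is
unconditionally stable for the gating subsystem (the ten Tusscher m-gate has
τ ≈ 0.001 ms at rest, which forward Euler cannot take at any practical
step). The splitting is first-order: halving both steps roughly halves the
solution error, and the tests assert the observed ratio.

Evaluating the PMJ flux at the half step decouples the two domains but makes
the coupling explicit, hence conditionally stable: for a myocardial load
capacitance C = h_M³ β C_m, the explicit exchange diverges once Δt is large
against R_PMJ·C. Divergence is detected — any non-finite potential or
|V| > 500 mV flags the run `unstable` and stops it — and is always reported
as a status, never propagated as silent NaN. Propagation *block* (a
terminal that activates while its coupled myocardium never does) is a
physical outcome and is classified separately from instability.

The diffusion systems are solved by Jacobi-preconditioned conjugate
gradients warm-started from the previous potentials (defaults: relative
tolerance 1e−10, 5000 iterations; convergence requires both the raw and
preconditioned residual norms to pass). BiCG is available for operators
without the symmetry guarantee. Solver non-convergence aborts with the
residual; it is distinct from the instability flag.

## Ionic models

Models are plugins: `n_states` (state 1 is always V), a resting state, the
Hodgkin–Huxley gate indices, and one vectorised rate evaluator returning the
total ionic current, all state derivatives, and (y∞, τ) per gate. The rest
state of every shipped model is a genuine fixed point (residual < 1e−6 per
ms, asserted by tests).

**Phenomenological model (default).** A cubic excitation–recovery model in
the Aliev–Panfilov form mapped to physiological units, V = −85 + 100·u, with
k = 8, a = 0.1, eps0 = 0.01, mu1 = 0.14, mu2 = 0.3 and a time scaling
tau = 2.5 ms chosen so that, with the benchmark conductivities
(sigma_f = 1.334 mS/cm, beta = 1400 /cm), a planar wave travels at ≈ 30 cm/s
along the fibre — a realistic human transmural velocity. Its rest state
(−85 mV, 0) is exact by construction, the upstroke clears 0 mV under the
benchmark stimulus (53 pA/pF, 2 ms), and it repolarises below −70 mV within
a few hundred ms. All fast tests use it.

**ten Tusscher ventricular model.** The ten Tusscher–Panfilov epicardial
model with the intracellular Na⁺ and K⁺ concentrations clamped at their
quiescent values, giving 17 dynamic states of which 12 are Rush–Larsen
gates. The clamp is deliberate: the full model's Na/K balance drifts on the
minutes scale and only equilibrates at non-physiological concentrations
(pinning Na_i at 8.69 mM forces the potassium balance to K_i ≈ 481 mM at
V ≈ −119 mV), so no physiological resting fixed point exists without it.
With the clamp, the resting state frozen into the source satisfies the
fixed-point invariant to < 1e−13 per ms (computed by a Levenberg–Marquardt
solve of the steady-state equations after a 5 s unstimulated settle). The
clamp is a standard reduction for single-beat propagation studies; it would
not be appropriate for pacing-rate or overload protocols.

## Pseudo-ECG

Electrode potentials assume an unbounded homogeneous volume conductor:
φ_e = (1/4π sigma_b) Σ_i s_i/‖r_i‖, where s_i = −(K V)_i is the discrete
volume integral of ∇·(σ∇V) taken from the diffusion stiffness operator —
the same object the PDE solve uses, so the source is available at every
step. Uniform fields give exactly zero; φ_e is linear in deviations from
rest, decays as 1/r per source element, and scales as 1/sigma_b — all
asserted as exact tests. Electrodes must lie outside the tissue (distance
> h/2 from every center). No torso geometry is modelled; clinical lead
placement is configuration data.

## PMJ delay measurement and calibration sweeps

Local activation time is the first sample at or above the threshold
(−40 mV by default), without interpolation; terminal and nearest-coupled
traces are recorded at every diffusion step, so each activation time is
quantised to Δt_pde and each *delay* (a difference of two such times) to
2·Δt_pde. The "closest myocardium control volume" is the first entry of the
terminal's distance-sorted PMJ list; nearest-neighbour ties are broken by
ascending lattice lexicographic order (distances quantised to 12 significant
digits first so exact geometric ties are not split by rounding noise), which
makes PMJ maps deterministic and independent of grid storage order.
Calibration runs use a 50 ms window: long enough for anterograde activation,
short enough to keep a 2000-run design tractable; block is decided at the
end of the window.

Factorial sweeps are the full Cartesian product of named axes in
deterministic lexicographic order (first axis slowest), each run getting a
unique directory name encoding its parameters. Equispaced axis values
include both endpoints. The dispatcher executes every run exactly once in an
isolated directory, isolates failures (one diverging run never aborts the
batch) and produces aggregate tables that are byte-identical for any worker
count, since aggregation follows run order, not completion order.

## The calibration fixture, and what the tests do and do not show

The bundled preparation (`pmj_wedge_config()`) is a 0.5 × 0.5 × 0.25 cm
wedge (20 × 20 × 10 volumes at h_M = 250 um) with benchmark anisotropic bulk
conductivities and an isotropic endocardial layer (x < 0.1 cm), activated by
a single 0.5 cm Purkinje cable whose terminal sits half a voxel inside the
endocardial face. Free parameters not fixed by any published value were
chosen once on physiological grounds: sigma_P = 40 mS/cm gives the cable a
conduction velocity about five times the myocardial fibre velocity, in the
physiological Purkinje range; the endocardial conductivities are 0.2 mS/cm
("sparse") and 0.6 mS/cm ("dense").

On this preparation the expected source–sink phenomenology reproduces:
anterograde delay grows with R_PMJ up to propagation block, falls with
N_PMJ, falls when the myocardial mesh is refined, grows when the Purkinje
mesh is refined (a finer terminal volume delivers less current), and grows
with endocardial conductivity (more dispersion before threshold). Delays in
the conducting band are 5–20 ms, overlapping the experimentally reported
anterograde range. The monotone-trend assertions are made for
R_PMJ ≥ 1300 kOhm, the upper half of the calibration range, where the
junction resistance dominates the source impedance. Below ≈ 1000 kOhm this
fixture enters a terminal-loading regime — the phenomenological Purkinje
plateau has finite current capacity, so at low R_PMJ and large N_PMJ the
terminal itself sags and the delay-vs-N_PMJ relation flattens and can invert
by a few tenths of a millisecond. That regime is reported honestly by the
simulator; the trend tests simply do not claim monotonicity there.

More generally, passing tests on these fixtures demonstrate the numerical
contracts (conservation, operator correctness, convergence orders, trend
directions) on idealised geometries with uniform fibres and a
phenomenological membrane. They do not validate organ-level activation
sequences, real fibre architecture, detailed restitution, or clinical ECG
morphology.

## Numerical choices and problem sizes

Degenerate inputs are rejected eagerly: non-commensurate extents, empty
domains, non-integer step ratios, negative resistances, unknown
configuration keys. Empty-region retags warn and leave the grid unchanged.
Instability threshold: |V| > 500 mV. The activation map uses −1 as the
"never activated" sentinel in CSV output. Mesh-convergence checks run on a
reduced preparation — a 0.8 cm fibre-direction cable timed at x = 0.6 cm
against an h = 50 um reference — because the full 1500 ms benchmark cuboid
at three resolutions is an overnight job in interpreted R; the cable
preserves the quantity under study (fibre-direction activation-time error
vs h). Test problem sizes (4000-volume wedges, 50-volume solver oracles,
20-volume cables) were chosen so the whole suite exercises every contract
in a few minutes on one CPU.

## Known limitations

Voxelised geometry introduces staircase boundaries; no unstructured-mesh
ingestion. The PMJ coupling is explicit, so very small R_PMJ with large
steps destabilises (detected and flagged, with the fully implicit
alternative out of scope). The ten Tusscher variant clamps Na⁺/K⁺ and so
cannot study concentration-driven phenomena. The pseudo-ECG ignores torso
inhomogeneity. Space adaptivity is deliberately absent — on fixed uniform
grids the assembled operator is reused for the whole run, which is both
simpler and, in this setting, faster.
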