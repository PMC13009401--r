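# cardiofvm

A desk-scale simulator of cardiac electrical activation for the coupled
Purkinje–myocardium system, written for electrophysiology modellers who want
to study Purkinje–muscle junction (PMJ) behaviour — anterograde delay,
propagation block, discretisation sensitivity — without an HPC solver.

## The model

Both domains obey the monodomain reaction–diffusion equation

```
beta ( C_m dV/dt + I_ion(V, eta) ) = div( sigma grad V ) + beta I_stim
d eta / dt = f(V, eta)
```

with `V` the transmembrane potential (mV), `eta` the ionic state vector,
`beta` the surface-to-volume ratio (1/cm), `C_m` the membrane capacitance
(uF/cm²) and `sigma` the conductivity tensor (mS/cm). The myocardium is
discretised by the finite volume method on a uniform hexahedral voxel grid
with per-volume fibre triads `(f, s, n)` and conductivities
`(sigma_f, sigma_t, sigma_n)`; the Purkinje network is a rooted tree of 1-D
control volumes with harmonic-mean face conductivities and branching-aware
flux balances. Each Purkinje terminal couples resistively to its `N_PMJ`
nearest myocardial volumes:

```
J_PMJ = (1 / h_P^2) * sum_k (V_P - V_Mk) / R_PMJ        [uA/cm^2]
```

with reciprocal currents applied on the myocardial side so the exchange
conserves charge exactly. Time integration uses Godunov operator splitting:
explicit reaction sub-steps (forward Euler or Rush–Larsen for
Hodgkin–Huxley gates), PMJ currents evaluated at the half step (which
decouples the two diffusion solves, at the cost of conditional stability in
`R_PMJ` and `dt`), and backward-Euler diffusion solved by Jacobi-
preconditioned conjugate gradients. A pseudo-ECG is available as the
`1/||r||`-weighted sum of the diffusion source over an unbounded volume
conductor. Shipped ionic models: a 2-variable phenomenological excitable
model (fast, used by the test suite) and the ten Tusscher–Panfilov human
ventricular model (epicardial, Na/K-clamped; 17 states).

## Worked example

Measure the anterograde PMJ delay in the bundled calibration preparation — a
0.5 × 0.5 × 0.25 cm endocardial wedge activated by a single Purkinje
terminal — at a junction resistance of 1300 kOhm coupling 70 myocardial
volumes:

```r
library(cardiofvm)
cfg <- pmj_wedge_config(R_PMJ = 1300, N_PMJ = 70)
res <- run_simulation(cfg)
res
#> simulation_result: ok, t = [0, 50] ms, 4000 myocardial / 20 Purkinje volumes
measure_pmj_delays(res)
#>   terminal t_purkinje t_myocardium delay status
#> 1       20        3.8        15.42 11.62     ok
```

The terminal Purkinje volume crosses the −40 mV activation threshold 3.8 ms
after His pacing; its closest coupled myocardial volume follows at 15.42 ms,
an anterograde PMJ delay of 11.62 ms — the source–sink mismatch of a small
Purkinje source driving a myocardial bulk. Raising `R_PMJ` lengthens the
delay until propagation blocks (`status = "block"`); raising `N_PMJ` shortens
it. Sweeps over the coupling plane run through `sweep_spec()` /
`generate_sweep()` / `dispatch_batch()`, and `delay_heatmap()` aggregates the
records with block/instability masks.

Simulations can also be driven from INI configuration files (see
`inst/extdata/template.ini` for the dialect and units, and
`inst/extdata/benchmark_cuboid.ini` for the standard 64,000-volume
conduction benchmark) or from the shell via `inst/cli/cardiofvm.R`
(`simulate`, `sweep`, `pmj-delays`, `ecg`, `convert` subcommands). Results
can be written as EnSight Gold binary (compact) or legacy VTK files for
ParaView, plus activation-map, ECG and delay CSV tables.

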