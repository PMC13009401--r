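# Conduction benchmark: 1 x 1 x 1 cm myocardial cuboid, transverse
# anisotropy, corner stimulus. Units: cm, ms, mV, mS/cm, kOhm, pA/pF.

[main]
t_max = 1500
beta = 1400
cm = 1
output_interval = 2

[grid]
source = cuboid
extent = 1 1 1
h = 0.025
sigma = 1.334 0.176 0.176
fiber_axis = 1 0 0

[ode]
dt_ode = 0.01
dt_pde = 0.02
myocardium_model = ten_tusscher
purkinje_model = ten_tusscher
integrator = rush_larsen

[linear_solver]
method = cg
tol = 1e-10
maxit = 5000
preconditioner = jacobi

[stim_corner]
domain = myocardium
box = 0 0 0 0.15 0.15 0.15
start = 0
duration = 2
amplitude = 53
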