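# cardiofvm configuration template.
#
# Units are fixed throughout: lengths cm, times ms, potentials mV,
# conductivities mS/cm, PMJ resistance kOhm, stimulus amplitude pA/pF
# (per-capacitance convention: pA/pF = mV/ms at C_m = 1 uF/cm^2).
# Unknown sections or keys are errors.

[main]
t_max = 50                  # total simulated time, ms
beta = 1400                 # surface-to-volume ratio, 1/cm
cm = 1                      # membrane capacitance, uF/cm^2
output_interval = 1         # snapshot cadence, ms
# output_dir = out          # enable to write snapshot/CSV outputs
# formats = ensight vtk     # snapshot formats
activation_threshold = -40  # mV, local-activation-time threshold

[grid]                      # myocardial voxel grid (omit for Purkinje-only)
source = cuboid             # cuboid | file
extent = 0.5 0.5 0.25       # cm, each an integer multiple of h
h = 0.025                   # spacing, cm
sigma = 1.334 0.176 0.176   # sigma_f sigma_t sigma_n, mS/cm
fiber_axis = 1 0 0
region_endo = 0 0 0 0.1 0.5 0.25 0.2 0.2 0.2   # box lo/hi + isotropic sigma
# file = grid.txt           # with source = file

[purkinje]                  # Purkinje network (omit for myocardium-only)
source = tree               # tree | file
depth = 0                   # bifurcation levels (0 = straight cable)
branch_length = 0.5         # cm, integer multiple of h
h = 0.025                   # cm
sigma = 40                  # mS/cm
origin = -0.4625 0.2375 0.1125
direction = 1 0 0
# file = network.txt

[pmj]                       # Purkinje-muscle junction coupling
r_pmj = 1300                # junction resistance, kOhm
n_pmj = 55                  # coupled myocardial volumes per terminal

[ode]
dt_ode = 0.01               # reaction step, ms
dt_pde = 0.02               # diffusion step, ms (integer multiple of dt_ode)
myocardium_model = phenomenological
purkinje_model = phenomenological
integrator = rush_larsen    # rush_larsen | euler

[linear_solver]
method = cg                 # cg | bicg
tol = 1e-10
maxit = 5000
preconditioner = jacobi     # jacobi | none

[stim_his]                  # one [stim_<name>] section per stimulus
domain = purkinje           # myocardium | purkinje
box = -0.48 0.19 0.06 -0.39 0.29 0.16
start = 0                   # ms
duration = 2                # ms
amplitude = 53              # pA/pF

[ecg]                       # optional pseudo-ECG leads
sigma_b = 1                 # bath conductivity, mS/cm
electrode_V1 = 1.5 0.25 0.125
electrode_V2 = -1.0 0.25 0.125
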