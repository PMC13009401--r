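# Standard study fixtures: the conduction benchmark cuboid and the
# wedge-plus-single-terminal PMJ calibration preparation.

#' Benchmark cuboid configuration
#'
#' The standard conduction benchmark: a 1 x 1 x 1 cm myocardial cuboid with
#' transversely anisotropic conduction (sigma_f = 1.334, sigma_t = sigma_n =
#' 0.176 mS/cm), beta = 1400 1/cm, C_m = 1 uF/cm^2, discretised at h = 250 um
#' (64,000 control volumes), stimulated in a 0.15 x 0.15 x 0.15 cm corner
#' region for 2 ms at 53 pA/pF, with reaction step 0.01 ms and diffusion step
#' 0.02 ms.
#'
#' @param h spacing in cm (default 0.025).
#' @param t_max simulated time in ms; the full protocol runs 1500 ms, but a
#'   shorter window suffices to time activation.
#' @param model ionic model name for the myocardium.
#' @return a `run_config`.
#' @export
benchmark_cuboid_config <- function(h = 0.025, t_max = 1500,
                                    model = "ten_tusscher") {
  sim_config(
    grid = list(type = "cuboid", extent = c(1, 1, 1), h = h,
                sigma = c(1.334, 0.176, 0.176), fiber_axis = c(1, 0, 0)),
    beta = 1400, cm = 1, dt_ode = 0.01, dt_pde = 0.02, t_max = t_max,
    models = list(myocardium = model, purkinje = model),
    integrator = "rush_larsen",
    stimuli = list(stimulus(c(0, 0, 0, 0.15, 0.15, 0.15), 0, 2, 53)),
    output = list(interval = 2)
  )
}

#' Wedge + single-terminal PMJ calibration fixture
#'
#' A myocardial wedge activated by one Purkinje terminal, used to measure
#' anterograde PMJ delays as a function of the coupling parameters. The wedge
#' is 0.5 x 0.5 x 0.25 cm with the benchmark anisotropic bulk conductivities
#' and an isotropic endocardial layer (x < 0.1 cm) of conductivity
#' `sigma_endo`; a straight Purkinje cable of length 0.5 cm enters along x
#' with its terminal at the centre of the endocardial face, one half-voxel
#' inside the tissue. The His end of the cable is paced at t = 0 (2 ms,
#' 53 pA/pF). The Purkinje conductivity default (40 mS/cm) gives a cable
#' conduction velocity in the physiological Purkinje range (roughly 5 times
#' the myocardial fibre velocity).
#'
#' @param R_PMJ junction resistance, kOhm.
#' @param N_PMJ coupled myocardial volume count.
#' @param h_M myocardial spacing, cm.
#' @param h_P Purkinje spacing, cm (0.5 cm must be a multiple).
#' @param sigma_endo isotropic endocardial conductivity, mS/cm.
#' @param sigma_P Purkinje conductivity, mS/cm.
#' @param t_max window, ms (50 ms suffices for anterograde delays).
#' @param dt_ode,dt_pde time steps, ms.
#' @return a `run_config`.
#' @export
pmj_wedge_config <- function(R_PMJ, N_PMJ, h_M = 0.025, h_P = 0.025,
                             sigma_endo = 0.2, sigma_P = 40,
                             t_max = 50, dt_ode = 0.01, dt_pde = 0.02) {
  grid <- build_cuboid_grid(c(0.5, 0.5, 0.25), h_M, c(1.334, 0.176, 0.176))
  grid <- tag_region(grid, c(0, 0, 0, 0.1, 0.5, 0.25), "endo",
                     rep(sigma_endo, 3))
  m <- round(0.5 / h_P)
  terminal <- c(0.0125, 0.2375, 0.1125)
  origin <- terminal - c((m - 1) * h_P, 0, 0)
  network <- build_purkinje_tree(0, 0.5, h_P, sigma_P, origin = origin)
  sim_config(
    grid = grid, network = network,
    pmj = list(R_PMJ = R_PMJ, N_PMJ = N_PMJ),
    t_max = t_max, dt_ode = dt_ode, dt_pde = dt_pde,
    output = list(interval = 5),
    stimuli = list(stimulus(
      c(origin[1] - 0.01, origin[2] - 0.05, origin[3] - 0.05,
        origin[1] + 0.08, origin[2] + 0.05, origin[3] + 0.05),
      0, 2, 53, domain = "purkinje"
    ))
  )
}
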