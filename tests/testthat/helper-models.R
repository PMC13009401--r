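# Shared test fixtures, built in code.

# passive model: no ionic current, no extra states beyond a dummy
passive_model <- function() {
  ionic_model_spec(
    name = "passive", n_states = 2, rest_state = c(-85, 0),
    rates = function(states) {
      list(I_ion = numeric(nrow(states)),
           deriv = matrix(0, nrow(states), 2),
           gate_inf = NULL, gate_tau = NULL)
    }
  )
}

# linear decay model: dV/dt = -V (I_ion = V)
linear_model <- function() {
  ionic_model_spec(
    name = "linear", n_states = 1, rest_state = 0,
    rates = function(states) {
      list(I_ion = states[, 1], deriv = matrix(0, nrow(states), 1),
           gate_inf = NULL, gate_tau = NULL)
    }
  )
}

# single Hodgkin-Huxley gate with constant y_inf and tau; V frozen
gate_model <- function(y_inf = 1, tau = 1) {
  ionic_model_spec(
    name = "gate", n_states = 2, rest_state = c(0, y_inf),
    gating_indices = 2L,
    rates = function(states) {
      n <- nrow(states)
      list(
        I_ion = numeric(n),
        deriv = cbind(0, (y_inf - states[, 2]) / tau),
        gate_inf = matrix(y_inf, n, 1), gate_tau = matrix(tau, n, 1)
      )
    }
  )
}

# small coupled fixture: short myocardial cable + 5-volume Purkinje cable;
# fast enough for dispatcher and writer tests
tiny_coupled_config <- function(R_PMJ = 500, N_PMJ = 2, t_max = 10,
                                dt_ode = 0.01, dt_pde = 0.02) {
  h <- 0.05
  grid <- build_cuboid_grid(c(0.3, 0.1, 0.1), h, c(1.334, 0.176, 0.176))
  org <- c(0.025, 0.075, 0.075) - c(4 * h, 0, 0)
  net <- build_purkinje_tree(0, 5 * h, h, 40, origin = org)
  sim_config(
    grid = grid, network = net,
    pmj = list(R_PMJ = R_PMJ, N_PMJ = N_PMJ),
    t_max = t_max, dt_ode = dt_ode, dt_pde = dt_pde,
    output = list(interval = 1),
    stimuli = list(stimulus(
      c(org[1] - 0.01, org[2] - 0.05, org[3] - 0.05,
        org[1] + 0.11, org[2] + 0.05, org[3] + 0.05),
      0, 2, 53, domain = "purkinje"
    ))
  )
}
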