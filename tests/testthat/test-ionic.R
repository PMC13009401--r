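test_that("forward Euler advances the membrane by dt * (-I_ion + I_stim)", {
  m <- passive_model()
  st <- rest_state_block(m, 4)
  expect_equal(step_forward_euler(m, st, 0.01, 0), st)
  # benchmark stimulus amplitude: 53 pA/pF for dt = 0.01 ms -> +0.53 mV
  st2 <- step_forward_euler(m, st, 0.01, 53)
  expect_equal(st2[, 1], st[, 1] + 0.53)
  # linear decay: V0 = 1, dt = 0.1 -> 0.9
  lm <- linear_model()
  st3 <- step_forward_euler(lm, matrix(1, 1, 1), 0.1)
  expect_equal(st3[1, 1], 0.9)
})

test_that("both integrators reject non-finite derivatives with the volume index", {
  bad <- ionic_model_spec(
    name = "bad", n_states = 1, rest_state = 0,
    rates = function(states) {
      I <- numeric(nrow(states))
      I[2] <- NaN
      list(I_ion = I, deriv = matrix(0, nrow(states), 1),
           gate_inf = NULL, gate_tau = NULL)
    }
  )
  st <- matrix(0, 3, 1)
  expect_error(step_forward_euler(bad, st, 0.01), "volume 2")
  expect_error(step_rush_larsen(bad, st, 0.01), "volume 2")
})

test_that("Rush-Larsen integrates constant-rate gates exactly", {
  dt <- 0.37
  m <- gate_model(y_inf = 1, tau = dt)
  st <- matrix(c(0, 0), 1)
  st <- step_rush_larsen(m, st, dt)
  expect_equal(st[1, 2], 1 - exp(-1), tolerance = 1e-12)
  # fixed point: y0 = y_inf stays put for any dt
  for (dt2 in c(1e-3, 1, 50)) {
    stfp <- step_rush_larsen(m, matrix(c(0, 1), 1), dt2)
    expect_equal(stfp[1, 2], 1)
  }
  expect_error(step_rush_larsen(gate_model(tau = -1), matrix(c(0, 0), 1), 0.1),
               "tau > 0")
})

test_that("Rush-Larsen gates stay bounded for any dt", {
  m <- gate_model(y_inf = 0.8, tau = 0.01)
  for (dt in c(0.01, 1, 100)) {
    y <- 0
    st <- matrix(c(0, y), 1)
    for (k in 1:20) {
      st <- step_rush_larsen(m, st, dt)
      expect_gte(st[1, 2], 0)
      expect_lte(st[1, 2], 0.8)
    }
  }
})

test_that("Rush-Larsen and forward Euler agree to O(dt^2) on gates", {
  m <- gate_model(y_inf = 1, tau = 2)
  one_step_diff <- function(dt) {
    rl <- step_rush_larsen(m, matrix(c(0, 0.2), 1), dt)[1, 2]
    fe <- step_forward_euler(m, matrix(c(0, 0.2), 1), dt)[1, 2]
    abs(rl - fe)
  }
  ratio <- one_step_diff(1e-3) / one_step_diff(1e-4)
  expect_gt(ratio, 80)
  expect_lt(ratio, 120)
})

test_that("both integrators converge to the same trajectory at order >= 1", {
  lm <- linear_model()
  run <- function(stepper, dt) {
    st <- matrix(1, 1, 1)
    for (k in seq_len(round(1 / dt))) st <- stepper(lm, st, dt)
    st[1, 1]
  }
  exact <- exp(-1)
  for (stepper in list(step_forward_euler, step_rush_larsen)) {
    e1 <- abs(run(stepper, 0.1) - exact)
    e2 <- abs(run(stepper, 0.05) - exact)
    expect_gt(e1 / e2, 1.7) # observed order >= 1
  }
})

test_that("shipped rest states are fixed points of the dynamics", {
  for (name in c("phenomenological", "ten_tusscher")) {
    m <- ionic_model(name)
    st <- rest_state_block(m, 1)
    rt <- m$rates(st)
    drift <- max(abs(c(-rt$I_ion, rt$deriv[, -1])))
    expect_lt(drift, 1e-6)
    expect_equal(m$n_states, length(m$rest_state))
    expect_equal(ionic_model(name)$n_states, m$n_states)
  }
})

test_that("the phenomenological cell fires and repolarises under the benchmark stimulus", {
  m <- ionic_model("phenomenological")
  st <- rest_state_block(m, 1)
  dt <- 0.01
  peak <- -Inf
  for (k in seq_len(round(400 / dt))) {
    t <- (k - 1) * dt
    st <- step_forward_euler(m, st, dt, if (t < 2) 53 else 0)
    peak <- max(peak, st[1, 1])
  }
  expect_gt(peak, 0)
  expect_lt(st[1, 1], -70)
})

test_that("requesting an unregistered model lists the available ones", {
  expect_error(ionic_model("no_such_model"),
               "phenomenological.*ten_tusscher|ten_tusscher.*phenomenological")
})
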