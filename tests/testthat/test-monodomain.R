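test_that("the stiffness operator annihilates constants and is symmetric", {
  g <- build_cuboid_grid(c(0.15, 0.2, 0.1), 0.05, c(1.334, 0.176, 0.176),
                         fiber_axis = c(1, 2, 0) / sqrt(5))
  sys <- assemble_myocardium(g, beta = 1400, C_m = 1, dt_pde = 0.02)
  K <- as.matrix(sys$K)
  expect_lt(max(abs(rowSums(K))), 1e-12)
  expect_lt(max(abs(K - t(K))), 1e-14)
  expect_lt(max(abs(K %*% rep(3.7, sys$n))), 1e-11)
  # full operator SPD
  ev <- eigen(as.matrix(sys$A), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("a 2-volume isotropic cable assembles the hand-computed entries", {
  g <- build_cuboid_grid(c(0.2, 0.1, 0.1), 0.1, c(1, 1, 1))
  sys <- assemble_myocardium(g, beta = 1400, C_m = 1, dt_pde = 0.02)
  A <- as.matrix(sys$A)
  expect_equal(A[1, 2], -0.1) # -sigma * h
  expect_equal(A[1, 1], 0.1^3 * 1400 / 0.02 + 0.1)
  expect_equal(A, t(A))
})

test_that("axis-aligned fibres reproduce the 7-point anisotropic stencil", {
  sig <- c(1.334, 0.176, 0.49)
  h <- 0.025
  g <- build_cuboid_grid(c(3, 4, 5) * h, h, sig)
  sys <- assemble_myocardium(g, beta = 1400, C_m = 1, dt_pde = 0.02)
  # independent 7-point oracle: diagonal tensor, face sigma = mean of the
  # two adjacent volumes (uniform here), coefficient sigma_aa * h
  n <- nrow(g$index)
  Ko <- matrix(0, n, n)
  for (p in seq_len(n)) {
    for (a in 1:3) {
      for (dir in c(-1, 1)) {
        nb <- g$index[p, ]
        nb[a] <- nb[a] + dir
        q <- which(g$index[, 1] == nb[1] & g$index[, 2] == nb[2] &
                     g$index[, 3] == nb[3])
        if (length(q)) {
          Ko[p, p] <- Ko[p, p] + sig[a] * h
          Ko[p, q] <- Ko[p, q] - sig[a] * h
        }
      }
    }
  }
  expect_equal(as.matrix(sys$K), Ko, tolerance = 1e-13,
               ignore_attr = TRUE)
})

test_that("Purkinje assembly is tridiagonal on a cable with harmonic-mean faces", {
  net <- build_purkinje_tree(0, 0.1, 0.025, 2)
  sys <- assemble_purkinje(net, beta = 1400, C_m = 1, dt_pde = 0.02)
  K <- as.matrix(sys$K)
  expect_lt(max(abs(K %*% rep(1, sys$n))), 1e-14)
  expect_true(all(K[abs(row(K) - col(K)) > 1] == 0))
  # two-segment cable sigma1 then sigma2: interface face = harmonic mean
  nodes <- cbind(seq(0, by = 0.025, length.out = 4), 0, 0)
  edges <- data.frame(parent = 1:3, child = 2:4, sigma = c(4, 4, 1))
  net2 <- purkinje_network(nodes, edges, 0.025)
  K2 <- as.matrix(assemble_purkinje(net2, 1400, 1, 0.02)$K)
  expect_equal(K2[2, 3], -4 * 0.025) # within segment 1
  expect_equal(K2[3, 4], -(2 * 4 * 1 / (4 + 1)) * 0.025) # harmonic mean
})

test_that("a bifurcation volume couples to its parent and both children", {
  net <- build_purkinje_tree(1, 0.1, 0.025, 2)
  sys <- assemble_purkinje(net, 1400, 1, 0.02)
  K <- as.matrix(sys$K)
  branching <- which(vapply(net$children, length, integer(1)) == 2)
  expect_equal(sum(K[branching, -branching] != 0), 3)
  # terminal rows carry only the upstream flux
  for (tm in net$terminals) {
    expect_equal(sum(K[tm, -tm] != 0), 1)
  }
})

test_that("PMJ currents follow the resistive junction law and conserve charge", {
  g <- build_cuboid_grid(c(0.1, 0.1, 0.05), 0.025, c(1, 1, 1))
  net <- build_purkinje_tree(0, 0.1, 0.025, 2,
                             origin = c(-0.0625, 0.0375, 0.0125))
  map <- map_pmjs(net, g, N_PMJ = 1, R_PMJ = 1000)
  nP <- nrow(net$nodes)
  nM <- nrow(g$index)
  # equal potentials -> zero everywhere
  cur0 <- compute_pmj_currents(rep(-85, nP), rep(-85, nM), map, 0.025)
  expect_equal(cur0$flux, 0)
  expect_equal(cur0$terminal_current, 0)
  # 1 mV over 1000 kOhm across one volume with h_P = 0.025 cm
  V_P <- rep(-85, nP)
  V_P[map$terminals] <- -84
  cur1 <- compute_pmj_currents(V_P, rep(-85, nM), map, 0.025)
  expect_equal(cur1$flux, 1 / 1000 / 0.025^2) # 1.6 uA/cm^2
  expect_equal(cur1$currents[[1]], 1e-3) # uA into the myocardium
  expect_equal(cur1$terminal_current, -1e-3)
  # retrograde sign
  cur2 <- compute_pmj_currents(rep(-90, nP), rep(-85, nM), map, 0.025)
  expect_lt(cur2$currents[[1]], 0)
  # conservation with many coupled volumes and arbitrary potentials
  map5 <- map_pmjs(net, g, N_PMJ = 5, R_PMJ = 700)
  set.seed(11)
  cur5 <- compute_pmj_currents(rnorm(nP, -40, 30), rnorm(nM, -80, 10),
                               map5, 0.025)
  expect_equal(cur5$terminal_current + sum(cur5$currents[[1]]), 0)
})

test_that("the coupled resting state is an equilibrium of advance_step", {
  cfg <- tiny_coupled_config()
  cfg$stimuli <- list()
  res <- run_simulation(cfg)
  expect_equal(res$status, "ok")
  expect_lt(max(abs(res$V_M - (-85))), 1e-9)
  expect_lt(max(abs(res$V_P - (-85))), 1e-9)
  expect_true(all(is.na(res$lat_M)))
})

test_that("the diffusion solve conserves total charge under no-flux boundaries", {
  register_ionic_model(passive_model())
  g <- build_cuboid_grid(c(0.2, 0.15, 0.1), 0.05, c(1.334, 0.176, 0.176))
  sys <- assemble_myocardium(g, 1400, 1, 0.02)
  set.seed(5)
  V0 <- rnorm(sys$n, -60, 25)
  state <- list(M = cbind(V0, 0), P = NULL)
  models <- list(M = passive_model())
  total0 <- sum(V0) * sys$volume
  for (k in 1:10) {
    adv <- advance_step(state, list(M = sys), models,
                        function(t) list(M = 0, P = 0), 0,
                        0.01, 0.02,
                        solver = list(method = "cg", tol = 1e-12,
                                      maxit = 5000,
                                      preconditioner = "jacobi"))
    state <- adv$state
  }
  total1 <- sum(state$M[, 1]) * sys$volume
  expect_lt(abs(total1 - total0) / abs(total0), 1e-8)
})

test_that("PMJ source currents sum to zero across domains at every step", {
  cfg <- tiny_coupled_config(R_PMJ = 300, N_PMJ = 3, t_max = 6)
  res <- run_simulation(cfg)
  grid <- res$grid
  net <- res$network
  systems <- list(
    M = assemble_myocardium(grid, cfg$beta, cfg$cm, cfg$dt_pde),
    P = assemble_purkinje(net, cfg$beta, cfg$cm, cfg$dt_pde),
    map = res$map
  )
  models <- list(M = ionic_model("phenomenological"),
                 P = ionic_model("phenomenological"))
  state <- list(M = rest_state_block(models$M, systems$M$n),
                P = rest_state_block(models$P, systems$P$n))
  stim <- cfg$stimuli[[1]]
  nodes_in <- net$nodes[, 1] >= stim$box[1] & net$nodes[, 1] < stim$box[4]
  stim_fun <- function(t) {
    IP <- numeric(systems$P$n)
    if (t >= stim$start && t < stim$start + stim$duration) {
      IP[nodes_in] <- stim$amplitude
    }
    list(M = 0, P = IP)
  }
  for (k in 1:100) {
    adv <- advance_step(state, systems, models, stim_fun,
                        (k - 1) * 0.02, 0.01, 0.02)
    state <- adv$state
    expect_lt(abs(adv$pmj$terminal_current +
                    sum(unlist(adv$pmj$currents))), 1e-12)
  }
})

test_that("halving the splitting steps halves the solution error", {
  g <- build_cuboid_grid(c(0.25, 0.025, 0.025), 0.025,
                         c(1.334, 0.176, 0.176))
  v_at <- function(dt_pde) {
    cfg <- sim_config(
      grid = g, t_max = 20, dt_ode = dt_pde / 2, dt_pde = dt_pde,
      integrator = "euler",
      output = list(interval = 20),
      stimuli = list(stimulus(c(0, 0, 0, 0.05, 1, 1), 0, 2, 53)),
      solver = list(method = "cg", tol = 1e-12, maxit = 5000,
                    preconditioner = "jacobi")
    )
    res <- run_simulation(cfg)
    res$V_M[, ncol(res$V_M)]
  }
  ref <- v_at(0.01)
  e1 <- max(abs(v_at(0.08) - ref))
  e2 <- max(abs(v_at(0.04) - ref))
  expect_gt(e1 / e2, 1.4)
  expect_lt(e1 / e2, 3.2)
})

test_that("explicit PMJ coupling instability is detected and flagged, never silent NaN", {
  cfg <- tiny_coupled_config(R_PMJ = 1, N_PMJ = 1, t_max = 20,
                             dt_ode = 0.25, dt_pde = 0.5)
  res <- run_simulation(cfg)
  expect_equal(res$status, "unstable")
  expect_true(is.finite(res$unstable_t))
  # everything recorded before the abort is finite
  expect_true(all(is.finite(res$V_M[, res$times < res$unstable_t])))
  # the same configuration at the benchmark step sizes is stable
  res_ok <- run_simulation(tiny_coupled_config(R_PMJ = 100, N_PMJ = 1,
                                               t_max = 20))
  expect_equal(res_ok$status, "ok")
})

test_that("a single resting volume stays flat for the whole window", {
  g <- build_cuboid_grid(c(0.05, 0.05, 0.05), 0.05, c(1, 1, 1))
  cfg <- sim_config(grid = g, t_max = 10, output = list(interval = 1))
  res <- run_simulation(cfg)
  expect_equal(res$status, "ok")
  expect_equal(as.numeric(res$V_M), rep(-85, ncol(res$V_M)))
})
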