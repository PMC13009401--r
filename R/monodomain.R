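# Finite-volume assembly and the Godunov operator-splitting time loop.
#
# Discrete backward-Euler diffusion system, per domain:
#     (M + K) V^{n+1} = M V^{n+1/2} + S
# with M = diag(h^3 beta C_m / dt) (uA/mV), K the flux (stiffness) operator
# (K V = -integral of div(sigma grad V) over each control volume; mS*cm scale
# so that K V is in uA), and S the explicit PMJ source currents in uA.
# Conductivities in mS/cm, potentials in mV, so mV * mS = uA.

# per-volume symmetric conductivity tensor, columns (xx, yy, zz, xy, xz, yz)
.conductivity_tensors <- function(grid) {
  f <- grid$fibers[, 1:3, drop = FALSE]
  s <- grid$fibers[, 4:6, drop = FALSE]
  n <- grid$fibers[, 7:9, drop = FALSE]
  sf <- grid$sigma[, 1]
  st <- grid$sigma[, 2]
  sn <- grid$sigma[, 3]
  cbind(
    xx = sf * f[, 1]^2 + st * s[, 1]^2 + sn * n[, 1]^2,
    yy = sf * f[, 2]^2 + st * s[, 2]^2 + sn * n[, 2]^2,
    zz = sf * f[, 3]^2 + st * s[, 3]^2 + sn * n[, 3]^2,
    xy = sf * f[, 1] * f[, 2] + st * s[, 1] * s[, 2] + sn * n[, 1] * n[, 2],
    xz = sf * f[, 1] * f[, 3] + st * s[, 1] * s[, 3] + sn * n[, 1] * n[, 3],
    yz = sf * f[, 2] * f[, 3] + st * s[, 2] * s[, 3] + sn * n[, 2] * n[, 3]
  )
}

#' Assemble the myocardial diffusion system
#'
#' Face-flux finite-volume assembly on the voxel grid. The flux normal to a
#' face uses the two face-adjacent volumes with the face conductivity tensor
#' taken as the arithmetic average of the two volume tensors; transverse
#' (cross-derivative) terms use centred differences over the face's lateral
#' neighbour pairs. Missing neighbours impose zero flux. The operator is
#' explicitly symmetrised (1/2 (A + A')) and the maximum relative asymmetry
#' recorded; if it exceeds 1e-8 the solver layer switches to BiCG.
#'
#' @param grid a `cartesian_grid`.
#' @param beta surface-to-volume ratio, 1/cm.
#' @param C_m membrane capacitance, uF/cm^2.
#' @param dt_pde diffusion time step, ms.
#' @return a `monodomain_system`: `A` (full backward-Euler operator),
#'   `K` (stiffness part), `M_diag`, geometry metadata, `asymmetry`,
#'   `use_bicg`.
#' @export
assemble_myocardium <- function(grid, beta = 1400, C_m = 1, dt_pde = 0.02) {
  stopifnot(inherits(grid, "cartesian_grid"), dt_pde > 0)
  if (any(grid$sigma < 0)) stop("negative conductivity in grid")
  n <- nrow(grid$index)
  h <- grid$h
  Tm <- .conductivity_tensors(grid)
  key <- grid$key
  offs <- c(2^40, 2^20, 1)
  # cross-term column of the tensor for axis pair (a, b)
  cross_col <- matrix(c(NA, 4, 5, 4, NA, 6, 5, 6, NA), 3, 3)
  ti <- list()
  tj <- list()
  tx <- list()
  push <- function(i, j, x) {
    m <- length(ti) + 1
    ti[[m]] <<- i
    tj[[m]] <<- j
    tx[[m]] <<- x
  }
  for (a in 1:3) {
    q <- match(key + offs[a], key)
    p <- which(!is.na(q))
    if (!length(p)) next
    q <- q[p]
    # normal flux: h^2 * sigma_aa_face * (Vq - Vp)/h
    caa <- 0.5 * (Tm[p, a] + Tm[q, a]) * h
    push(p, p, caa)
    push(q, q, caa)
    push(p, q, -caa)
    push(q, p, -caa)
    for (b in setdiff(1:3, a)) {
      cab <- 0.5 * (Tm[p, cross_col[a, b]] + Tm[q, cross_col[a, b]])
      if (all(cab == 0)) next
      pb_up <- match(key[p] + offs[b], key)
      pb_dn <- match(key[p] - offs[b], key)
      qb_up <- match(key[q] + offs[b], key)
      qb_dn <- match(key[q] - offs[b], key)
      ok1 <- !is.na(pb_up) & !is.na(pb_dn)
      ok2 <- !is.na(qb_up) & !is.na(qb_dn)
      nav <- ok1 + ok2
      use <- nav > 0 & cab != 0
      if (!any(use)) next
      # flux into p: h^2 * sigma_ab * dV/db at face, with
      # dV/db ~ sum of available centred pairs / (2 h nav)
      base <- cab[use] * h / (2 * nav[use])
      pu <- p[use]
      qu <- q[use]
      add_pair <- function(up, dn, okm) {
        sel <- okm[use]
        if (!any(sel)) return()
        c0 <- base[sel]
        # K = -flux; current into p is +c0*(V_up - V_dn), into q is opposite
        push(pu[sel], up[use][sel], -c0)
        push(pu[sel], dn[use][sel], c0)
        push(qu[sel], up[use][sel], c0)
        push(qu[sel], dn[use][sel], -c0)
      }
      add_pair(pb_up, pb_dn, ok1)
      add_pair(qb_up, qb_dn, ok2)
    }
  }
  K <- if (length(ti)) {
    Matrix::sparseMatrix(
      i = unlist(ti), j = unlist(tj), x = unlist(tx), dims = c(n, n)
    )
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(n, n))
  }
  .finish_system(K, n, h, beta, C_m, dt_pde, domain = "myocardium",
                 centers = grid$centers)
}

.finish_system <- function(K, n, h, beta, C_m, dt_pde, domain, centers) {
  Kt <- Matrix::t(K)
  scale <- max(abs(K))
  asym <- if (scale > 0) max(abs(K - Kt)) / scale else 0
  K <- (K + Kt) / 2
  M_diag <- rep(h^3 * beta * C_m / dt_pde, n)
  A <- K + Matrix::Diagonal(n, M_diag)
  structure(
    list(
      A = methods::as(A, "CsparseMatrix"),
      K = methods::as(K, "CsparseMatrix"),
      M_diag = M_diag, n = n, h = h, volume = h^3,
      beta = beta, C_m = C_m, dt_pde = dt_pde,
      asymmetry = asym, use_bicg = asym > 1e-8,
      domain = domain, centers = centers
    ),
    class = "monodomain_system"
  )
}

#' Assemble the 1-D Purkinje diffusion system
#'
#' Backward-Euler operator on the network graph. Each adjacency (parent or
#' child) contributes one face flux with face conductivity the harmonic mean
#' of the two adjacent volume conductivities; a branching volume's row sums
#' the fluxes to all its children plus the upstream flux; terminal rows carry
#' only the upstream flux (the PMJ term enters as an explicit source).
#'
#' @param network a `purkinje_network`.
#' @inheritParams assemble_myocardium
#' @return a `monodomain_system`.
#' @export
assemble_purkinje <- function(network, beta = 1400, C_m = 1, dt_pde = 0.02) {
  stopifnot(inherits(network, "purkinje_network"), dt_pde > 0)
  n <- nrow(network$nodes)
  h <- network$h
  e <- network$edges
  if (nrow(e)) {
    sp <- network$node_sigma[e$parent]
    sc <- network$node_sigma[e$child]
    sig <- ifelse(sp + sc > 0, 2 * sp * sc / (sp + sc), 0)
    c_e <- sig * h # h^2 face area * grad/h
    K <- Matrix::sparseMatrix(
      i = c(e$parent, e$child, e$parent, e$child),
      j = c(e$parent, e$child, e$child, e$parent),
      x = c(c_e, c_e, -c_e, -c_e),
      dims = c(n, n)
    )
  } else {
    K <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                              x = numeric(0), dims = c(n, n))
  }
  .finish_system(K, n, h, beta, C_m, dt_pde, domain = "purkinje",
                 centers = network$nodes)
}

#' Evaluate PMJ coupling currents
#'
#' For each terminal, the junction flux is
#' `J_PMJ = (1 / h_P^2) * sum_k (V_P - V_Mk) / R_PMJ` (uA/cm^2, since
#' mV / kOhm = uA). The current `J_PMJ * h_P^2` leaves the terminal Purkinje
#' volume and each coupled myocardial volume k receives the reciprocal
#' current `(V_P - V_Mk) / R_PMJ` (uA), so the exchange conserves current
#' exactly. A positive terminal-to-volume difference drives anterograde
#' (Purkinje to myocardium) flow; a negative one retrograde.
#'
#' @param V_P Purkinje potential vector, mV.
#' @param V_M myocardial potential vector, mV.
#' @param map a `pmj_map`.
#' @param h_P Purkinje spacing, cm.
#' @return a `pmj_currents` list: per-terminal `flux` (uA/cm^2),
#'   `terminal_current` (uA, sign = into the terminal volume), and per-
#'   terminal myocardial `volumes` / `currents` (uA, into each volume).
#' @export
compute_pmj_currents <- function(V_P, V_M, map, h_P) {
  stopifnot(inherits(map, "pmj_map"))
  nt <- length(map$terminals)
  flux <- numeric(nt)
  term_cur <- numeric(nt)
  myo_cur <- vector("list", nt)
  for (t in seq_len(nt)) {
    vp <- V_P[map$terminals[t]]
    vm <- V_M[map$volumes[[t]]]
    cur <- (vp - vm) / map$R_PMJ # uA into each myocardial volume
    myo_cur[[t]] <- cur
    term_cur[t] <- -sum(cur)
    flux[t] <- sum(cur) / h_P^2
  }
  structure(
    list(
      terminals = map$terminals, flux = flux,
      terminal_current = term_cur, volumes = map$volumes,
      currents = myo_cur
    ),
    class = "pmj_currents"
  )
}

.solve_domain <- function(system, b, solver, x0) {
  if (isTRUE(system$use_bicg) || identical(solver$method, "bicg")) {
    sol <- bicg_solve(system$A, b, tol = solver$tol, maxit = solver$maxit,
                      x0 = x0)
  } else {
    sol <- cg_solve(system$A, b, tol = solver$tol, maxit = solver$maxit,
                    preconditioner = solver$preconditioner, x0 = x0)
  }
  if (!sol$report$converged) {
    stop(sprintf(
      "linear solver failed to converge (%s, %d iterations, residual %.3e)",
      sol$report$method, sol$report$iterations, sol$report$residual
    ))
  }
  sol
}

#' Advance the coupled state by one diffusion step
#'
#' Godunov operator splitting: (1) `dt_pde / dt_ode` explicit reaction
#' sub-steps in both domains; (2) PMJ currents evaluated at the half step,
#' which decouples the two domains; (3) two independent backward-Euler
#' diffusion solves with the PMJ currents as right-hand-side sources.
#'
#' @param state `list(M = state matrix or NULL, P = state matrix or NULL)`.
#' @param systems `list(M = monodomain_system, P = monodomain_system,
#'   map = pmj_map)` (each element optional).
#' @param models `list(M = ionic_model, P = ionic_model)`.
#' @param stim_fun function of time (ms) returning
#'   `list(M = pA/pF vector or 0, P = ...)`.
#' @param t time at the start of the step, ms.
#' @param dt_ode,dt_pde reaction and diffusion steps, ms (integer ratio).
#' @param integrator `"rush_larsen"` or `"euler"`.
#' @param solver solver settings list.
#' @return `list(state, pmj, reports, unstable)`; `unstable` is `TRUE` when
#'   any potential left the physiological range (|V| > 500 mV) or became
#'   non-finite, which is reported rather than propagated as silent NaN.
#' @export
advance_step <- function(state, systems, models, stim_fun, t,
                         dt_ode, dt_pde,
                         integrator = "rush_larsen",
                         solver = list(method = "cg", tol = 1e-10,
                                       maxit = 5000,
                                       preconditioner = "jacobi")) {
  n_sub <- round(dt_pde / dt_ode)
  if (abs(dt_pde / dt_ode - n_sub) > 1e-9) {
    stop("dt_pde must be an integer multiple of dt_ode")
  }
  stepper <- if (integrator == "euler") step_forward_euler else
    step_rush_larsen
  unstable <- FALSE
  # (1) reaction sub-steps
  res <- tryCatch({
    for (s in seq_len(n_sub)) {
      ts <- t + (s - 1) * dt_ode
      stim <- stim_fun(ts)
      if (!is.null(state$M)) {
        state$M <- stepper(models$M, state$M, dt_ode, stim$M)
      }
      if (!is.null(state$P)) {
        state$P <- stepper(models$P, state$P, dt_ode, stim$P)
      }
    }
    state
  }, error = function(e) e)
  if (inherits(res, "error")) {
    return(list(state = state, pmj = NULL, reports = NULL, unstable = TRUE,
                message = conditionMessage(res)))
  }
  state <- res
  # (2) PMJ currents at the half step
  pmj <- NULL
  S_M <- 0
  S_P <- 0
  if (!is.null(systems$map) && !is.null(state$M) && !is.null(state$P)) {
    pmj <- compute_pmj_currents(state$P[, 1], state$M[, 1], systems$map,
                                systems$P$h)
    S_P <- numeric(systems$P$n)
    S_P[pmj$terminals] <- pmj$terminal_current
    S_M <- numeric(systems$M$n)
    for (k in seq_along(pmj$terminals)) {
      idx <- pmj$volumes[[k]]
      S_M[idx] <- S_M[idx] + pmj$currents[[k]]
    }
  }
  # (3) independent implicit diffusion solves
  reports <- list()
  if (!is.null(state$M)) {
    b <- systems$M$M_diag * state$M[, 1] + S_M
    sol <- .solve_domain(systems$M, b, solver, x0 = state$M[, 1])
    state$M[, 1] <- sol$x
    reports$M <- sol$report
  }
  if (!is.null(state$P)) {
    b <- systems$P$M_diag * state$P[, 1] + S_P
    sol <- .solve_domain(systems$P, b, solver, x0 = state$P[, 1])
    state$P[, 1] <- sol$x
    reports$P <- sol$report
  }
  vals <- c(if (!is.null(state$M)) state$M[, 1],
            if (!is.null(state$P)) state$P[, 1])
  if (!all(is.finite(vals)) || max(abs(vals)) > 500) unstable <- TRUE
  list(state = state, pmj = pmj, reports = reports, unstable = unstable)
}

#' Run a full simulation
#'
#' Materialises the configured geometry, assembles both diffusion systems and
#' the PMJ map, then advances the coupled state to `t_max`, recording V
#' snapshots at the output cadence, local activation times (first crossing of
#' the activation threshold, checked at every diffusion step), per-terminal
#' PMJ traces (terminal Purkinje V and its nearest coupled myocardial V at
#' every diffusion step), and pseudo-ECG traces when a lead set is
#' configured. The scheme contains no randomness: results are deterministic
#' given a configuration.
#'
#' @param config a `run_config` from [sim_config()] or [parse_config()].
#' @return a `simulation_result`: `times`, `V_M`, `V_P` (snapshot matrices),
#'   `lat_M`, `lat_P` (ms, `NA` = never activated), `pmj_times`,
#'   `pmj_terminal_V`, `pmj_myocardium_V`, `ecg`, `status` (`"ok"` or
#'   `"unstable"`), solver iteration summary, and the materialised geometry.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  grid <- materialise_grid(config$grid)
  network <- materialise_network(config$network)
  if (is.null(grid) && is.null(network)) {
    stop("configuration defines no domain")
  }
  systems <- list()
  models <- list()
  state <- list(M = NULL, P = NULL)
  if (!is.null(grid)) {
    systems$M <- assemble_myocardium(grid, config$beta, config$cm,
                                     config$dt_pde)
    models$M <- ionic_model(config$models$myocardium)
    state$M <- rest_state_block(models$M, systems$M$n)
  }
  if (!is.null(network)) {
    systems$P <- assemble_purkinje(network, config$beta, config$cm,
                                   config$dt_pde)
    models$P <- ionic_model(config$models$purkinje)
    state$P <- rest_state_block(models$P, systems$P$n)
  }
  map <- NULL
  if (!is.null(config$pmj) && !is.null(grid) && !is.null(network)) {
    map <- map_pmjs(network, grid, config$pmj$N_PMJ, config$pmj$R_PMJ)
    systems$map <- map
  }
  # stimulus masks
  stim_masks <- lapply(config$stimuli, function(st) {
    pts <- if (st$domain == "myocardium") {
      if (is.null(grid)) stop("myocardial stimulus but no grid")
      grid$centers
    } else {
      if (is.null(network)) stop("Purkinje stimulus but no network")
      network$nodes
    }
    inside <- pts[, 1] >= st$box[1] & pts[, 1] < st$box[4] &
      pts[, 2] >= st$box[2] & pts[, 2] < st$box[5] &
      pts[, 3] >= st$box[3] & pts[, 3] < st$box[6]
    list(domain = st$domain, mask = which(inside), start = st$start,
         stop = st$start + st$duration, amplitude = st$amplitude)
  })
  nM <- if (is.null(grid)) 0 else systems$M$n
  nP <- if (is.null(network)) 0 else systems$P$n
  stim_fun <- function(t) {
    IM <- 0
    IP <- 0
    for (sm in stim_masks) {
      if (t >= sm$start && t < sm$stop && length(sm$mask)) {
        if (sm$domain == "myocardium") {
          if (identical(IM, 0)) IM <- numeric(nM)
          IM[sm$mask] <- IM[sm$mask] + sm$amplitude
        } else {
          if (identical(IP, 0)) IP <- numeric(nP)
          IP[sm$mask] <- IP[sm$mask] + sm$amplitude
        }
      }
    }
    list(M = IM, P = IP)
  }
  n_steps <- round(config$t_max / config$dt_pde)
  out_every <- max(1L, as.integer(round(config$output$interval /
                                          config$dt_pde)))
  snap_steps <- unique(c(0L, seq(out_every, n_steps, by = out_every)))
  n_snap <- length(snap_steps)
  thr <- config$activation_threshold
  V_M <- if (nM) matrix(NA_real_, nM, n_snap) else NULL
  V_P <- if (nP) matrix(NA_real_, nP, n_snap) else NULL
  lat_M <- if (nM) rep(NA_real_, nM) else NULL
  lat_P <- if (nP) rep(NA_real_, nP) else NULL
  nt <- if (is.null(map)) 0 else length(map$terminals)
  pmj_terminal_V <- if (nt) matrix(NA_real_, n_steps + 1, nt) else NULL
  pmj_myo_V <- if (nt) matrix(NA_real_, n_steps + 1, nt) else NULL
  nearest <- if (nt) vapply(map$volumes, `[`, integer(1), 1) else integer(0)
  ecg <- if (!is.null(config$leads) && nM) {
    matrix(NA_real_, n_snap, nrow(config$leads$electrodes))
  } else {
    NULL
  }
  max_iter <- c(M = 0L, P = 0L)
  record <- function(col, step) {
    if (nM) V_M[, col] <<- state$M[, 1]
    if (nP) V_P[, col] <<- state$P[, 1]
    if (!is.null(ecg)) {
      ecg[col, ] <<- compute_pseudo_ecg(systems$M$K, state$M[, 1], grid,
                                        config$leads)
    }
  }
  track <- function(t) {
    if (nM) {
      hit <- is.na(lat_M) & state$M[, 1] >= thr
      if (any(hit)) lat_M[hit] <<- t
    }
    if (nP) {
      hit <- is.na(lat_P) & state$P[, 1] >= thr
      if (any(hit)) lat_P[hit] <<- t
    }
    if (nt) {
      row <- as.integer(round(t / config$dt_pde)) + 1L
      pmj_terminal_V[row, ] <<- state$P[map$terminals, 1]
      pmj_myo_V[row, ] <<- state$M[nearest, 1]
    }
  }
  track(0)
  record(1, 0L)
  status <- "ok"
  unstable_t <- NA_real_
  snap_col <- 1L
  for (step in seq_len(n_steps)) {
    t0 <- (step - 1) * config$dt_pde
    adv <- advance_step(state, systems, models, stim_fun, t0,
                        config$dt_ode, config$dt_pde,
                        integrator = config$integrator,
                        solver = config$solver)
    state <- adv$state
    if (!is.null(adv$reports$M)) {
      max_iter["M"] <- max(max_iter["M"], adv$reports$M$iterations)
    }
    if (!is.null(adv$reports$P)) {
      max_iter["P"] <- max(max_iter["P"], adv$reports$P$iterations)
    }
    if (adv$unstable) {
      status <- "unstable"
      unstable_t <- step * config$dt_pde
      break
    }
    t1 <- step * config$dt_pde
    track(t1)
    if (step %in% snap_steps) {
      snap_col <- snap_col + 1L
      record(snap_col, step)
    }
  }
  result <- structure(
    list(
      times = snap_steps * config$dt_pde,
      V_M = V_M, V_P = V_P, lat_M = lat_M, lat_P = lat_P,
      pmj_times = if (nt) (0:n_steps) * config$dt_pde else NULL,
      pmj_terminal_V = pmj_terminal_V, pmj_myocardium_V = pmj_myo_V,
      ecg = ecg, status = status, unstable_t = unstable_t,
      max_solver_iterations = max_iter,
      grid = grid, network = network, map = map, config = config
    ),
    class = "simulation_result"
  )
  if (!is.null(config$output$dir)) {
    write_result(result, config$output$dir, config$output$formats)
  }
  result
}

#' Write the configured output files of a result
#'
#' Writes the requested snapshot formats plus the activation map and, when
#' present, ECG and PMJ-delay CSV tables. Everything recorded up to an
#' instability abort is flushed.
#'
#' @param result a `simulation_result`.
#' @param dir output directory.
#' @param formats subset of `c("ensight", "vtk")`.
#' @export
write_result <- function(result, dir, formats = "ensight") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if ("ensight" %in% formats) write_ensight_gold(result, dir)
  if ("vtk" %in% formats) write_vtk_legacy(result, dir, mode = "binary")
  if (!is.null(result$lat_M)) {
    write_activation_map(result, file.path(dir, "activation_map.csv"))
  }
  if (!is.null(result$ecg)) {
    write_ecg_csv(result, file.path(dir, "ecg.csv"))
  }
  if (!is.null(result$map)) {
    write_delay_csv(measure_pmj_delays(result),
                    file.path(dir, "pmj_delays.csv"))
  }
  invisible(dir)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "simulation_result: %s, t = [0, %g] ms, %d myocardial / %d Purkinje volumes\n",
    x$status, max(x$times),
    if (is.null(x$V_M)) 0 else nrow(x$V_M),
    if (is.null(x$V_P)) 0 else nrow(x$V_P)
  ))
  invisible(x)
}

#' @export
print.monodomain_system <- function(x, ...) {
  cat(sprintf(
    "monodomain_system (%s): %d volumes, h = %g cm, dt = %g ms, asymmetry %.2e%s\n",
    x$domain, x$n, x$h, x$dt_pde, x$asymmetry,
    if (x$use_bicg) " (BiCG)" else ""
  ))
  invisible(x)
}
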