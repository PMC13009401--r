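# Ionic-model plugin layer.
#
# A model is a list (class `ionic_model`) with:
#   name            model identifier
#   n_states        state count; state 1 is always V (mV)
#   state_names     character vector
#   rest_state      resting fixed point (max |d/dt| < 1e-6 per ms)
#   gating_indices  state columns with Hodgkin-Huxley form
#                   dy/dt = (y_inf - y)/tau, eligible for Rush-Larsen
#   rates(states)   given an n x n_states matrix, returns
#                     I_ion      total ionic current, pA/pF (= mV/ms at
#                                C_m = 1 uF/cm^2)
#                     deriv      n x n_states matrix of d(state)/dt for all
#                                states except column 1 (V is advanced by the
#                                integrator from I_ion and I_stim)
#                     gate_inf, gate_tau   n x length(gating_indices)
#                                matrices (steady states and time constants)
#
# Currents use the per-capacitance convention throughout: pA/pF, so the
# membrane update is dV/dt = -I_ion + I_stim in mV/ms. The capacitance C_m
# enters the diffusion (PDE) side of the splitting separately.

.ionic_registry <- new.env(parent = emptyenv())

#' Define an ionic model specification
#'
#' Constructor for plugin ionic models conforming to the interface used by
#' the reaction steppers and the monodomain loop.
#'
#' @param name model identifier.
#' @param n_states number of state variables (state 1 is V, mV).
#' @param rest_state numeric vector of length `n_states`.
#' @param rates function mapping an `n x n_states` state matrix to
#'   `list(I_ion, deriv, gate_inf, gate_tau)`; see the package vignette.
#' @param gating_indices integer vector of Hodgkin-Huxley gate columns.
#' @param state_names optional character names.
#' @return an `ionic_model`.
#' @export
ionic_model_spec <- function(name, n_states, rest_state, rates,
                             gating_indices = integer(0),
                             state_names = NULL) {
  stopifnot(n_states >= 1, length(rest_state) == n_states,
            is.function(rates))
  gating_indices <- as.integer(gating_indices)
  if (any(gating_indices < 2 | gating_indices > n_states)) {
    stop("gating_indices must lie in 2..n_states (V is never a gate)")
  }
  if (is.null(state_names)) state_names <- paste0("s", seq_len(n_states))
  structure(
    list(
      name = name, n_states = as.integer(n_states),
      state_names = state_names, rest_state = as.numeric(rest_state),
      gating_indices = gating_indices, rates = rates
    ),
    class = "ionic_model"
  )
}

#' Register an ionic model under a name
#' @param model an `ionic_model`.
#' @export
register_ionic_model <- function(model) {
  stopifnot(inherits(model, "ionic_model"))
  assign(model$name, model, envir = .ionic_registry)
  invisible(model$name)
}

#' List registered ionic model names
#' @export
list_ionic_models <- function() sort(ls(.ionic_registry))

#' Retrieve a registered ionic model
#' @param name model identifier.
#' @return an `ionic_model`.
#' @export
ionic_model <- function(name) {
  if (!exists(name, envir = .ionic_registry, inherits = FALSE)) {
    stop(sprintf(
      "unknown ionic model '%s'; available models: %s",
      name, paste(list_ionic_models(), collapse = ", ")
    ))
  }
  get(name, envir = .ionic_registry, inherits = FALSE)
}

#' Initialise a cell-state block at rest
#' @param model an `ionic_model`.
#' @param n_volumes number of control volumes.
#' @return `n_volumes x n_states` matrix.
#' @export
rest_state_block <- function(model, n_volumes) {
  matrix(model$rest_state, nrow = n_volumes, ncol = model$n_states,
         byrow = TRUE, dimnames = list(NULL, model$state_names))
}

#' Forward-Euler reaction sub-step
#'
#' Advances the membrane and all state variables one explicit step:
#' `V <- V + dt * (-I_ion + I_stim)` and `eta <- eta + dt * f(V, eta)`.
#'
#' @param model an `ionic_model`.
#' @param states `n x n_states` matrix (column 1 is V, mV).
#' @param dt step in ms.
#' @param I_stim per-volume stimulus, pA/pF (scalar 0 allowed).
#' @return updated state matrix.
#' @export
step_forward_euler <- function(model, states, dt, I_stim = 0) {
  stopifnot(dt > 0)
  rt <- model$rates(states)
  dV <- -rt$I_ion + I_stim
  if (!all(is.finite(dV))) {
    stop(sprintf("non-finite membrane derivative at volume %d",
                 which(!is.finite(dV))[1]))
  }
  states[, 1] <- states[, 1] + dt * dV
  if (model$n_states > 1) {
    d <- rt$deriv[, -1, drop = FALSE]
    if (!all(is.finite(d))) {
      bad <- which(!is.finite(d), arr.ind = TRUE)[1, 1]
      stop(sprintf("non-finite state derivative at volume %d", bad))
    }
    states[, -1] <- states[, -1, drop = FALSE] + dt * d
  }
  states
}

#' Rush-Larsen reaction sub-step
#'
#' Hodgkin-Huxley gates are advanced exactly for frozen coefficients,
#' `y <- y_inf + (y - y_inf) * exp(-dt / tau)`, which is unconditionally
#' stable for the gating subsystem; V and all non-gate states take a forward
#' Euler step.
#'
#' @inheritParams step_forward_euler
#' @return updated state matrix.
#' @export
step_rush_larsen <- function(model, states, dt, I_stim = 0) {
  stopifnot(dt > 0)
  rt <- model$rates(states)
  dV <- -rt$I_ion + I_stim
  if (!all(is.finite(dV))) {
    stop(sprintf("non-finite membrane derivative at volume %d",
                 which(!is.finite(dV))[1]))
  }
  g <- model$gating_indices
  new <- states
  new[, 1] <- states[, 1] + dt * dV
  if (model$n_states > 1) {
    rest <- setdiff(seq_len(model$n_states)[-1], g)
    if (length(rest)) {
      new[, rest] <- states[, rest, drop = FALSE] +
        dt * rt$deriv[, rest, drop = FALSE]
    }
    if (length(g)) {
      tau <- rt$gate_tau
      if (any(tau <= 0)) stop("Rush-Larsen requires tau > 0 for every gate")
      yinf <- rt$gate_inf
      y <- states[, g, drop = FALSE]
      new[, g] <- yinf + (y - yinf) * exp(-dt / tau)
    }
  }
  new
}

# ---------------------------------------------------------------------------
# Built-in model: 2-variable phenomenological excitable model
#
# A cubic excitation-recovery model (Aliev-Panfilov form) mapped onto
# physiological units: V = V_rest + V_amp * u with u the dimensionless
# excitation variable and w the recovery variable. The resting state
# (V_rest, 0) is an exact fixed point. `tau` (ms) sets the upstroke speed and
# hence, with the tissue diffusivity, the conduction velocity.

#' Construct the phenomenological 2-variable model
#'
#' @param k,a cubic excitation parameters (dimensionless).
#' @param eps0,mu1,mu2 recovery-rate parameters (dimensionless).
#' @param tau time scaling, ms per dimensionless time unit; smaller values
#'   give a faster upstroke.
#' @param V_rest,V_amp resting potential and amplitude, mV.
#' @return an `ionic_model` with states (V, w).
#' @export
phenomenological_model <- function(k = 8, a = 0.1, eps0 = 0.01, mu1 = 0.14,
                                   mu2 = 0.3, tau = 2.5,
                                   V_rest = -85, V_amp = 100) {
  rates <- function(states) {
    u <- (states[, 1] - V_rest) / V_amp
    w <- states[, 2]
    du <- (k * u * (u - a) * (1 - u) - u * w) / tau
    eps <- eps0 + mu1 * w / (u + mu2)
    dw <- eps * (-w - k * u * (u - a - 1)) / tau
    list(
      I_ion = -V_amp * du,
      deriv = cbind(0, dw),
      gate_inf = NULL, gate_tau = NULL
    )
  }
  ionic_model_spec(
    name = "phenomenological", n_states = 2,
    rest_state = c(V_rest, 0), rates = rates,
    gating_indices = integer(0), state_names = c("V", "w")
  )
}

# ---------------------------------------------------------------------------
# Built-in model: ten Tusscher-Panfilov human ventricular model (epicardial
# variant) with the intracellular Na+ and K+ concentrations clamped at their
# quiescent values, giving 17 dynamic state variables. The clamp removes the
# well-known slow Na/K drift of the full model, whose sodium-potassium
# balance only equilibrates at non-physiological concentrations; with the
# clamp the resting state below is an exact fixed point of the dynamics
# (max |d/dt| < 1e-13 per ms, obtained by a Levenberg-Marquardt solve of the
# steady-state equations after a 5000 ms unstimulated Rush-Larsen settle).
# Twelve states are Hodgkin-Huxley gates and integrate exactly under
# Rush-Larsen.

ten_tusscher_rates <- function(states, Nai = 8.686676621, Ki = 137.0121853) {
  V <- states[, 1]
  Xr1 <- states[, 2]; Xr2 <- states[, 3]; Xs <- states[, 4]
  m <- states[, 5]; h <- states[, 6]; j <- states[, 7]
  d <- states[, 8]; f <- states[, 9]; f2 <- states[, 10]
  fCass <- states[, 11]; s <- states[, 12]; r <- states[, 13]
  Cai <- states[, 14]; CaSR <- states[, 15]; CaSS <- states[, 16]
  Rq <- states[, 17]

  Rgas <- 8314.472; Temp <- 310; Fa <- 96485.3415
  rtof <- Rgas * Temp / Fa
  Ko <- 5.4; Nao <- 140; Cao <- 2
  Cm <- 0.185; Vc <- 0.016404; Vsr <- 0.001094; Vss <- 0.00005468
  GNa <- 14.838; GK1 <- 5.405; GKr <- 0.153; Gto <- 0.294; GKs <- 0.392
  GCaL <- 0.0000398; GbNa <- 0.00029; GbCa <- 0.000592
  GpK <- 0.0146; GpCa <- 0.1238; KpCa <- 0.0005
  PNaK <- 2.724; KmK <- 1; KmNa <- 40
  knaca <- 1000; Ksat <- 0.1; alpha_naca <- 2.5; gamma_naca <- 0.35
  KmNai <- 87.5; KmCa <- 1.38; pKNa <- 0.03

  EK <- rtof * log(Ko / Ki)
  ENa <- rtof * log(Nao / Nai)
  EKs <- rtof * log((Ko + pKNa * Nao) / (Ki + pKNa * Nai))
  ECa <- 0.5 * rtof * log(Cao / Cai)

  # gate steady states / time constants
  minf <- 1 / (1 + exp((-56.86 - V) / 9.03))^2
  am <- 1 / (1 + exp((-60 - V) / 5))
  bm <- 0.1 / (1 + exp((V + 35) / 5)) + 0.1 / (1 + exp((V - 50) / 200))
  taum <- am * bm
  hinf <- 1 / (1 + exp((V + 71.55) / 7.43))^2
  lowV <- V < -40
  ah <- ifelse(lowV, 0.057 * exp(-(V + 80) / 6.8), 0)
  bh <- ifelse(lowV, 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V),
               0.77 / (0.13 * (1 + exp(-(V + 10.66) / 11.1))))
  tauh <- 1 / (ah + bh)
  jinf <- hinf
  aj <- ifelse(lowV,
               (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
                 (V + 37.78) / (1 + exp(0.311 * (V + 79.23))),
               0)
  bj <- ifelse(lowV,
               0.02424 * exp(-0.01052 * V) /
                 (1 + exp(-0.1378 * (V + 40.14))),
               0.6 * exp(0.057 * V) / (1 + exp(-0.1 * (V + 32))))
  tauj <- 1 / (aj + bj)
  xr1inf <- 1 / (1 + exp((-26 - V) / 7))
  taur1 <- 450 / (1 + exp((-45 - V) / 10)) * 6 / (1 + exp((V + 30) / 11.5))
  xr2inf <- 1 / (1 + exp((V + 88) / 24))
  taur2 <- 3 / (1 + exp((-60 - V) / 20)) * 1.12 / (1 + exp((V - 60) / 20))
  xsinf <- 1 / (1 + exp((-5 - V) / 14))
  taus_ <- 1400 / sqrt(1 + exp((5 - V) / 6)) / (1 + exp((V - 35) / 15)) + 80
  dinf <- 1 / (1 + exp((-8 - V) / 7.5))
  taud <- (1.4 / (1 + exp((-35 - V) / 13)) + 0.25) *
    (1.4 / (1 + exp((V + 5) / 5))) + 1 / (1 + exp((50 - V) / 20))
  finf <- 1 / (1 + exp((V + 20) / 7))
  tauf <- 1102.5 * exp(-((V + 27)^2) / 225) + 200 / (1 + exp((13 - V) / 10)) +
    180 / (1 + exp((V + 30) / 10)) + 20
  f2inf <- 0.67 / (1 + exp((V + 35) / 7)) + 0.33
  tauf2 <- 562 * exp(-((V + 27)^2) / 240) + 31 / (1 + exp((25 - V) / 10)) +
    80 / (1 + exp((V + 30) / 10))
  fcassinf <- 0.6 / (1 + (CaSS / 0.05)^2) + 0.4
  taufcass <- 80 / (1 + (CaSS / 0.05)^2) + 2
  sinf <- 1 / (1 + exp((V + 20) / 5)) # epicardial
  taus2 <- 85 * exp(-((V + 45)^2) / 320) + 5 / (1 + exp((V - 20) / 5)) + 3
  rinf <- 1 / (1 + exp((20 - V) / 6))
  taur <- 9.5 * exp(-((V + 40)^2) / 1800) + 0.8

  # membrane currents (pA/pF)
  INa <- GNa * m^3 * h * j * (V - ENa)
  vf <- (V - 15) * Fa / (Rgas * Temp)
  expvf <- exp(2 * vf)
  ICaL <- GCaL * d * f * f2 * fCass * 4 * (V - 15) * Fa / rtof *
    (0.25 * CaSS * expvf - Cao) / (expvf - 1)
  Ito <- Gto * r * s * (V - EK)
  IKr <- GKr * sqrt(Ko / 5.4) * Xr1 * Xr2 * (V - EK)
  IKs <- GKs * Xs^2 * (V - EKs)
  aK1 <- 0.1 / (1 + exp(0.06 * (V - EK - 200)))
  bK1 <- (3 * exp(0.0002 * (V - EK + 100)) + exp(0.1 * (V - EK - 10))) /
    (1 + exp(-0.5 * (V - EK)))
  IK1 <- GK1 * sqrt(Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK)
  INaK <- PNaK * Ko * Nai /
    ((Ko + KmK) * (Nai + KmNa) *
       (1 + 0.1245 * exp(-0.1 * V / rtof) + 0.0353 * exp(-V / rtof)))
  INaCa <- knaca *
    (exp(gamma_naca * V / rtof) * Nai^3 * Cao -
       exp((gamma_naca - 1) * V / rtof) * Nao^3 * Cai * alpha_naca) /
    ((KmNai^3 + Nao^3) * (KmCa + Cao) *
       (1 + Ksat * exp((gamma_naca - 1) * V / rtof)))
  IpCa <- GpCa * Cai / (Cai + KpCa)
  IpK <- GpK * (V - EK) / (1 + exp((25 - V) / 5.98))
  IbNa <- GbNa * (V - ENa)
  IbCa <- GbCa * (V - ECa)
  I_ion <- INa + IK1 + Ito + IKr + IKs + ICaL + INaCa + INaK + IpCa + IpK +
    IbCa + IbNa

  # calcium handling
  Vmaxup <- 0.006375; Kup <- 0.00025
  Vrel <- 0.102; k1p <- 0.15; k2p <- 0.045; k3 <- 0.060; k4 <- 0.005
  EC <- 1.5; maxsr <- 2.5; minsr <- 1; Vleak <- 0.00036; Vxfer <- 0.0038
  Bufc <- 0.2; Kbufc <- 0.001; Bufsr <- 10; Kbufsr <- 0.3
  Bufss <- 0.4; Kbufss <- 0.00025
  Ileak <- Vleak * (CaSR - Cai)
  Iup <- Vmaxup / (1 + Kup^2 / Cai^2)
  Ixfer <- Vxfer * (CaSS - Cai)
  kcasr <- maxsr - (maxsr - minsr) / (1 + (EC / CaSR)^2)
  k1 <- k1p / kcasr
  k2 <- k2p * kcasr
  dRq <- -k2 * CaSS * Rq + k4 * (1 - Rq)
  O <- k1 * CaSS^2 * Rq / (k3 + k1 * CaSS^2)
  Irel <- Vrel * O * (CaSR - CaSS)
  bufc <- 1 / (1 + Bufc * Kbufc / (Cai + Kbufc)^2)
  dCai <- bufc * ((Ileak - Iup) * Vsr / Vc + Ixfer -
                    (IbCa + IpCa - 2 * INaCa) * Cm / (2 * Vc * Fa))
  bufsr <- 1 / (1 + Bufsr * Kbufsr / (CaSR + Kbufsr)^2)
  dCaSR <- bufsr * (Iup - Irel - Ileak)
  bufss <- 1 / (1 + Bufss * Kbufss / (CaSS + Kbufss)^2)
  dCaSS <- bufss * (-ICaL * Cm / (2 * Vss * Fa) + Irel * Vsr / Vss -
                      Ixfer * Vc / Vss)

  gate_inf <- cbind(xr1inf, xr2inf, xsinf, minf, hinf, jinf, dinf, finf,
                    f2inf, fcassinf, sinf, rinf)
  gate_tau <- cbind(taur1, taur2, taus_, taum, tauh, tauj, taud, tauf,
                    tauf2, taufcass, taus2, taur)
  deriv <- cbind(
    0,
    (xr1inf - Xr1) / taur1, (xr2inf - Xr2) / taur2, (xsinf - Xs) / taus_,
    (minf - m) / taum, (hinf - h) / tauh, (jinf - j) / tauj,
    (dinf - d) / taud, (finf - f) / tauf, (f2inf - f2) / tauf2,
    (fcassinf - fCass) / taufcass, (sinf - s) / taus2, (rinf - r) / taur,
    dCai, dCaSR, dCaSS, dRq
  )
  list(I_ion = I_ion, deriv = deriv, gate_inf = gate_inf,
       gate_tau = gate_tau)
}

.tt_state_names <- c(
  "V", "Xr1", "Xr2", "Xs", "m", "h", "j", "d", "f", "f2", "fCass", "s", "r",
  "Cai", "CaSR", "CaSS", "Rq"
)
.tt_gating <- 2:13
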