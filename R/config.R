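# Run configuration: programmatic constructor and validation.
#
# Fixed unit conventions: cm, ms, mV, mS/cm, kOhm, pA/pF.

#' Define a stimulus block
#'
#' A box-shaped current stimulus. In the myocardium the box selects volume
#' centers; in the Purkinje domain it selects network node coordinates (e.g.
#' a small box around the His-bundle root).
#'
#' @param box `c(xlo, ylo, zlo, xhi, yhi, zhi)` in cm, half-open.
#' @param start onset, ms.
#' @param duration duration, ms.
#' @param amplitude stimulus current, pA/pF.
#' @param domain `"myocardium"` or `"purkinje"`.
#' @return a `stimulus` list.
#' @export
stimulus <- function(box, start, duration, amplitude,
                     domain = c("myocardium", "purkinje")) {
  domain <- match.arg(domain)
  stopifnot(length(box) == 6, duration > 0)
  structure(
    list(box = as.numeric(box), start = start, duration = duration,
         amplitude = amplitude, domain = domain),
    class = "stimulus"
  )
}

#' Build a simulation configuration
#'
#' Collects geometry, membrane, discretisation, coupling, stimulus, solver
#' and output settings into a validated `run_config`. Geometry may be given
#' as constructed objects ([build_cuboid_grid()], [build_purkinje_tree()],
#' [read_grid()], [read_network()]) or as declarative spec lists (as produced
#' by [parse_config()]), which [run_simulation()] materialises.
#'
#' @param grid a `cartesian_grid`, a spec list, or `NULL` (Purkinje-only run).
#' @param network a `purkinje_network`, a spec list, or `NULL`.
#' @param pmj `list(R_PMJ = kOhm, N_PMJ = count)` or `NULL` for no coupling.
#' @param beta surface-to-volume ratio, 1/cm (both domains).
#' @param cm membrane capacitance, uF/cm^2 (both domains).
#' @param dt_ode reaction step, ms.
#' @param dt_pde diffusion step, ms; must be an integer multiple of `dt_ode`.
#' @param t_max total simulated time, ms.
#' @param models `list(myocardium = name, purkinje = name)` of registered
#'   ionic models.
#' @param integrator `"rush_larsen"` or `"euler"` (reaction sub-steps).
#' @param stimuli list of [stimulus()] blocks.
#' @param solver `list(method, tol, maxit, preconditioner)`.
#' @param output `list(interval = ms, dir = path or NULL, formats = chr)`.
#' @param leads a `lead_set` from [lead_set()] or `NULL` (no pseudo-ECG).
#' @param activation_threshold mV; local activation time is the first
#'   diffusion step at which V crosses this value.
#' @return a `run_config`.
#' @export
sim_config <- function(grid = NULL, network = NULL, pmj = NULL,
                       beta = 1400, cm = 1,
                       dt_ode = 0.01, dt_pde = 0.02, t_max = 50,
                       models = list(myocardium = "phenomenological",
                                     purkinje = "phenomenological"),
                       integrator = c("rush_larsen", "euler"),
                       stimuli = list(),
                       solver = list(method = "cg", tol = 1e-10,
                                     maxit = 5000,
                                     preconditioner = "jacobi"),
                       output = list(interval = 1, dir = NULL,
                                     formats = character()),
                       leads = NULL,
                       activation_threshold = -40) {
  integrator <- match.arg(integrator)
  if (t_max <= 0) stop("t_max must be positive")
  if (dt_ode <= 0 || dt_pde <= 0) stop("time steps must be positive")
  ratio <- dt_pde / dt_ode
  if (abs(ratio - round(ratio)) > 1e-9 || round(ratio) < 1) {
    stop(sprintf(
      "dt_pde (%g) must be an integer multiple of dt_ode (%g)",
      dt_pde, dt_ode
    ))
  }
  if (!is.null(pmj)) {
    if (is.null(pmj$R_PMJ) || pmj$R_PMJ <= 0) {
      stop("pmj$R_PMJ must be positive (kOhm)")
    }
    if (is.null(pmj$N_PMJ) || pmj$N_PMJ < 1) stop("pmj$N_PMJ must be >= 1")
  }
  for (st in stimuli) {
    stopifnot(inherits(st, "stimulus"))
    if (st$start + st$duration > t_max || st$start < 0) {
      warning(sprintf(
        "stimulus window [%g, %g] ms extends outside the simulated window [0, %g] ms",
        st$start, st$start + st$duration, t_max
      ))
    }
  }
  solver <- utils::modifyList(
    list(method = "cg", tol = 1e-10, maxit = 5000, preconditioner = "jacobi"),
    solver
  )
  output <- utils::modifyList(
    list(interval = 1, dir = NULL, formats = character()), output
  )
  structure(
    list(
      grid = grid, network = network, pmj = pmj, beta = beta, cm = cm,
      dt_ode = dt_ode, dt_pde = dt_pde, t_max = t_max, models = models,
      integrator = integrator, stimuli = stimuli, solver = solver,
      output = output, leads = leads,
      activation_threshold = activation_threshold
    ),
    class = "run_config"
  )
}

# Materialise geometry spec lists into objects (identity for objects).
materialise_grid <- function(g) {
  if (is.null(g) || inherits(g, "cartesian_grid")) return(g)
  stopifnot(is.list(g), !is.null(g$type))
  switch(g$type,
    cuboid = {
      grid <- build_cuboid_grid(g$extent, g$h, g$sigma,
                                fiber_axis = g$fiber_axis %||% c(1, 0, 0))
      if (!is.null(g$regions)) {
        for (rg in g$regions) {
          grid <- tag_region(grid, rg$box, rg$tag, rg$sigma)
        }
      }
      grid
    },
    file = read_grid(g$file),
    stop(sprintf("unknown grid spec type '%s'", g$type))
  )
}

materialise_network <- function(p) {
  if (is.null(p) || inherits(p, "purkinje_network")) return(p)
  stopifnot(is.list(p), !is.null(p$type))
  switch(p$type,
    tree = build_purkinje_tree(
      p$depth, p$branch_length, p$h, p$sigma,
      origin = p$origin %||% c(0, 0, 0),
      direction = p$direction %||% c(1, 0, 0)
    ),
    file = read_network(p$file),
    stop(sprintf("unknown purkinje spec type '%s'", p$type))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
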