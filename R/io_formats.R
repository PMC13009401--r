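# Configuration parsing (INI dialect), result writers (EnSight Gold, legacy
# VTK, CSV) and compact readers used for verification.
#
# Units in configuration files are fixed: cm, ms, mV, mS/cm, kOhm, pA/pF.

# ---------------------------------------------------------------------------
# INI configuration

.ini_allowed <- list(
  main = c("t_max", "beta", "cm", "output_interval", "output_dir",
           "formats", "activation_threshold"),
  grid = c("source", "extent", "h", "sigma", "fiber_axis", "file"),
  purkinje = c("source", "depth", "branch_length", "h", "sigma", "origin",
               "direction", "file"),
  pmj = c("r_pmj", "n_pmj"),
  ode = c("dt_ode", "dt_pde", "myocardium_model", "purkinje_model",
          "integrator"),
  linear_solver = c("method", "tol", "maxit", "preconditioner"),
  stim = c("domain", "box", "start", "duration", "amplitude"),
  ecg = c("sigma_b")
)

.parse_num_vec <- function(x, key, n = NULL) {
  v <- suppressWarnings(as.numeric(strsplit(trimws(x), "\\s+")[[1]]))
  if (anyNA(v)) stop(sprintf("key '%s': unparseable numeric value '%s'",
                             key, x))
  if (!is.null(n) && length(v) != n) {
    stop(sprintf("key '%s': expected %d values, got %d", key, n, length(v)))
  }
  v
}

#' Parse an INI simulation configuration
#'
#' Sections: `[main]`, `[grid]`, `[purkinje]`, `[pmj]`, `[ode]`,
#' `[linear_solver]`, `[stim_*]` (one per stimulus), `[ecg]`. Unknown
#' sections or keys are errors, not warnings; `[main]` and `[ode]` are
#' mandatory, as is at least one domain section. In `[grid]`, optional
#' `region_<tag>` keys (`x0 y0 z0 x1 y1 z1 sigma_f sigma_t sigma_n`) retag
#' box regions; in `[ecg]`, `electrode_<label>` keys give positions.
#'
#' @param path configuration file.
#' @return a `run_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  lines <- readLines(path)
  section <- NULL
  kv <- list()
  order <- character(0)
  for (ln in seq_along(lines)) {
    raw <- sub("[#;].*$", "", lines[ln])
    s <- trimws(raw)
    if (!nzchar(s)) next
    if (grepl("^\\[.*\\]$", s)) {
      section <- sub("^\\[(.*)\\]$", "\\1", s)
      if (section %in% names(kv)) {
        stop(sprintf("line %d: duplicate section [%s]", ln, section))
      }
      kv[[section]] <- list()
      order <- c(order, section)
    } else if (grepl("=", s, fixed = TRUE)) {
      if (is.null(section)) stop(sprintf("line %d: key outside a section", ln))
      key <- trimws(sub("=.*$", "", s))
      val <- trimws(sub("^[^=]*=", "", s))
      kv[[section]][[key]] <- val
    } else {
      stop(sprintf("line %d: expected 'key = value' or '[section]'", ln))
    }
  }
  known <- function(sec) {
    base <- sub("^stim_.*$", "stim", sec)
    if (!base %in% names(.ini_allowed)) {
      stop(sprintf("unknown section [%s]", sec))
    }
    allowed <- .ini_allowed[[base]]
    for (key in names(kv[[sec]])) {
      extra_ok <- (base == "grid" && grepl("^region_", key)) ||
        (base == "ecg" && grepl("^electrode_", key))
      if (!key %in% allowed && !extra_ok) {
        stop(sprintf("unknown key '%s' in section [%s]", key, sec))
      }
    }
  }
  for (sec in names(kv)) known(sec)
  for (sec in c("main", "ode")) {
    if (!sec %in% names(kv)) {
      stop(sprintf("missing mandatory section [%s]", sec))
    }
  }
  if (!any(c("grid", "purkinje") %in% names(kv))) {
    stop("missing mandatory domain section: need [grid] and/or [purkinje]")
  }
  g <- function(sec, key, default = NULL) {
    v <- kv[[sec]][[key]]
    if (is.null(v)) default else v
  }
  num <- function(sec, key, default = NULL) {
    v <- g(sec, key)
    if (is.null(v)) return(default)
    out <- suppressWarnings(as.numeric(v))
    if (is.na(out)) stop(sprintf("key '%s' in [%s]: not a number", key, sec))
    out
  }
  grid_spec <- NULL
  if ("grid" %in% names(kv)) {
    src <- g("grid", "source", "cuboid")
    grid_spec <- if (src == "file") {
      list(type = "file", file = g("grid", "file"))
    } else {
      regions <- list()
      for (key in names(kv$grid)) {
        if (grepl("^region_", key)) {
          v <- .parse_num_vec(kv$grid[[key]], key, 9)
          regions[[length(regions) + 1]] <- list(
            tag = sub("^region_", "", key), box = v[1:6], sigma = v[7:9]
          )
        }
      }
      sp <- list(
        type = "cuboid",
        extent = .parse_num_vec(g("grid", "extent"), "extent", 3),
        h = num("grid", "h"),
        sigma = .parse_num_vec(g("grid", "sigma"), "sigma", 3),
        fiber_axis = .parse_num_vec(g("grid", "fiber_axis", "1 0 0"),
                                    "fiber_axis", 3)
      )
      if (length(regions)) sp$regions <- regions
      sp
    }
  }
  purk_spec <- NULL
  if ("purkinje" %in% names(kv)) {
    src <- g("purkinje", "source", "tree")
    purk_spec <- if (src == "file") {
      list(type = "file", file = g("purkinje", "file"))
    } else {
      list(
        type = "tree",
        depth = as.integer(num("purkinje", "depth", 0)),
        branch_length = num("purkinje", "branch_length"),
        h = num("purkinje", "h"),
        sigma = num("purkinje", "sigma"),
        origin = .parse_num_vec(g("purkinje", "origin", "0 0 0"),
                                "origin", 3),
        direction = .parse_num_vec(g("purkinje", "direction", "1 0 0"),
                                   "direction", 3)
      )
    }
  }
  pmj <- NULL
  if ("pmj" %in% names(kv)) {
    pmj <- list(R_PMJ = num("pmj", "r_pmj"),
                N_PMJ = as.integer(num("pmj", "n_pmj")))
    if (is.na(pmj$R_PMJ) || pmj$R_PMJ <= 0) {
      stop("r_pmj must be a positive resistance in kOhm")
    }
  }
  stimuli <- list()
  for (sec in order[grepl("^stim_", order)]) {
    stimuli[[length(stimuli) + 1]] <- stimulus(
      box = .parse_num_vec(g(sec, "box"), "box", 6),
      start = num(sec, "start", 0),
      duration = num(sec, "duration"),
      amplitude = num(sec, "amplitude"),
      domain = g(sec, "domain", "myocardium")
    )
    names(stimuli)[length(stimuli)] <- sub("^stim_", "", sec)
  }
  leads <- NULL
  if ("ecg" %in% names(kv)) {
    labels <- character(0)
    pos <- NULL
    for (key in names(kv$ecg)) {
      if (grepl("^electrode_", key)) {
        labels <- c(labels, sub("^electrode_", "", key))
        pos <- rbind(pos, .parse_num_vec(kv$ecg[[key]], key, 3))
      }
    }
    if (length(labels)) {
      leads <- lead_set(labels, pos, sigma_b = num("ecg", "sigma_b", 1))
    }
  }
  fmts <- g("main", "formats", "")
  fmts <- if (nzchar(fmts)) strsplit(fmts, "\\s+")[[1]] else character(0)
  sim_config(
    grid = grid_spec, network = purk_spec, pmj = pmj,
    beta = num("main", "beta", 1400), cm = num("main", "cm", 1),
    dt_ode = num("ode", "dt_ode"), dt_pde = num("ode", "dt_pde"),
    t_max = num("main", "t_max"),
    models = list(
      myocardium = g("ode", "myocardium_model", "phenomenological"),
      purkinje = g("ode", "purkinje_model", "phenomenological")
    ),
    integrator = g("ode", "integrator", "rush_larsen"),
    stimuli = stimuli,
    solver = list(
      method = g("linear_solver", "method", "cg"),
      tol = num("linear_solver", "tol", 1e-10),
      maxit = as.integer(num("linear_solver", "maxit", 5000)),
      preconditioner = g("linear_solver", "preconditioner", "jacobi")
    ),
    output = list(
      interval = num("main", "output_interval", 1),
      dir = g("main", "output_dir"), formats = fmts
    ),
    leads = leads,
    activation_threshold = num("main", "activation_threshold", -40)
  )
}

#' Write a configuration to the INI format
#'
#' Inverse of [parse_config()] for configurations whose geometry is given as
#' declarative specs (grids or networks already materialised as objects must
#' be saved with [write_grid()]/[write_network()] and referenced with
#' `source = file`).
#'
#' @param config a `run_config`.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(config$grid, "cartesian_grid") ||
        inherits(config$network, "purkinje_network")) {
    stop(paste(
      "config holds materialised geometry objects; save them with",
      "write_grid()/write_network() and reference them via source = file"
    ))
  }
  vfmt <- function(v) paste(.fmt(v), collapse = " ")
  out <- c(
    "[main]",
    paste("t_max =", .fmt(config$t_max)),
    paste("beta =", .fmt(config$beta)),
    paste("cm =", .fmt(config$cm)),
    paste("output_interval =", .fmt(config$output$interval)),
    if (!is.null(config$output$dir)) paste("output_dir =", config$output$dir),
    if (length(config$output$formats)) {
      paste("formats =", paste(config$output$formats, collapse = " "))
    },
    paste("activation_threshold =", .fmt(config$activation_threshold))
  )
  if (!is.null(config$grid)) {
    gsp <- config$grid
    out <- c(out, "", "[grid]")
    if (gsp$type == "file") {
      out <- c(out, "source = file", paste("file =", gsp$file))
    } else {
      out <- c(out, "source = cuboid",
               paste("extent =", vfmt(gsp$extent)),
               paste("h =", .fmt(gsp$h)),
               paste("sigma =", vfmt(gsp$sigma)),
               paste("fiber_axis =", vfmt(gsp$fiber_axis %||% c(1, 0, 0))))
      for (rg in gsp$regions %||% list()) {
        out <- c(out, sprintf("region_%s = %s", rg$tag,
                              vfmt(c(rg$box, rg$sigma))))
      }
    }
  }
  if (!is.null(config$network)) {
    psp <- config$network
    out <- c(out, "", "[purkinje]")
    if (psp$type == "file") {
      out <- c(out, "source = file", paste("file =", psp$file))
    } else {
      out <- c(out, "source = tree",
               paste("depth =", psp$depth),
               paste("branch_length =", .fmt(psp$branch_length)),
               paste("h =", .fmt(psp$h)),
               paste("sigma =", .fmt(psp$sigma)),
               paste("origin =", vfmt(psp$origin %||% c(0, 0, 0))),
               paste("direction =", vfmt(psp$direction %||% c(1, 0, 0))))
    }
  }
  if (!is.null(config$pmj)) {
    out <- c(out, "", "[pmj]",
             paste("r_pmj =", .fmt(config$pmj$R_PMJ)),
             paste("n_pmj =", config$pmj$N_PMJ))
  }
  out <- c(out, "", "[ode]",
           paste("dt_ode =", .fmt(config$dt_ode)),
           paste("dt_pde =", .fmt(config$dt_pde)),
           paste("myocardium_model =", config$models$myocardium),
           paste("purkinje_model =", config$models$purkinje),
           paste("integrator =", config$integrator))
  out <- c(out, "", "[linear_solver]",
           paste("method =", config$solver$method),
           paste("tol =", .fmt(config$solver$tol)),
           paste("maxit =", config$solver$maxit),
           paste("preconditioner =", config$solver$preconditioner))
  nm <- names(config$stimuli)
  for (si in seq_along(config$stimuli)) {
    st <- config$stimuli[[si]]
    label <- if (!is.null(nm) && nzchar(nm[si])) nm[si] else as.character(si)
    out <- c(out, "", sprintf("[stim_%s]", label),
             paste("domain =", st$domain),
             paste("box =", vfmt(st$box)),
             paste("start =", .fmt(st$start)),
             paste("duration =", .fmt(st$duration)),
             paste("amplitude =", .fmt(st$amplitude)))
  }
  if (!is.null(config$leads)) {
    out <- c(out, "", "[ecg]",
             paste("sigma_b =", .fmt(config$leads$sigma_b)))
    e <- config$leads$electrodes
    for (r in seq_len(nrow(e))) {
      out <- c(out, sprintf("electrode_%s = %s", e$label[r],
                            vfmt(c(e$x[r], e$y[r], e$z[r]))))
    }
  }
  writeLines(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Hexahedral cell geometry shared by the EnSight and VTK writers

# corner offsets in standard hexa8 order
.hex_corners <- matrix(c(
  0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0,
  0, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1
), ncol = 3, byrow = TRUE)

# unique corner nodes + 8-column connectivity for cube cells centred at
# `centers` with edge length `h`
.hex_mesh <- function(centers, h) {
  n <- nrow(centers)
  corners <- matrix(0, n * 8, 3)
  for (c8 in 1:8) {
    corners[seq_len(n) + (c8 - 1) * n, ] <-
      centers + h * matrix(.hex_corners[c8, ] - 0.5, n, 3, byrow = TRUE)
  }
  key <- paste(round(corners[, 1] / h * 2), round(corners[, 2] / h * 2),
               round(corners[, 3] / h * 2))
  uniq <- !duplicated(key)
  nodes <- corners[uniq, , drop = FALSE]
  id <- match(key, key[uniq])
  conn <- matrix(id, n, 8) # column c8 = corner c8 of each cell
  list(nodes = nodes, conn = conn)
}

.result_parts <- function(result) {
  parts <- list()
  if (!is.null(result$V_M)) {
    parts$myocardium <- list(
      mesh = .hex_mesh(result$grid$centers, result$grid$h),
      V = result$V_M
    )
  }
  if (!is.null(result$V_P)) {
    parts$purkinje <- list(
      mesh = .hex_mesh(result$network$nodes, result$network$h),
      V = result$V_P
    )
  }
  if (!length(parts)) stop("result contains no snapshots")
  parts
}

# ---------------------------------------------------------------------------
# EnSight Gold (binary)

.ens_str <- function(con, s) {
  r <- charToRaw(s)
  writeBin(c(r[seq_len(min(80, length(r)))],
             raw(max(0, 80 - length(r)))), con)
}

#' Write a simulation result in EnSight Gold binary format
#'
#' One `.case` index, one binary geometry file (an unstructured hexa8 part
#' per domain), and one binary per-element scalar file per snapshot, with
#' 80-character record headers and 32-bit reals as the Gold binary layout
#' requires. Loadable by standard visualisation tools.
#'
#' @param result a `simulation_result` with at least one snapshot.
#' @param dir output directory (created if needed).
#' @param name base name for the case.
#' @return the case file path, invisibly.
#' @export
write_ensight_gold <- function(result, dir, name = "simulation") {
  parts <- .result_parts(result)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop(sprintf("cannot create output directory '%s'", dir))
  }
  geof <- file.path(dir, paste0(name, ".geo"))
  con <- file(geof, "wb")
  .ens_str(con, "C Binary")
  .ens_str(con, "cardiofvm EnSight Gold geometry")
  .ens_str(con, "hexahedral control volumes")
  .ens_str(con, "node id off")
  .ens_str(con, "element id off")
  for (p in seq_along(parts)) {
    mesh <- parts[[p]]$mesh
    .ens_str(con, "part")
    writeBin(as.integer(p), con, size = 4, endian = "little")
    .ens_str(con, names(parts)[p])
    .ens_str(con, "coordinates")
    writeBin(as.integer(nrow(mesh$nodes)), con, size = 4, endian = "little")
    for (a in 1:3) {
      writeBin(as.numeric(mesh$nodes[, a]), con, size = 4,
               endian = "little")
    }
    .ens_str(con, "hexa8")
    writeBin(as.integer(nrow(mesh$conn)), con, size = 4, endian = "little")
    writeBin(as.integer(t(mesh$conn)), con, size = 4, endian = "little")
  }
  close(con)
  n_snap <- length(result$times)
  for (s in seq_len(n_snap)) {
    vf <- file.path(dir, sprintf("%s.Vm.%04d.scl", name, s - 1))
    con <- file(vf, "wb")
    .ens_str(con, sprintf("transmembrane potential, t = %g ms",
                          result$times[s]))
    for (p in seq_along(parts)) {
      .ens_str(con, "part")
      writeBin(as.integer(p), con, size = 4, endian = "little")
      .ens_str(con, "hexa8")
      writeBin(as.numeric(parts[[p]]$V[, s]), con, size = 4,
               endian = "little")
    }
    close(con)
  }
  casef <- file.path(dir, paste0(name, ".case"))
  writeLines(c(
    "FORMAT",
    "type: ensight gold",
    "",
    "GEOMETRY",
    sprintf("model: %s.geo", name),
    "",
    "VARIABLE",
    sprintf("scalar per element: 1 Vm %s.Vm.****.scl", name),
    "",
    "TIME",
    "time set: 1",
    sprintf("number of steps: %d", n_snap),
    "filename start number: 0",
    "filename increment: 1",
    paste("time values:", paste(result$times, collapse = " "))
  ), casef)
  invisible(casef)
}

#' Read one part's scalars back from an EnSight Gold scalar file
#'
#' Minimal reader used for verification: walks the 80-byte record headers of
#' a per-element scalar file and returns the float32 values of each part.
#'
#' @param path scalar file.
#' @param n_elements integer vector of element counts per part.
#' @return list of numeric vectors, one per part.
#' @export
read_ensight_scalar <- function(path, n_elements) {
  con <- file(path, "rb")
  on.exit(close(con))
  rstr <- function() {
    trimws(rawToChar(readBin(con, "raw", 80)[1:79]))
  }
  desc <- rstr()
  out <- vector("list", length(n_elements))
  for (p in seq_along(n_elements)) {
    if (rstr() != "part") stop("malformed scalar file: expected 'part'")
    pid <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (rstr() != "hexa8") stop("malformed scalar file: expected 'hexa8'")
    out[[p]] <- readBin(con, "numeric", n_elements[p], size = 4,
                        endian = "little")
  }
  out
}

# ---------------------------------------------------------------------------
# Legacy VTK (unstructured grid, hexahedral cells, V as cell data)

#' Write a simulation result as legacy VTK files
#'
#' One unstructured-grid file per snapshot containing the hexahedral cells of
#' every domain with the transmembrane potential as cell data. ASCII and
#' binary (big-endian, as the legacy format requires) modes agree to float32
#' precision.
#'
#' @param result a `simulation_result`.
#' @param dir output directory.
#' @param mode `"ascii"` or `"binary"`.
#' @param name base file name.
#' @return character vector of file paths, invisibly.
#' @export
write_vtk_legacy <- function(result, dir, mode = c("ascii", "binary"),
                             name = "simulation") {
  mode <- match.arg(mode)
  parts <- .result_parts(result)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop(sprintf("cannot create output directory '%s'", dir))
  }
  # merge parts into one grid (node offsets)
  nodes <- do.call(rbind, lapply(parts, function(p) p$mesh$nodes))
  offs <- cumsum(c(0, vapply(parts, function(p) nrow(p$mesh$nodes),
                             numeric(1))))
  conn <- do.call(rbind, lapply(seq_along(parts), function(p) {
    parts[[p]]$mesh$conn + offs[p]
  }))
  nn <- nrow(nodes)
  ne <- nrow(conn)
  paths <- character(length(result$times))
  for (s in seq_along(result$times)) {
    vals <- unlist(lapply(parts, function(p) p$V[, s]), use.names = FALSE)
    path <- file.path(dir, sprintf("%s_%04d.vtk", name, s - 1))
    paths[s] <- path
    if (mode == "ascii") {
      con <- file(path, "w")
      writeLines(c(
        "# vtk DataFile Version 3.0",
        sprintf("cardiofvm snapshot t = %g ms", result$times[s]),
        "ASCII",
        "DATASET UNSTRUCTURED_GRID",
        sprintf("POINTS %d float", nn),
        apply(nodes, 1, function(r) paste(sprintf("%.9g", r), collapse = " ")),
        sprintf("CELLS %d %d", ne, 9 * ne),
        apply(conn, 1, function(r) paste(c(8, r - 1), collapse = " ")),
        sprintf("CELL_TYPES %d", ne),
        rep("12", ne),
        sprintf("CELL_DATA %d", ne),
        "SCALARS Vm float 1",
        "LOOKUP_TABLE default",
        sprintf("%.9g", vals)
      ), con)
      close(con)
    } else {
      con <- file(path, "wb")
      wl <- function(x) writeChar(paste0(x, "\n"), con, eos = NULL)
      wl("# vtk DataFile Version 3.0")
      wl(sprintf("cardiofvm snapshot t = %g ms", result$times[s]))
      wl("BINARY")
      wl("DATASET UNSTRUCTURED_GRID")
      wl(sprintf("POINTS %d float", nn))
      writeBin(as.numeric(t(nodes)), con, size = 4, endian = "big")
      wl("")
      wl(sprintf("CELLS %d %d", ne, 9 * ne))
      writeBin(as.integer(t(cbind(8L, conn - 1L))), con, size = 4,
               endian = "big")
      wl("")
      wl(sprintf("CELL_TYPES %d", ne))
      writeBin(rep(12L, ne), con, size = 4, endian = "big")
      wl("")
      wl(sprintf("CELL_DATA %d", ne))
      wl("SCALARS Vm float 1")
      wl("LOOKUP_TABLE default")
      writeBin(as.numeric(vals), con, size = 4, endian = "big")
      wl("")
      close(con)
    }
  }
  invisible(paths)
}

#' Read a legacy VTK unstructured-grid file
#'
#' Minimal reader for verification: returns points, hexahedral connectivity
#' and the `Vm` cell scalars from files written in either mode.
#'
#' @param path a `.vtk` file.
#' @return `list(points, cells, values)`.
#' @export
read_vtk_legacy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rline <- function() {
    chars <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1)
      if (!length(b) || b == as.raw(10)) break
      chars <- c(chars, b)
    }
    rawToChar(chars)
  }
  h1 <- rline()
  if (!grepl("^# vtk DataFile", h1)) stop("not a legacy VTK file")
  rline() # title
  mode <- rline()
  rline() # dataset
  pts_hdr <- rline()
  nn <- as.integer(strsplit(pts_hdr, "\\s+")[[1]][2])
  read_f <- function(count) {
    if (mode == "BINARY") {
      readBin(con, "numeric", count, size = 4, endian = "big")
    } else {
      out <- numeric(0)
      while (length(out) < count) {
        out <- c(out, as.numeric(strsplit(trimws(rline()), "\\s+")[[1]]))
      }
      out
    }
  }
  read_i <- function(count) {
    if (mode == "BINARY") {
      readBin(con, "integer", count, size = 4, endian = "big")
    } else {
      out <- integer(0)
      while (length(out) < count) {
        out <- c(out, as.integer(strsplit(trimws(rline()), "\\s+")[[1]]))
      }
      out
    }
  }
  pts <- matrix(read_f(3 * nn), ncol = 3, byrow = TRUE)
  if (mode == "BINARY") rline()
  cells_hdr <- rline()
  ne <- as.integer(strsplit(cells_hdr, "\\s+")[[1]][2])
  rawcells <- read_i(9 * ne)
  cells <- matrix(rawcells, ncol = 9, byrow = TRUE)[, -1, drop = FALSE] + 1L
  if (mode == "BINARY") rline()
  rline() # CELL_TYPES header
  read_i(ne)
  if (mode == "BINARY") rline()
  rline() # CELL_DATA
  rline() # SCALARS
  rline() # LOOKUP_TABLE
  vals <- read_f(ne)
  list(points = pts, cells = cells, values = vals)
}

# ---------------------------------------------------------------------------
# CSV writers

#' Write a per-volume activation map
#'
#' Lattice indices plus the local activation time in ms; volumes that never
#' crossed the threshold carry the sentinel value -1.
#'
#' @param result a `simulation_result` with a myocardial domain.
#' @param path output CSV.
#' @export
write_activation_map <- function(result, path) {
  if (is.null(result$lat_M)) stop("result has no myocardial activation map")
  if (length(result$lat_M) != nrow(result$grid$index)) {
    stop("activation map length does not match the grid")
  }
  lat <- ifelse(is.na(result$lat_M), -1, result$lat_M)
  df <- data.frame(
    i = result$grid$index[, 1], j = result$grid$index[, 2],
    k = result$grid$index[, 3], lat_ms = lat
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write pseudo-ECG traces as a time-by-lead CSV
#' @param result a `simulation_result` with ECG traces.
#' @param path output CSV.
#' @export
write_ecg_csv <- function(result, path) {
  if (is.null(result$ecg)) stop("result has no ECG traces")
  if (nrow(result$ecg) != length(result$times)) {
    stop("ECG trace length does not match the snapshot count")
  }
  df <- data.frame(time_ms = result$times, result$ecg)
  names(df) <- c("time_ms", result$config$leads$electrodes$label)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read PMJ delay records
#' @param records data.frame from [measure_pmj_delays()] (optionally with
#'   sweep metadata columns).
#' @param path CSV path.
#' @export
write_delay_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_delay_csv
#' @export
read_delay_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
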