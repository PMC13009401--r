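# PMJ delay measurement, block/instability classification, factorial sweep
# generation and concurrent batch dispatch.

#' Local activation time of a sampled trace
#'
#' First-sample threshold crossing, without interpolation: the time of the
#' first sample with `V >= threshold` (so the resolution equals the sampling
#' cadence), or `NA` when the trace never crosses.
#'
#' @param V numeric vector of uniformly sampled potentials, mV.
#' @param times sample times, ms.
#' @param threshold activation threshold, mV (default -40).
#' @return activation time in ms, or `NA_real_`.
#' @export
measure_activation_time <- function(V, times, threshold = -40) {
  if (length(V) == 0) stop("empty trace")
  if (length(V) != length(times)) stop("trace and time vectors differ in length")
  hit <- which(V >= threshold)
  if (!length(hit)) return(NA_real_)
  times[hit[1]]
}

#' Measure anterograde PMJ delays
#'
#' For every Purkinje terminal: the delay is the activation-time difference
#' (at the -40 mV threshold by default) between the closest coupled
#' myocardial control volume and the terminal Purkinje control volume.
#' A terminal whose coupled volume never activates while the run completed is
#' classified as propagation `block`; any terminal of a run that tripped the
#' instability detector is classified `unstable`.
#'
#' @param result a `simulation_result` with PMJ traces.
#' @param map the `pmj_map` (defaults to the one stored in the result).
#' @param threshold activation threshold, mV.
#' @return data.frame with columns `terminal`, `t_purkinje`, `t_myocardium`,
#'   `delay`, `status` (one row per terminal).
#' @export
measure_pmj_delays <- function(result, map = result$map, threshold = -40) {
  stopifnot(inherits(result, "simulation_result"))
  if (is.null(map)) stop("result has no PMJ map")
  nt <- length(map$terminals)
  if (is.null(result$pmj_terminal_V) || ncol(result$pmj_terminal_V) != nt) {
    stop("result is missing PMJ traces for the mapped terminals")
  }
  out <- vector("list", nt)
  for (k in seq_len(nt)) {
    vp <- result$pmj_terminal_V[, k]
    vm <- result$pmj_myocardium_V[, k]
    keep <- !is.na(vp)
    if (!any(keep)) {
      stop(sprintf("missing trace for terminal %d", map$terminals[k]))
    }
    tp <- measure_activation_time(vp[keep], result$pmj_times[keep], threshold)
    tm <- measure_activation_time(vm[keep], result$pmj_times[keep], threshold)
    status <- if (identical(result$status, "unstable")) {
      "unstable"
    } else if (!is.na(tp) && !is.na(tm)) {
      "ok"
    } else {
      "block"
    }
    out[[k]] <- data.frame(
      terminal = map$terminals[k],
      t_purkinje = tp, t_myocardium = tm,
      delay = if (status == "ok") tm - tp else NA_real_,
      status = status, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Define a factorial sweep
#'
#' @param axes named list of non-empty value vectors; the run count is the
#'   product of axis lengths.
#' @param base optional baseline `run_config`.
#' @param apply optional `function(config, params)` that applies one
#'   parameter combination to the baseline configuration.
#' @return a `sweep_spec`.
#' @export
sweep_spec <- function(axes, base = NULL, apply = NULL) {
  if (!length(axes) || is.null(names(axes)) || any(!nzchar(names(axes)))) {
    stop("axes must be a non-empty named list")
  }
  for (nm in names(axes)) {
    if (!length(axes[[nm]])) stop(sprintf("axis '%s' is empty", nm))
  }
  structure(list(axes = axes, base = base, apply = apply),
            class = "sweep_spec")
}

#' Generate all run configurations of a factorial sweep
#'
#' Full Cartesian product in deterministic lexicographic axis order: the
#' first axis varies slowest. Each run receives a unique directory name
#' encoding its parameter values.
#'
#' @param spec a `sweep_spec`.
#' @return list of runs, each `list(id, dir, params, config)` (`config` is
#'   `NULL` unless the spec carries a baseline and an apply function).
#' @export
generate_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  axes <- spec$axes
  # expand.grid varies the first factor fastest; reverse to make the first
  # axis the most significant, then restore column order
  grid <- expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(axes)), drop = FALSE]
  names(grid) <- names(axes)
  n <- nrow(grid)
  width <- max(4L, nchar(as.character(n)))
  runs <- vector("list", n)
  for (r in seq_len(n)) {
    params <- as.list(grid[r, , drop = FALSE])
    names(params) <- names(axes)
    enc <- paste(
      vapply(seq_along(params), function(a) {
        val <- format(params[[a]], trim = TRUE, scientific = FALSE)
        paste0(names(params)[a], "-", gsub("[^0-9A-Za-z.+-]", "_", val))
      }, character(1)),
      collapse = "_"
    )
    cfg <- if (!is.null(spec$base) && !is.null(spec$apply)) {
      spec$apply(spec$base, params)
    } else {
      NULL
    }
    runs[[r]] <- list(
      id = r,
      dir = sprintf(paste0("run_%0", width, "d_%s"), r, enc),
      params = params, config = cfg
    )
  }
  runs
}

.default_runner <- function(run) {
  res <- run_simulation(run$config)
  delays <- if (!is.null(res$map)) measure_pmj_delays(res) else NULL
  list(status = res$status, delays = delays, result = NULL)
}

#' Execute a batch of runs
#'
#' Each run executes exactly once; failures are isolated (a diverging or
#' erroring run is recorded in the manifest and never aborts the batch), and
#' the aggregated tables are identical for any worker count.
#'
#' @param runs list of runs from [generate_sweep()].
#' @param workers number of concurrent worker processes (forked).
#' @param out_dir optional directory; each run then writes its delay table
#'   into an isolated working subdirectory named after the run.
#' @param runner `function(run) -> list(status, delays)`; the default runs
#'   [run_simulation()] on `run$config` and measures PMJ delays.
#' @return a `batch_manifest`: `runs` (per-run status data.frame) and
#'   `delays` (aggregated delay table with run id and parameter columns).
#' @export
dispatch_batch <- function(runs, workers = 1, out_dir = NULL,
                           runner = .default_runner) {
  stopifnot(workers >= 1)
  if (!length(runs)) {
    return(structure(
      list(
        runs = data.frame(id = integer(0), dir = character(0),
                          status = character(0), error = character(0),
                          stringsAsFactors = FALSE),
        delays = NULL
      ),
      class = "batch_manifest"
    ))
  }
  dirs <- vapply(runs, `[[`, character(1), "dir")
  if (anyDuplicated(dirs)) {
    stop(sprintf("duplicate run directory '%s'", dirs[anyDuplicated(dirs)]))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  exec_one <- function(run) {
    out <- tryCatch(runner(run), error = function(e) {
      list(status = "failed", delays = NULL,
           error = conditionMessage(e))
    })
    out$error <- out$error %||% NA_character_
    if (!is.null(out_dir) && !is.null(out$delays)) {
      rd <- file.path(out_dir, run$dir)
      dir.create(rd, recursive = TRUE, showWarnings = FALSE)
      write_delay_csv(out$delays, file.path(rd, "pmj_delays.csv"))
    }
    out
  }
  results <- if (workers > 1) {
    parallel::mclapply(runs, exec_one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(runs, exec_one)
  }
  status <- vapply(results, function(r) {
    if (inherits(r, "try-error")) "failed" else r$status
  }, character(1))
  errors <- vapply(results, function(r) {
    if (inherits(r, "try-error")) as.character(r) else r$error
  }, character(1))
  manifest_runs <- data.frame(
    id = vapply(runs, `[[`, numeric(1), "id"),
    dir = dirs, status = status, error = errors,
    stringsAsFactors = FALSE
  )
  delay_rows <- list()
  for (r in seq_along(runs)) {
    d <- results[[r]]$delays
    if (is.null(d)) next
    meta <- data.frame(run = runs[[r]]$id, stringsAsFactors = FALSE)
    for (nm in names(runs[[r]]$params)) meta[[nm]] <- runs[[r]]$params[[nm]]
    delay_rows[[length(delay_rows) + 1]] <-
      cbind(meta[rep(1, nrow(d)), , drop = FALSE], d)
  }
  delays <- if (length(delay_rows)) {
    out <- do.call(rbind, delay_rows)
    rownames(out) <- NULL
    out
  } else {
    NULL
  }
  structure(list(runs = manifest_runs, delays = delays),
            class = "batch_manifest")
}

#' Mean-delay heatmap over the (R_PMJ, N_PMJ) plane
#'
#' Aggregates delay records from a completed sweep into a matrix of mean
#' anterograde delays (rows = R_PMJ values ascending, columns = N_PMJ values
#' ascending) plus block / unstable / missing cell masks. Missing
#' combinations are flagged, never silently filled.
#'
#' @param records data.frame with columns `R_PMJ`, `N_PMJ`, `delay`,
#'   `status`.
#' @param path optional CSV output path.
#' @return list with `R_PMJ`, `N_PMJ`, `delay` (matrix), `block`,
#'   `unstable`, `missing` (logical matrices).
#' @export
delay_heatmap <- function(records, path = NULL) {
  need <- c("R_PMJ", "N_PMJ", "delay", "status")
  if (!all(need %in% names(records))) {
    stop("records must contain columns R_PMJ, N_PMJ, delay, status")
  }
  rv <- sort(unique(records$R_PMJ))
  nv <- sort(unique(records$N_PMJ))
  delay <- matrix(NA_real_, length(rv), length(nv),
                  dimnames = list(format(rv), format(nv)))
  block <- unstable <- missing_m <- matrix(FALSE, length(rv), length(nv),
                                           dimnames = dimnames(delay))
  for (i in seq_along(rv)) {
    for (j in seq_along(nv)) {
      sel <- records$R_PMJ == rv[i] & records$N_PMJ == nv[j]
      if (!any(sel)) {
        missing_m[i, j] <- TRUE
        next
      }
      st <- records$status[sel]
      if (any(st == "unstable")) {
        unstable[i, j] <- TRUE
      } else if (any(st == "block")) {
        block[i, j] <- TRUE
      } else {
        delay[i, j] <- mean(records$delay[sel])
      }
    }
  }
  if (any(missing_m)) {
    warning(sprintf("%d missing (R_PMJ, N_PMJ) cells flagged",
                    sum(missing_m)))
  }
  out <- list(R_PMJ = rv, N_PMJ = nv, delay = delay, block = block,
              unstable = unstable, missing = missing_m)
  if (!is.null(path)) {
    cell <- ifelse(out$missing, "missing",
                   ifelse(out$unstable, "unstable",
                          ifelse(out$block, "block",
                                 format(out$delay, digits = 10))))
    df <- data.frame(R_PMJ = rep(rv, times = length(nv)),
                     N_PMJ = rep(nv, each = length(rv)),
                     value = as.vector(cell), stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  }
  out
}
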