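test_that("activation time is the first sample at or above threshold", {
  expect_equal(measure_activation_time(c(-85, -85, -30), c(0, 1, 2)), 2)
  expect_true(is.na(measure_activation_time(c(-85, -80, -70), c(0, 1, 2))))
  expect_equal(measure_activation_time(c(0, -85), c(0, 1)), 0)
  expect_error(measure_activation_time(numeric(0), numeric(0)), "empty")
})

fake_result <- function(vp, vm, times, status = "ok") {
  map <- structure(
    list(terminals = 5L, volumes = list(3L), distances = list(0.01),
         R_PMJ = 1000, N_PMJ = 1L),
    class = "pmj_map"
  )
  structure(
    list(
      status = status, map = map, pmj_times = times,
      pmj_terminal_V = matrix(vp, ncol = 1),
      pmj_myocardium_V = matrix(vm, ncol = 1)
    ),
    class = "simulation_result"
  )
}

test_that("PMJ delays classify ok, block and unstable records", {
  times <- seq(0, 20, by = 2)
  vp <- c(rep(-85, 5), rep(0, 6)) # crosses at 10 ms
  vm <- c(rep(-85, 7), rep(0, 4)) # crosses at 14 ms
  d <- measure_pmj_delays(fake_result(vp, vm, times))
  expect_equal(d$status, "ok")
  expect_equal(d$delay, 4)
  expect_equal(d$t_purkinje, 10)
  # myocardial volume never crosses -> block, no delay
  db <- measure_pmj_delays(fake_result(vp, rep(-85, 11), times))
  expect_equal(db$status, "block")
  expect_true(is.na(db$delay))
  # instability flag dominates
  du <- measure_pmj_delays(fake_result(vp, vm, times, status = "unstable"))
  expect_equal(du$status, "unstable")
  expect_true(is.na(du$delay))
})

test_that("sweep generation produces the full ordered Cartesian product", {
  sp <- sweep_spec(list(R = c(100, 200), N = c(1, 2, 3)))
  runs <- generate_sweep(sp)
  expect_length(runs, 6)
  # lexicographic: first axis varies slowest
  expect_equal(vapply(runs, function(r) r$params$R, numeric(1)),
               c(100, 100, 100, 200, 200, 200))
  expect_equal(vapply(runs, function(r) r$params$N, numeric(1)),
               c(1, 2, 3, 1, 2, 3))
  dirs <- vapply(runs, `[[`, character(1), "dir")
  expect_false(anyDuplicated(dirs) > 0)
  # stable across regeneration
  expect_identical(dirs, vapply(generate_sweep(sp), `[[`, character(1),
                                "dir"))
  single <- generate_sweep(sweep_spec(list(R = 5)))
  expect_length(single, 1)
  expect_error(sweep_spec(list(R = numeric(0))), "empty")
  expect_error(sweep_spec(list()), "non-empty")
})

test_that("batch dispatch is deterministic across worker counts and isolates failures", {
  base <- tiny_coupled_config(t_max = 6)
  apply_params <- function(config, params) {
    config$pmj$R_PMJ <- params$R_PMJ
    config$pmj$N_PMJ <- as.integer(params$N_PMJ)
    config
  }
  sp <- sweep_spec(list(R_PMJ = c(100, 400), N_PMJ = c(1, 3)),
                   base = base, apply = apply_params)
  runs <- generate_sweep(sp)
  expect_length(runs, 4)
  d1 <- withr::local_tempdir()
  d4 <- withr::local_tempdir()
  m1 <- dispatch_batch(runs, workers = 1, out_dir = d1)
  m4 <- dispatch_batch(runs, workers = 4, out_dir = d4)
  expect_equal(m1$runs$status, rep("ok", 4))
  expect_identical(m1$delays, m4$delays)
  f1 <- file.path(d1, "delays.csv")
  f4 <- file.path(d4, "delays.csv")
  write_delay_csv(m1$delays, f1)
  write_delay_csv(m4$delays, f4)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f4, "raw", file.size(f4)))
  # per-run isolated directories exist
  expect_true(all(file.exists(file.path(d1, m1$runs$dir,
                                        "pmj_delays.csv"))))
  # a failing run is recorded without aborting the others
  bomb <- function(run) {
    if (run$params$R_PMJ == 400) stop("synthetic failure")
    .default <- getFromNamespace(".default_runner", "cardiofvm")
    .default(run)
  }
  mfail <- dispatch_batch(runs, workers = 2, runner = bomb)
  expect_equal(sum(mfail$runs$status == "failed"), 2)
  expect_equal(sum(mfail$runs$status == "ok"), 2)
  expect_match(mfail$runs$error[mfail$runs$status == "failed"][1],
               "synthetic failure")
  # zero runs: empty manifest, success
  m0 <- dispatch_batch(list(), workers = 3)
  expect_equal(nrow(m0$runs), 0)
  # duplicate directories rejected before launch
  dup <- runs
  dup[[2]]$dir <- dup[[1]]$dir
  expect_error(dispatch_batch(dup), "duplicate")
})

test_that("delay heatmaps aggregate means and flag block/unstable/missing cells", {
  rec <- expand.grid(R_PMJ = c(100, 200), N_PMJ = c(10, 20))
  rec$delay <- c(1, 2, 0.5, 1.5)
  rec$status <- "ok"
  hm <- delay_heatmap(rec)
  expect_equal(dim(hm$delay), c(2, 2))
  expect_false(any(hm$block | hm$unstable | hm$missing))
  expect_equal(hm$delay["100", "10"], 1)
  # duplicated cell records average; block and unstable mask cells
  rec2 <- rbind(rec, data.frame(R_PMJ = 100, N_PMJ = 10, delay = 3,
                                status = "ok"))
  expect_equal(delay_heatmap(rec2)$delay["100", "10"], 2)
  rec3 <- rec
  rec3$status <- c("ok", "block", "unstable", "ok")
  hm3 <- delay_heatmap(rec3)
  expect_true(hm3$block["200", "10"])
  expect_true(hm3$unstable["100", "20"])
  expect_true(is.na(hm3$delay["200", "10"]))
  # incomplete grids are flagged, not filled
  expect_warning(hm4 <- delay_heatmap(rec[-2, ]), "missing")
  expect_true(hm4$missing["200", "10"])
  # CSV output round-trips the cell labels
  path <- withr::local_tempfile(fileext = ".csv")
  delay_heatmap(rec3, path = path)
  csv <- utils::read.csv(path)
  expect_equal(nrow(csv), 4)
  expect_true("block" %in% csv$value)
})
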