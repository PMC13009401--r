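test_that("cuboid grids have the product volume count and centred volumes", {
  cases <- list(
    list(extent = c(0.05, 0.05, 0.05), h = 0.05, n = 1),
    list(extent = c(1, 0.025, 0.025), h = 0.025, n = 40),
    list(extent = c(0.2, 0.15, 0.1), h = 0.05, n = 4 * 3 * 2)
  )
  for (cs in cases) {
    g <- build_cuboid_grid(cs$extent, cs$h, c(1, 1, 1))
    expect_equal(nrow(g$index), cs$n)
    expect_equal(g$centers, (g$index + 0.5) * cs$h)
    expect_false(anyDuplicated(g$key) > 0)
  }
})

test_that("non-commensurate extent is rejected naming the axis", {
  expect_error(build_cuboid_grid(c(0.11, 0.1, 0.1), 0.025, c(1, 1, 1)),
               "along x")
  expect_error(build_cuboid_grid(c(0.1, 0.1, 0.13), 0.025, c(1, 1, 1)),
               "along z")
})

test_that("tag_region retags exactly the centers inside the half-open box", {
  g <- build_cuboid_grid(c(0.2, 0.2, 0.2), 0.05, c(1, 1, 1))
  all_tagged <- tag_region(g, c(0, 0, 0, 1, 1, 1), "endo", c(2, 2, 2))
  expect_true(all(all_tagged$tag == "endo"))
  expect_true(all(all_tagged$sigma == 2))
  expect_warning(
    unchanged <- tag_region(g, c(5, 5, 5, 6, 6, 6), "endo", c(2, 2, 2)),
    "no volume centers"
  )
  expect_identical(unchanged$tag, g$tag)
  # lower half along x of a 4^3 grid: enumeration oracle
  half <- tag_region(g, c(0, 0, 0, 0.1, 0.2, 0.2), "endo", c(2, 2, 2))
  oracle <- sum(g$centers[, 1] >= 0 & g$centers[, 1] < 0.1)
  expect_equal(oracle, 32)
  expect_equal(sum(half$tag == "endo"), oracle)
})

test_that("binary-tree fixtures satisfy the terminal and volume counts", {
  for (depth in 0:3) {
    for (m in c(4, 20)) {
      bl <- m * 0.025
      net <- build_purkinje_tree(depth, bl, 0.025, 2)
      expect_length(net$terminals, 2^depth)
      expect_equal(nrow(net$nodes), (2^(depth + 1) - 1) * m)
      # spacing invariant along every edge
      d <- sqrt(rowSums((net$nodes[net$edges$parent, , drop = FALSE] -
                           net$nodes[net$edges$child, , drop = FALSE])^2))
      expect_true(all(abs(d - 0.025) < 1e-8))
    }
  }
  expect_error(build_purkinje_tree(1, 0.11, 0.025, 2), "integer multiple")
})

test_that("the bifurcation volume of a depth-1 tree has two children", {
  net <- build_purkinje_tree(1, 0.1, 0.025, 2)
  n_children <- vapply(net$children, length, integer(1))
  expect_equal(sum(n_children == 2), 1)
  # the branching volume is the tip of the root branch
  expect_equal(which(n_children == 2), 4L)
})

test_that("map_pmjs matches a brute-force distance sort and is storage-order invariant", {
  g <- build_cuboid_grid(c(0.2, 0.2, 0.1), 0.05, c(1, 1, 1))
  net <- build_purkinje_tree(1, 0.1, 0.05, 2, origin = c(-0.12, 0.08, 0.05))
  for (N in c(1, 5, nrow(g$index))) {
    map <- map_pmjs(net, g, N_PMJ = N, R_PMJ = 1000)
    for (t in seq_along(map$terminals)) {
      p <- net$nodes[map$terminals[t], ]
      d <- sqrt(colSums((t(g$centers) - p)^2))
      ord <- order(d, g$index[, 1], g$index[, 2], g$index[, 3])
      expect_equal(map$volumes[[t]], ord[seq_len(N)])
      expect_false(anyDuplicated(map$volumes[[t]]) > 0)
      expect_true(!is.unsorted(d[map$volumes[[t]]]))
    }
  }
  # storage-order invariance: permute the grid rows, compare lattice indices
  set.seed(7)
  perm <- sample(nrow(g$index))
  gp <- cardiofvm:::new_cartesian_grid(
    g$index[perm, ], g$h, g$tag[perm], g$sigma[perm, ], g$fibers[perm, ]
  )
  m1 <- map_pmjs(net, g, 5, 1000)
  m2 <- map_pmjs(net, gp, 5, 1000)
  for (t in seq_along(m1$terminals)) {
    expect_equal(g$index[m1$volumes[[t]], ], gp$index[m2$volumes[[t]], ])
  }
  expect_error(map_pmjs(net, g, nrow(g$index) + 1, 1000), "exceeds")
})

test_that("distance ties break by ascending lattice lexicographic order", {
  g <- build_cuboid_grid(c(0.1, 0.1, 0.1), 0.05, c(1, 1, 1))
  # terminal at the exact grid midpoint: all 8 centers equidistant
  net <- purkinje_network(matrix(c(0.05, 0.05, 0.05), 1),
                          data.frame(parent = integer(0),
                                     child = integer(0),
                                     sigma = numeric(0)), 0.05)
  map <- map_pmjs(net, g, 8, 1000)
  expect_equal(g$index[map$volumes[[1]], ],
               g$index[order(g$index[, 1], g$index[, 2], g$index[, 3]), ])
})

test_that("grid files round-trip exactly and malformed files name the line", {
  g <- build_cuboid_grid(c(0.2, 0.15, 0.1), 0.05, c(1.334, 0.176, 0.176),
                         fiber_axis = c(1, 1, 0) / sqrt(2))
  g <- tag_region(g, c(0, 0, 0, 0.1, 1, 1), "endo", c(0.2, 0.2, 0.2))
  path <- withr::local_tempfile(fileext = ".txt")
  write_grid(g, path)
  g2 <- read_grid(path)
  expect_identical(g2$index, g$index)
  expect_identical(g2$tag, g$tag)
  expect_equal(g2$sigma, g$sigma, tolerance = 1e-12)
  expect_equal(g2$fibers, g$fibers, tolerance = 1e-12)
  expect_equal(g2$h, g$h)
  # malformed line -> error naming the line number
  lines <- readLines(path)
  lines[3] <- "1 2 3 bulk not_a_number"
  writeLines(lines, path)
  expect_error(read_grid(path), "line 3")
  writeLines(character(0), path)
  expect_error(read_grid(path), "empty")
  writeLines("h 0.05", path)
  expect_error(read_grid(path), "no volumes")
})

test_that("network files round-trip and invariant violations are rejected", {
  net <- build_purkinje_tree(2, 0.1, 0.025, 2.5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_network(net, path)
  n2 <- read_network(path)
  expect_equal(n2$nodes, net$nodes, tolerance = 1e-12)
  expect_identical(n2$edges$parent, net$edges$parent)
  expect_identical(n2$edges$child, net$edges$child)
  expect_equal(n2$terminals, net$terminals)
  expect_equal(n2$root, net$root)
  # two roots: 4 nodes, edges only into 3 and 4
  writeLines(c(
    "h 0.025",
    "1 0 0 0", "2 0.025 0 0", "3 1 0 0", "4 1.025 0 0",
    "1 2 2", "3 4 2"
  ), path)
  expect_error(read_network(path), "exactly one root")
  # malformed edge line
  writeLines(c("h 0.025", "1 0 0 0", "2 0.025 0 0", "1 2"), path)
  expect_error(read_network(path), "line 4")
})
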