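# Voxel grids, Purkinje networks and PMJ coupling maps.
#
# Conventions (fixed across the package):
#   * lattice indices are 0-based integers (i, j, k)
#   * volume centers sit at (index + 0.5) * h, in cm
#   * boxes are half-open [lo, hi)
#   * fibre triads are stored per volume as a 9-column matrix
#     (fx fy fz sx sy sz nx ny nz), conductivities as (sigma_f, sigma_t,
#     sigma_n) in mS/cm

# Encode a 0-based lattice index triple as a single numeric key for O(1)
# neighbour lookup via match(). Indices are offset by 1 so that -1 (used when
# probing a neighbour off the lattice edge) still encodes to a valid key.
.lattice_key <- function(index) {
  (index[, 1] + 1) * 2^40 + (index[, 2] + 1) * 2^20 + (index[, 3] + 1)
}

.default_fibers <- function(n) {
  matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = n), nrow = n)
}

#' Construct a Cartesian voxel grid
#'
#' Internal constructor shared by [build_cuboid_grid()] and [read_grid()].
#' Validates the grid invariants: unique lattice indices, orthonormal fibre
#' triads, non-negative conductivities.
#'
#' @param index integer matrix (n x 3) of 0-based lattice indices.
#' @param h spacing in cm.
#' @param tag character vector of region labels.
#' @param sigma numeric matrix (n x 3) of (sigma_f, sigma_t, sigma_n), mS/cm.
#' @param fibers numeric matrix (n x 9) of fibre triads, or `NULL` for the
#'   canonical axes.
#' @return an object of class `cartesian_grid`.
#' @keywords internal
new_cartesian_grid <- function(index, h, tag, sigma, fibers = NULL) {
  if (!is.matrix(index)) index <- matrix(index, ncol = 3)
  storage.mode(index) <- "integer"
  dimnames(index) <- NULL
  n <- nrow(index)
  if (n < 1) stop("grid must contain at least one volume")
  if (h <= 0) stop("spacing h must be positive")
  if (is.null(fibers)) fibers <- .default_fibers(n)
  if (length(tag) == 1) tag <- rep(tag, n)
  if (is.vector(sigma) && length(sigma) == 3) {
    sigma <- matrix(sigma, nrow = n, ncol = 3, byrow = TRUE)
  }
  keys <- .lattice_key(index)
  if (anyDuplicated(keys)) stop("duplicate lattice indices in grid")
  if (any(sigma < 0)) stop("conductivities must be non-negative")
  # orthonormality of each (f, s, n) triad
  f <- fibers[, 1:3, drop = FALSE]
  s <- fibers[, 4:6, drop = FALSE]
  nn <- fibers[, 7:9, drop = FALSE]
  dot <- function(a, b) rowSums(a * b)
  err <- pmax(
    abs(dot(f, f) - 1), abs(dot(s, s) - 1), abs(dot(nn, nn) - 1),
    abs(dot(f, s)), abs(dot(f, nn)), abs(dot(s, nn))
  )
  if (any(err > 1e-10)) stop("fibre triads must be orthonormal (tol 1e-10)")
  centers <- (index + 0.5) * h
  extent <- (apply(index, 2, max) + 1) * h
  structure(
    list(
      h = h, extent = extent, index = index, centers = centers,
      tag = tag, sigma = sigma, fibers = fibers, key = keys
    ),
    class = "cartesian_grid"
  )
}

#' Build a full cuboid voxel grid
#'
#' Discretises an axis-aligned cuboid into cubic control volumes of spacing
#' `h`, with a uniform fibre field and uniform conductivities. This is the
#' geometry of the standard conduction benchmark: a 1 x 1 x 1 cm block at
#' h = 0.025 cm yields 64,000 control volumes.
#'
#' @param extent lengths (cm) along x, y, z; each must be an integer multiple
#'   of `h` (to 1e-9 relative).
#' @param h spacing in cm.
#' @param sigma conductivity triple (sigma_f, sigma_t, sigma_n) in mS/cm.
#' @param fiber_axis unit vector giving the fibre direction; the sheet and
#'   normal directions complete a right-handed orthonormal triad. Defaults to
#'   the x axis.
#' @param tag region label applied to every volume.
#' @return a `cartesian_grid`.
#' @examples
#' g <- build_cuboid_grid(c(1, 1, 1), 0.025, c(1.334, 0.176, 0.176))
#' nrow(g$index) # 64000
#' @export
build_cuboid_grid <- function(extent, h, sigma, fiber_axis = c(1, 0, 0),
                              tag = "bulk") {
  stopifnot(length(extent) == 3, h > 0)
  n_axis <- extent / h
  for (a in 1:3) {
    if (abs(n_axis[a] - round(n_axis[a])) > 1e-9 * max(1, n_axis[a])) {
      stop(sprintf(
        "extent along %s (%g cm) is not an integer multiple of h = %g cm",
        c("x", "y", "z")[a], extent[a], h
      ))
    }
  }
  n_axis <- as.integer(round(n_axis))
  idx <- as.matrix(expand.grid(
    i = 0:(n_axis[1] - 1), j = 0:(n_axis[2] - 1), k = 0:(n_axis[3] - 1)
  ))
  fibers <- .triad_from_axis(fiber_axis, nrow(idx))
  g <- new_cartesian_grid(idx, h, tag, sigma, fibers)
  g$extent <- extent
  g
}

# Complete a fibre axis into an orthonormal (f, s, n) triad, replicated n times.
.triad_from_axis <- function(f, n) {
  f <- f / sqrt(sum(f^2))
  ref <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  s <- ref - sum(ref * f) * f
  s <- s / sqrt(sum(s^2))
  nv <- c(
    f[2] * s[3] - f[3] * s[2],
    f[3] * s[1] - f[1] * s[3],
    f[1] * s[2] - f[2] * s[1]
  )
  matrix(rep(c(f, s, nv), each = n), nrow = n)
}

#' Retag a box-shaped region of a grid
#'
#' Volumes whose centers lie inside the half-open box `[lo, hi)` receive the
#' given tag and conductivity triple (used e.g. for isotropic dense/sparse
#' endocardial layers). Volumes outside are untouched.
#'
#' @param grid a `cartesian_grid`.
#' @param box numeric vector `c(xlo, ylo, zlo, xhi, yhi, zhi)` in cm.
#' @param tag region label for the selected volumes.
#' @param sigma conductivity triple applied to the selected volumes.
#' @return the modified grid. An empty intersection raises a warning and
#'   returns the grid unchanged.
#' @export
tag_region <- function(grid, box, tag, sigma) {
  stopifnot(inherits(grid, "cartesian_grid"), length(box) == 6)
  lo <- box[1:3]
  hi <- box[4:6]
  inside <- grid$centers[, 1] >= lo[1] & grid$centers[, 1] < hi[1] &
    grid$centers[, 2] >= lo[2] & grid$centers[, 2] < hi[2] &
    grid$centers[, 3] >= lo[3] & grid$centers[, 3] < hi[3]
  if (!any(inside)) {
    warning("tag_region: box contains no volume centers; grid unchanged")
    return(grid)
  }
  grid$tag[inside] <- tag
  grid$sigma[inside, ] <- matrix(sigma, nrow = sum(inside), ncol = 3,
                                 byrow = TRUE)
  grid
}

#' Construct a Purkinje network from nodes and edges
#'
#' Validates the network invariants: exactly one root, connectivity, a single
#' parent per non-root node, and consecutive node spacing equal to `h` (to
#' 1e-8). Each node inherits the conductivity of the edge to its parent (the
#' root inherits from its first child edge); face conductivities between
#' adjacent volumes are later taken as harmonic means of these node values.
#'
#' @param nodes numeric matrix (n x 3) of 1-D control-volume centers, cm.
#' @param edges data.frame with columns `parent`, `child` (1-based node ids)
#'   and `sigma` (mS/cm).
#' @param h spacing in cm.
#' @return an object of class `purkinje_network` with fields `nodes`, `edges`,
#'   `h`, `parent`, `children`, `root`, `terminals`, `node_sigma`.
#' @export
purkinje_network <- function(nodes, edges, h) {
  if (!is.matrix(nodes)) nodes <- matrix(nodes, ncol = 3)
  n <- nrow(nodes)
  if (n < 1) stop("network must contain at least one node")
  if (h <= 0) stop("spacing h must be positive")
  parent <- rep(NA_integer_, n)
  if (n > 1) {
    if (anyDuplicated(edges$child)) {
      stop("network invariant violated: a node has more than one parent")
    }
    parent[edges$child] <- as.integer(edges$parent)
  }
  roots <- which(is.na(parent))
  if (length(roots) != 1) {
    stop(sprintf(
      "network must have exactly one root, found %d", length(roots)
    ))
  }
  root <- roots
  if (n > 1 && nrow(edges) != n - 1) {
    stop(sprintf(
      "network with %d nodes must have %d edges, got %d",
      n, n - 1, nrow(edges)
    ))
  }
  # connectivity: walk up from every node
  depth_guard <- n + 1
  for (v in seq_len(n)) {
    u <- v
    steps <- 0
    while (!is.na(parent[u])) {
      u <- parent[u]
      steps <- steps + 1
      if (steps > depth_guard) stop("network contains a cycle")
    }
    if (u != root) stop("network is not connected")
  }
  # spacing invariant
  if (n > 1) {
    d <- sqrt(rowSums((nodes[edges$parent, , drop = FALSE] -
                         nodes[edges$child, , drop = FALSE])^2))
    if (any(abs(d - h) > 1e-8)) {
      stop("consecutive node distance must equal h (tol 1e-8)")
    }
  }
  children <- vector("list", n)
  if (n > 1) {
    for (e in seq_len(nrow(edges))) {
      p <- edges$parent[e]
      children[[p]] <- c(children[[p]], as.integer(edges$child[e]))
    }
  }
  n_children <- vapply(children, length, integer(1))
  terminals <- which(n_children == 0)
  node_sigma <- rep(NA_real_, n)
  if (n > 1) {
    node_sigma[edges$child] <- edges$sigma
    node_sigma[root] <- edges$sigma[match(root, edges$parent)]
  } else {
    node_sigma[1] <- 0
  }
  structure(
    list(
      nodes = nodes, edges = edges, h = h, parent = parent,
      children = children, root = root, terminals = terminals,
      node_sigma = node_sigma
    ),
    class = "purkinje_network"
  )
}

#' Build a symmetric binary-tree Purkinje fixture
#'
#' Generates a rooted binary tree of straight branches in the x-y plane.
#' Depth 0 is a single straight cable; each additional level splits every
#' branch tip into two children rotated +/- 45 degrees from the parent
#' direction. Terminal count is `2^depth`; total volume count is
#' `(2^(depth+1) - 1) * branch_length / h_P`.
#'
#' @param depth non-negative integer number of bifurcation levels.
#' @param branch_length branch length in cm; integer multiple of `h_P`.
#' @param h_P node spacing in cm.
#' @param sigma_P conductivity (mS/cm) assigned to every edge.
#' @param origin coordinates (cm) of the first (root) node.
#' @param direction initial growth direction (unit vector, x-y plane used for
#'   bifurcation rotations).
#' @return a `purkinje_network`.
#' @export
build_purkinje_tree <- function(depth, branch_length, h_P, sigma_P,
                                origin = c(0, 0, 0),
                                direction = c(1, 0, 0)) {
  stopifnot(depth >= 0, h_P > 0)
  m <- branch_length / h_P
  if (abs(m - round(m)) > 1e-9 * max(1, m)) {
    stop(sprintf(
      "branch_length %g cm is not an integer multiple of h_P = %g cm",
      branch_length, h_P
    ))
  }
  m <- as.integer(round(m))
  if (m < 1) stop("branch must contain at least one volume")
  direction <- direction / sqrt(sum(direction^2))
  nodes <- list()
  edges <- list()
  nid <- 0
  add_branch <- function(start, dir, attach_to, level) {
    # one branch of m volumes; returns id of its last node
    prev <- attach_to
    pos <- start
    for (q in seq_len(m)) {
      nid <<- nid + 1
      nodes[[nid]] <<- pos
      if (!is.na(prev)) {
        edges[[length(edges) + 1]] <<- c(prev, nid, sigma_P)
      }
      prev <- nid
      pos <- pos + h_P * dir
    }
    tip <- prev
    if (level < depth) {
      ang <- atan2(dir[2], dir[1])
      for (rot in c(pi / 4, -pi / 4)) {
        cd <- c(cos(ang + rot), sin(ang + rot), 0)
        add_branch(nodes[[tip]] + h_P * cd, cd, tip, level + 1)
      }
    }
    tip
  }
  add_branch(origin, direction, NA_integer_, 0)
  nodes <- do.call(rbind, nodes)
  edges <- if (length(edges)) {
    e <- do.call(rbind, edges)
    data.frame(parent = as.integer(e[, 1]), child = as.integer(e[, 2]),
               sigma = e[, 3])
  } else {
    data.frame(parent = integer(0), child = integer(0), sigma = numeric(0))
  }
  purkinje_network(nodes, edges, h_P)
}

#' Map Purkinje terminals to their nearest myocardial volumes
#'
#' For every terminal node, finds the `N_PMJ` active myocardial volumes whose
#' centers are closest (Euclidean distance), breaking distance ties by
#' ascending lattice lexicographic order (i, then j, then k) so the result is
#' deterministic and independent of the grid's storage order.
#'
#' @param network a `purkinje_network`.
#' @param grid a `cartesian_grid`.
#' @param N_PMJ number of myocardial volumes coupled to each terminal.
#' @param R_PMJ junction resistance in kOhm (mV / kOhm = uA).
#' @return an object of class `pmj_map`: per-terminal integer vectors of grid
#'   row indices (sorted by ascending distance), plus `R_PMJ`, `N_PMJ`.
#' @export
map_pmjs <- function(network, grid, N_PMJ, R_PMJ) {
  stopifnot(inherits(network, "purkinje_network"),
            inherits(grid, "cartesian_grid"))
  if (N_PMJ < 1) stop("N_PMJ must be >= 1")
  if (R_PMJ <= 0) stop("R_PMJ must be positive")
  nvol <- nrow(grid$centers)
  if (N_PMJ > nvol) {
    stop(sprintf(
      "N_PMJ = %d exceeds the number of active volumes (%d)", N_PMJ, nvol
    ))
  }
  volumes <- vector("list", length(network$terminals))
  dists <- vector("list", length(network$terminals))
  for (t in seq_along(network$terminals)) {
    p <- network$nodes[network$terminals[t], ]
    d2 <- (grid$centers[, 1] - p[1])^2 + (grid$centers[, 2] - p[2])^2 +
      (grid$centers[, 3] - p[3])^2
    # quantize so that exact geometric ties are not split by rounding noise,
    # then break them by lattice lexicographic order
    ord <- order(signif(d2, 12), grid$index[, 1], grid$index[, 2],
                 grid$index[, 3])
    sel <- ord[seq_len(N_PMJ)]
    volumes[[t]] <- sel
    dists[[t]] <- sqrt(d2[sel])
  }
  structure(
    list(
      terminals = network$terminals, volumes = volumes, distances = dists,
      R_PMJ = R_PMJ, N_PMJ = as.integer(N_PMJ)
    ),
    class = "pmj_map"
  )
}

# ---------------------------------------------------------------------------
# Plain-text formats
#
# Grid:    header "h <cm>", then per volume
#          "i j k tag sf st sn fx fy fz sx sy sz nx ny nz"
# Network: header "h <cm>", then node lines "id x y z",
#          then edge lines "parent child sigma"

.fmt <- function(x) sprintf("%.17g", x)

#' Write a grid to its plain-text format
#' @param grid a `cartesian_grid`.
#' @param path output file.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "cartesian_grid"))
  lines <- c(
    paste("h", .fmt(grid$h)),
    paste(
      grid$index[, 1], grid$index[, 2], grid$index[, 3], grid$tag,
      .fmt(grid$sigma[, 1]), .fmt(grid$sigma[, 2]), .fmt(grid$sigma[, 3]),
      .fmt(grid$fibers[, 1]), .fmt(grid$fibers[, 2]), .fmt(grid$fibers[, 3]),
      .fmt(grid$fibers[, 4]), .fmt(grid$fibers[, 5]), .fmt(grid$fibers[, 6]),
      .fmt(grid$fibers[, 7]), .fmt(grid$fibers[, 8]), .fmt(grid$fibers[, 9])
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a grid from its plain-text format
#' @param path input file.
#' @return a `cartesian_grid`.
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) stop("grid file is empty")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2 || hdr[1] != "h") {
    stop("grid file line 1: expected header 'h <cm>'")
  }
  h <- as.numeric(hdr[2])
  if (is.na(h)) stop("grid file line 1: unparseable spacing")
  if (length(lines) < 2) stop("grid file contains no volumes")
  n <- length(lines) - 1
  index <- matrix(0L, n, 3)
  tag <- character(n)
  sigma <- matrix(0, n, 3)
  fibers <- matrix(0, n, 9)
  for (r in seq_len(n)) {
    f <- strsplit(trimws(lines[r + 1]), "\\s+")[[1]]
    if (length(f) != 16) {
      stop(sprintf("grid file line %d: expected 16 fields, got %d",
                   r + 1, length(f)))
    }
    ijk <- suppressWarnings(as.integer(f[1:3]))
    vals <- suppressWarnings(as.numeric(f[5:16]))
    if (anyNA(ijk) || anyNA(vals)) {
      stop(sprintf("grid file line %d: unparseable numeric field", r + 1))
    }
    index[r, ] <- ijk
    tag[r] <- f[4]
    sigma[r, ] <- vals[1:3]
    fibers[r, ] <- vals[4:12]
  }
  new_cartesian_grid(index, h, tag, sigma, fibers)
}

#' Write a Purkinje network to its plain-text format
#' @param network a `purkinje_network`.
#' @param path output file.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "purkinje_network"))
  n <- nrow(network$nodes)
  lines <- c(
    paste("h", .fmt(network$h)),
    paste(seq_len(n), .fmt(network$nodes[, 1]), .fmt(network$nodes[, 2]),
          .fmt(network$nodes[, 3]))
  )
  if (nrow(network$edges)) {
    lines <- c(lines, paste(network$edges$parent, network$edges$child,
                            .fmt(network$edges$sigma)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Purkinje network from its plain-text format
#' @param path input file.
#' @return a `purkinje_network`.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) stop("network file is empty")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2 || hdr[1] != "h") {
    stop("network file line 1: expected header 'h <cm>'")
  }
  h <- as.numeric(hdr[2])
  nodes <- list()
  edges <- list()
  for (r in seq_along(lines)[-1]) {
    f <- strsplit(trimws(lines[r]), "\\s+")[[1]]
    if (length(f) == 4) {
      id <- suppressWarnings(as.integer(f[1]))
      xyz <- suppressWarnings(as.numeric(f[2:4]))
      if (is.na(id) || anyNA(xyz)) {
        stop(sprintf("network file line %d: unparseable node line", r))
      }
      if (length(edges)) {
        stop(sprintf("network file line %d: node line after edge lines", r))
      }
      nodes[[id]] <- xyz
    } else if (length(f) == 3) {
      pcs <- suppressWarnings(as.numeric(f))
      if (anyNA(pcs)) {
        stop(sprintf("network file line %d: unparseable edge line", r))
      }
      edges[[length(edges) + 1]] <- pcs
    } else {
      stop(sprintf("network file line %d: expected 3 or 4 fields, got %d",
                   r, length(f)))
    }
  }
  if (!length(nodes)) stop("network file contains no nodes")
  nodes <- do.call(rbind, nodes)
  edges <- if (length(edges)) {
    e <- do.call(rbind, edges)
    data.frame(parent = as.integer(e[, 1]), child = as.integer(e[, 2]),
               sigma = e[, 3])
  } else {
    data.frame(parent = integer(0), child = integer(0), sigma = numeric(0))
  }
  purkinje_network(nodes, edges, h)
}

#' @export
print.cartesian_grid <- function(x, ...) {
  cat(sprintf(
    "cartesian_grid: %d volumes, h = %g cm, extent %s cm, tags: %s\n",
    nrow(x$index), x$h, paste(signif(x$extent, 6), collapse = " x "),
    paste(unique(x$tag), collapse = ", ")
  ))
  invisible(x)
}

#' @export
print.purkinje_network <- function(x, ...) {
  cat(sprintf(
    "purkinje_network: %d volumes, h = %g cm, %d terminal(s), root at node %d\n",
    nrow(x$nodes), x$h, length(x$terminals), x$root
  ))
  invisible(x)
}

#' @export
print.pmj_map <- function(x, ...) {
  cat(sprintf(
    "pmj_map: %d terminal(s), N_PMJ = %d, R_PMJ = %g kOhm\n",
    length(x$terminals), x$N_PMJ, x$R_PMJ
  ))
  invisible(x)
}
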