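# Pseudo-ECG over an unbounded homogeneous volume conductor.
#
# The extracellular potential at an electrode is the 1/||r||-weighted sum of
# the diffusion source term: phi_e = (1 / 4 pi sigma_b) * sum_i (div(sigma
# grad V))_i / ||r_i||, with the discrete volume-integrated source taken from
# the stiffness operator of the PDE solve (available at every timestep).

#' Define a pseudo-ECG lead set
#'
#' @param labels electrode names.
#' @param positions numeric matrix (n x 3) of electrode coordinates, cm.
#' @param sigma_b bath conductivity, mS/cm.
#' @return a `lead_set`.
#' @export
lead_set <- function(labels, positions, sigma_b = 1) {
  if (!is.matrix(positions)) positions <- matrix(positions, ncol = 3)
  stopifnot(length(labels) == nrow(positions), sigma_b > 0)
  structure(
    list(
      electrodes = data.frame(
        label = labels, x = positions[, 1], y = positions[, 2],
        z = positions[, 3], stringsAsFactors = FALSE
      ),
      sigma_b = sigma_b
    ),
    class = "lead_set"
  )
}

#' Compute pseudo-ECG electrode potentials
#'
#' Evaluates the unbounded-volume-conductor potential at each electrode from
#' the current myocardial potential field. The discrete source for volume i
#' is `-(K V)_i`, the volume integral of `div(sigma grad V)` produced by the
#' finite-volume stiffness operator, so a spatially uniform V yields exactly
#' zero at every electrode.
#'
#' @param systemK stiffness operator `K` of the myocardial system (the `K`
#'   field of a `monodomain_system`).
#' @param V_M myocardial potential vector, mV.
#' @param grid the `cartesian_grid` the operator was assembled on.
#' @param leads a `lead_set`; every electrode must lie outside all volumes
#'   (distance to every volume center > h/2).
#' @return numeric vector of per-lead potentials (arbitrary units,
#'   mV cm^2 mS/cm scaling).
#' @export
compute_pseudo_ecg <- function(systemK, V_M, grid, leads) {
  stopifnot(inherits(leads, "lead_set"))
  src <- -as.numeric(systemK %*% V_M)
  pos <- as.matrix(leads$electrodes[, c("x", "y", "z")])
  out <- numeric(nrow(pos))
  for (e in seq_len(nrow(pos))) {
    r <- sqrt((grid$centers[, 1] - pos[e, 1])^2 +
                (grid$centers[, 2] - pos[e, 2])^2 +
                (grid$centers[, 3] - pos[e, 3])^2)
    if (any(r < grid$h / 2)) {
      stop(sprintf(
        "electrode '%s' lies inside a tissue volume (min distance %.4g cm < h/2)",
        leads$electrodes$label[e], min(r)
      ))
    }
    out[e] <- sum(src / r) / (4 * pi * leads$sigma_b)
  }
  names(out) <- leads$electrodes$label
  out
}

#' Pearson correlation between simulated and reference ECG traces
#'
#' @param sim numeric matrix (time x leads) of simulated traces.
#' @param reference matrix of the same shape.
#' @return `list(per_lead, mean)`; a zero-variance lead is flagged with an
#'   `NA` correlation and excluded from the unweighted mean.
#' @export
correlate_ecg <- function(sim, reference) {
  if (!is.matrix(sim)) sim <- as.matrix(sim)
  if (!is.matrix(reference)) reference <- as.matrix(reference)
  if (!all(dim(sim) == dim(reference))) {
    stop("simulated and reference traces must have identical dimensions")
  }
  if (nrow(sim) < 2) stop("traces must contain at least 2 samples")
  per <- vapply(seq_len(ncol(sim)), function(l) {
    if (stats::sd(sim[, l]) == 0 || stats::sd(reference[, l]) == 0) {
      NA_real_
    } else {
      stats::cor(sim[, l], reference[, l])
    }
  }, numeric(1))
  if (!is.null(colnames(sim))) names(per) <- colnames(sim)
  list(per_lead = per, mean = mean(per, na.rm = TRUE))
}
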