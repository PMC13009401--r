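# Sparse iterative solvers with an explicit convergence contract.
#
# The backward-Euler diffusion systems assembled by the monodomain module are
# symmetric positive definite, so conjugate gradients with Jacobi
# preconditioning is the workhorse; BiCG is available for operators whose
# assembly asymmetry exceeds the symmetrisation tolerance.

new_solve_report <- function(method, iterations, residual, residual_prec,
                             converged, reason = NA_character_) {
  structure(
    list(
      method = method, iterations = iterations, residual = residual,
      residual_preconditioned = residual_prec, converged = converged,
      reason = reason
    ),
    class = "solve_report"
  )
}

#' @export
print.solve_report <- function(x, ...) {
  cat(sprintf(
    "%s: %s in %d iteration(s), residual %.3e (preconditioned %.3e)%s\n",
    x$method, if (x$converged) "converged" else "NOT converged",
    x$iterations, x$residual, x$residual_preconditioned,
    if (is.na(x$reason)) "" else paste0(" [", x$reason, "]")
  ))
  invisible(x)
}

#' Preconditioned conjugate gradient solve
#'
#' Solves `A x = b` for symmetric positive definite `A` (dense or sparse
#' `Matrix`). Convergence is declared when both the raw and the
#' preconditioned relative residual norms fall below `tol`; both norms are
#' reported.
#'
#' @param A symmetric matrix or `Matrix` sparse matrix.
#' @param b right-hand side vector.
#' @param tol relative residual tolerance.
#' @param maxit iteration cap.
#' @param preconditioner `"jacobi"` (default) or `"none"`.
#' @param x0 optional initial guess (warm start).
#' @return `list(x = solution, report = solve_report)`.
#' @export
cg_solve <- function(A, b, tol = 1e-10, maxit = 5000,
                     preconditioner = c("jacobi", "none"), x0 = NULL) {
  preconditioner <- match.arg(preconditioner)
  n <- length(b)
  if (nrow(A) != n || ncol(A) != n) {
    stop(sprintf("dimension mismatch: A is %d x %d, b has length %d",
                 nrow(A), ncol(A), n))
  }
  minv <- if (preconditioner == "jacobi") {
    d <- as.numeric(Matrix::diag(A))
    if (any(d == 0)) {
      preconditioner <- "none"
      rep(1, n)
    } else {
      1 / d
    }
  } else {
    rep(1, n)
  }
  bnorm <- sqrt(sum(b^2))
  bnorm_p <- sqrt(sum(b * minv * b))
  if (bnorm == 0) {
    return(list(x = numeric(n), report = new_solve_report(
      "cg", 0L, 0, 0, TRUE
    )))
  }
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  r <- b - as.numeric(A %*% x)
  z <- minv * r
  p <- z
  rz <- sum(r * z)
  rnorm <- sqrt(sum(r^2))
  rnorm_p <- sqrt(rz)
  it <- 0L
  reason <- NA_character_
  while ((rnorm > tol * bnorm || rnorm_p > tol * bnorm_p) && it < maxit) {
    Ap <- as.numeric(A %*% p)
    pAp <- sum(p * Ap)
    if (!is.finite(pAp) || pAp <= 0) {
      reason <- sprintf("breakdown: p'Ap = %g (operator not SPD?)", pAp)
      break
    }
    alpha <- rz / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- minv * r
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
    rnorm <- sqrt(sum(r^2))
    rnorm_p <- sqrt(max(rz, 0))
    it <- it + 1L
  }
  converged <- is.na(reason) && rnorm <= tol * bnorm && rnorm_p <= tol * bnorm_p
  if (!converged && is.na(reason)) reason <- "maxit reached"
  list(x = x, report = new_solve_report(
    "cg", it, rnorm / bnorm, rnorm_p / max(bnorm_p, .Machine$double.xmin),
    converged, reason
  ))
}

#' Biconjugate gradient solve
#'
#' As [cg_solve()] but without the symmetry precondition; used when the
#' assembled operator's asymmetry exceeds the symmetrisation tolerance.
#'
#' @inheritParams cg_solve
#' @return `list(x = solution, report = solve_report)`.
#' @export
bicg_solve <- function(A, b, tol = 1e-10, maxit = 5000, x0 = NULL) {
  n <- length(b)
  if (nrow(A) != n || ncol(A) != n) {
    stop(sprintf("dimension mismatch: A is %d x %d, b has length %d",
                 nrow(A), ncol(A), n))
  }
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) {
    return(list(x = numeric(n), report = new_solve_report(
      "bicg", 0L, 0, 0, TRUE
    )))
  }
  At <- Matrix::t(A)
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  r <- b - as.numeric(A %*% x)
  rt <- r
  p <- r
  pt <- rt
  rr <- sum(rt * r)
  rnorm <- sqrt(sum(r^2))
  it <- 0L
  reason <- NA_character_
  while (rnorm > tol * bnorm && it < maxit) {
    Ap <- as.numeric(A %*% p)
    ptAp <- sum(pt * Ap)
    if (!is.finite(ptAp) || abs(ptAp) < .Machine$double.xmin) {
      reason <- "breakdown: pt'Ap vanished"
      break
    }
    alpha <- rr / ptAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    rt <- rt - alpha * as.numeric(At %*% pt)
    rr_new <- sum(rt * r)
    if (!is.finite(rr_new)) {
      reason <- "breakdown: non-finite inner product"
      break
    }
    if (abs(rr) < .Machine$double.xmin) {
      reason <- "breakdown: rt'r vanished"
      break
    }
    beta <- rr_new / rr
    rr <- rr_new
    p <- r + beta * p
    pt <- rt + beta * pt
    rnorm <- sqrt(sum(r^2))
    it <- it + 1L
  }
  converged <- is.na(reason) && rnorm <= tol * bnorm && is.finite(rnorm)
  if (!converged && is.na(reason)) reason <- "maxit reached"
  list(x = x, report = new_solve_report(
    "bicg", it, rnorm / bnorm, rnorm / bnorm, converged, reason
  ))
}
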