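# Variational optical flow with the Charbonnier penalty.
#
# The velocity field w = (u, v) between consecutive frames minimises
#
#   E[u, v] = sum  rho(Ed^2) + alpha * rho(Es^2),
#   Ed = Dx u + Dy v + Dt,   Es^2 = |grad u|^2 + |grad v|^2,
#   rho(s) = sqrt(s + beta^2),
#
# whose Euler-Lagrange equations are solved by lagged-nonlinearity fixed
# point iteration: with rho_d = rho'(Ed^2)/alpha and rho_s = rho'(Es^2)
# frozen, the remaining problem is linear in (u, v) and is solved exactly as
# a sparse system; rho_d and rho_s are then refreshed and the process
# repeats until the relative update is below tolerance.
# rho'(s) = 1 / (2 sqrt(s + beta^2)), the analytic derivative of rho.
# For beta >> 1 rho' is effectively constant and the solution coincides with
# the classical quadratic-penalty (Horn-Schunck) flow.

circ_diff <- function(a, b) {
  # circular subtraction a (-) b into (-pi, pi]
  d <- (a - b + pi) %% (2 * pi) - pi
  d[d == -pi] <- pi
  d
}

# shift a matrix by (dr, dc) with replicate boundary
shift_rep <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# 1D derivative along dimension `along` (1 = rows/y, 2 = cols/x).
# Linear data: five-point stencil (1/12)[-1, 8, 0, -8, 1] in the interior,
# centred differences one point from the edge, forward/backward at the edge.
# Circular (phase) data: wraps at +/-pi invalidate the wide stencil pair
# (its span of 4 grid spaces can exceed half a cycle), so centred circular
# differences are used throughout the interior, forward/backward circular
# differences at the edges.
deriv_1d <- function(m, along, circular) {
  if (along == 2L) return(t(deriv_1d(t(m), 1L, circular)))
  n <- nrow(m)
  dd <- if (circular) circ_diff else function(a, b) a - b
  out <- matrix(0, n, ncol(m))
  if (!circular && n >= 5L) {
    i <- 3:(n - 2)
    out[i, ] <- (8 * dd(m[i + 1, , drop = FALSE], m[i - 1, , drop = FALSE]) -
                   dd(m[i + 2, , drop = FALSE], m[i - 2, , drop = FALSE])) / 12
    ctr <- c(2L, n - 1L)
  } else {
    ctr <- if (n >= 3L) 2:(n - 1L) else integer(0)
  }
  for (i in ctr)
    out[i, ] <- dd(m[i + 1, , drop = FALSE], m[i - 1, , drop = FALSE]) / 2
  out[1, ] <- dd(m[2, , drop = FALSE], m[1, , drop = FALSE])
  out[n, ] <- dd(m[n, , drop = FALSE], m[n - 1, , drop = FALSE])
  out
}

#' Spatial derivatives of a frame
#'
#' Five-point-stencil spatial derivatives `(Dx, Dy)` of a 2D scalar field;
#' `x` is the column direction, `y` the row direction.  Near the edges
#' centred then one-sided differences are used.  For phase data all
#' differences are computed with circular subtraction
#' `mod(a - b + pi, 2*pi) - pi` so that wraps at +/-pi do not corrupt the
#' stencil.
#'
#' @param frame numeric matrix (rows = y, cols = x).
#' @param is_phase treat values as angles in radians.
#' @return list with matrices `Dx` and `Dy` (units per grid space).
#' @export
spatial_derivatives <- function(frame, is_phase = FALSE) {
  stopifnot(is.matrix(frame))
  list(Dx = deriv_1d(frame, 2L, is_phase),
       Dy = deriv_1d(frame, 1L, is_phase))
}

#' Temporal derivative between two frames
#'
#' Forward difference `frame_t1 - frame_t` (circular for phase data), in
#' units per time step.
#'
#' @param frame_t,frame_t1 numeric matrices of identical shape.
#' @param is_phase treat values as angles.
#' @return matrix `Dt`.
#' @export
temporal_derivative <- function(frame_t, frame_t1, is_phase = FALSE) {
  if (!all(dim(frame_t) == dim(frame_t1))) stop("frame shape mismatch")
  if (is_phase) circ_diff(frame_t1, frame_t) else frame_t1 - frame_t
}

# centred-difference gradient with replicate boundary (plain, not circular:
# applied to u, v and rho_s which are ordinary fields)
grad_centred <- function(m) {
  gx <- (shift_rep(m, 0L, 1L) - shift_rep(m, 0L, -1L)) / 2
  gy <- (shift_rep(m, 1L, 0L) - shift_rep(m, -1L, 0L)) / 2
  list(gx = gx, gy = gy)
}

# Precomputed assembly structure for the 2n x 2n Euler-Lagrange system.
#
# The smoothness term -div(rho_s grad .) is discretised in divergence
# (flux) form with face-averaged diffusivities: symmetric positive
# semidefinite with replicate (Neumann) boundary, the stable
# discretisation for the lagged-nonlinearity iteration (to second order it
# equals the expanded rho_s Laplacian + grad(rho_s).grad form).  The full
# system (smoothness blocks for u and v plus the data-term diagonals and
# u-v coupling) has a fixed sparsity pattern, so triplet indices are built
# once and only the values are refreshed per iteration.
flow_operators <- function(nr, nc) {
  n <- nr * nc
  idx <- matrix(seq_len(n), nr, nc)
  # horizontal and vertical lattice edges, each once
  e_i <- c(as.vector(idx[, -nc]), as.vector(idx[-nr, ]))
  e_j <- c(as.vector(idx[, -1L]), as.vector(idx[-1L, ]))
  dg <- seq_len(n)
  # per block: off-diagonals (i,j) and (j,i), edge-sum diagonal entries
  # (i,i) and (j,j) (duplicates are summed by the triplet->CSC coercion),
  # then the data-term diagonal; cross blocks couple u and v
  blk <- function(off) c(e_i + off, e_j + off, e_i + off, e_j + off, dg + off)
  i_all <- c(blk(0L), blk(n), dg, n + dg)
  j_all <- c(e_j, e_i, e_i, e_j, dg,
             e_j + n, e_i + n, e_i + n, e_j + n, dg + n,
             n + dg, dg)
  list(n = n, n_edge = length(e_i), edge_i = e_i, edge_j = e_j,
       i_all = i_all, j_all = j_all)
}

# numeric values matching flow_operators()$i_all/j_all
flow_system_values <- function(ops, rho_s, rho_d, Dx, Dy, eps = 1e-12) {
  w <- (rho_s[ops$edge_i] + rho_s[ops$edge_j]) / 2
  sm <- c(-w, -w, w, w)
  c(sm, rho_d * Dx * Dx + eps,
    sm, rho_d * Dy * Dy + eps,
    rho_d * Dx * Dy, rho_d * Dx * Dy)
}

charbonnier <- function(s, beta) sqrt(s + beta^2)
charbonnier_deriv <- function(s, beta) 1 / (2 * sqrt(s + beta^2))

flow_energy <- function(u, v, Dx, Dy, Dt, alpha, beta) {
  Ed <- Dx * u + Dy * v + Dt
  gu <- grad_centred(u); gv <- grad_centred(v)
  Es2 <- gu$gx^2 + gu$gy^2 + gv$gx^2 + gv$gy^2
  sum(charbonnier(Ed^2, beta)) + alpha * sum(charbonnier(Es2, beta))
}

#' Optical flow between two frames
#'
#' Estimates the velocity field `(u, v)` (grid spaces per time step) carrying
#' `frame_t` onto `frame_t1` by minimising the Charbonnier-penalised
#' data-constancy-plus-smoothness functional.  The nonlinearity is handled
#' by fixed-point iteration: the penalty-derivative weights are frozen, the
#' resulting linear Euler-Lagrange system over all sites is solved exactly
#' (sparse LU), and the weights are refreshed until the relative update of
#' the field falls below `tol`.
#'
#' @param frame_t,frame_t1 numeric matrices of identical shape (>= 2x2).
#' @param alpha smoothness weight (> 0); larger values give smoother,
#'   eventually uniform fields.  Default 0.1.
#' @param beta Charbonnier constant (> 0); `beta >> 1` reduces to the
#'   quadratic (Horn-Schunck) penalty.  Default 10.
#' @param is_phase use circular derivatives (input in radians).
#' @param tol relative L2 update for convergence (default 1e-6).
#' @param max_iter outer iteration cap (default 500).
#' @param init optional list `(u, v)` warm start.
#' @return list with matrices `u`, `v`, iteration count `n_iter`, final
#'   relative update `residual`, `converged` flag, and the energy trace
#'   `energy` of the discrete functional across outer iterations.
#' @export
solve_flow_frame <- function(frame_t, frame_t1, alpha = 0.1, beta = 10,
                             is_phase = FALSE, tol = 1e-6, max_iter = 500L,
                             init = NULL, ops = NULL) {
  if (!all(dim(frame_t) == dim(frame_t1))) stop("frame shape mismatch")
  if (!all(is.finite(frame_t)) || !all(is.finite(frame_t1)))
    stop("frames must be finite")
  if (alpha <= 0) stop("alpha must be > 0")
  if (beta <= 0) stop("beta must be > 0")
  nr <- nrow(frame_t); nc <- ncol(frame_t); n <- nr * nc
  sd_ <- spatial_derivatives(frame_t, is_phase)
  Dx <- as.vector(sd_$Dx); Dy <- as.vector(sd_$Dy)
  Dt <- as.vector(temporal_derivative(frame_t, frame_t1, is_phase))
  if (is.null(ops)) ops <- flow_operators(nr, nc)
  u <- if (is.null(init)) numeric(n) else as.vector(init$u)
  v <- if (is.null(init)) numeric(n) else as.vector(init$v)
  energy <- numeric(0)
  n_iter <- 0L; rel <- Inf
  chol_cache <- NULL
  for (it in seq_len(max_iter)) {
    n_iter <- it
    Ed <- Dx * u + Dy * v + Dt
    gu <- grad_centred(matrix(u, nr, nc)); gv <- grad_centred(matrix(v, nr, nc))
    Es2 <- as.vector(gu$gx^2 + gu$gy^2 + gv$gx^2 + gv$gy^2)
    rho_d <- charbonnier_deriv(Ed^2, beta) / alpha
    rho_s <- charbonnier_deriv(Es2, beta)
    energy <- c(energy,
                flow_energy(matrix(u, nr, nc), matrix(v, nr, nc),
                            matrix(Dx, nr, nc), matrix(Dy, nr, nc),
                            matrix(Dt, nr, nc), alpha, beta))
    A <- Matrix::sparseMatrix(
      i = ops$i_all, j = ops$j_all,
      x = flow_system_values(ops, rho_s, rho_d, Dx, Dy),
      dims = c(2L * n, 2L * n), symmetric = FALSE)
    A <- Matrix::forceSymmetric(A, uplo = "L")
    b <- c(-rho_d * Dx * Dt, -rho_d * Dy * Dt)
    if (is.null(chol_cache)) {
      chol_cache <- Matrix::Cholesky(A, LDL = FALSE, super = TRUE)
    } else {
      chol_cache <- Matrix::update(chol_cache, A)
    }
    sol <- as.vector(Matrix::solve(chol_cache, b, system = "A"))
    un <- sol[seq_len(n)]; vn <- sol[n + seq_len(n)]
    num <- sqrt(sum((un - u)^2 + (vn - v)^2))
    den <- sqrt(sum(un^2 + vn^2))
    rel <- if (den > 0) num / den else num
    u <- un; v <- vn
    if (rel < tol) break
  }
  energy <- c(energy,
              flow_energy(matrix(u, nr, nc), matrix(v, nr, nc),
                          matrix(Dx, nr, nc), matrix(Dy, nr, nc),
                          matrix(Dt, nr, nc), alpha, beta))
  list(u = matrix(u, nr, nc), v = matrix(v, nr, nc),
       n_iter = n_iter, residual = rel, converged = rel < tol,
       energy = energy)
}

#' Velocity field series for a whole recording
#'
#' Applies [solve_flow_frame()] to every consecutive frame pair of every
#' trial, warm-starting each solve from the previous time step's field.
#' Field `t` maps frame `t` onto frame `t + 1`, so there is one fewer time
#' step than frames.
#'
#' @param data numeric 3D array (row, col, time) or 4D (row, col, time,
#'   trial), e.g. a phase or amplitude field from [split_phase_amplitude()].
#' @param alpha,beta,is_phase,tol,max_iter see [solve_flow_frame()].
#' @return an object of class `velocity_field_series`: arrays `u`, `v` of
#'   shape (row, col, time-step, trial), parameter record, and per-step
#'   solver diagnostics `n_iter`, `residual`, `converged`.
#' @export
compute_velocity_fields <- function(data, alpha = 0.1, beta = 10,
                                    is_phase = FALSE, tol = 1e-6,
                                    max_iter = 500L) {
  d <- dim(data)
  if (length(d) == 3L) { dim(data) <- d <- c(d, 1L) }
  stopifnot(length(d) == 4L, d[3] >= 2L)
  nt <- d[3] - 1L
  u <- array(0, c(d[1], d[2], nt, d[4]))
  v <- array(0, c(d[1], d[2], nt, d[4]))
  n_iter <- matrix(0L, nt, d[4])
  residual <- matrix(0, nt, d[4])
  converged <- matrix(TRUE, nt, d[4])
  ops <- flow_operators(d[1], d[2])
  for (p in seq_len(d[4])) {
    init <- NULL
    for (t in seq_len(nt)) {
      sol <- solve_flow_frame(data[, , t, p], data[, , t + 1L, p],
                              alpha = alpha, beta = beta, is_phase = is_phase,
                              tol = tol, max_iter = max_iter, init = init,
                              ops = ops)
      u[, , t, p] <- sol$u; v[, , t, p] <- sol$v
      n_iter[t, p] <- sol$n_iter
      residual[t, p] <- sol$residual
      converged[t, p] <- sol$converged
      init <- sol
    }
  }
  structure(list(u = u, v = v, alpha = alpha, beta = beta,
                 is_phase = is_phase, n_iter = n_iter, residual = residual,
                 converged = converged),
            class = "velocity_field_series")
}

#' @export
print.velocity_field_series <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf(
    "<velocity_field_series> %d x %d grid, %d step(s), %d trial(s), alpha = %g, beta = %g\n",
    d[1], d[2], d[3], d[4], x$alpha, x$beta))
  if (any(!x$converged))
    cat(sprintf("  warning: %d step(s) did not converge\n", sum(!x$converged)))
  invisible(x)
}
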