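# Shared fixtures: analytic vector fields and phase movies built in code.

# coordinate matrices for an nr x nc grid (0-based, x = cols, y = rows)
grid_xy <- function(nr, nc) {
  list(x = outer(rep(1, nr), 0:(nc - 1)),
       y = outer(0:(nr - 1), rep(1, nc)))
}

# linear critical-point fields centred at (cx, cy)
field_source <- function(nr = 12, nc = 12, cx = 5.5, cy = 5.5) {
  g <- grid_xy(nr, nc)
  list(u = g$x - cx, v = g$y - cy)
}
field_saddle <- function(nr = 12, nc = 12, cx = 5.5, cy = 5.5) {
  g <- grid_xy(nr, nc)
  list(u = g$x - cx, v = -(g$y - cy))
}
field_rotation <- function(nr = 12, nc = 12, cx = 5.5, cy = 5.5) {
  g <- grid_xy(nr, nc)
  list(u = -(g$y - cy), v = g$x - cx)
}
field_uniform <- function(nr = 12, nc = 12, u0 = 1, v0 = 0) {
  list(u = matrix(u0, nr, nc), v = matrix(v0, nr, nc))
}

# wrapped plane-wave phase frame theta = k*x - w*t
phase_plane_frame <- function(t, k = 2 * pi / 5, w = 2 * pi * 0.01,
                              nr = 12, nc = 12, angle = 0) {
  g <- grid_xy(nr, nc)
  s <- g$x * cos(angle) + g$y * sin(angle)
  ((k * s - w * t) + pi) %% (2 * pi) - pi
}

# smooth Gaussian bump frame, centre (cx, cy)
bump_frame <- function(cx, cy, nr = 15, nc = 15, width2 = 8) {
  g <- grid_xy(nr, nc)
  exp(-((g$x - cx)^2 + (g$y - cy)^2) / width2)
}

# total variation of a vector field (sum of absolute neighbour differences)
field_total_variation <- function(u, v) {
  tv <- function(m) sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
  tv(u) + tv(v)
}

# independent dense Horn-Schunck (quadratic penalty) solver used as the
# closed-form oracle for the beta -> Inf limit.  Same discretisation
# definitions as the package but assembled naively with dense algebra.
hs_closed_form <- function(frame_t, frame_t1, alpha, is_phase = FALSE) {
  nr <- nrow(frame_t); nc <- ncol(frame_t); n <- nr * nc
  sd_ <- spatial_derivatives(frame_t, is_phase)
  Dx <- as.vector(sd_$Dx); Dy <- as.vector(sd_$Dy)
  Dt <- as.vector(temporal_derivative(frame_t, frame_t1, is_phase))
  idx <- matrix(seq_len(n), nr, nc)
  S <- matrix(0, n, n)
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    i <- idx[rr, cc]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- rr + d[1]; c2 <- cc + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      j <- idx[r2, c2]
      S[i, j] <- S[i, j] - 1
      S[i, i] <- S[i, i] + 1
    }
  }
  A <- rbind(cbind(S + diag(Dx * Dx / alpha), diag(Dx * Dy / alpha)),
             cbind(diag(Dx * Dy / alpha), S + diag(Dy * Dy / alpha)))
  b <- c(-Dx * Dt / alpha, -Dy * Dt / alpha)
  sol <- solve(A + diag(1e-12, 2 * n), b)
  list(u = matrix(sol[seq_len(n)], nr, nc),
       v = matrix(sol[n + seq_len(n)], nr, nc))
}

# relative L2 difference between two fields
rel_l2 <- function(a, b) {
  sqrt(sum((a$u - b$u)^2 + (a$v - b$v)^2)) /
    sqrt(sum(b$u^2 + b$v^2))
}

# run the per-frame detector over a velocity field series, optional extent
# filter (the toolbox default Lradius)
detect_series <- function(vf, Lradius = 0, Ledge = 2) {
  lapply(seq_len(dim(vf$u)[3]), function(t) {
    d <- detect_critical_points_frame(vf$u[, , t, 1], vf$v[, , t, 1],
                                      Ledge = Ledge)
    d[d$extent >= Lradius, , drop = FALSE]
  })
}

# one full scaled benchmark run: random two-pattern spec -> phase movie ->
# flow -> detection -> accuracy metrics
fig_benchmark_run <- function(seed, alpha, beta, noise, Lradius = 2,
                              tol = 1e-4) {
  specs <- random_fig_spec(seed = seed)
  sim <- simulate_patterns(specs, grid = attr(specs, "grid"),
                           n_steps = attr(specs, "n_steps"),
                           noise_sigma_rel = noise, seed = seed + 1000L)
  vf <- compute_velocity_fields(sim$phase, alpha = alpha, beta = beta,
                                is_phase = TRUE, tol = tol)
  det <- detect_series(vf, Lradius = Lradius)
  evaluate_detection(sim$truth[sim$truth$t <= length(det), ], det,
                     match_radius = 2)
}
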