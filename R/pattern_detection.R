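# Per-time-step pattern detection: critical points of the velocity field,
# their Jacobian classification, spatial extent by winding number, and the
# global plane-wave / synchrony order parameters.
#
# Coordinates are 0-based continuous grid units: a point (x, y) lies at
# column x, row y; grid nodes sit at integer coordinates.

#' Locate critical points of a velocity field
#'
#' Finds all points where `u = v = 0` by intersecting, within each unit grid
#' cell, the bilinearly interpolated zero-level curves of `u` and `v`.  The
#' bilinear system reduces to a quadratic per cell; both roots are tested
#' for membership in the cell.  Detections closer than `merge_dist` grid
#' spaces are merged (mean position).
#'
#' @param u,v numeric matrices of identical shape (rows = y, cols = x).
#' @param merge_dist duplicate-merging radius in grid spaces (default 0.1).
#' @return data.frame with columns `x`, `y` (0-based continuous grid
#'   coordinates); zero rows if the field has no zeros.
#' @export
find_critical_points <- function(u, v, merge_dist = 0.1) {
  stopifnot(all(dim(u) == dim(v)), all(is.finite(u)), all(is.finite(v)))
  nr <- nrow(u); nc <- ncol(u)
  tol <- 1e-9
  pts <- list()
  for (cc in seq_len(nc - 1L)) for (rr in seq_len(nr - 1L)) {
    # local cell coords: xi along x (cols), eta along y (rows), both in [0,1]
    a0 <- u[rr, cc]
    a1 <- u[rr, cc + 1L] - a0
    a2 <- u[rr + 1L, cc] - a0
    a3 <- u[rr, cc] - u[rr, cc + 1L] - u[rr + 1L, cc] + u[rr + 1L, cc + 1L]
    b0 <- v[rr, cc]
    b1 <- v[rr, cc + 1L] - b0
    b2 <- v[rr + 1L, cc] - b0
    b3 <- v[rr, cc] - v[rr, cc + 1L] - v[rr + 1L, cc] + v[rr + 1L, cc + 1L]
    # eliminate eta: quadratic A xi^2 + B xi + C = 0
    A <- a3 * b1 - a1 * b3
    B <- a3 * b0 + a2 * b1 - a1 * b2 - a0 * b3
    C <- a2 * b0 - a0 * b2
    if (abs(A) < tol) {
      roots <- if (abs(B) < tol) numeric(0) else -C / B
    } else {
      disc <- B^2 - 4 * A * C
      if (disc < 0) next
      sq <- sqrt(disc)
      roots <- c((-B + sq) / (2 * A), (-B - sq) / (2 * A))
    }
    for (xi in roots) {
      if (!is.finite(xi) || xi < -tol || xi > 1 + tol) next
      den_u <- a2 + a3 * xi
      den_v <- b2 + b3 * xi
      eta <- if (abs(den_u) >= abs(den_v)) {
        if (abs(den_u) < tol) next else -(a0 + a1 * xi) / den_u
      } else -(b0 + b1 * xi) / den_v
      if (!is.finite(eta) || eta < -tol || eta > 1 + tol) next
      # verify both fields vanish (guards the eliminated equation)
      uval <- a0 + a1 * xi + a2 * eta + a3 * xi * eta
      vval <- b0 + b1 * xi + b2 * eta + b3 * xi * eta
      if (abs(uval) > 1e-6 || abs(vval) > 1e-6) next
      pts[[length(pts) + 1L]] <- c(cc - 1L + xi, rr - 1L + eta)
    }
  }
  if (length(pts) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0)))
  m <- do.call(rbind, pts)
  # merge duplicates (cell-edge intersections found from both sides)
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(m))) {
      if (j <= i || !keep[j]) next
      if (sqrt(sum((m[i, ] - m[j, ])^2)) < merge_dist) {
        m[i, ] <- (m[i, ] + m[j, ]) / 2
        keep[j] <- FALSE
      }
    }
  }
  m <- m[keep, , drop = FALSE]
  data.frame(x = m[, 1], y = m[, 2])
}

#' Jacobian of the velocity field at a point
#'
#' The four partial derivatives are computed by centred differences at the
#' four grid nodes surrounding `pos` and bilinearly interpolated to `pos`.
#'
#' @param u,v velocity component matrices.
#' @param pos numeric `c(x, y)`, 0-based continuous grid coordinates; must
#'   be at least one grid space from the boundary so the centred stencil
#'   fits around every corner of the enclosing cell.
#' @return 2x2 matrix `J = [[du/dx, du/dy], [dv/dx, dv/dy]]`.
#' @export
jacobian_at <- function(u, v, pos) {
  nr <- nrow(u); nc <- ncol(u)
  x <- pos[1]; y <- pos[2]
  cx <- floor(x); cy <- floor(y)
  if (cx >= nc - 1L) cx <- nc - 2L
  if (cy >= nr - 1L) cy <- nr - 2L
  # corners need centred differences: indices cx..cx+1 in 0-based must have
  # both neighbours, i.e. cx >= 1 and cx + 1 <= nc - 2
  if (cx < 1L || cx + 1L > nc - 2L || cy < 1L || cy + 1L > nr - 2L)
    stop("position too close to the boundary for the Jacobian stencil")
  xi <- x - cx; eta <- y - cy
  corner_grad <- function(f, r, c) {
    # r, c are 1-based node indices
    c(dx = (f[r, c + 1L] - f[r, c - 1L]) / 2,
      dy = (f[r + 1L, c] - f[r - 1L, c]) / 2)
  }
  bil <- function(g00, g10, g01, g11)
    g00 * (1 - xi) * (1 - eta) + g10 * xi * (1 - eta) +
    g01 * (1 - xi) * eta + g11 * xi * eta
  r0 <- cy + 1L; c0 <- cx + 1L
  gu00 <- corner_grad(u, r0, c0);      gu10 <- corner_grad(u, r0, c0 + 1L)
  gu01 <- corner_grad(u, r0 + 1L, c0); gu11 <- corner_grad(u, r0 + 1L, c0 + 1L)
  gv00 <- corner_grad(v, r0, c0);      gv10 <- corner_grad(v, r0, c0 + 1L)
  gv01 <- corner_grad(v, r0 + 1L, c0); gv11 <- corner_grad(v, r0 + 1L, c0 + 1L)
  matrix(c(bil(gu00["dx"], gu10["dx"], gu01["dx"], gu11["dx"]),
           bil(gv00["dx"], gv10["dx"], gv01["dx"], gv11["dx"]),
           bil(gu00["dy"], gu10["dy"], gu01["dy"], gu11["dy"]),
           bil(gv00["dy"], gv10["dy"], gv01["dy"], gv11["dy"])),
         2, 2)
}

#' Classify a critical point from its Jacobian
#'
#' Nodes have `det > 0` and `tr^2 >= 4 det`, foci `det > 0` and
#' `tr^2 < 4 det`, saddles `det < 0`.  Under the default (`"paper"`)
#' stability convention, nodes and foci with `tr > 0` are labelled stable
#' and `tr < 0` unstable; `"standard"` inverts the labels to the usual
#' dynamical-systems convention (attracting = stable = `tr < 0`).  In terms
#' of flow geometry `tr > 0` is always outward motion (source / spiral-out)
#' and `tr < 0` inward motion (sink / spiral-in), independent of the naming
#' convention.
#'
#' @param J 2x2 Jacobian matrix.
#' @param stability_convention `"paper"` (default) or `"standard"`.
#' @return list with `cls` (one of `stable_node`, `unstable_node`,
#'   `stable_focus`, `unstable_focus`, `saddle`, `degenerate`), `tau`
#'   (trace), `delta` (determinant), and `motion` (`"outward"`, `"inward"`,
#'   `"saddle"`, `"neutral"` or `"degenerate"`).
#' @export
classify_critical_point <- function(J,
                                    stability_convention = c("paper",
                                                             "standard")) {
  stability_convention <- match.arg(stability_convention)
  stopifnot(all(is.finite(J)))
  tau <- J[1, 1] + J[2, 2]
  delta <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  if (delta == 0)
    return(list(cls = "degenerate", tau = tau, delta = delta,
                motion = "degenerate"))
  if (delta < 0)
    return(list(cls = "saddle", tau = tau, delta = delta, motion = "saddle"))
  # tie tau^2 = 4*delta -> node; compared with a relative tolerance because
  # radially symmetric patterns sit exactly on this boundary and last-bit
  # noise would otherwise flip the class between frames
  boundary_tol <- 1e-6 * max(tau^2, 4 * delta)
  kind <- if (tau^2 >= 4 * delta - boundary_tol) "node" else "focus"
  motion <- if (tau > 0) "outward" else if (tau < 0) "inward" else "neutral"
  stab <- if (tau == 0) {
    "unstable"          # neutral centre, reported unstable with motion flag
  } else if (stability_convention == "paper") {
    if (tau > 0) "stable" else "unstable"
  } else {
    if (tau < 0) "stable" else "unstable"
  }
  list(cls = paste0(stab, "_", kind), tau = tau, delta = delta,
       motion = motion)
}

#' Winding number (Poincare index) along a closed path
#'
#' Sums the circular differences of successive velocity-vector angles around
#' a closed counter-clockwise path and divides by `2*pi`.  The result is +1
#' inside node and focus patterns, -1 inside saddle patterns and 0 when no
#' critical point is enclosed.
#'
#' @param u,v velocity component matrices.
#' @param path integer matrix or data.frame with columns `x`, `y` of 0-based
#'   grid-node coordinates forming a closed counter-clockwise loop (the
#'   closing edge back to the first point is implicit).
#' @return nearest integer winding number; the raw value is attached as
#'   attribute `"raw"`.
#' @export
winding_number <- function(u, v, path) {
  path <- as.matrix(path)
  n <- nrow(path)
  stopifnot(n >= 3L)
  ang <- numeric(n)
  for (k in seq_len(n)) {
    r <- path[k, 2] + 1L; c <- path[k, 1] + 1L
    uv <- c(u[r, c], v[r, c])
    if (uv[1] == 0 && uv[2] == 0)
      stop(sprintf("zero-magnitude vector on path at (x=%d, y=%d)",
                   path[k, 1], path[k, 2]))
    ang[k] <- atan2(uv[2], uv[1])
  }
  dsum <- sum(circ_diff(ang[c(2:n, 1L)], ang))
  w <- dsum / (2 * pi)
  out <- as.integer(round(w))
  attr(out, "raw") <- w
  out
}

# grid sites whose rounded distance to `centre` equals r, ordered CCW;
# NULL if the ring has < 3 sites or touches outside the grid
ring_sites <- function(centre, r, nr, nc) {
  x0 <- centre[1]; y0 <- centre[2]
  xr <- seq.int(max(0L, floor(x0 - r - 1)), min(nc - 1L, ceiling(x0 + r + 1)))
  yr <- seq.int(max(0L, floor(y0 - r - 1)), min(nr - 1L, ceiling(y0 + r + 1)))
  g <- expand.grid(x = xr, y = yr)
  d <- sqrt((g$x - x0)^2 + (g$y - y0)^2)
  sel <- round(d) == r
  # the ring band [r - 0.5, r + 0.5] must lie strictly inside the grid;
  # a ring touching the boundary terminates the extent search
  if (x0 - (r + 0.5) <= 0 || x0 + (r + 0.5) >= nc - 1 ||
      y0 - (r + 0.5) <= 0 || y0 + (r + 0.5) >= nr - 1)
    return(NULL)
  g <- g[sel, , drop = FALSE]
  if (nrow(g) < 3L) return(NULL)
  ang <- atan2(g$y - y0, g$x - x0)
  g[order(ang), , drop = FALSE]
}

#' Approximately circular closed path around a point
#'
#' Returns the grid sites whose rounded Euclidean distance to `centre`
#' equals `r`, ordered counter-clockwise by angle — the discretised ring
#' used for winding-number evaluation and extent measurement.
#'
#' @param centre numeric `c(x, y)` in 0-based grid coordinates.
#' @param r ring radius in grid spaces.
#' @param nrow,ncol grid dimensions.
#' @return data.frame with columns `x`, `y`, or `NULL` if the ring band
#'   `[r - 0.5, r + 0.5]` does not fit strictly inside the grid or has
#'   fewer than 3 sites.
#' @export
ring_path <- function(centre, r, nrow, ncol) ring_sites(centre, r, nrow, ncol)

#' Spatial extent of a critical-point pattern
#'
#' Evaluates the winding number on discretised, approximately circular paths
#' of radius 1, 2, 3, ... grid spaces around the critical point.  The extent
#' is the largest radius such that every ring up to it returns the index
#' expected for the point's class (+1 for nodes/foci, -1 for saddles).
#' Rings that would extend past the grid boundary terminate the search, as
#' does any ring carrying a zero-magnitude vector.
#'
#' @param u,v velocity component matrices.
#' @param pos numeric `c(x, y)` centre.
#' @param cls class string from [classify_critical_point()] (or `"saddle"`).
#' @param max_radius optional search cap.
#' @return integer extent radius in grid spaces (0 if the first ring fails).
#' @export
pattern_extent <- function(u, v, pos, cls, max_radius = Inf) {
  expected <- if (identical(cls, "saddle")) -1L else 1L
  nr <- nrow(u); nc <- ncol(u)
  extent <- 0L
  r <- 1L
  while (r <= max_radius) {
    ring <- ring_sites(pos, r, nr, nc)
    if (is.null(ring)) break
    wn <- tryCatch(winding_number(u, v, ring), error = function(e) NA_integer_)
    if (is.na(wn) || wn != expected) break
    extent <- r
    r <- r + 1L
  }
  extent
}

#' Plane-wave order parameter
#'
#' `phi = ||sum w|| / sum ||w||` over all sites: 1 when every vector points
#' the same way (coherent planar motion), 0 when vectors cancel.
#'
#' @param u,v velocity component matrices.
#' @return scalar in `[0, 1]`.
#' @export
order_parameter_phi <- function(u, v) {
  denom <- sum(sqrt(u^2 + v^2))
  if (denom == 0) stop("order parameter undefined for an all-zero field")
  sqrt(sum(u)^2 + sum(v)^2) / denom
}

#' Synchrony order parameter (resultant vector length of phase)
#'
#' `R = |sum exp(i*theta)| / N` over the `N` sites: 1 when all phases are
#' equal (widespread synchrony); `1 - R` is the circular variance.
#'
#' @param theta matrix of phases in radians.
#' @return scalar in `[0, 1]`.
#' @export
order_parameter_R <- function(theta) {
  stopifnot(all(is.finite(theta)))
  Mod(sum(exp(1i * theta))) / length(theta)
}

#' Detect super-threshold intervals of an order-parameter series
#'
#' An interval is a run of time steps in which the statistic exceeds its
#' threshold at least every `tgap + 1` steps (sub-threshold gaps of at most
#' `tgap` steps are bridged) and whose total duration is at least `tdur`.
#'
#' @param x numeric series (one trial).
#' @param threshold detection threshold in `(0, 1)`.
#' @param tdur minimum duration in time steps (default 5).
#' @param tgap maximum bridged gap in time steps (default 1).
#' @return data.frame with columns `t_start`, `t_end` (1-based indices into
#'   `x`) and `duration`.
#' @export
detect_global_intervals <- function(x, threshold, tdur = 5L, tgap = 1L) {
  stopifnot(threshold > 0, threshold < 1)
  above <- which(x > threshold)
  if (length(above) == 0L)
    return(data.frame(t_start = integer(0), t_end = integer(0),
                      duration = integer(0)))
  brk <- which(diff(above) > tgap + 1L)
  starts <- above[c(1L, brk + 1L)]
  ends <- above[c(brk, length(above))]
  keep <- (ends - starts + 1L) >= tdur
  data.frame(t_start = starts[keep], t_end = ends[keep],
             duration = ends[keep] - starts[keep] + 1L)
}

#' Detect and classify all critical points in one velocity field
#'
#' Convenience wrapper: locates zeros ([find_critical_points()]), discards
#' those within `Ledge` grid spaces of the boundary, classifies the rest by
#' their Jacobian and measures their spatial extent.
#'
#' @param u,v velocity component matrices.
#' @param Ledge minimum distance from the grid edge in grid spaces
#'   (default 2); velocity fields are least reliable near the boundary.
#' @param stability_convention passed to [classify_critical_point()].
#' @return data.frame with columns `x`, `y`, `cls`, `motion`, `tau`,
#'   `delta`, `extent`.
#' @export
detect_critical_points_frame <- function(u, v, Ledge = 2,
                                         stability_convention = "paper") {
  cps <- find_critical_points(u, v)
  nr <- nrow(u); nc <- ncol(u)
  out <- list()
  for (i in seq_len(nrow(cps))) {
    x <- cps$x[i]; y <- cps$y[i]
    if (x < Ledge || y < Ledge || x > nc - 1 - Ledge || y > nr - 1 - Ledge)
      next
    J <- tryCatch(jacobian_at(u, v, c(x, y)), error = function(e) NULL)
    if (is.null(J)) next
    cl <- classify_critical_point(J, stability_convention)
    if (cl$cls == "degenerate") next
    ext <- pattern_extent(u, v, c(x, y), cl$cls)
    out[[length(out) + 1L]] <- data.frame(
      x = x, y = y, cls = cl$cls, motion = cl$motion,
      tau = cl$tau, delta = cl$delta, extent = ext)
  }
  if (length(out) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), cls = character(0),
                      motion = character(0), tau = numeric(0),
                      delta = numeric(0), extent = integer(0)))
  do.call(rbind, out)
}
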