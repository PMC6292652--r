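# Spatiotemporal mode extraction: singular value decomposition of stacked
# velocity fields, in a real (u and v concatenated across sites) and a
# complex (u + iv) variant.  No mean-centering is applied by default:
# a constant drift in propagation direction is itself a meaningful mode.

#' Stack a velocity field series into a decomposition matrix
#'
#' Rows are observations (time steps, trials concatenated along time),
#' columns are recording sites.  The real variant concatenates the two
#' components, `[u | v]`, giving `2 * n_sites` columns; the complex variant
#' forms `u + i v` with `n_sites` columns.
#'
#' @param series a `velocity_field_series` from [compute_velocity_fields()],
#'   or a list with arrays `u`, `v` of shape (row, col, step, trial).
#' @param variant `"real"` or `"complex"`.
#' @return numeric or complex matrix (time x features) with attributes
#'   `grid` (c(rows, cols)) and `variant`.
#' @export
stack_velocity_fields <- function(series, variant = c("real", "complex")) {
  variant <- match.arg(variant)
  u <- series$u; v <- series$v
  d <- dim(u)
  if (length(d) == 3L) { dim(u) <- dim(v) <- d <- c(d, 1L) }
  n_sites <- d[1] * d[2]
  nt <- d[3] * d[4]
  um <- matrix(aperm(u, c(3, 4, 1, 2)), nt, n_sites)
  vm <- matrix(aperm(v, c(3, 4, 1, 2)), nt, n_sites)
  out <- if (variant == "real") cbind(um, vm) else um + 1i * vm
  attr(out, "grid") <- d[1:2]
  attr(out, "variant") <- variant
  out
}

#' Singular value decomposition of stacked velocity fields
#'
#' Thin SVD `w = T S R*` of the (time x feature) matrix: columns of `R` are
#' spatial modes (vector fields), rows of the temporal matrix give each
#' mode's time course, and mode `k` explains a fraction `s_k^2 / sum(s^2)`
#' of the total variance.  A deterministic phase convention is applied: each
#' spatial mode is rotated/negated so its largest-magnitude component is
#' positive real, with the temporal mode adjusted to compensate.
#'
#' @param mat matrix from [stack_velocity_fields()], or any numeric/complex
#'   matrix (time x features).
#' @param center subtract each column's mean before decomposing (default
#'   FALSE: direction biases are part of the signal; with centering the
#'   loadings coincide with principal components).
#' @param normalize scale each column to unit variance (default FALSE;
#'   discouraged for velocity data).
#' @return object of class `svd_result`: `singular_values`,
#'   `variance_fraction`, `temporal_modes` (time x mode), `spatial_modes`
#'   (feature x mode), `variant`, `grid`, `column_means`.
#' @export
decompose_velocity_fields <- function(mat, center = FALSE, normalize = FALSE) {
  stopifnot(is.matrix(mat), all(is.finite(Mod(mat))))
  variant <- attr(mat, "variant")
  if (is.null(variant)) variant <- if (is.complex(mat)) "complex" else "real"
  grid <- attr(mat, "grid")
  mu <- NULL
  if (center) {
    mu <- colMeans(mat)
    mat <- sweep(mat, 2, mu)
  }
  if (normalize) {
    sdv <- apply(mat, 2, function(z) sqrt(mean(Mod(z - mean(z))^2)))
    sdv[sdv == 0] <- 1
    mat <- sweep(mat, 2, sdv, "/")
  }
  total <- sum(Mod(mat)^2)
  if (total == 0) {
    return(structure(list(singular_values = numeric(0),
                          variance_fraction = numeric(0),
                          temporal_modes = mat[, 0, drop = FALSE],
                          spatial_modes = t(mat)[, 0, drop = FALSE],
                          variant = variant, grid = grid,
                          column_means = mu),
                     class = "svd_result"))
  }
  s <- svd(mat)
  keep <- s$d > max(dim(mat)) * .Machine$double.eps * s$d[1]
  d <- s$d[keep]
  Tm <- s$u[, keep, drop = FALSE]
  R <- s$v[, keep, drop = FALSE]
  # deterministic sign/phase: largest-|.| component of each spatial mode
  # made positive real
  for (k in seq_along(d)) {
    i <- which.max(Mod(R[, k]))
    z <- R[i, k]
    ph <- z / Mod(z)
    # T S R* is invariant under (T_k, R_k) -> (c T_k, d R_k) iff
    # c * conj(d) = 1; with d = 1/ph and |ph| = 1, c = 1/ph as well
    R[, k] <- R[, k] / ph
    Tm[, k] <- Tm[, k] / ph
  }
  structure(list(singular_values = d,
                 variance_fraction = d^2 / sum(d^2),
                 temporal_modes = Tm, spatial_modes = R,
                 variant = variant, grid = grid, column_means = mu),
            class = "svd_result")
}

#' @export
print.svd_result <- function(x, ...) {
  cat(sprintf("<svd_result> %s variant, %d mode(s)\n", x$variant,
              length(x$singular_values)))
  if (length(x$singular_values)) {
    vf <- utils::head(x$variance_fraction, 5)
    cat("  variance fractions:", paste(signif(vf, 3), collapse = ", "),
        if (length(x$variance_fraction) > 5) "...\n" else "\n")
  }
  invisible(x)
}

#' Rank-k reconstruction from an SVD result
#'
#' @param result an `svd_result`.
#' @param k number of modes to keep (`1 <= k <= n_modes`); the full rank
#'   reproduces the decomposed matrix to numerical tolerance.
#' @return reconstructed (time x feature) matrix.
#' @export
reconstruct_modes <- function(result, k) {
  n <- length(result$singular_values)
  if (k < 1 || k > n) stop("k out of range 1..", n)
  idx <- seq_len(k)
  out <- result$temporal_modes[, idx, drop = FALSE] %*%
    diag(result$singular_values[idx], k, k) %*%
    Conj(t(result$spatial_modes[, idx, drop = FALSE]))
  if (!is.null(result$column_means)) out <- sweep(out, 2, -result$column_means)
  out
}

#' Extract the k-th spatial mode as a velocity field
#'
#' @param result an `svd_result` with grid metadata.
#' @param k mode index.
#' @return list with matrices `u`, `v` on the original grid.
#' @export
mode_field <- function(result, k) {
  g <- result$grid
  if (is.null(g)) stop("result carries no grid metadata")
  m <- result$spatial_modes[, k]
  n_sites <- g[1] * g[2]
  # feature order matches stack_velocity_fields: site index is column-major
  # over (row, col)
  if (result$variant == "real") {
    u <- matrix(Re(m[seq_len(n_sites)]), g[1], g[2])
    v <- matrix(Re(m[n_sites + seq_len(n_sites)]), g[1], g[2])
  } else {
    u <- matrix(Re(m), g[1], g[2])
    v <- matrix(Im(m), g[1], g[2])
  }
  list(u = u, v = v)
}

#' Per-mode summary with automatic structure classification
#'
#' For each retained mode: variance fraction, temporal coefficients, and a
#' classification of the mode's dominant structure obtained by running the
#' pattern detector on the mode's own vector field — plane-wave-like if its
#' order parameter exceeds `Tpw`, otherwise the classified critical points.
#'
#' @param result an `svd_result` with grid metadata.
#' @param n_modes number of leading modes to report (default up to 6).
#' @param Tpw plane-wave threshold on the mode field (default 0.85).
#' @param Ledge edge margin for critical-point classification (default 2).
#' @return list of per-mode lists: `k`, `variance_fraction`, `time_course`,
#'   `field`, `phi`, `structure` (`"plane_wave"` or `"critical_points"`),
#'   `critical_points` data.frame.
#' @export
mode_report <- function(result, n_modes = NULL, Tpw = 0.85, Ledge = 2) {
  nm <- length(result$singular_values)
  if (is.null(n_modes)) n_modes <- min(6L, nm)
  n_modes <- min(n_modes, nm)
  out <- vector("list", n_modes)
  for (k in seq_len(n_modes)) {
    f <- mode_field(result, k)
    phi <- if (all(f$u == 0 & f$v == 0)) NA_real_
           else order_parameter_phi(f$u, f$v)
    if (!is.na(phi) && phi > Tpw) {
      structure_k <- "plane_wave"
      cps <- data.frame()
    } else {
      structure_k <- "critical_points"
      cps <- detect_critical_points_frame(f$u, f$v, Ledge = Ledge)
    }
    out[[k]] <- list(k = k,
                     variance_fraction = result$variance_fraction[k],
                     time_course = result$temporal_modes[, k],
                     field = f, phi = phi, structure = structure_k,
                     critical_points = cps)
  }
  out
}
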