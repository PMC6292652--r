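# Ground-truth synthetic wave patterns.
#
# A simulated pattern is z(x, y, t) = A(x, y, t) * exp(i (k s(x, y, t) - w t))
# where s is the spatial phase profile selecting the pattern type:
#   source/sink : s = +/- r                (radial distance to the centre)
#   spiral      : s = +/- (r + atan2(dy, dx) / k)
#   saddle      : s = +/- (|dx| - |dy|)
#   plane wave  : s = x cos(phi0) + y sin(phi0)   (extension: exercises the
#                 global order-parameter detectors; not a critical point)
# and A is a Gaussian envelope A0 * exp(-r^2 / (2 c^2)) centred on the
# (drifting) pattern centre.  Centres move as (x0 + vx t, y0 + vy t).
# Multiple patterns sum; complex white noise is added with SD proportional
# to the local summed amplitude.

#' Specify one synthetic wave pattern
#'
#' @param ptype `"source_sink"`, `"spiral"`, `"saddle"` or `"plane_wave"`.
#' @param x0,y0 initial centre in 0-based grid coordinates (for
#'   `plane_wave`: ignored).
#' @param vx,vy centre drift in grid spaces per time step.
#' @param A0 maximum amplitude (> 0).
#' @param c_width Gaussian envelope width in grid spaces (> 0).
#' @param k wavenumber, rad per grid space (> 0).
#' @param w angular frequency, rad per time step.
#' @param sign +1 for expansion (source / spiral-out) or -1 for contraction
#'   (sink / spiral-in); for saddles and plane waves it flips the phase
#'   gradient direction.
#' @param direction propagation direction in radians, `plane_wave` only.
#' @param envelope `"super_gaussian"` (default) for the compact
#'   `A0 exp(-(r^2)^2 / (2 c^2))` profile, whose effective radius
#'   `(2 c^2)^(1/4)` keeps neighbouring patterns separable at the
#'   randomisation protocol's minimum spacing; `"gaussian"` for the broad
#'   conventional `A0 exp(-r^2 / (2 c^2))`.
#' @return a `pattern_spec` list.
#' @export
pattern_spec <- function(ptype = c("source_sink", "spiral", "saddle",
                                   "plane_wave"),
                         x0 = 0, y0 = 0, vx = 0, vy = 0, A0 = 1, c_width = 4,
                         k = 2 * pi / 5, w = 2 * pi * 0.01, sign = 1,
                         direction = 0, envelope = c("super_gaussian",
                                                     "gaussian")) {
  ptype <- match.arg(ptype)
  envelope <- match.arg(envelope)
  stopifnot(A0 > 0, c_width > 0, k > 0, sign %in% c(-1, 1))
  structure(list(ptype = ptype, x0 = x0, y0 = y0, vx = vx, vy = vy, A0 = A0,
                 c_width = c_width, k = k, w = w, sign = sign,
                 direction = direction, envelope = envelope),
            class = "pattern_spec")
}

pattern_centre <- function(spec, t) c(spec$x0 + spec$vx * t,
                                      spec$y0 + spec$vy * t)

#' Spatial phase profile of a pattern
#'
#' @param spec a [pattern_spec()].
#' @param x,y coordinates (vectors or matrices, 0-based grid units).
#' @param t time step (0-based).
#' @return the phase profile `s(x, y, t)` (same shape as `x`).
#' @export
phase_profile <- function(spec, x, y, t) {
  ct <- pattern_centre(spec, t)
  dx <- x - ct[1]; dy <- y - ct[2]
  s <- switch(spec$ptype,
    source_sink = sqrt(dx^2 + dy^2),
    spiral = sqrt(dx^2 + dy^2) + atan2(dy, dx) / spec$k,
    saddle = abs(dx) - abs(dy),
    plane_wave = x * cos(spec$direction) + y * sin(spec$direction))
  spec$sign * s
}

#' Amplitude envelope of a pattern
#'
#' Symmetric radial envelope centred on the (drifting) pattern centre:
#' `A0 * exp(-(r^2)^2 / (2 c^2))` by default (a compact super-Gaussian), or
#' the conventional Gaussian `A0 * exp(-r^2 / (2 c^2))`; plane waves have a
#' flat envelope `A0`.
#'
#' @inheritParams phase_profile
#' @return amplitude values (same shape as `x`).
#' @export
amplitude_profile <- function(spec, x, y, t) {
  if (spec$ptype == "plane_wave")
    return(array(spec$A0, dim = dim(as.array(x))) + 0 * x)
  ct <- pattern_centre(spec, t)
  r2 <- (x - ct[1])^2 + (y - ct[2])^2
  arg <- if (spec$envelope == "super_gaussian") r2^2 else r2
  spec$A0 * exp(-arg / (2 * spec$c_width^2))
}

#' Simulate a synthetic wave recording
#'
#' Sums the complex fields of all patterns over a (rows x cols) grid for
#' `n_steps` time steps and adds complex Gaussian noise whose standard
#' deviation at each site/step is `noise_sigma_rel` times the local summed
#' amplitude (both real and imaginary parts are perturbed so that phase
#' noise remains well defined where the amplitude is small).
#'
#' @param patterns list of [pattern_spec()]s (a single spec is accepted).
#' @param grid integer `c(rows, cols)`.
#' @param n_steps number of time steps.
#' @param noise_sigma_rel relative noise SD (>= 0).
#' @param noise_mode `"mean"` (default): noise SD is `noise_sigma_rel`
#'   times the grand mean of the summed amplitude envelope, uniform across
#'   sites (noise levels quoted "relative to average signal amplitude");
#'   `"local"`: SD proportional to each site/step's own summed amplitude.
#' @param fs nominal sampling frequency attached to the outputs (default 1:
#'   times in steps).
#' @param seed optional integer seed for reproducible noise.
#' @return list with `z` (complex rows x cols x steps array), `phase`,
#'   `amplitude`, `real` (views of `z`), `truth` (data.frame of per-step
#'   ground-truth centres: `t`, `pattern`, `ptype`, `motion`, `x`, `y`),
#'   `fs`, and the echoed `patterns`.
#' @export
simulate_patterns <- function(patterns, grid = c(12L, 12L), n_steps = 10L,
                              noise_sigma_rel = 0,
                              noise_mode = c("mean", "local"),
                              fs = 1, seed = NULL) {
  noise_mode <- match.arg(noise_mode)
  if (inherits(patterns, "pattern_spec")) patterns <- list(patterns)
  stopifnot(length(patterns) >= 1L, noise_sigma_rel >= 0)
  if (!is.null(seed)) set.seed(seed)
  nr <- grid[1]; nc <- grid[2]
  x <- outer(rep(1, nr), 0:(nc - 1L))
  y <- outer(0:(nr - 1L), rep(1, nc))
  z <- array(0i, c(nr, nc, n_steps))
  amp_sum <- array(0, c(nr, nc, n_steps))
  truth <- list()
  for (t in seq_len(n_steps)) {
    t0 <- t - 1L
    for (pi_ in seq_along(patterns)) {
      sp <- patterns[[pi_]]
      s <- phase_profile(sp, x, y, t0)
      A <- amplitude_profile(sp, x, y, t0)
      z[, , t] <- z[, , t] + A * exp(1i * (sp$k * s - sp$w * t0))
      amp_sum[, , t] <- amp_sum[, , t] + A
      if (sp$ptype != "plane_wave") {
        ct <- pattern_centre(sp, t0)
        motion <- if (sp$ptype == "saddle") "saddle"
                  else if (sp$sign > 0) "outward" else "inward"
        truth[[length(truth) + 1L]] <- data.frame(
          t = t, pattern = pi_, ptype = sp$ptype, motion = motion,
          x = ct[1], y = ct[2])
      }
    }
  }
  if (noise_sigma_rel > 0) {
    n <- length(z)
    sd_field <- if (noise_mode == "mean") rep(mean(amp_sum), n) else amp_sum
    z <- z + complex(real = stats::rnorm(n, sd = noise_sigma_rel * sd_field),
                     imaginary = stats::rnorm(n,
                                              sd = noise_sigma_rel * sd_field))
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(t = integer(0), pattern = integer(0), ptype = character(0),
               motion = character(0), x = numeric(0), y = numeric(0))
  list(z = z, phase = Arg(z), amplitude = Mod(z), real = Re(z),
       truth = truth, fs = fs, patterns = patterns)
}

#' Random simulation spec following the benchmark protocol
#'
#' Two drifting patterns on a 12 x 12 grid over 10 steps, both with
#' `w = 2*pi*0.01` and `k = 2*pi/5`: centres uniform over the grid but
#' rejected if within 2 grid spaces of each other or of an edge; drifts
#' uniform on [-0.1, 0.1] grid/step; `A0` uniform on [1, 2]; Gaussian width
#' uniform on [3, 5].  By default the two patterns are an expanding source
#' and a contracting sink; alternatively random types can be drawn.
#'
#' @param seed integer seed (reproducible spec).
#' @param grid,n_steps protocol grid (defaults 12 x 12 x 10).
#' @param types `"source_sink"` (default: one source + one sink) or
#'   `"random"`: each pattern drawn from source, sink, spiral-in,
#'   spiral-out, saddle.
#' @param max_draws rejection-sampling cap (default 1e4).
#' @return list of two [pattern_spec()]s with attribute `"grid"`,
#'   `"n_steps"`.
#' @export
random_fig_spec <- function(seed = NULL, grid = c(12L, 12L), n_steps = 10L,
                            types = c("source_sink", "random"),
                            max_draws = 1e4) {
  types <- match.arg(types)
  if (!is.null(seed)) set.seed(seed)
  nr <- grid[1]; nc <- grid[2]
  margin <- 2
  for (draw in seq_len(max_draws)) {
    xs <- stats::runif(2, 0, nc - 1)
    ys <- stats::runif(2, 0, nr - 1)
    edge_ok <- all(xs >= margin & xs <= nc - 1 - margin &
                   ys >= margin & ys <= nr - 1 - margin)
    sep_ok <- sqrt(diff(xs)^2 + diff(ys)^2) >= margin
    if (edge_ok && sep_ok) break
    if (draw == max_draws) stop("rejection sampling exceeded max_draws")
  }
  kinds <- if (types == "source_sink") {
    list(c("source_sink", 1), c("source_sink", -1))
  } else {
    lapply(1:2, function(i) {
      pick <- sample(c("source+", "source-", "spiral+", "spiral-", "saddle"),
                     1)
      switch(pick,
             "source+" = c("source_sink", 1), "source-" = c("source_sink", -1),
             "spiral+" = c("spiral", 1), "spiral-" = c("spiral", -1),
             "saddle" = c("saddle", 1))
    })
  }
  specs <- lapply(1:2, function(i)
    pattern_spec(ptype = kinds[[i]][1], x0 = xs[i], y0 = ys[i],
                 vx = stats::runif(1, -0.1, 0.1),
                 vy = stats::runif(1, -0.1, 0.1),
                 A0 = stats::runif(1, 1, 2),
                 c_width = stats::runif(1, 3, 5),
                 k = 2 * pi / 5, w = 2 * pi * 0.01,
                 sign = as.numeric(kinds[[i]][2])))
  attr(specs, "grid") <- grid
  attr(specs, "n_steps") <- n_steps
  specs
}

#' White-noise surrogate of a recording
#'
#' Independent Gaussian series per site/trial with the same sample mean and
#' standard deviation as the corresponding site of the source recording.
#' Reprocessing surrogates through the identical pipeline reveals which
#' detected patterns could arise from filtering/smoothing alone.
#'
#' @param rec a [recording()].
#' @param seed optional integer seed.
#' @return a surrogate [recording()].
#' @export
make_surrogate <- function(rec, seed = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (!is.null(seed)) set.seed(seed)
  sig <- rec$signal
  d <- dim(sig)
  for (p in seq_len(d[4])) for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    x <- sig[r, c, , p]
    sig[r, c, , p] <- stats::rnorm(d[3], mean = mean(x), sd = stats::sd(x))
  }
  recording(sig, fs = rec$fs, grid_spacing = rec$grid_spacing)
}

# truth motion + detection class compatibility: a true source must be
# detected as an outward node/focus-free node etc.
truth_matches_cls <- function(truth_ptype, truth_motion, det_cls, det_motion) {
  det_kind <- ifelse(grepl("node", det_cls), "node",
                     ifelse(grepl("focus", det_cls), "focus", "saddle"))
  true_kind <- switch(truth_ptype, source_sink = "node", spiral = "focus",
                      saddle = "saddle")
  if (det_kind != true_kind) return(FALSE)
  if (true_kind == "saddle") return(TRUE)
  det_motion == truth_motion
}

#' Detection accuracy against ground truth
#'
#' Per frame, greedily matches (by distance) each true centre to the nearest
#' unmatched detection within `match_radius`, irrespective of class.  Three
#' complementary metrics are reported: the mean displacement over matches
#' (localisation accuracy), the percentage of true patterns that are either
#' unmatched (missed) or matched by a detection of incompatible class
#' (misclassified), and the number of unmatched detections per time step
#' (spurious patterns).
#'
#' @param truth ground-truth data.frame from [simulate_patterns()] (columns
#'   `t`, `ptype`, `motion`, `x`, `y`), times in detection frames.
#' @param detections list of per-frame data.frames from
#'   [detect_critical_points_frame()].
#' @param match_radius maximum matching distance in grid spaces (default 2).
#' @return list with `mean_displacement`, `pct_missed_or_misclassified`,
#'   `false_per_step`, and counts `n_true`, `n_matched`, `n_correct`,
#'   `n_false`.
#' @export
evaluate_detection <- function(truth, detections, match_radius = 2) {
  n_true <- 0L; n_matched <- 0L; n_correct <- 0L; n_false <- 0L
  disp <- numeric(0)
  for (t in seq_along(detections)) {
    det <- detections[[t]]
    tru <- truth[truth$t == t, , drop = FALSE]
    n_true <- n_true + nrow(tru)
    used <- rep(FALSE, if (is.null(det)) 0L else nrow(det))
    if (nrow(tru) > 0L && !is.null(det) && nrow(det) > 0L) {
      cand <- list()
      for (i in seq_len(nrow(tru))) for (j in seq_len(nrow(det))) {
        dd <- sqrt((tru$x[i] - det$x[j])^2 + (tru$y[i] - det$y[j])^2)
        if (dd <= match_radius) cand[[length(cand) + 1L]] <- c(i, j, dd)
      }
      if (length(cand)) {
        cand <- do.call(rbind, cand)
        cand <- cand[order(cand[, 3]), , drop = FALSE]
        tdone <- rep(FALSE, nrow(tru))
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (tdone[i] || used[j]) next
          tdone[i] <- TRUE; used[j] <- TRUE
          n_matched <- n_matched + 1L
          disp <- c(disp, cand[k, 3])
          if (truth_matches_cls(tru$ptype[i], tru$motion[i],
                                det$cls[j], det$motion[j]))
            n_correct <- n_correct + 1L
        }
      }
    }
    n_false <- n_false + sum(!used)
  }
  list(mean_displacement = if (length(disp)) mean(disp) else NA_real_,
       pct_missed_or_misclassified =
         if (n_true > 0) 100 * (n_true - n_correct) / n_true else NA_real_,
       false_per_step = n_false / max(length(detections), 1L),
       n_true = n_true, n_matched = n_matched, n_correct = n_correct,
       n_false = n_false)
}
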