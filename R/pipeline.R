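# Pipeline orchestration: preprocess -> filter -> optical flow -> per-frame
# detection -> tracking -> transitions -> SVD, with surrogate comparison and
# a threshold-inspection report in place of interactive threshold tuning.

default_config <- function() {
  list(
    signal = "phase",               # phase | amplitude | raw
    normalize = list(method = "none", baseline_window = NULL),
    downsample = list(factor = 1L),
    smooth = list(sigma = 0),
    filter = list(method = "none", band = NULL, center = NULL, n_cycles = 6),
    flow = list(alpha = 0.1, beta = 10, tol = 1e-6, max_iter = 500L),
    detect = list(Tpw = 0.85, Tsyn = 0.8, Ledge = 2, Lradius = 2,
                  combine_nodes_foci = FALSE, combine_spiral_in_out = FALSE,
                  stability_convention = "paper"),
    track = list(Ldisp = 0.5, tgap = 1L, tdur = 5L),
    transitions = list(window_ms = 50, window_steps = NULL),
    svd = list(variant = "both", center = FALSE, normalize = FALSE),
    seed = 1L)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' @param cfg a nested list of options, or the path of a YAML file holding
#'   one (requires the `yaml` package).  Unset keys take package defaults.
#' @return validated config list.
#' @export
load_config <- function(cfg = list()) {
  if (is.character(cfg)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read config files")
    cfg <- yaml::read_yaml(cfg)
  }
  cfg <- merge_config(default_config(), cfg)
  if (!cfg$signal %in% c("phase", "amplitude", "raw"))
    stop("signal must be one of phase, amplitude, raw")
  if (cfg$flow$alpha <= 0) stop("flow.alpha must be > 0")
  if (cfg$flow$beta <= 0) stop("flow.beta must be > 0")
  for (th in c("Tpw", "Tsyn"))
    if (cfg$detect[[th]] <= 0 || cfg$detect[[th]] >= 1)
      stop("detect.", th, " must lie in (0, 1)")
  if (!cfg$filter$method %in% c("none", "hilbert", "morlet"))
    stop("filter.method must be none, hilbert or morlet")
  cfg
}

#' Run the full wave-pattern analysis pipeline
#'
#' Stages: preprocessing (bad-channel interpolation, optional
#' normalisation, spatial down-sampling and smoothing), oscillation
#' filtering, optical-flow velocity fields, per-frame critical-point
#' detection and order parameters, global-interval and critical-point
#' tracking, transition statistics (for multi-trial input) and vector-field
#' SVD.  Deterministic given the input and config.
#'
#' @param input a [recording()], or a complex (row, col, time) /
#'   (row, col, time, trial) array already representing the analytic signal
#'   (e.g. `z` from [simulate_patterns()]), or a file path readable by
#'   [load_recording()].
#' @param cfg configuration list or YAML path, see [load_config()].
#' @param fs sampling frequency when `input` is a bare array (default 1:
#'   time measured in steps).
#' @return a `results_bundle` list: `config`, `fs`, `order_parameters`
#'   (data.frame `trial`, `t`, `phi`, `R`), `critical_points` (per-frame
#'   table with trial and time), `patterns` (tracked instances incl. global
#'   plane-wave/synchrony rows, with `trial`), `transitions` (list:
#'   `observed`, `expected`, `significance`, `types`, `window_steps`),
#'   `svd` (list with `real` and/or `complex` [decompose_velocity_fields()]
#'   results), `fields` (the `velocity_field_series`).
#' @export
run_pipeline <- function(input, cfg = list(), fs = 1) {
  cfg <- load_config(cfg)
  set.seed(cfg$seed)

  ## --- input & preprocessing -------------------------------------------
  analytic <- NULL
  if (is.character(input)) input <- load_recording(input, fs = fs)
  if (is.complex(input)) {
    d <- dim(input)
    if (length(d) == 3L) dim(input) <- d <- c(d, 1L)
    analytic <- analytic_signal(input, fs = fs, band = NA_real_,
                                method = "none")
  } else if (inherits(input, "analytic_signal")) {
    analytic <- input
  } else if (!inherits(input, "recording")) {
    input <- recording(input, fs = fs)
  }

  if (is.null(analytic)) {
    rec <- input
    fs <- rec$fs
    if (any(!rec$channel_mask)) rec <- interpolate_bad_channels(rec)
    if (cfg$normalize$method != "none")
      rec <- normalize_sites(rec, cfg$normalize$method,
                             cfg$normalize$baseline_window)
    if (cfg$downsample$factor > 1L)
      rec <- downsample_spatial(rec, cfg$downsample$factor)
    if (cfg$smooth$sigma > 0) rec <- smooth_spatial(rec, cfg$smooth$sigma)
    analytic <- switch(cfg$filter$method,
      hilbert = filter_hilbert(rec, cfg$filter$band[1], cfg$filter$band[2]),
      morlet = filter_morlet(rec, cfg$filter$center,
                             n_cycles = cfg$filter$n_cycles),
      none = analytic_signal(rec$signal + 0i, fs = fs, band = NA_real_,
                             method = "none"))
  } else {
    fs <- analytic$fs
  }

  if (cfg$signal == "phase" && analytic$method == "none" &&
      all(Im(analytic$values) == 0))
    warning("signal = 'phase' on unfiltered real data is degenerate ",
            "(phase is 0 or pi everywhere); filter first or use ",
            "signal = 'raw'")

  pa <- split_phase_amplitude(analytic)
  data_in <- switch(cfg$signal,
                    phase = pa$phase,
                    amplitude = pa$amplitude,
                    raw = Re(analytic$values))
  is_phase <- cfg$signal == "phase"

  ## --- optical flow -----------------------------------------------------
  fields <- compute_velocity_fields(data_in, alpha = cfg$flow$alpha,
                                    beta = cfg$flow$beta,
                                    is_phase = is_phase,
                                    tol = cfg$flow$tol,
                                    max_iter = cfg$flow$max_iter)
  d <- dim(fields$u)
  nt <- d[3]; ntr <- d[4]

  ## --- per-frame detection ---------------------------------------------
  op <- vector("list", ntr)
  cp_frames <- vector("list", ntr)
  for (p in seq_len(ntr)) {
    phi <- numeric(nt); Rv <- rep(NA_real_, nt)
    frames <- vector("list", nt)
    for (t in seq_len(nt)) {
      u <- fields$u[, , t, p]; v <- fields$v[, , t, p]
      phi[t] <- if (all(u == 0 & v == 0)) NA_real_
                else order_parameter_phi(u, v)
      if (is_phase) Rv[t] <- order_parameter_R(pa$phase[, , t, p])
      frames[[t]] <- detect_critical_points_frame(
        u, v, Ledge = cfg$detect$Ledge,
        stability_convention = cfg$detect$stability_convention)
    }
    op[[p]] <- data.frame(trial = p, t = seq_len(nt), phi = phi, R = Rv)
    cp_frames[[p]] <- frames
  }
  order_parameters <- do.call(rbind, op)

  cps_tab <- list()
  for (p in seq_len(ntr)) for (t in seq_len(nt)) {
    fr <- cp_frames[[p]][[t]]
    if (nrow(fr)) cps_tab[[length(cps_tab) + 1L]] <-
        cbind(data.frame(trial = p, t = t), fr)
  }
  critical_points <- if (length(cps_tab)) do.call(rbind, cps_tab) else
    data.frame(trial = integer(0), t = integer(0), x = numeric(0),
               y = numeric(0), cls = character(0), motion = character(0),
               tau = numeric(0), delta = numeric(0), extent = integer(0))

  ## --- tracking ---------------------------------------------------------
  patterns <- list()
  for (p in seq_len(ntr)) {
    opp <- op[[p]]
    pw <- intervals_to_patterns(
      detect_global_intervals(ifelse(is.na(opp$phi), -Inf, opp$phi),
                              cfg$detect$Tpw, cfg$track$tdur, cfg$track$tgap),
      "plane_wave")
    sy <- if (is_phase) intervals_to_patterns(
      detect_global_intervals(ifelse(is.na(opp$R), -Inf, opp$R),
                              cfg$detect$Tsyn, cfg$track$tdur,
                              cfg$track$tgap), "synchrony")
      else intervals_to_patterns(
        data.frame(t_start = integer(0), t_end = integer(0),
                   duration = integer(0)), "synchrony")
    cp <- link_patterns(cp_frames[[p]], Ldisp = cfg$track$Ldisp,
                        tgap = cfg$track$tgap, tdur = cfg$track$tdur,
                        Lradius = cfg$detect$Lradius,
                        combine_nodes_foci = cfg$detect$combine_nodes_foci,
                        combine_spiral_in_out =
                          cfg$detect$combine_spiral_in_out)
    all_p <- rbind(pw, sy, cp)
    if (nrow(all_p)) all_p <- cbind(data.frame(trial = p), all_p)
    patterns[[p]] <- all_p
  }
  patterns_tab <- do.call(rbind, patterns[vapply(patterns, nrow, 0L) > 0])
  if (is.null(patterns_tab))
    patterns_tab <- cbind(data.frame(trial = integer(0)),
                          intervals_to_patterns(
                            data.frame(t_start = integer(0),
                                       t_end = integer(0),
                                       duration = integer(0)), "none")[0, ])

  ## --- transitions ------------------------------------------------------
  wsteps <- cfg$transitions$window_steps
  if (is.null(wsteps)) wsteps <- max(1L, round(cfg$transitions$window_ms /
                                                 1000 * fs))
  all_types <- c("plane_wave", "synchrony", "sink", "source", "spiral_in",
                 "spiral_out", "saddle")
  types <- all_types[all_types %in% patterns_tab$ptype]
  transitions <- NULL
  if (length(types) >= 1L && nrow(patterns_tab) > 0L) {
    obs <- array(0L, c(length(types), length(types), ntr),
                 dimnames = list(from = types, to = types, NULL))
    expc <- array(0, dim(obs), dimnames = dimnames(obs))
    ttrial_s <- nt / fs
    for (p in seq_len(ntr)) {
      pp <- patterns_tab[patterns_tab$trial == p, , drop = FALSE]
      obs[, , p] <- count_transitions(pp, wsteps, types = types)
      nct <- table(factor(pp$ptype, levels = types))
      for (i in seq_along(types)) for (j in seq_along(types)) {
        if (i == j) next
        expc[i, j, p] <- expected_transitions(nct[i], nct[j],
                                              wsteps / fs, ttrial_s)
      }
    }
    sig <- if (ntr >= 2L) transition_significance(obs, expc) else NULL
    transitions <- list(observed = obs, expected = expc, significance = sig,
                        types = types, window_steps = wsteps)
  }

  ## --- SVD --------------------------------------------------------------
  svd_res <- list()
  if (cfg$svd$variant %in% c("real", "both"))
    svd_res$real <- decompose_velocity_fields(
      stack_velocity_fields(fields, "real"),
      center = cfg$svd$center, normalize = cfg$svd$normalize)
  if (cfg$svd$variant %in% c("complex", "both"))
    svd_res$complex <- decompose_velocity_fields(
      stack_velocity_fields(fields, "complex"),
      center = cfg$svd$center, normalize = cfg$svd$normalize)

  structure(list(config = cfg, fs = fs,
                 order_parameters = order_parameters,
                 critical_points = critical_points,
                 patterns = patterns_tab,
                 transitions = transitions,
                 svd = svd_res, fields = fields),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  d <- dim(x$fields$u)
  cat(sprintf("<results_bundle> %d x %d grid, %d step(s), %d trial(s)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  %d critical-point detection(s), %d tracked pattern(s)\n",
              nrow(x$critical_points), nrow(x$patterns)))
  invisible(x)
}

# per-type summary of one pattern table: count/s, % time active, duration
pattern_summary <- function(patterns, nt, fs, types) {
  out <- data.frame(ptype = types, count_per_s = 0, pct_time = 0,
                    mean_duration = NA_real_)
  for (i in seq_along(types)) {
    pp <- patterns[patterns$ptype == types[i], , drop = FALSE]
    if (nrow(pp) == 0L) next
    active <- logical(nt)
    for (k in seq_len(nrow(pp)))
      active[pp$t_start[k]:pp$t_end[k]] <- TRUE
    out$count_per_s[i] <- nrow(pp) / (nt / fs)
    out$pct_time[i] <- 100 * mean(active)
    out$mean_duration[i] <- mean(pp$duration) / fs
  }
  out
}

#' Compare pattern statistics between real data and white-noise surrogates
#'
#' Runs the full pipeline on the input and on `n` surrogate datasets
#' ([make_surrogate()]), and summarises, per pattern type: patterns
#' detected per second, percentage of recording time active, and mean
#' duration (seconds), with across-replicate SEM for the surrogates.
#'
#' @param rec a [recording()].
#' @param cfg pipeline configuration (list or YAML path).
#' @param n number of surrogate replicates (>= 1).
#' @param seed base seed; surrogate `i` uses `seed + i`.
#' @return list with data.frames `real` and `surrogate` (columns `ptype`,
#'   `count_per_s`, `pct_time`, `mean_duration`, and for surrogates the
#'   `*_sem` columns, `NA` when `n = 1`).
#' @export
run_surrogate_comparison <- function(rec, cfg = list(), n = 10, seed = 1L) {
  stopifnot(inherits(rec, "recording"), n >= 1)
  cfg <- load_config(cfg)
  types <- c("plane_wave", "synchrony", "sink", "source", "spiral_in",
             "spiral_out", "saddle")
  res_real <- run_pipeline(rec, cfg)
  nt <- dim(res_real$fields$u)[3]
  real_sum <- pattern_summary(res_real$patterns, nt, res_real$fs, types)
  reps <- vector("list", n)
  for (i in seq_len(n)) {
    sur <- make_surrogate(rec, seed = seed + i)
    res_s <- run_pipeline(sur, cfg)
    reps[[i]] <- pattern_summary(res_s$patterns, nt, res_s$fs, types)
  }
  agg <- function(col) {
    m <- sapply(reps, function(r) r[[col]])
    if (is.null(dim(m))) m <- matrix(m, nrow = length(types))
    data.frame(mean = rowMeans(m, na.rm = TRUE),
               sem = if (n > 1) apply(m, 1, function(x)
                 stats::sd(x, na.rm = TRUE) / sqrt(sum(is.finite(x))))
               else rep(NA_real_, length(types)))
  }
  cs <- agg("count_per_s"); pt <- agg("pct_time"); md <- agg("mean_duration")
  surrogate_sum <- data.frame(
    ptype = types,
    count_per_s = cs$mean, count_per_s_sem = cs$sem,
    pct_time = pt$mean, pct_time_sem = pt$sem,
    mean_duration = md$mean, mean_duration_sem = md$sem)
  list(real = real_sum, surrogate = surrogate_sum, n = n)
}

# bimodality coefficient (Sarle): (skew^2 + 1) / kurtosis, with kurtosis as
# the non-excess fourth standardised moment; > 5/9 + margin suggests more
# than one mode (uniform scores exactly 5/9)
bimodality_coefficient <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0) return(NA_real_)
  m <- mean(x); s <- stats::sd(x) * sqrt((n - 1) / n)
  g1 <- mean((x - m)^3) / s^3
  g2 <- mean((x - m)^4) / s^4
  (g1^2 + 1) / g2
}

#' Threshold-inspection report for order-parameter series
#'
#' Static replacement for interactive threshold tuning: histograms of the
#' plane-wave and synchrony order parameters across the recording, a
#' multimodality flag (bimodality coefficient above 0.555), and candidate
#' thresholds (the default, plus the histogram dip between modes when the
#' distribution is flagged multimodal).
#'
#' @param order_parameters data.frame with columns `phi` and (optionally)
#'   `R`, e.g. from [run_pipeline()] results.
#' @param breaks histogram bin count (default 20).
#' @param plot draw base-graphics histograms (default FALSE).
#' @return list per statistic: `histogram` (counts/mids), `bimodality`,
#'   `multimodal` flag, `candidate_threshold`.
#' @export
threshold_inspection_report <- function(order_parameters, breaks = 20,
                                        plot = FALSE) {
  stats_cols <- intersect(c("phi", "R"), names(order_parameters))
  defaults <- c(phi = 0.85, R = 0.8)
  if (length(stats_cols) == 0L) stop("no phi or R column found")
  out <- list()
  for (sc in stats_cols) {
    x <- order_parameters[[sc]]
    x <- x[is.finite(x)]
    if (length(x) == 0L) stop("empty order-parameter series for ", sc)
    h <- graphics::hist(x, breaks = seq(0, 1, length.out = breaks + 1),
                        plot = FALSE)
    bc <- bimodality_coefficient(x)
    multi <- is.finite(bc) && bc > 0.555
    cand <- unname(defaults[sc])
    if (multi && length(x) >= 10L) {
      km <- stats::kmeans(x, centers = 2, nstart = 5)
      cand <- mean(range(tapply(x, km$cluster, mean)))
    }
    if (plot) {
      graphics::hist(x, breaks = h$breaks, main = paste("distribution of", sc),
                     xlab = sc)
      graphics::abline(v = cand, lty = 2)
    }
    out[[sc]] <- list(histogram = list(counts = h$counts, mids = h$mids),
                      bimodality = bc, multimodal = multi,
                      candidate_threshold = cand)
  }
  out
}
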