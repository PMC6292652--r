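# Temporal linking of per-frame detections into persistent pattern
# instances, plus observed-vs-expected transition statistics.

# map a per-frame classification to a pattern-type label
cls_to_ptype <- function(cls, motion, combine_nodes_foci = FALSE,
                         combine_spiral_in_out = FALSE) {
  kind <- ifelse(grepl("node", cls), "node",
                 ifelse(grepl("focus", cls), "focus", "saddle"))
  pt <- character(length(cls))
  pt[kind == "saddle"] <- "saddle"
  pt[kind == "node" & motion == "outward"] <- "source"
  pt[kind == "node" & motion != "outward"] <- "sink"
  pt[kind == "focus" & motion == "outward"] <- "spiral_out"
  pt[kind == "focus" & motion != "outward"] <- "spiral_in"
  if (combine_nodes_foci) {
    pt[pt %in% c("source", "spiral_out")] <- "source"
    pt[pt %in% c("sink", "spiral_in")] <- "sink"
  }
  if (combine_spiral_in_out)
    pt[pt %in% c("spiral_in", "spiral_out")] <- "spiral"
  pt
}

#' Link per-frame critical points into persistent patterns
#'
#' Chains critical points of the same pattern type across time: a detection
#' continues an active chain when it appears within `tgap + 1` time steps of
#' the chain's last observation and within `Ldisp` grid spaces of its last
#' position.  Matching is greedy per frame by smallest displacement, ties
#' broken by earliest detection order.  Chains shorter than `tdur` steps or
#' with mean spatial extent below `Lradius` are discarded.
#'
#' @param frames list of per-frame data.frames as produced by
#'   [detect_critical_points_frame()] (columns `x`, `y`, `cls`, `motion`,
#'   `extent`), time-ordered, one trial.
#' @param Ldisp maximum displacement between successive observations, grid
#'   spaces (default 0.5).
#' @param tgap maximum bridged time gap, steps (default 1).
#' @param tdur minimum duration, steps (default 5).
#' @param Lradius minimum mean extent, grid spaces (default 2).
#' @param combine_nodes_foci treat nodes and foci of the same motion sense
#'   as one type (default FALSE).
#' @param combine_spiral_in_out merge spiral-in/spiral-out (default FALSE).
#' @return data.frame of pattern instances: `ptype`, `t_start`, `t_end`,
#'   `duration`, `mean_extent`, plus a list-column `trajectory` of per-step
#'   positions (gap positions linearly interpolated).
#' @export
link_patterns <- function(frames, Ldisp = 0.5, tgap = 1L, tdur = 5L,
                          Lradius = 2, combine_nodes_foci = FALSE,
                          combine_spiral_in_out = FALSE) {
  active <- list()   # each: ptype, ts (times), xs, ys, exts
  done <- list()
  for (t in seq_along(frames)) {
    fr <- frames[[t]]
    # retire chains whose last observation is too old to extend
    if (length(active)) {
      last_t <- vapply(active, function(ch) ch$ts[length(ch$ts)], 0)
      expired <- t - last_t > tgap + 1L
      done <- c(done, active[expired])
      active <- active[!expired]
    }
    if (is.null(fr) || nrow(fr) == 0L) next
    pt <- cls_to_ptype(fr$cls, fr$motion, combine_nodes_foci,
                       combine_spiral_in_out)
    matched_chain <- rep(FALSE, length(active))
    matched_det <- rep(FALSE, nrow(fr))
    # candidate pairs within the gate, greedy by displacement then det order
    if (length(active)) {
      cand <- list()
      for (ci in seq_along(active)) {
        ch <- active[[ci]]
        for (di in seq_len(nrow(fr))) {
          if (pt[di] != ch$ptype) next
          dsp <- sqrt((fr$x[di] - ch$xs[length(ch$xs)])^2 +
                      (fr$y[di] - ch$ys[length(ch$ys)])^2)
          if (dsp <= Ldisp)
            cand[[length(cand) + 1L]] <- c(ci, di, dsp)
        }
      }
      if (length(cand)) {
        cand <- do.call(rbind, cand)
        cand <- cand[order(cand[, 3], cand[, 2]), , drop = FALSE]
        for (k in seq_len(nrow(cand))) {
          ci <- cand[k, 1]; di <- cand[k, 2]
          if (matched_chain[ci] || matched_det[di]) next
          ch <- active[[ci]]
          ch$ts <- c(ch$ts, t); ch$xs <- c(ch$xs, fr$x[di])
          ch$ys <- c(ch$ys, fr$y[di]); ch$exts <- c(ch$exts, fr$extent[di])
          active[[ci]] <- ch
          matched_chain[ci] <- TRUE; matched_det[di] <- TRUE
        }
      }
    }
    for (di in which(!matched_det)) {
      active[[length(active) + 1L]] <- list(
        ptype = pt[di], ts = t, xs = fr$x[di], ys = fr$y[di],
        exts = fr$extent[di])
    }
  }
  done <- c(done, active)
  keep <- list()
  for (ch in done) {
    dur <- ch$ts[length(ch$ts)] - ch$ts[1] + 1L
    if (dur < tdur) next
    if (mean(ch$exts) < Lradius) next
    traj <- data.frame(
      t = seq.int(ch$ts[1], ch$ts[length(ch$ts)]),
      x = stats::approx(ch$ts, ch$xs, xout = seq.int(ch$ts[1],
                                                     ch$ts[length(ch$ts)]))$y,
      y = stats::approx(ch$ts, ch$ys, xout = seq.int(ch$ts[1],
                                                     ch$ts[length(ch$ts)]))$y)
    keep[[length(keep) + 1L]] <- data.frame(
      ptype = ch$ptype, t_start = ch$ts[1], t_end = ch$ts[length(ch$ts)],
      duration = dur, mean_extent = mean(ch$exts))
    keep[[length(keep)]]$trajectory <- list(traj)
  }
  if (length(keep) == 0L) {
    out <- data.frame(ptype = character(0), t_start = integer(0),
                      t_end = integer(0), duration = integer(0),
                      mean_extent = numeric(0))
    out$trajectory <- list()
    return(out)
  }
  do.call(rbind, keep)
}

#' Convert interval detections into pattern-instance rows
#'
#' Plane-wave and synchrony intervals from [detect_global_intervals()] are
#' global patterns without a trajectory; this gives them the same tabular
#' form as [link_patterns()] output so they can join transition analysis.
#'
#' @param intervals data.frame from [detect_global_intervals()].
#' @param ptype `"plane_wave"` or `"synchrony"`.
#' @return data.frame matching the [link_patterns()] schema.
#' @export
intervals_to_patterns <- function(intervals, ptype) {
  if (nrow(intervals) == 0L) {
    out <- data.frame(ptype = character(0), t_start = integer(0),
                      t_end = integer(0), duration = integer(0),
                      mean_extent = numeric(0))
    out$trajectory <- list()
    return(out)
  }
  out <- data.frame(ptype = ptype, t_start = intervals$t_start,
                    t_end = intervals$t_end, duration = intervals$duration,
                    mean_extent = NA_real_)
  out$trajectory <- replicate(nrow(out), NULL, simplify = FALSE)
  out
}

#' Count observed pattern transitions
#'
#' For each ordered pair of pattern types (pA, pB), counts occurrences of a
#' pB instance starting within `window` time steps after a pA instance ends
#' (`0 < t_start(B) - t_end(A) <= window`).  Same-type transitions are
#' excluded by default, since a bridged gap already represents the
#' continuation of one pattern.
#'
#' @param patterns data.frame of pattern instances for one trial
#'   ([link_patterns()] schema).
#' @param window transition window in time steps (e.g. 50 ms * fs).
#' @param types character vector fixing the type set (and matrix order);
#'   defaults to the types present.
#' @param include_self count A -> A transitions (default FALSE).
#' @return square integer matrix of counts, rows = initial type, columns =
#'   following type.
#' @export
count_transitions <- function(patterns, window, types = NULL,
                              include_self = FALSE) {
  if (is.null(types)) types <- sort(unique(patterns$ptype))
  m <- matrix(0L, length(types), length(types),
              dimnames = list(from = types, to = types))
  if (nrow(patterns) == 0L) return(m)
  for (a in seq_len(nrow(patterns))) for (b in seq_len(nrow(patterns))) {
    if (a == b) next
    if (!include_self && patterns$ptype[a] == patterns$ptype[b]) next
    dt <- patterns$t_start[b] - patterns$t_end[a]
    if (dt > 0 && dt <= window) {
      ta <- patterns$ptype[a]; tb <- patterns$ptype[b]
      if (ta %in% types && tb %in% types)
        m[ta, tb] <- m[ta, tb] + 1L
    }
  }
  m
}

#' Expected transition count under the random-times null
#'
#' If `nA` patterns of type A and `nB` of type B begin and end at uniformly
#' random times in a trial of length `ttrial`, the expected number of B
#' onsets falling within `window` of an A offset is
#' `nA * nB * window / ttrial`.
#'
#' @param nA,nB pattern counts.
#' @param window transition window (same time units as `ttrial`,
#'   e.g. seconds).
#' @param ttrial trial length.
#' @return expected count (numeric).
#' @export
expected_transitions <- function(nA, nB, window, ttrial) {
  stopifnot(ttrial > 0)
  nA * nB * window / ttrial
}

#' Observed-vs-expected transition significance across trials
#'
#' Per ordered type pair, a paired t-test of observed against expected
#' counts across trials, Bonferroni-corrected over the number of testable
#' pairs.  The fractional change is `mean(obs)/mean(exp) - 1`.
#'
#' @param obs,exp 3D arrays (type x type x trial) of observed and expected
#'   counts, as from [count_transitions()] and [expected_transitions()] per
#'   trial.
#' @param alpha significance level after correction (default 0.05).
#' @return list with matrices `frac_change`, `p_value` (corrected; `NA`
#'   where the pair is constant/absent across trials), `significant`, and
#'   scalar `n_pairs` used in the correction.
#' @export
transition_significance <- function(obs, exp, alpha = 0.05) {
  stopifnot(length(dim(obs)) == 3L, all(dim(obs) == dim(exp)))
  ntr <- dim(obs)[3]
  if (ntr < 2L) stop("at least 2 trials are required for the paired test")
  k <- dim(obs)[1]
  frac <- matrix(NA_real_, k, k, dimnames = dimnames(obs)[1:2])
  pv <- matrix(NA_real_, k, k, dimnames = dimnames(obs)[1:2])
  testable <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    o <- obs[i, j, ]; e <- exp[i, j, ]
    if (all(o == 0) && all(e == 0)) next
    me <- mean(e)
    frac[i, j] <- if (me > 0) mean(o) / me - 1 else NA_real_
    d <- o - e
    if (stats::sd(d) == 0) next   # degenerate paired test
    testable[i, j] <- TRUE
    pv[i, j] <- stats::t.test(o, e, paired = TRUE)$p.value
  }
  n_pairs <- sum(testable)
  pcorr <- pmin(pv * n_pairs, 1)
  list(frac_change = frac, p_value = pcorr,
       significant = !is.na(pcorr) & pcorr < alpha, n_pairs = n_pairs)
}
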