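#' Construct a Recording object
#'
#' A `recording` holds a real-valued signal sampled on a regular 2D square
#' lattice over time, possibly across repeated trials, in the canonical axis
#' order (row, col, time, trial).  Rows increase downward and columns
#' rightward; throughout the package `x` refers to the column coordinate and
#' `y` to the row coordinate, both 0-based continuous grid units, and
#' velocities are expressed in grid spaces per time step.
#'
#' Channels (row, col sites) containing any non-finite sample are flagged as
#' invalid in `channel_mask` and their samples set to `NA`; use
#' [interpolate_bad_channels()] to fill them before analysis.
#'
#' @param signal numeric array with 2 to 4 dimensions.  Missing trailing
#'   dimensions are added: a 3D array is taken as (row, col, time) with a
#'   single trial.
#' @param fs sampling frequency in Hz.
#' @param grid_spacing physical distance per grid step (informational only).
#' @param channel_mask optional logical matrix (rows x cols), `TRUE` for
#'   valid channels.  Sites with non-finite samples are always flagged
#'   invalid in addition to this mask.
#' @return an object of class `recording` with fields `signal`, `fs`,
#'   `grid_spacing` and `channel_mask`.
#' @export
recording <- function(signal, fs, grid_spacing = NULL, channel_mask = NULL) {
  if (!is.numeric(signal) && !is.complex(signal))
    stop("signal must be a numeric array")
  d <- dim(signal)
  if (is.null(d)) stop("signal must have at least 2 dimensions")
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(d) == 3L) d <- c(d, 1L)
  if (length(d) != 4L) stop("signal must be coercible to a 4D array")
  dim(signal) <- d
  if (d[1] < 2L || d[2] < 2L)
    stop("spatial dimensions must each have at least 2 sites")
  if (d[3] < 2L) stop("time dimension must have at least 2 samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")

  bad <- apply(!is.finite(signal), c(1, 2), any)
  if (is.null(channel_mask)) {
    channel_mask <- !bad
  } else {
    stopifnot(is.logical(channel_mask), all(dim(channel_mask) == d[1:2]))
    channel_mask <- channel_mask & !bad
  }
  if (any(!channel_mask)) {
    idx <- which(!channel_mask, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) signal[idx[k, 1], idx[k, 2], , ] <- NA_real_
  }
  structure(
    list(signal = signal, fs = fs, grid_spacing = grid_spacing,
         channel_mask = channel_mask),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<recording> %d x %d grid, %d frames, %d trial(s), fs = %g Hz\n",
              d[1], d[2], d[3], d[4], x$fs))
  nb <- sum(!x$channel_mask)
  if (nb > 0) cat(sprintf("  %d invalid channel(s)\n", nb))
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$signal)

#' Load a recording from disk
#'
#' Reads a 2D-lattice recording from an HDF5 container (including MAT v7.3
#' files, which are HDF5 underneath) or from a native `.rds` file, and
#' permutes axes into the canonical (row, col, time, trial) order.
#'
#' @param path file to read (`.h5`, `.hdf5`, `.mat` via the `rhdf5` package,
#'   or `.rds`).
#' @param fs sampling frequency in Hz.  For `.rds` files holding a
#'   `recording` object this is taken from the file when omitted.
#' @param layout character string declaring the axis order of the stored
#'   array, one letter per dimension: `r` row, `c` column, `t` time,
#'   `p` trial.  Default `"rctp"`; 3D arrays default to `"rct"` (one trial).
#' @param dataset for HDF5 input, the name of the dataset to read; by
#'   default the first 3D/4D numeric dataset found.
#' @param grid_spacing optional physical grid step, stored as metadata.
#' @return a [recording()] object.
#' @export
load_recording <- function(path, fs = NULL, layout = NULL, dataset = NULL,
                           grid_spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    obj <- readRDS(path)
    if (inherits(obj, "recording")) return(obj)
    arr <- obj
  } else if (ext %in% c("h5", "hdf5", "mat")) {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("the rhdf5 package is required to read HDF5/MAT v7.3 files")
    if (is.null(dataset)) {
      info <- rhdf5::h5ls(path)
      ds <- info[info$otype == "H5I_DATASET", , drop = FALSE]
      nd <- vapply(strsplit(ds$dim, " x "), length, 1L)
      ds <- ds[nd >= 3L & nd <= 4L, , drop = FALSE]
      if (nrow(ds) == 0L) stop("no 3D/4D dataset found in ", path)
      dataset <- paste0(sub("/$", "", ds$group[1]), "/", ds$name[1])
    }
    arr <- rhdf5::h5read(path, dataset)
    if (is.null(fs)) {
      fsd <- try(rhdf5::h5read(path, "fs"), silent = TRUE)
      if (!inherits(fsd, "try-error")) fs <- as.numeric(fsd)
    }
  } else {
    stop("unsupported file extension: .", ext,
         " (supported: .h5, .hdf5, .mat [v7.3], .rds)")
  }
  if (is.null(fs)) stop("fs must be supplied (not present in file)")
  nd <- length(dim(arr))
  if (is.null(nd) || nd < 2L || nd > 4L)
    stop("stored array is not 2D-4D, cannot coerce to a recording")
  if (is.null(layout)) layout <- substr("rctp", 1L, nd)
  ax <- strsplit(layout, "")[[1]]
  if (length(ax) != nd || anyDuplicated(ax) ||
      !all(ax %in% c("r", "c", "t", "p")))
    stop("layout must use each of r, c, t, p at most once, one per dimension")
  perm <- match(c("r", "c", "t", "p"), ax)
  present <- !is.na(perm)
  arr <- aperm(arr, perm[present])
  dfull <- rep(1L, 4L)
  dfull[present] <- dim(arr)
  dim(arr) <- dfull
  recording(arr, fs = fs, grid_spacing = grid_spacing)
}

#' Save a recording to disk
#'
#' Writes the canonical 4D array plus sampling metadata either to a native
#' `.rds` file (bit-exact round trip) or an HDF5 file with datasets
#' `/signal` (row, col, time, trial) and `/fs`.
#'
#' @param rec a [recording()] object.
#' @param path destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    saveRDS(rec, path)
  } else if (ext %in% c("h5", "hdf5")) {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("the rhdf5 package is required to write HDF5 files")
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(rec$signal, path, "signal")
    rhdf5::h5write(rec$fs, path, "fs")
    rhdf5::h5closeAll()
  } else stop("unsupported file extension: .", ext)
  invisible(path)
}

#' Interpolate invalid channels
#'
#' Fills channels flagged invalid in `channel_mask` with the arithmetic mean
#' of their valid 4-neighbours (up/down/left/right), applied synchronously
#' and iteratively until every channel is filled.  Synchronous application
#' makes the result independent of channel ordering.
#'
#' @param rec a [recording()].
#' @return a `recording` with all channels valid.
#' @export
interpolate_bad_channels <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  mask <- rec$channel_mask
  if (all(mask)) return(rec)
  sig <- rec$signal
  d <- dim(sig)
  while (any(!mask)) {
    bad <- which(!mask, arr.ind = TRUE)
    fills <- vector("list", nrow(bad))
    fillable <- logical(nrow(bad))
    for (k in seq_len(nrow(bad))) {
      r <- bad[k, 1]; c <- bad[k, 2]
      nb <- rbind(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
      nb <- nb[nb[, 1] >= 1L & nb[, 1] <= d[1] &
               nb[, 2] >= 1L & nb[, 2] <= d[2], , drop = FALSE]
      nb <- nb[mask[nb], , drop = FALSE]
      if (nrow(nb) == 0L) next
      acc <- array(0, d[3:4])
      for (j in seq_len(nrow(nb))) acc <- acc + sig[nb[j, 1], nb[j, 2], , ]
      fills[[k]] <- acc / nrow(nb)
      fillable[k] <- TRUE
    }
    if (!any(fillable))
      stop("invalid channels with no valid neighbours anywhere; cannot interpolate")
    for (k in which(fillable)) sig[bad[k, 1], bad[k, 2], , ] <- fills[[k]]
    mask[bad[fillable, , drop = FALSE]] <- TRUE
  }
  recording(sig, fs = rec$fs, grid_spacing = rec$grid_spacing)
}

#' Normalise recording sites
#'
#' Removes per-site offset/scale factors (uneven electrode impedance, dye
#' intensity) prior to amplitude-pattern analysis, either by z-scoring each
#' site/trial time series or by subtracting a baseline-window mean.
#'
#' @param rec a [recording()] with all channels valid.
#' @param method `"zscore"`, `"baseline_subtract"` or `"none"`.
#' @param baseline_window integer vector `c(from, to)` of time indices used
#'   for `baseline_subtract`; defaults to the whole series.
#' @return a normalised `recording`.
#' @export
normalize_sites <- function(rec,
                            method = c("zscore", "baseline_subtract", "none"),
                            baseline_window = NULL) {
  stopifnot(inherits(rec, "recording"))
  method <- match.arg(method)
  if (method == "none") return(rec)
  if (any(!rec$channel_mask))
    stop("recording has invalid channels; run interpolate_bad_channels() first")
  sig <- rec$signal
  d <- dim(sig)
  if (method == "baseline_subtract") {
    if (is.null(baseline_window)) baseline_window <- c(1L, d[3])
    bw <- as.integer(baseline_window)
    if (length(bw) != 2L || bw[1] < 1L || bw[2] > d[3] || bw[1] > bw[2])
      stop("baseline_window must lie within the time axis")
  }
  for (p in seq_len(d[4])) for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    x <- sig[r, c, , p]
    if (method == "zscore") {
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0)
        stop(sprintf("zero-variance site (row %d, col %d, trial %d) under zscore",
                     r, c, p))
      sig[r, c, , p] <- (x - mean(x)) / s
    } else {
      sig[r, c, , p] <- x - mean(x[bw[1]:bw[2]])
    }
  }
  recording(sig, fs = rec$fs, grid_spacing = rec$grid_spacing)
}

#' Check temporal sampling adequacy
#'
#' Optical flow assumes frame-to-frame changes are small.  For each
#' site/trial series this computes the maximum absolute one-step change
#' divided by that site's full range, and reports the across-site maximum.
#' Values above 0.10 suggest the sampling frequency is too low for reliable
#' flow estimation; values below 0.01 suggest the data can safely be
#' down-sampled in time.
#'
#' @param rec a [recording()].
#' @return a list with `max_frac_change`, `warn_high` and `warn_low`.
#' @export
check_sampling_adequacy <- function(rec, high = 0.10, low = 0.01) {
  stopifnot(inherits(rec, "recording"))
  sig <- rec$signal
  d <- dim(sig)
  mx <- 0
  for (p in seq_len(d[4])) for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    x <- sig[r, c, , p]
    if (any(!is.finite(x))) next
    rg <- max(x) - min(x)
    frac <- if (rg == 0) 0 else max(abs(diff(x))) / rg
    if (frac > mx) mx <- frac
  }
  list(max_frac_change = mx, warn_high = mx > high, warn_low = mx < low)
}

#' Spatially down-sample a recording
#'
#' Replaces each `factor` x `factor` block of sites with its mean, reducing
#' the density of the grid (and of the later velocity fields).  If `factor`
#' does not divide a spatial dimension the trailing rows/columns are
#' truncated with a warning.
#'
#' @param rec a [recording()].
#' @param factor positive integer block size.
#' @return a down-sampled `recording`; `fs` is unchanged.
#' @export
downsample_spatial <- function(rec, factor) {
  stopifnot(inherits(rec, "recording"))
  factor <- as.integer(factor)
  d <- dim(rec$signal)
  if (factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(rec)
  if (factor > min(d[1:2])) stop("factor larger than a spatial dimension")
  nr <- d[1] %/% factor; nc <- d[2] %/% factor
  if (nr * factor != d[1] || nc * factor != d[2])
    warning("factor does not divide the grid; trailing rows/cols truncated")
  sig <- rec$signal[seq_len(nr * factor), seq_len(nc * factor), , , drop = FALSE]
  out <- array(0, c(nr, nc, d[3], d[4]))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    blk <- sig[(i - 1L) * factor + seq_len(factor),
               (j - 1L) * factor + seq_len(factor), , , drop = FALSE]
    out[i, j, , ] <- apply(blk, c(3, 4), mean)
  }
  recording(out, fs = rec$fs, grid_spacing =
              if (is.null(rec$grid_spacing)) NULL else rec$grid_spacing * factor)
}

#' Spatially smooth a recording with a Gaussian kernel
#'
#' Optional pre-flow smoothing for noisy data.  Convolves each frame with a
#' symmetric 2D Gaussian (replicate-padded at the boundary).
#'
#' @param rec a [recording()].
#' @param sigma Gaussian standard deviation in grid spaces.
#' @return a smoothed `recording`.
#' @export
smooth_spatial <- function(rec, sigma) {
  stopifnot(inherits(rec, "recording"), sigma > 0)
  h <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(-h:h, sd = sigma)
  g <- g / sum(g)
  sig <- rec$signal
  d <- dim(sig)
  for (p in seq_len(d[4])) for (t in seq_len(d[3])) {
    fr <- sig[, , t, p]
    fr <- apply(fr, 2, conv_replicate, g = g)          # along rows
    fr <- t(apply(fr, 1, conv_replicate, g = g))       # along cols
    sig[, , t, p] <- fr
  }
  recording(sig, fs = rec$fs, grid_spacing = rec$grid_spacing)
}

# 1D convolution with replicate padding
conv_replicate <- function(x, g) {
  h <- (length(g) - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, g, sides = 2))[(h + 1L):(h + length(x))]
}
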