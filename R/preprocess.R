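#' Wavelet-denoise a pulse record
#'
#' Removes high-frequency noise by soft universal thresholding of the detail
#' coefficients of a periodized Daubechies-4 decomposition. The default
#' level, `ceiling(log2(fs / 8))`, places the approximation band below
#' roughly 8 Hz at any sampling rate, retaining pulse morphology while the
#' thresholded detail bands carry the noise.
#'
#' @param record A `pulse_record` (see [generate_record()]) or any list with
#'   `samples` and `fs`.
#' @param level Decomposition depth; the signal must be at least `2^level`
#'   samples long.
#' @return The record with `samples` replaced by the denoised signal (same
#'   length and sampling rate).
#' @export
denoise <- function(record, level = NULL) {
  stopifnot(is.numeric(record$samples), is.numeric(record$fs))
  if (is.null(level)) level <- max(1L, ceiling(log2(record$fs / 8)))
  if (length(record$samples) < 2^level)
    stop("decomposition level ", level, " too deep for signal of length ",
         length(record$samples))
  record$samples <- wt_denoise(record$samples, level)
  record
}

#' A single extracted pulse cycle
#'
#' @param samples Amplitudes (raw units), length >= 16, finite.
#' @param fs Sampling rate in Hz.
#' @param subject_id,cycle_index Provenance.
#' @return A `pulse_cycle` list.
#' @export
pulse_cycle <- function(samples, fs, subject_id = NA_character_,
                        cycle_index = NA_integer_) {
  stopifnot(length(samples) >= 16, all(is.finite(samples)), fs > 0)
  structure(list(samples = samples, fs = fs, subject_id = subject_id,
                 cycle_index = cycle_index),
            class = "pulse_cycle")
}

# Local maxima of v above a threshold, keeping at most one peak per
# refractory window (larger value wins).
.peaks <- function(v, thr, refractory) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n] &
                  v[2:(n - 1)] > thr) + 1L
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand)
    if (all(abs(i - kept) >= refractory)) kept <- c(kept, i)
  sort(kept)
}

#' Segment a pulse record into cycles
#'
#' Foot-based segmentation: each cycle starts at the local minimum
#' (waveform foot) preceding a maximal upstroke. Upstrokes are local maxima
#' of the smoothed first difference above half its peak value; a first pass
#' with a 0.3 s refractory period estimates the median cycle length, and the
#' final pass uses a refractory period of 0.4 x that estimate. The input is
#' assumed to be denoised.
#'
#' @param record A `pulse_record`-like list with `samples` and `fs`.
#' @return List of [pulse_cycle()]s partitioning the span from the first
#'   detected foot to the end of the record, with the detected feet (1-based
#'   start indices) in attribute `"feet"`. An empty list (with a warning) if
#'   no cycles are detectable.
#' @export
segment_cycles <- function(record) {
  x <- record$samples
  fs <- record$fs
  n <- length(x)
  slope <- diff(x)
  win <- max(1L, as.integer(round(fs * 0.05)))
  if (win > 1) {
    k <- rep(1 / win, win)
    slope <- as.numeric(stats::filter(slope, k, sides = 2))
    slope[is.na(slope)] <- 0
  }
  smax <- max(slope)
  if (!is.finite(smax) || smax <= .Machine$double.eps * max(1, max(abs(x)))) {
    warning("no detectable cycles: signal has no upstrokes")
    return(list())
  }
  up <- .peaks(slope, 0.5 * smax, max(2L, as.integer(round(0.3 * fs))))
  if (length(up) == 0) {
    warning("no detectable cycles: no upstroke exceeded the slope threshold")
    return(list())
  }
  med <- if (length(up) >= 2) median(diff(up)) else round(0.8 * fs)
  up <- .peaks(slope, 0.5 * smax, max(2L, as.integer(round(0.4 * med))))
  back <- max(2L, as.integer(round(0.35 * med)))
  fwd <- max(2L, as.integer(round(0.5 * med)))
  # Local linear baseline over a window [lo, hi], fitted to the lowest 30%
  # of the first `pl_len` samples (the pre-upstroke plateau). Removes the
  # slow wander tilt without distorting the waveform shape.
  detrended_window <- function(lo, hi, pl_len) {
    seg <- x[lo:hi]
    pl <- seg[seq_len(pl_len)]
    sel <- which(pl <= stats::quantile(pl, 0.3, names = FALSE))
    if (length(sel) >= 2 && stats::var(sel) > 0) {
      b <- stats::cov(sel, pl[sel]) / stats::var(sel)
      a <- mean(pl[sel]) - b * mean(sel)
    } else {
      b <- 0
      a <- min(pl)
    }
    seg - (a + b * seq_along(seg))
  }
  # foot criterion: last pre-upstroke sample within 6% of the plateau level
  foot_in_window <- function(w, pl_len) {
    base <- stats::quantile(w[seq_len(pl_len)], 0.1, names = FALSE)
    amp <- max(w) - base
    cross <- which(w[seq_len(pl_len)] <= base + 0.06 * amp)
    if (length(cross) == 0) which.min(w[seq_len(pl_len)]) else max(cross)
  }
  feet <- vapply(up, function(u) {
    lo <- max(1L, u - back)
    hi <- min(n, u + fwd)
    w <- detrended_window(lo, hi, u - lo + 1L)
    lo + foot_in_window(w, u - lo + 1L) - 1L
  }, 0L)
  # refine: align every foot to the ensemble-median window around the
  # upstroke (removing per-foot detection jitter), then re-anchor the
  # common phase by applying the foot criterion to the low-noise template
  wb <- max(2L, as.integer(round(0.15 * med)))
  wf <- max(4L, as.integer(round(0.25 * med)))
  for (pass in 1:2) {
    sr <- if (pass == 1) 8L else 4L
    ok <- feet - wb - sr >= 1L & feet + wf + sr <= n
    if (sum(ok) < 3) break
    wins <- vapply(feet[ok], function(f)
      detrended_window(f - wb, f + wf, wb + 1L),
      numeric(wb + wf + 1L))
    templ <- apply(wins, 1, median)
    anchor <- foot_in_window(templ, min(length(templ), wb + 4L)) - (wb + 1L)
    shifts <- seq.int(-sr, sr)
    feet <- vapply(seq_along(feet), function(i) {
      f <- feet[i]
      if (!ok[i]) return(f)
      ssd <- vapply(shifts, function(d) {
        w <- detrended_window(f + d - wb, f + d + wf, wb + 1L)
        sum((w - templ)^2)
      }, 0)
      f + shifts[which.min(ssd)] + anchor
    }, 0L)
    feet <- feet[feet >= 1L & feet <= n]
  }
  feet <- sort(unique(feet))
  starts <- feet
  ends <- c(feet[-1] - 1L, n)
  keep <- (ends - starts + 1L) >= 16L
  starts <- starts[keep]
  ends <- ends[keep]
  if (length(starts) == 0) {
    warning("no detectable cycles: all candidate cycles too short")
    return(list())
  }
  out <- lapply(seq_along(starts), function(i)
    pulse_cycle(x[starts[i]:ends[i]], fs,
                subject_id = record$subject_id, cycle_index = i))
  attr(out, "feet") <- starts
  out
}

#' Resample a cycle to a fixed number of points
#'
#' Piecewise-linear interpolation onto a uniform grid spanning the cycle;
#' the first and last raw samples are preserved exactly.
#'
#' @param cycle A [pulse_cycle()] or numeric vector of length >= 2.
#' @param n_points Output length (200 by default).
#' @return Numeric vector of length `n_points`.
#' @export
resample_cycle <- function(cycle, n_points = 200) {
  y <- if (inherits(cycle, "pulse_cycle")) cycle$samples else cycle
  if (length(y) < 2) stop("cycle must contain at least 2 samples")
  approx(x = seq(0, 1, length.out = length(y)), y = y,
         xout = seq(0, 1, length.out = n_points))$y
}

#' Normalize cycle amplitude to the 0-200 range
#'
#' Affine map sending the cycle minimum to 0 and maximum to 200.
#'
#' @param values Non-constant numeric vector (length 200 for the standard
#'   pipeline).
#' @return A `normalized_cycle` numeric vector with min 0 and max 200.
#' @export
normalize_amplitude <- function(values) {
  values <- unclass(values)
  stopifnot(is.numeric(values), all(is.finite(values)))
  r <- range(values)
  if (r[1] == r[2])
    stop("degenerate cycle: constant amplitude cannot be normalized")
  structure((values - r[1]) / (r[2] - r[1]) * 200, class = "normalized_cycle")
}

.round_half_up <- function(x) floor(x + 0.5)

#' Rasterize a normalized cycle into a 200 x 200 image
#'
#' Column `x` carries the curve at the row corresponding to its amplitude
#' (y axis upward, row 1 at the top): amplitude `v` maps to 0-based row
#' `199 - round(v)` from the top, with rounded amplitudes clamped to 199.
#' Vertically adjacent samples are connected by filling the full span
#' between consecutive rows in the current column, so each column holds
#' exactly one contiguous foreground run and the trace is 8-connected.
#' Background pixels are 0, the curve is 255.
#'
#' @param values A `normalized_cycle` (length 200, values in 0-200).
#' @return A `pulse_image`: 200 x 200 integer matrix of 0/255.
#' @export
rasterize <- function(values) {
  v <- unclass(values)
  stopifnot(length(v) == 200, all(is.finite(v)))
  if (any(v < 0 | v > 200))
    stop("normalized values must lie in [0, 200]")
  r0 <- pmin(199, .round_half_up(v))      # 0-based amplitude row
  rows <- 200L - as.integer(r0)           # 1-based row from top
  img <- matrix(0L, 200, 200)
  img[rows[1], 1] <- 255L
  for (x in 2:200) {
    span <- sort(c(rows[x - 1], rows[x]))
    img[span[1]:span[2], x] <- 255L
  }
  structure(img, class = c("pulse_image", class(img)))
}

#' Recover per-column amplitudes from a pulse image
#'
#' Inverts [rasterize()]: for each column, among the endpoints of the
#' foreground run, the row farthest from the previous column's recovered row
#' is the sample row (the nearer endpoint belongs to the connecting fill).
#' Recovery is exact up to the +/-1-unit rounding/clamping quantization.
#'
#' @param img A `pulse_image`.
#' @return Numeric vector of 200 recovered amplitudes in 0-199.
#' @export
image_to_values <- function(img) {
  stopifnot(nrow(img) == 200, ncol(img) == 200)
  vals <- numeric(200)
  prev <- NA_integer_
  for (x in 1:200) {
    fg <- which(img[, x] > 0)
    if (length(fg) == 0) stop("column ", x, " has no foreground pixel")
    ends <- c(fg[1], fg[length(fg)])
    row <- if (is.na(prev)) ends[1]
    else ends[which.max(abs(ends - prev))]
    vals[x] <- 200 - row
    prev <- row
  }
  vals
}

#' Full preprocessing chain for one record
#'
#' denoise -> segment -> 200-point resampling -> 0-200 normalization ->
#' 200 x 200 rasterization. Degenerate (constant) cycles are dropped.
#'
#' @param record A `pulse_record`.
#' @param denoise_level Passed to [denoise()].
#' @return List with `cycles` (the segmented [pulse_cycle()]s),
#'   `normalized` (list of `normalized_cycle`s) and `images` (list of
#'   `pulse_image`s), one entry per kept cycle.
#' @export
preprocess_record <- function(record, denoise_level = NULL) {
  den <- denoise(record, level = denoise_level)
  cycles <- segment_cycles(den)
  normalized <- list()
  images <- list()
  kept <- list()
  for (cy in cycles) {
    rs <- resample_cycle(cy, 200)
    if (max(rs) == min(rs)) next
    nc <- normalize_amplitude(rs)
    kept[[length(kept) + 1L]] <- cy
    normalized[[length(normalized) + 1L]] <- nc
    images[[length(images) + 1L]] <- rasterize(nc)
  }
  list(cycles = kept, normalized = normalized, images = images)
}

#' Write / read a pulse image as 8-bit grayscale PNG
#'
#' @param img A `pulse_image` (0/255 integer matrix).
#' @param path File path.
#' @return `read_pulse_png()` returns a `pulse_image`; the round trip is
#'   lossless.
#' @export
write_pulse_png <- function(img, path) {
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' @rdname write_pulse_png
#' @export
read_pulse_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  structure(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)),
            class = c("pulse_image", "matrix", "array"))
}

#' Read a raw pulse record from CSV
#'
#' Expects columns `time_s` and `amplitude` as written by
#' [write_record_csv()].
#'
#' @param path CSV path.
#' @param subject_id,label Metadata to attach.
#' @return A `pulse_record` (without ground-truth boundaries).
#' @export
read_record_csv <- function(path, subject_id = NA_character_,
                            label = NA_character_) {
  d <- read.csv(path)
  stopifnot(all(c("time_s", "amplitude") %in% names(d)), nrow(d) >= 2)
  fs <- 1 / median(diff(d$time_s))
  structure(list(samples = d$amplitude, fs = fs, true_boundaries = NULL,
                 true_label = label, subject_id = subject_id, clean = NULL),
            class = "pulse_record")
}

#' @rdname read_record_csv
#' @param record A `pulse_record` to write.
#' @export
write_record_csv <- function(record, path) {
  d <- data.frame(time_s = (seq_along(record$samples) - 1) / record$fs,
                  amplitude = record$samples)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
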