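# Glottal cycle detection from the EGG first derivative (dEGG).  Positive
# dEGG peaks mark contacting events, the standard cycle landmark; boundary
# positions are refined to sub-sample accuracy by parabolic interpolation
# so that cycle-shape descriptors are not polluted by sample-grid jitter.

#' High-pass precondition an EGG signal
#'
#' Removes electrode/baseline drift with a zero-phase 4th-order Butterworth
#' high-pass (applied forward and backward).
#'
#' @param egg an [egg_signal].
#' @param cutoff_hz high-pass cutoff in Hz (default 20, well below any
#'   phonation frequency of interest).
#' @return The filtered [egg_signal].
#' @export
precondition_egg <- function(egg, cutoff_hz = 20) {
  stopifnot(inherits(egg, "sampled_signal"))
  if (is.null(cutoff_hz) || cutoff_hz <= 0) return(egg)
  bf <- signal::butter(2, cutoff_hz / (egg$fs / 2), type = "high")
  # reflect-pad so the filter transient decays outside the signal
  x <- egg$samples
  np <- min(length(x) - 1L, ceiling(egg$fs / cutoff_hz * 2))
  pad <- c(2 * x[1L] - x[(np + 1L):2L], x, 2 * x[length(x)] -
             x[(length(x) - 1L):(length(x) - np)])
  y <- as.numeric(signal::filtfilt(bf, pad))
  egg$samples <- y[(np + 1L):(np + length(x))]
  egg
}

#' First derivative of the EGG (dEGG)
#'
#' Optionally smooths the EGG with a centred moving average, then takes the
#' first difference scaled by the sampling rate. Under the contact-positive
#' polarity convention, contacting events appear as positive dEGG peaks.
#'
#' @param egg an [egg_signal] (or any [sampled_signal]).
#' @param smoothing_len odd moving-average length in samples (1 = none).
#' @return A `c("degg_signal", "sampled_signal")` of length `n - 1`; sample
#'   `i` sits at the midpoint between input samples `i` and `i + 1`.
#' @export
compute_degg <- function(egg, smoothing_len = 1L) {
  stopifnot(inherits(egg, "sampled_signal"))
  smoothing_len <- as.integer(smoothing_len)
  if (smoothing_len < 1L || smoothing_len %% 2L == 0L)
    stop("smoothing_len must be odd and >= 1")
  x <- egg$samples
  if (length(x) <= smoothing_len)
    stop("signal shorter than smoothing_len")
  if (smoothing_len > 1L) {
    k <- rep(1 / smoothing_len, smoothing_len)
    sm <- stats::filter(x, k, sides = 2)
    # fill filter edges with the original samples
    idx <- which(is.na(sm))
    sm[idx] <- x[idx]
    x <- as.numeric(sm)
  }
  d <- diff(x) * egg$fs
  out <- sampled_signal(d, egg$fs, t0 = egg$t0 + 0.5 / egg$fs,
                        unit = paste0("d/dt ", egg$unit))
  class(out) <- c("degg_signal", class(out))
  out
}

# Shared pulse-peak picker.  Local maxima above an adaptive threshold
# (fraction of the running peak amplitude in a +-neighbourhood -- a high
# quantile would sit at the noise level for narrow pulses -- with a global
# floor so silent stretches stay peak-free), then greedy amplitude-ranked
# enforcement of the minimum spacing fs/fo_max: of any two candidates
# closer than the minimum period, the larger peak survives.  Returns
# fractional sample positions (sub-sample refinement below).
find_pulse_peaks <- function(x, fs, fo_min, fo_max,
                             rel_threshold = 0.2,
                             neighbourhood_s = 0.05,
                             floor_frac = 0.1) {
  n <- length(x)
  pos <- pmax(x, 0)
  # coarse running local maximum, evaluated every 10 ms and interpolated
  hop <- max(1L, round(0.010 * fs))
  half <- max(1L, round(neighbourhood_s * fs))
  centers <- seq(1L, n, by = hop)
  local_max <- vapply(centers, function(c0) {
    lo <- max(1L, c0 - half); hi <- min(n, c0 + half)
    max(pos[lo:hi])
  }, numeric(1))
  local_scale <- stats::approx(centers, local_max, xout = seq_len(n),
                               rule = 2)$y
  thr <- rel_threshold * pmax(local_scale, floor_frac * max(pos))
  core <- 2:(n - 1L)
  is_peak <- x[core] > x[core - 1L] & x[core] >= x[core + 1L] &
    x[core] > thr[core]
  cand <- core[is_peak]
  if (length(cand) == 0L) return(numeric(0))
  min_dist <- fs / fo_max
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(n)
  blocked <- logical(n)
  for (i in ord) {
    if (blocked[i]) next
    keep[i] <- TRUE
    lo <- max(1L, ceiling(i - min_dist)); hi <- min(n, floor(i + min_dist))
    blocked[lo:hi] <- TRUE
  }
  peaks <- sort(which(keep))
  # Two-pass sub-sample refinement.  Pass 1: parabolic interpolation on
  # the raw samples gives fractional peak positions and hence a smooth
  # local period estimate.  Pass 2: the peak is re-located on a Gaussian-
  # kernel-smoothed version of the signal whose bandwidth is a fixed
  # fraction of the local period.  Period-proportional smoothing keeps
  # the (tiny) systematic peak shift constant in *phase* units across an
  # fo glide, so cycle-shape descriptors do not drift with fo, while the
  # kernel average suppresses noise-induced boundary jitter on broad
  # peaks.
  parab <- function(i) {
    if (i <= 1L || i >= n) return(as.numeric(i))
    den <- x[i - 1L] - 2 * x[i] + x[i + 1L]
    if (den >= 0) return(as.numeric(i))
    i + max(-0.5, min(0.5, 0.5 * (x[i - 1L] - x[i + 1L]) / den))
  }
  rough <- vapply(peaks, parab, numeric(1))
  gaps <- diff(rough)
  period_at <- function(k) {
    g <- c(if (k > 1L) gaps[k - 1L], if (k < length(rough)) gaps[k])
    min(g)
  }
  h <- 1 / 16
  refine <- function(k) {
    p0 <- rough[k]
    sigma <- max(1, period_at(k) / 24)
    reach <- ceiling(4 * sigma)
    lo <- max(1L, floor(p0) - reach - 3L)
    hi <- min(n, ceiling(p0) + reach + 3L)
    grid <- seq(max(lo + 1, p0 - 3), min(hi - 1, p0 + 3), by = h)
    if (length(grid) < 3L) return(p0)
    w_mat <- outer(grid, lo:hi, function(p, j) stats::dnorm(j - p, sd = sigma))
    y <- as.numeric(w_mat %*% x[lo:hi]) / rowSums(w_mat)
    j <- which.max(y)
    if (j <= 1L || j >= length(y)) return(grid[j])
    den <- y[j - 1L] - 2 * y[j] + y[j + 1L]
    if (den >= 0) return(grid[j])
    grid[j] + h * max(-0.5, min(0.5, 0.5 * (y[j - 1L] - y[j + 1L]) / den))
  }
  sort(vapply(seq_along(peaks), refine, numeric(1)))
}

#' Detect glottal cycles from the dEGG
#'
#' One boundary per contacting event (positive dEGG peak). Boundary spacing
#' is constrained to `[fs/fo_max, fs/fo_min]`; of conflicting candidate
#' peaks the larger one is kept. Cycles whose implied fundamental frequency
#' falls outside `[fo_min, fo_max]` (e.g. across an unvoiced gap) are
#' retained in the boundary list but flagged invalid.
#'
#' @param degg a `degg_signal` from [compute_degg()].
#' @param fo_min,fo_max admissible fundamental-frequency range in Hz,
#'   both within (20, 2000).
#' @return A `cycle_segmentation`: list with `boundaries` (fractional,
#'   1-based sample positions of cycle starts), `fo` (Hz per cycle),
#'   `valid` (logical per cycle), `fs`, `t0`, `n_samples`, `source`.
#' @export
detect_cycles <- function(degg, fo_min = 150, fo_max = 1200) {
  stopifnot(inherits(degg, "sampled_signal"))
  if (!(fo_min < fo_max) || fo_min <= 20 || fo_max >= 2000)
    stop("need 20 < fo_min < fo_max < 2000 Hz")
  b <- find_pulse_peaks(degg$samples, degg$fs, fo_min, fo_max)
  if (length(b) >= 4L) {
    # periodicity check: voiced signals evolve their period smoothly,
    # aperiodic input yields erratic peak spacing
    rel_jump <- abs(diff(diff(b))) / diff(b)[-1L]
    if (stats::median(rel_jump) > 0.2)
      stop("unvoiced or too short: no stable periodicity in dEGG peaks")
  }
  # dEGG sample i sits midway between source samples i and i+1: shift
  # boundaries by half a sample into source-signal coordinates
  make_segmentation(b + 0.5, degg$fs, degg$t0 - 0.5 / degg$fs,
                    length(degg$samples) + 1L, fo_min, fo_max,
                    source = "degg")
}

make_segmentation <- function(boundaries, fs, t0, n_samples,
                              fo_min, fo_max, source) {
  if (length(boundaries) < 4L)
    stop("unvoiced or too short: fewer than 3 cycles detected")
  fo <- fs / diff(boundaries)
  valid <- fo >= fo_min & fo <= fo_max
  if (sum(valid) < 3L)
    stop("unvoiced or too short: fewer than 3 valid cycles")
  structure(
    list(boundaries = boundaries, fo = fo, valid = valid,
         fs = fs, t0 = t0, n_samples = n_samples,
         fo_min = fo_min, fo_max = fo_max, source = source),
    class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf(
    "<cycle_segmentation> %d cycles (%d valid) from %s, fo %.1f-%.1f Hz\n",
    length(x$fo), sum(x$valid), x$source,
    min(x$fo[x$valid]), max(x$fo[x$valid])))
  invisible(x)
}

#' Per-cycle midpoint times of a segmentation
#' @param seg a `cycle_segmentation`.
#' @param valid_only drop invalid cycles (default TRUE).
#' @return Numeric vector of cycle midpoint times in seconds.
#' @export
cycle_times <- function(seg, valid_only = TRUE) {
  b <- seg$boundaries
  mid <- (b[-length(b)] + b[-1L]) / 2
  tt <- sample_to_time(mid, seg$fs, seg$t0)
  if (valid_only) tt[seg$valid] else tt
}

#' Extract, resample and normalize individual cycles
#'
#' Each valid cycle is sampled at `n_resample` uniformly spaced points of
#' glottal *phase*, not of time: the phase map is a monotone cubic
#' interpolant through the cycle boundaries, so a fundamental-frequency
#' sweep within a cycle does not masquerade as a cycle-shape change.
#' Sample values are taken by cubic-spline interpolation at the resulting
#' fractional positions (shape independent of how many raw samples a
#' cycle spans). Each cycle is then normalized to zero mean and unit
#' peak-to-peak amplitude, making the result a pure shape descriptor.
#'
#' @param egg the signal the segmentation was computed from (EGG for shape
#'   analysis; any [sampled_signal] works, e.g. dEGG for wavegrams).
#' @param seg a `cycle_segmentation`.
#' @param n_resample points per cycle, >= 16.
#' @param normalize `"ptp"` (zero mean, unit peak-to-peak; default) or
#'   `"none"`.
#' @return Numeric matrix, one row per valid cycle, with attributes
#'   `cycle_times` (midpoint s), `cycle_index` (index into `seg$fo`) and
#'   `degenerate` (logical; flat cycles, left as zeros).
#' @export
extract_cycles <- function(egg, seg, n_resample = 64L,
                           normalize = c("ptp", "none")) {
  normalize <- match.arg(normalize)
  n_resample <- as.integer(n_resample)
  if (n_resample < 16L) stop("n_resample must be >= 16")
  stopifnot(inherits(seg, "cycle_segmentation"))
  x <- egg$samples
  b <- seg$boundaries
  idx <- which(seg$valid)
  phase <- (seq_len(n_resample) - 1L) / n_resample
  out <- matrix(0, nrow = length(idx), ncol = n_resample)
  degenerate <- logical(length(idx))
  sf <- stats::splinefun(seq_along(x), x, method = "natural")
  # position as a monotone function of cycle phase (boundary i <-> phase i)
  psf <- if (length(b) >= 4L)
    stats::splinefun(seq_along(b), b, method = "monoH.FC")
  else function(p) stats::approx(seq_along(b), b, xout = p)$y
  for (k in seq_along(idx)) {
    i <- idx[k]
    pos <- psf(i + phase)
    row <- sf(pmin(pmax(pos, 1), length(x)))
    if (normalize == "ptp") {
      ptp <- max(row) - min(row)
      if (ptp < .Machine$double.eps * max(1, max(abs(row)))) {
        degenerate[k] <- TRUE
        row <- rep(0, n_resample)
      } else {
        row <- (row - mean(row)) / ptp
      }
    }
    out[k, ] <- row
  }
  attr(out, "cycle_times") <- cycle_times(seg)
  attr(out, "cycle_index") <- idx
  attr(out, "degenerate") <- degenerate
  out
}
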