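# Open quotient statistics from the glottal area waveform (GAW), over the
# 11 analysis windows aligned on maximum FDSE_w.

#' Detect glottal cycles from a GAW
#'
#' Video-native cycle detection for recordings whose camera clock is not
#' shared with the EGG: area maxima are located with the same adaptive
#' peak picker as dEGG contacting events, and each cycle boundary is
#' placed at the last area minimum preceding the subsequent opening.
#'
#' @param gaw a [gaw_series].
#' @param fo_min,fo_max admissible fundamental-frequency range in Hz.
#' @return A `cycle_segmentation` with `source = "gaw"`.
#' @export
gaw_cycles <- function(gaw, fo_min = 150, fo_max = 1200) {
  stopifnot(inherits(gaw, "gaw_series"))
  if (!(fo_min < fo_max) || fo_min <= 20 || fo_max >= 2000)
    stop("need 20 < fo_min < fo_max < 2000 Hz")
  x <- gaw$samples
  if (max(x) - min(x) <= .Machine$double.eps)
    stop("unvoiced or too short: constant glottal area")
  peaks <- find_pulse_peaks(x - min(x), gaw$fs, fo_min, fo_max)
  if (length(peaks) < 4L)
    stop("unvoiced or too short: fewer than 3 cycles detected")
  pk <- round(peaks)
  b <- vapply(seq_len(length(pk) - 1L), function(i) {
    span <- pk[i]:pk[i + 1L]
    v <- x[span]
    # last near-minimum sample before the next opening; a 5% threshold
    # crossing is robust to noise on the flat closed phase, where the
    # literal minimum wanders
    thr <- min(v) + 0.05 * (max(v) - min(v))
    as.numeric(span[max(which(v <= thr))])
  }, numeric(1))
  b <- unique(b)
  make_segmentation(b, gaw$fs, gaw$t0, length(x), fo_min, fo_max,
                    source = "gaw")
}

#' Per-cycle open quotient of the GAW
#'
#' The open quotient of a cycle is the fraction of its samples whose area
#' exceeds the cycle baseline (the cycle minimum) by more than
#' `open_threshold_frac` of the cycle peak-to-peak amplitude -- the
#' relative, time-normalized duration of glottal opening per vibratory
#' cycle. A small positive threshold guards against segmentation noise on
#' the closed phase.
#'
#' @param gaw a [gaw_series].
#' @param seg a `cycle_segmentation` (typically from [gaw_cycles()]).
#' @param open_threshold_frac threshold as a fraction of the cycle
#'   peak-to-peak amplitude, in \[0, 0.2).
#' @return An `oq_trace`: data.frame with columns `cycle`, `t_mid` (s),
#'   `oq` (`NA` for degenerate flat cycles).
#' @export
open_quotient <- function(gaw, seg, open_threshold_frac = 0.02) {
  stopifnot(inherits(seg, "cycle_segmentation"))
  if (!(open_threshold_frac >= 0 && open_threshold_frac < 0.2))
    stop("open_threshold_frac must be in [0, 0.2)")
  x <- gaw$samples
  b <- seg$boundaries
  idx <- which(seg$valid)
  oq <- rep(NA_real_, length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    span <- ceiling(b[i]):min(length(x), ceiling(b[i + 1L]) - 1L)
    if (length(span) < 2L) next
    v <- x[span]
    ptp <- max(v) - min(v)
    if (ptp <= .Machine$double.eps * max(1, max(abs(v)))) next  # degenerate
    thr <- min(v) + open_threshold_frac * ptp
    oq[k] <- sum(v > thr) / length(v)
  }
  out <- data.frame(cycle = idx, t_mid = cycle_times(seg), oq = oq)
  class(out) <- c("oq_trace", class(out))
  out
}

#' Window means, between-window differences and their SD of the OQ
#'
#' Averages the per-cycle open quotient within each of the 11 aligned
#' analysis windows (cycle-to-window assignment by cycle midpoint, the
#' same rule the FDSE windowing uses), then forms the 10 between-window
#' differences delta_OQ and their standard deviation across windows.
#' Missing windows propagate; differences involving a missing window are
#' `NA` and are excluded pairwise from the SD.
#'
#' @param oq an `oq_trace` from [open_quotient()].
#' @param ws a `window_set` (from [fdse_windows()] for EGG-aligned
#'   analysis, or [manual_window_set()]).
#' @return A `window_oq`: list with `oq_per_window` (data.frame: `window`
#'   -5..5, `oq_mean`, `n_cycles`), `delta_oq` (10 values), `sd_delta_oq`.
#' @export
window_oq <- function(oq, ws) {
  stopifnot(inherits(ws, "window_set"))
  w <- ws$windows
  oq_mean <- rep(NA_real_, nrow(w))
  n_cyc <- integer(nrow(w))
  for (i in seq_len(nrow(w))) {
    if (is.na(w$t_start[i])) next
    inside <- !is.na(oq$oq) & oq$t_mid >= w$t_start[i] & oq$t_mid < w$t_end[i]
    if (any(inside)) {
      oq_mean[i] <- mean(oq$oq[inside])
      n_cyc[i] <- sum(inside)
    }
  }
  delta <- diff(oq_mean)
  sd_delta <- if (sum(!is.na(delta)) >= 2L) stats::sd(delta, na.rm = TRUE)
              else NA_real_
  structure(
    list(oq_per_window = data.frame(window = w$window, oq_mean = oq_mean,
                                    n_cycles = n_cyc),
         delta_oq = delta, sd_delta_oq = sd_delta),
    class = "window_oq")
}

#' @export
print.window_oq <- function(x, ...) {
  cat(sprintf("<window_oq> mean OQ %.3f-%.3f across windows, SD(delta OQ) = %.4f\n",
              min(x$oq_per_window$oq_mean, na.rm = TRUE),
              max(x$oq_per_window$oq_mean, na.rm = TRUE), x$sd_delta_oq))
  invisible(x)
}
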