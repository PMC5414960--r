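# Fourier-descriptor sample entropy (FDSE).  Each normalized EGG cycle is
# reduced to its first two DFT components (a 4-dimensional real shape
# descriptor); the sample entropy of the descriptor sequence quantifies
# cycle-to-cycle waveform instability, independent of fo and amplitude.

#' Fourier descriptors of extracted cycles
#'
#' Per cycle, the DFT of the `n_resample`-point normalized waveform is
#' taken; components k = 1 and k = 2 (DC excluded) are retained and scaled
#' by `1/n_resample`, giving a 4-dimensional real descriptor
#' (Re1, Im1, Re2, Im2) per cycle. Because each cycle is anchored at the
#' contacting event, the phases are meaningful and the real/imaginary
#' representation avoids phase-wrap discontinuities.
#'
#' @param cycles matrix from [extract_cycles()] (one normalized cycle per
#'   row).
#' @return An `fd_series`: numeric matrix (cycles x 4) with columns
#'   `re1, im1, re2, im2` and attribute `cycle_times`.
#' @export
fourier_descriptors <- function(cycles) {
  stopifnot(is.matrix(cycles))
  n <- ncol(cycles)
  X <- t(apply(cycles, 1L, stats::fft)) / n
  if (nrow(cycles) == 1L) X <- matrix(X, nrow = 1L)
  out <- cbind(re1 = Re(X[, 2L]), im1 = Im(X[, 2L]),
               re2 = Re(X[, 3L]), im2 = Im(X[, 3L]))
  attr(out, "cycle_times") <- attr(cycles, "cycle_times")
  attr(out, "cycle_index") <- attr(cycles, "cycle_index")
  class(out) <- c("fd_series", class(out))
  out
}

#' Sample entropy of a scalar or vector series
#'
#' The negative natural logarithm of the conditional probability that two
#' subsequences similar for `m` points remain similar at the next point,
#' self-matches excluded, under the max-norm. Similarity tolerance per
#' component is `r` times that component's standard deviation, with an
#' absolute floor `r_floor` below which differences are treated as
#' identical (numerically constant series would otherwise have an
#' ill-defined, SD-relative tolerance).
#'
#' @param series numeric vector or matrix (observations x components).
#' @param m embedding length in points (>= 1).
#' @param r tolerance as a fraction of the per-component SD, in (0, 1).
#' @param r_floor absolute per-component tolerance floor (same units as
#'   `series`).
#' @param tol optional absolute per-component tolerance vector; when given
#'   it overrides the SD-based tolerance (used by [fdse_cycle_trace()] to
#'   hold the tolerance fixed across sliding blocks).
#' @return Non-negative entropy value, or `NA` with attribute
#'   `undefined = TRUE` when no template pair matches at length `m`
#'   (or the series is too short).
#' @export
sample_entropy <- function(series, m = 2L, r = 0.2, r_floor = 0,
                           tol = NULL) {
  if (!is.matrix(series)) series <- matrix(series, ncol = 1L)
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  if (!(r > 0 && r < 1)) stop("r must be in (0, 1)")
  n <- nrow(series)
  if (n <= m + 1L) return(undefined_entropy())
  if (is.null(tol)) tol <- pmax(r * apply(series, 2L, stats::sd), r_floor)
  tol <- rep_len(tol, ncol(series))
  tol[tol <= 0] <- .Machine$double.eps
  # pointwise similarity: max-norm over components within tolerance
  S <- matrix(TRUE, n, n)
  for (j in seq_len(ncol(series))) {
    d <- abs(outer(series[, j], series[, j], "-"))
    S <- S & (d <= tol[j])
  }
  nt <- n - m  # templates 1..nt so that point m+1 exists for all
  run <- S[seq_len(nt), seq_len(nt), drop = FALSE]
  for (t in seq_len(m - 1L)) {
    run <- run & S[seq_len(nt) + t, seq_len(nt) + t, drop = FALSE]
  }
  B <- (sum(run) - nt) / 2  # matched pairs i < j at length m
  A_run <- run & S[seq_len(nt) + m, seq_len(nt) + m, drop = FALSE]
  A <- (sum(A_run) - nt) / 2
  if (B == 0) return(undefined_entropy())
  if (A == 0) {
    # no pair stays similar at m+1: the conditional probability is below
    # the smallest measurable value 1/B; report the ceiling ln(B)
    return(structure(log(B), capped = TRUE))
  }
  -log(A / B)
}

undefined_entropy <- function() structure(NA_real_, undefined = TRUE)

#' Cycle-based FDSE trace
#'
#' Sample entropy of the descriptor sequence over a sliding block of
#' `block_len` consecutive cycles (hop 1); each value is assigned to the
#' block-centre cycle. The similarity tolerance is computed once from the
#' per-component SD of the *whole* descriptor series (subject to the
#' absolute floor) and held fixed across blocks, so that block values are
#' mutually comparable: a regime change inside one block must not widen
#' that block's own tolerance and mask itself. Undefined entropies (no
#' template matches) propagate as `NA`.
#'
#' @param fds an `fd_series` from [fourier_descriptors()].
#' @param m,r,r_floor sample entropy parameters, see [sample_entropy()].
#' @param block_len cycles per block (> m + 1).
#' @return An `entropy_trace`: data.frame with columns `cycle` (index into
#'   the descriptor rows), `t_mid` (s, block-centre cycle midpoint) and
#'   `fdse_c`.
#' @export
fdse_cycle_trace <- function(fds, m = 2L, r = 0.2, r_floor = 0.005,
                             block_len = 40L) {
  block_len <- as.integer(block_len)
  if (block_len <= m + 1L) stop("block_len must exceed m + 1")
  n <- nrow(fds)
  if (n < block_len)
    stop(sprintf("need >= %d cycles for block_len = %d", block_len, block_len))
  tt <- attr(fds, "cycle_times")
  n_blocks <- n - block_len + 1L
  centre <- seq_len(n_blocks) + block_len %/% 2L
  tol <- pmax(r * apply(fds, 2L, stats::sd), r_floor)
  vals <- vapply(seq_len(n_blocks), function(b) {
    v <- sample_entropy(fds[b:(b + block_len - 1L), , drop = FALSE],
                        m = m, r = r, r_floor = r_floor, tol = tol)
    as.numeric(v)
  }, numeric(1))
  out <- data.frame(cycle = centre, t_mid = tt[centre], fdse_c = vals)
  class(out) <- c("entropy_trace", class(out))
  attr(out, "block_len") <- block_len
  attr(out, "params") <- list(m = m, r = r, r_floor = r_floor)
  out
}

#' Window-based FDSE and the 11-window alignment
#'
#' The phonation is divided into consecutive 25 ms segments anchored at the
#' signal start; the window-based entropy FDSE_w of a segment is the mean
#' of the cycle-based values whose block-centre cycle midpoint falls inside
#' it (undefined values excluded). The segment attaining the global maximum
#' FDSE_w (ties: earliest) becomes window 0, and the 11 consecutive
#' segments indexed -5..+5 centred there form the analysis window set;
#' windows clamped off either signal edge are flagged missing.
#'
#' @param trace an `entropy_trace` from [fdse_cycle_trace()].
#' @param seg the `cycle_segmentation` the trace derives from (supplies the
#'   time span and grid anchor).
#' @param window_len window length in seconds (default 0.025).
#' @return A `window_set`: list with `windows` (data.frame: `window` -5..5,
#'   `t_start`, `t_end`, `fdse_w`, `n_values`, `missing`), `center_segment`,
#'   `segments` (the full scanned grid), `window_len`.
#' @export
fdse_windows <- function(trace, seg, window_len = 0.025) {
  t_start <- seg$t0
  t_end <- seg$t0 + seg$n_samples / seg$fs
  n_seg <- floor((t_end - t_start) / window_len)
  if (n_seg < 1L) stop("signal shorter than one analysis window")
  starts <- t_start + (seq_len(n_seg) - 1L) * window_len
  bin <- floor((trace$t_mid - t_start) / window_len) + 1L
  ok <- !is.na(trace$fdse_c) & bin >= 1L & bin <= n_seg
  fdse_w <- rep(NA_real_, n_seg)
  counts <- integer(n_seg)
  if (any(ok)) {
    agg <- tapply(trace$fdse_c[ok], bin[ok], mean)
    fdse_w[as.integer(names(agg))] <- as.numeric(agg)
    cts <- table(bin[ok])
    counts[as.integer(names(cts))] <- as.integer(cts)
  }
  if (all(is.na(fdse_w))) stop("no defined FDSE_w value in any segment")
  center <- which(fdse_w == max(fdse_w, na.rm = TRUE))[1L]  # earliest tie
  win_idx <- -5:5
  seg_idx <- center + win_idx
  in_range <- seg_idx >= 1L & seg_idx <= n_seg
  windows <- data.frame(
    window = win_idx,
    t_start = starts[ifelse(in_range, seg_idx, NA)],
    t_end = starts[ifelse(in_range, seg_idx, NA)] + window_len,
    fdse_w = ifelse(in_range, fdse_w[pmin(pmax(seg_idx, 1L), n_seg)], NA),
    n_values = ifelse(in_range, counts[pmin(pmax(seg_idx, 1L), n_seg)], 0L))
  windows$missing <- !in_range | is.na(windows$fdse_w)
  out <- list(windows = windows, center_segment = center,
              segments = data.frame(segment = seq_len(n_seg),
                                    t_start = starts, fdse_w = fdse_w,
                                    n_values = counts),
              window_len = window_len)
  class(out) <- "window_set"
  out
}

#' @export
print.window_set <- function(x, ...) {
  w0 <- x$windows[x$windows$window == 0L, ]
  cat(sprintf(
    "<window_set> 11 x %g ms windows; window 0 at %.4f-%.4f s, FDSE_w = %.4g\n",
    x$window_len * 1000, w0$t_start, w0$t_end, w0$fdse_w))
  invisible(x)
}

#' Maximum window-based FDSE
#'
#' The FDSE_w value of window 0, i.e. the global maximum over the scanned
#' 25 ms segments: the study's per-phonation summary of how strongly the
#' EGG waveform was altered within any analysis window.
#'
#' @param ws a `window_set` from [fdse_windows()].
#' @return Numeric scalar.
#' @export
max_fdse_w <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  ws$windows$fdse_w[ws$windows$window == 0L]
}

# Construct a window_set on a fixed grid centred at a given time, without
# an entropy trace -- used when GAW/field data are analyzed on their own.
#' Build an analysis window set centred at a chosen time
#'
#' For GAW- or field-only analyses where no EGG-derived alignment exists:
#' 11 consecutive windows of `window_len` seconds with window 0 starting at
#' the grid segment containing `center_time`.
#'
#' @param center_time time (s) the centre window should cover.
#' @param t0,t_end signal start and end times (s).
#' @param window_len window length in seconds.
#' @return A `window_set` (with `fdse_w` all `NA`).
#' @export
manual_window_set <- function(center_time, t0, t_end, window_len = 0.025) {
  n_seg <- floor((t_end - t0) / window_len)
  center <- floor((center_time - t0) / window_len) + 1L
  if (center < 1L || center > n_seg) stop("center_time outside the signal")
  starts <- t0 + (seq_len(n_seg) - 1L) * window_len
  seg_idx <- center + (-5:5)
  in_range <- seg_idx >= 1L & seg_idx <= n_seg
  windows <- data.frame(
    window = -5:5,
    t_start = starts[ifelse(in_range, seg_idx, NA)],
    t_end = starts[ifelse(in_range, seg_idx, NA)] + window_len,
    fdse_w = NA_real_, n_values = 0L, missing = !in_range)
  structure(list(windows = windows, center_segment = center,
                 segments = data.frame(segment = seq_len(n_seg),
                                       t_start = starts,
                                       fdse_w = NA_real_, n_values = 0L),
                 window_len = window_len),
            class = "window_set")
}
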