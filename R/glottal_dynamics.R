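# Spatio-temporal glottal opening/closing contours: for every position
# along the anterior-posterior (A-P) glottal midline, the cycle-normalized
# instants at which the local glottal width diverges from and converges to
# zero, averaged within each analysis window.

#' Per-cycle, per-position opening and closing instants
#'
#' For each valid cycle and A-P position: the opening instant is the first
#' frame whose local width exceeds `open_threshold`; the closing instant is
#' the first subsequent frame at or below it. "Zero" is operationalized as
#' width <= `open_threshold` (default 0.5 px) to absorb segmentation
#' quantization. Positions that never open within a cycle yield a missing
#' pair; positions open for the entire cycle yield the pair (0, 1) in
#' normalized units and a never-closed flag (also set when a position
#' opens but fails to re-close before the cycle ends).
#'
#' @param field a [displacement_field].
#' @param seg a `cycle_segmentation` on the same time base (frame rate must
#'   match `field$fs_video`).
#' @param open_threshold width threshold in pixels, >= 0.
#' @return A `glottal_instants`: list of matrices (`open`, `close`, both
#'   cycles x positions, frames relative to cycle start, `NA` = missing)
#'   plus `never_closed` (logical matrix), `cycle_dur` (frames),
#'   `cycle_index`, `t_mid`.
#' @export
local_open_close_instants <- function(field, seg, open_threshold = 0.5) {
  stopifnot(inherits(field, "displacement_field"),
            inherits(seg, "cycle_segmentation"))
  if (open_threshold < 0) stop("open_threshold must be >= 0")
  if (abs(field$fs_video - seg$fs) > 1e-9)
    stop("field frame rate and segmentation sampling rate differ")
  n_frames <- nrow(field$width)
  if (max(seg$boundaries) > n_frames + 1)
    stop("segmentation extends beyond the displacement field")
  b <- seg$boundaries
  idx <- which(seg$valid)
  P <- field$n_positions
  open_m <- matrix(NA_real_, length(idx), P)
  close_m <- matrix(NA_real_, length(idx), P)
  never <- matrix(FALSE, length(idx), P)
  dur <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    f0 <- ceiling(b[i]); f1 <- min(n_frames, ceiling(b[i + 1L]) - 1L)
    if (f1 <= f0) next
    dur[k] <- b[i + 1L] - b[i]
    seg_w <- field$width[f0:f1, , drop = FALSE]
    for (p in seq_len(P)) {
      w <- seg_w[, p]
      is_open <- w > open_threshold
      if (!any(is_open)) next  # never opens: missing pair
      if (all(is_open)) {      # open the whole cycle
        open_m[k, p] <- 0
        close_m[k, p] <- dur[k]
        never[k, p] <- TRUE
        next
      }
      o <- which(is_open)[1L]
      after <- which(!is_open & seq_along(w) > o)
      open_m[k, p] <- (f0 + o - 1L) - b[i]
      if (length(after) == 0L) {  # opens but never re-closes
        close_m[k, p] <- dur[k]
        never[k, p] <- TRUE
      } else {
        close_m[k, p] <- (f0 + after[1L] - 1L) - b[i]
      }
    }
  }
  structure(
    list(open = open_m, close = close_m, never_closed = never,
         cycle_dur = dur, cycle_index = idx, t_mid = cycle_times(seg)),
    class = "glottal_instants")
}

#' Cycle-normalize and window-average opening/closing instants
#'
#' Divides each cycle's instants by that cycle's duration and averages
#' them per analysis window and A-P position over all contributing cycles
#' (missing pairs skipped, never imputed). Coverage counts are published
#' so sparse positions remain visible.
#'
#' @param instants a `glottal_instants` from [local_open_close_instants()].
#' @param ws a `window_set` giving the 11 aligned analysis windows.
#' @return A list of 11 `contour_pair` objects (index -5..5, `NULL` for
#'   empty windows): each a data.frame with columns `position` (0-based,
#'   anterior = 0), `open`, `close` (normalized intra-cycle time),
#'   `coverage` (cycles contributing), `never_closed_frac`.
#' @export
normalize_and_average <- function(instants, ws) {
  stopifnot(inherits(instants, "glottal_instants"),
            inherits(ws, "window_set"))
  P <- ncol(instants$open)
  open_n <- instants$open / instants$cycle_dur
  close_n <- instants$close / instants$cycle_dur
  w <- ws$windows
  out <- vector("list", nrow(w))
  names(out) <- sprintf("window_%d", w$window)
  for (i in seq_len(nrow(w))) {
    if (is.na(w$t_start[i])) next
    rows <- instants$t_mid >= w$t_start[i] & instants$t_mid < w$t_end[i]
    if (!any(rows)) next
    o <- open_n[rows, , drop = FALSE]
    cl <- close_n[rows, , drop = FALSE]
    nv <- instants$never_closed[rows, , drop = FALSE]
    coverage <- colSums(!is.na(o))
    cp <- data.frame(
      position = seq_len(P) - 1L,
      open = ifelse(coverage > 0, colMeans(o, na.rm = TRUE), NA),
      close = ifelse(coverage > 0, colMeans(cl, na.rm = TRUE), NA),
      coverage = coverage,
      never_closed_frac = ifelse(coverage > 0,
                                 colSums(nv & !is.na(o)) / pmax(coverage, 1L),
                                 NA))
    attr(cp, "window_index") <- w$window[i]
    class(cp) <- c("contour_pair", class(cp))
    out[[i]] <- cp
  }
  out
}

#' Scalar descriptors of one window's contour pair
#'
#' Quantifies a spatio-temporal opening/closing pattern: the mean open
#' duration (close minus open, averaged over defined positions), the A-P
#' opening-delay slope (least-squares slope of the opening contour versus
#' position index, in normalized time per position) and the fraction of
#' positions that failed to close (never-closed in more than half of their
#' contributing cycles).
#'
#' @param cp a `contour_pair` (or `NULL`).
#' @return A one-row data.frame: `mean_open_duration`, `ap_delay_slope`,
#'   `never_closed_frac`, `n_positions` (all `NA` if fewer than 3 defined
#'   positions).
#' @export
contour_summary_metrics <- function(cp) {
  empty <- data.frame(mean_open_duration = NA_real_,
                      ap_delay_slope = NA_real_,
                      never_closed_frac = NA_real_, n_positions = 0L)
  if (is.null(cp)) return(empty)
  ok <- !is.na(cp$open) & !is.na(cp$close) & cp$coverage > 0
  if (sum(ok) < 3L) return(empty)
  fit <- stats::lm(open ~ position, data = cp[ok, ])
  data.frame(
    mean_open_duration = mean(cp$close[ok] - cp$open[ok]),
    ap_delay_slope = unname(stats::coef(fit)[2L]),
    never_closed_frac = mean(cp$never_closed_frac[ok] > 0.5),
    n_positions = sum(ok))
}
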