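# Wavegrams: successive amplitude-normalized EGG (or dEGG) cycles stacked
# as image columns, visualizing cycle-shape evolution across a phonation.

#' Build a wavegram matrix
#'
#' Each valid cycle is resampled to `n_rows` points along normalized
#' intra-cycle time and min-max normalized to \[0, 1\]; consecutive cycles
#' form consecutive columns. Degenerate (flat) cycles map to a column of
#' 0.5 with a warning.
#'
#' @param sig an [egg_signal] or `degg_signal` (any [sampled_signal]).
#' @param seg a `cycle_segmentation` for `sig`.
#' @param n_rows intra-cycle resolution, >= 32 (default 256).
#' @return A `wavegram`: matrix (`n_rows` x cycles, values in \[0, 1\],
#'   row 1 = intra-cycle time 0) with attributes `column_times` (s) and
#'   `source` (first class of `sig`).
#' @export
build_wavegram <- function(sig, seg, n_rows = 256L) {
  n_rows <- as.integer(n_rows)
  if (n_rows < 32L) stop("n_rows must be >= 32")
  cyc <- extract_cycles(sig, seg, n_resample = n_rows, normalize = "none")
  degen <- 0L
  m <- apply(cyc, 1L, function(row) {
    ptp <- max(row) - min(row)
    if (ptp < .Machine$double.eps * max(1, max(abs(row)))) {
      degen <<- degen + 1L
      rep(0.5, length(row))
    } else {
      (row - min(row)) / ptp
    }
  })
  if (degen > 0L)
    warning(sprintf("%d degenerate (flat) cycle(s) rendered as 0.5", degen))
  attr(m, "column_times") <- attr(cyc, "cycle_times")
  attr(m, "source") <- class(sig)[1L]
  class(m) <- c("wavegram", class(m))
  m
}

#' Render a wavegram to a PNG file
#'
#' Deterministic rendering (fixed linear grayscale, no metadata): time on
#' x, normalized intra-cycle time on y (0 at the bottom), intensity
#' mapping amplitude. Identical wavegrams yield byte-identical files.
#'
#' @param w a `wavegram`.
#' @param path output PNG path.
#' @param px_per_cycle horizontal pixels per cycle column (default 1).
#' @return `path`, invisibly.
#' @export
render_wavegram <- function(w, path, px_per_cycle = 1L) {
  stopifnot(inherits(w, "wavegram"))
  px_per_cycle <- as.integer(px_per_cycle)
  img <- unclass(w)
  if (px_per_cycle > 1L)
    img <- img[, rep(seq_len(ncol(img)), each = px_per_cycle), drop = FALSE]
  img <- img[rev(seq_len(nrow(img))), , drop = FALSE]  # row 1 -> bottom
  png::writePNG(img, target = path)
  invisible(path)
}
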