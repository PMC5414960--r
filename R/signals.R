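#' @keywords internal
"_PACKAGE"

#' Uniformly sampled signal
#'
#' Base container for all time series handled by the package: a numeric
#' sample vector, a sampling rate in Hz and a start-time offset in seconds.
#' The time of sample `i` (1-based) is `t0 + (i - 1) / fs`.
#'
#' @param samples numeric vector of finite values, length >= 2.
#' @param fs sampling rate in Hz, > 0.
#' @param t0 start-time offset in seconds.
#' @param unit free-text amplitude unit label.
#' @return An object of class `sampled_signal`.
#' @export
sampled_signal <- function(samples, fs, t0 = 0, unit = "a.u.") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("a sampled_signal needs at least 2 samples")
  if (!all(is.finite(samples)))
    stop("sampled_signal values must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  structure(
    list(samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0),
         unit = unit),
    class = "sampled_signal")
}

#' Electroglottographic (EGG) signal
#'
#' An EGG signal is proportional to relative vocal-fold contact area; the
#' package-wide polarity convention is that larger values mean greater
#' contact, so that contacting events appear as positive peaks in the first
#' derivative (dEGG).
#'
#' @inheritParams sampled_signal
#' @param polarity either `"contact-positive"` (already in convention) or
#'   `"contact-negative"` (samples are negated on construction).
#' @return An object of class `c("egg_signal", "sampled_signal")`.
#' @export
egg_signal <- function(samples, fs, t0 = 0, polarity = "contact-positive") {
  polarity <- match.arg(polarity, c("contact-positive", "contact-negative"))
  if (polarity == "contact-negative") samples <- -as.numeric(samples)
  x <- sampled_signal(samples, fs, t0, unit = "rel. contact area")
  x$polarity <- "contact-positive"
  class(x) <- c("egg_signal", class(x))
  x
}

#' Glottal area waveform (GAW)
#'
#' Time series of projected glottal area per video frame, as produced by
#' glottal segmentation of high-speed videoendoscopy footage.
#'
#' @param area non-negative numeric vector (pixel^2 or normalized units).
#' @param fs_video video frame rate in Hz.
#' @param t0 start-time offset in seconds.
#' @return An object of class `c("gaw_series", "sampled_signal")`.
#' @export
gaw_series <- function(area, fs_video, t0 = 0) {
  area <- as.numeric(area)
  if (any(area < 0, na.rm = TRUE))
    stop("glottal area must be non-negative; clip upstream (see read_gaw_csv)")
  x <- sampled_signal(area, fs_video, t0, unit = "area")
  class(x) <- c("gaw_series", class(x))
  x
}

#' Medio-lateral displacement field
#'
#' Glottal width as a function of video frame (rows) and anterior-posterior
#' position (columns, index 1 = anterior). The row sum is proportional to
#' the glottal area waveform up to spatial discretization.
#'
#' @param width non-negative numeric matrix, frames x positions.
#' @param fs_video video frame rate in Hz.
#' @param t0 start-time offset in seconds.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(width, fs_video, t0 = 0) {
  width <- as.matrix(width)
  if (!is.numeric(width) || any(!is.finite(width)))
    stop("width matrix must be finite numeric")
  if (any(width < 0)) stop("glottal width must be non-negative")
  if (ncol(width) < 3L) stop("need at least 3 anterior-posterior positions")
  if (nrow(width) < 2L) stop("need at least 2 frames")
  if (!is.numeric(fs_video) || fs_video <= 0) stop("fs_video must be > 0")
  structure(
    list(width = width, fs_video = as.numeric(fs_video),
         t0 = as.numeric(t0), n_positions = ncol(width)),
    class = "displacement_field")
}

#' Perceptual rating table
#'
#' Integer scores on a 1-5 scale, raters in rows, stimuli in columns.
#' Complete matrices are required so that the intraclass correlation is
#' well defined.
#'
#' @param scores integer matrix (rater x stimulus), values in 1..5.
#' @param duplicate_pair optional integer pair: column indices holding the
#'   duplicated stimulus used to probe rater self-consistency.
#' @return An object of class `rating_table`.
#' @export
rating_table <- function(scores, duplicate_pair = NULL) {
  scores <- as.matrix(scores)
  if (any(is.na(scores))) stop("rating table must have no missing cells")
  if (!all(scores %in% 1:5)) stop("all scores must be integers in 1..5")
  storage.mode(scores) <- "integer"
  if (nrow(scores) < 2L || ncol(scores) < 2L)
    stop("need at least 2 raters and 2 stimuli")
  if (!is.null(duplicate_pair)) {
    stopifnot(length(duplicate_pair) == 2L,
              all(duplicate_pair %in% seq_len(ncol(scores))))
  }
  structure(list(scores = scores, duplicate_pair = duplicate_pair),
            class = "rating_table")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<%s> %d samples @ %g Hz, t0 = %g s, duration %.4f s\n",
              class(x)[1L], length(x$samples), x$fs, x$t0,
              length(x$samples) / x$fs))
  invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "<displacement_field> %d frames x %d A-P positions @ %g fps\n",
    nrow(x$width), x$n_positions, x$fs_video))
  invisible(x)
}

#' @export
print.rating_table <- function(x, ...) {
  cat(sprintf("<rating_table> %d raters x %d stimuli (scale 1-5)%s\n",
              nrow(x$scores), ncol(x$scores),
              if (is.null(x$duplicate_pair)) "" else
                sprintf(", duplicate pair (%d, %d)",
                        x$duplicate_pair[1L], x$duplicate_pair[2L])))
  invisible(x)
}

# sample index (1-based, possibly fractional) -> time in seconds
sample_to_time <- function(i, fs, t0) t0 + (i - 1) / fs

signal_duration <- function(x) length(x$samples) / x$fs
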