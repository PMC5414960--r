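# File I/O: WAV (PCM16 / float32 RIFF), GAW and displacement CSVs, rating
# CSVs, plus run configuration and logging.  CSV dialect throughout:
# comma-separated, "." decimal, UTF-8, one header line.

#' Read a WAV file into an audio and an EGG channel
#'
#' Reads an uncompressed RIFF/WAVE file (PCM 16-bit or IEEE float 32-bit)
#' holding time-synchronized acoustic and electroglottographic channels
#' sampled at a common rate. The EGG polarity is normalized so that greater
#' vocal-fold contact maps to larger values; with `polarity = "auto"` the
#' orientation is inferred from the skewness of the first difference
#' (contacting slopes are steeper than de-contacting ones, so the dEGG of a
#' correctly oriented signal is right-skewed).
#'
#' @param path WAV file path.
#' @param egg_channel 1-based index of the EGG channel (default 2).
#' @param audio_channel 1-based index of the acoustic channel (default 1).
#' @param polarity `"auto"`, `"contact-positive"` or `"contact-negative"`.
#' @return A list with elements `audio` ([sampled_signal]) and
#'   `egg` ([egg_signal]), sharing `fs` and length.
#' @export
read_wav <- function(path, egg_channel = 2L, audio_channel = 1L,
                     polarity = "auto") {
  w <- read_wav_raw(path)
  if (egg_channel > w$n_channels || egg_channel < 1L)
    stop(sprintf("EGG channel %d requested but file has %d channel(s)",
                 egg_channel, w$n_channels))
  if (audio_channel > w$n_channels || audio_channel < 1L)
    stop(sprintf("audio channel %d requested but file has %d channel(s)",
                 audio_channel, w$n_channels))
  egg_samples <- w$data[, egg_channel]
  if (polarity == "auto") {
    d <- diff(egg_samples)
    s <- mean((d - mean(d))^3)
    polarity <- if (s < 0) "contact-negative" else "contact-positive"
  }
  list(audio = sampled_signal(w$data[, audio_channel], w$fs, unit = "Pa"),
       egg = egg_signal(egg_samples, w$fs, polarity = polarity))
}

# Minimal RIFF/WAVE parser: PCM16 (format 1) and IEEE float32 (format 3).
read_wav_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format   = readBin(body[1:2], "integer", 1L, 2L, endian = "little"),
        channels = readBin(body[3:4], "integer", 1L, 2L, endian = "little"),
        fs       = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits     = readBin(body[15:16], "integer", 1L, 2L, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("WAV file missing fmt/data chunk: ", path)
  if (fmt$fs <= 0) stop("WAV file reports non-positive sampling rate")
  if (fmt$format == 1L && fmt$bits == 16L) {
    v <- readBin(data_raw, "integer", length(data_raw) / 2L, 2L,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    v <- readBin(data_raw, "double", length(data_raw) / 4L, 4L,
                 endian = "little")
  } else {
    stop(sprintf("unsupported WAV format (format=%d, bits=%d); need PCM16 or float32",
                 fmt$format, fmt$bits))
  }
  n <- length(v) %/% fmt$channels
  list(data = matrix(v[seq_len(n * fmt$channels)], ncol = fmt$channels,
                     byrow = TRUE),
       fs = fmt$fs, n_channels = fmt$channels)
}

#' Write one or two signals to a WAV file
#'
#' @param signals a [sampled_signal] or a list of them (equal `fs`, length);
#'   written as interleaved channels.
#' @param path output path.
#' @param format `"float32"` (lossless for doubles within float precision)
#'   or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signals, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  if (inherits(signals, "sampled_signal")) signals <- list(signals)
  fs <- unique(vapply(signals, function(s) s$fs, numeric(1)))
  if (length(fs) != 1L) stop("all channels must share one sampling rate")
  n <- unique(vapply(signals, function(s) length(s$samples), integer(1)))
  if (length(n) != 1L) stop("all channels must share one length")
  k <- length(signals)
  inter <- as.vector(t(vapply(signals, function(s) s$samples, numeric(n))))
  bits <- if (format == "pcm16") 16L else 32L
  bytes_per <- bits / 8L
  data_size <- as.integer(n * k * bytes_per)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(if (format == "pcm16") 1L else 3L, k), con, 2L,
           endian = "little")
  writeBin(as.integer(fs), con, 4L, endian = "little")
  writeBin(as.integer(fs * k * bytes_per), con, 4L, endian = "little")
  writeBin(c(as.integer(k * bytes_per), bits), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4L, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(pmax(-32768, pmin(32767, round(inter * 32768))))
    writeBin(q, con, 2L, endian = "little")
  } else {
    writeBin(inter, con, 4L, endian = "little")
  }
  invisible(path)
}

#' Read a glottal area waveform CSV
#'
#' Expects a two-column CSV with header: (`time_s`, `area`) or
#' (`frame`, `area`). With a time column the frame rate is inferred and
#' uniform sampling is verified (maximum jitter below half a frame period);
#' with a frame column `fs_video` must be supplied. Negative areas (possible
#' segmentation artifacts) are clipped to zero with a warning.
#'
#' @param path CSV path.
#' @param fs_video frame rate in Hz; required when the first column holds
#'   frame indices.
#' @return A [gaw_series]; attribute `n_clipped` counts clipped samples.
#' @export
read_gaw_csv <- function(path, fs_video = NULL) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("GAW CSV needs two columns (time|frame, area)")
  first <- tolower(names(df)[1L])
  if (grepl("time", first)) {
    tt <- df[[1L]]
    if (any(diff(tt) <= 0)) stop("non-monotone time column in ", path)
    period <- stats::median(diff(tt))
    if (max(abs(diff(tt) - period)) > period / 2)
      stop("non-uniform sampling in ", path)
    fs_video <- 1 / period
    t0 <- tt[1L]
  } else {
    if (is.null(fs_video))
      stop("GAW CSV has frame indices; fs_video must be supplied")
    if (any(diff(df[[1L]]) <= 0)) stop("non-monotone frame column in ", path)
    t0 <- df[[1L]][1L] / fs_video
  }
  area <- df[[2L]]
  n_clipped <- sum(area < 0)
  if (n_clipped > 0) {
    warning(sprintf("%d negative area value(s) clipped to 0", n_clipped))
    area[area < 0] <- 0
  }
  out <- gaw_series(area, fs_video, t0 = t0)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Write a glottal area waveform CSV
#'
#' Writes `(time_s, area)` with 17 significant digits so that values
#' round-trip bit-exactly through [read_gaw_csv()].
#'
#' @param gaw a [gaw_series].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gaw_csv <- function(gaw, path) {
  tt <- sample_to_time(seq_along(gaw$samples), gaw$fs, gaw$t0)
  lines <- c("time_s,area",
             sprintf("%.17g,%.17g", tt, gaw$samples))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a medio-lateral displacement field CSV
#'
#' First column: 0-based frame index; remaining columns: glottal width at
#' anterior-posterior positions 0..n-1 (anterior first). Ragged rows are a
#' format error (caught by the CSV parser).
#'
#' @param path CSV path.
#' @param fs_video frame rate in Hz.
#' @return A [displacement_field].
#' @export
read_displacement_csv <- function(path, fs_video) {
  df <- utils::read.csv(path)
  if (ncol(df) < 4L)
    stop("displacement CSV needs a frame column plus >= 3 positions")
  if (any(is.na(as.matrix(df))))
    stop("ragged or non-numeric rows in ", path)
  if (any(diff(df[[1L]]) <= 0)) stop("non-monotone frame column in ", path)
  t0 <- df[[1L]][1L] / fs_video
  displacement_field(as.matrix(df[, -1L, drop = FALSE]), fs_video, t0 = t0)
}

#' Write a medio-lateral displacement field CSV
#'
#' @param field a [displacement_field].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_displacement_csv <- function(field, path) {
  n <- nrow(field$width)
  header <- paste(c("frame", sprintf("pos%03d", seq_len(field$n_positions) - 1L)),
                  collapse = ",")
  frame0 <- round(field$t0 * field$fs_video)
  body <- vapply(seq_len(n), function(i) {
    paste(c(sprintf("%d", frame0 + i - 1L),
            sprintf("%.17g", field$width[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a rater-by-stimulus score CSV
#'
#' First column: rater id; remaining columns: one stimulus each, integer
#' scores 1-5.
#'
#' @param path CSV path.
#' @param duplicate_pair optional indices of the duplicated-stimulus columns.
#' @return A [rating_table].
#' @export
read_ratings_csv <- function(path, duplicate_pair = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  rating_table(m, duplicate_pair = duplicate_pair)
}

#' Write a rating table CSV
#' @param rt a [rating_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ratings_csv <- function(rt, path) {
  df <- data.frame(rater = rownames(rt$scores) %||%
                     sprintf("R%02d", seq_len(nrow(rt$scores))),
                   rt$scores, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default analysis configuration
#'
#' All tunable parameters of the pipeline with their defaults, as one flat
#' list. [read_config()] merges a YAML file over these.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    fo_min = 150, fo_max = 1200,       # Hz; A3-A5 with margin
    highpass_hz = 20,                  # EGG drift removal (4th order)
    smoothing_len = 1,                 # dEGG pre-smoothing, samples (odd)
    n_resample = 64,                   # points per normalized cycle
    samp_en_m = 2, samp_en_r = 0.2,    # sample entropy embedding/tolerance
    samp_en_floor = 0.005,             # absolute tolerance floor
    block_len = 40,                    # cycles per FDSE_c sliding block
    window_len = 0.025,                # s, analysis window
    open_threshold_frac = 0.02,        # GAW open quotient threshold
    contour_threshold = 0.5,           # px, local opening threshold
    icc_form = "ICC2k")
}

#' Read a YAML configuration file
#'
#' @param path YAML file; keys as in [default_config()].
#' @return Full configuration list (file values over defaults).
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    warning("unknown config keys ignored: ", paste(unknown, collapse = ", "))
  cfg[intersect(names(user), names(cfg))] <-
    user[intersect(names(user), names(cfg))]
  cfg
}

# Structured logging to stderr with a per-session run id.
the <- new.env(parent = emptyenv())

#' Log a pipeline message to stderr
#' @param fmt sprintf format string.
#' @param ... values for `fmt`.
#' @return The formatted message, invisibly.
#' @export
pass_log <- function(fmt, ...) {
  if (is.null(the$run_id))
    the$run_id <- sprintf("%08x", as.integer(Sys.time()) %% .Machine$integer.max)
  msg <- sprintf("[%s %s] %s", format(Sys.time(), "%H:%M:%OS3"),
                 the$run_id, sprintf(fmt, ...))
  message(msg)
  invisible(msg)
}
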