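# Synthetic study inputs: stereotypical EGG pitch glides, GAW/displacement
# triplets realizing the four observed transition strategies, and rater
# score matrices.  Every generator also emits its ground truth so recovery
# can be tested cycle by cycle.
#
# Study conditions emulated by the defaults: 1-second upward pitch glides
# (220->440 Hz, or 440->880 Hz for the upper task) with the fo change
# concentrated in a 50 ms interval centred at 0.5 s, recorded at 20 kHz.

#' Specification of one synthetic pitch glide
#'
#' @param fo_start,fo_end fundamental frequency endpoints in Hz, both in
#'   \[100, 1200\].
#' @param duration phonation duration in seconds.
#' @param fs sampling / frame rate in Hz.
#' @param transition_center time (s) the fo transition is centred on.
#' @param transition_width width (s) of the fo transition interval,
#'   in (0, duration).
#' @param strategy transition strategy:
#'   `"stereotypical"` (fixed cycle shape; the fo-invariance control),
#'   `"smooth_oq_up"` (gradual OQ increase, i.e. decreasing closure),
#'   `"smooth_oq_down"` (gradual OQ decrease, i.e. increasing closure),
#'   `"abrupt"` (OQ and fo step plus a transient cycle-to-cycle
#'   instability burst within the transition interval, as register breaks
#'   exhibit), or `"contact_loss"` (episodic near-total loss of vocal-fold
#'   contact around the transition).
#' @param oq_start,oq_end open-quotient endpoints in \[0.2, 0.95\];
#'   `NULL` selects per-strategy defaults.
#' @param noise_sd additive Gaussian noise SD relative to the signal SD.
#' @param seed integer RNG seed; all generators are reproducible under it.
#' @return A `glide_spec` list.
#' @export
glide_spec <- function(fo_start = 220, fo_end = 440, duration = 1,
                       fs = 20000,
                       transition_center = 0.5, transition_width = 0.05,
                       strategy = c("stereotypical", "smooth_oq_up",
                                    "smooth_oq_down", "abrupt",
                                    "contact_loss"),
                       oq_start = NULL, oq_end = NULL,
                       noise_sd = 0, seed = 1L) {
  strategy <- match.arg(strategy)
  if (!(transition_width > 0 && transition_width < duration))
    stop("need 0 < transition_width < duration")
  if (any(c(fo_start, fo_end) < 100 | c(fo_start, fo_end) > 1200))
    stop("fo endpoints must lie in [100, 1200] Hz")
  oq_default <- switch(strategy,
    stereotypical = c(0.60, 0.60),
    smooth_oq_up = c(0.55, 0.75),
    smooth_oq_down = c(0.75, 0.55),
    abrupt = c(0.50, 0.85),
    contact_loss = c(0.60, 0.70))
  oq_start <- oq_start %||% oq_default[1L]
  oq_end <- oq_end %||% oq_default[2L]
  if (strategy == "stereotypical") oq_end <- oq_start  # fixed shape
  if (any(c(oq_start, oq_end) < 0.2 | c(oq_start, oq_end) > 0.95))
    stop("oq endpoints must lie in [0.2, 0.95]")
  structure(
    list(fo_start = fo_start, fo_end = fo_end, duration = duration,
         fs = fs, transition_center = transition_center,
         transition_width = transition_width, strategy = strategy,
         oq_start = oq_start, oq_end = oq_end, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "glide_spec")
}

# Phase track and per-cycle parameters shared by the EGG and the
# GAW/field generators.  Returns the per-sample phase (cycles), exact
# fractional-sample cycle boundaries, and per-cycle oq/amplitude tracks
# after strategy modification.  Consumes RNG draws (call set.seed first).
glide_kinematics <- function(spec) {
  n <- round(spec$duration * spec$fs)
  tt <- (seq_len(n) - 1L) / spec$fs
  tc <- spec$transition_center; tw <- spec$transition_width
  fo <- if (spec$strategy == "abrupt") {
    ifelse(tt < tc, spec$fo_start, spec$fo_end)
  } else {
    spec$fo_start + (spec$fo_end - spec$fo_start) /
      (1 + exp(-12 * (tt - tc) / tw))
  }
  phi <- cumsum(fo) / spec$fs
  phi <- phi - phi[1L]
  n_cycles <- floor(phi[n])
  # fractional boundary where phi crosses each integer 0..n_cycles
  boundaries <- numeric(n_cycles + 1L)
  boundaries[1L] <- 1
  j <- 1L
  for (c in seq_len(n_cycles)) {
    while (phi[j + 1L] < c) j <- j + 1L
    boundaries[c + 1L] <- j + (c - phi[j]) / (phi[j + 1L] - phi[j])
  }
  t_cycle <- (boundaries[seq_len(n_cycles)] - 1) / spec$fs
  ramp <- function(t) {
    u <- pmin(1, pmax(0, (t - (tc - tw / 2)) / tw))
    spec$oq_start + (spec$oq_end - spec$oq_start) * u
  }
  oq <- switch(spec$strategy,
    stereotypical = rep(spec$oq_start, n_cycles),
    smooth_oq_up = ramp(t_cycle),
    smooth_oq_down = ramp(t_cycle),
    abrupt = ifelse(t_cycle < tc, spec$oq_start, spec$oq_end),
    contact_loss = ramp(t_cycle))
  amp <- rep(1, n_cycles)
  loss <- rep(FALSE, n_cycles)
  if (spec$strategy == "abrupt") {
    # register break: besides the fo/OQ step, a transient burst of
    # cycle-to-cycle instability (abortive oscillation-mode switches)
    # around the break
    burst <- t_cycle >= tc - 1.5 * tw & t_cycle <= tc + 1.5 * tw
    oq[burst] <- pmin(0.95, pmax(0.3,
      oq[burst] + stats::rnorm(sum(burst), 0, 0.12)))
    amp[burst] <- exp(stats::rnorm(sum(burst), 0, 0.3))
  }
  if (spec$strategy == "contact_loss") {
    # brief abductory gestures: two ~15 ms episodes without contact
    centers <- stats::runif(2L, tc - 0.10, tc + 0.10)
    for (ec in centers) {
      ep <- t_cycle >= ec - 0.0075 & t_cycle <= ec + 0.0075
      loss <- loss | ep
    }
    oq[loss] <- 0.95
    amp[loss] <- 0.15
  }
  list(n = n, tt = tt, fo = fo, phi = phi, n_cycles = n_cycles,
       boundaries = boundaries, t_cycle = t_cycle,
       oq = oq, amp = amp, loss = loss)
}

#' Synthesize an EGG pitch glide
#'
#' Accumulates phase from the fo track (sigmoid transition, or a hard step
#' for the abrupt strategy), shapes each cycle with a raised-cosine
#' contact pulse whose contact quotient is `1 - OQ`, applies the strategy's
#' OQ/amplitude track and adds Gaussian measurement noise.
#'
#' @param spec a [glide_spec()].
#' @return A list: `egg` ([egg_signal]) and `truth` (`synth_truth`:
#'   `boundaries` fractional sample positions, `fo_track` per sample,
#'   `oq_per_cycle`, `amp_per_cycle`, `loss_cycles`, `transition_time`,
#'   `strategy`, `n_cycles`).
#' @export
synth_egg <- function(spec) {
  stopifnot(inherits(spec, "glide_spec"))
  set.seed(spec$seed)
  k <- glide_kinematics(spec)
  cyc <- pmin(floor(k$phi) + 1L, k$n_cycles)
  u <- k$phi - floor(k$phi)
  e <- k$amp[cyc] * egg_pulse_vec(u, 1 - k$oq[cyc])
  if (spec$noise_sd > 0)
    e <- e + stats::rnorm(k$n, 0, spec$noise_sd * stats::sd(e))
  truth <- structure(
    list(boundaries = k$boundaries, fo_track = k$fo,
         oq_per_cycle = k$oq, amp_per_cycle = k$amp,
         loss_cycles = which(k$loss),
         transition_time = spec$transition_center,
         strategy = spec$strategy, n_cycles = k$n_cycles),
    class = "synth_truth")
  list(egg = egg_signal(e, spec$fs), truth = truth)
}

# Raised-cosine contact pulse with asymmetric rise (contacting steeper
# than de-contacting, as in real EGG).  u in [0,1): cycle phase from the
# contacting event; cq: contact quotient = 1 - oq (vectorized over both).
egg_pulse_vec <- function(u, cq, rise_frac = 0.3) {
  a <- rise_frac * cq
  out <- numeric(length(u))
  r1 <- u < a
  out[r1] <- 0.5 * (1 - cos(pi * u[r1] / a[r1]))
  r2 <- !r1 & u < cq
  out[r2] <- 0.5 * (1 + cos(pi * (u[r2] - a[r2]) / (cq[r2] - a[r2])))
  out
}

#' Synthesize a GAW / displacement-field pair
#'
#' Emulates glottal segmentation outputs on the same kinematic track as
#' [synth_egg()]: per cycle and A-P position, the local width pulse opens
#' at normalized time `cq + ap_delay_slope * p` and closes at
#' `1 - ap_delay_slope * p` (a zipper pattern; position 0 = anterior spans
#' the full open phase, so the programmed OQ is preserved in the area row
#' sum). Posterior positions can be made permanently open, and the
#' contact-loss strategy inserts episodes with no closed phase anywhere.
#'
#' @param spec a [glide_spec()].
#' @param n_positions A-P positions (>= 8).
#' @param ap_delay_slope opening delay per position index, in normalized
#'   intra-cycle time.
#' @param never_closed_frac fraction of posterior positions that never
#'   close (width floored above threshold).
#' @param amplitude peak single-position width in pixels.
#' @return A list: `gaw` ([gaw_series]), `field` ([displacement_field]),
#'   `truth` (as in [synth_egg()], plus `open_norm`/`close_norm` matrices
#'   of programmed per-cycle per-position instants relative to the
#'   *area-minimum* cycle start, and `never_closed_positions`).
#' @export
synth_gaw_field <- function(spec, n_positions = 32L, ap_delay_slope = 0.004,
                            never_closed_frac = 0, amplitude = 10) {
  stopifnot(inherits(spec, "glide_spec"))
  n_positions <- as.integer(n_positions)
  if (n_positions < 8L) stop("n_positions must be >= 8")
  max_shift <- ap_delay_slope * (n_positions - 1L)
  if (max_shift >= min(1 - spec$oq_start, 1 - spec$oq_end, 0.45))
    stop("ap_delay_slope too large for the programmed OQ range")
  set.seed(spec$seed + 1L)
  k <- glide_kinematics(spec)
  cyc <- pmin(floor(k$phi) + 1L, k$n_cycles)
  u <- k$phi - floor(k$phi)
  cq <- 1 - k$oq[cyc]
  p_idx <- seq_len(n_positions) - 1L
  W <- matrix(0, k$n, n_positions)
  for (p in p_idx) {
    o_p <- cq + ap_delay_slope * p
    c_p <- 1 - ap_delay_slope * p
    open_now <- u > o_p & u < c_p
    W[open_now, p + 1L] <- amplitude * k$amp[cyc[open_now]] *
      sqrt(sin(pi * (u[open_now] - o_p[open_now]) /
                 (c_p - o_p[open_now])))
  }
  n_never <- round(never_closed_frac * n_positions)
  never_pos <- if (n_never > 0)
    seq(n_positions - n_never + 1L, n_positions) else integer(0)
  if (n_never > 0)
    W[, never_pos] <- W[, never_pos] + 1.5  # floored open: never closes
  if (spec$strategy == "contact_loss" && length(k$loss)) {
    loss_samples <- which(k$loss[cyc])
    W[loss_samples, ] <- W[loss_samples, ] + 1.5
  }
  if (spec$noise_sd > 0)
    W <- pmax(W + matrix(stats::rnorm(length(W), 0,
                                      spec$noise_sd * amplitude),
                         nrow(W)), 0)
  gaw <- gaw_series(rowSums(W), spec$fs)
  field <- displacement_field(W, spec$fs)
  # programmed instants relative to the area-minimum boundary (phase cq_c),
  # in normalized intra-cycle time: open at slope*p, close at oq_c - slope*p
  open_norm <- outer(rep(1, k$n_cycles), ap_delay_slope * p_idx)
  close_norm <- outer(k$oq, rep(1, n_positions)) -
    outer(rep(1, k$n_cycles), ap_delay_slope * p_idx)
  truth <- structure(
    list(boundaries = k$boundaries, fo_track = k$fo,
         oq_per_cycle = k$oq, amp_per_cycle = k$amp,
         loss_cycles = which(k$loss),
         transition_time = spec$transition_center,
         strategy = spec$strategy, n_cycles = k$n_cycles,
         open_norm = open_norm, close_norm = close_norm,
         never_closed_positions = never_pos,
         ap_delay_slope = ap_delay_slope),
    class = "synth_truth")
  list(gaw = gaw, field = field, truth = truth)
}

#' Synthesize a rater score matrix
#'
#' Each cell is `clip(round(true + rater_bias + noise), 1, 5)`; one
#' stimulus is presented twice (independent noise on the repeat), as in
#' the study's rating design.
#'
#' @param true_scores numeric vector of underlying stimulus severities in
#'   \[1, 5\] (one per stimulus).
#' @param n_raters number of raters.
#' @param rater_noise_sd per-cell Gaussian noise SD (score units).
#' @param rater_bias_sd per-rater additive bias SD.
#' @param duplicate_stimulus index of the stimulus presented twice, or
#'   `NULL` for none.
#' @param seed integer RNG seed.
#' @return A [rating_table]; the duplicate column (if any) is appended
#'   last and recorded in `duplicate_pair`.
#' @export
synth_ratings <- function(true_scores, n_raters = 12L,
                          rater_noise_sd = 0.5, rater_bias_sd = 0.3,
                          duplicate_stimulus = 1L, seed = 1L) {
  if (any(true_scores < 1 | true_scores > 5))
    stop("true_scores must lie in [1, 5]")
  set.seed(seed)
  n_stim <- length(true_scores)
  truth <- true_scores
  labels <- names(true_scores) %||% sprintf("stim%02d", seq_len(n_stim))
  dup_pair <- NULL
  if (!is.null(duplicate_stimulus)) {
    truth <- c(truth, true_scores[duplicate_stimulus])
    labels <- c(labels, paste0(labels[duplicate_stimulus], "_repeat"))
    dup_pair <- c(duplicate_stimulus, n_stim + 1L)
  }
  bias <- stats::rnorm(n_raters, 0, rater_bias_sd)
  raw <- outer(bias, truth, "+") +
    matrix(stats::rnorm(n_raters * length(truth), 0, rater_noise_sd),
           n_raters)
  scores <- pmax(pmin(round(raw), 5L), 1L)
  dimnames(scores) <- list(sprintf("R%02d", seq_len(n_raters)), labels)
  rating_table(scores, duplicate_pair = dup_pair)
}

#' Synthesize a full study cohort
#'
#' 10 participants x 2 pitch-glide tasks (220->440 Hz and 440->880 Hz).
#' Each phonation draws a transition severity 1..5 that selects the
#' strategy (1-3: smooth OQ ramps of growing excursion, 4: contact loss,
#' 5: abrupt break) and serves as the true perceptual score. Task-level
#' mean OQ endpoints emulate the observed cohort behaviour: the mean OQ
#' rises by about 10% across the lower and about 18% across the upper
#' glide. Rater noise is calibrated so that the 12-rater ICC is about
#' 0.85.
#'
#' @param n_participants number of participants (default 10).
#' @param seed integer RNG seed.
#' @param noise_sd per-signal measurement noise (relative SD).
#' @return A list: `phonations` (list of lists with `participant`, `task`,
#'   `spec`, `severity`, `egg`, `gaw`, `truth`), `ratings`
#'   ([rating_table] over 12 raters, one duplicated stimulus), and
#'   `stimulus_key` (data.frame mapping stimulus labels to phonations).
#' @export
synth_cohort <- function(n_participants = 10L, seed = 1L, noise_sd = 0.01) {
  set.seed(seed)
  tasks <- data.frame(task = c("lower", "upper"),
                      fo_start = c(220, 440), fo_end = c(440, 880),
                      oq_start = c(0.60, 0.60), oq_end = c(0.66, 0.708))
  phonations <- list()
  severities <- numeric(0)
  labels <- character(0)
  for (p in seq_len(n_participants)) {
    for (ti in 1:2) {
      sev <- sample(1:5, 1L)
      strategy <- c("smooth_oq_up", "smooth_oq_up", "smooth_oq_up",
                    "contact_loss", "abrupt")[sev]
      # severity widens the OQ excursion for the smooth strategies
      excursion <- (tasks$oq_end[ti] - tasks$oq_start[ti]) *
        (0.25 + 0.25 * sev) + stats::rnorm(1L, 0, 0.01)
      oq_start <- tasks$oq_start[ti] + stats::rnorm(1L, 0, 0.01)
      sub_seed <- (seed * 1000L + p * 10L + ti) %% .Machine$integer.max
      spec <- glide_spec(
        fo_start = tasks$fo_start[ti], fo_end = tasks$fo_end[ti],
        strategy = strategy,
        oq_start = oq_start, oq_end = min(0.95, oq_start + excursion),
        noise_sd = noise_sd, seed = sub_seed,
        transition_center = 0.5 + stats::runif(1L, -0.05, 0.05))
      eg <- synth_egg(spec)
      gf <- synth_gaw_field(spec)
      label <- sprintf("S%d_%s", p, tasks$task[ti])
      phonations[[label]] <- list(participant = sprintf("S%d", p),
                                  task = tasks$task[ti], spec = spec,
                                  severity = sev, egg = eg$egg,
                                  gaw = gf$gaw, truth = eg$truth)
      severities <- c(severities, sev)
      labels <- c(labels, label)
    }
  }
  names(severities) <- labels
  ratings <- synth_ratings(severities, n_raters = 12L,
                           rater_noise_sd = 1.8, rater_bias_sd = 0.4,
                           duplicate_stimulus = 1L,
                           seed = seed + 7L)
  list(phonations = phonations, ratings = ratings,
       stimulus_key = data.frame(
         stimulus = labels,
         participant = sub("_(lower|upper)$", "", labels),
         task = sub("^S\\d+_", "", labels),
         severity = severities))
}
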