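# Hand-made displacement fields with known opening/closing structure.
rect_field <- function(n_cycles = 8, period = 100, open_from = 41,
                       open_to = 80, positions = 8, fs = 20000,
                       width = 3) {
  one <- matrix(0, period, positions)
  one[open_from:open_to, ] <- width
  displacement_field(do.call(rbind, replicate(n_cycles, one,
                                              simplify = FALSE)), fs)
}

test_that("synchronous rectangular opening gives equal instants everywhere", {
  fld <- rect_field(n_cycles = 24)
  seg <- manual_segmentation(seq(1, 2401, by = 100), 20000, 2400)
  inst <- local_open_close_instants(fld, seg, open_threshold = 0.5)
  expect_true(all(abs(inst$open - 40) <= 1))
  expect_true(all(abs(inst$close - 80) <= 1))
  expect_false(any(inst$never_closed))
  ws <- manual_window_set(0.06, 0, 0.12, window_len = 0.01)
  cps <- normalize_and_average(inst, ws)
  cp <- cps[["window_0"]]
  m <- contour_summary_metrics(cp)
  expect_equal(m$ap_delay_slope, 0, tolerance = 1e-9)
  expect_equal(m$mean_open_duration, 0.40, tolerance = 0.011)
  expect_equal(m$never_closed_frac, 0)
})

test_that("a permanently closed anterior third yields missing pairs there", {
  fld <- rect_field()
  fld$width[, 1:3] <- 0   # anterior positions never open
  seg <- manual_segmentation(seq(1, 801, by = 100), 20000, 800)
  inst <- local_open_close_instants(fld, seg)
  expect_true(all(is.na(inst$open[, 1:3])))
  expect_true(all(!is.na(inst$open[, 4:8])))
})

test_that("positions open across the whole cycle get (0, 1) and a flag", {
  fld <- rect_field()
  fld$width[, 8] <- 5   # posterior gap: never closes
  seg <- manual_segmentation(seq(1, 801, by = 100), 20000, 800)
  inst <- local_open_close_instants(fld, seg)
  expect_true(all(inst$never_closed[, 8]))
  expect_true(all(inst$open[, 8] == 0))
  expect_equal(inst$close[, 8], inst$cycle_dur)
})

test_that("open precedes close at every defined position in every window", {
  spec <- glide_spec(strategy = "contact_loss", noise_sd = 0.01, seed = 5)
  gf <- synth_gaw_field(spec, ap_delay_slope = 0.003)
  seg <- gaw_cycles(gf$gaw)
  inst <- local_open_close_instants(gf$field, seg)
  ok <- !is.na(inst$open)
  expect_true(all(inst$open[ok] <= inst$close[ok]))
  cps <- normalize_and_average(inst, manual_window_set(0.5, 0, 1))
  for (cp in cps) {
    if (is.null(cp)) next
    def <- !is.na(cp$open)
    expect_true(all(cp$open[def] <= cp$close[def]))
    expect_true(all(cp$open[def] >= 0 & cp$close[def] <= 1 + 1e-9))
  }
})

test_that("the programmed zipper delay slope is recovered per window", {
  spec <- glide_spec(strategy = "smooth_oq_up", noise_sd = 0.01, seed = 2)
  gf <- synth_gaw_field(spec, ap_delay_slope = 0.004)
  seg <- gaw_cycles(gf$gaw)
  inst <- local_open_close_instants(gf$field, seg)
  cps <- normalize_and_average(inst, manual_window_set(0.5, 0, 1))
  for (i in c(1, 6, 11)) {
    m <- contour_summary_metrics(cps[[i]])
    expect_lt(abs(m$ap_delay_slope - 0.004) / 0.004, 0.10)
  }
})

test_that("doubling the frame rate changes contours by under one frame", {
  contour_of <- function(fs) {
    spec <- glide_spec(strategy = "stereotypical", fs = fs, noise_sd = 0,
                       seed = 3)
    gf <- synth_gaw_field(spec, ap_delay_slope = 0.003)
    seg <- gaw_cycles(gf$gaw)
    inst <- local_open_close_instants(gf$field, seg)
    cps <- normalize_and_average(inst, manual_window_set(0.5, 0, 1))
    cps[["window_0"]]
  }
  c20 <- contour_of(20000)
  c40 <- contour_of(40000)
  # one frame at 20 kHz is ~0.007 of a 330 Hz cycle
  frame_norm <- 330 / 20000
  expect_lt(max(abs(c20$open - c40$open), na.rm = TRUE), frame_norm)
  expect_lt(max(abs(c20$close - c40$close), na.rm = TRUE), frame_norm)
})

test_that("contour open-phase duration agrees with the GAW open quotient", {
  spec <- glide_spec(strategy = "stereotypical", oq_start = 0.6,
                     noise_sd = 0.01, seed = 7)
  gf <- synth_gaw_field(spec, ap_delay_slope = 0.002)
  seg <- gaw_cycles(gf$gaw)
  ws <- manual_window_set(0.5, 0, 1)
  woq <- window_oq(open_quotient(gf$gaw, seg), ws)
  cps <- normalize_and_average(local_open_close_instants(gf$field, seg), ws)
  for (i in c(1, 6, 11)) {
    m <- contour_summary_metrics(cps[[i]])
    oq_w <- woq$oq_per_window$oq_mean[i]
    if (is.na(oq_w) || is.na(m$mean_open_duration)) next
    expect_lt(abs(m$mean_open_duration - oq_w), 0.05)
  }
})
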